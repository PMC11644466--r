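#' Per-group trait summaries
#'
#' Aggregates per-plant trait records into mean, sample SD (n - 1
#' denominator) and n per group, in the classic "mean +/- SD per cultivar
#' x system" layout. Groups with a single record report `NA` for the SD
#' rather than zero. Rows are ordered deterministically by group label.
#'
#' @param records data frame of per-plant traits (one row per plant).
#' @param group_by character vector of grouping columns.
#' @param traits character vector of numeric trait columns to summarize.
#' @return A data frame with columns `group_by..., trait, n, mean, sd`.
#' @examples
#' df <- data.frame(archetype = "a", system = "2D", fd = c(1, 2, 3))
#' summarize_traits(df, c("archetype", "system"), "fd")  # mean 2, sd 1
#' @export
summarize_traits <- function(records,
                             group_by = c("archetype", "system"),
                             traits = c("total_root_length_cm", "fd")) {
  stopifnot(is.data.frame(records), nrow(records) > 0,
            all(group_by %in% names(records)),
            all(traits %in% names(records)))
  key <- interaction(records[group_by], drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(levels(key), function(lv) {
    sub <- records[key == lv, , drop = FALSE]
    do.call(rbind, lapply(traits, function(tr) {
      v <- sub[[tr]]
      cbind(sub[1, group_by, drop = FALSE],
            data.frame(trait = tr, n = length(v), mean = mean(v),
                       sd = if (length(v) >= 2) sd(v) else NA_real_))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Ratio between two group means
#'
#' The "x times longer" contrast arithmetic used when comparing group
#' means (e.g. mean total root lengths of 530.4 vs 21.2 cm give a 25-fold
#' contrast after rounding).
#'
#' @param mean_a,mean_b group means; `mean_b` must be positive.
#' @return `mean_a / mean_b`.
#' @examples
#' round(contrast_ratio(530.4, 21.2))  # 25
#' @export
contrast_ratio <- function(mean_a, mean_b) {
  if (mean_b <= 0) stop("contrast_ratio requires a positive denominator")
  mean_a / mean_b
}

#' Default end-to-end pipeline configuration
#'
#' Study conditions for [run_pipeline()]: both built-in archetypes, three
#' replicate plants per archetype per phenotyping system (rhizobox/2-D
#' photography at 0.05 cm/px, pot/3-D CT surrogate on a 128^3 grid), and
#' the CT contrast/noise and segmentation settings.
#'
#' @return A nested list; edit fields or load overrides with
#'   [read_pipeline_config()].
#' @export
default_pipeline_config <- function() {
  list(schema_version = 1,
       base_seed = 101,
       n_per_group = 3,
       archetypes = list(casino_like = casino_archetype(),
                         woodstock_like = woodstock_archetype()),
       rhizobox = list(height_cm = 40.6, width_cm = 25.4, depth_cm = 1.5),
       pot = list(diameter_cm = 15, height_cm = 13),
       raster2d = list(pitch_cm_per_px = 0.05, thickness_px = 3),
       grid3d = list(size = 128, radius_voxels = 2),
       ct = list(root_intensity = 0.65, medium_intensity = 0.35,
                 noise_sd = 0.01),
       segmentation = list(method = "otsu", min_component_voxels = 27))
}

#' Read a pipeline configuration file
#'
#' YAML key-value file; entries override the defaults of
#' [default_pipeline_config()]. Archetype entries are lists of
#' [archetype_params()] arguments.
#'
#' @param path YAML file path.
#' @return A configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config()
  for (nm in names(user)) {
    if (nm == "archetypes") {
      cfg$archetypes <- lapply(user$archetypes,
                               function(a) do.call(archetype_params, a))
      names(cfg$archetypes) <- names(user$archetypes)
    } else if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
      cfg[[nm]][names(user[[nm]])] <- user[[nm]]
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  cfg
}

#' Run the full 2-D vs 3-D phenotyping pipeline
#'
#' For every archetype and replicate: grow a root system in a rhizobox,
#' photograph it (binary rasterization), skeletonize and measure (total
#' root length, box-counting FD); independently grow a system in a pot,
#' voxelize it, simulate a CT volume, segment it, skeletonize in 3-D and
#' measure (length, cube-counting FD). Per-plant seeds are derived
#' deterministically from `config$base_seed`, so a rerun under the same
#' configuration reproduces the output files byte for byte.
#'
#' @param config configuration list, see [default_pipeline_config()].
#' @param out_dir output directory; created if missing. Writes
#'   `traits.csv`, `summary.csv` and `pipeline_log.txt`.
#' @return Invisibly, a list with `traits` and `summary` data frames.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  stopifnot(is.list(config), length(config$archetypes) > 0,
            config$n_per_group >= 1)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- c(sprintf("rsatraits pipeline, schema %s",
                         config$schema_version),
                 sprintf("base_seed: %d", config$base_seed))
  box <- do.call(rhizobox_domain, config$rhizobox)
  pot <- do.call(pot_domain, config$pot)
  grid <- pot_grid(pot, config$grid3d$size)
  sow_idx <- c(floor(grid$nx / 2) + 1, floor(grid$ny / 2) + 1, 1)

  rows <- list()
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", what,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  ai <- 0
  for (arch_name in names(config$archetypes)) {
    ai <- ai + 1
    params <- config$archetypes[[arch_name]]
    for (rep in seq_len(config$n_per_group)) {
      seed2d <- config$base_seed + 1000L * ai + rep
      seed3d <- config$base_seed + 1000L * ai + 500L + rep
      log_lines <- c(log_lines,
                     sprintf("%s rep %d: seed2d %d seed3d %d",
                             arch_name, rep, seed2d, seed3d))

      sys2 <- stage("generate 2D",
                    generate_root_system(params, box, seed2d))
      img <- stage("rasterize",
                   rasterize_2d(sys2, config$raster2d$pitch_cm_per_px,
                                config$raster2d$thickness_px))
      sk2 <- stage("skeletonize 2D", skeletonize_2d(img))
      fd2 <- stage("fd boxcount", fd_boxcount(sk2))
      rows[[length(rows) + 1]] <- data.frame(
        plant_id = sprintf("%s_2D_%d", arch_name, rep),
        archetype = arch_name, system = "2D", seed = seed2d,
        ground_truth_length_cm = ground_truth_length(sys2),
        total_root_length_cm = total_root_length(sk2),
        fd = fd2$fd, r_squared = fd2$r_squared,
        n_scales = length(fd2$sizes))

      sys3 <- stage("generate 3D",
                    generate_root_system(params, pot, seed3d))
      mask <- stage("voxelize",
                    voxelize_3d(sys3, grid, config$grid3d$radius_voxels))
      vol <- stage("simulate CT",
                   simulate_ct(mask, config$ct$root_intensity,
                               config$ct$medium_intensity,
                               config$ct$noise_sd, seed = seed3d + 1L))
      seg <- stage("segment",
                   segment_volume(vol, method = config$segmentation$method,
                                  sowing_index = sow_idx,
                                  min_component_voxels =
                                    config$segmentation$min_component_voxels))
      sk3 <- stage("skeletonize 3D", skeletonize_3d(seg))
      fd3 <- stage("fd cubecount", fd_cubecount(sk3))
      rows[[length(rows) + 1]] <- data.frame(
        plant_id = sprintf("%s_3D_%d", arch_name, rep),
        archetype = arch_name, system = "3D", seed = seed3d,
        ground_truth_length_cm = ground_truth_length(sys3),
        total_root_length_cm = total_root_length(sk3),
        fd = fd3$fd, r_squared = fd3$r_squared,
        n_scales = length(fd3$sizes))
    }
  }
  traits <- do.call(rbind, rows)
  summary <- summarize_traits(traits)
  write.csv(traits, file.path(out_dir, "traits.csv"), row.names = FALSE)
  write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  writeLines(log_lines, file.path(out_dir, "pipeline_log.txt"))
  invisible(list(traits = traits, summary = summary))
}
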