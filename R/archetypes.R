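#' Root-system archetype parameters
#'
#' Parameter set driving the stochastic growth model in
#' [generate_root_system()]. Lateral (secondary) root lengths are drawn from
#' a log-normal distribution parameterized on the natural scale by
#' `lateral_length_mean_cm` / `lateral_length_sd_cm`; tertiary roots, when a
#' secondary bears them (probability `tertiary_prob`), reuse the same
#' density rule with lengths scaled by `tertiary_length_scale`.
#'
#' @param taproot_length_cm target arc length of the taproot, cm.
#' @param step_cm growth-step length, cm.
#' @param lateral_density_per_cm expected number of laterals per cm of
#'   parent root.
#' @param lateral_length_mean_cm,lateral_length_sd_cm natural-scale mean and
#'   SD of lateral length, cm.
#' @param tertiary_prob probability in `[0, 1]` that a secondary root bears
#'   tertiaries.
#' @param tertiary_length_scale multiplier applied to lateral lengths for
#'   tertiary roots.
#' @param branch_angle_mean_deg,branch_angle_sd_deg insertion angle of a
#'   lateral relative to its parent's local direction, degrees.
#' @param gravitropism downward bias of the growth direction per step, in
#'   `[0, 1]` (0 = none, 1 = strictly downward aim).
#' @param step_deflection_sd_deg SD of the Gaussian angular wobble applied
#'   to each growth step, degrees.
#' @param name label carried into generated systems.
#' @return An object of class `archetype_params`.
#' @seealso [casino_archetype()], [woodstock_archetype()]
#' @export
archetype_params <- function(taproot_length_cm,
                             step_cm = 0.25,
                             lateral_density_per_cm = 0,
                             lateral_length_mean_cm = 0,
                             lateral_length_sd_cm = 0,
                             tertiary_prob = 0,
                             tertiary_length_scale = 0.3,
                             branch_angle_mean_deg = 60,
                             branch_angle_sd_deg = 15,
                             gravitropism = 0.3,
                             step_deflection_sd_deg = 6,
                             name = "custom") {
  stopifnot(taproot_length_cm > 0, step_cm > 0,
            lateral_density_per_cm >= 0,
            lateral_length_mean_cm >= 0, lateral_length_sd_cm >= 0,
            tertiary_prob >= 0, tertiary_prob <= 1,
            tertiary_length_scale >= 0,
            gravitropism >= 0, gravitropism <= 1,
            step_deflection_sd_deg >= 0)
  structure(list(taproot_length_cm = taproot_length_cm,
                 step_cm = step_cm,
                 lateral_density_per_cm = lateral_density_per_cm,
                 lateral_length_mean_cm = lateral_length_mean_cm,
                 lateral_length_sd_cm = lateral_length_sd_cm,
                 tertiary_prob = tertiary_prob,
                 tertiary_length_scale = tertiary_length_scale,
                 branch_angle_mean_deg = branch_angle_mean_deg,
                 branch_angle_sd_deg = branch_angle_sd_deg,
                 gravitropism = gravitropism,
                 step_deflection_sd_deg = step_deflection_sd_deg,
                 name = name),
            class = "archetype_params")
}

#' Built-in cultivar-like archetypes
#'
#' Two fixed parameter sets spanning the classic contrast seen among soybean
#' cultivars at the V1 stage: a taproot-dominant architecture (a highly
#' dominant primary root, few and short secondary roots, almost no
#' tertiaries) and a highly branched one (many longer secondaries plus
#' tertiary roots). The constants are model choices tuned to that
#' qualitative contrast, not measurements.
#'
#' @return An `archetype_params` object.
#' @examples
#' casino_archetype()$tertiary_prob
#' woodstock_archetype()$lateral_density_per_cm
#' @export
casino_archetype <- function() {
  archetype_params(taproot_length_cm = 28,
                   step_cm = 0.25,
                   lateral_density_per_cm = 0.25,
                   lateral_length_mean_cm = 1.2,
                   lateral_length_sd_cm = 0.6,
                   tertiary_prob = 0.02,
                   branch_angle_mean_deg = 65,
                   branch_angle_sd_deg = 15,
                   gravitropism = 0.4,
                   step_deflection_sd_deg = 6,
                   name = "casino_like")
}

#' @rdname casino_archetype
#' @export
woodstock_archetype <- function() {
  archetype_params(taproot_length_cm = 35,
                   step_cm = 0.25,
                   lateral_density_per_cm = 1.8,
                   lateral_length_mean_cm = 4,
                   lateral_length_sd_cm = 2,
                   tertiary_prob = 0.6,
                   branch_angle_mean_deg = 60,
                   branch_angle_sd_deg = 15,
                   gravitropism = 0.25,
                   step_deflection_sd_deg = 8,
                   name = "woodstock_like")
}

#' @export
print.archetype_params <- function(x, ...) {
  cat(sprintf("archetype '%s': taproot %.1f cm, %.2f laterals/cm (mean %.1f cm), tertiary prob %.2f\n",
              x$name, x$taproot_length_cm, x$lateral_density_per_cm,
              x$lateral_length_mean_cm, x$tertiary_prob))
  invisible(x)
}

#' Read archetype parameters from a key-value configuration file
#'
#' The file is YAML-style `key: value` pairs with any subset of the
#' [archetype_params()] arguments; unspecified fields keep their defaults.
#'
#' @param path file path.
#' @return An `archetype_params` object.
#' @export
read_archetype_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(archetype_params))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown archetype fields: ", paste(bad, collapse = ", "))
  do.call(archetype_params, vals)
}
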