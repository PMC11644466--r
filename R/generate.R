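normalize3 <- function(v) {
  len <- sqrt(sum(v^2))
  if (!is.finite(len) || len < 1e-12) return(NULL)
  v / len
}

# Orthonormal basis perpendicular to unit vector d.
perp_basis <- function(d) {
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- normalize3(ref - sum(ref * d) * d)
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# Rotate unit vector d by angle_rad toward azimuth phi in its normal plane.
tilt_direction <- function(d, angle_rad, phi) {
  b <- perp_basis(d)
  normalize3(cos(angle_rad) * d +
             sin(angle_rad) * (cos(phi) * b$e1 + sin(phi) * b$e2))
}

perturb_direction <- function(d, sd_deg) {
  if (sd_deg <= 0) return(d)
  theta <- rnorm(1, 0, sd_deg * pi / 180)
  phi <- runif(1, 0, 2 * pi)
  tilt_direction(d, theta, phi)
}

polyline_length <- function(points) {
  if (nrow(points) < 2) return(0)
  d <- diff(points)
  sum(sqrt(rowSums(d^2)))
}

# Step-growth of one root axis: direction = previous direction blended with
# the downward unit vector by the gravitropism weight, plus Gaussian wobble.
# Steps leaving the domain are clipped at the boundary and the next step is
# re-aimed inward (tangential component plus inward normal, no reflection).
grow_axis <- function(p0, dir0, budget_cm, params, domain) {
  dir <- normalize3(dir0)
  if (is.null(dir)) dir <- c(0, 0, 1)
  pts <- vector("list", ceiling(budget_cm / params$step_cm) + 2)
  pts[[1]] <- p0
  npts <- 1
  p <- p0
  remaining <- budget_cm
  stuck <- 0
  down <- c(0, 0, 1)
  g <- params$gravitropism
  maxit <- 6 * ceiling(budget_cm / params$step_cm) + 60
  it <- 0
  while (remaining > 1e-8 && it < maxit) {
    it <- it + 1
    step <- min(params$step_cm, remaining)
    d <- normalize3((1 - g) * dir + g * down)
    if (is.null(d)) d <- down
    d <- perturb_direction(d, params$step_deflection_sd_deg)
    target <- p + step * d
    t <- clip_fraction(domain, p, target)
    if (t >= 1 - 1e-9) {
      p <- target
      npts <- npts + 1; pts[[npts]] <- p
      remaining <- remaining - step
      dir <- d
      stuck <- 0
    } else {
      nin <- inward_normal(domain, p + t * step * d)
      nout <- -nin
      dtan <- d - sum(d * nout) * nout
      if (t > 1e-3) {
        p <- p + (t * step * (1 - 1e-9)) * d
        npts <- npts + 1; pts[[npts]] <- p
        remaining <- remaining - t * step
        stuck <- 0
      } else {
        stuck <- stuck + 1
        if (stuck >= 4) {            # wedged in a corner: forfeit this step
          remaining <- remaining - step
          stuck <- 0
        }
      }
      dir <- normalize3(dtan + 0.7 * nin)
      if (is.null(dir)) dir <- if (sum(nin^2) > 0) nin else down
    }
  }
  do.call(rbind, pts[seq_len(npts)])
}

# Interpolate position and unit tangent at arc-length s along a polyline.
interp_polyline <- function(points, s) {
  d <- diff(points)
  seg_len <- sqrt(rowSums(d^2))
  cum <- c(0, cumsum(seg_len))
  s <- min(max(s, 0), cum[length(cum)])
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- min(i, nrow(points) - 1)
  f <- if (seg_len[i] > 0) (s - cum[i]) / seg_len[i] else 0
  pos <- points[i, ] + f * d[i, ]
  tan <- normalize3(d[i, ])
  if (is.null(tan)) tan <- c(0, 0, 1)
  list(pos = pos, tangent = tan)
}

rlnorm_natural <- function(n, mean_nat, sd_nat) {
  if (mean_nat <= 0) return(rep(0, n))
  if (sd_nat <= 0) return(rep(mean_nat, n))
  sdlog2 <- log(1 + (sd_nat / mean_nat)^2)
  rlnorm(n, meanlog = log(mean_nat) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Generate a stochastic root system
#'
#' Grows a taproot-dominant or branched root system inside a confinement
#' domain. The taproot grows stepwise downward from the sowing point with a
#' gravitropism-weighted direction and Gaussian angular wobble; laterals
#' spawn as a Poisson process along their parent (expected
#' `lateral_density_per_cm` per cm, attachment positions uniform along arc
#' length) with log-normal lengths and Gaussian insertion angles; a
#' secondary bears tertiaries with probability `tertiary_prob`. All
#' geometry is clipped to the domain; growth steps hitting a wall are
#' re-aimed inward. The result is bitwise reproducible for a fixed
#' `(params, domain, seed)` triple.
#'
#' @param params an [archetype_params()] object.
#' @param domain an `rsa_domain` from [rhizobox_domain()] or [pot_domain()].
#' @param seed integer seed for the generator's private RNG stream.
#' @return An object of class `root_system`: a list of root segments (each
#'   with `id`, `parent_id`, `order`, and a matrix of xyz points in cm),
#'   plus the domain, seed and archetype name.
#' @examples
#' sys <- generate_root_system(casino_archetype(), rhizobox_domain(), seed = 1)
#' ground_truth_length(sys)
#' @export
generate_root_system <- function(params, domain, seed) {
  stopifnot(inherits(params, "archetype_params"),
            inherits(domain, "rsa_domain"))
  if (params$step_cm <= 0) stop("step_cm must be positive")
  seed <- as.integer(seed)

  withr::with_seed(seed, {
    segments <- list()
    sow <- c(0, 0, 0)
    tap_pts <- grow_axis(sow, c(0, 0, 1), params$taproot_length_cm,
                         params, domain)
    segments[[1]] <- list(id = 1L, parent_id = NA_integer_, order = 0L,
                          points = tap_pts)
    next_id <- 2L

    spawn_laterals <- function(parent, length_scale) {
      out <- list()
      L <- polyline_length(parent$points)
      lambda <- params$lateral_density_per_cm * L
      if (lambda <= 0) return(out)
      n <- rpois(1, lambda)
      if (n == 0) return(out)
      at <- sort(runif(n, 0, L))
      lens <- rlnorm_natural(n, params$lateral_length_mean_cm * length_scale,
                             params$lateral_length_sd_cm * length_scale)
      for (i in seq_len(n)) {
        if (lens[i] < 2e-3) next
        loc <- interp_polyline(parent$points, at[i])
        alpha <- rnorm(1, params$branch_angle_mean_deg,
                       params$branch_angle_sd_deg) * pi / 180
        phi <- runif(1, 0, 2 * pi)
        d0 <- tilt_direction(loc$tangent, alpha, phi)
        if (is.null(d0)) next
        pts <- grow_axis(loc$pos, d0, lens[i], params, domain)
        if (is.null(pts) || nrow(pts) < 2) next
        out[[length(out) + 1]] <- list(parent_id = parent$id,
                                       order = parent$order + 1L,
                                       points = pts)
      }
      out
    }

    secondaries <- spawn_laterals(segments[[1]], 1)
    for (s in secondaries) {
      s$id <- next_id; next_id <- next_id + 1L
      segments[[length(segments) + 1]] <- s[c("id", "parent_id", "order", "points")]
    }
    sec_ids <- which(vapply(segments, function(s) s$order == 1L, logical(1)))
    for (k in sec_ids) {
      if (runif(1) >= params$tertiary_prob) next
      tert <- spawn_laterals(segments[[k]], params$tertiary_length_scale)
      for (s in tert) {
        s$id <- next_id; next_id <- next_id + 1L
        segments[[length(segments) + 1]] <- s[c("id", "parent_id", "order", "points")]
      }
    }

    structure(list(segments = segments, domain = domain, seed = seed,
                   archetype_name = params$name),
              class = "root_system")
  })
}

#' @export
print.root_system <- function(x, ...) {
  orders <- vapply(x$segments, `[[`, integer(1), "order")
  cat(sprintf("root system '%s' (seed %d): %d segments (%d primary, %d secondary, %d tertiary), total length %.1f cm\n",
              x$archetype_name, x$seed, length(x$segments),
              sum(orders == 0), sum(orders == 1), sum(orders == 2),
              ground_truth_length(x)))
  invisible(x)
}

validate_root_system <- function(system) {
  if (!inherits(system, "root_system") || length(system$segments) == 0)
    stop("not a valid root_system: no segments")
  orders <- vapply(system$segments, `[[`, integer(1), "order")
  if (sum(orders == 0) != 1)
    stop("a root_system must have exactly one order-0 (taproot) segment")
  invisible(system)
}

#' Exact total root length of a generated system
#'
#' Sums the Euclidean arc length of every segment polyline. This is the
#' geometric ground truth against which raster-based length estimates are
#' benchmarked.
#'
#' @param system a `root_system`.
#' @return Total length in cm.
#' @export
ground_truth_length <- function(system) {
  validate_root_system(system)
  sum(vapply(system$segments, function(s) polyline_length(s$points),
             numeric(1)))
}

#' Serialize a root system to CSV (plus sidecar metadata)
#'
#' One row per polyline point: `segment_id, parent_id, order, x_cm, y_cm,
#' z_cm`. Seed, archetype and domain go to a YAML sidecar at
#' `<path>.meta.yaml`.
#'
#' @param system a `root_system`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_root_system <- function(system, path) {
  validate_root_system(system)
  df <- do.call(rbind, lapply(system$segments, function(s) {
    data.frame(segment_id = s$id, parent_id = s$parent_id, order = s$order,
               x_cm = s$points[, 1], y_cm = s$points[, 2],
               z_cm = s$points[, 3])
  }))
  write.csv(df, path, row.names = FALSE)
  meta <- list(seed = system$seed, archetype = system$archetype_name,
               domain = unclass(system$domain))
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_root_system
#' @export
read_root_system <- function(path) {
  df <- read.csv(path)
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  dom <- if (meta$domain$shape == "rhizobox")
    rhizobox_domain(meta$domain$height_cm, meta$domain$width_cm,
                    meta$domain$depth_cm)
  else
    pot_domain(meta$domain$diameter_cm, meta$domain$height_cm)
  segs <- lapply(split(df, df$segment_id), function(d) {
    list(id = d$segment_id[1], parent_id = d$parent_id[1],
         order = as.integer(d$order[1]),
         points = unname(as.matrix(d[, c("x_cm", "y_cm", "z_cm")])))
  })
  segs <- segs[order(vapply(segs, `[[`, numeric(1), "id"))]
  names(segs) <- NULL
  structure(list(segments = segs, domain = dom, seed = as.integer(meta$seed),
                 archetype_name = meta$archetype),
            class = "root_system")
}
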