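#' Growth domains
#'
#' Containers that confine simulated root growth. The coordinate system has
#' its origin at the sowing point (top center of the container), x and y
#' horizontal and z pointing downward, all in cm. A rhizobox is a thin
#' quasi-planar box (`depth_cm` is the thin axis, y); a pot is an upright
#' cylinder.
#'
#' @param height_cm vertical extent (z), cm.
#' @param width_cm lateral extent (x) of the rhizobox, cm.
#' @param depth_cm thin-axis extent (y) of the rhizobox, cm; must be much
#'   smaller than `width_cm`.
#' @param diameter_cm top diameter of the pot, cm.
#' @return An object of class `rsa_domain`.
#' @examples
#' rhizobox_domain()
#' pot_domain()
#' @export
rhizobox_domain <- function(height_cm = 40.6, width_cm = 25.4, depth_cm = 1.5) {
  stopifnot(height_cm > 0, width_cm > 0, depth_cm > 0)
  if (depth_cm >= width_cm / 2)
    stop("a rhizobox must be quasi-planar: depth_cm much smaller than width_cm")
  structure(list(shape = "rhizobox", height_cm = height_cm,
                 width_cm = width_cm, depth_cm = depth_cm),
            class = "rsa_domain")
}

#' @rdname rhizobox_domain
#' @export
pot_domain <- function(diameter_cm = 15, height_cm = 13) {
  stopifnot(diameter_cm > 0, height_cm > 0)
  structure(list(shape = "pot", diameter_cm = diameter_cm,
                 height_cm = height_cm),
            class = "rsa_domain")
}

#' @export
print.rsa_domain <- function(x, ...) {
  if (x$shape == "rhizobox")
    cat(sprintf("rhizobox domain: %.1f H x %.1f L x %.1f W cm\n",
                x$height_cm, x$width_cm, x$depth_cm))
  else
    cat(sprintf("pot domain: %.1f cm diameter x %.1f cm height\n",
                x$diameter_cm, x$height_cm))
  invisible(x)
}

#' Test whether points lie inside a growth domain
#'
#' @param domain an `rsa_domain`.
#' @param points numeric matrix with columns x, y, z (cm), or a length-3
#'   vector.
#' @param tol boundary tolerance in cm.
#' @return Logical vector, one entry per point.
#' @export
domain_contains <- function(domain, points, tol = 1e-6) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  x <- points[, 1]; y <- points[, 2]; z <- points[, 3]
  if (domain$shape == "rhizobox") {
    abs(x) <= domain$width_cm / 2 + tol &
      abs(y) <= domain$depth_cm / 2 + tol &
      z >= -tol & z <= domain$height_cm + tol
  } else {
    r <- domain$diameter_cm / 2
    x^2 + y^2 <= r^2 + tol & z >= -tol & z <= domain$height_cm + tol
  }
}

# Largest t in [0, 1] with p + t (q - p) inside the domain, assuming p inside.
clip_fraction <- function(domain, p, q) {
  v <- q - p
  t <- 1
  axis_clip <- function(pi, vi, lo, hi) {
    if (vi > 0 && pi + vi > hi) return((hi - pi) / vi)
    if (vi < 0 && pi + vi < lo) return((lo - pi) / vi)
    1
  }
  if (domain$shape == "rhizobox") {
    t <- min(t,
             axis_clip(p[1], v[1], -domain$width_cm / 2, domain$width_cm / 2),
             axis_clip(p[2], v[2], -domain$depth_cm / 2, domain$depth_cm / 2),
             axis_clip(p[3], v[3], 0, domain$height_cm))
  } else {
    t <- min(t, axis_clip(p[3], v[3], 0, domain$height_cm))
    r2 <- (domain$diameter_cm / 2)^2
    a <- v[1]^2 + v[2]^2
    if (a > 1e-12) {
      b <- 2 * (p[1] * v[1] + p[2] * v[2])
      cc <- p[1]^2 + p[2]^2 - r2
      disc <- b^2 - 4 * a * cc
      if (disc >= 0) {
        texit <- (-b + sqrt(disc)) / (2 * a)
        if (texit >= 0) t <- min(t, texit)
      }
    }
  }
  max(0, min(1, t))
}

# Unit vector pointing from a boundary point back into the domain interior;
# zero vector when the point is interior.
inward_normal <- function(domain, p, tol = 1e-6) {
  n <- c(0, 0, 0)
  if (domain$shape == "rhizobox") {
    if (p[1] >= domain$width_cm / 2 - tol) n[1] <- n[1] - 1
    if (p[1] <= -domain$width_cm / 2 + tol) n[1] <- n[1] + 1
    if (p[2] >= domain$depth_cm / 2 - tol) n[2] <- n[2] - 1
    if (p[2] <= -domain$depth_cm / 2 + tol) n[2] <- n[2] + 1
  } else {
    r <- domain$diameter_cm / 2
    rad <- sqrt(p[1]^2 + p[2]^2)
    if (rad >= r - tol && rad > 0) {
      n[1] <- -p[1] / rad; n[2] <- -p[2] / rad
    }
  }
  if (p[3] >= domain$height_cm - tol) n[3] <- -1
  if (p[3] <= tol) n[3] <- 1
  len <- sqrt(sum(n^2))
  if (len > 0) n / len else n
}
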