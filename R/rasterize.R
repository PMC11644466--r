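#' Voxel grid geometry
#'
#' Dimensions and physical voxel pitch of a 3-D raster. The default
#' arguments reproduce the geometry of a clinical CT root scan: 500 slices
#' of 512 x 512 pixels at 0.21 x 0.21 x 0.2 mm per voxel.
#'
#' @param nx,ny,nz grid dimensions (x, y, z = slice axis).
#' @param voxel_x_mm,voxel_y_mm,voxel_z_mm physical voxel edge lengths, mm.
#' @return An object of class `voxel_grid`.
#' @examples
#' grid_volume_dm3(voxel_grid())  # 1.156 dm^3
#' @export
voxel_grid <- function(nx = 512, ny = 512, nz = 500,
                       voxel_x_mm = 0.21, voxel_y_mm = 0.21,
                       voxel_z_mm = 0.2) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1,
            voxel_x_mm > 0, voxel_y_mm > 0, voxel_z_mm > 0)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 nz = as.integer(nz),
                 voxel_x_mm = voxel_x_mm, voxel_y_mm = voxel_y_mm,
                 voxel_z_mm = voxel_z_mm),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel grid %d x %d x %d, voxel %.3g x %.3g x %.3g mm (%.3f dm^3)\n",
              x$nx, x$ny, x$nz, x$voxel_x_mm, x$voxel_y_mm, x$voxel_z_mm,
              grid_volume_dm3(x)))
  invisible(x)
}

#' A cubic voxel grid covering a pot domain
#'
#' Convenience constructor: an `n` x `n` x `n` grid whose physical extent
#' matches the pot diameter laterally and the pot height axially.
#'
#' @param domain a pot `rsa_domain`.
#' @param n grid size per axis.
#' @return A `voxel_grid`.
#' @export
pot_grid <- function(domain, n = 128) {
  stopifnot(domain$shape == "pot")
  voxel_grid(n, n, n,
             voxel_x_mm = domain$diameter_cm * 10 / n,
             voxel_y_mm = domain$diameter_cm * 10 / n,
             voxel_z_mm = domain$height_cm * 10 / n)
}

#' Physical volume of a voxel grid
#'
#' @param grid a `voxel_grid`.
#' @return Scanned volume in dm^3.
#' @export
grid_volume_dm3 <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  grid$nx * grid$ny * grid$nz *
    grid$voxel_x_mm * grid$voxel_y_mm * grid$voxel_z_mm / 1e6
}

#' Raster containers
#'
#' Constructors for the raster representations flowing through the
#' pipeline: a 2-D binary image (photograph stand-in; rows run with depth,
#' columns with lateral position), a 3-D binary mask, and a 3-D grayscale
#' volume (CT stand-in), each carrying physical pitch metadata. Useful for
#' wrapping user-supplied imagery; the simulation side produces them via
#' [rasterize_2d()], [voxelize_3d()] and [simulate_ct()].
#'
#' @param pixels logical matrix of foreground pixels.
#' @param pitch_cm_per_px pixel pitch, cm.
#' @param mask logical 3-D array.
#' @param intensities numeric 3-D array.
#' @param grid a [voxel_grid()] matching the array dimensions.
#' @return An object of class `binary_image_2d`, `binary_volume_3d` or
#'   `gray_volume_3d`.
#' @export
binary_image_2d <- function(pixels, pitch_cm_per_px) {
  stopifnot(is.matrix(pixels), is.logical(pixels), pitch_cm_per_px > 0,
            max(dim(pixels)) >= 2)
  structure(list(pixels = pixels, pitch_cm_per_px = pitch_cm_per_px),
            class = "binary_image_2d")
}

#' @export
print.binary_image_2d <- function(x, ...) {
  cat(sprintf("binary 2-D image %d x %d px at %.4g cm/px, %d foreground px\n",
              nrow(x$pixels), ncol(x$pixels), x$pitch_cm_per_px,
              sum(x$pixels)))
  invisible(x)
}

#' @rdname binary_image_2d
#' @export
binary_volume_3d <- function(mask, grid) {
  stopifnot(is.logical(mask),
            identical(dim(mask), c(grid$nx, grid$ny, grid$nz)))
  structure(list(mask = mask, grid = grid), class = "binary_volume_3d")
}

#' @export
print.binary_volume_3d <- function(x, ...) {
  cat(sprintf("binary volume %d x %d x %d, %d foreground voxels\n",
              x$grid$nx, x$grid$ny, x$grid$nz, sum(x$mask)))
  invisible(x)
}

#' @rdname binary_image_2d
#' @export
gray_volume_3d <- function(intensities, grid) {
  stopifnot(is.numeric(intensities),
            identical(dim(intensities), c(grid$nx, grid$ny, grid$nz)))
  structure(list(intensities = intensities, grid = grid),
            class = "gray_volume_3d")
}

#' @export
print.gray_volume_3d <- function(x, ...) {
  cat(sprintf("grayscale volume %d x %d x %d, intensity range [%.3g, %.3g]\n",
              x$grid$nx, x$grid$ny, x$grid$nz,
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

# Dilate a logical matrix/array by a set of integer offsets (rows = offsets).
dilate_offsets <- function(raster, offsets) {
  dims <- dim(raster)
  idx <- which(raster)
  if (length(idx) == 0 || nrow(offsets) == 0) return(raster)
  coords <- arrayInd(idx, dims)
  out <- raster
  for (k in seq_len(nrow(offsets))) {
    shifted <- sweep(coords, 2, offsets[k, ], "+")
    ok <- rep(TRUE, nrow(shifted))
    for (a in seq_along(dims))
      ok <- ok & shifted[, a] >= 1 & shifted[, a] <= dims[a]
    if (!any(ok)) next
    lin <- shifted[ok, 1, drop = TRUE]
    mult <- 1
    for (a in seq_along(dims)[-1]) {
      mult <- mult * dims[a - 1]
      lin <- lin + (shifted[ok, a] - 1) * mult
    }
    out[lin] <- TRUE
  }
  out
}

square_offsets <- function(thickness_px) {
  lo <- -((thickness_px - 1) %/% 2)
  hi <- thickness_px %/% 2
  as.matrix(expand.grid(lo:hi, lo:hi))
}

ball_offsets <- function(radius) {
  if (radius <= 0) return(matrix(integer(0), ncol = 3))
  g <- as.matrix(expand.grid(-radius:radius, -radius:radius, -radius:radius))
  g[rowSums(g^2) <= radius^2 + 1e-9, , drop = FALSE]
}

# Collect all polyline edges of a system as start/end coordinate matrices.
system_edges <- function(system) {
  pieces <- lapply(system$segments, function(s) {
    n <- nrow(s$points)
    if (n < 2) return(NULL)
    cbind(s$points[-n, , drop = FALSE], s$points[-1, , drop = FALSE])
  })
  do.call(rbind, pieces)
}

#' Rasterize a rhizobox root system to a 2-D binary image
#'
#' Projects the thin (y) axis away and draws every polyline edge by
#' supercover rasterization (all pixels the continuous segment touches),
#' then dilates to the requested line thickness. Row index runs with depth
#' z (row 1 = sowing level), column index with lateral position x; the
#' image extent covers the whole rhizobox face.
#'
#' @param system a `root_system` grown in a rhizobox domain.
#' @param pitch_cm_per_px pixel pitch, cm.
#' @param thickness_px drawn line thickness in pixels (square structuring
#'   element of this width; 1 = no dilation).
#' @return A `binary_image_2d`.
#' @export
rasterize_2d <- function(system, pitch_cm_per_px, thickness_px = 1) {
  validate_root_system(system)
  stopifnot(pitch_cm_per_px > 0, thickness_px >= 1)
  if (system$domain$shape != "rhizobox")
    stop("rasterize_2d is defined for rhizobox-domain systems only")
  dom <- system$domain
  nrow_px <- floor(dom$height_cm / pitch_cm_per_px) + 1
  ncol_px <- floor(dom$width_cm / pitch_cm_per_px) + 1
  e <- system_edges(system)
  # world (x, z) -> pixel (col, row), 0-based continuous coordinates
  col0 <- (e[, 1] + dom$width_cm / 2) / pitch_cm_per_px
  row0 <- e[, 3] / pitch_cm_per_px
  col1 <- (e[, 4] + dom$width_cm / 2) / pitch_cm_per_px
  row1 <- e[, 6] / pitch_cm_per_px
  px <- .raster_edges_2d(col0, row0, col1, row1, nrow_px, ncol_px)
  if (thickness_px > 1)
    px <- dilate_offsets(px, square_offsets(thickness_px))
  binary_image_2d(px, pitch_cm_per_px)
}

#' Voxelize a root system onto a 3-D grid
#'
#' Supercover rasterization of every polyline edge in 3-D, dilated by a
#' Euclidean ball of `radius_voxels`. The sowing point (world origin) maps
#' to the center of the top slice: voxel indices
#' `(nx/2, ny/2, 0)` in 0-based coordinates.
#'
#' @param system a `root_system`.
#' @param grid a `voxel_grid`; the system must fit its physical extent.
#' @param radius_voxels dilation radius in voxels (0 = thin trace).
#' @return A `binary_volume_3d`.
#' @export
voxelize_3d <- function(system, grid, radius_voxels = 1) {
  validate_root_system(system)
  stopifnot(inherits(grid, "voxel_grid"), radius_voxels >= 0)
  vx <- grid$voxel_x_mm / 10; vy <- grid$voxel_y_mm / 10
  vz <- grid$voxel_z_mm / 10
  pts <- do.call(rbind, lapply(system$segments, `[[`, "points"))
  gx <- pts[, 1] / vx + grid$nx / 2
  gy <- pts[, 2] / vy + grid$ny / 2
  gz <- pts[, 3] / vz
  for (axis in list(list(gx, grid$nx, "x"), list(gy, grid$ny, "y"),
                    list(gz, grid$nz, "z"))) {
    bad <- which(axis[[1]] < 0 | axis[[1]] > axis[[2]])
    if (length(bad) > 0)
      stop(sprintf("system exceeds grid extent on the %s axis at point %d (%.3f voxel units, grid size %d)",
                   axis[[3]], bad[1], axis[[1]][bad[1]], axis[[2]]))
  }
  e <- system_edges(system)
  x0 <- e[, 1] / vx + grid$nx / 2; y0 <- e[, 2] / vy + grid$ny / 2
  z0 <- e[, 3] / vz
  x1 <- e[, 4] / vx + grid$nx / 2; y1 <- e[, 5] / vy + grid$ny / 2
  z1 <- e[, 6] / vz
  m <- .raster_edges_3d(x0, y0, z0, x1, y1, z1,
                        c(grid$nx, grid$ny, grid$nz))
  dim(m) <- c(grid$nx, grid$ny, grid$nz)
  if (radius_voxels > 0)
    m <- dilate_offsets(m, ball_offsets(radius_voxels))
  binary_volume_3d(m, grid)
}

#' Simulate a CT-like grayscale volume from a root mask
#'
#' A deliberately minimal CT surrogate: constant `root_intensity` on the
#' mask, constant `medium_intensity` elsewhere, plus i.i.d. Gaussian noise.
#' No beam hardening or partial-volume blur is modeled.
#'
#' @param mask a `binary_volume_3d` ground-truth root mask.
#' @param root_intensity,medium_intensity class intensities (must differ).
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param seed integer seed; output is reproducible per seed.
#' @return A `gray_volume_3d`.
#' @export
simulate_ct <- function(mask, root_intensity = 0.65, medium_intensity = 0.35,
                        noise_sd = 0.01, seed = 1) {
  stopifnot(inherits(mask, "binary_volume_3d"), noise_sd >= 0)
  if (root_intensity == medium_intensity)
    stop("root and medium intensities must differ (no contrast)")
  withr::with_seed(as.integer(seed), {
    v <- array(medium_intensity, dim = dim(mask$mask))
    v[mask$mask] <- root_intensity
    if (noise_sd > 0)
      v <- v + array(rnorm(length(v), 0, noise_sd), dim = dim(v))
    gray_volume_3d(v, mask$grid)
  })
}
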