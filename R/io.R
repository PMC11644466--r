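#' Raster file I/O
#'
#' Binary 2-D images are stored as PNG (foreground = white); grayscale and
#' binary volumes as multi-page TIFF, one page per z-slice with slice 1 the
#' top of the volume. Physical pitch metadata travels in a YAML sidecar at
#' `<path>.meta.yaml`; the readers fall back to explicit arguments when no
#' sidecar exists.
#'
#' @param image a `binary_image_2d`.
#' @param skel a 2-D `skeleton`.
#' @param volume a `gray_volume_3d`.
#' @param mask a `binary_volume_3d`.
#' @param path file path.
#' @param pitch_cm_per_px,grid metadata overrides when no sidecar is found.
#' @param threshold intensity above which a TIFF page pixel is foreground
#'   when reading a mask.
#' @name raster-io
NULL

write_pitch_sidecar <- function(path, meta) {
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
}

read_pitch_sidecar <- function(path) {
  sc <- paste0(path, ".meta.yaml")
  if (file.exists(sc)) yaml::read_yaml(sc) else NULL
}

#' @rdname raster-io
#' @export
write_image_png <- function(image, path) {
  stopifnot(inherits(image, "binary_image_2d"))
  png::writePNG(image$pixels * 1, path)
  write_pitch_sidecar(path, list(pitch_cm_per_px = image$pitch_cm_per_px))
  invisible(path)
}

#' @rdname raster-io
#' @export
read_image_png <- function(path, pitch_cm_per_px = NULL) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  meta <- read_pitch_sidecar(path)
  if (!is.null(meta)) pitch_cm_per_px <- meta$pitch_cm_per_px
  if (is.null(pitch_cm_per_px))
    stop("no pitch metadata: pass pitch_cm_per_px or provide a sidecar")
  binary_image_2d(a > 0.5, pitch_cm_per_px)
}

#' @rdname raster-io
#' @export
write_skeleton_png <- function(skel, path) {
  stopifnot(inherits(skel, "skeleton"), skel$dims == 2)
  png::writePNG(skel$raster * 1, path)
  write_pitch_sidecar(path, list(pitch_cm_per_px = skel$pitch_cm[1]))
  invisible(path)
}

grid_meta <- function(grid) {
  list(nx = grid$nx, ny = grid$ny, nz = grid$nz,
       voxel_x_mm = grid$voxel_x_mm, voxel_y_mm = grid$voxel_y_mm,
       voxel_z_mm = grid$voxel_z_mm)
}

grid_from_meta <- function(meta, dims) {
  if (!is.null(meta)) do.call(voxel_grid, meta)
  else voxel_grid(dims[1], dims[2], dims[3], 1, 1, 1)
}

# volume arrays are (x, y, z); TIFF pages are matrices (row, col) = (y, x)
vol_to_pages <- function(a) {
  lapply(seq_len(dim(a)[3]), function(k) t(a[, , k]))
}

pages_to_vol <- function(pages) {
  dims <- c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages))
  a <- array(0, dims)
  for (k in seq_along(pages)) a[, , k] <- t(pages[[k]])
  a
}

#' @rdname raster-io
#' @export
write_volume_tiff <- function(volume, path) {
  stopifnot(inherits(volume, "gray_volume_3d"))
  v <- volume$intensities
  lo <- min(v); hi <- max(v)
  scaled <- if (hi > lo) (v - lo) / (hi - lo) else v * 0
  tiff::writeTIFF(vol_to_pages(scaled), path, bits.per.sample = 16)
  write_pitch_sidecar(path, c(grid_meta(volume$grid),
                              list(intensity_min = lo, intensity_max = hi)))
  invisible(path)
}

#' @rdname raster-io
#' @export
read_volume_tiff <- function(path, grid = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  a <- pages_to_vol(pages)
  meta <- read_pitch_sidecar(path)
  if (!is.null(meta)) {
    if (!is.null(meta$intensity_min))
      a <- a * (meta$intensity_max - meta$intensity_min) + meta$intensity_min
    grid <- grid_from_meta(meta[c("nx", "ny", "nz", "voxel_x_mm",
                                  "voxel_y_mm", "voxel_z_mm")], dim(a))
  } else if (is.null(grid)) {
    grid <- grid_from_meta(NULL, dim(a))
  }
  gray_volume_3d(a, grid)
}

#' @rdname raster-io
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(inherits(mask, "binary_volume_3d"))
  tiff::writeTIFF(vol_to_pages(mask$mask * 1), path, bits.per.sample = 8)
  write_pitch_sidecar(path, grid_meta(mask$grid))
  invisible(path)
}

#' @rdname raster-io
#' @export
read_mask_tiff <- function(path, grid = NULL, threshold = 0.5) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  a <- pages_to_vol(pages)
  meta <- read_pitch_sidecar(path)
  if (!is.null(meta))
    grid <- grid_from_meta(meta[c("nx", "ny", "nz", "voxel_x_mm",
                                  "voxel_y_mm", "voxel_z_mm")], dim(a))
  else if (is.null(grid)) grid <- grid_from_meta(NULL, dim(a))
  binary_volume_3d(a > threshold, grid)
}
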