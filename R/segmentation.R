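#' Segment a CT-like grayscale volume into a binary root mask
#'
#' Global thresholding (Otsu's bimodal split on a 256-bin histogram of the
#' whole volume, or a user-fixed value) followed by 26-connectivity
#' connected-component filtering. The polarity flag states which side of
#' the threshold is root: `"bright"` keeps intensities above it, `"dark"`
#' below. If `sowing_index` is given, only the component containing that
#' voxel is kept; otherwise all components with at least
#' `min_component_voxels` voxels survive.
#'
#' @param volume a `gray_volume_3d`.
#' @param method `"otsu"` (default, parameter-free) or `"fixed"`.
#' @param threshold numeric threshold, required for `method = "fixed"`.
#' @param polarity which side of the threshold is root.
#' @param sowing_index optional 1-based voxel index `c(x, y, z)` known to
#'   lie on the root (e.g. under the sowing point).
#' @param min_component_voxels drop components smaller than this.
#' @return A `binary_volume_3d`.
#' @export
segment_volume <- function(volume, method = c("otsu", "fixed"),
                           threshold = NULL,
                           polarity = c("bright", "dark"),
                           sowing_index = NULL,
                           min_component_voxels = 0) {
  stopifnot(inherits(volume, "gray_volume_3d"))
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  v <- volume$intensities
  if (method == "otsu") {
    rng <- range(v)
    if (diff(rng) == 0)
      stop("no bimodal split: volume has constant intensity")
    # global Otsu over the whole volume as a single frame
    threshold <- EBImage::otsu(matrix(v, ncol = 1), range = rng, levels = 256)
  } else {
    if (is.null(threshold)) stop("method 'fixed' requires a threshold")
  }
  mask <- if (polarity == "bright") v > threshold else v < threshold
  dims <- dim(v)
  lab <- .label_components(mask, dims, 26L)
  dim(lab) <- dims
  keep <- array(FALSE, dims)
  if (!is.null(sowing_index)) {
    stopifnot(length(sowing_index) == 3)
    l0 <- lab[sowing_index[1], sowing_index[2], sowing_index[3]]
    if (l0 > 0) {
      keep <- lab == l0
    } else {
      warning("sowing_index voxel is background; falling back to the component-size filter")
      if (min_component_voxels > 1) {
        tab <- tabulate(lab)
        big <- which(tab >= min_component_voxels)
        if (length(big) > 0) keep <- array(lab %in% big, dims)
      } else {
        keep <- mask
      }
    }
  } else if (min_component_voxels > 1) {
    tab <- tabulate(lab)
    big <- which(tab >= min_component_voxels)
    if (length(big) > 0) keep <- array(lab %in% big, dims)
  } else {
    keep <- mask
  }
  if (!any(keep))
    warning("segmentation produced an empty mask")
  binary_volume_3d(keep, volume$grid)
}

#' Dice overlap between two binary masks
#'
#' `2 |A and B| / (|A| + |B|)`; 1 for identical non-empty masks, defined as
#' 1 when both are empty.
#'
#' @param a,b logical arrays of identical dimension (or objects carrying a
#'   `mask`/`pixels`/`raster` slot).
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_overlap <- function(a, b) {
  pick <- function(x) {
    if (is.logical(x)) return(x)
    for (slot in c("mask", "pixels", "raster"))
      if (!is.null(x[[slot]])) return(x[[slot]])
    stop("cannot extract a logical raster")
  }
  a <- pick(a); b <- pick(b)
  stopifnot(identical(dim(a), dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
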