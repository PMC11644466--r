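new_skeleton <- function(raster, pitch_cm) {
  ndim <- length(dim(raster))
  stopifnot(ndim %in% c(2, 3), is.logical(raster),
            length(pitch_cm) == ndim, all(pitch_cm > 0))
  structure(list(raster = raster, dims = ndim, pitch_cm = pitch_cm),
            class = "skeleton")
}

#' Wrap a raster as a skeleton object
#'
#' Attaches pitch metadata to a logical raster so the trait estimators can
#' run on it directly. No thinning is performed: use this for rasters that
#' are already unit-thickness, or for reference geometries (a digitized
#' line, a filled square or cube) whose box-counting behavior is known
#' analytically.
#'
#' @param raster logical matrix (2-D) or 3-D array.
#' @param pitch_cm physical cell spacing per axis, cm (recycled to the
#'   number of axes).
#' @return A `skeleton`.
#' @examples
#' line <- matrix(FALSE, 64, 64); line[32, ] <- TRUE
#' fd_boxcount(as_skeleton(line, 0.1))$fd  # 1
#' @export
as_skeleton <- function(raster, pitch_cm = 1) {
  ndim <- length(dim(raster))
  new_skeleton(raster, rep_len(pitch_cm, ndim))
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("%d-D skeleton, %s grid, %d foreground cells, pitch (%s) cm\n",
              x$dims, paste(dim(x$raster), collapse = " x "),
              sum(x$raster), paste(signif(x$pitch_cm, 4), collapse = ", ")))
  invisible(x)
}

#' Skeletonize a binary raster to unit thickness
#'
#' Topology-preserving sequential thinning by simple-point deletion with
#' directional subiterations: in 2-D, 8-connected foreground over
#' 4-connected background; in 3-D, 26-connected foreground over 6-connected
#' background. Curve endpoints are retained, the connected-component count
#' is preserved, the skeleton is a subset of the input foreground, and the
#' operation is idempotent. Optionally, terminal branches shorter than
#' `prune_px` cells are pruned afterwards (off by default; pruning slightly
#' lowers fractal-dimension estimates).
#'
#' @param image a `binary_image_2d`.
#' @param mask a `binary_volume_3d`.
#' @param prune_px prune terminal branches shorter than this many cells
#'   (0 = no pruning).
#' @return A `skeleton` (2-D or 3-D) carrying per-axis pitch in cm.
#' @export
skeletonize_2d <- function(image, prune_px = 0) {
  stopifnot(inherits(image, "binary_image_2d"))
  if (!any(image$pixels)) {
    warning("empty foreground: returning an empty skeleton")
    return(new_skeleton(image$pixels, rep(image$pitch_cm_per_px, 2)))
  }
  sk <- .thin_2d(image$pixels)
  sk <- prune_skeleton_raster(sk, prune_px)
  new_skeleton(sk, rep(image$pitch_cm_per_px, 2))
}

#' @rdname skeletonize_2d
#' @export
skeletonize_3d <- function(mask, prune_px = 0) {
  stopifnot(inherits(mask, "binary_volume_3d"))
  pitch <- c(mask$grid$voxel_x_mm, mask$grid$voxel_y_mm,
             mask$grid$voxel_z_mm) / 10
  if (!any(mask$mask)) {
    warning("empty foreground: returning an empty skeleton")
    return(new_skeleton(mask$mask, pitch))
  }
  sk <- .thin_3d(mask$mask, dim(mask$mask))
  dim(sk) <- dim(mask$mask)
  sk <- prune_skeleton_raster(sk, prune_px)
  new_skeleton(sk, pitch)
}

# Neighbor offsets (full set) for 8- or 26-connectivity.
full_offsets <- function(ndim) {
  if (ndim == 2) g <- as.matrix(expand.grid(-1:1, -1:1))
  else g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# Remove terminal branches shorter than k cells (single pass): walk from
# each degree-1 cell to the nearest junction; delete the walked path if it
# is shorter than k and ends at a junction.
prune_skeleton_raster <- function(raster, k) {
  if (k <= 0 || !any(raster)) return(raster)
  dims <- dim(raster)
  offs <- full_offsets(length(dims))
  idx <- which(raster)
  coords <- arrayInd(idx, dims)
  pos <- integer(prod(dims)); pos[idx] <- seq_along(idx)
  lin_of <- function(cc) {
    l <- cc[, 1]
    mult <- 1
    for (a in seq_along(dims)[-1]) {
      mult <- mult * dims[a - 1]
      l <- l + (cc[, a] - 1) * mult
    }
    l
  }
  neighbors_of <- function(i) {
    cc <- sweep(offs, 2, coords[i, ], "+")
    ok <- rep(TRUE, nrow(cc))
    for (a in seq_along(dims))
      ok <- ok & cc[, a] >= 1 & cc[, a] <= dims[a]
    nb <- pos[lin_of(cc[ok, , drop = FALSE])]
    nb[nb > 0]
  }
  deg <- vapply(seq_along(idx), function(i) length(neighbors_of(i)),
                integer(1))
  drop <- logical(length(idx))
  for (e in which(deg == 1)) {
    path <- e
    prev <- 0L
    cur <- e
    repeat {
      nb <- setdiff(neighbors_of(cur), prev)
      if (length(nb) != 1 || length(path) >= k) break
      nxt <- nb[1]
      if (deg[nxt] > 2) {          # reached a junction: prune the spur
        drop[path] <- TRUE
        break
      }
      prev <- cur; cur <- nxt
      path <- c(path, cur)
    }
  }
  out <- raster
  out[idx[drop]] <- FALSE
  out
}

#' Skeleton cells as a data frame
#'
#' @param skel a `skeleton`.
#' @return A data frame of 0-based cell indices: in 2-D `x` (column) and
#'   `y` (row, increasing with depth); in 3-D `x`, `y`, `z`.
#' @export
skeleton_df <- function(skel) {
  stopifnot(inherits(skel, "skeleton"))
  cc <- arrayInd(which(skel$raster), dim(skel$raster)) - 1L
  if (skel$dims == 2)
    data.frame(x = cc[, 2], y = cc[, 1])
  else
    data.frame(x = cc[, 1], y = cc[, 2], z = cc[, 3])
}
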