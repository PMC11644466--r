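# Half set of neighbor offsets (one per unordered pair direction).
half_offsets <- function(ndim) {
  offs <- full_offsets(ndim)
  keep <- apply(offs, 1, function(o) {
    nz <- which(o != 0)[1]
    o[nz] > 0
  })
  offs[keep, , drop = FALSE]
}

# Adjacency graph of skeleton cells (8-neighborhood in 2-D, 26 in 3-D);
# edge weight = Euclidean distance between cell centers under the
# anisotropic pitch.
skeleton_graph <- function(skel) {
  dims <- dim(skel$raster)
  idx <- which(skel$raster)
  n <- length(idx)
  pos <- integer(prod(dims)); pos[idx] <- seq_len(n)
  coords <- arrayInd(idx, dims)
  offs <- half_offsets(skel$dims)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    shifted <- sweep(coords, 2, o, "+")
    ok <- rep(TRUE, n)
    for (a in seq_along(dims))
      ok <- ok & shifted[, a] >= 1 & shifted[, a] <= dims[a]
    lin <- shifted[ok, 1]
    mult <- 1
    for (a in seq_along(dims)[-1]) {
      mult <- mult * dims[a - 1]
      lin <- lin + (shifted[ok, a] - 1) * mult
    }
    nb <- pos[lin]
    hit <- nb > 0
    from <- c(from, which(ok)[hit])
    to <- c(to, nb[hit])
    w <- c(w, rep(sqrt(sum((o * skel$pitch_cm)^2)), sum(hit)))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(from) > 0)
    g <- igraph::add_edges(g, rbind(from, to), weight = w)
  g
}

#' Total root length of a skeleton
#'
#' Builds the adjacency graph of skeleton cells (8-neighborhood in 2-D,
#' 26-neighborhood in 3-D) with edge weights equal to the Euclidean
#' distance between cell centers under the anisotropic pitch, and sums the
#' edge weights of a minimum-spanning forest (one tree per connected
#' component). The spanning forest avoids double-counting the
#' diagonal-plus-orthogonal cliques a digital curve produces; all minimum
#' spanning forests share the same total weight, so the result does not
#' depend on tie-breaking.
#'
#' @param skel a `skeleton` with pitch metadata.
#' @return Total length in cm (0, with a warning, for an empty skeleton).
#' @export
total_root_length <- function(skel) {
  stopifnot(inherits(skel, "skeleton"))
  if (!any(skel$raster)) {
    warning("empty skeleton: total root length 0")
    return(0)
  }
  g <- skeleton_graph(skel)
  if (igraph::ecount(g) == 0) return(0)
  f <- igraph::mst(g, weights = igraph::E(g)$weight)
  sum(igraph::E(f)$weight)
}

#' Occupied-box count at one grid scale
#'
#' Counts the cells of a nested dyadic grid of edge length `size`
#' (anchored at the array origin) that contain at least one foreground
#' skeleton cell.
#'
#' @param skel a `skeleton`.
#' @param size box/cube edge length in cells (>= 1).
#' @return Integer count.
#' @export
count_boxes <- function(skel, size) {
  stopifnot(inherits(skel, "skeleton"))
  size <- as.integer(size)
  if (size < 1) stop("size must be >= 1")
  dims <- dim(skel$raster)
  if (size > max(dims))
    stop(sprintf("box size %d exceeds the array extent (max dim %d)",
                 size, max(dims)))
  idx <- which(skel$raster)
  if (length(idx) == 0) return(0L)
  cc <- (arrayInd(idx, dims) - 1L) %/% size
  nb <- (dims - 1L) %/% size + 1L
  code <- cc[, 1]
  mult <- 1
  for (a in seq_along(dims)[-1]) {
    mult <- mult * nb[a - 1]
    code <- code + cc[, a] * mult
  }
  length(unique(code))
}

default_scale_schedule <- function(dims) {
  smax <- floor(min(dims) / 4)
  if (smax < 1) return(integer(0))
  2^(0:floor(log2(smax)))
}

fd_fit <- function(skel, sizes, dmax) {
  if (!any(skel$raster)) stop("empty skeleton: fractal dimension undefined")
  if (is.null(sizes)) sizes <- default_scale_schedule(dim(skel$raster))
  sizes <- sort(unique(as.integer(sizes)))
  if (length(sizes) < 4)
    stop("insufficient scale range: need at least 4 box sizes")
  counts <- vapply(sizes, function(s) count_boxes(skel, s), integer(1))
  x <- log(1 / sizes)
  y <- log(counts)
  mx <- mean(x); my <- mean(y)
  vxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / vxx
  intercept <- my - slope * mx
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - my)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(sizes = sizes, counts = counts, fd = slope,
                 intercept = intercept, r_squared = r2, dims = dmax),
            class = "fd_estimate")
}

#' Fractal dimension by box counting (2-D) or cube counting (3-D)
#'
#' Overlays nested dyadic grids anchored at the array origin (default edge
#' lengths 1, 2, 4, ... up to `floor(min_dim / 4)`, so the coarsest scale
#' still holds at least ~4 boxes per axis), counts occupied boxes at each
#' scale, and fits log(count) against log(1/size) by unweighted ordinary
#' least squares. The slope is the FD estimate. With nested dyadic grids
#' each refinement multiplies the count by at most `2^d`, so the estimate
#' is guaranteed to lie in `[0, 2]` for box counting and `[0, 3]` for cube
#' counting; a digitized straight line gives 1, a filled square 2, a
#' filled cube 3, a single cell 0.
#'
#' @param skel a 2-D (`fd_boxcount`) or 3-D (`fd_cubecount`) `skeleton`
#'   with at least 4 usable scales (smallest grid dimension >= 32 under the
#'   default schedule).
#' @param sizes optional integer vector overriding the scale schedule.
#' @return An `fd_estimate`: sizes, counts, fitted slope (`fd`),
#'   intercept and `r_squared`.
#' @examples
#' px <- matrix(FALSE, 64, 64); px[32, ] <- TRUE
#' fd_boxcount(skeletonize_2d(binary_image_2d(px, 0.1)))$fd  # 1
#' @export
fd_boxcount <- function(skel, sizes = NULL) {
  stopifnot(inherits(skel, "skeleton"))
  if (skel$dims != 2) stop("fd_boxcount expects a 2-D skeleton")
  fd_fit(skel, sizes, 2)
}

#' @rdname fd_boxcount
#' @export
fd_cubecount <- function(skel, sizes = NULL) {
  stopifnot(inherits(skel, "skeleton"))
  if (skel$dims != 3) stop("fd_cubecount expects a 3-D skeleton")
  fd_fit(skel, sizes, 3)
}

#' @export
print.fd_estimate <- function(x, ...) {
  cat(sprintf("%s-counting FD estimate: %.3f (r^2 = %.4f, %d scales %d..%d)\n",
              if (x$dims == 2) "box" else "cube", x$fd, x$r_squared,
              length(x$sizes), min(x$sizes), max(x$sizes)))
  invisible(x)
}
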