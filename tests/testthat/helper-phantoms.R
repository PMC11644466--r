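# Fixtures built in code: reference rasters and small stochastic phantoms.

# Straight axis-aligned line in an n x n image (one full row).
line_image <- function(n = 512, pitch = 0.1) {
  px <- matrix(FALSE, n, n)
  px[n %/% 2, ] <- TRUE
  binary_image_2d(px, pitch)
}

filled_square <- function(n = 512, pitch = 0.1) {
  as_skeleton(matrix(TRUE, n, n), pitch)
}

single_pixel_image <- function(n = 512, pitch = 0.1) {
  px <- matrix(FALSE, n, n)
  px[7, 11] <- TRUE
  as_skeleton(px, pitch)
}

# Straight z-aligned voxel line spanning the full z extent.
line_volume <- function(nxy = 64, nz = 256, pitch = 0.1) {
  a <- array(FALSE, c(nxy, nxy, nz))
  a[nxy %/% 2, nxy %/% 2, ] <- TRUE
  as_skeleton(a, pitch)
}

filled_cube <- function(n = 128, pitch = 0.1) {
  as_skeleton(array(TRUE, c(n, n, n)), pitch)
}

# Random blobby 2-D mask: union of filled axis-aligned rectangles.
random_blob_image <- function(seed, n = 48, nblobs = 3) {
  withr::with_seed(seed, {
    px <- matrix(FALSE, n, n)
    for (i in seq_len(nblobs)) {
      r0 <- sample(n - 8, 1); c0 <- sample(n - 8, 1)
      h <- sample(3:8, 1); w <- sample(3:8, 1)
      px[r0:min(n, r0 + h), c0:min(n, c0 + w)] <- TRUE
    }
    px
  })
}

# Sparse random raster for box-counting oracle checks.
random_sparse_raster <- function(seed, dims, p = 0.05) {
  withr::with_seed(seed, array(runif(prod(dims)) < p, dims))
}

# Independent brute-force occupied-box count: explicit loop over grid cells.
brute_force_count <- function(raster, size) {
  dims <- dim(raster)
  nb <- (dims - 1L) %/% size + 1L
  cnt <- 0L
  if (length(dims) == 2) {
    for (bi in seq_len(nb[1])) for (bj in seq_len(nb[2])) {
      rows <- ((bi - 1L) * size + 1L):min(dims[1], bi * size)
      cols <- ((bj - 1L) * size + 1L):min(dims[2], bj * size)
      if (any(raster[rows, cols])) cnt <- cnt + 1L
    }
  } else {
    for (bi in seq_len(nb[1])) for (bj in seq_len(nb[2])) for (bk in seq_len(nb[3])) {
      xs <- ((bi - 1L) * size + 1L):min(dims[1], bi * size)
      ys <- ((bj - 1L) * size + 1L):min(dims[2], bj * size)
      zs <- ((bk - 1L) * size + 1L):min(dims[3], bk * size)
      if (any(raster[xs, ys, zs])) cnt <- cnt + 1L
    }
  }
  cnt
}

# Component count of a logical raster (8- or 26-connectivity).
n_components <- function(raster) {
  dims <- dim(raster)
  conn <- if (length(dims) == 2) 8L else 26L
  if (length(dims) == 2) dims <- c(dims, 1L)
  max(rsatraits:::.label_components(as.logical(raster), dims, conn), 0L)
}

# A taproot-only archetype: one wobbly polyline, no laterals.
polyline_archetype <- function(length_cm = 25) {
  archetype_params(taproot_length_cm = length_cm, lateral_density_per_cm = 0,
                   gravitropism = 0.3, step_deflection_sd_deg = 6,
                   name = "polyline")
}

# A perfectly straight vertical taproot (no wobble, full gravitropism).
straight_archetype <- function(length_cm = 10) {
  archetype_params(taproot_length_cm = length_cm, lateral_density_per_cm = 0,
                   gravitropism = 1, step_deflection_sd_deg = 0,
                   name = "straight")
}
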