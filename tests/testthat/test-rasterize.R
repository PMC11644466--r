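test_that("the CT grid volume arithmetic is exact", {
  expect_equal(round(grid_volume_dm3(voxel_grid()), 3), 1.156)
  expect_equal(grid_volume_dm3(voxel_grid(1, 1, 1, 1, 1, 1)), 1e-6)
  g1 <- voxel_grid(64, 64, 100, 0.3, 0.3, 0.5)
  g2 <- voxel_grid(64, 64, 200, 0.3, 0.3, 0.5)
  expect_equal(grid_volume_dm3(g2), 2 * grid_volume_dm3(g1))
})

test_that("a straight vertical taproot rasterizes to one thin pixel column", {
  sys <- generate_root_system(straight_archetype(10), rhizobox_domain(), 1)
  img <- rasterize_2d(sys, 0.1, thickness_px = 1)
  cols <- unique(which(img$pixels, arr.ind = TRUE)[, 2])
  expect_identical(length(cols), 1L)
  expect_equal(sum(img$pixels), 101)
})

test_that("2-D rasterization is a supercover: dense samples land on foreground", {
  sys <- generate_root_system(polyline_archetype(15), rhizobox_domain(), 4)
  pitch <- 0.05
  img <- rasterize_2d(sys, pitch, thickness_px = 1)
  dom <- sys$domain
  pts <- sys$segments[[1]]$points
  for (i in seq_len(nrow(pts) - 1)) {
    for (f in seq(0, 1, by = 0.1)) {
      p <- pts[i, ] + f * (pts[i + 1, ] - pts[i, ])
      row <- floor(p[3] / pitch) + 1
      col <- floor((p[1] + dom$width_cm / 2) / pitch) + 1
      expect_true(img$pixels[row, col])
    }
  }
  # supercover lower bound on foreground pixel count
  expect_gte(sum(img$pixels),
             ceiling(ground_truth_length(sys) / (pitch * sqrt(2))))
})

test_that("pot-domain systems cannot be photographed in 2-D", {
  sys <- generate_root_system(casino_archetype(), pot_domain(), 1)
  expect_error(rasterize_2d(sys, 0.1), "rhizobox")
})

test_that("voxelization spans the expected slices and grows with dilation radius", {
  # straight 2 cm root on the CT-like grid: voxel_z 0.2 mm -> 101 slices
  sys <- generate_root_system(straight_archetype(2), rhizobox_domain(), 1)
  grid <- voxel_grid(64, 64, 128, 0.5, 0.5, 0.2)
  m <- voxelize_3d(sys, grid, radius_voxels = 0)
  zs <- range(which(apply(m$mask, 3, any)))
  expect_equal(zs[2] - zs[1] + 1, 101)

  m0 <- voxelize_3d(sys, grid, radius_voxels = 0)
  m1 <- voxelize_3d(sys, grid, radius_voxels = 1)
  expect_true(all(m1$mask[m0$mask]))      # dilation monotonicity
  expect_gt(sum(m1$mask), sum(m0$mask))
  expect_identical(m1$mask, voxelize_3d(sys, grid, 1)$mask)  # determinism
})

test_that("a system exceeding the grid extent is rejected, naming the axis", {
  sys <- generate_root_system(straight_archetype(10), rhizobox_domain(), 1)
  small <- voxel_grid(32, 32, 32, 1, 1, 1)   # 3.2 cm deep < 10 cm root
  expect_error(voxelize_3d(sys, small), "z axis")
})

test_that("the CT surrogate has the stated class statistics and is seeded", {
  sys <- generate_root_system(casino_archetype(), pot_domain(), 2)
  m <- voxelize_3d(sys, pot_grid(pot_domain(), 48), 1)
  noiseless <- simulate_ct(m, 0.7, 0.2, noise_sd = 0, seed = 1)
  expect_setequal(unique(as.vector(noiseless$intensities)), c(0.2, 0.7))

  v1 <- simulate_ct(m, 0.7, 0.2, noise_sd = 0.05, seed = 9)
  v2 <- simulate_ct(m, 0.7, 0.2, noise_sd = 0.05, seed = 9)
  expect_identical(v1$intensities, v2$intensities)

  # CLT check on the mask-voxel mean
  n <- sum(m$mask)
  expect_lt(abs(mean(v1$intensities[m$mask]) - 0.7), 3 * 0.05 / sqrt(n))

  expect_error(simulate_ct(m, 0.5, 0.5), "contrast")
})

test_that("rasterization shifts with the system by whole pitches", {
  sys <- generate_root_system(polyline_archetype(8), rhizobox_domain(), 6)
  pitch <- 0.1
  img <- rasterize_2d(sys, pitch, 1)
  shifted <- sys
  shifted$segments <- lapply(sys$segments, function(s) {
    s$points[, 3] <- s$points[, 3] + 5 * pitch
    s
  })
  img2 <- rasterize_2d(shifted, pitch, 1)
  a <- which(img$pixels, arr.ind = TRUE)
  b <- which(img2$pixels, arr.ind = TRUE)
  expect_equal(nrow(a), nrow(b))
  expect_setequal(paste(a[, 1] + 5, a[, 2]), paste(b[, 1], b[, 2]))
})

test_that("images and volumes round-trip through PNG and multi-page TIFF", {
  sys <- generate_root_system(casino_archetype(), rhizobox_domain(), 8)
  img <- rasterize_2d(sys, 0.1, 2)
  p <- withr::local_tempfile(fileext = ".png")
  write_image_png(img, p)
  back <- read_image_png(p)
  expect_identical(back$pixels, img$pixels)
  expect_equal(back$pitch_cm_per_px, 0.1)

  m <- voxelize_3d(sys, voxel_grid(48, 48, 48, 6, 6, 9), 1)
  tf <- withr::local_tempfile(fileext = ".tif")
  write_mask_tiff(m, tf)
  mb <- read_mask_tiff(tf)
  expect_identical(mb$mask, m$mask)
  expect_equal(mb$grid, m$grid)

  v <- simulate_ct(m, seed = 1)
  tv <- withr::local_tempfile(fileext = ".tif")
  write_volume_tiff(v, tv)
  vb <- read_volume_tiff(tv)
  expect_equal(dim(vb$intensities), dim(v$intensities))
  # 16-bit quantization: recovered within one gray level
  expect_lt(max(abs(vb$intensities - v$intensities)),
            diff(range(v$intensities)) / 65535 * 2)
})
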