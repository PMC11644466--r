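test_that("skeleton length arithmetic is exact on axis-aligned and diagonal lines", {
  # 101 voxels along z at 0.2 mm: 100 gaps x 0.02 cm = 2 cm
  a <- array(FALSE, c(8, 8, 101)); a[4, 4, ] <- TRUE
  g <- voxel_grid(8, 8, 101, 0.21, 0.21, 0.2)
  sk <- skeletonize_3d(binary_volume_3d(a, g))
  expect_equal(total_root_length(sk), 2, tolerance = 1e-12)

  # xy diagonal of 101 voxels at 0.21 mm pitch
  b <- array(FALSE, c(101, 101, 3))
  for (i in 1:101) b[i, i, 2] <- TRUE
  g2 <- voxel_grid(101, 101, 3, 0.21, 0.21, 0.2)
  sk2 <- as_skeleton(b, c(0.021, 0.021, 0.02))
  expect_equal(total_root_length(sk2), 100 * 0.021 * sqrt(2),
               tolerance = 1e-12)
})

test_that("skeleton length recovers generator ground truth within 5%", {
  box <- rhizobox_domain()
  for (s in 1:20) {
    sys <- generate_root_system(polyline_archetype(25), box, s)
    sk <- skeletonize_2d(rasterize_2d(sys, 0.05, 3))
    expect_lt(abs(total_root_length(sk) - ground_truth_length(sys)) /
                ground_truth_length(sys), 0.05)
  }
})

test_that("length is additive over disjoint skeleton pieces", {
  px1 <- matrix(FALSE, 40, 40); px1[10, 5:25] <- TRUE
  px2 <- matrix(FALSE, 40, 40); px2[30, 8:33] <- TRUE
  l1 <- total_root_length(as_skeleton(px1, 0.1))
  l2 <- total_root_length(as_skeleton(px2, 0.1))
  both <- total_root_length(as_skeleton(px1 | px2, 0.1))
  expect_equal(both, l1 + l2, tolerance = 1e-12)
  expect_warning(expect_equal(
    total_root_length(as_skeleton(matrix(FALSE, 4, 4), 1)), 0), "empty")
})

test_that("count_boxes matches a brute-force grid scan on small rasters", {
  cases <- list(
    list(r = random_sparse_raster(1, c(64, 64), 0.04), sizes = c(1, 2, 3, 5, 7, 16, 64)),
    list(r = random_sparse_raster(2, c(37, 53), 0.08), sizes = c(1, 2, 4, 9, 37)),
    list(r = random_blob_image(3), sizes = c(1, 2, 3, 6, 48)),
    list(r = random_sparse_raster(4, c(24, 24, 24), 0.02), sizes = c(1, 2, 3, 8, 24)),
    list(r = random_sparse_raster(5, c(17, 23, 31), 0.05), sizes = c(1, 2, 5, 17)))
  for (cs in cases) {
    sk <- as_skeleton(cs$r, 1)
    for (s in cs$sizes)
      expect_identical(count_boxes(sk, s), brute_force_count(cs$r, s))
  }
})

test_that("count_boxes honors the identity scale, point rule and nesting bounds", {
  r <- random_sparse_raster(6, c(48, 48), 0.05)
  sk <- as_skeleton(r, 1)
  expect_identical(count_boxes(sk, 1), sum(r))
  pt <- single_pixel_image(64)
  for (s in c(1, 2, 5, 16, 64)) expect_identical(count_boxes(pt, s), 1L)
  # nested dyadic bounds between scales s and 2s
  for (seed in 7:12) {
    r <- random_sparse_raster(seed, c(64, 64), 0.03)
    sk <- as_skeleton(r, 1)
    for (s in c(1, 2, 4, 8, 16)) {
      c1 <- count_boxes(sk, s); c2 <- count_boxes(sk, 2 * s)
      expect_lte(c2, c1)
      expect_gte(c2, c1 / 4)
    }
  }
  expect_error(count_boxes(sk, 200), "exceeds")
  expect_error(count_boxes(sk, 0), ">= 1")
})

test_that("FD estimates hit the Euclidean limits exactly", {
  expect_equal(fd_boxcount(skeletonize_2d(line_image(512)))$fd, 1,
               tolerance = 1e-12)
  expect_equal(fd_boxcount(filled_square(512))$fd, 2, tolerance = 1e-12)
  expect_equal(fd_boxcount(single_pixel_image(512))$fd, 0, tolerance = 1e-12)
  expect_equal(fd_cubecount(line_volume(64, 256),
                            sizes = c(1, 2, 4, 8, 16))$fd, 1,
               tolerance = 1e-12)
  expect_equal(fd_cubecount(filled_cube(128))$fd, 3, tolerance = 1e-12)
  # flat slab has plane dimension under cube counting
  slab <- array(FALSE, c(128, 128, 8)); slab[, , 4] <- TRUE
  expect_equal(fd_cubecount(as_skeleton(slab, 1),
                            sizes = c(1, 2, 4, 8, 16, 32))$fd, 2,
               tolerance = 1e-12)
})

test_that("FD estimators enforce their preconditions", {
  expect_error(fd_boxcount(line_volume(64, 64)), "2-D")
  expect_error(fd_cubecount(filled_square(64)), "3-D")
  expect_error(fd_boxcount(as_skeleton(matrix(TRUE, 8, 8), 1)),
               "insufficient scale range")
  expect_error(fd_boxcount(as_skeleton(matrix(FALSE, 64, 64), 1)), "empty")
})

test_that("FD estimates respect the dimension bounds on stochastic skeletons", {
  box <- rhizobox_domain(); pot <- pot_domain()
  g <- pot_grid(pot, 64)
  for (s in 1:12) {
    p <- if (s %% 2) casino_archetype() else woodstock_archetype()
    fd2 <- fd_boxcount(skeletonize_2d(rasterize_2d(
      generate_root_system(p, box, s), 0.1, 2)))
    expect_gte(fd2$fd, 0); expect_lte(fd2$fd, 2)
    expect_true(all(diff(fd2$counts) <= 0))
    fd3 <- fd_cubecount(skeletonize_3d(voxelize_3d(
      generate_root_system(p, pot, s), g, 1)))
    expect_gte(fd3$fd, 0); expect_lte(fd3$fd, 3)
  }
})

test_that("the branched archetype scores higher than the taproot-dominant one in both systems", {
  box <- rhizobox_domain(); pot <- pot_domain()
  g <- pot_grid(pot, 64)
  measure <- function(params, s) {
    sk2 <- skeletonize_2d(rasterize_2d(generate_root_system(params, box, s),
                                       0.1, 2))
    sk3 <- skeletonize_3d(voxelize_3d(generate_root_system(params, pot, s),
                                      g, 1))
    c(len2 = total_root_length(sk2), fd2 = fd_boxcount(sk2)$fd,
      len3 = total_root_length(sk3), fd3 = fd_cubecount(sk3)$fd)
  }
  cas <- vapply(1:30, function(s) measure(casino_archetype(), s), numeric(4))
  wood <- vapply(1:30, function(s) measure(woodstock_archetype(), s), numeric(4))
  m_cas <- rowMeans(cas); m_wood <- rowMeans(wood)
  expect_gt(m_wood["len2"], m_cas["len2"])
  expect_gt(m_wood["fd2"], m_cas["fd2"])
  expect_gt(m_wood["len3"], m_cas["len3"])
  expect_gt(m_wood["fd3"], m_cas["fd3"])
})
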