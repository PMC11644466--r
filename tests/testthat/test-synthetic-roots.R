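test_that("archetype presets encode the taproot-dominant vs branched contrast", {
  cas <- casino_archetype()
  wood <- woodstock_archetype()
  expect_lte(cas$tertiary_prob, 0.05)
  expect_gt(wood$tertiary_prob, 0)
  expect_lt(cas$lateral_density_per_cm, wood$lateral_density_per_cm)
  expect_gt(wood$lateral_length_mean_cm, cas$lateral_length_mean_cm)
  # pure constants: repeated calls identical
  expect_identical(cas, casino_archetype())
  expect_identical(wood, woodstock_archetype())
})

test_that("branched archetype outgrows the taproot-dominant one on average", {
  box <- rhizobox_domain()
  lens <- vapply(1:100, function(s) {
    c(ground_truth_length(generate_root_system(casino_archetype(), box, s)),
      ground_truth_length(generate_root_system(woodstock_archetype(), box, s)))
  }, numeric(2))
  expect_gt(mean(lens[2, ]), mean(lens[1, ]))
})

test_that("generation is deterministic and respects confinement", {
  wood <- woodstock_archetype()
  pot <- pot_domain()
  a <- generate_root_system(wood, pot, 7)
  b <- generate_root_system(wood, pot, 7)
  expect_identical(a, b)

  pts <- do.call(rbind, lapply(a$segments, `[[`, "points"))
  r <- pot$diameter_cm / 2
  expect_true(all(pts[, 1]^2 + pts[, 2]^2 <= r^2 + 1e-6))
  expect_true(all(pts[, 3] >= -1e-6 & pts[, 3] <= pot$height_cm + 1e-6))

  box <- rhizobox_domain()
  for (s in c(1, 23, 999)) {
    sys <- generate_root_system(wood, box, s)
    p <- do.call(rbind, lapply(sys$segments, `[[`, "points"))
    expect_true(all(domain_contains(box, p)))
  }
})

test_that("branch orders are consistent and exactly one taproot exists", {
  sys <- generate_root_system(woodstock_archetype(), rhizobox_domain(), 11)
  orders <- vapply(sys$segments, `[[`, integer(1), "order")
  expect_identical(sum(orders == 0L), 1L)
  ids <- vapply(sys$segments, `[[`, integer(1), "id")
  for (seg in sys$segments) {
    if (seg$order == 0L) next
    parent <- sys$segments[[match(seg$parent_id, ids)]]
    expect_identical(seg$order, parent$order + 1L)
  }
  # every segment has at least 2 distinct consecutive points
  for (seg in sys$segments) {
    expect_gte(nrow(seg$points), 2)
    expect_true(all(rowSums(diff(seg$points)^2) > 0))
  }
})

test_that("ground-truth length matches brute-force re-summation and is additive", {
  sys <- generate_root_system(woodstock_archetype(), rhizobox_domain(), 5)
  brute <- sum(vapply(sys$segments, function(s) {
    tot <- 0
    for (i in seq_len(nrow(s$points) - 1))
      tot <- tot + sqrt(sum((s$points[i + 1, ] - s$points[i, ])^2))
    tot
  }, numeric(1)))
  expect_equal(ground_truth_length(sys), brute, tolerance = 1e-12)

  # invariant under segment reordering
  shuffled <- sys
  shuffled$segments <- rev(sys$segments)
  expect_equal(ground_truth_length(shuffled), ground_truth_length(sys))
})

test_that("a lateral-free straight taproot has exactly its budgeted length", {
  sys <- generate_root_system(straight_archetype(10), rhizobox_domain(), 1)
  expect_identical(length(sys$segments), 1L)
  expect_equal(ground_truth_length(sys), 10, tolerance = 1e-9)
})

test_that("degenerate inputs are rejected", {
  expect_error(archetype_params(taproot_length_cm = 10, step_cm = 0),
               "step_cm")
  expect_error(archetype_params(taproot_length_cm = 10, tertiary_prob = 1.5))
  expect_error(ground_truth_length(structure(list(segments = list()),
                                            class = "root_system")),
               "no segments")
})

test_that("root systems round-trip through CSV with sidecar metadata", {
  sys <- generate_root_system(casino_archetype(), pot_domain(), 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_root_system(sys, path)
  back <- read_root_system(path)
  expect_equal(back$seed, sys$seed)
  expect_equal(back$archetype_name, sys$archetype_name)
  expect_equal(back$domain, sys$domain)
  expect_equal(length(back$segments), length(sys$segments))
  expect_equal(ground_truth_length(back), ground_truth_length(sys),
               tolerance = 1e-9)
})

test_that("archetype overrides load from a key-value config file", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("taproot_length_cm: 12.5", "lateral_density_per_cm: 0.5",
               "name: custom_test"), path)
  p <- read_archetype_config(path)
  expect_equal(p$taproot_length_cm, 12.5)
  expect_equal(p$lateral_density_per_cm, 0.5)
  expect_equal(p$name, "custom_test")
  expect_equal(p$step_cm, casino_archetype()$step_cm)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("no_such_field: 1", bad)
  expect_error(read_archetype_config(bad), "unknown archetype fields")
})
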