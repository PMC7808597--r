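test_that("phantom intensities follow region membership", {
  spec <- phantom_spec(noise_sd = 0)
  ph <- make_phantom(spec)
  hc <- round(spec$heart$center / spec$spacing) + 1
  expect_equal(ph$image$values[hc[1], hc[2], hc[3]],
               unname(spec$intensities["heart"]))
  expect_equal(ph$image$values[1, 1, 1], unname(spec$intensities["air"]))
  lc <- round(spec$lungs[[1]]$center / spec$spacing) + 1
  expect_equal(ph$image$values[lc[1], lc[2], lc[3]],
               unname(spec$intensities["lung"]))
})

test_that("truth heart volume matches the analytic ellipsoid volume", {
  ph <- default_phantom()
  analytic <- 4 / 3 * pi * prod(ph$spec$heart$radii)
  voxel <- sum(ph$heart$values) * prod(ph$spec$spacing)
  expect_lt(abs(voxel - analytic) / analytic, 0.05)
})

test_that("phantoms are deterministic in the seed and truth disjoint", {
  a <- make_phantom(phantom_spec(seed = 9))
  b <- make_phantom(phantom_spec(seed = 9))
  expect_identical(a$image$values, b$image$values)
  c2 <- make_phantom(phantom_spec(seed = 10))
  expect_false(identical(a$image$values, c2$image$values))
  expect_equal(sum(a$heart$values * a$lungs$values), 0)
})

test_that("degenerate geometry is rejected", {
  expect_error(phantom_spec(heart = list(center = c(80, 88, 66),
                                         radii = c(0, 23, 25),
                                         angle_deg = 0)), "radii")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
})

test_that("cohort perturbation scales with the variation parameter", {
  base <- phantom_spec()
  same <- make_cohort(3, base, variation = 0, seed = 5)
  for (m in same)
    expect_identical(m$heart$values, make_phantom(base)$heart$values)

  co <- make_cohort(12, base, variation = 0.1, seed = 6)
  r1 <- vapply(co, function(m) m$spec$heart$radii[1], numeric(1))
  rel_sd <- stats::sd(r1) / base$heart$radii[1]
  expect_gt(rel_sd, 0.04)
  expect_lt(rel_sd, 0.2)
  expect_false(identical(co[[1]]$image$values, co[[2]]$image$values))
  expect_error(make_cohort(1), "at least 2")
})

test_that("4D study reproduces the commanded respiratory excursion", {
  ph <- default_phantom()

  still <- make_4d_study(ph, motion_spec(amplitude_mm = 0))
  for (p in still$phases[-1])
    expect_identical(p$truth$values, ph$heart$values)

  st <- make_4d_study(ph, motion_spec(amplitude_mm = 10))
  expect_identical(st$phases[[1]]$image$values, ph$image$values)
  expect_identical(st$phases[[1]]$truth$values, ph$heart$values)
  expect_equal(vapply(st$phases, function(p) p$label, character(1))[1:3],
               c("0%", "10%", "20%"))

  c0 <- colMeans(voxel_to_physical(ph$heart,
                                   which(ph$heart$values > 0,
                                         arr.ind = TRUE) - 1))
  t5 <- st$phases[[6]]$truth
  c5 <- colMeans(voxel_to_physical(t5, which(t5$values > 0,
                                             arr.ind = TRUE) - 1))
  # phase 5 of 10 is full inhale: the whole amplitude, mostly inferior
  expect_lt(abs((c0[3] - c5[3]) - 10), 1.25)
  expect_lt(abs(sqrt(sum((c5 - c0)^2)) - sqrt(10^2 + 3^2)) , 1.25)

  union <- Reduce(function(a, b) pmax(a, b),
                  lapply(st$phases, function(p) p$truth$values))
  um <- tiny_mask(union, spacing = ph$heart$spacing)
  bu <- mask_bounding_box(um, 0)
  b0 <- mask_bounding_box(ph$heart, 0)
  si_gain <- (bu$hi[3] - bu$lo[3]) - (b0$hi[3] - b0$lo[3])
  expect_lt(abs(si_gain * ph$heart$spacing[3] - 10), 2.5 + 1e-9)

  expect_error(make_4d_study(ph, motion_spec(amplitude_mm = 200)),
               "outside the grid")
})

test_that("the MIP is the voxelwise maximum over phases", {
  ph <- small_phantom(seed = 2)
  st <- make_4d_study(ph, motion_spec(amplitude_mm = 8))
  mip <- mip_image(st)
  stack <- sapply(st$phases, function(p) as.numeric(p$image$values))
  expect_equal(as.numeric(mip$values), apply(stack, 1, max))
})
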