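# Rigid and demons recovery tests construct the moving image by resampling
# the fixed phantom through a known transform T; the registration then has to
# recover the inverse map T^{-1} (transforms map fixed-space points into
# moving space, the resampling convention).

rigid_affine <- function(tr) {
  list(M = tr$rotation,
       t = as.numeric(tr$center - tr$rotation %*% tr$center + tr$translation))
}

rigid_errors <- function(recovered, truth, at) {
  A <- rigid_affine(truth)
  inv <- list(M = t(A$M), t = as.numeric(-t(A$M) %*% A$t))
  R <- rigid_affine(recovered)
  terr <- sqrt(sum(((R$M - inv$M) %*% at + R$t - inv$t)^2))
  aerr <- acos(min(1, (sum(diag(R$M %*% t(inv$M))) - 1) / 2)) * 180 / pi
  c(translation_mm = terr, rotation_deg = aerr)
}

test_that("rigid registration recovers identity, shifts and rotations", {
  ph <- small_phantom(seed = 21)
  ctr <- heartseg4d:::phys_center(ph$image)

  rec0 <- rigid_register(ph$image, ph$image)
  e0 <- rigid_errors(rec0, rigid_transform(center = ctr), ctr)
  expect_lt(e0["translation_mm"], 0.1)
  expect_lt(e0["rotation_deg"], 0.1)

  tr <- rigid_transform(translation = c(4, -2, 0), center = ctr)
  mov <- apply_to_image(tr, ph$image)
  rec <- rigid_register(ph$image, mov)
  # under the fixed-to-moving convention the inverse shift is recovered
  expect_lt(max(abs(rec$translation - c(-4, 2, 0))), 0.5)
  e <- rigid_errors(rec, tr, ctr)
  expect_lt(e["translation_mm"], 0.5)

  rot <- rigid_transform(heartseg4d:::euler_rotation(c(0, 0, 5 * pi / 180)),
                         center = ctr)
  movr <- apply_to_image(rot, ph$image)
  recr <- rigid_register(ph$image, movr)
  er <- rigid_errors(recr, rot, ctr)
  expect_lt(er["rotation_deg"], 0.5)
  expect_lt(er["translation_mm"], 0.5)

  far <- ph$image
  far$origin <- far$origin + 5000
  expect_error(rigid_register(ph$image, far), "overlap")
})

test_that("demons on identical images returns a near-zero field", {
  ph <- small_phantom(seed = 22)
  fld <- demons_register(ph$image, ph$image)
  mag <- sqrt(rowSums(fld$vectors^2))
  expect_lt(mean(mag), 0.1 * min(ph$image$spacing))
})

test_that("demons decreases the recorded similarity metric", {
  ph <- small_phantom(seed = 23)
  tr <- rigid_transform(translation = c(5, 0, -4))
  mov <- apply_to_image(tr, ph$image)
  fld <- demons_register(ph$image, mov)
  final <- fld$log[[length(fld$log)]]
  expect_lte(final$msd_final, final$msd_initial)
  expect_error(demons_register(ph$image,
                               tiny_image(array(NaN, dim(ph$image$values)),
                                          spacing = ph$image$spacing)),
               "finite|NaN")
})

test_that("demons recovers a known smooth displacement", {
  ph <- small_phantom(seed = 24)
  img <- ph$image
  d <- dim(img$values)
  idx <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
  pts <- voxel_to_physical(img, idx)
  w <- exp(-rowSums(sweep(pts, 2, ph$spec$heart$center)^2) / (2 * 20^2))
  vec <- cbind(0 * w, 2 * w, -5.7 * w)      # peak 6 mm
  truth_field <- deformation_field(vec, img)
  fixed <- apply_to_image(truth_field, img)

  rec <- demons_register(fixed, img)
  hr <- as.numeric(ph$heart$values) > 0
  err <- sqrt(rowSums((rec$vectors - vec)^2))
  expect_lt(mean(err[hr]), min(img$spacing))

  warped <- apply_to_mask(rec, ph$heart, fixed)
  displaced <- apply_to_mask(truth_field, ph$heart, fixed)
  expect_gte(dsc(warped, displaced), 0.95)
  expect_gte(field_positive_jacobian_fraction(rec, ph$heart), 0.99)
})

test_that("transform application follows interpolation contracts", {
  set.seed(25)
  img <- tiny_image(array(stats::rnorm(10^3), c(10, 10, 10)),
                    spacing = c(2, 2, 2))

  ident <- rigid_transform()
  expect_lt(max(abs(apply_to_image(ident, img)$values - img$values)), 1e-6)

  shift <- rigid_transform(translation = c(2, 0, 0))  # one voxel in x
  out <- apply_to_image(shift, img)
  expect_equal(out$values[1:9, , ], img$values[2:10, , ], tolerance = 1e-9)

  # shift then inverse shift: interior recovered within interpolation error
  zero <- deformation_field(matrix(0, 1000, 3), img)
  back <- apply_to_image(rigid_transform(translation = c(-2, 0, 0)), out)
  expect_equal(back$values[3:8, 3:8, 3:8], img$values[3:8, 3:8, 3:8],
               tolerance = 1e-9)

  m <- random_mask(c(10, 10, 10), p = 0.3, spacing = c(2, 2, 2))
  expect_identical(apply_to_mask(ident, m)$values, m$values)
  shifted <- apply_to_mask(shift, m)
  expect_equal(shifted$values[1:9, , ], m$values[2:10, , ])
  expect_true(all(shifted$values %in% c(0, 1)))
})

test_that("composition equals sequential application", {
  # a smooth analytic image keeps interpolation error far below the contrast
  d <- c(48, 48, 48)
  idx <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
  tmp <- hs_image(array(0, d), spacing = rep(160 / 48, 3))
  pts0 <- voxel_to_physical(tmp, idx)
  vals <- 500 * exp(-rowSums(sweep(pts0, 2, c(80, 70, 90))^2) / (2 * 30^2))
  img <- hs_image(array(vals, d), spacing = rep(160 / 48, 3))
  n <- prod(d)
  zero <- deformation_field(matrix(0, n, 3), img)
  pts <- pts0
  w <- exp(-rowSums(sweep(pts, 2, c(80, 80, 80))^2) / (2 * 25^2))
  fld <- deformation_field(cbind(3 * w, -2 * w, 2 * w), img)

  ident <- rigid_transform()
  expect_equal(compose_transforms(ident, fld)$vectors, fld$vectors,
               tolerance = 1e-12)

  rig <- rigid_transform(heartseg4d:::euler_rotation(c(0, 0, 0.05)),
                         c(3, -1, 2), heartseg4d:::phys_center(img))
  comp0 <- compose_transforms(rig, zero)
  a <- apply_to_image(comp0, img)
  b <- apply_to_image(rig, img)
  expect_lt(max(abs(a$values - b$values)), 1e-6)

  comp <- compose_transforms(rig, fld)
  seq1 <- apply_to_image(fld, apply_to_image(rig, img), img)
  direct <- apply_to_image(comp, img)
  rng <- diff(range(img$values))
  interior <- direct$values[5:44, 5:44, 5:44] - seq1$values[5:44, 5:44, 5:44]
  expect_lt(mean(abs(interior)) / rng, 1e-3)
})
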