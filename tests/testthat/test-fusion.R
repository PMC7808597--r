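# Label-fusion machinery. Constructed propagated-atlas lists let the
# consensus/selection/fusion operations be tested without running any
# registration.

fake_propagated <- function(mask, image = NULL, id = "a") {
  if (is.null(image))
    image <- hs_image(array(0, dim(mask$values)), mask$spacing, mask$origin,
                      mask$direction)
  structure(list(id = id, warped_image = image, warped_mask = mask,
                 deviation_mm = NA_real_),
            class = "propagated_atlas")
}

heart_ball <- function(center_vox = c(16, 16, 16), r_vox = 8,
                       dims = c(32, 32, 32), spacing = c(2.5, 2.5, 2.5)) {
  idx <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]),
                               seq_len(dims[3])))
  inside <- colSums((t(idx) - center_vox)^2) <= r_vox^2
  tiny_mask(array(as.numeric(inside), dims), spacing = spacing)
}

test_that("consensus is the strict per-voxel majority", {
  m <- heart_ball()
  same <- lapply(1:4, function(i) fake_propagated(m, id = paste0("a", i)))
  expect_identical(consensus_mask(same)$values, m$values)

  set.seed(31)
  rand <- lapply(1:5, function(i)
    fake_propagated(random_mask(c(6, 6, 6), p = 0.4), id = paste0("r", i)))
  cons <- consensus_mask(rand)
  expect_identical(cons$values,
                   oracle_majority(lapply(rand, function(p) p$warped_mask)))

  # 3 atlases: 2 votes in, 1 vote out
  v1 <- tiny_mask(array(0, c(3, 3, 3))); v1$values[1, 1, 1] <- 1
  v2 <- tiny_mask(array(0, c(3, 3, 3))); v2$values[1, 1, 1] <- 1
  v3 <- tiny_mask(array(0, c(3, 3, 3))); v3$values[2, 2, 2] <- 1
  c3 <- consensus_mask(lapply(list(v1, v2, v3), fake_propagated))
  expect_equal(c3$values[1, 1, 1], 1)
  expect_equal(c3$values[2, 2, 2], 0)
  # even split resolves to background
  v4 <- tiny_mask(array(0, c(3, 3, 3))); v4$values[2, 2, 2] <- 1
  c4 <- consensus_mask(lapply(list(v1, v2, v3, v4), fake_propagated))
  expect_equal(c4$values[2, 2, 2], 0)

  expect_error(consensus_mask(same[1:2]), "at least 3")
})

test_that("deviation scores are MASD to the consensus, order-independent", {
  # a mask displaced far beyond its own size scores its translation; a
  # single-voxel mask makes that exact
  m <- heart_ball(r_vox = 0)
  cons <- m
  shifted <- shift_mask(m, c(4, 0, 0))      # 4 voxels * 2.5 mm = 10 mm
  props <- list(fake_propagated(m, id = "same"),
                fake_propagated(shifted, id = "shifted"),
                fake_propagated(m, id = "same2"))
  scored <- atlas_deviation_scores(props, cons)
  expect_equal(scored[[1]]$deviation_mm, 0)
  expect_equal(scored[[2]]$deviation_mm, 10)
  rev_scored <- atlas_deviation_scores(rev(props), cons)
  expect_equal(scored[[2]]$deviation_mm, rev_scored[[2]]$deviation_mm)

  empty <- fake_propagated(tiny_mask(array(0, dim(m$values)),
                                     spacing = m$spacing), id = "empty")
  scored2 <- atlas_deviation_scores(list(empty), cons)
  expect_identical(scored2[[1]]$deviation_mm, Inf)
})

test_that("atlas selection fences outliers and respects the floor", {
  m <- heart_ball()
  mk <- function(dev, id) {
    p <- fake_propagated(m, id = id); p$deviation_mm <- dev; p
  }
  equal <- lapply(1:6, function(i) mk(1.3, paste0("e", i)))
  kept <- select_atlases(equal)
  expect_equal(length(kept), 6L)

  mixed <- c(lapply(1:7, function(i) mk(1 + 0.1 * i, paste0("c", i))),
             list(mk(25, "outlier")))
  kept2 <- select_atlases(mixed)
  log2 <- attr(kept2, "selection_log")
  expect_true(all(log2$decision[log2$id == "outlier"] == "rejected"))
  expect_false("outlier" %in% vapply(kept2, function(p) p$id, character(1)))

  # min_retained = n means nothing is ever rejected
  kept3 <- select_atlases(mixed, fusion_config(min_retained = 8))
  expect_equal(length(kept3), 8L)
  expect_error(select_atlases(mixed[1:2]), "min_retained")
})

test_that("local weights are inverse local disagreement", {
  set.seed(32)
  d <- c(8, 8, 8)
  tgt <- tiny_image(array(stats::rnorm(prod(d), 0, 50), d),
                    spacing = c(2.5, 2.5, 2.5))
  cfg <- fusion_config(patch_radius_mm = 5, epsilon = 1)

  w_same <- local_weight(tgt, tgt, cfg)
  expect_true(all(abs(w_same - 1) < 1e-12))   # 1/epsilon with epsilon = 1

  off <- tgt; off$values <- off$values + 100
  w_off <- local_weight(tgt, off, cfg)
  expect_true(all(w_same > w_off))

  # patch means match the exhaustive triple loop
  other <- tiny_image(array(stats::rnorm(prod(d), 0, 50), d),
                      spacing = c(2.5, 2.5, 2.5))
  w <- local_weight(tgt, other, cfg)
  rvox <- round(5 / 2.5)
  mad <- oracle_patch_mad(tgt$values, other$values, rep(rvox, 3))
  expect_equal(w, 1 / (1 + mad), tolerance = 1e-9)
  expect_true(all(is.finite(w)) && all(w > 0))
})

test_that("fusion reduces to its closed forms", {
  m <- heart_ball()
  cfg <- fusion_config()
  unan <- lapply(1:4, function(i) fake_propagated(m, id = paste0("u", i)))
  wts <- lapply(1:4, function(i) array(1, dim(m$values)))
  fused <- fuse_labels(unan, wts, cfg)
  expect_identical(fused$mask$values, m$values)
  expect_true(all(fused$probability %in% c(0, 1)))

  # equal weights reduce to majority vote with >= threshold ties included
  set.seed(33)
  rand <- lapply(1:4, function(i)
    fake_propagated(random_mask(c(5, 5, 5), p = 0.5), id = paste0("r", i)))
  wr <- lapply(1:4, function(i) array(2.7, c(5, 5, 5)))
  fr <- fuse_labels(rand, wr, cfg)
  votes <- Reduce(`+`, lapply(rand, function(p) p$warped_mask$values))
  expect_identical(fr$mask$values, array(as.numeric(votes / 4 >= 0.5),
                                         c(5, 5, 5)))

  # hand-built two-atlas case: weights (3, 1), masks (1, 0) -> p = 0.75
  a1 <- tiny_mask(array(1, c(2, 1, 1)))
  a2 <- tiny_mask(array(0, c(2, 1, 1)))
  f2 <- fuse_labels(list(fake_propagated(a1), fake_propagated(a2)),
                    list(array(3, c(2, 1, 1)), array(1, c(2, 1, 1))), cfg)
  expect_equal(as.numeric(f2$probability), c(0.75, 0.75))
  expect_equal(as.numeric(f2$mask$values), c(1, 1))
})

test_that("fusion probability is permutation-invariant and monotone", {
  set.seed(34)
  cfg <- fusion_config()
  d <- c(6, 6, 6)
  masks <- lapply(1:5, function(i) random_mask(d, p = 0.4))
  props <- lapply(seq_along(masks), function(i)
    fake_propagated(masks[[i]], id = paste0("p", i)))
  wts <- lapply(1:5, function(i) array(stats::runif(prod(d), 0.5, 3), d))

  f1 <- fuse_labels(props, wts, cfg)
  perm <- sample(5)
  f2 <- fuse_labels(props[perm], wts[perm], cfg)
  expect_equal(f1$probability, f2$probability, tolerance = 1e-12)
  expect_identical(f1$mask$values, f2$mask$values)
  expect_true(all(f1$probability >= 0 & f1$probability <= 1))

  # adding an all-ones atlas can only increase the probability
  extra <- fake_propagated(tiny_mask(array(1, d)), id = "ones")
  f3 <- fuse_labels(c(props, list(extra)),
                    c(wts, list(array(1, d))), cfg)
  expect_true(all(f3$probability >= f1$probability - 1e-12))
})

test_that("atlas propagation requires 3 atlases and recovers a self-atlas", {
  ph <- small_phantom(seed = 35)
  case <- heartseg4d:::crop_to_heart_voi(ph$image,
                                         list(heart = ph$heart))
  target <- case$image
  truth <- case$masks$heart
  atl <- list(atlas_entry("self", target, truth),
              atlas_entry("self2", target, truth),
              atlas_entry("self3", target, truth))
  expect_error(propagate_atlases(target, atl[1:2]), "at least 3")
  prop <- propagate_atlases(target, atl)
  expect_equal(length(prop), 3L)
  for (p in prop) expect_gte(dsc(p$warped_mask, truth), 0.99)
})
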