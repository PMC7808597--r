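test_that("constructors enforce geometry and value invariants", {
  expect_error(hs_image(array(1, c(2, 2, 2)), spacing = c(1, -1, 1)),
               "positive")
  expect_error(hs_image(array(c(1, NA), c(2, 2, 2))), "finite")
  expect_error(hs_image(array(1, c(2, 2, 2)),
                        direction = matrix(1, 3, 3)), "orthonormal")
  expect_error(hs_mask(array(2, c(2, 2, 2))), "0 or 1")
  expect_error(voxel_box(c(2, 0, 0), c(1, 4, 4)), "lo <= hi")
})

test_that("write/read round-trips preserve values and geometry", {
  set.seed(42)
  img <- tiny_image(array(stats::rnorm(4^3, sd = 300), c(4, 4, 4)),
                    spacing = c(2, 2.5, 3), origin = c(10, -5, 2))
  msk <- tiny_mask(array(as.numeric(stats::runif(4^3) < 0.4), c(4, 4, 4)),
                   spacing = c(2, 2.5, 3), origin = c(10, -5, 2))
  for (ext in c(".nii.gz", ".nii", ".mha")) {
    f <- tempfile(fileext = ext)
    write_volume(img, f)
    r <- read_volume(f)
    expect_lt(max(abs(r$values - img$values)), 1e-6)
    expect_lt(max(abs(r$spacing - img$spacing)), 1e-6)
    expect_lt(max(abs(r$origin - img$origin)), 1e-6)
    expect_lt(max(abs(r$direction - img$direction)), 1e-6)
    fm <- tempfile(fileext = ext)
    write_volume(msk, fm)
    rm2 <- read_volume(fm, as_mask = TRUE)
    expect_identical(rm2$values, msk$values)
  }
})

test_that("constant 4^3 volume round-trips exactly", {
  img <- tiny_image(array(7, c(4, 4, 4)))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(img, f)
  r <- read_volume(f)
  expect_equal(r$values, img$values)
})

test_that("mask reading binarizes nonzero values", {
  vals <- array(0, c(3, 3, 3)); vals[2, 2, 2] <- 2; vals[1, 1, 1] <- 2
  img <- tiny_image(vals)
  f <- tempfile(fileext = ".mha")
  write_volume(img, f)
  m <- read_volume(f, as_mask = TRUE)
  expect_true(all(m$values %in% c(0, 1)))
  expect_equal(sum(m$values), 2)
})

test_that("unreadable input is rejected with a diagnostic", {
  expect_error(read_volume(tempfile(fileext = ".nii")), "not found")
  bad <- tempfile(fileext = ".mha")
  writeLines(c("ObjectType = Image", "NDims = 3", "DimSize = 4 4 4",
               "ElementType = MET_DOUBLE", "ElementDataFile = LOCAL"), bad)
  expect_error(read_volume(bad), "truncated")
  xyz <- tempfile(fileext = ".xyz")
  writeLines("not an image", xyz)
  expect_error(read_volume(xyz), "unsupported")
})

test_that("resampling onto the source grid is the identity", {
  set.seed(1)
  img <- tiny_image(array(stats::rnorm(5^3), c(5, 5, 5)), spacing = c(2, 1, 3))
  out <- resample(img, img, "linear")
  expect_lt(max(abs(out$values - img$values)), 1e-6)
})

test_that("mask resampling is closed over {0,1}", {
  set.seed(2)
  m <- random_mask(c(6, 6, 6), spacing = c(2, 2, 2))
  ref <- tiny_image(array(0, c(9, 9, 9)), spacing = c(1.3, 1.3, 1.3),
                    origin = c(0.4, -0.2, 0.7))
  for (interp in c("nearest", "linear")) {
    out <- resample(m, ref, interp)
    expect_true(all(out$values %in% c(0, 1)))
  }
})

test_that("constant images stay constant inside the support", {
  img <- tiny_image(array(55, c(8, 8, 8)), spacing = c(2, 2, 2))
  ref <- tiny_image(array(0, c(5, 5, 5)), spacing = c(2.1, 2.1, 2.1),
                    origin = c(1, 1, 1))
  out <- resample(img, ref, "linear")
  expect_true(all(abs(out$values - 55) < 1e-9))
})

test_that("crop preserves physical coordinates and composes", {
  set.seed(3)
  img <- tiny_image(array(stats::rnorm(8^3), c(8, 8, 8)),
                    spacing = c(1.5, 2, 2.5), origin = c(5, 6, 7))
  full <- crop(img, voxel_box(c(0, 0, 0), c(8, 8, 8)))
  expect_equal(full$values, img$values)
  expect_equal(full$origin, img$origin)

  box <- voxel_box(c(2, 2, 2), c(6, 6, 6))
  cr <- crop(img, box)
  expect_equal(dim(cr$values), c(4L, 4L, 4L))
  expect_equal(as.numeric(voxel_to_physical(cr, c(0, 0, 0))),
               as.numeric(voxel_to_physical(img, box$lo)))

  # nested crops equal the composed crop
  cr2 <- crop(cr, voxel_box(c(1, 0, 2), c(3, 4, 4)))
  direct <- crop(img, voxel_box(c(3, 2, 4), c(5, 6, 6)))
  expect_equal(cr2$values, direct$values)
  expect_equal(cr2$origin, direct$origin)

  expect_error(crop(img, voxel_box(c(0, 0, 0), c(9, 8, 8))), "outside")
})

test_that("mask bounding boxes contain every foreground voxel", {
  m <- tiny_mask(array(0, c(8, 8, 8)))
  m$values[4, 4, 4] <- 1
  b <- mask_bounding_box(m, 0)
  expect_equal(b$lo, rep(3L, 3))
  expect_equal(b$hi, rep(4L, 3))

  m2 <- tiny_mask(array(0, c(8, 8, 8)), spacing = c(2.5, 2.5, 2.5))
  m2$values[4, 4, 4] <- 1
  b2 <- mask_bounding_box(m2, 5)     # ceil(5/2.5) = 2 voxels
  expect_equal(b2$lo, rep(1L, 3))
  expect_equal(b2$hi, rep(6L, 3))

  set.seed(4)
  for (rep in 1:20) {
    mr <- random_mask(c(7, 7, 7), p = 0.05)
    br <- mask_bounding_box(mr, 0)
    w <- which(mr$values > 0, arr.ind = TRUE) - 1
    expect_true(all(t(w) >= br$lo) && all(t(w) < br$hi))
  }
  expect_error(mask_bounding_box(tiny_mask(array(0, c(3, 3, 3)))), "empty")
})
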