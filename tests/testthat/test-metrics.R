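test_that("surface extraction matches counting and the exhaustive scan", {
  m1 <- tiny_mask(array(0, c(5, 5, 5)))
  m1$values[3, 3, 3] <- 1
  sp <- surface_points(m1)
  expect_equal(nrow(sp), 1L)
  expect_equal(as.numeric(sp), c(2, 2, 2))

  cube <- tiny_mask(array(0, c(5, 5, 5)))
  cube$values[2:4, 2:4, 2:4] <- 1
  expect_equal(nrow(surface_points(cube)), 26L)

  set.seed(11)
  for (rep in 1:10) {
    m <- random_mask(c(6, 6, 6), p = 0.3, spacing = c(1.5, 1, 2))
    got <- surface_points(m)
    want <- oracle_surface_points(m)
    expect_equal(got[order(got[, 1], got[, 2], got[, 3]), , drop = FALSE],
                 want[order(want[, 1], want[, 2], want[, 3]), , drop = FALSE],
                 ignore_attr = TRUE)
  }
  expect_error(surface_points(tiny_mask(array(0, c(3, 3, 3)))), "empty")
})

test_that("dsc follows its closed form", {
  a <- tiny_mask(array(0, c(4, 4, 4))); a$values[1:2, 1:4, 1] <- 1
  expect_equal(dsc(a, a), 1.0)
  b <- tiny_mask(array(0, c(4, 4, 4))); b$values[3:4, 1:4, 4] <- 1
  expect_equal(dsc(a, b), 0.0)
  c2 <- tiny_mask(array(0, c(4, 4, 4))); c2$values[1:2, 1:2, 1] <- 1
  c2$values[3:4, 3:4, 4] <- 1  # |B|=8, |A and B| = 4
  expect_equal(dsc(a, c2), 0.5)
  expect_equal(dsc(a, c2), dsc(c2, a))
  empty <- tiny_mask(array(0, c(4, 4, 4)))
  expect_error(dsc(empty, empty), "empty")
  off <- tiny_mask(array(1, c(4, 4, 4)), origin = c(1, 0, 0))
  expect_error(dsc(a, off), "share a grid")
})

test_that("masd and hd reproduce hand cases and the brute-force oracle", {
  a <- tiny_mask(array(0, c(8, 8, 8))); a$values[1, 1, 1] <- 1
  b <- tiny_mask(array(0, c(8, 8, 8))); b$values[4, 5, 1] <- 1
  expect_equal(masd(a, b), 5.0)          # 3-4-5 triangle
  expect_equal(hd(a, b), 5.0)
  expect_equal(masd(a, a), 0.0)
  expect_equal(hd(a, a), 0.0)

  set.seed(12)
  for (rep in 1:25) {
    sp <- sample(c(1, 1.5, 2.5), 3, replace = TRUE)
    ma <- random_mask(c(8, 8, 8), p = 0.15, spacing = sp)
    mb <- random_mask(c(8, 8, 8), p = 0.15, spacing = sp)
    expect_equal(masd(ma, mb), oracle_masd(ma, mb), tolerance = 1e-9)
    expect_equal(hd(ma, mb), oracle_hd(ma, mb), tolerance = 1e-9)
    expect_gte(hd(ma, mb), masd(ma, mb))
    expect_equal(masd(ma, mb), masd(mb, ma))
    expect_equal(hd(ma, mb), hd(mb, ma))
  }
})

test_that("cohort tables aggregate mean and sample sd per phase", {
  res <- data.frame(patient = c("P1", "P2", "P3"), phase = "0%",
                    dsc = c(0.90, 0.92, 0.94),
                    masd_mm = c(1, 2, 3), hd_mm = c(5, 6, 7))
  tab <- cohort_table(res)
  r0 <- tab[tab$phase == "0%", ]
  expect_equal(r0$dsc_mean, 0.92)
  expect_equal(r0$dsc_sd, stats::sd(c(0.90, 0.92, 0.94)))
  expect_equal(attr(tab, "n"), 3L)

  single <- cohort_table(res[1, ])
  expect_equal(single$dsc_sd[1], 0)

  # pooled all-phases row equals the mean over the flattened value list
  res2 <- rbind(res, transform(res, phase = "50%", dsc = dsc + 0.01))
  tab2 <- cohort_table(res2)
  pooled <- tab2[tab2$phase == "Average (all phases)", ]
  expect_equal(pooled$dsc_mean, mean(res2$dsc))
  expect_equal(pooled$masd_mean_mm, mean(res2$masd_mm))

  # PRV rows aggregate separately
  res3 <- rbind(res, transform(res, phase = "PRV"))
  tab3 <- cohort_table(res3)
  expect_true("PRV" %in% tab3$phase)
  expect_false("PRV" %in% tab3$phase[tab3$phase == "Average (all phases)"])
  expect_error(cohort_table(res[0, ]), "nonempty")
})

test_that("cohort tables write as CSV", {
  res <- data.frame(patient = "P1", phase = "0%", dsc = 0.9, masd_mm = 1,
                    hd_mm = 4)
  f <- tempfile(fileext = ".csv")
  write_cohort_table(cohort_table(res), f)
  back <- utils::read.csv(f)
  expect_equal(back$dsc_mean[1], 0.9)
})
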