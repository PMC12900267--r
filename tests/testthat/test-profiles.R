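test_that("treatments at the control median give a zero profile", {
  set.seed(1)
  ctrl <- matrix(rep(c(1, 2, 3, 4, 5), 6), 5, 6)  # per-feature median 3
  trt <- matrix(3, 1, 6)
  prof <- zscoreProfiles(make_plate(ctrl, list(cpdA = trt)))
  expect_equal(unname(zMatrix(prof)[, 1]), rep(0, 6))
  expect_equal(unname(induction(prof)), 0)
  expect_false(unname(isActive(prof)))
})

test_that("z-scores follow the robust median/MAD arithmetic", {
  # single feature, controls {1,2,3,4,5}: median 3, MAD 1, scale 1.4826
  ctrl <- matrix(c(1, 2, 3, 4, 5), 5, 2)
  ctrl[, 2] <- c(10, 20, 30, 40, 50)  # second feature keeps the plate honest
  trt <- matrix(c(6, 30), 1, 2)
  prof <- zscoreProfiles(make_plate(ctrl, list(cpdA = trt)))
  expect_equal(zMatrix(prof)["f_0001", 1], (6 - 3) / 1.4826)
  expect_equal(zMatrix(prof)["f_0002", 1], 0)
})

test_that("induction applies the >= 5 percent activity rule at the boundary", {
  z29 <- c(rep(3.5, 29), rep(0, 550))
  r29 <- induction(z29)
  expect_equal(r29$induction, 100 * 29 / 579)
  expect_true(r29$active)
  z28 <- c(rep(3.5, 28), rep(0, 551))
  r28 <- induction(z28)
  expect_equal(r28$induction, 100 * 28 / 579)
  expect_false(r28$active)
  # exactly at theta counts as altered
  expect_equal(induction(c(3, rep(0, 9)))$induction, 10)
})

test_that("well order does not affect the profiles", {
  set.seed(9)
  ctrl <- matrix(rnorm(6 * 5, 50, 2), 6, 5)
  trt <- matrix(rnorm(4 * 5, 55, 2), 4, 5)
  plate <- make_plate(ctrl, list(a = trt[1:2, ], b = trt[3:4, ]))
  perm <- sample(ncol(plate))
  shuffled <- plate[, perm]
  p1 <- zscoreProfiles(plate)
  p2 <- zscoreProfiles(shuffled)
  expect_identical(zMatrix(p1), zMatrix(p2))
  expect_identical(induction(p1), induction(p2))
})

test_that("replicate wells are aggregated by median before scaling", {
  ctrl <- matrix(rep(c(1, 2, 3, 4, 5), 2), 5, 2)
  reps <- matrix(c(5, 6, 10, 3, 3, 3), 3, 2)  # medians 6 and 3
  prof <- zscoreProfiles(make_plate(ctrl, list(a = reps)))
  expect_identical(ncol(prof), 1L)
  expect_equal(zMatrix(prof)["f_0001", 1], (6 - 3) / 1.4826)
  expect_equal(zMatrix(prof)["f_0002", 1], 0)
})

test_that("fewer than 4 control wells is fatal", {
  ctrl <- matrix(1:9 + 0, 3, 3)
  trt <- matrix(1, 1, 3)
  expect_error(zscoreProfiles(make_plate(ctrl, list(a = trt))), "4 control")
})

test_that("zero-MAD features get a substituted scale and are flagged", {
  ctrl <- cbind(
    c(1, 2, 3, 4, 5),        # healthy feature
    c(3, 3, 3, 3, 9),        # MAD 0, not constant
    c(7, 7, 7, 7, 7)         # constant: excluded
  )
  trt <- matrix(c(3, 9, 7), 1, 3)
  prof <- suppressWarnings(zscoreProfiles(make_plate(ctrl, list(a = trt))))
  rd <- rowData(prof)
  expect_identical(unname(rd$mad_substituted), c(FALSE, TRUE, FALSE))
  expect_identical(unname(rd$excluded), c(FALSE, FALSE, TRUE))
  # substituted scale = smallest positive control MAD (feature 1: MAD 1)
  expect_equal(zMatrix(prof)["f_0002", 1], (9 - 3) / 1.4826)
  expect_true(is.na(zMatrix(prof)["f_0003", 1]))
  # excluded feature leaves the induction denominator
  expect_equal(unname(induction(prof)), 100 * 1 / 2)
})

test_that("biosimilarity has the definitional fixed points", {
  set.seed(4)
  p <- rnorm(20)
  expect_equal(biosimilarity(p, p)$biosim, 100)
  expect_true(biosimilarity(p, p)$similar)
  expect_equal(biosimilarity(p, -p)$biosim, -100)
  expect_false(biosimilarity(p, -p)$similar)
  expect_equal(biosimilarity(c(1, 2, 3, 4), c(2, 4, 6, 8))$biosim, 100)
})

test_that("biosimilarity is scale-invariant with the sign of the factor", {
  set.seed(5)
  p <- rnorm(15)
  expect_equal(biosimilarity(2.7 * p, p)$biosim, 100)
  expect_equal(biosimilarity(-0.3 * p, p)$biosim, -100)
})

test_that("constant profiles raise an undefined-correlation error", {
  expect_error(biosimilarity(rep(1, 5), rnorm(5)), "undefined correlation")
  expect_error(biosimilarity(rnorm(2), rnorm(2)), "fewer than 3")
})

test_that("biosimilarity matrices have forced structure", {
  set.seed(6)
  p <- rnorm(12)
  m <- biosimMatrix(cbind(a = p, b = p, c = -p))
  expect_equal(m, rbind(
    a = c(100, 100, -100), b = c(100, 100, -100), c = c(-100, -100, 100)
  ), ignore_attr = TRUE)
  q <- matrix(rnorm(12 * 4), 12, 4)
  mq <- biosimMatrix(q)
  expect_true(isSymmetric(mq))
  expect_identical(unname(diag(mq)), rep(100, 4))
  expect_equal(mq[2, 3], biosimilarity(q[, 2], q[, 3])$biosim)
})

test_that("profile CSV export round-trips induction and z values", {
  set.seed(10)
  ctrl <- matrix(rnorm(6 * 8, 10), 6, 8)
  trt <- matrix(rnorm(2 * 8, 14), 2, 8)
  prof <- zscoreProfiles(make_plate(ctrl, list(a = trt)))
  f <- withr::local_tempfile(fileext = ".csv")
  writeProfiles(prof, f)
  back <- utils::read.csv(f)
  expect_equal(back$induction, unname(induction(prof)))
  expect_equal(
    unname(as.matrix(back[, grepl("^f_", colnames(back))])[1, ]),
    unname(zMatrix(prof)[, 1])
  )
})
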