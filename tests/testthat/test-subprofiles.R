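toy_members <- function() {
  # 6 features x 3 members: features 1-3 consistently positive,
  # features 4-6 mixed in sign across members
  z <- cbind(
    m1 = c(3, 4, 2, 1.5, -2, 3),
    m2 = c(2.5, 3.5, 2.2, -1.5, 2, -3),
    m3 = c(3.2, 4.1, 2.4, 2.0, -2.5, 3.1)
  )
  rownames(z) <- sprintf("f_%04d", 1:6)
  z
}

test_that("same-direction features are selected with their medians", {
  z <- toy_members()
  sub <- suppressWarnings(extractSubprofile(z, "toy", consistency = 1, minAbsMedian = 1))
  expect_identical(featureIds(sub), sprintf("f_%04d", 1:3))
  expect_equal(
    unname(subprofileValues(sub)),
    unname(apply(z[1:3, ], 1, median))
  )
  expect_identical(sub@memberIds, c("m1", "m2", "m3"))
})

test_that("identical members keep all features above the magnitude cutoff", {
  p <- c(f_0001 = 4, f_0002 = -3, f_0003 = 0.5, f_0004 = 2)
  z <- cbind(m1 = p, m2 = p)
  sub <- extractSubprofile(z, "id", consistency = 1, minAbsMedian = 1)
  expect_identical(featureIds(sub), c("f_0001", "f_0002", "f_0004"))
  expect_equal(subprofileValues(sub), p[c(1, 2, 4)])
})

test_that("one sign-flipped member excludes a feature at strict consistency", {
  p <- c(f_0001 = 4, f_0002 = 3, f_0003 = 2)
  z <- cbind(m1 = p, m2 = p, m3 = p)
  z["f_0002", 3] <- -3
  sub <- suppressWarnings(extractSubprofile(z, "flip", consistency = 1))
  expect_false("f_0002" %in% featureIds(sub))
  # relaxed consistency readmits it
  sub2 <- suppressWarnings(extractSubprofile(z, "flip", consistency = 0.6))
  expect_true("f_0002" %in% featureIds(sub2))
})

test_that("empty selections fail with actionable guidance", {
  z <- cbind(m1 = c(a = 0.1, b = -0.1, c = 0.2), m2 = c(a = 0.1, b = -0.1, c = 0.2))
  expect_error(
    extractSubprofile(z, "none", minAbsMedian = 1),
    "no consistent features"
  )
})

test_that("member order does not change the subprofile", {
  z <- toy_members()
  a <- suppressWarnings(extractSubprofile(z, "x"))
  b <- suppressWarnings(extractSubprofile(z[, c(3, 1, 2)], "x"))
  expect_identical(featureIds(a), featureIds(b))
  expect_identical(subprofileValues(a), subprofileValues(b))
})

test_that("non-biosimilar members trigger a warning, not an error", {
  tail <- seq(-8, 8, length.out = 20)
  z <- cbind(m1 = c(rep(5, 10), tail), m2 = c(rep(5, 10), -tail))
  rownames(z) <- sprintf("f_%04d", 1:30)
  expect_warning(extractSubprofile(z, "w", minAbsMedian = 1), "biosimilarity")
})

test_that("cluster biosimilarity has identity and antisymmetry fixed points", {
  z <- toy_members()
  sub <- suppressWarnings(extractSubprofile(z, "toy"))
  p <- rep(0, 6)
  names(p) <- rownames(z)
  p[featureIds(sub)] <- subprofileValues(sub)
  expect_equal(clusterBiosim(p, sub), 100)
  expect_equal(clusterBiosim(-p, sub), -100)
})

test_that("too few shared features is an explicit error", {
  sub <- new(
    "Subprofile", clusterName = "tiny",
    featureIds = c("a", "b"), values = c(a = 2, b = 3),
    memberIds = "m", consistency = 1, minAbsMedian = 1
  )
  expect_error(clusterBiosim(c(a = 1, b = 2, c = 3), sub), "too small")
})

test_that("assignment recovers the generating cluster under noise", {
  set.seed(31)
  nf <- 60
  fid <- sprintf("f_%04d", seq_len(nf))
  mk <- function(idx, val) {
    v <- rep(0, nf)
    names(v) <- fid
    v[idx] <- val
    v
  }
  vA <- seq(2, 6, length.out = 15)
  subA <- new("Subprofile", clusterName = "A", featureIds = fid[1:15],
              values = structure(vA, names = fid[1:15]),
              memberIds = "r1", consistency = 1, minAbsMedian = 1)
  subB <- new("Subprofile", clusterName = "B", featureIds = fid[31:45],
              values = structure(-vA, names = fid[31:45]),
              memberIds = "r2", consistency = 1, minAbsMedian = 1)
  model <- clusterModel(list(subA, subB))
  prof <- mk(1:15, vA + rnorm(15, 0, 0.1))
  prof <- prof + rnorm(nf, 0, 0.1)
  asg <- assignClusters(matrix(prof, dimnames = list(fid, "p1")), model)
  expect_identical(asg$best_cluster, "A")
  # orthogonal profile: no cluster reaches the threshold
  ortho <- mk(16:30, 5)
  asgO <- assignClusters(matrix(ortho, dimnames = list(fid, "o")), model)
  expect_true(is.na(asgO$best_cluster))
})

test_that("ties go to the first-declared cluster and are logged", {
  fid <- sprintf("f_%04d", 1:10)
  vals <- structure(c(4, 3, 5, -2, 2), names = fid[1:5])
  mkSub <- function(nm) new(
    "Subprofile", clusterName = nm, featureIds = fid[1:5], values = vals,
    memberIds = "m", consistency = 1, minAbsMedian = 1
  )
  model <- clusterModel(list(mkSub("first"), mkSub("second")))
  p <- structure(c(vals, rep(0, 5)), names = fid)
  expect_message(
    asg <- assignClusters(matrix(p, dimnames = list(fid, "p")), model),
    "tie.*first-declared"
  )
  expect_identical(asg$best_cluster, "first")
})

test_that("features outside every subprofile cannot change the scores", {
  z <- toy_members()
  sub <- suppressWarnings(extractSubprofile(z, "toy"))
  p <- structure(c(2, 3, 1.5, 9, -9, 4), names = rownames(z))
  full <- clusterBiosim(p, sub)
  reduced <- clusterBiosim(p[featureIds(sub)], sub)
  expect_equal(full, reduced)
})

test_that("cluster models serialize to JSON and back", {
  z <- toy_members()
  sub <- suppressWarnings(extractSubprofile(z, "toy"))
  model <- clusterModel(list(sub))
  f <- withr::local_tempfile(fileext = ".json")
  writeClusterModel(model, f)
  back <- readClusterModel(f)
  expect_identical(clusterNames(back), "toy")
  s2 <- subprofiles(back)[["toy"]]
  expect_identical(featureIds(s2), featureIds(sub))
  expect_equal(subprofileValues(s2), subprofileValues(sub))
  expect_identical(s2@consistency, sub@consistency)
})
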