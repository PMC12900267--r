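small_spec <- function(...) {
  syntheticPlateSpec(
    nFeatures = 120, nControls = 12, k = 2, sPerCluster = 12,
    nPerCluster = 3, nInactive = 2, nReplicates = 2, ...
  )
}

test_that("plate generation is deterministic given the seed", {
  g1 <- genPlate(small_spec(seed = 5))
  g2 <- genPlate(small_spec(seed = 5))
  expect_identical(assay(g1$plate, "features"), assay(g2$plate, "features"))
  expect_identical(g1$truth, g2$truth)
  g3 <- genPlate(small_spec(seed = 6))
  expect_false(identical(assay(g1$plate, "features"), assay(g3$plate, "features")))
})

test_that("zero amplitude yields a null plate downstream", {
  # calibrated layout: 32-well DMSO panel, quadruplicate treatments
  spec <- syntheticPlateSpec(
    nFeatures = 200, nControls = 32, k = 2, sPerCluster = 20,
    nPerCluster = 0, nInactive = 60, amplitude = 0,
    concentrations = 10, seed = 3
  )
  prof <- zscoreProfiles(genPlate(spec)$plate)
  expect_lt(mean(induction(prof)), 1)
  expect_lt(mean(isActive(prof)), 0.02)
})

test_that("planted effects land in the expected induction range", {
  spec <- syntheticPlateSpec(
    k = 1, nPerCluster = 1, nInactive = 0, amplitude = 10, seed = 4
  )
  gen <- genPlate(spec)
  prof <- zscoreProfiles(gen$plate)
  top <- colData(prof)$concentration_um == 50
  # 10% of features carry the effect at ~8 sigma: induction close to 10%
  expect_gte(unname(induction(prof)[top]), 5)
  expect_lte(unname(induction(prof)[top]), 15)
})

test_that("ground truth is consistent with the generating spec", {
  spec <- small_spec(seed = 9)
  gen <- genPlate(spec)
  expect_identical(
    sort(unique(na.omit(gen$truth$cluster_labels))),
    c("cluster_1", "cluster_2")
  )
  expect_identical(lengths(gen$truth$effect_features), c(cluster_1 = 12L, cluster_2 = 12L))
  # templates are unit-norm and orthogonal (disjoint supports)
  tm <- gen$truth$templates
  expect_equal(colSums(tm^2), c(cluster_1 = 1, cluster_2 = 1))
  expect_equal(sum(tm[, 1] * tm[, 2]), 0)
  # expected means: controls sit at baseline for every feature
  ctrlWells <- colnames(gen$plate)[colData(gen$plate)$is_control]
  em <- gen$truth$expected_mean[ctrlWells, ]
  expect_true(all(apply(em, 2, function(x) length(unique(x)) == 1)))
})

test_that("toy compound classes are fully parseable with the curated contrasts", {
  cs <- genToyCompoundClasses(1)
  expect_identical(nSkipped(cs), 0L)
  expect_length(cs, 36)
  labs <- classLabels(cs)
  expect_setequal(unique(labs), c("np_like", "drug_like"))
  v <- nsps(cs)
  expect_gt(mean(v[labs == "np_like"]), mean(v[labs == "drug_like"]))
  hits <- matchesSubstructure(cs, aohiSmarts())
  expect_identical(sum(hits), 1L)
  expect_identical(names(hits)[hits], "mesembrine")
})

test_that("toy class content is seed-independent (only order shuffles)", {
  a <- genToyCompoundClasses(1)
  b <- genToyCompoundClasses(2)
  expect_setequal(unname(structures(a)), unname(structures(b)))
})

test_that("synthetic traces reproduce their targets exactly at zero noise", {
  targets <- list(basal = 80, proton_leak = 20, maximal = 130,
                  non_mitochondrial = 20)
  tr <- genOCRTrace(targets)
  mp <- mitoParams(tr)
  expect_identical(mp@basal, 80)
  expect_identical(mp@proton_leak, 20)
  expect_identical(mp@maximal, 130)
  expect_identical(mp@non_mitochondrial, 20)
  expect_identical(mp@atp_linked, 60)
  expect_identical(mp@spare_capacity, 50)
})

test_that("zero spare capacity makes the FCCP phase match baseline", {
  tr <- genOCRTrace(list(basal = 70, proton_leak = 10, maximal = 70,
                         non_mitochondrial = 15))
  pm <- phaseMeans(tr)
  expect_equal(pm$ocr_mean[pm$label == "FCCP"], pm$ocr_mean[pm$label == "baseline"])
  expect_equal(mitoParams(tr)@spare_capacity, 0)
})

test_that("inconsistent targets are rejected", {
  expect_error(
    genOCRTrace(list(basal = 80, proton_leak = 20, maximal = 130,
                     non_mitochondrial = 20, atp_linked = 10)),
    "atp_linked"
  )
  expect_error(
    genOCRTrace(list(basal = 80, proton_leak = 20, maximal = 130,
                     non_mitochondrial = 20, spare_capacity = 99)),
    "spare_capacity"
  )
})

test_that("noisy traces recover the basal target within the CLT bound", {
  targets <- list(basal = 80, proton_leak = 20, maximal = 130,
                  non_mitochondrial = 20)
  sigma <- 4
  basals <- vapply(1:60, function(s) {
    mitoParams(genOCRTrace(targets, noise = sigma, seed = s))@basal
  }, numeric(1))
  # each basal is a difference of two 3-point phase means: sd = sigma*sqrt(2/3)
  se <- sigma * sqrt(2 / 3) / sqrt(60)
  expect_lt(abs(mean(basals) - 80), 4 * se)
})
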