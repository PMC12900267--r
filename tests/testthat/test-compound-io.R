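test_that("SMILES files are read, canonicalized and skip-counted", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO", "c1ccccc1", "CC(=O)O"), f)
  cs <- readCompounds(f)
  expect_s4_class(cs, "CompoundSet")
  expect_length(cs, 3)
  expect_identical(nSkipped(cs), 0L)

  writeLines(c("CCO", "c1ccccc1", "C(", "CC(=O)O"), f)
  cs <- readCompounds(f)
  expect_length(cs, 3)
  expect_identical(nSkipped(cs), 1L)

  writeLines(character(), f)
  expect_error(readCompounds(f), "zero parseable")
  writeLines(c("C(", "xx"), f)
  expect_error(readCompounds(f), "zero parseable")
  expect_error(readCompounds("/nonexistent/x.smi"), "not found")
})

test_that("tab-separated ids and labels are honored; duplicate ids are fatal", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO\tm1\tsolvent", "c1ccccc1\tm2\tarene"), f)
  cs <- readCompounds(f)
  expect_identical(compoundIds(cs), c("m1", "m2"))
  expect_identical(unname(classLabels(cs)), c("solvent", "arene"))

  writeLines(c("CCO\tm1", "c1ccccc1\tm1"), f)
  expect_error(readCompounds(f), "m1")
})

test_that("CSV compound files round-trip through writeCompounds", {
  cs <- compoundSet(
    c("OCC", "c1ccccc1C", "CC(N)C(=O)O"),
    ids = c("a", "b", "c"), labels = c("x", "x", "y")
  )
  f <- withr::local_tempfile(fileext = ".csv")
  writeCompounds(cs, f)
  back <- readCompounds(f, format = "csv")
  expect_identical(structures(back), structures(cs))
  expect_identical(classLabels(back), classLabels(cs))
})

test_that("SDF input is parsed via the structure backend", {
  sdf <- withr::local_tempfile(fileext = ".sdf")
  # minimal V2000 records: ethanol and methane
  block <- function(name, atoms, bonds, atomLines, bondLines) {
    c(
      name, "  toy", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", atoms, bonds),
      atomLines, bondLines, "M  END", "$$$$"
    )
  }
  ethanol <- block(
    "ethanol", 3, 2,
    c(
      "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
      "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
      "    2.2000    1.2000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0"
    ),
    c("  1  2  1  0", "  2  3  1  0")
  )
  methane <- block(
    "methane", 1, 0,
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    character()
  )
  writeLines(c(ethanol, methane), sdf)
  cs <- readCompounds(sdf)
  expect_length(cs, 2)
  expect_setequal(unname(structures(cs)), c("CCO", "C"))
})

test_that("canonicalization is idempotent and keeps the largest fragment", {
  first <- canonicalizeSmiles(c("OCC", "C1=CC=CC=C1", "CCO.[Na+]"))
  again <- canonicalizeSmiles(first$canonical)
  expect_identical(again$canonical, first$canonical)
  expect_identical(first$canonical[3], "CCO")
})

test_that("duplicate structures within a label are dropped with a warning", {
  expect_warning(
    cs <- compoundSet(c("CCO", "OCC"), ids = c("a", "b"), labels = "x"),
    "duplicate"
  )
  expect_length(cs, 1)
  # same structure under different labels is allowed
  cs2 <- compoundSet(c("CCO", "OCC"), ids = c("a", "b"), labels = c("x", "y"))
  expect_length(cs2, 2)
})

test_that("feature tables read with preserved values, row order and metadata", {
  f <- withr::local_tempfile(fileext = ".csv")
  lines <- c(
    "plate_id,well_id,compound_id,concentration_um,is_control,g1,g2,g3,g4,g5,g6",
    sprintf("P1,w%03d,NA,NA,TRUE,%g,%g,%g,%g,%g,%g", 1:4, 1:4, 2, 3, 4, 5, 6),
    sprintf("P1,w%03d,cpdA,10,FALSE,%g,7,8,9,10,11", 5:8, 5:8)
  )
  writeLines(lines, f)
  plate <- readFeatureTable(f)
  expect_s4_class(plate, "PlateData")
  expect_identical(dim(assay(plate, "features")), c(6L, 8L))  # F x wells
  expect_identical(colnames(plate), sprintf("w%03d", 1:8))
  expect_identical(assay(plate, "features")["g1", "w006"], 6)
})

test_that("malformed feature cells are fatal with a cell address", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "plate_id,well_id,compound_id,concentration_um,is_control,g1,g2",
    "P1,w1,NA,NA,TRUE,1,2",
    "P1,w2,NA,NA,TRUE,1,oops",
    "P1,w3,NA,NA,TRUE,1,2",
    "P1,w4,cpd,10,FALSE,3,"
  ), f)
  expect_error(readFeatureTable(f), "row 2, column 'g2'")
})

test_that("feature tables round-trip at full precision", {
  set.seed(5)
  ctrl <- matrix(rnorm(5 * 7, 100, 3), 5, 7)
  trt <- matrix(rnorm(2 * 7, 100, 3), 2, 7)
  plate <- make_plate(ctrl, list(cpdA = trt))
  f <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(plate, f)
  back <- readFeatureTable(f)
  expect_identical(assay(back, "features"), assay(plate, "features"))
  expect_identical(as.data.frame(colData(back)), as.data.frame(colData(plate)))
})

test_that("writing honors the standard feature count and rejects empty tables", {
  set.seed(6)
  plate <- make_plate(
    matrix(rnorm(4 * 579), 4, 579),
    list(a = matrix(rnorm(579), 1, 579))
  )
  f <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(plate, f)
  header <- strsplit(readLines(f, n = 1), ",")[[1]]
  expect_length(header, 579 + 5)
  empty <- plate[, FALSE]
  expect_error(writeFeatureTable(empty, f), "empty")
})

test_that("plate validity enforces well annotation rules", {
  ctrl <- matrix(1:12 + 0, 4, 3)
  meta <- data.frame(
    plate_id = "P", well_id = paste0("w", 1:4),
    compound_id = c(NA, NA, NA, "x"),
    concentration_um = c(NA, NA, NA, -2),
    is_control = c(TRUE, TRUE, TRUE, FALSE)
  )
  expect_error(plateData(ctrl, meta), "positive")
  meta$concentration_um[4] <- 10
  expect_s4_class(plateData(ctrl, meta), "PlateData")
  meta$compound_id[4] <- NA
  expect_error(plateData(ctrl, meta), "control or carry")
})
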