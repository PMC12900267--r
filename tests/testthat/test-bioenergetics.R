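test_that("phase means segment the trace at injection times", {
  tr <- flat_trace(c(100, 100, 100, 100))
  pm <- phaseMeans(tr)
  expect_equal(pm$ocr_mean, rep(100, 4))
  expect_identical(pm$label, c("baseline", "oligomycin", "FCCP", "rotenone+antimycin"))
  tr2 <- ocrTrace(
    c(0, 5, 12, 17), c(100, 100, 40, 40),
    injections = data.frame(label = "compound", time_min = 8)
  )
  pm2 <- phaseMeans(tr2)
  expect_equal(pm2$ocr_mean, c(100, 40))
})

test_that("the MitoStress decomposition follows the stated identities", {
  tr <- flat_trace(c(100, 40, 150, 20))
  mp <- mitoParams(tr)
  expect_equal(unname(mitoValues(mp)), c(80, 60, 20, 130, 50, 20))
  # post-FCCP equal to baseline: zero spare capacity
  expect_equal(mitoParams(flat_trace(c(100, 40, 100, 20)))@spare_capacity, 0)
  # null respiration
  mp0 <- mitoParams(flat_trace(c(50, 50, 50, 50)))
  expect_equal(mp0@basal, 0)
  expect_equal(mp0@atp_linked, 0)
  expect_equal(mp0@maximal, 0)
})

test_that("atp_linked + proton_leak equals basal for arbitrary traces", {
  set.seed(12)
  for (i in 1:10) {
    lv <- sort(runif(4, 10, 200))[c(3, 2, 4, 1)]
    mp <- mitoParams(flat_trace(lv))
    expect_equal(mp@atp_linked + mp@proton_leak, mp@basal)
    expect_equal(mp@spare_capacity, mp@maximal - mp@basal)
  }
})

test_that("parameters are invariant under time shift and scale with OCR", {
  tr <- flat_trace(c(120, 50, 180, 25))
  shifted <- ocrTrace(
    tr@time + 37, tr@ocr, tr@ecar,
    transform(tr@injections, time_min = time_min + 37)
  )
  expect_equal(mitoValues(mitoParams(shifted)), mitoValues(mitoParams(tr)))
  scaled <- ocrTrace(tr@time, 3.5 * tr@ocr, tr@ecar, tr@injections)
  expect_equal(mitoValues(mitoParams(scaled)), 3.5 * mitoValues(mitoParams(tr)))
})

test_that("maximal respiration uses the best post-FCCP measurement", {
  tr <- flat_trace(c(100, 40, 150, 20))
  ocr <- tr@ocr
  ocr[8] <- 170  # one higher measurement inside the FCCP phase
  tr2 <- ocrTrace(tr@time, ocr, injections = tr@injections)
  expect_equal(mitoParams(tr2)@maximal, 150)
  ocr[7] <- 180
  tr3 <- ocrTrace(tr@time, ocr, injections = tr@injections)
  expect_equal(mitoParams(tr3)@maximal, 160)
})

test_that("acute changes report OCR and ECAR percent shifts", {
  tr <- ocrTrace(
    c(0, 5, 10, 15), c(100, 100, 80, 80), c(10, 10, 12, 12),
    data.frame(label = "compound", time_min = 7.5)
  )
  ch <- acuteChange(tr, "compound")
  expect_equal(unname(ch["ocr"]), -20)
  expect_equal(unname(ch["ecar"]), 20)
  trNull <- ocrTrace(
    c(0, 5, 10, 15), c(100, 100, 100, 100), c(10, 10, 12, 12),
    data.frame(label = "compound", time_min = 7.5)
  )
  chN <- acuteChange(trNull, "compound")
  expect_equal(unname(chN["ocr"]), 0)
  expect_equal(unname(chN["ecar"]), 20)
})

test_that("missing phases, labels and zero baselines are explicit errors", {
  tr <- ocrTrace(
    c(0, 5, 10, 15), c(100, 100, 40, 40),
    injections = data.frame(label = "oligomycin", time_min = 7.5)
  )
  expect_error(mitoParams(tr), "FCCP")
  expect_error(acuteChange(tr, "nonexistent"), "nonexistent")
  tr0 <- ocrTrace(
    c(0, 5, 10, 15), c(0, 0, 40, 40),
    injections = data.frame(label = "compound", time_min = 7.5)
  )
  expect_error(acuteChange(tr0, "compound"), "undefined percent change")
})

test_that("trace validity enforces ordering and phase occupancy", {
  expect_error(
    ocrTrace(c(0, 5, 5), c(1, 2, 3),
             injections = data.frame(label = "x", time_min = 2)),
    "strictly increasing"
  )
  expect_error(
    ocrTrace(c(0, 5, 10, 15), c(1, 2, 3, 4),
             injections = data.frame(label = "x", time_min = 12)),
    "fewer than 2"
  )
  expect_error(
    ocrTrace(c(0, 5, 10, 15), c(1, 2, 3, 4),
             injections = data.frame(label = "x", time_min = 20)),
    "inside the measurement range"
  )
})

test_that("replicate wells are averaged per timepoint when reading traces", {
  csv <- withr::local_tempfile(fileext = ".csv")
  inj <- withr::local_tempfile(fileext = ".json")
  df <- data.frame(
    time_min = rep(c(0, 5, 10, 15), each = 2),
    well_id = rep(c("A1", "A2"), 4),
    group = "cpd",
    ocr = c(98, 102, 99, 101, 38, 42, 21, 19),
    ecar = c(10, 10, 10, 10, 11, 13, 12, 12)
  )
  utils::write.csv(df, csv, row.names = FALSE)
  writeLines('[{"label": "compound", "time_min": 7.5}]', inj)
  tr <- readOCRTrace(csv, inj)
  expect_equal(tr@ocr, c(100, 100, 40, 20))
  expect_equal(tr@ecar, c(10, 10, 12, 12))
  expect_equal(phaseMeans(tr)$ocr_mean, c(100, 30))
})
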