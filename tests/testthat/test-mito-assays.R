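test_that("opening detection round-trips the generator truth", {
  for (n in c(3L, 7L, 10L)) {
    tr <- makeCrcTrace(crcTraceSpec(nRetained = n, noiseSd = 0))
    det <- detectMptpOpening(tr$trace)
    expect_equal(det$nRetained, n)
    expect_equal(det$openingTime, tr$truth$openingPulseTime)
  }
})

test_that("a burst at the very first pulse gives zero retention", {
  tr <- makeCrcTrace(crcTraceSpec(nRetained = 0L, noiseSd = 0))
  det <- detectMptpOpening(tr$trace)
  expect_equal(det$nRetained, 0L)
  expect_equal(det$openingTime, tr$truth$openingPulseTime)
})

test_that("a censored assay reports all pulses retained and no opening", {
  full <- makeCrcTrace(crcTraceSpec(nRetained = 5L, noiseSd = 0))
  tr <- full$trace
  ## truncate just before the triggering pulse
  cut <- tr@pulseTimes[6] - 1
  keep <- tr@time <= cut
  censored <- new("CrcTrace", time = tr@time[keep],
                  fluorescence = tr@fluorescence[keep],
                  pulseTimes = tr@pulseTimes[1:5],
                  proteinMg = tr@proteinMg, pulseVolumeUl = tr@pulseVolumeUl,
                  pulseConcUM = tr@pulseConcUM, chamberMl = tr@chamberMl)
  det <- detectMptpOpening(censored)
  expect_equal(det$nRetained, 5L)
  expect_true(is.na(det$openingTime))
})

test_that("opening detection tolerates moderate noise", {
  ok <- vapply(1:30, function(s) {
    tr <- makeCrcTrace(crcTraceSpec(nRetained = 6L, noiseSd = 5.6, seed = s))
    detectMptpOpening(tr$trace)$nRetained == 6L
  }, logical(1))
  expect_true(all(ok))
})

test_that("CRC converts retained pulses with the assay constants", {
  ## 10 uL x 500 uM = 5 nmol per pulse; / 0.5 mg = 10 nmol/mg per pulse
  tr <- makeCrcTrace(crcTraceSpec(nRetained = 7L, noiseSd = 0))
  res <- computeCrc(tr$trace)
  expect_equal(crcPerMg(res), 70)
  expect_equal(nRetained(res), 7L)

  tr0 <- makeCrcTrace(crcTraceSpec(nRetained = 0L, noiseSd = 0))
  expect_equal(crcPerMg(computeCrc(tr0$trace)), 0)
})

test_that("doubling the protein mass halves the CRC", {
  a <- makeCrcTrace(crcTraceSpec(nRetained = 6L, proteinMg = 0.5))
  b <- makeCrcTrace(crcTraceSpec(nRetained = 6L, proteinMg = 1.0))
  expect_equal(crcPerMg(computeCrc(a$trace)),
               2 * crcPerMg(computeCrc(b$trace)))
})

test_that("stage segmentation applies the settling period", {
  plan <- data.frame(label = c("GM", "ADP", "rotenone"),
                     time_s = c(0, 60, 120), ocr = c(1, 2, 3))
  ox <- makeOxygraphTrace(oxygraphSpec(stagePlan = plan, tailS = 60,
                                       initialO2 = 100))
  win <- segmentStages(ox$trace, settleFraction = 0.25)
  expect_equal(win$start, c(15, 75, 135))
  expect_equal(win$end, c(60, 120, 180))
  expect_equal(win$stage, c("GM", "GM+ADP", "+rotenone"))
})

test_that("a single event spans to the end of the trace", {
  plan <- data.frame(label = "ADP", time_s = 0, ocr = 10)
  ox <- makeOxygraphTrace(oxygraphSpec(stagePlan = plan, tailS = 120))
  win <- segmentStages(ox$trace)
  expect_equal(nrow(win), 1L)
  expect_equal(win$end, 120)
})

test_that("unordered events are rejected", {
  expect_error(
    new("OxygraphTrace", time = 0:100, o2Conc = rep(50, 101),
        events = data.frame(time_s = c(60, 30), label = c("GM", "ADP")),
        chamberMl = 2, proteinMg = 0.5),
    "increasing")
  expect_error(oxygraphSpec(stagePlan = data.frame(
    label = c("GM", "ADP"), time_s = c(60, 30), ocr = c(1, 2))),
    "increasing")
})

test_that("stage OCR converts the concentration slope correctly", {
  ## slope -3 nmol/mL/min, chamber 2 mL, protein 0.5 mg -> 12 nmol O2/min/mg
  time <- seq(0, 300, by = 1)
  o2 <- 150 - 3 / 60 * time
  tr <- new("OxygraphTrace", time = time, o2Conc = o2,
            events = data.frame(time_s = 0, label = "ADP"),
            chamberMl = 2, proteinMg = 0.5)
  win <- segmentStages(tr)
  expect_equal(computeStageOcr(tr, win[1, ]), 12, tolerance = 1e-12)

  flat <- new("OxygraphTrace", time = time, o2Conc = rep(100, length(time)),
              events = data.frame(time_s = 0, label = "ADP"),
              chamberMl = 2, proteinMg = 0.5)
  expect_equal(computeStageOcr(flat, win[1, ]), 0)
})

test_that("stage OCRs round-trip the generator truth exactly", {
  ox <- makeOxygraphTrace(oxygraphSpec())
  got <- stageOcrs(ox$trace)
  expect_equal(unname(got), unname(ox$truth), tolerance = 1e-9)
  expect_equal(names(got), names(ox$truth))
})

test_that("too-small stage windows are rejected", {
  tr <- new("OxygraphTrace", time = seq(0, 100, 10),
            o2Conc = seq(100, 90, -1),
            events = data.frame(time_s = 0, label = "ADP"),
            chamberMl = 2, proteinMg = 0.5)
  expect_error(computeStageOcr(tr, list(start = 95, end = 100)), "5 samples")
})

test_that("complex rates are stimulated-minus-inhibited differences", {
  ocrs <- c("GM" = 3, "GM+ADP" = 14, "+rotenone" = 2, "+succinate" = 16,
            "+TTFA" = 4, "+TMPD/ascorbate" = 30, "+azide" = 6)
  cr <- computeComplexRates(ocrs)
  expect_equal(complexRate(cr, "CI"), 12)
  expect_equal(complexRate(cr, "CII"), 12)
  expect_equal(complexRate(cr, "CIV"), 24)
  expect_length(cr@missingStages, 0)
})

test_that("a missing stage leaves its complex rate undefined and flagged", {
  ocrs <- c("GM+ADP" = 14, "+rotenone" = 2, "+succinate" = 16,
            "+TMPD/ascorbate" = 30, "+azide" = 6)
  cr <- computeComplexRates(ocrs)
  expect_equal(complexRate(cr, "CI"), 12)
  expect_true(is.na(complexRate(cr, "CII")))
  expect_true("+TTFA" %in% cr@missingStages)
  expect_false(is.na(complexRate(cr, "CIV")))
})

test_that("OCR units scale with protein and chamber volume", {
  time <- seq(0, 300, by = 1)
  o2 <- 150 - 3 / 60 * time
  mk <- function(chamber, protein)
    new("OxygraphTrace", time = time, o2Conc = o2,
        events = data.frame(time_s = 0, label = "ADP"),
        chamberMl = chamber, proteinMg = protein)
  win <- segmentStages(mk(2, 0.5))
  base <- computeStageOcr(mk(2, 0.5), win[1, ])
  expect_equal(computeStageOcr(mk(2, 1.0), win[1, ]), base / 2)
  expect_equal(computeStageOcr(mk(4, 0.5), win[1, ]), base * 2)
})

test_that("an O2-exhausting stage plan is rejected with a diagnostic", {
  plan <- data.frame(label = "ADP", time_s = 0, ocr = 100)
  expect_error(makeOxygraphTrace(oxygraphSpec(stagePlan = plan,
                                              initialO2 = 10, tailS = 600)),
               "exhausts")
})
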