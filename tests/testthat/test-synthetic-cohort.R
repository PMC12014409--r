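test_that("quartile fit reproduces hand-computed log-normal parameters", {
  p <- lognormalFromMedianIqr(1, exp(-0.6745), exp(0.6745))
  expect_equal(p$mu, 0)
  expect_equal(p$sigma, 1)
  expect_false(p$degenerate)

  q <- lognormalFromMedianIqr(105, 80, 118)
  expect_equal(q$mu, log(105))
  expect_equal(q$sigma,
               (log(118 / 105) / 0.6745 + log(105 / 80) / 0.6745) / 2)
})

test_that("degenerate and malformed quantile inputs are handled", {
  expect_warning(p <- lognormalFromMedianIqr(5, 5, 5), "degenerate")
  expect_equal(p$sigma, 0)
  expect_true(p$degenerate)
  expect_error(lognormalFromMedianIqr(10, 12, 15), "q25 <= median")
  expect_error(lognormalFromMedianIqr(-1, 1, 2), "positive")
  expect_error(lognormalFromMedianIqr(2, 1, 1.5), "q25 <= median")
})

test_that("large samples reproduce the target median closely", {
  targets <- list(c(105, 80, 118), c(48, 34, 61), c(6.93, 4.2, 9.2))
  for (tg in targets) {
    p <- lognormalFromMedianIqr(tg[1], tg[2], tg[3])
    draws <- withr::with_seed(42,
      stats::rlnorm(1e5, meanlog = p$mu, sdlog = p$sigma))
    expect_lt(abs(stats::median(draws) - tg[1]) / tg[1], 0.01)
  }
})

test_that("the default cohort has the study's arm sizes", {
  co <- makeCohort(cohortSpec())
  expect_equal(nrow(co$cohort), 52L)
  expect_equal(as.vector(table(co$cohort$group)[c("Sham", "tMCAO",
                                                  "tMCAO_CsA", "pMCAO")]),
               c(12L, 14L, 12L, 14L))
  expect_true(all(co$cohort$neuroscore %in% 0:5))
  expect_true(all(c("included", "exclusion_reason") %in% names(co$cohort)))
})

test_that("cohort generation is reproducible under its seed", {
  a <- makeCohort(cohortSpec(seed = 9L))
  b <- makeCohort(cohortSpec(seed = 9L))
  expect_identical(a$cohort, b$cohort)
  c2 <- makeCohort(cohortSpec(seed = 10L))
  expect_false(identical(a$cohort$crc_ipsi, c2$cohort$crc_ipsi))
})

test_that("large cohorts converge to the target endpoint medians", {
  spec <- cohortSpec(groupSizes = c(Sham = 2000L, tMCAO = 2000L,
                                    tMCAO_CsA = 2000L, pMCAO = 2000L),
                     exclusionProb = c(Sham = 0, tMCAO = 0,
                                       tMCAO_CsA = 0, pMCAO = 0),
                     seed = 3L)
  co <- makeCohort(spec)$cohort
  tg <- spec@endpointTargets
  for (g in c("tMCAO", "pMCAO")) {
    for (ep in c("aar_percent", "crc_ipsi", "ocr_CI_ipsi")) {
      want <- tg$median[tg$group == g & tg$endpoint == ep]
      got <- stats::median(co[[ep]][co$group == g])
      expect_lt(abs(got - want) / want, 0.03)
    }
  }
})

test_that("the severity factor couples endpoints without moving the marginals", {
  spec <- cohortSpec(groupSizes = c(Sham = 0L, tMCAO = 20000L,
                                    tMCAO_CsA = 0L, pMCAO = 0L),
                     exclusionProb = c(Sham = 0, tMCAO = 0,
                                       tMCAO_CsA = 0, pMCAO = 0),
                     severityCoupling = 0.6, seed = 4L)
  co <- makeCohort(spec)$cohort
  ## within-group log-scale correlation: +rho^2 between two lesion-side
  ## endpoints, -rho^2 between lesion-side and protective, 0 to contralateral
  expect_lt(abs(stats::cor(log(co$aar_percent), log(co$hlvc_percent)) - 0.36),
            0.04)
  expect_lt(abs(stats::cor(log(co$hlvc_percent), log(co$crc_ipsi)) + 0.36),
            0.04)
  expect_lt(abs(stats::cor(log(co$hlvc_percent), log(co$crc_contra))), 0.03)
  ## marginal median calibration is untouched by the coupling
  tg <- spec@endpointTargets
  want <- tg$median[tg$group == "tMCAO" & tg$endpoint == "crc_ipsi"]
  expect_lt(abs(stats::median(co$crc_ipsi) - want) / want, 0.03)
})

test_that("neuroscore draws follow the per-group category probabilities", {
  spec <- cohortSpec(groupSizes = c(Sham = 5000L, tMCAO = 0L,
                                    tMCAO_CsA = 0L, pMCAO = 0L), seed = 8L)
  co <- makeCohort(spec)$cohort
  ## Sham animals are overwhelmingly mild (scores 4-5)
  expect_gt(mean(co$neuroscore >= 4), 0.90)
  expect_equal(sum(co$neuroscore <= 2), 0)
})

test_that("invalid cohort specifications are rejected", {
  expect_error(cohortSpec(exclusionProb = c(Sham = 1.2, tMCAO = 0.1,
                                            tMCAO_CsA = 0.1, pMCAO = 0.1)),
               "exclusionProb")
  badProbs <- .defaultNeuroscoreProbs()
  badProbs[1, ] <- c(0.5, 0.5, 0.5, 0, 0, 0)
  expect_error(cohortSpec(neuroscoreProbs = badProbs), "summing to 1")
})
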