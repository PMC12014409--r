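test_that("median/IQR summaries use inclusive interpolation", {
  s <- summarizeMedianIqr(c(1, 2, 3, 4, 5))
  expect_equal(c(s@q25, s@median, s@q75), c(2, 3, 4))
  expect_equal(s@n, 5L)

  one <- summarizeMedianIqr(7)
  expect_equal(c(one@q25, one@median, one@q75), c(7, 7, 7))

  x <- c(9.1, 2.3, 5.5, 7.7, 1.2, 4.4)
  a <- summarizeMedianIqr(x)
  b <- summarizeMedianIqr(rev(sort(x)))
  expect_equal(c(a@median, a@q25, a@q75), c(b@median, b@q25, b@q75))
  expect_error(summarizeMedianIqr(numeric(0)), "empty")
})

test_that("separated small samples give the known exact Mann-Whitney result", {
  r <- mannWhitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(testStatistic(r)["U"]), 0)
  expect_equal(pValue(r), 0.1)   # 2/20 labelings as extreme
})

test_that("identical samples give p = 1 with a zero-variance note", {
  r <- mannWhitney(c(1, 2), c(1, 2))
  expect_equal(pValue(r), 1)
  r2 <- mannWhitney(c(3, 3, 3), c(3, 3))
  expect_equal(pValue(r2), 1)
  expect_match(r2@note, "zero variance")
})

test_that("the exact branch matches full enumeration for small groups", {
  set.seed(7)
  for (trial in 1:25) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    x <- stats::rnorm(m); y <- stats::rnorm(n, mean = stats::runif(1, -1, 1))
    got <- mannWhitney(x, y)
    oracle <- mwEnumerationOracle(x, y)
    expect_equal(unname(testStatistic(got)["U"]), oracle$U)
    expect_equal(pValue(got), oracle$p, tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis reproduces the hand-computed rank statistic", {
  r <- kruskalWallis(list(c(1, 2), c(3, 4), c(5, 6)))
  ## ranks 1..6, rank sums 3/7/11: H = 12/(6*7) * sum(R^2/2) - 3*7 = 32/7
  expect_equal(unname(testStatistic(r)["H"]), 32 / 7, tolerance = 1e-9)
  expect_equal(pValue(r), stats::pchisq(32 / 7, df = 2, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("degenerate Kruskal-Wallis inputs are handled", {
  r <- kruskalWallis(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(unname(testStatistic(r)["H"]), 0)
  expect_equal(pValue(r), 1)
  expect_error(kruskalWallis(list(c(1, 2))), "two nonempty groups")
})

test_that("with two groups H equals the squared standardized U statistic", {
  set.seed(21)
  x <- stats::rnorm(8); y <- stats::rnorm(9, 0.5)
  H <- unname(testStatistic(kruskalWallis(list(x, y)))["H"])
  m <- length(x); n <- length(y); N <- m + n
  U <- unname(testStatistic(mannWhitney(x, y))["U"])
  z <- (U - m * n / 2) / sqrt(m * n * (N + 1) / 12)
  expect_equal(H, z^2, tolerance = 1e-9)
})

test_that("neuroscores map onto the three outcome categories", {
  expect_equal(as.character(categorizeNeuroscore(c(0, 1, 2, 3, 4, 5))),
               c("severe", "severe", "moderate", "moderate", "mild", "mild"))
  expect_error(categorizeNeuroscore(6), "0..5")
  expect_error(categorizeNeuroscore(NA), "0..5")
})

test_that("chi-square on outcome tables matches the Pearson formula", {
  flat <- chiSquareOutcome(matrix(c(5, 5, 5, 5), 2))
  expect_equal(unname(testStatistic(flat)["X2"]), 0)
  expect_equal(pValue(flat), 1)

  diag2 <- chiSquareOutcome(matrix(c(10, 0, 0, 10), 2))
  expect_equal(unname(testStatistic(diag2)["X2"]), 20)
  expect_equal(unname(testStatistic(diag2)["df"]), 1)

  tab <- matrix(c(8, 3, 4, 9, 2, 6), nrow = 2)
  expect_equal(testStatistic(chiSquareOutcome(tab)),
               testStatistic(chiSquareOutcome(t(tab))))
  expect_error(chiSquareOutcome(matrix(c(0, 0, 3, 4), 2)), "margin")
  expect_match(chiSquareOutcome(matrix(c(2, 3, 4, 1), 2))@note,
               "expected count")
})

test_that("lesion-CRC correlation recovers monotone association", {
  x <- 1:8
  down <- correlateLesionCrc(x, rev(x) + 100)
  expect_equal(unname(effectValue(down)["rho"]), -1)
  up <- correlateLesionCrc(x, x * 2)
  expect_equal(unname(effectValue(up)["rho"]), 1)
})

test_that("small-sample Spearman p equals the permutation enumeration", {
  set.seed(11)
  for (trial in 1:10) {
    x <- sample(100, 5); y <- sample(100, 5)
    got <- correlateLesionCrc(x, y)
    expect_equal(pValue(got), spearmanPermutationOracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("constant correlation inputs are flagged undefined", {
  expect_warning(r <- correlateLesionCrc(rep(5, 6), 1:6), "constant")
  expect_true(is.na(pValue(r)))
  expect_error(correlateLesionCrc(1:3, 3:1), "at least 4")
})

test_that("ANCOVA recovers an exact vertical group shift", {
  aar <- c(30, 40, 50, 60, 35, 45, 55, 65)
  grp <- rep(c("A", "B"), each = 4)
  hlvc <- 0.8 * aar + ifelse(grp == "B", -10, 0)
  rec <- data.frame(aar_percent = aar, hlvc_percent = hlvc, group = grp)
  ## zero-residual designs make summary.lm warn about a perfect fit
  r <- suppressWarnings(ancovaLesionOnAar(rec))
  expect_equal(unname(effectValue(r)), -10, tolerance = 1e-9)

  ## same line in both groups: coefficient 0
  rec0 <- rec; rec0$hlvc_percent <- 0.8 * rec0$aar_percent
  expect_equal(unname(effectValue(suppressWarnings(ancovaLesionOnAar(rec0)))),
               0, tolerance = 1e-9)

  ## linearity: doubling the response doubles the coefficient
  rec2 <- rec; rec2$hlvc_percent <- 2 * rec2$hlvc_percent
  expect_equal(unname(effectValue(suppressWarnings(ancovaLesionOnAar(rec2)))),
               -20, tolerance = 1e-9)
})

test_that("degenerate ANCOVA designs are rejected", {
  rec <- data.frame(aar_percent = rep(50, 8),
                    hlvc_percent = stats::rnorm(8),
                    group = rep(c("A", "B"), each = 4))
  expect_error(ancovaLesionOnAar(rec), "collinear")
  expect_error(ancovaLesionOnAar(data.frame(aar_percent = 1:4,
                                            hlvc_percent = 1:4,
                                            group = c("A", "A", "A", "B"))),
               "at least 3")
})

test_that("ANCOVA detects the CsA lesion reduction on calibrated cohorts", {
  ## group-effect sign recovered on synthetic cohorts with a built-in effect
  hits <- vapply(1:20, function(s) {
    co <- makeCohort(cohortSpec(groupSizes = c(Sham = 0L, tMCAO = 50L,
                                               tMCAO_CsA = 50L, pMCAO = 0L),
                                seed = s))$cohort
    co$group <- factor(co$group, levels = c("tMCAO", "tMCAO_CsA"))
    a <- ancovaLesionOnAar(co)
    m <- mannWhitney(co$crc_ipsi[co$group == "tMCAO"],
                     co$crc_ipsi[co$group == "tMCAO_CsA"])
    (unname(effectValue(a)) < 0) && (unname(effectValue(m)["medianDiff"]) < 0)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("sample size search matches a numeric-integration power oracle", {
  d <- 1.21
  nT <- sampleSizeMW(d)$nT
  expect_gte(tPowerIntegrationOracle(nT, d), 0.8)
  expect_lt(tPowerIntegrationOracle(nT - 1, d), 0.8)
})

test_that("attrition and grouping inflate the randomized total correctly", {
  base <- sampleSizeMW(1.21, attrition = 0, nGroups = 4)
  expect_equal(base$nTotalRandomized, 4L * base$nPerGroup)
  infl <- sampleSizeMW(1.21, attrition = 0.3, nGroups = 4)
  expect_equal(infl$nTotalRandomized,
               as.integer(ceiling(4 * infl$nPerGroup / 0.7)))
  expect_error(sampleSizeMW(-1), "effectSize")
  expect_error(sampleSizeMW(1.21, alpha = 1.2), "alpha")
})

test_that("power increases monotonically with n at fixed effect size", {
  pw <- vapply(c(4, 8, 12, 16, 20),
               function(n) strokeIR:::.tTestPower(n, 1.21, 0.05, 2L),
               numeric(1))
  expect_true(all(diff(pw) > 0))
})
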