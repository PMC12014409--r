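#' @include AllClasses.R utils.R
NULL

#' Median and interquartile range of one group
#'
#' Summaries follow the reporting convention Median \[q25; q75\], with
#' quartiles by linear interpolation of order statistics (the inclusive
#' method, \code{quantile} type 7).
#'
#' @param values numeric vector, at least one finite value.
#' @return a \linkS4class{GroupSummary}
#' @examples
#' summarizeMedianIqr(c(1, 2, 3, 4, 5))
#' @export
summarizeMedianIqr <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 1L) stop("empty input: nothing to summarize")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  new("GroupSummary", n = length(values), median = q[2], q25 = q[1],
      q75 = q[3])
}

#' Two-sample Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided. The exact null distribution is used when the combined sample
#' size is at most 20 and there are no ties; otherwise the normal
#' approximation with tie and continuity correction. Identical samples
#' (zero variance overall) return p = 1 with a note.
#'
#' @param x,y numeric vectors (both nonempty).
#' @param mode "auto" (default branching rule), "exact" or "approximate".
#' @return a \linkS4class{TestResult} with the U statistic and the
#'   difference of group medians as effect descriptor
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mannWhitney <- function(x, y, mode = c("auto", "exact", "approximate")) {
  mode <- match.arg(mode)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y)) stop("both groups must be nonempty")
  effect <- c(medianDiff = stats::median(x) - stats::median(y))
  if (length(unique(c(x, y))) == 1L)
    return(new("TestResult", method = "Mann-Whitney (degenerate)",
               statistic = c(U = length(x) * length(y) / 2), pValue = 1,
               effect = effect, note = "zero variance: all values identical"))
  noTies <- !any(duplicated(c(x, y)))
  exact <- switch(mode,
                  auto = (length(x) + length(y) <= 20L) && noTies,
                  exact = TRUE, approximate = FALSE)
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact))
  new("TestResult",
      method = paste0("Mann-Whitney (",
                      if (exact) "exact" else "normal approximation", ")"),
      statistic = c(U = unname(ht$statistic)),
      pValue = min(ht$p.value, 1), effect = effect, note = character())
}

#' Kruskal-Wallis rank test across groups
#'
#' H with tie correction; p from the chi-square distribution with k - 1
#' degrees of freedom.
#'
#' @param groups list of numeric vectors, at least two nonempty groups.
#' @return a \linkS4class{TestResult}
#' @export
kruskalWallis <- function(groups) {
  groups <- lapply(groups, function(g) g[is.finite(g)])
  groups <- groups[vapply(groups, length, integer(1)) > 0L]
  if (length(groups) < 2L) stop("at least two nonempty groups are required")
  allv <- unlist(groups)
  if (length(unique(allv)) == 1L)
    return(new("TestResult", method = "Kruskal-Wallis (degenerate)",
               statistic = c(H = 0), pValue = 1, effect = numeric(),
               note = "zero variance: all values identical"))
  ht <- stats::kruskal.test(groups)
  new("TestResult", method = "Kruskal-Wallis",
      statistic = c(H = unname(ht$statistic), df = unname(ht$parameter)),
      pValue = ht$p.value, effect = numeric(), note = character())
}

#' Neuroscore outcome category
#'
#' Maps the 0-5 behavioural score onto the outcome categories:
#' mild (4-5), moderate (2-3), severe (0-1).
#'
#' @param score integer score(s) in 0..5.
#' @return factor with levels severe < moderate < mild
#' @export
categorizeNeuroscore <- function(score) {
  if (any(is.na(score)) || any(!score %in% 0:5))
    stop("neuroscores must lie in 0..5")
  cut(score, breaks = c(-0.5, 1.5, 3.5, 5.5),
      labels = c("severe", "moderate", "mild"), ordered_result = TRUE)
}

#' Chi-square test on a group-by-outcome contingency table
#'
#' Pearson chi-square without continuity correction,
#' df = (rows - 1)(cols - 1). A note is attached when any expected count
#' falls below 5.
#'
#' @param tab contingency table (matrix of nonnegative integers, at least
#'   2 x 2, every margin positive).
#' @return a \linkS4class{TestResult}
#' @export
chiSquareOutcome <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("contingency table must be at least 2 x 2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("contingency table must hold nonnegative integer counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("every row and column margin must be positive")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  note <- if (any(ht$expected < 5))
    "expected count < 5 in at least one cell" else character()
  new("TestResult", method = "Pearson chi-square",
      statistic = c(X2 = unname(ht$statistic), df = unname(ht$parameter)),
      pValue = ht$p.value, effect = numeric(), note = note)
}

#' Correlation between lesion burden and calcium retention capacity
#'
#' Spearman rank correlation by default (consistent with the nonparametric
#' framework; Pearson selectable). The exact permutation p value is used
#' for small tie-free samples, the t approximation otherwise.
#'
#' @param hlvcPercent lesion burden values.
#' @param crc paired CRC values (same length, n >= 4).
#' @param method "spearman" (default) or "pearson".
#' @return a \linkS4class{TestResult} with rho (or r) as effect
#' @export
correlateLesionCrc <- function(hlvcPercent, crc,
                               method = c("spearman", "pearson")) {
  method <- match.arg(method)
  keep <- is.finite(hlvcPercent) & is.finite(crc)
  x <- hlvcPercent[keep]; y <- crc[keep]
  if (length(x) < 4L) stop("at least 4 complete pairs are required")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("constant input vector: correlation undefined")
    return(new("TestResult", method = paste0(method, " correlation (degenerate)"),
               statistic = numeric(), pValue = NA_real_,
               effect = c(rho = NA_real_),
               note = "constant input vector: correlation undefined"))
  }
  exact <- method == "spearman" && length(x) <= 9L &&
    !any(duplicated(x)) && !any(duplicated(y))
  ht <- suppressWarnings(stats::cor.test(x, y, method = method, exact = exact))
  eff <- stats::setNames(unname(ht$estimate),
                         if (method == "spearman") "rho" else "r")
  new("TestResult",
      method = paste0(method, " correlation",
                      if (exact) " (exact)" else ""),
      statistic = stats::setNames(unname(ht$statistic), names(ht$statistic)),
      pValue = ht$p.value, effect = eff, note = character())
}

#' Covariate-adjusted lesion-vs-AAR group comparison
#'
#' "For a given AAR, is the lesion smaller in one group?" answered by
#' common-slope ANCOVA: ordinary least squares of the lesion burden on the
#' AAR plus a group indicator, with a two-sided t test on the group
#' coefficient.
#'
#' @param records data.frame with columns \code{aar_percent},
#'   \code{hlvc_percent} and \code{group} (exactly two levels, each with at
#'   least 3 records).
#' @return a \linkS4class{TestResult}; the effect is the adjusted
#'   difference in lesion burden of the second group vs the first
#' @export
ancovaLesionOnAar <- function(records) {
  need <- c("aar_percent", "hlvc_percent", "group")
  if (!all(need %in% names(records)))
    stop("records need columns aar_percent, hlvc_percent, group")
  records <- records[stats::complete.cases(records[, need]), , drop = FALSE]
  records$group <- factor(records$group)
  if (nlevels(records$group) != 2L)
    stop("exactly two groups are required")
  if (any(table(records$group) < 3L))
    stop("each group needs at least 3 records with AAR and lesion values")
  X <- stats::model.matrix(~ aar_percent + group, data = records)
  if (qr(X)$rank < ncol(X))
    stop("degenerate (collinear) design: cannot adjust for AAR")
  fit <- stats::lm(hlvc_percent ~ aar_percent + group, data = records)
  co <- summary(fit)$coefficients
  gRow <- grep("^group", rownames(co))
  eff <- co[gRow, "Estimate"]
  new("TestResult", method = "ANCOVA (common slope), group coefficient",
      statistic = c(t = unname(co[gRow, "t value"]),
                    df = fit$df.residual),
      pValue = unname(co[gRow, "Pr(>|t|)"]),
      effect = c(adjustedDifference = unname(eff)), note = character())
}

## Two-sided (or one-sided) power of the two-sample t test at n per group,
## from the noncentral t distribution.
.tTestPower <- function(n, d, alpha, tails) {
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  ## pt(..., ncp) warns about ~1e-12 precision limits; irrelevant here
  suppressWarnings(
    if (tails == 2L) {
      crit <- stats::qt(1 - alpha / 2, df)
      1 - stats::pt(crit, df, ncp) + stats::pt(-crit, df, ncp)
    } else {
      crit <- stats::qt(1 - alpha, df)
      1 - stats::pt(crit, df, ncp)
    })
}

#' A-priori sample size for a Mann-Whitney comparison
#'
#' Classical ARE-corrected computation: the smallest per-group n at which
#' the two-sample t test reaches the target power at effect size d (power
#' from the noncentral t distribution), inflated by the asymptotic
#' relative efficiency of the Mann-Whitney test vs the t test (0.955 for
#' normal shift alternatives), then the total randomized count inflated
#' for the anticipated attrition rate.
#'
#' @param effectSize standardized effect size d (> 0).
#' @param alpha significance level.
#' @param power target power.
#' @param tails 1 or 2.
#' @param are asymptotic relative efficiency divisor (default 0.955).
#' @param attrition anticipated exclusion rate in \[0, 1).
#' @param nGroups number of randomized groups.
#' @return list: \code{nT} (t-test n), \code{nPerGroup} (ARE-corrected),
#'   \code{nTotalRandomized}, \code{achievedPower}
#' @examples
#' sampleSizeMW(1.21, alpha = 0.05, power = 0.8, attrition = 0.3, nGroups = 4)
#' @export
sampleSizeMW <- function(effectSize, alpha = 0.05, power = 0.8, tails = 2L,
                         are = 0.955, attrition = 0, nGroups = 2L) {
  if (effectSize <= 0) stop("effectSize must be > 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)")
  if (!tails %in% c(1L, 2L)) stop("tails must be 1 or 2")
  if (attrition < 0 || attrition >= 1) stop("attrition must be in [0, 1)")
  nMax <- 100000L
  nT <- NA_integer_
  for (n in 2:nMax) {
    if (.tTestPower(n, effectSize, alpha, tails) >= power) {
      nT <- n
      break
    }
  }
  if (is.na(nT)) stop("target power unattainable within n <= ", nMax)
  nPerGroup <- as.integer(ceiling(nT / are))
  nTotal <- as.integer(ceiling(nGroups * nPerGroup / (1 - attrition)))
  list(nT = as.integer(nT), nPerGroup = nPerGroup,
       nTotalRandomized = nTotal,
       achievedPower = .tTestPower(nT, effectSize, alpha, tails))
}
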