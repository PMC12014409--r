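## Independent brute-force oracles used to pin expected values.

## Mann-Whitney by full enumeration of all C(m+n, m) group labelings of the
## pooled sample (no ties assumed); two-sided p by the doubled-tail
## convention.
mwEnumerationOracle <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  uObs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  labelings <- utils::combn(m + n, m)
  us <- apply(labelings, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  p1 <- if (uObs <= m * n / 2) mean(us <= uObs) else mean(us >= uObs)
  list(U = uObs, p = min(1, 2 * p1))
}

## All permutations of 1..n (n small).
allPermutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in allPermutations(n - 1L))
    for (k in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

## Exact two-sided Spearman p by permutation enumeration of |rho|.
spearmanPermutationOracle <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rhoObs <- suppressWarnings(stats::cor(rx, ry))
  rhos <- vapply(allPermutations(n),
                 function(p) stats::cor(rx, ry[p]), numeric(1))
  mean(abs(rhos) >= abs(rhoObs) - 1e-12)
}

## Two-sample t-test power by numeric integration of the noncentral t
## density (independent of the closed-form pt(..., ncp) path).
tPowerIntegrationOracle <- function(n, d, alpha = 0.05) {
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  crit <- stats::qt(1 - alpha / 2, df)
  dens <- function(x) suppressWarnings(stats::dt(x, df, ncp))
  up <- stats::integrate(dens, crit, Inf, rel.tol = 1e-10)$value
  lo <- stats::integrate(dens, -Inf, -crit, rel.tol = 1e-10)$value
  up + lo
}

## Noiseless replenishment curve for a given parameter set.
replenishmentCurve <- function(times, burstFrame, i0, a, beta,
                               baseline = i0) {
  tb <- times[burstFrame]
  ifelse(seq_along(times) < burstFrame, baseline,
         i0 + a * (1 - exp(-beta * (times - tb))))
}
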