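#' @include AllClasses.R utils.R
NULL

## Core burst-replenishment least squares, by variable projection: the model
## I(t) = I0 + A (1 - exp(-beta (t - t_burst))) is linear in (I0, A) given
## beta, so the fit reduces to a 1-D search over beta with a closed-form
## linear solve (A constrained >= 0) at each candidate. Exact on noiseless
## curves, no convergence failures, and cheap enough for whole volumes.
## t: post-burst times relative to the burst; y: post-burst intensities.
.fitReplenishmentCore <- function(t, y, betaMax = 100) {
  n <- length(y)
  ybar <- mean(y)
  syy <- sum((y - ybar)^2)

  linfit <- function(beta) {
    x <- 1 - exp(-beta * t)
    xbar <- mean(x)
    sxx <- sum((x - xbar)^2)
    if (sxx <= .Machine$double.eps * n) {
      ## regressor flat (beta ~ 0 or ~Inf relative to sampling): A undetermined
      return(list(i0 = ybar, a = 0, rss = syy))
    }
    sxy <- sum((x - xbar) * (y - ybar))
    a <- sxy / sxx
    if (a < 0) return(list(i0 = ybar, a = 0, rss = syy))
    list(i0 = ybar - a * xbar, a = a, rss = max(syy - a * sxy, 0))
  }

  if (syy <= .Machine$double.eps * max(1, ybar^2) * n) {
    ## constant curve: no replenishment, perfectly fit by A = 0
    return(list(i0 = ybar, a = 0, beta = 0, rss = 0, converged = TRUE))
  }

  opt <- stats::optimize(function(b) linfit(b)$rss,
                         interval = c(1e-8, betaMax), tol = 1e-10)
  beta <- opt$minimum
  fit <- linfit(beta)
  if (fit$a == 0) beta <- 0
  converged <- !(beta <= 1e-6 && fit$a > 1e-8 * max(abs(y))) &&
    is.finite(fit$rss)
  list(i0 = fit$i0, a = fit$a, beta = beta, rss = fit$rss,
       converged = converged)
}

#' Fit the burst-replenishment model to one time-intensity curve
#'
#' Least-squares estimates of \eqn{(I_0, A, \beta)} in
#' \eqn{I(t) = I_0 + A (1 - e^{-\beta (t - t_{burst})})} over the post-burst
#' samples, with bounds \eqn{A \ge 0}, \eqn{\beta \ge 0}. The fit uses
#' variable projection (1-D minimization over \eqn{\beta}, exact linear
#' solve for \eqn{I_0, A}), so it cannot diverge; \code{converged} is FALSE
#' when \eqn{\beta} collapses to the zero bound while \eqn{A > 0}.
#'
#' @param curve intensity series (a.u.), same length as \code{times}.
#' @param times frame times (s), strictly increasing.
#' @param burstFrame 1-based index of the destruction burst frame.
#' @param betaMax upper bound of the rate search (1/s).
#' @return a \linkS4class{ReplenishmentFit}
#' @examples
#' t <- seq(0, 50, by = 0.5)
#' y <- 10 + 50 * (1 - exp(-0.5 * pmax(t - 5, 0)))
#' fitReplenishment(y, t, burstFrame = 11)
#' @export
fitReplenishment <- function(curve, times, burstFrame, betaMax = 100) {
  if (length(curve) != length(times))
    stop("curve and times must have equal length")
  burstFrame <- asCount(burstFrame, "burstFrame")
  if (burstFrame < 1L || burstFrame > length(times))
    stop("burstFrame out of range")
  post <- burstFrame:length(times)
  if (length(post) < 5L)
    stop("at least 5 post-burst samples are required")
  y <- curve[post]
  if (any(!is.finite(y))) stop("non-finite intensity samples in curve")
  t <- times[post] - times[burstFrame]
  f <- .fitReplenishmentCore(t, y, betaMax)
  new("ReplenishmentFit", i0 = f$i0, a = f$a, beta = f$beta, rss = f$rss,
      converged = f$converged)
}

#' Compute a voxelwise perfusion map
#'
#' Fits the burst-replenishment model in every voxel of a dynamic CEUS
#' sequence and maps the perfusion index \eqn{PI = A\beta} (the standard
#' flow proxy of destruction-replenishment theory; \code{quantity} can be
#' set to \code{"A"} or \code{"beta"} alone for sensitivity analysis).
#' Voxels with non-finite traces or non-converged fits are flagged and set
#' NA; they are excluded from all downstream statistics, never zeroed.
#'
#' @param seq a \linkS4class{DynamicSequence}
#' @param quantity which fitted quantity the map encodes: \code{"AB"}
#'   (\eqn{A\beta}, default), \code{"A"} or \code{"beta"}.
#' @param betaMax upper bound of the rate search (1/s).
#' @param medianFilter apply an optional 3 x 3 in-plane median filter to the
#'   finished map (off by default; no smoothing is the reference behaviour).
#' @return an absolute (non-normalized) \linkS4class{PerfusionMap}
#' @export
computePerfusionMap <- function(seq, quantity = c("AB", "A", "beta"),
                                betaMax = 100, medianFilter = FALSE) {
  validObject(seq)
  quantity <- match.arg(quantity)
  d <- dim(seq@frames)
  nVox <- d[1] * d[3] * d[4]
  post <- seq@burstFrame:d[2]
  if (length(post) < 5L)
    stop("at least 5 post-burst frames are required")
  t <- seq@frameTimes[post] - seq@frameTimes[seq@burstFrame]

  ## (slice, time, row, col) -> voxel x post-burst-time matrix
  ymat <- matrix(aperm(seq@frames[, post, , , drop = FALSE], c(1, 3, 4, 2)),
                 nrow = nVox)
  values <- rep(NA_real_, nVox)
  conv <- rep(FALSE, nVox)
  for (v in seq_len(nVox)) {
    y <- ymat[v, ]
    if (any(!is.finite(y))) next
    f <- .fitReplenishmentCore(t, y, betaMax)
    if (!f$converged) next
    conv[v] <- TRUE
    values[v] <- switch(quantity, AB = f$a * f$beta, A = f$a, beta = f$beta)
  }
  if (!any(conv))
    stop("no voxel converged: the sequence carries no usable replenishment signal")
  dim(values) <- d[c(1, 3, 4)]
  dim(conv) <- d[c(1, 3, 4)]
  map <- new("PerfusionMap", values = values, converged = conv,
             relative = FALSE, voxelSize = seq@voxelSize,
             sliceSpacing = seq@sliceSpacing)
  if (medianFilter) map <- medianFilterMap(map) else map
}

#' In-plane 3 x 3 median filter of a perfusion map
#'
#' Optional smoothing step; non-converged voxels stay NA and do not
#' contribute to neighbours' medians.
#'
#' @param map a \linkS4class{PerfusionMap}
#' @return the filtered map
#' @export
medianFilterMap <- function(map) {
  v <- map@values
  d <- dim(v)
  out <- v
  for (s in seq_len(d[1])) {
    sl <- v[s, , ]
    for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
      if (!map@converged[s, i, j]) next
      nb <- sl[max(1, i - 1):min(d[2], i + 1), max(1, j - 1):min(d[3], j + 1)]
      out[s, i, j] <- stats::median(nb, na.rm = TRUE)
    }
  }
  new("PerfusionMap", values = out, converged = map@converged,
      relative = map@relative, voxelSize = map@voxelSize,
      sliceSpacing = map@sliceSpacing)
}

#' Normalize a perfusion map to the contralateral median
#'
#' Divides every converged voxel by the median perfusion index over the
#' converged contralateral-hemisphere voxels, so the contralateral median
#' of the output is exactly 1 (the operation is idempotent). Mirrors the
#' voxel-by-voxel normalization used to make per-animal maps comparable.
#'
#' @param map a \linkS4class{PerfusionMap}
#' @param partition a \linkS4class{HemispherePartition}
#' @return the relative \linkS4class{PerfusionMap}
#' @export
normalizePerfusion <- function(map, partition) {
  validObject(map); validObject(partition)
  if (!identical(dim(map@values), dim(partition@labels)))
    stop("map and partition dimensions differ")
  contra <- partition@labels == 2L & map@converged
  if (!any(contra))
    stop("no converged contralateral voxel to normalize against")
  m <- stats::median(map@values[contra])
  if (!is.finite(m) || m == 0)
    stop("contralateral median perfusion is zero; cannot normalize")
  new("PerfusionMap", values = map@values / m, converged = map@converged,
      relative = TRUE, voxelSize = map@voxelSize,
      sliceSpacing = map@sliceSpacing)
}

#' Segment the area at risk by relative hypoperfusion
#'
#' The AAR is the set of converged ipsilateral voxels whose relative
#' perfusion is strictly below the threshold (default 0.26, i.e.
#' hypoperfusion < 26\% of the contralateral hemisphere). The AAR volume is
#' reported as a percentage of the ipsilateral hemisphere volume, each
#' voxel weighted by its volume, with a per-slice breakdown.
#'
#' @param relativeMap a normalized \linkS4class{PerfusionMap}
#' @param partition a \linkS4class{HemispherePartition}
#' @param threshold relative hypoperfusion threshold (dimensionless).
#' @return an \linkS4class{AARResult}
#' @export
segmentAar <- function(relativeMap, partition, threshold = 0.26) {
  validObject(relativeMap); validObject(partition)
  if (!isTRUE(relativeMap@relative))
    stop("segmentAar needs a normalized (relative) map; run normalizePerfusion first")
  if (!identical(dim(relativeMap@values), dim(partition@labels)))
    stop("map and partition dimensions differ")
  ipsi <- partition@labels == 1L
  if (!any(ipsi)) stop("empty ipsilateral partition")
  mask <- ipsi & relativeMap@converged & !is.na(relativeMap@values) &
    relativeMap@values < threshold
  ## uniform voxel volume: the volume weighting reduces to voxel counts
  aarPercent <- 100 * sum(mask) / sum(ipsi)
  nSlice <- dim(mask)[1]
  perSlice <- vapply(seq_len(nSlice), function(s) {
    ni <- sum(ipsi[s, , ])
    if (ni == 0L) return(NA_real_)
    100 * sum(mask[s, , ]) / ni
  }, numeric(1))
  new("AARResult", mask = mask, aarPercent = aarPercent,
      perSlice = perSlice, threshold = threshold)
}
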