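#' @include AllClasses.R utils.R
NULL

## mean of the trace over [a, b]; falls back to the nearest sample
.windowMean <- function(time, value, a, b) {
  sel <- time >= a & time <= b
  if (!any(sel)) value[which.min(abs(time - (a + b) / 2))]
  else mean(value[sel])
}

#' Detect mPTP opening in a CRC fluorescence trace
#'
#' For each CaCl2 pulse the recovery ratio
#' \deqn{r_k = \frac{F(\mathrm{end\ of\ window}) - F_{pre}}{F_{peak} - F_{pre}}}
#' compares the fluorescence at the end of the inter-pulse window (a
#' fraction \code{window} of the pulse interval) with the post-pulse peak,
#' both relative to the pre-pulse baseline. A fully sequestered bolus
#' recovers to baseline (\eqn{r_k \approx 0}); the bolus that triggers
#' mPTP opening never recovers (\eqn{r_k \to 1}). Opening is the first
#' pulse with \eqn{r_k >} \code{recoveryThreshold}, or the onset of a
#' sustained monotone rise between pulses; if neither occurs the assay is
#' censored (\code{openingTime} NA, all usable pulses retained). The
#' triggering pulse is not counted as retained.
#'
#' @param trace a \linkS4class{CrcTrace}
#' @param recoveryThreshold recovery-ratio cutoff (default 0.5).
#' @param window fraction of the inter-pulse interval at which recovery is
#'   read out (default 0.9).
#' @param detrend subtract a linear baseline fitted to the pre-first-pulse
#'   segment (off by default).
#' @return list with \code{nRetained}, \code{openingTime} (NA when
#'   censored), \code{recoveryRatio} per pulse and \code{pulseUsable}
#'   flags (FALSE when a bolus produced no detectable jump)
#' @export
detectMptpOpening <- function(trace, recoveryThreshold = 0.5, window = 0.9,
                              detrend = FALSE) {
  validObject(trace)
  pt <- trace@pulseTimes
  if (length(pt) < 1L) stop("at least one pulse is required")
  tm <- trace@time
  f <- trace@fluorescence
  if (detrend && any(tm < pt[1])) {
    pre <- tm < pt[1]
    if (sum(pre) >= 2L) {
      co <- stats::coef(stats::lm(f[pre] ~ tm[pre]))
      f <- f - (co[1] + co[2] * tm) + mean(f[pre])
    }
  }
  interval <- if (length(pt) > 1L) stats::median(diff(pt))
  else max(tm) - pt[1]
  if (interval <= 0) stop("degenerate pulse spacing")

  P <- length(pt)
  ratio <- rep(NA_real_, P)
  usable <- rep(TRUE, P)
  jumps <- rep(NA_real_, P)
  for (k in seq_len(P)) {
    base <- .windowMean(tm, f, pt[k] - 0.1 * interval, pt[k] - 1e-9)
    peakWin <- tm >= pt[k] & tm <= min(pt[k] + window * interval, max(tm))
    if (!any(peakWin)) { usable[k] <- FALSE; next }
    peak <- max(f[peakWin])
    if (peak <= base) { usable[k] <- FALSE; next }
    endT <- min(pt[k] + window * interval, max(tm))
    fEnd <- .windowMean(tm, f, endT - 0.05 * interval, endT)
    ratio[k] <- (fEnd - base) / (peak - base)
    jumps[k] <- peak - base
  }

  openingIdx <- which(usable & !is.na(ratio) & ratio > recoveryThreshold)
  openingIdx <- if (length(openingIdx)) openingIdx[1] else NA_integer_
  openingTime <- if (is.na(openingIdx)) NA_real_ else pt[openingIdx]

  if (is.na(openingIdx)) {
    ## fallback: sustained monotone rise between pulses (no bolus trigger)
    rise <- .sustainedRiseOnset(tm, f, pt, interval,
                                minRise = stats::median(jumps, na.rm = TRUE) / 2)
    if (!is.na(rise$time)) {
      openingTime <- rise$time
      openingIdx <- rise$afterPulse + 1L   # opening before pulse afterPulse+1
    }
  }

  retainedUpTo <- if (is.na(openingIdx)) P else openingIdx - 1L
  nRetained <- sum(usable[seq_len(retainedUpTo)] &
                     !is.na(ratio[seq_len(retainedUpTo)]) &
                     ratio[seq_len(retainedUpTo)] <= recoveryThreshold)
  list(nRetained = as.integer(nRetained), openingTime = openingTime,
       recoveryRatio = ratio, pulseUsable = usable)
}

## Onset of a sustained monotone rise between pulses: a span of at least
## half an inter-pulse interval whose smoothed signal never decreases and
## rises by at least minRise in total. Returns the onset time and the index
## of the last pulse before it.
.sustainedRiseOnset <- function(tm, f, pt, interval, minRise) {
  if (!is.finite(minRise)) minRise <- (max(f) - min(f)) / 4
  dt <- stats::median(diff(tm))
  w <- max(3L, ceiling(2 / dt))
  fs <- stats::filter(f, rep(1 / w, w), sides = 2)
  gaps <- rbind(cbind(pt + 0.25 * interval, c(pt[-1], max(tm))))
  for (g in seq_len(nrow(gaps))) {
    sel <- which(tm >= gaps[g, 1] & tm <= gaps[g, 2] & !is.na(fs))
    if (length(sel) < 5L) next
    inc <- diff(fs[sel]) >= -1e-12
    r <- rle(inc)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      span <- tm[sel[ends[j] + 1L]] - tm[sel[starts[j]]]
      rise <- fs[sel[ends[j] + 1L]] - fs[sel[starts[j]]]
      if (!is.na(span) && span >= interval / 2 && rise >= minRise)
        return(list(time = tm[sel[starts[j]]], afterPulse = g))
    }
  }
  list(time = NA_real_, afterPulse = NA_integer_)
}

#' Compute the calcium retention capacity
#'
#' Runs \code{\link{detectMptpOpening}} and converts the retained pulses to
#' nmol Ca2+ per mg protein:
#' \deqn{CRC = n_{retained} \times \frac{V_{pulse}[\mu L] \times C_{pulse}[\mu M] \times 10^{-3}}{protein\,[mg]}.}
#' Under the default assay constants (10 uL of 500 uM CaCl2, 0.5 mg
#' protein) each retained pulse contributes 10 nmol/mg.
#'
#' @param trace a \linkS4class{CrcTrace}
#' @param recoveryThreshold,window,detrend passed to
#'   \code{\link{detectMptpOpening}}.
#' @return a \linkS4class{CrcResult}
#' @export
computeCrc <- function(trace, recoveryThreshold = 0.5, window = 0.9,
                       detrend = FALSE) {
  validObject(trace)
  if (trace@proteinMg <= 0) stop("proteinMg must be > 0")
  det <- detectMptpOpening(trace, recoveryThreshold, window, detrend)
  pulseNmol <- trace@pulseVolumeUl * trace@pulseConcUM * 1e-3
  crc <- det$nRetained * pulseNmol / trace@proteinMg
  new("CrcResult", nRetained = det$nRetained, openingTime = det$openingTime,
      crcNmolPerMg = crc, pulseUsable = det$pulseUsable)
}

#' Segment an oxygraph trace into titration stages
#'
#' Each stage runs from its substrate/inhibitor addition (plus a settling
#' period equal to \code{settleFraction} of the stage duration, skipping
#' injection artifacts) to the next addition; the last stage ends at the
#' end of the trace. Stages are named by the cumulative titration state
#' (GM, GM+ADP, +rotenone, +succinate, +TTFA, +TMPD/ascorbate, +azide).
#'
#' @param trace an \linkS4class{OxygraphTrace}
#' @param settleFraction fraction of each stage discarded after the
#'   injection (default 0.25).
#' @return data.frame with columns \code{stage}, \code{eventTime},
#'   \code{start}, \code{end}
#' @export
segmentStages <- function(trace, settleFraction = 0.25) {
  validObject(trace)
  ev <- trace@events
  if (nrow(ev) < 1L) stop("at least one titration event is required")
  if (nrow(ev) > 1L && any(diff(ev$time_s) <= 0))
    stop("unordered or overlapping titration events")
  if (settleFraction < 0 || settleFraction >= 1)
    stop("settleFraction must be in [0, 1)")
  tEnd <- max(trace@time)
  bounds <- c(ev$time_s, tEnd)
  data.frame(
    stage = unname(.stageNameMap[ev$label]),
    eventTime = ev$time_s,
    start = ev$time_s + settleFraction * (bounds[-1] - ev$time_s),
    end = bounds[-1],
    stringsAsFactors = FALSE)
}

#' Oxygen consumption rate of one stage
#'
#' Least-squares slope of the O2 concentration over the stage window,
#' converted to a mass-specific rate:
#' \deqn{OCR = -slope\,[\mathrm{nmol/mL/min}] \times chamber\,[mL] / protein\,[mg].}
#'
#' @param trace an \linkS4class{OxygraphTrace}
#' @param window one row of \code{\link{segmentStages}} output (or any
#'   list with \code{start} and \code{end} in seconds).
#' @return OCR in nmol O2/min/mg
#' @export
computeStageOcr <- function(trace, window) {
  validObject(trace)
  sel <- trace@time >= window$start & trace@time <= window$end
  if (sum(sel) < 5L)
    stop("fewer than 5 samples in the stage window")
  t <- trace@time[sel]
  y <- trace@o2Conc[sel]
  slopePerS <- stats::cov(t, y) / stats::var(t)
  -(slopePerS * 60) * trace@chamberMl / trace@proteinMg
}

#' Per-stage OCRs of a whole titration trace
#'
#' Convenience wrapper: segments the trace and computes the OCR of every
#' stage.
#'
#' @param trace an \linkS4class{OxygraphTrace}
#' @param settleFraction passed to \code{\link{segmentStages}}.
#' @return named numeric vector of stage OCRs (nmol O2/min/mg)
#' @export
stageOcrs <- function(trace, settleFraction = 0.25) {
  win <- segmentStages(trace, settleFraction)
  stats::setNames(
    vapply(seq_len(nrow(win)),
           function(i) computeStageOcr(trace, win[i, ]), numeric(1)),
    win$stage)
}

#' Inhibitor-sensitive complex respiration rates
#'
#' The complex-wise rates are stimulated-minus-inhibited differences of
#' stage OCRs: CI = OCR(GM+ADP) - OCR(+rotenone), CII = OCR(+succinate) -
#' OCR(+TTFA), CIV = OCR(+TMPD/ascorbate) - OCR(+azide). A missing stage
#' leaves the corresponding rate NA and flagged.
#'
#' @param ocrs named numeric vector of stage OCRs (names as produced by
#'   \code{\link{stageOcrs}}).
#' @return a \linkS4class{ComplexRates}
#' @export
computeComplexRates <- function(ocrs) {
  need <- list(CI = c("GM+ADP", "+rotenone"),
               CII = c("+succinate", "+TTFA"),
               CIV = c("+TMPD/ascorbate", "+azide"))
  missing <- character()
  rate <- function(pair) {
    absent <- setdiff(pair, names(ocrs))
    if (length(absent)) {
      missing <<- c(missing, absent)
      return(NA_real_)
    }
    unname(ocrs[pair[1]] - ocrs[pair[2]])
  }
  new("ComplexRates", stageOcr = ocrs,
      ci = rate(need$CI), cii = rate(need$CII), civ = rate(need$CIV),
      missingStages = unique(missing))
}
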