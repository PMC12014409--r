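#' @include AllClasses.R utils.R
NULL

#' Construct a CRC trace specification
#'
#' Defaults follow the assay protocol: 0.5 mg mitochondrial protein in a
#' 2 mL cuvette, a 2-minute stabilization phase, then 10 uL boluses of
#' 500 uM CaCl2 every 60 s. Each retained bolus contributes
#' 10 uL x 500 uM / 0.5 mg = 10 nmol Ca2+ per mg.
#'
#' @param nRetained pulses fully sequestered before mPTP opening.
#' @param pulseInterval seconds between boluses.
#' @param pulseJump fluorescence jump per bolus (a.u.).
#' @param uptakeTau uptake time constant (s).
#' @param recoveryFloor baseline fluorescence (a.u.).
#' @param burstSlope post-opening sustained rise (a.u./s).
#' @param samplingDt sampling period (s).
#' @param stabilizationS pre-pulse stabilization (s).
#' @param noiseSd additive Gaussian noise (a.u.).
#' @param proteinMg,pulseVolumeUl,pulseConcUM assay constants.
#' @param seed integer random seed.
#' @return a \linkS4class{CrcTraceSpec}
#' @export
crcTraceSpec <- function(nRetained = 7L, pulseInterval = 60, pulseJump = 100,
                         uptakeTau = 8, recoveryFloor = 20, burstSlope = 2,
                         samplingDt = 1, stabilizationS = 120, noiseSd = 0,
                         proteinMg = 0.5, pulseVolumeUl = 10,
                         pulseConcUM = 500, seed = 1L) {
  new("CrcTraceSpec", nRetained = asCount(nRetained, "nRetained"),
      pulseInterval = pulseInterval, pulseJump = pulseJump,
      uptakeTau = uptakeTau, recoveryFloor = recoveryFloor,
      burstSlope = burstSlope, samplingDt = samplingDt,
      stabilizationS = stabilizationS, noiseSd = noiseSd,
      proteinMg = proteinMg, pulseVolumeUl = pulseVolumeUl,
      pulseConcUM = pulseConcUM, seed = asCount(seed, "seed"))
}

#' Generate a synthetic calcium retention capacity trace
#'
#' Simulates the Calcium Green fluorescence of the CRC assay: pulses
#' 1..\code{nRetained} each produce an instantaneous fluorescence jump
#' followed by exponential decay back toward baseline (mitochondrial Ca2+
#' uptake); pulse \code{nRetained + 1} triggers mPTP opening, after which
#' the signal rises with slope \code{burstSlope} and never recovers.
#'
#' @param spec a \linkS4class{CrcTraceSpec}
#' @return list with \code{trace} (a \linkS4class{CrcTrace}) and
#'   \code{truth} (list with \code{nRetained} and \code{openingPulseTime}).
#' @examples
#' tr <- makeCrcTrace(crcTraceSpec(nRetained = 5))
#' computeCrc(tr$trace)
#' @export
makeCrcTrace <- function(spec) {
  validObject(spec)
  nPulses <- spec@nRetained + 1L
  pulseTimes <- spec@stabilizationS + (seq_len(nPulses) - 1L) * spec@pulseInterval
  openTime <- pulseTimes[nPulses]
  tEnd <- openTime + 1.5 * spec@pulseInterval
  time <- seq(0, tEnd, by = spec@samplingDt)

  f <- rep(spec@recoveryFloor, length(time))
  if (spec@nRetained > 0L) {
    for (k in seq_len(spec@nRetained)) {
      dt <- time - pulseTimes[k]
      on <- dt >= 0
      f[on] <- f[on] + spec@pulseJump * exp(-dt[on] / spec@uptakeTau)
    }
  }
  dt <- time - openTime
  on <- dt >= 0
  f[on] <- f[on] + spec@pulseJump + spec@burstSlope * dt[on]

  if (spec@noiseSd > 0)
    f <- f + withSeed(spec@seed, stats::rnorm(length(f), sd = spec@noiseSd))

  trace <- new("CrcTrace", time = time, fluorescence = f,
               pulseTimes = pulseTimes, proteinMg = spec@proteinMg,
               pulseVolumeUl = spec@pulseVolumeUl,
               pulseConcUM = spec@pulseConcUM, chamberMl = 2)
  list(trace = trace,
       truth = list(nRetained = spec@nRetained, openingPulseTime = openTime))
}

#' Default substrate-inhibitor titration plan
#'
#' Stage events of the standard protocol with plausible healthy-cortex
#' stage OCRs (nmol O2/min/mg): glutamate/pyruvate/malate (GM), ADP
#' (complex I stimulated), rotenone (CI inhibited), succinate (CII
#' stimulated), TTFA (CII inhibited), TMPD/ascorbate (CIV stimulated),
#' azide (CIV inhibited).
#'
#' @param ocrs named numeric vector of true stage OCRs, names from the
#'   titration vocabulary.
#' @param stageS duration of each stage (s).
#' @param startS time of the first event (s).
#' @return data.frame with columns label, time_s, ocr
#' @export
titrationPlan <- function(ocrs = c(GM = 3, ADP = 24, rotenone = 2,
                                   succinate = 16, TTFA = 4,
                                   TMPD_ascorbate = 25, azide = 6),
                          stageS = 180, startS = 60) {
  data.frame(label = names(ocrs),
             time_s = startS + (seq_along(ocrs) - 1L) * stageS,
             ocr = unname(ocrs), stringsAsFactors = FALSE)
}

#' Construct an oxygraph trace specification
#'
#' @param stagePlan data.frame (label, time_s, ocr); see
#'   \code{\link{titrationPlan}}.
#' @param initialO2 starting O2 concentration (nmol/mL).
#' @param chamberMl chamber volume (mL).
#' @param proteinMg mitochondrial protein (mg).
#' @param samplingDt sampling period (s).
#' @param tailS simulated duration after the last event (s).
#' @param noiseSd additive Gaussian concentration noise (nmol/mL).
#' @param seed integer random seed.
#' @return an \linkS4class{OxygraphSpec}
#' @export
oxygraphSpec <- function(stagePlan = titrationPlan(), initialO2 = 200,
                         chamberMl = 2, proteinMg = 0.5, samplingDt = 1,
                         tailS = 180, noiseSd = 0, seed = 1L) {
  new("OxygraphSpec", stagePlan = stagePlan, initialO2 = initialO2,
      chamberMl = chamberMl, proteinMg = proteinMg, samplingDt = samplingDt,
      tailS = tailS, noiseSd = noiseSd, seed = asCount(seed, "seed"))
}

#' Generate a synthetic oxygraph trace
#'
#' The O2 concentration is piecewise linear: within each titration stage it
#' falls at \eqn{OCR \times proteinMg / chamberMl} nmol/mL/min (flat before
#' the first event), plus optional Gaussian noise. A plan that would drive
#' the concentration below zero is rejected with a diagnostic.
#'
#' @param spec an \linkS4class{OxygraphSpec}
#' @return list with \code{trace} (an \linkS4class{OxygraphTrace}) and
#'   \code{truth} (named numeric vector of per-stage OCRs).
#' @examples
#' ox <- makeOxygraphTrace(oxygraphSpec())
#' computeComplexRates(stageOcrs(ox$trace))
#' @export
makeOxygraphTrace <- function(spec) {
  validObject(spec)
  plan <- spec@stagePlan
  tEnd <- plan$time_s[nrow(plan)] + spec@tailS
  time <- seq(0, tEnd, by = spec@samplingDt)

  ## concentration slope per second within each stage
  slopePerS <- -(plan$ocr * spec@proteinMg / spec@chamberMl) / 60
  breaks <- c(plan$time_s, tEnd)
  o2 <- rep(spec@initialO2, length(time))
  level <- spec@initialO2
  for (k in seq_len(nrow(plan))) {
    inStage <- time >= breaks[k] & time <= breaks[k + 1]
    o2[inStage] <- level + slopePerS[k] * (time[inStage] - breaks[k])
    level <- level + slopePerS[k] * (breaks[k + 1] - breaks[k])
  }
  if (min(o2) < 0)
    stop(sprintf(paste("stage plan exhausts chamber O2: concentration",
                       "reaches %.2f nmol/mL; lower stage OCRs, shorten",
                       "stages or raise initialO2"), min(o2)))
  if (spec@noiseSd > 0)
    o2 <- o2 + withSeed(spec@seed, stats::rnorm(length(o2), sd = spec@noiseSd))

  trace <- new("OxygraphTrace", time = time, o2Conc = o2,
               events = data.frame(time_s = plan$time_s, label = plan$label,
                                   stringsAsFactors = FALSE),
               chamberMl = spec@chamberMl, proteinMg = spec@proteinMg)
  truth <- stats::setNames(plan$ocr, unname(.stageNameMap[plan$label]))
  list(trace = trace, truth = truth)
}
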