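#' @import methods
NULL

## ---------------------------------------------------------------------------
## Simulation specification objects
## ---------------------------------------------------------------------------

#' CEUS phantom specification
#'
#' Parameters of the synthetic dynamic contrast-enhanced ultrasound (CEUS)
#' burst-replenishment phantom. The phantom mimics a per-occlusion
#' acquisition: a flat pre-burst plateau, a destruction burst, then per-voxel
#' replenishment \eqn{I(t) = I_0 + A(1 - e^{-\beta (t - t_{burst})})}.
#' Lesion (hypoperfused) voxels have their plateau amplitude scaled so that
#' the perfusion index \eqn{A\beta} equals \code{lesionRelativePerfusion}
#' times the contralateral value.
#'
#' @slot grid integer of length 3: slices, rows, cols (default 4 x 64 x 64,
#'   four slice levels as acquired).
#' @slot nFrames number of frames.
#' @slot frameInterval seconds between frames.
#' @slot burstFrame 1-based index of the destruction-burst frame.
#' @slot baselineIntensity pre-burst plateau and post-burst floor \eqn{I_0},
#'   arbitrary units.
#' @slot contralateralA plateau amplitude \eqn{A} of healthy tissue (a.u.).
#' @slot contralateralBeta replenishment rate \eqn{\beta} of healthy tissue
#'   (1/s).
#' @slot lesionRelativePerfusion lesion perfusion index relative to
#'   contralateral, in \[0, 1).
#' @slot lesionFraction fraction of ipsilateral-hemisphere voxels inside the
#'   lesion.
#' @slot noiseSd additive Gaussian intensity noise (a.u.).
#' @slot seed integer random seed.
#' @exportClass CeusPhantomSpec
setClass("CeusPhantomSpec",
  representation(
    grid = "integer",
    nFrames = "integer",
    frameInterval = "numeric",
    burstFrame = "integer",
    baselineIntensity = "numeric",
    contralateralA = "numeric",
    contralateralBeta = "numeric",
    lesionRelativePerfusion = "numeric",
    lesionFraction = "numeric",
    noiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("CeusPhantomSpec", function(object) {
  msg <- character()
  if (length(object@grid) != 3L || any(object@grid < 1L))
    msg <- c(msg, "grid must be 3 positive voxel counts (slices, rows, cols)")
  if (length(object@grid) == 3L && object@grid[3] < 2L)
    msg <- c(msg, "grid needs >= 2 columns to hold two hemispheres")
  if (object@nFrames < 2L) msg <- c(msg, "nFrames must be >= 2")
  if (object@burstFrame < 1L || object@burstFrame > object@nFrames)
    msg <- c(msg, "burstFrame must lie within 1..nFrames")
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
  if (object@lesionFraction < 0 || object@lesionFraction > 1)
    msg <- c(msg, "lesionFraction must be in [0, 1]")
  if (object@lesionRelativePerfusion < 0 || object@lesionRelativePerfusion >= 1)
    msg <- c(msg, "lesionRelativePerfusion must be in [0, 1)")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@contralateralA < 0 || object@contralateralBeta <= 0)
    msg <- c(msg, "contralateral A must be >= 0 and beta > 0")
  if (length(msg)) msg else TRUE
})

#' Calcium-retention-capacity trace specification
#'
#' Parameters of a synthetic Calcium Green fluorescence trace of the CRC
#' assay: isolated mitochondria sequester successive CaCl2 boluses (the
#' fluorescence of extramitochondrial Ca2+ jumps at each pulse, then decays
#' as Ca2+ is taken up) until the mitochondrial permeability transition pore
#' (mPTP) opens and the retained Ca2+ is released in a terminal burst.
#'
#' @slot nRetained pulses fully sequestered before mPTP opening (ground
#'   truth).
#' @slot pulseInterval seconds between pulses (default 60: one per minute).
#' @slot pulseJump fluorescence jump per bolus (a.u.).
#' @slot uptakeTau exponential uptake time constant (s).
#' @slot recoveryFloor baseline fluorescence (a.u.).
#' @slot burstSlope sustained fluorescence rise after opening (a.u./s).
#' @slot samplingDt sampling period (s); must resolve the inter-pulse
#'   interval.
#' @slot stabilizationS pre-pulse stabilization phase (s, default 120).
#' @slot noiseSd additive Gaussian noise (a.u.).
#' @slot proteinMg mitochondrial protein in the cuvette (mg, default 0.5).
#' @slot pulseVolumeUl bolus volume (uL, default 10).
#' @slot pulseConcUM bolus CaCl2 concentration (uM, default 500).
#' @slot seed integer random seed.
#' @exportClass CrcTraceSpec
setClass("CrcTraceSpec",
  representation(
    nRetained = "integer",
    pulseInterval = "numeric",
    pulseJump = "numeric",
    uptakeTau = "numeric",
    recoveryFloor = "numeric",
    burstSlope = "numeric",
    samplingDt = "numeric",
    stabilizationS = "numeric",
    noiseSd = "numeric",
    proteinMg = "numeric",
    pulseVolumeUl = "numeric",
    pulseConcUM = "numeric",
    seed = "integer"
  )
)

setValidity("CrcTraceSpec", function(object) {
  msg <- character()
  if (object@nRetained < 0L) msg <- c(msg, "nRetained must be >= 0")
  if (object@uptakeTau <= 0) msg <- c(msg, "uptakeTau must be > 0")
  if (object@samplingDt <= 0 || object@samplingDt >= object@pulseInterval)
    msg <- c(msg, "samplingDt must be positive and smaller than pulseInterval")
  if (object@pulseInterval <= 0) msg <- c(msg, "pulseInterval must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@proteinMg <= 0) msg <- c(msg, "proteinMg must be > 0")
  if (object@burstSlope <= 0) msg <- c(msg, "burstSlope must be > 0")
  if (length(msg)) msg else TRUE
})

#' Oxygraph trace specification
#'
#' Parameters of a synthetic closed-chamber respirometry trace under a
#' substrate-inhibitor titration: within each stage the O2 concentration
#' falls linearly at \eqn{-OCR \times mg / mL} (nmol/mL/min).
#'
#' @slot stagePlan data.frame with columns \code{label} (titration
#'   vocabulary), \code{time_s} (strictly increasing event times) and
#'   \code{ocr} (true stage OCR, nmol O2/min/mg).
#' @slot initialO2 starting O2 concentration (nmol/mL).
#' @slot chamberMl chamber volume (mL, default 2).
#' @slot proteinMg mitochondrial protein (mg, default 0.5).
#' @slot samplingDt sampling period (s).
#' @slot tailS duration simulated after the last event (s).
#' @slot noiseSd additive Gaussian noise on concentration (nmol/mL).
#' @slot seed integer random seed.
#' @exportClass OxygraphSpec
setClass("OxygraphSpec",
  representation(
    stagePlan = "data.frame",
    initialO2 = "numeric",
    chamberMl = "numeric",
    proteinMg = "numeric",
    samplingDt = "numeric",
    tailS = "numeric",
    noiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("OxygraphSpec", function(object) {
  msg <- character()
  p <- object@stagePlan
  if (nrow(p) < 1L) msg <- c(msg, "stagePlan must contain at least one stage")
  if (!all(c("label", "time_s", "ocr") %in% names(p)))
    msg <- c(msg, "stagePlan needs columns label, time_s, ocr")
  else {
    if (is.unsorted(p$time_s, strictly = TRUE))
      msg <- c(msg, "stage event times must be strictly increasing")
    if (any(p$ocr < 0)) msg <- c(msg, "stage OCRs must be >= 0")
  }
  if (object@initialO2 <= 0) msg <- c(msg, "initialO2 must be > 0")
  if (object@chamberMl <= 0 || object@proteinMg <= 0)
    msg <- c(msg, "chamberMl and proteinMg must be > 0")
  if (object@samplingDt <= 0) msg <- c(msg, "samplingDt must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort specification
#'
#' Group sizes, per-endpoint log-normal targets (parameterized by median and
#' quartiles), neuroscore category probabilities and exclusion rates of a
#' simulated MCAO cohort. Defaults are calibrated to a four-arm design
#' (Sham, tMCAO, tMCAO_CsA, pMCAO).
#'
#' @slot groupSizes named integer vector of animals per group.
#' @slot endpointTargets data.frame with columns \code{group},
#'   \code{endpoint}, \code{median}, \code{q25}, \code{q75}.
#' @slot neuroscoreProbs numeric matrix, one row per group, columns scores
#'   0..5; rows sum to 1.
#' @slot exclusionProb named numeric vector per group, in \[0, 1).
#' @slot severityCoupling loading of the latent per-animal ischemic
#'   severity factor, in \[0, 1): lesion-side endpoints (AAR, lesion
#'   burden) load positively, protective ipsilateral endpoints (CRC, OCR)
#'   negatively, contralateral endpoints not at all. Marginal
#'   distributions are unchanged; only the within-group dependence is.
#' @slot seed integer random seed.
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(
    groupSizes = "integer",
    endpointTargets = "data.frame",
    neuroscoreProbs = "matrix",
    exclusionProb = "numeric",
    severityCoupling = "numeric",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (is.null(names(object@groupSizes)) || any(object@groupSizes < 0L))
    msg <- c(msg, "groupSizes must be a named vector of non-negative counts")
  if (!all(c("group", "endpoint", "median", "q25", "q75") %in%
             names(object@endpointTargets)))
    msg <- c(msg, "endpointTargets needs columns group, endpoint, median, q25, q75")
  pr <- object@neuroscoreProbs
  if (ncol(pr) != 6L || any(pr < 0) ||
      any(abs(rowSums(pr) - 1) > 1e-8))
    msg <- c(msg, "neuroscoreProbs must have 6 columns (scores 0-5) with rows summing to 1")
  if (any(object@exclusionProb < 0 | object@exclusionProb >= 1))
    msg <- c(msg, "exclusionProb must be in [0, 1)")
  if (length(object@severityCoupling) != 1L ||
      object@severityCoupling < 0 || object@severityCoupling >= 1)
    msg <- c(msg, "severityCoupling must be a single value in [0, 1)")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Imaging containers
## ---------------------------------------------------------------------------

#' Dynamic contrast-enhanced ultrasound sequence
#'
#' A 4D intensity stack (slice, time, row, col) with frame times and the
#' index of the microbubble destruction burst. This is the input to
#' per-voxel burst-replenishment fitting.
#'
#' @slot frames 4D numeric array, dimensions (slice, time, row, col), a.u.
#' @slot frameTimes strictly increasing frame times (s).
#' @slot burstFrame 1-based index of the destruction burst frame.
#' @slot voxelSize in-plane voxel size (mm, length 2).
#' @slot sliceSpacing slice spacing (mm).
#' @exportClass DynamicSequence
setClass("DynamicSequence",
  representation(
    frames = "array",
    frameTimes = "numeric",
    burstFrame = "integer",
    voxelSize = "numeric",
    sliceSpacing = "numeric"
  )
)

setValidity("DynamicSequence", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 4L || any(d < 1L))
    msg <- c(msg, "frames must be a 4D array (slice, time, row, col) with all dims >= 1")
  if (length(d) == 4L && length(object@frameTimes) != d[2])
    msg <- c(msg, "frameTimes length must equal the time dimension")
  if (is.unsorted(object@frameTimes, strictly = TRUE))
    msg <- c(msg, "frameTimes must be strictly increasing")
  if (object@burstFrame < 1L || object@burstFrame > length(object@frameTimes))
    msg <- c(msg, "burstFrame out of range")
  if (length(object@voxelSize) != 2L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be two positive lengths (mm)")
  if (object@sliceSpacing <= 0) msg <- c(msg, "sliceSpacing must be > 0")
  if (length(msg)) msg else TRUE
})

#' Hemisphere partition
#'
#' Per-voxel hemisphere labels: 0 background, 1 ipsilateral (the occluded
#' right hemisphere), 2 contralateral.
#'
#' @slot labels 3D integer array (slice, row, col) with values in {0, 1, 2}.
#' @exportClass HemispherePartition
setClass("HemispherePartition", representation(labels = "array"))

setValidity("HemispherePartition", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3D array (slice, row, col)")
  if (!all(object@labels %in% c(0L, 1L, 2L)))
    msg <- c(msg, "labels must be 0 (background), 1 (ipsilateral) or 2 (contralateral)")
  if (length(msg)) msg else TRUE
})

#' Single-voxel burst-replenishment fit
#'
#' Least-squares estimates of the model
#' \eqn{I(t) = I_0 + A (1 - e^{-\beta (t - t_{burst})})} on the post-burst
#' samples of one time-intensity curve.
#'
#' @slot i0 post-burst baseline intensity (a.u.).
#' @slot a plateau amplitude (a.u., >= 0).
#' @slot beta replenishment rate (1/s, >= 0).
#' @slot rss residual sum of squares.
#' @slot converged logical convergence flag.
#' @exportClass ReplenishmentFit
setClass("ReplenishmentFit",
  representation(i0 = "numeric", a = "numeric", beta = "numeric",
                 rss = "numeric", converged = "logical"))

setValidity("ReplenishmentFit", function(object) {
  msg <- character()
  if (isTRUE(object@converged)) {
    if (!is.na(object@a) && object@a < 0) msg <- c(msg, "A must be >= 0")
    if (!is.na(object@beta) && object@beta < 0) msg <- c(msg, "beta must be >= 0")
    if (!is.na(object@rss) && object@rss < 0) msg <- c(msg, "rss must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Voxelwise perfusion map
#'
#' Per-voxel perfusion index \eqn{PI = A\beta} (a.u./s), or its
#' contralateral-median-normalized (dimensionless) form, with a mask of
#' voxels whose fit did not converge (these are excluded from all
#' downstream statistics, never zeroed).
#'
#' @slot values 3D numeric array (slice, row, col); NA where non-converged.
#' @slot converged 3D logical array.
#' @slot relative TRUE once normalized to the contralateral median.
#' @slot voxelSize in-plane voxel size (mm).
#' @slot sliceSpacing slice spacing (mm).
#' @exportClass PerfusionMap
setClass("PerfusionMap",
  representation(values = "array", converged = "array", relative = "logical",
                 voxelSize = "numeric", sliceSpacing = "numeric"))

setValidity("PerfusionMap", function(object) {
  msg <- character()
  if (!identical(dim(object@values), dim(object@converged)))
    msg <- c(msg, "values and converged must have identical dimensions")
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "perfusion map must be 3D (slice, row, col)")
  if (length(msg)) msg else TRUE
})

#' Area-at-risk segmentation result
#'
#' Voxels of the ipsilateral hemisphere whose relative perfusion falls
#' strictly below the hypoperfusion threshold, and the AAR expressed as a
#' percentage of the ipsilateral hemisphere volume.
#'
#' @slot mask 3D logical AAR mask (subset of ipsilateral voxels).
#' @slot aarPercent AAR as percent of ipsilateral hemisphere volume.
#' @slot perSlice per-slice AAR percent.
#' @slot threshold relative hypoperfusion threshold used (default 0.26).
#' @exportClass AARResult
setClass("AARResult",
  representation(mask = "array", aarPercent = "numeric",
                 perSlice = "numeric", threshold = "numeric"))

setValidity("AARResult", function(object) {
  msg <- character()
  if (object@aarPercent < 0 || object@aarPercent > 100)
    msg <- c(msg, "aarPercent must be within [0, 100]")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Lesion volumetry containers
## ---------------------------------------------------------------------------

#' Lesion label volume
#'
#' Integer label volume from manual contouring: 0 background, 1 lesion,
#' 2 ipsilateral non-lesion tissue, 3 contralateral hemisphere. Lesion
#' voxels are by construction a subset of the ipsilateral hemisphere
#' (labels 1 + 2).
#'
#' @slot labels 3D integer array.
#' @slot voxelVolume volume of one voxel (mm^3).
#' @exportClass LesionLabelVolume
setClass("LesionLabelVolume",
  representation(labels = "array", voxelVolume = "numeric"))

setValidity("LesionLabelVolume", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be 3D")
  if (!all(object@labels %in% 0:3))
    msg <- c(msg, "labels must be in {0 background, 1 lesion, 2 ipsi, 3 contra}")
  if (object@voxelVolume <= 0) msg <- c(msg, "voxelVolume must be > 0")
  if (length(msg)) msg else TRUE
})

#' Edema-corrected lesion volumetry
#'
#' Raw volumes plus the Gerriets edema-corrected lesion burden
#' \eqn{\%HLVc = 100 (HV_c - (HV_i - LV)) / HV_c} and, when an AAR percent
#' is supplied, the primary endpoint \eqn{100 \times \%HLVc / \%AAR}.
#'
#' @slot lv lesion volume (mm^3).
#' @slot hvi ipsilateral hemisphere volume, lesion included (mm^3).
#' @slot hvc contralateral hemisphere volume (mm^3).
#' @slot hlvcPercent edema-corrected lesion as percent of hemisphere.
#' @slot endpointRatio 100 x hlvcPercent / aarPercent (NA if no AAR given).
#' @slot negative TRUE when the corrected lesion is negative (reported, not
#'   clipped).
#' @exportClass LesionVolumetry
setClass("LesionVolumetry",
  representation(lv = "numeric", hvi = "numeric", hvc = "numeric",
                 hlvcPercent = "numeric", endpointRatio = "numeric",
                 negative = "logical"))

setValidity("LesionVolumetry", function(object) {
  if (object@lv > object@hvi + 1e-9) "lesion volume cannot exceed ipsilateral volume"
  else TRUE
})

## ---------------------------------------------------------------------------
## Mitochondrial assay containers
## ---------------------------------------------------------------------------

#' Calcium retention capacity trace
#'
#' Timed Calcium Green fluorescence (a proxy of extramitochondrial Ca2+)
#' with the times of the CaCl2 boluses and the assay constants needed to
#' convert retained pulses to nmol Ca2+ per mg protein.
#'
#' @slot time seconds, strictly increasing.
#' @slot fluorescence a.u.
#' @slot pulseTimes bolus injection times (s), within the trace span.
#' @slot proteinMg mitochondrial protein (mg).
#' @slot pulseVolumeUl bolus volume (uL).
#' @slot pulseConcUM bolus concentration (uM).
#' @slot chamberMl cuvette volume (mL).
#' @exportClass CrcTrace
setClass("CrcTrace",
  representation(time = "numeric", fluorescence = "numeric",
                 pulseTimes = "numeric", proteinMg = "numeric",
                 pulseVolumeUl = "numeric", pulseConcUM = "numeric",
                 chamberMl = "numeric"))

setValidity("CrcTrace", function(object) {
  msg <- character()
  if (length(object@time) != length(object@fluorescence))
    msg <- c(msg, "time and fluorescence must have equal length")
  if (is.unsorted(object@time, strictly = TRUE))
    msg <- c(msg, "time must be strictly increasing")
  if (length(object@pulseTimes) &&
      (min(object@pulseTimes) < min(object@time) ||
       max(object@pulseTimes) > max(object@time)))
    msg <- c(msg, "pulseTimes must lie within the trace span")
  if (object@proteinMg <= 0) msg <- c(msg, "proteinMg must be > 0")
  if (length(msg)) msg else TRUE
})

#' Calcium retention capacity result
#'
#' @slot nRetained pulses fully sequestered before mPTP opening.
#' @slot openingTime time of opening (s), NA when no opening observed.
#' @slot crcNmolPerMg CRC in nmol Ca2+ per mg protein.
#' @slot pulseUsable per-pulse usability flags (FALSE when the bolus
#'   produced no detectable fluorescence jump).
#' @exportClass CrcResult
setClass("CrcResult",
  representation(nRetained = "integer", openingTime = "numeric",
                 crcNmolPerMg = "numeric", pulseUsable = "logical"))

setValidity("CrcResult", function(object) {
  if (object@crcNmolPerMg < 0) "CRC must be >= 0" else TRUE
})

## Titration event vocabulary (cumulative substrate/inhibitor states)
.oxygraphVocabulary <- c("GM", "ADP", "rotenone", "succinate", "TTFA",
                         "TMPD_ascorbate", "azide")
.stageNameMap <- c(GM = "GM", ADP = "GM+ADP", rotenone = "+rotenone",
                   succinate = "+succinate", TTFA = "+TTFA",
                   TMPD_ascorbate = "+TMPD/ascorbate", azide = "+azide")

#' Oxygraph trace
#'
#' Closed-chamber O2 concentration over time with the ordered
#' substrate/inhibitor addition events of the titration protocol
#' (GM, ADP, rotenone, succinate, TTFA, TMPD/ascorbate, azide).
#'
#' @slot time seconds, strictly increasing.
#' @slot o2Conc O2 concentration (nmol/mL).
#' @slot events data.frame with columns \code{time_s} (increasing) and
#'   \code{label} (from the titration vocabulary).
#' @slot chamberMl chamber volume (mL).
#' @slot proteinMg mitochondrial protein (mg).
#' @exportClass OxygraphTrace
setClass("OxygraphTrace",
  representation(time = "numeric", o2Conc = "numeric", events = "data.frame",
                 chamberMl = "numeric", proteinMg = "numeric"))

setValidity("OxygraphTrace", function(object) {
  msg <- character()
  if (length(object@time) != length(object@o2Conc))
    msg <- c(msg, "time and o2Conc must have equal length")
  if (is.unsorted(object@time, strictly = TRUE))
    msg <- c(msg, "time must be strictly increasing")
  ev <- object@events
  if (!all(c("time_s", "label") %in% names(ev)))
    msg <- c(msg, "events needs columns time_s and label")
  else {
    if (!all(ev$label %in% .oxygraphVocabulary))
      msg <- c(msg, paste("event labels must be one of:",
                          paste(.oxygraphVocabulary, collapse = ", ")))
    if (nrow(ev) > 1L && is.unsorted(ev$time_s, strictly = TRUE))
      msg <- c(msg, "event times must be strictly increasing")
  }
  if (object@chamberMl <= 0 || object@proteinMg <= 0)
    msg <- c(msg, "chamberMl and proteinMg must be > 0")
  if (length(msg)) msg else TRUE
})

#' Complex-wise respiration rates
#'
#' Per-stage oxygen consumption rates and the inhibitor-sensitive
#' (stimulated minus inhibited) rates for complexes I, II and IV:
#' CI = OCR(GM+ADP) - OCR(+rotenone), CII = OCR(+succinate) - OCR(+TTFA),
#' CIV = OCR(+TMPD/ascorbate) - OCR(+azide); all in nmol O2/min/mg.
#'
#' @slot stageOcr named numeric vector of stage OCRs.
#' @slot ci,cii,civ inhibitor-sensitive rates; NA and flagged when a
#'   required stage is missing.
#' @slot missingStages labels of stages missing for a requested rate.
#' @exportClass ComplexRates
setClass("ComplexRates",
  representation(stageOcr = "numeric", ci = "numeric", cii = "numeric",
                 civ = "numeric", missingStages = "character"))

## ---------------------------------------------------------------------------
## Statistics containers
## ---------------------------------------------------------------------------

#' Median / interquartile-range summary
#'
#' @slot n sample size.
#' @slot median,q25,q75 order statistics by inclusive linear interpolation.
#' @exportClass GroupSummary
setClass("GroupSummary",
  representation(n = "integer", median = "numeric", q25 = "numeric",
                 q75 = "numeric"))

setValidity("GroupSummary", function(object) {
  if (object@q25 > object@median + 1e-12 || object@median > object@q75 + 1e-12)
    "quartiles must satisfy q25 <= median <= q75" else TRUE
})

#' Hypothesis test result
#'
#' @slot method test name.
#' @slot statistic test statistic (named).
#' @slot pValue two-sided p value in \[0, 1\] (NA when undefined).
#' @slot effect named effect descriptor(s) (median difference, rho,
#'   coefficient, ...).
#' @slot note diagnostic notes (zero variance, low expected counts, ...).
#' @exportClass TestResult
setClass("TestResult",
  representation(method = "character", statistic = "numeric",
                 pValue = "numeric", effect = "numeric", note = "character"))

setValidity("TestResult", function(object) {
  p <- object@pValue
  if (!is.na(p) && (p < 0 || p > 1)) "pValue must be within [0, 1]" else TRUE
})

## ---------------------------------------------------------------------------
## Pipeline containers
## ---------------------------------------------------------------------------

#' End-to-end pipeline configuration
#'
#' Bundles the cohort specification, imaging/assay simulation settings and
#' analysis options of a full synthetic run. All defaults equal the
#' defaults of the individual stage functions.
#'
#' @slot cohort a \linkS4class{CohortSpec}.
#' @slot ceus list of CEUS options (grid, nFrames, frameInterval,
#'   burstFrame, noiseSd, aarThreshold, lesionRelativePerfusion).
#' @slot crc list of CRC assay options (noiseSd, assay constants).
#' @slot oxphos list of oxygraph options.
#' @slot stats list of statistics options.
#' @slot seed global integer seed.
#' @slot outDir output directory ("" to keep results in memory only).
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(cohort = "CohortSpec", ceus = "list", crc = "list",
                 oxphos = "list", stats = "list", seed = "integer",
                 outDir = "character"))

#' Pipeline report
#'
#' @slot animals per-animal endpoint table (one row per randomized animal).
#' @slot summaries long-format group median/IQR table.
#' @slot tests named list of \linkS4class{TestResult} objects.
#' @slot provenance list: config hash, seed, package version.
#' @exportClass PipelineReport
setClass("PipelineReport",
  representation(animals = "data.frame", summaries = "data.frame",
                 tests = "list", provenance = "list"))
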