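#' @include AllClasses.R utils.R
NULL

#' Edema-corrected lesion burden (Gerriets correction)
#'
#' Vasogenic edema inflates the ipsilateral hemisphere at 24 h, so the raw
#' lesion volume overestimates the infarcted tissue. The corrected lesion
#' is the contralateral hemisphere volume minus the unlesioned ipsilateral
#' tissue, expressed as a percentage of the contralateral hemisphere:
#' \deqn{\%HLVc = 100 (HV_c - (HV_i - LV)) / HV_c.}
#' When the two hemispheres have equal volume the correction is the
#' identity (\eqn{100 LV / HV_c}). Negative results (unlesioned ipsilateral
#' tissue exceeding the contralateral hemisphere) are reported with a
#' warning, never clipped.
#'
#' @param lv lesion volume (mm^3).
#' @param hvi ipsilateral hemisphere volume, lesion included (mm^3).
#' @param hvc contralateral hemisphere volume (mm^3).
#' @return edema-corrected lesion, percent of hemisphere
#' @examples
#' gerrietsCorrectedLesion(30, 110, 100)  # 20: edema-corrected
#' @export
gerrietsCorrectedLesion <- function(lv, hvi, hvc) {
  if (any(!is.finite(c(lv, hvi, hvc)))) stop("volumes must be finite")
  if (hvc <= 0) stop("contralateral hemisphere volume must be > 0")
  if (lv < 0 || hvi <= 0) stop("volumes must be positive (lesion may be 0)")
  if (lv > hvi) stop("lesion volume cannot exceed the ipsilateral hemisphere")
  out <- 100 * (hvc - (hvi - lv)) / hvc
  if (out < 0)
    warning(sprintf("negative corrected lesion (%.2f%%): unlesioned ipsilateral tissue exceeds the contralateral hemisphere", out))
  out
}

#' Lesion-to-area-at-risk endpoint
#'
#' The primary endpoint of per-animal infarct normalization: the
#' edema-corrected lesion as a percentage of the area at risk,
#' \eqn{100 \times \%HLVc / \%AAR}. Values above 100\% mean the infarct
#' outgrew the initially hypoperfused territory.
#'
#' @param hlvcPercent edema-corrected lesion (percent of hemisphere).
#' @param aarPercent area at risk (percent of hemisphere).
#' @return percent; NA with a warning when \code{aarPercent} is 0
#'   (undefined; the animal should be flagged)
#' @export
endpointRatio <- function(hlvcPercent, aarPercent) {
  if (any(!is.finite(c(hlvcPercent, aarPercent))))
    stop("inputs must be finite")
  if (aarPercent < 0) stop("aarPercent must be >= 0")
  if (aarPercent == 0) {
    warning("aarPercent is 0: endpoint ratio undefined, animal flagged")
    return(NA_real_)
  }
  100 * hlvcPercent / aarPercent
}

#' Volumetry from a lesion label volume
#'
#' Computes lesion (label 1), ipsilateral (labels 1 + 2) and contralateral
#' (label 3) volumes as voxel count times voxel volume, the Gerriets
#' corrected \%HLVc, and (when an AAR percent is supplied) the
#' \%HLVc/\%AAR endpoint.
#'
#' @param labelVolume a \linkS4class{LesionLabelVolume}
#' @param aarPercent optional AAR percent for the endpoint ratio.
#' @return a \linkS4class{LesionVolumetry}
#' @export
volumetryFromLabels <- function(labelVolume, aarPercent = NA_real_) {
  validObject(labelVolume)
  lab <- labelVolume@labels
  vv <- labelVolume@voxelVolume
  lv <- sum(lab == 1L) * vv
  hvi <- sum(lab == 1L | lab == 2L) * vv
  hvc <- sum(lab == 3L) * vv
  if (hvc == 0) stop("label volume contains no contralateral voxels")
  if (hvi == 0) stop("label volume contains no ipsilateral voxels")
  hlvc <- withCallingHandlers(gerrietsCorrectedLesion(lv, hvi, hvc),
                              warning = function(w) invokeRestart("muffleWarning"))
  ratio <- if (is.na(aarPercent)) NA_real_ else endpointRatio(hlvc, aarPercent)
  new("LesionVolumetry", lv = lv, hvi = hvi, hvc = hvc, hlvcPercent = hlvc,
      endpointRatio = ratio, negative = hlvc < 0)
}

#' Apply the study inclusion/exclusion criteria to one animal record
#'
#' An animal is excluded from the study when it had no vascular occlusion
#' on per-occlusion Doppler or no perfusion defect on CEUS, and excluded
#' from analysis when follow-up was incomplete, the infarct lay outside the
#' MCA territory, or the lesion exceeded the AAR. The first failing
#' criterion, in protocol order, is the reported reason.
#'
#' @param record a one-row data.frame or named list carrying logical flags
#'   \code{occlusion_on_doppler}, \code{perfusion_defect_on_ceus},
#'   \code{complete_followup}, \code{infarct_in_mca_territory},
#'   \code{lesion_within_aar}.
#' @return list with \code{included} (logical), \code{reason} (character,
#'   "" when included) and \code{scope} ("study", "analysis" or "")
#' @export
applyExclusionCriteria <- function(record) {
  criteria <- data.frame(
    flag = c("occlusion_on_doppler", "perfusion_defect_on_ceus",
             "complete_followup", "infarct_in_mca_territory",
             "lesion_within_aar"),
    reason = c("no occlusion on per-occlusion Doppler",
               "no perfusion defect on CEUS",
               "incomplete follow-up",
               "infarct outside MCA territory",
               "lesion exceeds AAR"),
    scope = c("study", "study", "analysis", "analysis", "analysis"),
    stringsAsFactors = FALSE)
  for (f in criteria$flag) {
    v <- record[[f]]
    if (is.null(v) || length(v) != 1L || is.na(v) || !is.logical(v))
      stop("malformed record: missing or non-logical flag '", f, "'")
  }
  for (i in seq_len(nrow(criteria))) {
    if (!record[[criteria$flag[i]]])
      return(list(included = FALSE, reason = criteria$reason[i],
                  scope = criteria$scope[i]))
  }
  list(included = TRUE, reason = "", scope = "")
}

#' Generate a synthetic lesion label volume
#'
#' Builds a deterministic label volume (0 background, 1 lesion, 2
#' ipsilateral non-lesion, 3 contralateral) whose voxel counts realize a
#' target edema-corrected lesion burden: the ipsilateral hemisphere is
#' swollen by \code{swellingFraction} relative to the contralateral one and
#' the lesion voxel count is chosen so the Gerriets-corrected \%HLVc equals
#' \code{hlvcPercent} up to one-voxel quantization.
#'
#' @param hlvcPercent target edema-corrected lesion (percent of hemisphere).
#' @param swellingFraction ipsilateral swelling (e.g. 0.1 = 10\% edema).
#' @param nContraVox contralateral hemisphere voxel count.
#' @param nSlices number of axial slices.
#' @param voxelVolume voxel volume (mm^3).
#' @return list with \code{labels} (a \linkS4class{LesionLabelVolume}) and
#'   \code{truth} (realized voxel counts and exact \%HLVc)
#' @export
makeLesionLabels <- function(hlvcPercent, swellingFraction = 0.1,
                             nContraVox = 9000L, nSlices = 9L,
                             voxelVolume = 0.0137) {
  if (hlvcPercent < 0 || hlvcPercent > 100)
    stop("hlvcPercent must be in [0, 100]")
  nContra <- asCount(nContraVox, "nContraVox")
  nIpsi <- round(nContra * (1 + swellingFraction))
  nLesion <- round(nContra * hlvcPercent / 100 + (nIpsi - nContra))
  nLesion <- max(0L, min(nLesion, nIpsi))

  perSlice <- ceiling(nIpsi / nSlices)
  rows <- ceiling(sqrt(perSlice))
  half <- ceiling(perSlice / rows)
  labels <- array(0L, dim = c(nSlices, rows, 2L * half + 1L))

  ## fill order: rows within column, columns within half, slices outermost
  fillHalf <- function(labels, count, colOffset, value) {
    if (count == 0L) return(labels)
    idx <- cbind(rep(seq_len(nSlices), each = half * rows),
                 rep.int(rep(seq_len(rows), times = half), nSlices),
                 colOffset + rep.int(rep(seq_len(half), each = rows), nSlices))
    labels[idx[seq_len(count), , drop = FALSE]] <- value
    labels
  }
  labels <- fillHalf(labels, nContra, 0L, 3L)            # left: contralateral
  labels <- fillHalf(labels, nIpsi, half + 1L, 2L)       # right: ipsilateral
  ## carve the lesion out of the ipsilateral fill, innermost voxels first
  ipsiIdx <- which(labels == 2L)
  labels[ipsiIdx[seq_len(nLesion)]] <- 1L

  truth <- list(nLesion = nLesion, nIpsi = nIpsi, nContra = nContra,
                hlvcPercent = 100 * (nContra - (nIpsi - nLesion)) / nContra)
  list(labels = new("LesionLabelVolume", labels = labels,
                    voxelVolume = voxelVolume),
       truth = truth)
}
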