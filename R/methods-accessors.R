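#' @include AllGenerics.R
NULL

## --- DynamicSequence ------------------------------------------------------

#' @describeIn DynamicSequence the 4D intensity array (slice, time, row, col)
#' @param x a \code{DynamicSequence}
#' @export
setMethod("frames", "DynamicSequence", function(x) x@frames)

#' @describeIn DynamicSequence frame times in seconds
#' @export
setMethod("frameTimes", "DynamicSequence", function(x) x@frameTimes)

#' @describeIn DynamicSequence 1-based index of the destruction burst frame
#' @export
setMethod("burstFrame", "DynamicSequence", function(x) x@burstFrame)

setMethod("show", "DynamicSequence", function(object) {
  d <- dim(object@frames)
  cat("DynamicSequence:", d[1], "slices x", d[3], "x", d[4], "voxels,",
      d[2], "frames\n")
  cat("  frame times:", format(min(object@frameTimes), digits = 3), "-",
      format(max(object@frameTimes), digits = 4), "s; burst at frame",
      object@burstFrame, "\n")
  cat("  voxel:", paste(object@voxelSize, collapse = " x "), "mm, slice spacing",
      object@sliceSpacing, "mm\n")
})

## --- HemispherePartition --------------------------------------------------

#' @describeIn HemispherePartition the 3D label array
#' @param x a \code{HemispherePartition}
#' @export
setMethod("partitionLabels", "HemispherePartition", function(x) x@labels)

setMethod("show", "HemispherePartition", function(object) {
  tab <- table(factor(object@labels, levels = 0:2,
                      labels = c("background", "ipsilateral", "contralateral")))
  cat("HemispherePartition:", paste(dim(object@labels), collapse = " x "), "\n")
  print(tab)
})

## --- PerfusionMap ---------------------------------------------------------

#' @describeIn PerfusionMap 3D array of perfusion-index values (NA where the
#'   fit did not converge)
#' @param x a \code{PerfusionMap}
#' @export
setMethod("mapValues", "PerfusionMap", function(x) x@values)

#' @describeIn PerfusionMap 3D logical convergence mask
#' @export
setMethod("convergedMask", "PerfusionMap", function(x) x@converged)

#' @describeIn PerfusionMap TRUE once normalized to the contralateral median
#' @export
setMethod("isRelative", "PerfusionMap", function(x) x@relative)

setMethod("show", "PerfusionMap", function(object) {
  kind <- if (object@relative) "relative (contralateral median = 1)" else "A*beta (a.u./s)"
  v <- object@values[object@converged]
  cat("PerfusionMap [", kind, "]: ",
      paste(dim(object@values), collapse = " x "), "\n", sep = "")
  cat("  converged voxels:", sum(object@converged), "/", length(object@converged), "\n")
  if (length(v))
    cat("  range:", format(range(v), digits = 4), "\n")
})

## --- AARResult ------------------------------------------------------------

#' @describeIn AARResult logical AAR voxel mask
#' @param x an \code{AARResult}
#' @export
setMethod("aarMask", "AARResult", function(x) x@mask)

#' @describeIn AARResult AAR as percent of the ipsilateral hemisphere
#' @export
setMethod("aarPercent", "AARResult", function(x) x@aarPercent)

setMethod("show", "AARResult", function(object) {
  cat(sprintf("AARResult: %.2f%% of ipsilateral hemisphere (threshold < %.2f)\n",
              object@aarPercent, object@threshold))
  cat("  per-slice %:", paste(sprintf("%.1f", object@perSlice), collapse = ", "), "\n")
})

## --- LesionVolumetry ------------------------------------------------------

#' @describeIn LesionVolumetry edema-corrected lesion, percent of hemisphere
#' @param x a \code{LesionVolumetry}
#' @export
setMethod("hlvcPercent", "LesionVolumetry", function(x) x@hlvcPercent)

#' @describeIn LesionVolumetry the %HLVc/%AAR primary endpoint (NA when no
#'   AAR was supplied)
#' @export
setMethod("endpointRatioValue", "LesionVolumetry", function(x) x@endpointRatio)

setMethod("show", "LesionVolumetry", function(object) {
  cat(sprintf("LesionVolumetry: LV %.1f, HVi %.1f, HVc %.1f mm^3\n",
              object@lv, object@hvi, object@hvc))
  cat(sprintf("  %%HLVc (edema-corrected) = %.2f%%", object@hlvcPercent))
  if (object@negative) cat("  [warning: negative corrected lesion]")
  cat("\n")
  if (!is.na(object@endpointRatio))
    cat(sprintf("  %%HLVc/%%AAR = %.2f%%\n", object@endpointRatio))
})

## --- CRC ------------------------------------------------------------------

setMethod("show", "CrcTrace", function(object) {
  cat("CrcTrace:", length(object@time), "samples,",
      length(object@pulseTimes), "pulses;",
      sprintf("%.2g mg protein, %g uL x %g uM boluses\n",
              object@proteinMg, object@pulseVolumeUl, object@pulseConcUM))
})

#' @describeIn CrcResult pulses fully sequestered before mPTP opening
#' @param x a \code{CrcResult}
#' @export
setMethod("nRetained", "CrcResult", function(x) x@nRetained)

#' @describeIn CrcResult opening time (s); NA when no opening detected
#' @export
setMethod("openingTime", "CrcResult", function(x) x@openingTime)

#' @describeIn CrcResult calcium retention capacity, nmol Ca2+ per mg
#' @export
setMethod("crcPerMg", "CrcResult", function(x) x@crcNmolPerMg)

setMethod("show", "CrcResult", function(object) {
  cat(sprintf("CrcResult: %d pulses retained -> CRC = %.1f nmol Ca2+/mg",
              object@nRetained, object@crcNmolPerMg))
  if (is.na(object@openingTime)) cat("  (no opening observed)\n")
  else cat(sprintf("  (mPTP opening at %.0f s)\n", object@openingTime))
})

## --- Oxygraph -------------------------------------------------------------

setMethod("show", "OxygraphTrace", function(object) {
  cat("OxygraphTrace:", length(object@time), "samples,",
      nrow(object@events), "titration events (",
      paste(object@events$label, collapse = ", "), ")\n")
})

#' @describeIn ComplexRates named vector of per-stage OCRs (nmol O2/min/mg)
#' @param x a \code{ComplexRates}
#' @export
setMethod("stageOcr", "ComplexRates", function(x) x@stageOcr)

#' @describeIn ComplexRates inhibitor-sensitive rate for \code{complex}
#'   ("CI", "CII" or "CIV"); NA when the required stage is missing
#' @param complex one of "CI", "CII", "CIV"
#' @export
setMethod("complexRate", "ComplexRates", function(x, complex) {
  switch(match.arg(complex, c("CI", "CII", "CIV")),
         CI = x@ci, CII = x@cii, CIV = x@civ)
})

setMethod("show", "ComplexRates", function(object) {
  cat("ComplexRates (nmol O2/min/mg):\n  stages:\n")
  for (nm in names(object@stageOcr))
    cat(sprintf("    %-16s %7.3f\n", nm, object@stageOcr[[nm]]))
  cat(sprintf("  CI = %.3f, CII = %.3f, CIV = %.3f\n",
              object@ci, object@cii, object@civ))
  if (length(object@missingStages))
    cat("  missing stages:", paste(object@missingStages, collapse = ", "), "\n")
})

## --- Statistics -----------------------------------------------------------

setMethod("show", "GroupSummary", function(object) {
  cat(sprintf("n = %d, median %.3g [%.3g; %.3g]\n",
              object@n, object@median, object@q25, object@q75))
})

#' @describeIn TestResult two-sided p value
#' @param x a \code{TestResult}
#' @export
setMethod("pValue", "TestResult", function(x) x@pValue)

#' @describeIn TestResult the test statistic
#' @export
setMethod("testStatistic", "TestResult", function(x) x@statistic)

#' @describeIn TestResult named effect descriptor(s)
#' @export
setMethod("effectValue", "TestResult", function(x) x@effect)

setMethod("show", "TestResult", function(object) {
  cat(object@method, ": ", sep = "")
  if (length(object@statistic))
    cat(paste(names(object@statistic), "=",
              format(object@statistic, digits = 4), collapse = ", "), ", ", sep = "")
  cat("p =", format(object@pValue, digits = 4), "\n")
  if (length(object@effect))
    cat("  effect:", paste(names(object@effect), "=",
                           format(object@effect, digits = 4), collapse = ", "), "\n")
  if (length(object@note)) cat("  note:", paste(object@note, collapse = "; "), "\n")
})

## --- Pipeline -------------------------------------------------------------

#' @describeIn PipelineReport per-animal endpoint table
#' @param x a \code{PipelineReport}
#' @export
setMethod("animalTable", "PipelineReport", function(x) x@animals)

#' @describeIn PipelineReport long-format group median/IQR table
#' @export
setMethod("groupSummaries", "PipelineReport", function(x) x@summaries)

#' @describeIn PipelineReport named list of \linkS4class{TestResult}s
#' @export
setMethod("testResults", "PipelineReport", function(x) x@tests)

setMethod("show", "PipelineReport", function(object) {
  cat("PipelineReport:", nrow(object@animals), "animals,",
      length(object@tests), "tests\n")
  cat("  groups:", paste(names(table(object@animals$group)),
                         table(object@animals$group), collapse = ", "), "\n")
  cat("  seed:", object@provenance$seed, "\n")
})
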