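#' @include AllClasses.R
NULL

#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @export
setGeneric("burstFrame", function(x) standardGeneric("burstFrame"))
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
#' @export
setGeneric("convergedMask", function(x) standardGeneric("convergedMask"))
#' @export
setGeneric("isRelative", function(x) standardGeneric("isRelative"))
#' @export
setGeneric("aarMask", function(x) standardGeneric("aarMask"))
#' @export
setGeneric("aarPercent", function(x) standardGeneric("aarPercent"))
#' @export
setGeneric("partitionLabels", function(x) standardGeneric("partitionLabels"))
#' @export
setGeneric("hlvcPercent", function(x) standardGeneric("hlvcPercent"))
#' @export
setGeneric("endpointRatioValue", function(x) standardGeneric("endpointRatioValue"))
#' @export
setGeneric("nRetained", function(x) standardGeneric("nRetained"))
#' @export
setGeneric("openingTime", function(x) standardGeneric("openingTime"))
#' @export
setGeneric("crcPerMg", function(x) standardGeneric("crcPerMg"))
#' @export
setGeneric("stageOcr", function(x) standardGeneric("stageOcr"))
#' @export
setGeneric("complexRate", function(x, complex) standardGeneric("complexRate"))
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @export
setGeneric("testStatistic", function(x) standardGeneric("testStatistic"))
#' @export
setGeneric("effectValue", function(x) standardGeneric("effectValue"))
#' @export
setGeneric("animalTable", function(x) standardGeneric("animalTable"))
#' @export
setGeneric("groupSummaries", function(x) standardGeneric("groupSummaries"))
#' @export
setGeneric("testResults", function(x) standardGeneric("testResults"))
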