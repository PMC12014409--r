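#' @include AllClasses.R utils.R
NULL

## Volumes travel as NIfTI-1 with axes (row, col, slice[, time]); the
## in-memory layout is (slice[, time], row, col).

#' Write a dynamic sequence as 4D NIfTI plus a frame-times CSV
#'
#' @param seq a \linkS4class{DynamicSequence}
#' @param niftiPath output NIfTI path (.nii or .nii.gz).
#' @param timesCsv output CSV path (columns frame, time_s, burst_frame).
#' @return invisibly, the NIfTI path
#' @export
writeDynamicSequence <- function(seq, niftiPath, timesCsv) {
  validObject(seq)
  arr <- aperm(seq@frames, c(3, 4, 1, 2))   # (row, col, slice, time)
  img <- RNifti::asNifti(arr, pixdim = c(seq@voxelSize, seq@sliceSpacing,
                                         diff(seq@frameTimes[1:2])))
  RNifti::writeNifti(img, niftiPath)
  utils::write.csv(
    data.frame(frame = seq_along(seq@frameTimes), time_s = seq@frameTimes,
               burst_frame = seq@burstFrame),
    timesCsv, row.names = FALSE)
  invisible(niftiPath)
}

#' Read a dynamic sequence from 4D NIfTI plus a frame-times CSV
#'
#' @param niftiPath 4D NIfTI path.
#' @param timesCsv CSV with columns \code{frame}, \code{time_s} and
#'   optionally \code{burst_frame}.
#' @param burstFrame 1-based burst frame; overrides the CSV column.
#' @param voxelSize,sliceSpacing geometry overrides (mm); taken from the
#'   NIfTI header when NULL.
#' @return a \linkS4class{DynamicSequence}
#' @export
readDynamicSequence <- function(niftiPath, timesCsv, burstFrame = NULL,
                                voxelSize = NULL, sliceSpacing = NULL) {
  img <- RNifti::readNifti(niftiPath)
  if (length(dim(img)) != 4L) stop("expected a 4D NIfTI volume")
  tt <- utils::read.csv(timesCsv)
  if (!all(c("frame", "time_s") %in% names(tt)))
    stop("frame-times CSV needs columns frame and time_s")
  if (is.null(burstFrame)) {
    if (!"burst_frame" %in% names(tt))
      stop("burstFrame not given and no burst_frame column in the CSV")
    burstFrame <- tt$burst_frame[1]
  }
  pd <- RNifti::pixdim(img)
  arr <- aperm(unclass(img)[, , , , drop = FALSE], c(3, 4, 1, 2))
  new("DynamicSequence", frames = arr,
      frameTimes = tt$time_s[order(tt$frame)],
      burstFrame = asCount(burstFrame, "burstFrame"),
      voxelSize = if (is.null(voxelSize)) pd[1:2] else voxelSize,
      sliceSpacing = if (is.null(sliceSpacing)) pd[3] else sliceSpacing)
}

## 3D label volumes: (row, col, slice) on disk <-> (slice, row, col) in memory
.writeLabelNifti <- function(labels, path) {
  RNifti::writeNifti(RNifti::asNifti(aperm(labels, c(2, 3, 1))), path)
  invisible(path)
}
.readLabelNifti <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D NIfTI label volume")
  arr <- aperm(unclass(img)[, , , drop = FALSE], c(3, 1, 2))
  storage.mode(arr) <- "integer"
  arr
}

#' Write / read a hemisphere partition as integer-label NIfTI
#'
#' Labels: 1 ipsilateral, 2 contralateral, 0 background.
#' @param partition a \linkS4class{HemispherePartition}
#' @param path NIfTI file path.
#' @return \code{readPartition}: a \linkS4class{HemispherePartition}
#' @export
writePartition <- function(partition, path) {
  validObject(partition)
  .writeLabelNifti(partition@labels, path)
}

#' @rdname writePartition
#' @export
readPartition <- function(path) {
  new("HemispherePartition", labels = .readLabelNifti(path))
}

#' Write / read a lesion label volume as NIfTI
#'
#' Labels: 0 background, 1 lesion, 2 ipsilateral non-lesion,
#' 3 contralateral.
#' @param labelVolume a \linkS4class{LesionLabelVolume}
#' @param path NIfTI file path.
#' @param voxelVolume voxel volume (mm^3) for \code{readLesionLabels}.
#' @return \code{readLesionLabels}: a \linkS4class{LesionLabelVolume}
#' @export
writeLesionLabels <- function(labelVolume, path) {
  validObject(labelVolume)
  .writeLabelNifti(labelVolume@labels, path)
}

#' @rdname writeLesionLabels
#' @export
readLesionLabels <- function(path, voxelVolume) {
  new("LesionLabelVolume", labels = .readLabelNifti(path),
      voxelVolume = voxelVolume)
}

#' Read / write assay traces as two-column CSV
#'
#' Traces are exchanged as CSV with columns \code{time_s} and
#' \code{value}; events (pulse times or titration additions) as CSV with
#' \code{time_s} and, for the oxygraph, \code{label}.
#'
#' @param path CSV path.
#' @param eventsPath events CSV path.
#' @param proteinMg,pulseVolumeUl,pulseConcUM,chamberMl assay constants.
#' @return \code{readCrcTrace}: a \linkS4class{CrcTrace};
#'   \code{readOxygraphTrace}: an \linkS4class{OxygraphTrace}
#' @export
readCrcTrace <- function(path, eventsPath, proteinMg = 0.5,
                         pulseVolumeUl = 10, pulseConcUM = 500,
                         chamberMl = 2) {
  tr <- utils::read.csv(path)
  ev <- utils::read.csv(eventsPath)
  if (!all(c("time_s", "value") %in% names(tr)))
    stop("trace CSV needs columns time_s and value")
  if (!"time_s" %in% names(ev)) stop("events CSV needs a time_s column")
  new("CrcTrace", time = tr$time_s, fluorescence = tr$value,
      pulseTimes = ev$time_s, proteinMg = proteinMg,
      pulseVolumeUl = pulseVolumeUl, pulseConcUM = pulseConcUM,
      chamberMl = chamberMl)
}

#' @rdname readCrcTrace
#' @export
readOxygraphTrace <- function(path, eventsPath, chamberMl = 2,
                              proteinMg = 0.5) {
  tr <- utils::read.csv(path)
  ev <- utils::read.csv(eventsPath)
  if (!all(c("time_s", "value") %in% names(tr)))
    stop("trace CSV needs columns time_s and value")
  if (!all(c("time_s", "label") %in% names(ev)))
    stop("events CSV needs columns time_s and label")
  new("OxygraphTrace", time = tr$time_s, o2Conc = tr$value,
      events = ev[, c("time_s", "label")], chamberMl = chamberMl,
      proteinMg = proteinMg)
}

#' @rdname readCrcTrace
#' @param trace a \linkS4class{CrcTrace} or \linkS4class{OxygraphTrace}
#' @export
writeTraceCsv <- function(trace, path, eventsPath) {
  validObject(trace)
  if (is(trace, "CrcTrace")) {
    utils::write.csv(data.frame(time_s = trace@time,
                                value = trace@fluorescence),
                     path, row.names = FALSE)
    utils::write.csv(data.frame(time_s = trace@pulseTimes),
                     eventsPath, row.names = FALSE)
  } else {
    utils::write.csv(data.frame(time_s = trace@time, value = trace@o2Conc),
                     path, row.names = FALSE)
    utils::write.csv(trace@events, eventsPath, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write a cohort table as CSV
#'
#' One row per animal; the column dictionary is the animal-record schema
#' (id, group, neuroscore, aar_percent, hlvc_percent, endpoint_ratio,
#' crc_ipsi, crc_contra, ocr_\{CI,CII,CIV\}_\{ipsi,contra\}, the five
#' inclusion flags, included, exclusion_reason).
#'
#' @param cohort data.frame of animal records.
#' @param path CSV path.
#' @return \code{readCohortCsv}: the cohort data.frame
#' @export
writeCohortCsv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortCsv
#' @export
readCohortCsv <- function(path) {
  co <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "group")
  missing <- setdiff(need, names(co))
  if (length(missing))
    stop("cohort CSV schema violation: missing column(s) ",
         paste(missing, collapse = ", "))
  co
}
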