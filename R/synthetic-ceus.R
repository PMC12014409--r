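#' @include AllClasses.R utils.R
NULL

#' Construct a CEUS phantom specification
#'
#' Defaults reproduce the acquisition geometry of a per-occlusion mouse
#' brain scan: 4 slice levels of 64 x 64 voxels, 120 frames at 0.5 s, with
#' the destruction burst after a 5 s pre-burst plateau. Healthy-tissue
#' kinetics default to \eqn{A = 50} a.u., \eqn{\beta = 0.15} /s, so the
#' replenishment (time constant ~6.7 s) fills most of the 55 s post-burst
#' window instead of saturating within the first few frames.
#'
#' @param grid integer of length 3 (slices, rows, cols).
#' @param nFrames number of frames.
#' @param frameInterval seconds between frames.
#' @param burstFrame 1-based burst frame index.
#' @param baselineIntensity pre-burst plateau / post-burst floor (a.u.).
#' @param contralateralA healthy plateau amplitude (a.u.).
#' @param contralateralBeta healthy replenishment rate (1/s).
#' @param lesionRelativePerfusion lesion perfusion index relative to
#'   contralateral tissue, in \[0, 1).
#' @param lesionFraction fraction of ipsilateral voxels inside the lesion.
#' @param noiseSd additive Gaussian intensity noise (a.u.).
#' @param seed integer random seed.
#' @return a \linkS4class{CeusPhantomSpec}
#' @export
ceusPhantomSpec <- function(grid = c(4L, 64L, 64L), nFrames = 120L,
                            frameInterval = 0.5, burstFrame = 11L,
                            baselineIntensity = 60, contralateralA = 50,
                            contralateralBeta = 0.15,
                            lesionRelativePerfusion = 0.1,
                            lesionFraction = 0.3, noiseSd = 0, seed = 1L) {
  new("CeusPhantomSpec",
      grid = as.integer(grid), nFrames = asCount(nFrames, "nFrames"),
      frameInterval = frameInterval, burstFrame = asCount(burstFrame, "burstFrame"),
      baselineIntensity = baselineIntensity, contralateralA = contralateralA,
      contralateralBeta = contralateralBeta,
      lesionRelativePerfusion = lesionRelativePerfusion,
      lesionFraction = lesionFraction, noiseSd = noiseSd,
      seed = asCount(seed, "seed"))
}

## Hemisphere partition of a (slices, rows, cols) grid: the right half of
## each axial slice (higher column indices) is the ipsilateral, occluded
## hemisphere; the left half is contralateral. With an odd column count the
## middle column is background (midline).
phantomPartition <- function(grid) {
  labels <- array(0L, dim = grid)
  half <- grid[3] %/% 2L
  labels[, , seq_len(half)] <- 2L
  labels[, , (grid[3] - half + 1L):grid[3]] <- 1L
  new("HemispherePartition", labels = labels)
}

## Deterministic quasi-spherical lesion: the n ipsilateral voxels closest to
## the lesion centre (centroid of the ipsilateral hemisphere), slice distance
## weighted by the grid aspect so the lesion spans slices.
lesionMaskFromFraction <- function(partition, lesionFraction) {
  labels <- partition@labels
  d <- dim(labels)
  ipsi <- which(labels == 1L, arr.ind = TRUE)
  n <- round(lesionFraction * nrow(ipsi))
  mask <- array(FALSE, dim = d)
  if (n == 0L) return(mask)
  centre <- colMeans(ipsi)
  sliceScale <- max(d[2], d[3]) / max(d[1], 1L)
  dist2 <- (sliceScale * (ipsi[, 1] - centre[1]))^2 +
    (ipsi[, 2] - centre[2])^2 + (ipsi[, 3] - centre[3])^2
  ord <- order(dist2, ipsi[, 1], ipsi[, 2], ipsi[, 3])
  sel <- ipsi[ord[seq_len(n)], , drop = FALSE]
  mask[sel] <- TRUE
  mask
}

#' Generate a synthetic CEUS burst-replenishment sequence
#'
#' Builds a 4D phantom with known per-voxel ground truth. Every voxel shows
#' the pre-burst plateau at \code{baselineIntensity}; from the burst frame
#' onwards the intensity follows
#' \eqn{I_0 + A (1 - e^{-\beta (t - t_{burst})})} with \eqn{I_0} equal to the
#' baseline. Lesion voxels (a contiguous region covering
#' \code{lesionFraction} of the ipsilateral hemisphere) have their plateau
#' amplitude scaled so that \eqn{A \beta} equals
#' \code{lesionRelativePerfusion} times the contralateral product. Additive
#' Gaussian noise is applied to every frame. The output is bit-reproducible
#' under the spec's seed.
#'
#' @param spec a \linkS4class{CeusPhantomSpec}
#' @return list with elements \code{sequence} (\linkS4class{DynamicSequence}),
#'   \code{partition} (\linkS4class{HemispherePartition}) and \code{truth}
#'   (list: logical \code{mask} of lesion voxels, per-voxel \code{a},
#'   \code{beta} and \code{pi} arrays).
#' @examples
#' ph <- makeCeusPhantom(ceusPhantomSpec(grid = c(2, 16, 16), nFrames = 40))
#' ph$sequence
#' @export
makeCeusPhantom <- function(spec) {
  validObject(spec)
  g <- spec@grid
  if (any(g == 0L)) stop("degenerate grid: all dimensions must be >= 1")
  times <- (seq_len(spec@nFrames) - 1L) * spec@frameInterval
  tBurst <- times[spec@burstFrame]

  partition <- phantomPartition(g)
  mask <- lesionMaskFromFraction(partition, spec@lesionFraction)

  aMap <- array(spec@contralateralA, dim = g)
  betaMap <- array(spec@contralateralBeta, dim = g)
  ## scale A so that A*beta = rel * contralateral A*beta
  aMap[mask] <- spec@contralateralA * spec@lesionRelativePerfusion
  piMap <- aMap * betaMap

  nVox <- prod(g)
  post <- spec@burstFrame:spec@nFrames
  ## vectorized over voxels: build (voxel x time) then permute
  aVec <- as.vector(aMap)
  bVec <- as.vector(betaMap)
  postCurve <- outer(bVec, times[post] - tBurst,
                     function(b, dt) 1 - exp(-b * dt)) * aVec +
    spec@baselineIntensity
  voxTime <- matrix(spec@baselineIntensity, nrow = nVox, ncol = spec@nFrames)
  voxTime[, post] <- postCurve
  if (spec@noiseSd > 0) {
    noise <- withSeed(spec@seed,
                      matrix(stats::rnorm(nVox * spec@nFrames, sd = spec@noiseSd),
                             nrow = nVox))
    voxTime <- voxTime + noise
  }
  ## voxel index runs over (slice, row, col); target layout (slice, time, row, col)
  frames <- aperm(array(voxTime, dim = c(g[1], g[2], g[3], spec@nFrames)),
                  c(1, 4, 2, 3))

  seqObj <- new("DynamicSequence", frames = frames, frameTimes = times,
                burstFrame = spec@burstFrame, voxelSize = c(0.1, 0.1),
                sliceSpacing = 1.5)
  list(sequence = seqObj, partition = partition,
       truth = list(mask = mask, a = aMap, beta = betaMap, pi = piMap))
}
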