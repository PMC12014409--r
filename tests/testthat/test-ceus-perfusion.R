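test_that("noiseless curves are recovered to high precision", {
  times <- seq(0, 59.5, by = 0.5)
  cases <- list(c(i0 = 10, a = 50, beta = 0.5),
                c(i0 = 0, a = 80, beta = 0.05),
                c(i0 = 40, a = 5, beta = 2))
  for (p in cases) {
    y <- replenishmentCurve(times, 11L, p["i0"], p["a"], p["beta"])
    f <- fitReplenishment(y, times, 11L)
    expect_true(f@converged)
    expect_lt(abs(f@i0 - p["i0"]), 1e-6)
    expect_lt(abs(f@a - p["a"]), 1e-6)
    expect_lt(abs(f@beta - p["beta"]), 1e-6)
  }
})

test_that("a constant curve fits as zero replenishment", {
  times <- seq(0, 30, by = 0.5)
  f <- fitReplenishment(rep(7, length(times)), times, 5L)
  expect_true(f@converged)
  expect_equal(f@a, 0)
  expect_equal(f@i0, 7)
  expect_equal(f@a * f@beta, 0)   # perfusion index zero
})

test_that("the fitted plateau equals I0 + A", {
  times <- seq(0, 40, by = 0.5)
  y <- replenishmentCurve(times, 6L, 12, 33, 0.4)
  f <- fitReplenishment(y, times, 6L)
  ## model prediction at t -> Inf
  expect_equal(f@i0 + f@a, 12 + 33, tolerance = 1e-6)
})

test_that("degenerate inputs to the curve fit are rejected", {
  times <- seq(0, 3, by = 0.5)
  expect_error(fitReplenishment(rep(1, 7), times, 4L), "5 post-burst")
  y <- replenishmentCurve(seq(0, 30, 0.5), 3L, 5, 10, 0.5)
  y[10] <- NaN
  expect_error(fitReplenishment(y, seq(0, 30, 0.5), 3L), "non-finite")
  expect_error(fitReplenishment(y[-1], seq(0, 30, 0.5), 3L), "equal length")
})

test_that("perfusion maps recover phantom structure", {
  ph <- makeCeusPhantom(ceusPhantomSpec(grid = c(2L, 16L, 16L), nFrames = 60L,
                                        lesionFraction = 0, noiseSd = 0))
  pm <- computePerfusionMap(ph$sequence)
  v <- mapValues(pm)[convergedMask(pm)]
  expect_lt(stats::sd(v) / mean(v), 1e-6)   # homogeneous: CV ~ 0

  ph2 <- makeCeusPhantom(ceusPhantomSpec(grid = c(2L, 16L, 16L),
                                         nFrames = 60L, lesionFraction = 0.3,
                                         lesionRelativePerfusion = 0.1,
                                         noiseSd = 0))
  pm2 <- computePerfusionMap(ph2$sequence)
  contra <- partitionLabels(ph2$partition) == 2L
  lesionPi <- mean(mapValues(pm2)[ph2$truth$mask])
  contraPi <- mean(mapValues(pm2)[contra])
  expect_equal(lesionPi / contraPi, 0.1, tolerance = 1e-6)
})

test_that("a non-finite voxel is flagged without poisoning neighbours", {
  ph <- makeCeusPhantom(ceusPhantomSpec(grid = c(2L, 8L, 8L), nFrames = 30L,
                                        noiseSd = 0))
  fr <- frames(ph$sequence)
  fr[1, 15, 3, 3] <- NaN
  seqBad <- new("DynamicSequence", frames = fr,
                frameTimes = frameTimes(ph$sequence), burstFrame = 11L,
                voxelSize = c(0.1, 0.1), sliceSpacing = 1.5)
  pm <- computePerfusionMap(seqBad)
  expect_false(convergedMask(pm)[1, 3, 3])
  expect_true(is.na(mapValues(pm)[1, 3, 3]))
  expect_true(all(convergedMask(pm)[2, , ]))
  expect_false(any(is.na(mapValues(pm)[2, , ])))
})

test_that("normalization divides by the contralateral median", {
  ph <- makeCeusPhantom(ceusPhantomSpec(grid = c(2L, 8L, 8L), nFrames = 30L,
                                        noiseSd = 0))
  pm <- computePerfusionMap(ph$sequence)
  rel <- normalizePerfusion(pm, ph$partition)
  contra <- partitionLabels(ph$partition) == 2L & convergedMask(rel)
  expect_equal(stats::median(mapValues(rel)[contra]), 1)
  expect_true(isRelative(rel))

  ## uniform map of value 7 becomes all ones
  uni <- new("PerfusionMap", values = array(7, dim = c(1, 4, 4)),
             converged = array(TRUE, dim = c(1, 4, 4)), relative = FALSE,
             voxelSize = c(0.1, 0.1), sliceSpacing = 1)
  part <- new("HemispherePartition",
              labels = array(rep(c(2L, 1L), each = 8), dim = c(1, 4, 4)))
  expect_equal(unique(as.vector(mapValues(normalizePerfusion(uni, part)))), 1)

  ## contralateral values {2, 4, 6}: divisor is their median 4
  vals <- array(0, dim = c(1, 1, 6))
  vals[1, 1, ] <- c(2, 4, 6, 8, 8, 8)
  part2 <- new("HemispherePartition",
               labels = array(c(2L, 2L, 2L, 1L, 1L, 1L), dim = c(1, 1, 6)))
  m2 <- new("PerfusionMap", values = vals,
            converged = array(TRUE, dim = c(1, 1, 6)), relative = FALSE,
            voxelSize = c(0.1, 0.1), sliceSpacing = 1)
  expect_equal(as.vector(mapValues(normalizePerfusion(m2, part2))),
               c(2, 4, 6, 8, 8, 8) / 4)
})

test_that("normalization is idempotent", {
  ph <- makeCeusPhantom(ceusPhantomSpec(grid = c(2L, 8L, 8L), nFrames = 30L,
                                        noiseSd = 1))
  pm <- computePerfusionMap(ph$sequence)
  rel1 <- normalizePerfusion(pm, ph$partition)
  rel2 <- normalizePerfusion(rel1, ph$partition)
  expect_equal(mapValues(rel2), mapValues(rel1))
})

test_that("normalization rejects a zero or absent contralateral median", {
  zero <- new("PerfusionMap", values = array(0, dim = c(1, 2, 2)),
              converged = array(TRUE, dim = c(1, 2, 2)), relative = FALSE,
              voxelSize = c(0.1, 0.1), sliceSpacing = 1)
  part <- new("HemispherePartition",
              labels = array(c(2L, 2L, 1L, 1L), dim = c(1, 2, 2)))
  expect_error(normalizePerfusion(zero, part), "zero")
  noContra <- new("HemispherePartition",
                  labels = array(1L, dim = c(1, 2, 2)))
  expect_error(normalizePerfusion(zero, noContra), "contralateral")
})

test_that("AAR segmentation matches the phantom ground truth exactly", {
  ph <- makeCeusPhantom(ceusPhantomSpec(grid = c(2L, 16L, 16L), nFrames = 60L,
                                        lesionFraction = 0.3,
                                        lesionRelativePerfusion = 0.1,
                                        noiseSd = 0))
  rel <- normalizePerfusion(computePerfusionMap(ph$sequence), ph$partition)
  aar <- segmentAar(rel, ph$partition, threshold = 0.26)
  expect_identical(aarMask(aar), ph$truth$mask)
  nIpsi <- sum(partitionLabels(ph$partition) == 1L)
  expect_lte(abs(aarPercent(aar) - 30), 100 / nIpsi)  # one-voxel quantization
})

test_that("a uniform relative map yields zero AAR", {
  uni <- new("PerfusionMap", values = array(1, dim = c(1, 4, 4)),
             converged = array(TRUE, dim = c(1, 4, 4)), relative = TRUE,
             voxelSize = c(0.1, 0.1), sliceSpacing = 1)
  part <- new("HemispherePartition",
              labels = array(rep(c(2L, 1L), each = 8), dim = c(1, 4, 4)))
  expect_equal(aarPercent(segmentAar(uni, part)), 0)
})

test_that("a voxel exactly at the threshold is excluded (strict inequality)", {
  vals <- array(1, dim = c(1, 2, 4))
  vals[1, 1, 3] <- 0.26   # exactly at threshold
  vals[1, 2, 3] <- 0.25999
  part <- new("HemispherePartition",
              labels = array(rep(c(2L, 1L), each = 4), dim = c(1, 2, 4)))
  m <- new("PerfusionMap", values = vals,
           converged = array(TRUE, dim = c(1, 2, 4)), relative = TRUE,
           voxelSize = c(0.1, 0.1), sliceSpacing = 1)
  aar <- segmentAar(m, part, threshold = 0.26)
  expect_false(aarMask(aar)[1, 1, 3])
  expect_true(aarMask(aar)[1, 2, 3])
})

test_that("AAR percent is monotone in threshold and lesion fraction", {
  ph <- makeCeusPhantom(ceusPhantomSpec(grid = c(2L, 12L, 12L), nFrames = 40L,
                                        lesionFraction = 0.3,
                                        lesionRelativePerfusion = 0.1,
                                        noiseSd = 2, seed = 5L))
  rel <- normalizePerfusion(computePerfusionMap(ph$sequence), ph$partition)
  pcts <- vapply(c(0.1, 0.26, 0.5, 0.9),
                 function(th) aarPercent(segmentAar(rel, ph$partition, th)),
                 numeric(1))
  expect_true(all(diff(pcts) >= 0))

  byFrac <- vapply(c(0.1, 0.3, 0.5), function(fr) {
    p <- makeCeusPhantom(ceusPhantomSpec(grid = c(2L, 12L, 12L),
                                         nFrames = 40L, lesionFraction = fr,
                                         lesionRelativePerfusion = 0.1,
                                         noiseSd = 0))
    r <- normalizePerfusion(computePerfusionMap(p$sequence), p$partition)
    aarPercent(segmentAar(r, p$partition))
  }, numeric(1))
  expect_true(all(diff(byFrac) > 0))
})

test_that("segmentation requires a relative map and a nonempty ipsilateral side", {
  ph <- makeCeusPhantom(ceusPhantomSpec(grid = c(1L, 6L, 6L), nFrames = 30L,
                                        noiseSd = 0))
  pm <- computePerfusionMap(ph$sequence)
  expect_error(segmentAar(pm, ph$partition), "relative")
  rel <- normalizePerfusion(pm, ph$partition)
  allContra <- new("HemispherePartition",
                   labels = array(2L, dim = dim(partitionLabels(ph$partition))))
  expect_error(segmentAar(rel, allContra), "ipsilateral")
})

test_that("noisy maps keep the median perfusion error small", {
  ## noise at 5% of the plateau amplitude across > 1000 voxels, at the
  ## default 120-frame acquisition length
  ph <- makeCeusPhantom(ceusPhantomSpec(grid = c(2L, 24L, 24L), nFrames = 120L,
                                        lesionFraction = 0, noiseSd = 2.5,
                                        seed = 11L))
  pm <- computePerfusionMap(ph$sequence)
  truthPi <- ph$truth$pi[convergedMask(pm)]
  est <- mapValues(pm)[convergedMask(pm)]
  relErr <- abs(est - truthPi) / truthPi
  expect_gt(length(relErr), 1000)
  expect_lt(stats::median(relErr), 0.05)
})
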