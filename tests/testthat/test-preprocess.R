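mont8 <- makeSphericalMontage(8)
sineRec <- function(f, fs = 250, dur = 10, phase = 0.3) {
  tt <- (0:(fs * dur - 1)) / fs
  EEGRecording(matrix(rep(sin(2 * pi * f * tt + phase), 8), 8, byrow = TRUE),
               fs, mont8)
}
rmsRatio <- function(a, b) sqrt(mean(potentials(a)^2) / mean(potentials(b)^2))

test_that("bandpass attenuates the stop band and passes the pass band", {
  r <- sineRec(0.1)
  expect_lt(rmsRatio(bandpassFilter(r), r), 0.05)
  r <- sineRec(10)
  expect_lt(abs(rmsRatio(bandpassFilter(r), r) - 1), 0.05)
  expect_error(bandpassFilter(sineRec(1), lowHz = 1, highHz = 200), "Nyquist")
})

test_that("zero-phase filtering yields an even impulse response", {
  imp <- matrix(0, 8, 2001); imp[, 1001] <- 1
  y <- potentials(bandpassFilter(EEGRecording(imp, 250, mont8)))[1, ]
  expect_equal(y[1001 + 1:300], y[1001 - 1:300], tolerance = 1e-10)
})

test_that("downsampling preserves in-band content and DC", {
  tt <- (0:3999) / 1000
  r <- EEGRecording(matrix(rep(sin(2 * pi * 30 * tt), 8), 8, byrow = TRUE),
                    1000, mont8)
  d <- downsampleRecording(r, 250)
  expect_equal(ncol(potentials(d)), 1000)
  expect_equal(samplingRate(d), 250)
  expect_lt(abs(sqrt(mean(potentials(d)[1, ]^2) / 0.5) - 1), 0.05)

  dc <- downsampleRecording(EEGRecording(matrix(5, 8, 1000), 1000, mont8),
                            250)
  expect_equal(as.vector(potentials(dc)), rep(5, 8 * 250), tolerance = 1e-3)
  expect_error(downsampleRecording(r, 2000), "exceeds")
})

test_that("spherical-spline interpolation reconstructs spline-basis fields", {
  mont <- makeSphericalMontage(32)
  pos <- mont@positions
  src <- pos[c(3, 17, 25), ]
  G <- matrix(microstates:::.splineG(pmin(pmax(pos %*% t(src), -1), 1)),
              nrow(pos))
  v <- G %*% c(1, -2.5, 1.5) + 0.3      # zero-sum coefficients: a true spline
  rec <- EEGRecording(matrix(rep(v, 3), ncol = 3), 250, mont)
  out <- sphericalSplineInterpolate(rec, badChannels = c("E5", "E20"),
                                    lambda = 0)
  expect_lt(max(abs(potentials(out)[c(5, 20), 1] - v[c(5, 20)])) /
            max(abs(v)), 1e-6)
  # good channels untouched
  expect_identical(potentials(out)[-c(5, 20), ], potentials(rec)[-c(5, 20), ])

  # constant topography stays constant
  cr <- EEGRecording(matrix(2.5, 32, 2), 250, mont)
  ci <- sphericalSplineInterpolate(cr, badChannels = "E7")
  expect_equal(potentials(ci)[7, ], c(2.5, 2.5), tolerance = 1e-6)

  # no bad channels is the identity; all-bad errors
  expect_identical(potentials(sphericalSplineInterpolate(rec,
                                                         character())),
                   potentials(rec))
  expect_error(sphericalSplineInterpolate(rec,
                                          channelNames(mont)[1:29]),
               "4 good channels")
})

test_that("average referencing centers frames, idempotently", {
  r <- EEGRecording(matrix(c(1, 3), 2, 1),
                    250, SensorMontage(c("a", "b"),
                                       rbind(c(0, 0, 1), c(1, 0, 0))))
  ar <- averageReference(r)
  expect_equal(as.vector(potentials(ar)), c(-1, 1))
  expect_equal(potentials(averageReference(ar)), potentials(ar))
  expect_equal(gfp(ar), gfp(r))
})

test_that("GFP is the population spatial SD, polarity-invariant", {
  mont2 <- SensorMontage(c("a", "b"), rbind(c(0, 0, 1), c(1, 0, 0)))
  r <- EEGRecording(matrix(c(1, -1, 0, 0), 2), 250, mont2)
  expect_equal(gfp(r), c(1, 0))
  rn <- EEGRecording(-matrix(c(1, -1, 0, 0), 2), 250, mont2)
  expect_equal(gfp(rn), gfp(r))
  # equals RMS over channels for centered data
  X <- matrix(rnorm(8 * 50), 8)
  rc <- averageReference(EEGRecording(X, 250, mont8))
  expect_equal(gfp(rc), sqrt(colMeans(potentials(rc)^2)))
})

test_that("GFP peaks are strict local maxima at the expected density", {
  expect_identical(gfpPeaks(c(0, 1, 0, 2, 0)), c(2L, 4L))
  expect_identical(gfpPeaks(1:10), integer(0))
  tt <- (0:2499) / 250
  pk <- gfpPeaks(abs(sin(2 * pi * 10 * tt)))
  expect_gt(length(pk) / 10, 18)      # ~20 rectified peaks per second
  expect_lt(length(pk) / 10, 22)
  # minimum separation keeps the larger peak
  expect_identical(gfpPeaks(c(0, 1, 0.9, 2, 0), minSeparation = 3), 4L)
})

test_that("processing history records the pipeline order", {
  fx <- fixtureRecording(nChannels = 8, durationS = 2, seed = 3)
  out <- averageReference(downsampleRecording(
    bandpassFilter(fx$recording, 1, 40), 125))
  expect_match(processingHistory(out)[2], "bandpass")
  expect_match(processingHistory(out)[3], "downsample")
  expect_match(processingHistory(out)[4], "average-reference")
})
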