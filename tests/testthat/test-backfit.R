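test_that("winner-takes-all labeling assigns, withholds, ignores polarity", {
  mont <- fixtureMontage(12)
  tpl <- makeTemplateMaps(mont, 3, seed = 4)
  M <- maps(tpl)
  # frames equal to map 2 (scaled, sign-flipped) -> all labeled 2
  X <- cbind(3 * M[2, ], -1.5 * M[2, ], M[2, ])
  rec <- EEGRecording(X, 250, mont)
  seg <- labelFrames(rec, tpl)
  expect_identical(frameLabels(seg), rep(2L, 3))
  expect_equal(frameCorr(seg), rep(1, 3), tolerance = 1e-9)

  # a frame orthogonal to every map stays unassigned
  set.seed(1)
  v <- rnorm(12); v <- v - mean(v)
  v <- v - as.vector(t(M) %*% solve(tcrossprod(M), M %*% v))
  seg2 <- labelFrames(EEGRecording(cbind(v, M[1, ]), 250, mont), tpl)
  expect_identical(frameLabels(seg2), c(0L, 1L))
  expect_true(is.na(frameCorr(seg2)[1]))

  # sign flip of a frame leaves its label unchanged
  seg3 <- labelFrames(EEGRecording(cbind(-v, -M[1, ]), 250, mont), tpl)
  expect_identical(frameLabels(seg3), frameLabels(seg2))

  expect_error(labelFrames(EEGRecording(matrix(1.0, 4, 2), 250,
                                        fixtureMontage(4)), tpl),
               "channel count")
})

test_that("smoothing removes isolated flips but respects unanimity", {
  mont <- fixtureMontage(12)
  tpl <- makeTemplateMaps(mont, 2, seed = 9)
  lab <- rep(1L, 41); lab[21] <- 2L
  # evidence: every frame mildly prefers its own label
  cm <- matrix(0.6, 2, 41)
  cm[cbind(lab, 1:41)] <- 0.8
  seg <- MicrostateSegmentation(lab, 2, 250, corr = cm[cbind(lab, 1:41)],
                                gfp = rep(1, 41))
  sm <- smoothLabels(seg, corrMatrix = cm)
  expect_identical(frameLabels(sm), rep(1L, 41))

  # zero smoothness weight is the identity
  id <- smoothLabels(seg, corrMatrix = cm, smoothnessWeight = 0)
  expect_identical(frameLabels(id), lab)

  # an unassigned frame never gains a label
  lab0 <- lab; lab0[5] <- 0L
  seg0 <- MicrostateSegmentation(lab0, 2, 250,
                                 corr = ifelse(lab0 > 0,
                                               cm[cbind(pmax(lab0, 1),
                                                        1:41)], NA),
                                 gfp = rep(1, 41))
  sm0 <- smoothLabels(seg0, corrMatrix = cm)
  expect_identical(frameLabels(sm0)[5], 0L)

  # alternating comb coalesces into few long runs
  comb <- rep(c(1L, 2L), 30)
  cmc <- matrix(0.7, 2, 60)
  segc <- MicrostateSegmentation(comb, 2, 250, corr = rep(0.7, 60),
                                 gfp = rep(1, 60))
  smc <- smoothLabels(segc, corrMatrix = cmc)
  expect_lte(nrow(segmentTable(smc)), 2)
})

test_that("short segments are split in half and absorbed, to a fixed point", {
  # interior rejection with re-merge
  seg <- runsSeg(A = 20, B = 4, A = 20)
  out <- rejectSmallSegments(seg, 5)
  expect_identical(segmentTable(out),
                   data.frame(state = 1L, start = 1L, length = 44L))
  # odd split: first floor(5/2)=2 frames to A, last 3 to C
  seg <- runsSeg(A = 20, B = 5, C = 20)
  out <- rejectSmallSegments(seg, 5)
  expect_identical(segmentTable(out)$state, c(1L, 3L))
  expect_identical(segmentTable(out)$length, c(22L, 23L))
  # boundary short segment wholly absorbed by its only neighbor
  seg <- runsSeg(B = 3, A = 30)
  out <- rejectSmallSegments(seg, 5)
  expect_identical(segmentTable(out),
                   data.frame(state = 1L, start = 1L, length = 33L))
  # cascading: absorption creates a new short run, re-run to fixed point
  seg <- runsSeg(A = 6, B = 4, A = 2, C = 30)
  out <- rejectSmallSegments(seg, 5)
  runs <- segmentTable(out)
  expect_true(all(runs$length > 5))
  expect_equal(sum(runs$length), 42)
  # a short segment with no labeled neighbor becomes unassigned
  lab <- c(rep(0L, 10), rep(2L, 3), rep(0L, 10))
  out <- rejectSmallSegments(MicrostateSegmentation(lab, 2, 250), 5)
  expect_identical(frameLabels(out), rep(0L, 23))
})

test_that("full backfitting recovers planted labels and drops short runs", {
  fx <- fixtureRecording(nChannels = 24, durationS = 30, snr = 10, seed = 17)
  gm <- MicrostateMapSet(maps(fx$templates), level = "group")
  seg <- backfitSubject(averageReference(fx$recording), gm)
  runs <- segmentTable(seg)
  expect_true(all(runs$length > 5))
  lab <- frameLabels(seg)
  truth <- frameLabels(fx$sequence)
  agree <- mean(lab[lab > 0L] == truth[lab > 0L])
  expect_gte(agree, 0.9)
  # determinism
  seg2 <- backfitSubject(averageReference(fx$recording), gm)
  expect_identical(frameLabels(seg2), lab)
  # polarity invariance end to end
  flipped <- EEGRecording(-potentials(fx$recording), 250, fx$montage)
  seg3 <- backfitSubject(averageReference(flipped), gm)
  expect_identical(frameLabels(seg3), lab)
})
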