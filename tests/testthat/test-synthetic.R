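test_that("template maps are zero-mean, unit-norm and mutually dissimilar", {
  mont <- fixtureMontage(32)
  one <- makeTemplateMaps(mont, 1, seed = 1)
  expect_equal(rowMeans(maps(one)), 0, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(sum(maps(one)^2), 1, tolerance = 1e-12)

  # pairwise bound over many seeds
  worst <- 0
  for (s in 1:100) {
    M <- maps(makeTemplateMaps(mont, 4, seed = s))
    off <- abs(tcrossprod(M))
    diag(off) <- 0
    worst <- max(worst, max(off))
  }
  expect_lte(worst, 0.6)

  # seeding contract
  expect_identical(maps(makeTemplateMaps(mont, 4, seed = 9)),
                   maps(makeTemplateMaps(mont, 4, seed = 9)))
  expect_error(makeTemplateMaps(mont, 40), "channel count")
})

test_that("state sequences respect planted mean durations and transitions", {
  spec1 <- simulationSpec(nChannels = 8, K = 1, durationS = 10)
  sq1 <- simulateStateSequence(spec1, seed = 1)
  expect_equal(nrow(segmentTable(sq1)), 1)
  expect_equal(segmentTable(sq1)$length, 2500)

  spec <- simulationSpec(nChannels = 8, K = 4, durationS = 300,
                         meanDurationsMs = rep(80, 4))
  for (s in 1:3) {
    sq <- simulateStateSequence(spec, seed = s)
    runs <- segmentTable(sq)
    meanMs <- mean(runs$length) * 1000 / 250
    expect_lt(abs(meanMs - 80) / 80, 0.05)
  }

  # uniform successor frequencies under the uniform transition matrix
  sq <- simulateStateSequence(spec, seed = 11)
  st <- segmentTable(sq)$state
  trans <- table(st[-length(st)], st[-1])
  expect_gt(chisq.test(trans[trans > 0])$p.value, 1e-4)
})

test_that("synthetic EEG expresses the active map and honors the seed", {
  fx <- fixtureRecording(nChannels = 16, durationS = 10, snr = Inf, seed = 4)
  # noiseless: every nonzero frame is proportional to the active template
  d <- potentials(fx$recording)
  g <- gfp(fx$recording)
  live <- which(g > 1e-8)
  lab <- frameLabels(fx$sequence)
  rs <- vapply(live[seq(1, length(live), by = 25)], function(t)
    spatialCorrelation(d[, t], maps(fx$templates)[lab[t], ]), 0)
  expect_equal(rs, rep(1, length(rs)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # every frame average-referenced
  expect_lt(max(abs(colMeans(d))), 1e-10)

  fx2 <- fixtureRecording(nChannels = 16, durationS = 10, snr = Inf, seed = 4)
  expect_identical(potentials(fx$recording), potentials(fx2$recording))
})

test_that("winner-takes-all at GFP peaks recovers planted labels", {
  for (snr in c(10, 2)) {
    fx <- fixtureRecording(nChannels = 32, durationS = 30, snr = snr,
                           seed = 21)
    g <- gfp(fx$recording)
    pk <- gfpPeaks(g)
    seg <- labelFrames(averageReference(fx$recording), fx$templates,
                       minCorr = 0)
    rec <- mean(frameLabels(seg)[pk] == frameLabels(fx$sequence)[pk])
    expect_gte(rec, if (snr >= 10) 0.95 else 0.80)
  }
})

test_that("generator ground truth matches the metrics module exactly", {
  spec <- simulationSpec(nChannels = 8, K = 4, durationS = 60)
  coh <- simulateCohort(cohortSpec(groupSizes = c(2, 2),
                                   groupNames = c("a", "b")),
                        spec, metricsOnly = TRUE, seed = 5)
  met <- metricsTable(coh$sequences, groups = coh$groups)
  expect_equal(met$duration_ms, coh$truth$duration_ms, tolerance = 1e-12)
  expect_equal(met$coverage_pct, coh$truth$coverage_pct, tolerance = 1e-12)
  expect_equal(met$occurrence_per_s, coh$truth$occurrence_per_s,
               tolerance = 1e-12)
})

test_that("cohort questionnaire tracks the designated state's occurrence", {
  spec <- simulationSpec(nChannels = 8, K = 4, durationS = 30)
  coh <- simulateCohort(cohortSpec(groupSizes = c(50, 50),
                                   groupNames = c("a", "b"),
                                   corrTarget = 0.3),
                        spec, metricsOnly = TRUE, seed = 42)
  expect_true(all(coh$questionnaire[, -(1:2)] >= 1 &
                  coh$questionnaire[, -(1:2)] <= 5))
  dom <- arsqDomains(coh$questionnaire)
  occ <- coh$truth$occurrence_per_s[coh$truth$state == 3]
  r <- pearsonCorr(occ, dom$visual_thought)$r
  expect_lt(abs(r - 0.3), 0.15)
})

test_that("planted duration multipliers shift group truth in direction", {
  spec <- simulationSpec(nChannels = 8, K = 4, durationS = 30)
  mult <- matrix(1, 3, 4); mult[1, 3] <- 0.75
  hits <- 0
  for (s in 1:10) {
    coh <- simulateCohort(cohortSpec(groupSizes = c(10, 20, 20),
                                     durationMultipliers = mult),
                          spec, metricsOnly = TRUE, seed = 100 + s)
    d <- coh$truth[coh$truth$state == 3, ]
    m <- tapply(d$duration_ms, d$group, mean)
    p <- anovaOneway(d$duration_ms, d$group)$p
    if (m[["g1"]] < m[["g2"]] && m[["g1"]] < m[["g3"]] && p < 0.05)
      hits <- hits + 1
  }
  expect_gte(hits, 9)
})
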