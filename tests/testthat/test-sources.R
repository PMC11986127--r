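# shared small head model
srcMont <- makeSphericalMontage(48)
srcLf <- buildSphericalLeadfield(srcMont, nPoints = 220, seed = 5)

test_that("the spherical lead field is finite, linear and antisymmetric", {
  G <- gain(srcLf)
  expect_true(all(is.finite(G)))
  expect_true(all(colSums(G^2) > 0))
  # linearity: doubling the moment doubles the potentials; flip negates
  q <- c(0.3, -1, 0.5)
  j <- 37
  topo <- G[, 3 * (j - 1) + 1:3, drop = FALSE] %*% q
  topo2 <- G[, 3 * (j - 1) + 1:3, drop = FALSE] %*% (2 * q)
  expect_equal(topo2, 2 * topo, tolerance = 1e-12)
  topoN <- G[, 3 * (j - 1) + 1:3, drop = FALSE] %*% (-q)
  expect_equal(topoN, -topo, tolerance = 1e-12)
  # columns are average-referenced
  expect_lt(max(abs(colMeans(G))), 1e-12)
})

test_that("the inverse localizes cortical point sources within 2 grid steps", {
  co <- pointCoords(srcLf)
  D <- as.matrix(dist(co))
  h <- median(apply(D, 1, function(r) min(r[r > 0])))
  inv <- loretaInverse(srcLf, lambda = 1e-4)
  targets <- rbind(c(0.4, 0.3, 0.5), c(-0.3, -0.4, 0.4), c(0.1, 0.6, 0.3))
  targets <- targets / sqrt(rowSums(targets^2)) * 0.72
  errs <- apply(targets, 1, function(tc) {
    j <- which.min(colSums((t(co) - tc)^2))
    topo <- gain(srcLf)[, 3 * (j - 1) + 1:3] %*% c(1, 0.5, 0.2)
    est <- applyInverse(inv, topo)
    jhat <- which.max(est@currentDensity[, 1])
    sqrt(sum((co[jhat, ] - co[j, ])^2))
  })
  expect_true(all(errs <= 2 * h + 1e-9))
})

test_that("regularization shrinks and the operator is linear", {
  j <- 100
  topo <- gain(srcLf)[, 3 * (j - 1) + 1:3] %*% c(1, 0, 0)
  big <- loretaInverse(srcLf, lambda = 1e8)
  expect_lt(max(applyInverse(big, topo)@currentDensity), 1e-6)
  inv <- loretaInverse(srcLf, lambda = 1e-2)
  expect_equal(max(abs(applyInverse(inv, matrix(0, 48, 1))@currentDensity)),
               0)
  J1 <- applyInverse(inv, topo, norm = FALSE)
  J2 <- applyInverse(inv, 3 * topo, norm = FALSE)
  expect_equal(J2, 3 * J1, tolerance = 1e-9)
  expect_error(loretaInverse(srcLf, lambda = -1), "nonnegative")
})

test_that("localization improves on average with sensor count", {
  errFor <- function(nSens) {
    mont <- makeSphericalMontage(nSens)
    lf <- buildSphericalLeadfield(mont, nPoints = 150, seed = 2)
    co <- pointCoords(lf)
    inv <- loretaInverse(lf, lambda = 1e-4)
    sel <- which(sqrt(rowSums(co^2)) > 0.5 & co[, 3] > 0)
    mean(vapply(sel, function(j) {
      topo <- gain(lf)[, 3 * (j - 1) + 1:3] %*% c(1, 0.5, 0.2)
      est <- applyInverse(inv, topo)
      sqrt(sum((co[which.max(est@currentDensity[, 1]), ] - co[j, ])^2))
    }, 0))
  }
  expect_lte(errFor(64), errFor(16))
})

test_that("per-point standardization centers, scales and warns on flats", {
  set.seed(4)
  cd <- matrix(abs(rnorm(30 * 50)), 30, 50)
  est <- new("SourceEstimate", currentDensity = cd, standardized = FALSE)
  z <- standardizePoints(est)
  expect_lt(max(abs(rowMeans(z@currentDensity))), 1e-10)
  expect_equal(apply(z@currentDensity, 1, sd), rep(1, 30), tolerance = 1e-10)
  # scale invariance
  z5 <- standardizePoints(new("SourceEstimate", currentDensity = 5 * cd,
                              standardized = FALSE))
  expect_equal(z5@currentDensity, z@currentDensity, tolerance = 1e-10)
  # constant rows -> 0 with warning; single frame errors
  cd[3, ] <- 7
  expect_warning(zf <- standardizePoints(new("SourceEstimate",
                                             currentDensity = cd,
                                             standardized = FALSE)),
                 "constant")
  expect_equal(zf@currentDensity[3, ], rep(0, 50))
  expect_error(standardizePoints(new("SourceEstimate",
                                     currentDensity = cd[, 1, drop = FALSE],
                                     standardized = FALSE)), "2 frames")
})

test_that("gated microstate averaging recovers a planted deep source", {
  co <- pointCoords(srcLf)
  j <- which.min(colSums((t(co) - c(0.25, 0.25, 0.45))^2))
  G3 <- gain(srcLf)[, 3 * (j - 1) + 1:3]
  src <- as.vector(G3 %*% c(0.2, 1, 0.4))
  tpl <- makeTemplateMaps(srcMont, 2, seed = 3)
  n <- 400
  lab <- rep(c(1L, 2L), n / 2)
  amp <- runif(n, 0.5, 2)
  X <- matrix(0, 48, n)
  X[, lab == 1L] <- outer(maps(tpl)[1, ], amp[lab == 1L])
  X[, lab == 2L] <- outer(src / sqrt(sum(src^2)), amp[lab == 2L])
  rec <- EEGRecording(X + rnorm(48 * n, 0, 1e-4), 250, srcMont)
  gm <- MicrostateMapSet(rbind(maps(tpl)[1, ], src), level = "group")
  seg <- labelFrames(averageReference(rec), gm)
  inv <- loretaInverse(srcLf, lambda = 1e-4)
  res <- microstateSourceAverage(rec, seg, 2L, inv)
  expect_gt(res$nFrames, 100)
  h <- median(apply(as.matrix(dist(co)), 1, function(r) min(r[r > 0])))
  expect_lte(sqrt(sum((co[which.max(res$values), ] - co[j, ])^2)), 2 * h)
  # frame order invariance
  perm <- sample(n)
  rec2 <- EEGRecording(potentials(rec)[, perm], 250, srcMont)
  seg2 <- MicrostateSegmentation(frameLabels(seg)[perm], 2, 250,
                                 corr = frameCorr(seg)[perm],
                                 gfp = seg@gfp[perm])
  res2 <- microstateSourceAverage(rec2, seg2, 2L, inv)
  expect_equal(res2$values, res$values, tolerance = 1e-9)
  expect_equal(res2$nFrames, res$nFrames)
  # an impossible gate yields a missing result with warning
  expect_warning(miss <- microstateSourceAverage(rec, seg, 2L, inv,
                                                 corrGate = 1.01),
                 "gate")
  expect_true(all(is.na(miss$values)))
})
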