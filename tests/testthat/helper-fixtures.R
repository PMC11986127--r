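# Shared fixture builders; everything is generated in code at test time.

fixtureMontage <- function(n = 16) makeSphericalMontage(n)

# a planted-structure recording with its ground truth
fixtureRecording <- function(nChannels = 16, durationS = 20, snr = 10,
                             K = 4, seed = 1) {
  mont <- fixtureMontage(nChannels)
  tpl <- makeTemplateMaps(mont, K, seed = seed)
  spec <- simulationSpec(nChannels = nChannels, durationS = durationS,
                        K = K, snr = snr)
  sq <- simulateStateSequence(spec, seed = seed + 1)
  rec <- simulateEEG(tpl, sq, mont, spec, seed = seed + 2)
  list(recording = rec, sequence = sq, templates = tpl, montage = mont,
       spec = spec)
}

# segmentation from an explicit run-length encoding, e.g. runsSeg(A=20, B=4)
runsSeg <- function(..., nStates = NULL, rate = 250) {
  runs <- c(...)
  states <- match(names(runs), LETTERS)
  lab <- rep(states, runs)
  if (is.null(nStates)) nStates <- max(states)
  MicrostateSegmentation(lab, nStates, rate)
}

# brute-force optimal GEV over every assignment of n topographies into k
# clusters (full assignment, polarity ignored): per cluster the optimal
# centroid is the leading eigenvector of the GFP^2-weighted scatter of the
# normalized topographies, contributing its leading eigenvalue.
bruteForceGev <- function(X, k) {
  X <- sweep(X, 2, colMeans(X))
  n <- ncol(X)
  w2 <- colMeans(X^2)                       # gfp^2
  Xn <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  tot <- sum(w2)
  best <- -Inf
  idx <- rep(1L, n)
  repeat {
    if (length(unique(idx)) == k) {
      val <- 0
      for (j in seq_len(k)) {
        cols <- which(idx == j)
        A <- crossprod(t(Xn[, cols, drop = FALSE]) * sqrt(w2[cols]))
        val <- val + eigen(A, symmetric = TRUE,
                           only.values = TRUE)$values[1]
      }
      if (val > best) best <- val
    }
    p <- n
    while (p >= 1 && idx[p] == k) { idx[p] <- 1L; p <- p - 1L }
    if (p == 0) break
    idx[p] <- idx[p] + 1L
  }
  best / tot
}
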