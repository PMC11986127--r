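## Signal conditioning: zero-phase Butterworth bandpass, anti-aliased
## downsampling, Perrin spherical-spline bad-channel interpolation, average
## referencing, and the GFP series with peak extraction.

.withHistory <- function(recording, data, step, samplingRate = NULL) {
  new("EEGRecording", data = data,
      samplingRate = if (is.null(samplingRate)) recording@samplingRate
                     else samplingRate,
      montage = recording@montage, badChannels = recording@badChannels,
      history = c(recording@history, step))
}

## Forward-backward filtering with odd-symmetric reflection padding at both
## ends, so that 5-minute segments carry no start-up transients and the net
## phase response is zero.
.zeroPhase <- function(b, a, x, padLen) {
  n <- length(x)
  padLen <- min(padLen, n - 1)
  pre <- 2 * x[1] - x[seq(padLen + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - padLen)]
  y <- c(pre, x, post)
  y <- signal::filter(b, a, y)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(padLen + 1):(padLen + n)]
}

#' Zero-phase Butterworth bandpass filter
#'
#' Second-order Butterworth bandpass (-12 dB/octave roll-off per edge)
#' applied forward and backward to cancel the phase shift, with reflection
#' padding to suppress edge transients. The 1 Hz high-pass edge removes DC.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param lowHz,highHz band edges in Hz (defaults 1 and 40).
#' @param order filter order per edge (default 2).
#' @return The filtered \linkS4class{EEGRecording} (same length and rate).
#' @export
bandpassFilter <- function(recording, lowHz = 1, highHz = 40, order = 2) {
  fs <- samplingRate(recording)
  if (!(lowHz > 0 && lowHz < highHz && highHz < fs / 2))
    stop(sprintf("band [%g, %g] Hz invalid for sampling rate %g Hz (Nyquist %g)",
                 lowHz, highHz, fs, fs / 2))
  bf <- signal::butter(order, c(lowHz, highHz) / (fs / 2), type = "pass")
  padLen <- max(12, round(3 * fs / lowHz))
  d <- potentials(recording)
  out <- t(apply(d, 1, function(x) .zeroPhase(bf$b, bf$a, x, padLen)))
  dimnames(out) <- dimnames(d)
  .withHistory(recording, out,
               sprintf("bandpass:%g-%gHz,order%d,zero-phase", lowHz, highHz,
                       order))
}

#' Downsample a recording with anti-alias filtering
#'
#' Applies a zero-phase 4th-order Butterworth low-pass at 90% of the target
#' Nyquist frequency before resampling. Integer decimation keeps every
#' r-th sample; non-integer ratios resample by linear interpolation at the
#' new sample times.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param targetHz new sampling rate (default 250), must not exceed the
#'   current rate.
#' @return The resampled \linkS4class{EEGRecording}.
#' @export
downsampleRecording <- function(recording, targetHz = 250) {
  fs <- samplingRate(recording)
  if (targetHz > fs)
    stop(sprintf("target rate %g Hz exceeds source rate %g Hz", targetHz, fs))
  d <- potentials(recording)
  if (targetHz == fs) return(.withHistory(recording, d, "downsample:noop"))
  cutoff <- 0.9 * targetHz / 2
  bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
  padLen <- max(12, round(3 * fs / cutoff))
  filt <- t(apply(d, 1, function(x) .zeroPhase(bf$b, bf$a, x, padLen)))
  ratio <- fs / targetHz
  n <- ncol(d)
  if (abs(ratio - round(ratio)) < 1e-9) {
    idx <- seq(1, n, by = round(ratio))
    out <- filt[, idx, drop = FALSE]
  } else {
    tOld <- (seq_len(n) - 1) / fs
    tNew <- seq(0, tOld[n], by = 1 / targetHz)
    out <- t(apply(filt, 1, function(x) approx(tOld, x, xout = tNew)$y))
  }
  rownames(out) <- rownames(d)
  .withHistory(recording, out, sprintf("downsample:%gHz", targetHz),
               samplingRate = targetHz)
}

## Perrin-style spherical-spline kernel g(x), x = cosine of the angle
## between two unit-sphere positions; spline order m, Legendre series
## truncated at nTerms.
.splineG <- function(x, m = 4, nTerms = 7) {
  n <- seq_len(nTerms)
  P <- .legendreP(x, nTerms)          # length(x) x nTerms
  coef <- (2 * n + 1) / (n^m * (n + 1)^m)
  as.vector(P %*% coef) / (4 * pi)
}

## Legendre polynomials P_1..P_nmax via the Bonnet recurrence.
.legendreP <- function(x, nmax) {
  out <- matrix(0, length(x), nmax)
  pPrev <- rep(1, length(x))          # P_0
  p <- x                              # P_1
  out[, 1] <- p
  if (nmax > 1) for (n in 2:nmax) {
    pNext <- ((2 * n - 1) * x * p - (n - 1) * pPrev) / n
    out[, n] <- pNext
    pPrev <- p; p <- pNext
  }
  out
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces the listed channels with spherical-spline estimates from the
#' remaining good channels (spline order m = 4, 7-term Legendre expansion,
#' small ridge on the spline system), leaving good channels untouched.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param badChannels channel names to interpolate; defaults to the
#'   recording's own bad-channel list.
#' @param m spline order (default 4).
#' @param nTerms Legendre truncation (default 7).
#' @param lambda ridge added to the spline system diagonal (default 1e-5).
#' @return The repaired \linkS4class{EEGRecording} with an empty bad-channel
#'   list.
#' @export
sphericalSplineInterpolate <- function(recording,
                                       badChannels = NULL,
                                       m = 4, nTerms = 7, lambda = 1e-5) {
  if (is.null(badChannels)) badChannels <- recording@badChannels
  nm <- channelNames(recording)
  if (!length(badChannels))
    return(.withHistory(recording, potentials(recording), "interpolate:none"))
  unknown <- setdiff(badChannels, nm)
  if (length(unknown))
    stop("unknown bad channels: ", paste(unknown, collapse = ", "))
  good <- setdiff(nm, badChannels)
  if (length(good) < 4)
    stop("at least 4 good channels are required for spline interpolation")
  pos <- recording@montage@positions
  gi <- match(good, nm); bi <- match(badChannels, nm)
  cosGG <- pmin(pmax(tcrossprod(pos[gi, , drop = FALSE]), -1), 1)
  cosBG <- pmin(pmax(pos[bi, , drop = FALSE] %*% t(pos[gi, , drop = FALSE]),
                     -1), 1)
  G <- matrix(.splineG(as.vector(cosGG), m, nTerms), length(gi))
  Gb <- matrix(.splineG(as.vector(cosBG), m, nTerms), length(bi))
  ng <- length(gi)
  A <- rbind(cbind(G + diag(lambda, ng), rep(1, ng)),
             c(rep(1, ng), 0))
  d <- potentials(recording)
  rhs <- rbind(d[gi, , drop = FALSE], 0)
  sol <- solve(A, rhs)
  sol <- sol + solve(A, rhs - A %*% sol)   # one refinement step

  cc <- sol[seq_len(ng), , drop = FALSE]
  c0 <- sol[ng + 1, ]
  est <- Gb %*% cc + matrix(c0, length(bi), ncol(d), byrow = TRUE)
  out <- d
  out[bi, ] <- est
  res <- .withHistory(recording, out,
                      sprintf("interpolate:%s", paste(badChannels,
                                                      collapse = ",")))
  res@badChannels <- character()
  res
}

#' Re-reference a recording to the common average
#'
#' Subtracts the instantaneous channel mean from every frame, so each
#' column of the data has zero mean. Idempotent; leaves GFP unchanged on
#' already-centered data.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @return The re-referenced \linkS4class{EEGRecording}.
#' @export
averageReference <- function(recording) {
  d <- potentials(recording)
  out <- sweep(d, 2, colMeans(d))
  .withHistory(recording, out, "average-reference")
}

#' Global field power series
#'
#' GFP(t) is the spatial standard deviation of the average-referenced
#' topography at frame t (population convention, divide by the number of
#' channels); for centered data this equals the RMS over channels. GFP is
#' invariant to polarity flips.
#'
#' @param recording an \linkS4class{EEGRecording} (centered internally).
#' @return Numeric vector, one nonnegative value per frame.
#' @export
gfp <- function(recording) {
  d <- potentials(recording)
  d <- sweep(d, 2, colMeans(d))
  sqrt(colMeans(d^2))
}

#' Local maxima of a GFP series
#'
#' Strict local maxima; when a minimum separation is requested, peaks are
#' admitted in decreasing height order and any peak closer than the
#' separation to an already-admitted one is dropped.
#'
#' @param gfpSeries numeric GFP values.
#' @param minSeparation minimum distance between retained peaks, in frames
#'   (0 keeps all strict maxima).
#' @return Integer frame indices of the peaks, in increasing order.
#' @export
gfpPeaks <- function(gfpSeries, minSeparation = 0) {
  n <- length(gfpSeries)
  if (n < 3) return(integer())
  i <- 2:(n - 1)
  peaks <- i[gfpSeries[i] > gfpSeries[i - 1] & gfpSeries[i] > gfpSeries[i + 1]]
  if (minSeparation > 0 && length(peaks) > 1) {
    ord <- peaks[order(gfpSeries[peaks], decreasing = TRUE)]
    kept <- integer()
    for (p in ord)
      if (!length(kept) || min(abs(kept - p)) >= minSeparation)
        kept <- c(kept, p)
    peaks <- sort(kept)
  }
  peaks
}
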