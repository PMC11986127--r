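## Distributed source imaging on a synthetic spherical head model: an
## analytic dipole-in-homogeneous-sphere forward solution on a quasi-uniform
## solution grid, a Laplacian-weighted minimum-norm (LORETA-style) inverse,
## per-point standardization over time, and correlation-gated averaging over
## microstate-labeled frames.

## Associated Legendre P_n^1 (no Condon-Shortley phase) and P_n, accumulated
## into the two angular kernels of the single-sphere dipole potential.
.sphereKernels <- function(cosg, b, nTerms = 40) {
  s <- sqrt(pmax(0, 1 - cosg^2))
  pPrev <- rep(1, length(cosg)); p <- cosg           # P_0, P_1
  qPrev <- rep(0, length(cosg)); q <- s              # P_0^1, P_1^1
  F1 <- 3 * b^0 * p                                  # n = 1 terms
  F2 <- 3 * b^0 * q
  for (n in 2:nTerms) {
    pNext <- ((2 * n - 1) * cosg * p - (n - 1) * pPrev) / n
    qNext <- ((2 * n - 1) * cosg * q - n * qPrev) / (n - 1)
    coef <- (2 * n + 1) / n * b^(n - 1)
    F1 <- F1 + coef * n * pNext
    F2 <- F2 + coef * qNext
    pPrev <- p; p <- pNext
    qPrev <- q; q <- qNext
  }
  list(F1 = F1, F2 = F2)
}

#' Spherical-head lead field
#'
#' Analytic quasi-static forward model of a current dipole inside a
#' homogeneous unit conducting sphere, evaluated at the montage sensors for
#' a quasi-uniform grid of solution points within radius
#' \code{maxRadius}. Columns come in triplets (x, y, z orientation) per
#' point and are average-referenced across sensors.
#'
#' @param montage a \linkS4class{SensorMontage} (sensors on the unit
#'   sphere).
#' @param nPoints requested number of solution points (default 800).
#' @param maxRadius outer radius of the source space (default 0.85).
#' @param nTerms Legendre-series truncation (default 40).
#' @param seed seed for the down-sampling of grid points (optional).
#' @return A \linkS4class{LeadField}.
#' @export
buildSphericalLeadfield <- function(montage, nPoints = 800, maxRadius = 0.85,
                                    nTerms = 40, seed = NULL) {
  stopifnot(nPoints >= 1)
  if (!is.null(seed)) set.seed(seed)
  ## cubic grid sized to over-cover, then seeded down-sampling
  h <- (4 / 3 * pi * maxRadius^3 / nPoints)^(1 / 3)
  repeat {
    ax <- seq(-maxRadius, maxRadius, by = h)
    g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
    r <- sqrt(rowSums(g^2))
    g <- g[r <= maxRadius & r >= 0.05, , drop = FALSE]
    if (nrow(g) >= nPoints) break
    h <- h * 0.93
  }
  if (nrow(g) > nPoints)
    g <- g[sort(sample.int(nrow(g), nPoints)), , drop = FALSE]
  E <- montage@positions
  S <- nrow(E); P <- nrow(g)
  gain <- matrix(0, S, 3 * P)
  for (j in seq_len(P)) {
    b <- sqrt(sum(g[j, ]^2))
    rhat <- g[j, ] / b
    cosg <- pmin(pmax(as.vector(E %*% rhat), -1), 1)
    ker <- .sphereKernels(cosg, b, nTerms)
    tang <- E - outer(cosg, rhat)            # un-normalized tangential dirs
    tn <- sqrt(rowSums(tang^2))
    tang <- tang / ifelse(tn > 1e-12, tn, 1)
    tang[tn <= 1e-12, ] <- 0
    for (k in 1:3) {
      v <- (rhat[k] * ker$F1 + tang[, k] * ker$F2) / (4 * pi)
      gain[, 3 * (j - 1) + k] <- v - mean(v)
    }
  }
  rownames(gain) <- channelNames(montage)
  new("LeadField", gain = gain, pointCoords = g,
      modelDesc = sprintf("homogeneous sphere, %d points <= r %.2f, %d-term series",
                          P, maxRadius, nTerms))
}

## Unnormalized graph Laplacian over the solution points (kNN graph).
.pointLaplacian <- function(coords, kNN = 6) {
  P <- nrow(coords)
  D <- as.matrix(dist(coords))
  A <- matrix(0, P, P)
  for (i in seq_len(P)) {
    nb <- order(D[i, ])[2:min(kNN + 1, P)]
    A[i, nb] <- 1
  }
  A <- pmax(A, t(A))
  diag(rowSums(A)) - A
}

#' Laplacian-weighted minimum-norm (LORETA-style) inverse operator
#'
#' Builds the linear operator J = W^-1 G' (G W^-1 G' + lambda * c * I)^-1
#' mapping average-referenced sensor topographies to 3-orientation point
#' currents, with W the squared discrete spatial Laplacian over solution
#' points (applied per orientation) and c the mean diagonal of G W^-1 G'
#' (so lambda is scale-free). lambda = 0 requires the unregularized system
#' to be invertible.
#'
#' @param leadfield a \linkS4class{LeadField}.
#' @param lambda relative Tikhonov regularization (default 1/9, the
#'   fixed-SNR heuristic 1/snr^2 at snr = 3).
#' @param kNN neighbors in the Laplacian graph (default 6).
#' @return A list of class \code{msInverseOperator} with the operator
#'   matrix \code{K} (3P x sensors) and the lead field.
#' @export
loretaInverse <- function(leadfield, lambda = 1 / 9, kNN = 6) {
  if (lambda < 0) stop("lambda must be nonnegative")
  G <- gain(leadfield)
  P <- nrow(pointCoords(leadfield))
  S <- nrow(G)
  L <- .pointLaplacian(pointCoords(leadfield), kNN)
  Wp <- crossprod(L) + diag(1e-8, P)
  ## W = Wp (x) I3 with orientation-major triplets: solve per orientation
  B <- matrix(0, 3 * P, S)                  # W^-1 G'
  for (k in 1:3) {
    rows <- 3 * (seq_len(P) - 1) + k
    B[rows, ] <- as.matrix(solve(Wp, t(G[, rows, drop = FALSE])))
  }
  A <- G %*% B
  cc <- mean(diag(A))
  Areg <- A + diag(lambda * cc, S)
  Kmat <- tryCatch(t(solve(t(Areg), t(B))),
                   error = function(e)
                     stop("singular sensor covariance; use lambda > 0"))
  out <- list(K = Kmat, leadfield = leadfield, lambda = lambda)
  class(out) <- "msInverseOperator"
  out
}

#' Apply an inverse operator to sensor topographies
#'
#' @param inverseOp an \code{msInverseOperator}.
#' @param topographies sensors x frames matrix (average-referenced
#'   internally).
#' @param norm reduce the 3 orientation components to their Euclidean norm
#'   per point (default TRUE).
#' @return With \code{norm}, a \linkS4class{SourceEstimate} (points x
#'   frames); otherwise the raw 3P x frames current matrix.
#' @export
applyInverse <- function(inverseOp, topographies, norm = TRUE) {
  X <- as.matrix(topographies)
  X <- sweep(X, 2, colMeans(X))
  J <- inverseOp$K %*% X                    # 3P x frames
  if (!norm) return(J)
  P <- nrow(J) / 3
  idx <- 3 * (seq_len(P) - 1)
  cd <- sqrt(J[idx + 1, , drop = FALSE]^2 + J[idx + 2, , drop = FALSE]^2 +
             J[idx + 3, , drop = FALSE]^2)
  new("SourceEstimate", currentDensity = cd, standardized = FALSE)
}

#' Standardize each solution point across time
#'
#' Z-scores every point's current-density time series (mean 0, SD 1 across
#' frames), eliminating depth-dependent activation biases. Points with a
#' constant series are set to 0 with a warning.
#'
#' @param estimate a \linkS4class{SourceEstimate} with >= 2 frames.
#' @return The standardized \linkS4class{SourceEstimate}.
#' @export
standardizePoints <- function(estimate) {
  cd <- estimate@currentDensity
  if (ncol(cd) < 2) stop("standardization needs at least 2 frames")
  mu <- rowMeans(cd)
  sdv <- apply(cd, 1, sd)
  flat <- sdv == 0
  if (any(flat)) {
    warning(sum(flat), " solution point(s) with constant series set to 0")
    sdv[flat] <- 1
  }
  z <- (cd - mu) / sdv
  z[flat, ] <- 0
  new("SourceEstimate", currentDensity = z, standardized = TRUE)
}

#' Mean standardized source activity of one microstate
#'
#' Inverts the whole recording, standardizes each solution point across all
#' frames, and averages the standardized current density over the frames
#' labeled with the given state whose winning |correlation| exceeds the
#' gate (0.9: only frames expressing the map cleanly are used).
#'
#' @param recording the backfitted \linkS4class{EEGRecording}.
#' @param segmentation its \linkS4class{MicrostateSegmentation} with
#'   per-frame correlations.
#' @param state state index.
#' @param inverseOp an \code{msInverseOperator} on the recording's montage.
#' @param corrGate minimum winning |correlation| (default 0.9).
#' @return List with \code{values} (per-point mean standardized activation;
#'   all-NA when no frame qualifies, with a warning) and \code{nFrames}.
#' @export
microstateSourceAverage <- function(recording, segmentation, state,
                                    inverseOp, corrGate = 0.9) {
  lab <- frameLabels(segmentation)
  corr <- frameCorr(segmentation)
  sel <- which(lab == state & !is.na(corr) & corr > corrGate)
  P <- nrow(pointCoords(inverseOp$leadfield))
  if (!length(sel)) {
    warning("no frames of state ", state, " pass the correlation gate")
    return(list(values = rep(NA_real_, P), nFrames = 0L))
  }
  est <- applyInverse(inverseOp, potentials(recording))
  est <- standardizePoints(est)
  list(values = rowMeans(est@currentDensity[, sel, drop = FALSE]),
       nFrames = length(sel))
}
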