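## Polarity-invariant modified k-means over EEG topographies, global
## explained variance, meta-criterion selection of the number of maps, and
## the two-stage (subject, then pooled group) segmentation.

#' Spatial correlation between two topographies
#'
#' Pearson correlation across channels of two zero-mean topographies; with
#' \code{ignorePolarity} the absolute value is returned, treating a map and
#' its sign-inverse as identical.
#'
#' @param a,b numeric vectors over the same channels.
#' @param ignorePolarity return |r| (default TRUE).
#' @return Correlation in [-1, 1] (or [0, 1] when polarity is ignored).
#' @export
spatialCorrelation <- function(a, b, ignorePolarity = TRUE) {
  if (length(a) != length(b)) stop("topographies differ in channel count")
  a <- a - mean(a); b <- b - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-variance topography")
  r <- sum(a * b) / (na * nb)
  if (ignorePolarity) abs(r) else r
}

## Centered, unit-norm columns; drop-in for correlation by crossproduct.
.normCols <- function(X) {
  X <- sweep(X, 2, colMeans(X))
  nrm <- sqrt(colSums(X^2))
  nrm[nrm == 0] <- 1
  sweep(X, 2, nrm, "/")
}

## Leading principal direction of the columns of X (channels x n), by power
## iteration warm-started at `start`; returns a zero-mean unit vector.
.leadingDirection <- function(X, start = NULL) {
  S <- tcrossprod(X)                 # C x C scatter
  v <- if (is.null(start)) X[, 1] else start
  v <- v / sqrt(sum(v^2))
  for (i in 1:50) {
    w <- S %*% v
    nw <- sqrt(sum(w^2))
    if (nw == 0) break
    w <- as.vector(w) / nw
    if (sum(abs(w - v)) < 1e-10 || sum(abs(w + v)) < 1e-10) { v <- w; break }
    v <- w
  }
  v <- v - mean(v)
  n <- sqrt(sum(v^2))
  if (n == 0) stop("degenerate cluster: constant topographies")
  v / n
}

#' Global explained variance of a labeled sample set
#'
#' GEV is the GFP-squared-weighted share of topographic variance explained
#' by the assigned maps: sum over assigned samples of (GFP_t * r_t)^2
#' divided by the sum over all samples of GFP_t^2, where r_t is the spatial
#' correlation between sample t and its assigned map. Unassigned samples
#' contribute only to the denominator.
#'
#' @param topographies channels x samples matrix.
#' @param gfpAtSamples per-sample GFP; computed from the topographies when
#'   NULL.
#' @param mapset a \linkS4class{MicrostateMapSet} (or K x channels matrix).
#' @param assignment integer per-sample state (0 = unassigned).
#' @param ignorePolarity use |correlation| (default TRUE).
#' @return Fraction in [0, 1].
#' @export
gevOfSolution <- function(topographies, mapset, assignment,
                          gfpAtSamples = NULL, ignorePolarity = TRUE) {
  X <- as.matrix(topographies)
  if (is.null(gfpAtSamples))
    gfpAtSamples <- sqrt(colMeans(sweep(X, 2, colMeans(X))^2))
  tot <- sum(gfpAtSamples^2)
  if (tot == 0) stop("all-zero GFP: variance is undefined")
  M <- if (is(mapset, "MicrostateMapSet")) maps(mapset) else as.matrix(mapset)
  Xn <- .normCols(X)
  Mn <- .normCols(t(M))              # channels x K, centered unit columns
  idx <- which(assignment > 0L)
  if (!length(idx)) return(0)
  r <- colSums(Mn[, assignment[idx], drop = FALSE] * Xn[, idx, drop = FALSE])
  if (ignorePolarity) r <- abs(r)
  sum((gfpAtSamples[idx] * r)^2) / tot
}

#' Polarity-invariant modified k-means clustering of topographies
#'
#' Samples are assigned to the map with the highest absolute spatial
#' correlation (winner-takes-all); samples whose best |correlation| falls
#' below \code{minAssignCorr} stay unassigned and are excluded from centroid
#' updates. Centroids are updated as the first principal direction of the
#' topographies assigned to them (polarity-invariant update); a sign-aligned
#' weighted mean is available as a cheaper alternative. The best of
#' \code{nRestarts} random restarts by GEV is returned.
#'
#' @param topographies channels x samples matrix of zero-mean topographies.
#' @param k number of clusters (<= number of samples).
#' @param nRestarts random restarts (default 100).
#' @param minAssignCorr assignment threshold on |correlation| (default 0.5);
#'   use 0 to force full assignment.
#' @param gfpAtSamples per-sample GFP for the GEV weighting; computed from
#'   the topographies when NULL.
#' @param centroid "pca" (first principal direction, default) or
#'   "meansign" (sign-aligned mean).
#' @param tol relative GEV convergence tolerance (default 1e-6).
#' @param maxIter iteration cap per restart (default 300).
#' @param seed RNG seed for restart initialization (optional).
#' @return A list of class \code{msClusterSolution}: \code{mapset}
#'   (\linkS4class{MicrostateMapSet}), \code{assignment}, \code{corr}
#'   (per-sample winning |r|), \code{gev}.
#' @export
modifiedKMeans <- function(topographies, k, nRestarts = 100,
                           minAssignCorr = 0.5, gfpAtSamples = NULL,
                           centroid = c("pca", "meansign"),
                           tol = 1e-6, maxIter = 300, seed = NULL) {
  centroid <- match.arg(centroid)
  X <- as.matrix(topographies)
  n <- ncol(X); C <- nrow(X)
  if (k > n) stop(sprintf("k = %d exceeds the %d available topographies",
                          k, n))
  if (!is.null(seed)) set.seed(seed)
  X <- sweep(X, 2, colMeans(X))
  if (any(colSums(X^2) == 0)) stop("topographies must be nonzero")
  if (is.null(gfpAtSamples)) gfpAtSamples <- sqrt(colMeans(X^2))
  w2 <- gfpAtSamples^2
  tot <- sum(w2)
  if (tot == 0) stop("all-zero GFP")
  Xn <- .normCols(X)

  best <- NULL
  for (r in seq_len(nRestarts)) {
    init <- sample.int(n, k)
    M <- Xn[, init, drop = FALSE]    # channels x k centroids
    gevPrev <- -Inf; assign <- integer(n); amax <- numeric(n)
    for (it in seq_len(maxIter)) {
      A <- abs(crossprod(M, Xn))     # k x n |correlations|
      assign <- max.col(t(A), ties.method = "first")
      amax <- A[cbind(assign, seq_len(n))]
      assign[amax < minAssignCorr] <- 0L
      ## empty clusters reseeded from the worst-fit assigned topography
      for (j in which(tabulate(assign, k) == 0L)) {
        cand <- which(assign > 0L)
        pick <- if (length(cand)) cand[which.min(amax[cand])]
                else sample.int(n, 1)
        M[, j] <- Xn[, pick]
        assign[pick] <- j; amax[pick] <- 1
      }
      for (j in seq_len(k)) {
        cols <- which(assign == j)
        if (!length(cols)) next
        M[, j] <- if (centroid == "pca")
          .leadingDirection(X[, cols, drop = FALSE], start = M[, j])
        else {
          sgn <- sign(crossprod(M[, j, drop = FALSE],
                                Xn[, cols, drop = FALSE]))
          sgn[sgn == 0] <- 1
          v <- as.vector(X[, cols, drop = FALSE] %*% as.vector(sgn))
          v <- v - mean(v)
          v / sqrt(sum(v^2))
        }
      }
      gevNow <- sum(w2[assign > 0L] * amax[assign > 0L]^2) / tot
      if (is.finite(gevPrev) && gevNow - gevPrev < tol * max(gevPrev, 1e-12))
        break
      gevPrev <- gevNow
    }
    A <- abs(crossprod(M, Xn))
    assign <- max.col(t(A), ties.method = "first")
    amax <- A[cbind(assign, seq_len(n))]
    assign[amax < minAssignCorr] <- 0L
    gevNow <- sum(w2[assign > 0L] * amax[assign > 0L]^2) / tot
    if (is.null(best) || gevNow > best$gev)
      best <- list(M = M, assignment = assign, corr = amax, gev = gevNow)
  }
  res <- list(mapset = MicrostateMapSet(t(best$M), level = "subject",
                                        fitGev = best$gev),
              assignment = best$assignment, corr = best$corr, gev = best$gev)
  class(res) <- "msClusterSolution"
  res
}

#' @export
print.msClusterSolution <- function(x, ...) {
  cat(sprintf("modified k-means solution: k = %d, GEV = %.3f, %d/%d assigned\n",
              nStates(x$mapset), x$gev, sum(x$assignment > 0L),
              length(x$assignment)))
  invisible(x)
}

#' Meta-criterion choice of the number of microstate maps
#'
#' Ensemble vote over three standard criteria evaluated on the per-k
#' clustering solutions: Krzanowski-Lai index on the GFP^2-weighted
#' unexplained dispersion W(k), the Pascual-Marqui cross-validation
#' criterion, and the maximum-distance elbow of the W curve. The chosen k is
#' the median of the three votes (snapped to the nearest candidate k). The
#' exact meta-criterion of the Cartool toolbox is unpublished; this ensemble
#' is a documented approximation.
#'
#' @param solutions named list of \code{msClusterSolution}, one per k.
#' @param topographies the channels x samples matrix the solutions were fit
#'   to.
#' @param gfpAtSamples per-sample GFP (computed when NULL).
#' @return List with \code{k} (chosen) and \code{diagnostics} (per-k table
#'   of GEV, W, CV, KL plus each criterion's vote).
#' @export
selectOptimalK <- function(solutions, topographies, gfpAtSamples = NULL) {
  ks <- as.integer(names(solutions))
  if (any(is.na(ks))) ks <- vapply(solutions, function(s) nStates(s$mapset), 1L)
  ord <- order(ks); ks <- ks[ord]; solutions <- solutions[ord]
  X <- sweep(as.matrix(topographies), 2, colMeans(as.matrix(topographies)))
  C <- nrow(X); n <- ncol(X)
  if (is.null(gfpAtSamples)) gfpAtSamples <- sqrt(colMeans(X^2))
  tot <- sum(gfpAtSamples^2)
  gev <- vapply(solutions, function(s) s$gev, 0)
  W <- (1 - gev) * tot
  ## Pascual-Marqui predictive-residual criterion
  totSS <- sum(X^2)
  cv <- vapply(seq_along(ks), function(i) {
    s <- solutions[[i]]
    expl <- sum((sqrt(colSums(X^2))[s$assignment > 0L] *
                 s$corr[s$assignment > 0L])^2)
    sig2 <- (totSS - expl) / (n * (C - 1))
    if (C - 1 - ks[i] <= 0) return(Inf)
    sig2 * ((C - 1) / (C - 1 - ks[i]))^2
  }, 0)
  ## Krzanowski-Lai on W(k)
  kl <- rep(NA_real_, length(ks))
  if (length(ks) >= 3) {
    diffs <- rep(NA_real_, length(ks))
    for (i in 2:length(ks))
      diffs[i] <- ks[i - 1]^(2 / C) * W[i - 1] - ks[i]^(2 / C) * W[i]
    for (i in 2:(length(ks) - 1))
      if (!is.na(diffs[i]) && !is.na(diffs[i + 1]) && diffs[i + 1] != 0)
        kl[i] <- abs(diffs[i] / diffs[i + 1])
  }
  ## elbow: farthest point from the chord of the normalized W curve
  elbow <- NA_integer_
  if (length(ks) >= 3) {
    kx <- (ks - ks[1]) / (ks[length(ks)] - ks[1])
    wy <- if (max(W) > min(W)) (W - min(W)) / (max(W) - min(W)) else W * 0
    d <- abs((wy[length(ks)] - wy[1]) * kx - (kx[length(ks)] - kx[1]) * wy +
             kx[length(ks)] * wy[1] - wy[length(ks)] * kx[1])
    elbow <- ks[which.max(d)]
  }
  votes <- c(kl = if (all(is.na(kl))) NA_integer_ else ks[which.max(kl)],
             cv = ks[which.min(cv)],
             elbow = elbow)
  votes <- votes[!is.na(votes)]
  kChosen <- if (!length(votes)) ks[1] else {
    med <- median(votes)
    ks[which.min(abs(ks - med))]
  }
  list(k = as.integer(kChosen),
       diagnostics = data.frame(k = ks, gev = gev, W = W, cv = cv, kl = kl),
       votes = votes)
}

## Neighbor-averaging spatial smoothing: each channel replaced by the mean
## of itself and its nNeighbors nearest sensors.
.spatialSmooth <- function(recording, nNeighbors = 6) {
  pos <- recording@montage@positions
  D <- as.matrix(dist(pos))
  d <- potentials(recording)
  out <- d
  for (i in seq_len(nrow(d))) {
    nb <- order(D[i, ])[seq_len(min(nNeighbors + 1, nrow(d)))]
    out[i, ] <- colMeans(d[nb, , drop = FALSE])
  }
  .withHistory(recording, out, sprintf("spatial-smooth:%dnn", nNeighbors))
}

#' Subject-level microstate segmentation
#'
#' Extracts topographies at GFP peaks of the (average-referenced) recording,
#' runs polarity-invariant modified k-means for every candidate k, and keeps
#' the solution chosen by the meta-criterion. An optional neighbor-averaging
#' spatial filter smooths the data first.
#'
#' @param recording a preprocessed \linkS4class{EEGRecording}.
#' @param kRange candidate cluster numbers (default 1:12).
#' @param nRestarts restarts per k (default 100).
#' @param minAssignCorr assignment threshold (default 0.5).
#' @param spatialFilter apply neighbor-averaging smoothing first (default
#'   FALSE).
#' @param minPeakSeparation minimum GFP-peak separation in frames (default 0).
#' @param seed RNG seed (optional); per-k runs derive seeds from it.
#' @param ... passed to \code{\link{modifiedKMeans}}.
#' @return An \code{msClusterSolution} for the chosen k, with the
#'   selection diagnostics in attribute \code{"selection"} and the peak
#'   indices in attribute \code{"peaks"}.
#' @export
subjectSegmentation <- function(recording, kRange = 1:12, nRestarts = 100,
                                minAssignCorr = 0.5, spatialFilter = FALSE,
                                minPeakSeparation = 0, seed = NULL, ...) {
  if (spatialFilter) recording <- .spatialSmooth(recording)
  recording <- averageReference(recording)
  g <- gfp(recording)
  pk <- gfpPeaks(g, minPeakSeparation)
  if (length(pk) < 2) stop("too few GFP peaks for clustering")
  if (length(pk) < max(kRange)) {
    warning(sprintf("only %d GFP peaks: truncating k range at %d",
                    length(pk), length(pk)))
    kRange <- kRange[kRange <= length(pk)]
  }
  X <- potentials(recording)[, pk, drop = FALSE]
  sols <- list()
  for (k in kRange) {
    s <- if (is.null(seed)) NULL else seed + k
    sols[[as.character(k)]] <- modifiedKMeans(X, k, nRestarts = nRestarts,
                                              minAssignCorr = minAssignCorr,
                                              gfpAtSamples = g[pk],
                                              seed = s, ...)
  }
  if (length(kRange) >= 3) {
    sel <- selectOptimalK(sols, X, gfpAtSamples = g[pk])
    chosen <- sols[[as.character(sel$k)]]
  } else {
    sel <- list(k = max(kRange), diagnostics = NULL, votes = NULL)
    chosen <- sols[[as.character(max(kRange))]]
  }
  attr(chosen, "selection") <- sel
  attr(chosen, "peaks") <- pk
  chosen
}

#' Group-level clustering of pooled subject maps
#'
#' Pools the retained subject-level maps of all participants into one
#' polarity-invariant clustering (a single analysis across groups, since
#' separate subgroup maps inflate false-positive rates), selects k by the
#' same meta-criterion, and canonically orders the resulting maps.
#'
#' @param subjectMapSets list of \linkS4class{MicrostateMapSet}, one per
#'   subject, all over the same channels.
#' @param montage the shared \linkS4class{SensorMontage}, used for canonical
#'   A-D ordering (optional; unordered when NULL).
#' @param kRange candidate cluster numbers (default 1:15).
#' @param nRestarts restarts per k (default 200).
#' @param minAssignCorr assignment threshold (default 0.5).
#' @param seed RNG seed (optional).
#' @param ... passed to \code{\link{modifiedKMeans}}.
#' @return A group-level \linkS4class{MicrostateMapSet} with selection
#'   diagnostics in attribute \code{"selection"}.
#' @export
groupClustering <- function(subjectMapSets, montage = NULL, kRange = 1:15,
                            nRestarts = 200, minAssignCorr = 0.5,
                            seed = NULL, ...) {
  if (length(subjectMapSets) < 2)
    stop("group clustering needs at least 2 subjects")
  ncols <- vapply(subjectMapSets, function(m) ncol(maps(m)), 1L)
  if (length(unique(ncols)) != 1)
    stop("subjects have differing channel counts: ",
         paste(unique(ncols), collapse = " vs "))
  X <- t(do.call(rbind, lapply(subjectMapSets, maps)))   # channels x maps
  if (ncol(X) < max(kRange)) kRange <- kRange[kRange <= ncol(X)]
  sols <- list()
  for (k in kRange) {
    s <- if (is.null(seed)) NULL else seed + 1000L + k
    sols[[as.character(k)]] <- modifiedKMeans(X, k, nRestarts = nRestarts,
                                              minAssignCorr = minAssignCorr,
                                              gfpAtSamples = rep(1, ncol(X)),
                                              seed = s, ...)
  }
  if (length(kRange) >= 3) {
    sel <- selectOptimalK(sols, X, gfpAtSamples = rep(1, ncol(X)))
    chosen <- sols[[as.character(sel$k)]]
  } else {
    sel <- list(k = max(kRange), diagnostics = NULL, votes = NULL)
    chosen <- sols[[as.character(max(kRange))]]
  }
  ms <- MicrostateMapSet(maps(chosen$mapset), level = "group",
                         fitGev = chosen$gev)
  perMapGev <- vapply(seq_len(nStates(ms)), function(j)
    sum(chosen$corr[chosen$assignment == j]^2), 0)
  if (!is.null(montage)) ms <- canonicalizeMapOrder(ms, montage, perMapGev)
  attr(ms, "selection") <- sel
  ms
}

#' Canonical A-D ordering of group maps
#'
#' Orders maps by best polarity-invariant match to idealized canonical
#' templates built from the sensor positions: A (right-frontal to
#' left-posterior), B (left-frontal to right-posterior), C (frontal to
#' occipital), D (frontocentral extremum). Unmatched maps are appended in
#' decreasing explained-variance order with labels M5, M6, ...
#'
#' @param mapset a \linkS4class{MicrostateMapSet}.
#' @param montage the \linkS4class{SensorMontage} (x right, y anterior,
#'   z up).
#' @param perMapGev optional per-map explained-variance weights used to
#'   order unmatched maps.
#' @return The reordered, relabeled \linkS4class{MicrostateMapSet}.
#' @export
canonicalizeMapOrder <- function(mapset, montage, perMapGev = NULL) {
  pos <- montage@positions
  tpl <- rbind(A = pos[, 1] + pos[, 2],
               B = -pos[, 1] + pos[, 2],
               C = pos[, 2],
               D = pos[, 3])
  M <- maps(mapset)
  if (is.null(perMapGev)) perMapGev <- rep(0, nrow(M))
  sim <- matrix(0, nrow(tpl), nrow(M))
  for (i in seq_len(nrow(tpl)))
    for (j in seq_len(nrow(M)))
      sim[i, j] <- spatialCorrelation(tpl[i, ], M[j, ])
  order <- integer(0); labels <- character(0)
  used <- rep(FALSE, nrow(M))
  for (step in seq_len(min(nrow(tpl), nrow(M)))) {
    simMasked <- sim
    simMasked[, used] <- -Inf
    simMasked[rownames(tpl) %in% labels, ] <- -Inf
    ij <- arrayInd(which.max(simMasked), dim(sim))
    order <- c(order, ij[2]); labels <- c(labels, rownames(tpl)[ij[1]])
    used[ij[2]] <- TRUE
  }
  rest <- which(!used)
  if (length(rest)) {
    rest <- rest[order(perMapGev[rest], decreasing = TRUE)]
    order <- c(order, rest)
    labels <- c(labels, paste0("M", seq(5, length.out = length(rest))))
  }
  ## sort matched maps into A, B, C, D display order
  matched <- seq_along(labels) <= sum(labels %in% rownames(tpl))
  mOrd <- order(labels[matched])
  order <- c(order[matched][mOrd], order[!matched])
  labels <- c(labels[matched][mOrd], labels[!matched])
  MicrostateMapSet(M[order, , drop = FALSE], level = mapset@level,
                   labels = labels, fitGev = fitGev(mapset))
}
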