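## Winner-takes-all backfitting of group maps onto every frame of a
## recording, windowed-vote temporal smoothing, and rejection of short
## segments by the split-in-half absorption rule.

#' Winner-takes-all frame labeling
#'
#' Each frame of the (average-referenced) recording is labeled with the map
#' of highest absolute spatial correlation; frames whose best |correlation|
#' falls below \code{minCorr} are left unassigned (label 0). Polarity is
#' ignored.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param groupMaps a \linkS4class{MicrostateMapSet}.
#' @param minCorr assignment threshold (default 0.5).
#' @return A \linkS4class{MicrostateSegmentation} carrying per-frame winning
#'   correlations and GFP, plus the full K x frames correlation matrix in
#'   attribute \code{"corrMatrix"} (needed by the smoother).
#' @export
labelFrames <- function(recording, groupMaps, minCorr = 0.5) {
  M <- maps(groupMaps)
  d <- potentials(recording)
  if (ncol(M) != nrow(d))
    stop(sprintf("map channel count (%d) does not match recording (%d)",
                 ncol(M), nrow(d)))
  d <- sweep(d, 2, colMeans(d))
  g <- sqrt(colMeans(d^2))
  Xn <- .normCols(d)
  Mn <- .normCols(t(M))
  A <- abs(crossprod(Mn, Xn))                  # K x T
  lab <- max.col(t(A), ties.method = "first")
  amax <- A[cbind(lab, seq_len(ncol(A)))]
  lab[amax < minCorr | g == 0] <- 0L
  seg <- MicrostateSegmentation(lab, nrow(M), samplingRate(recording),
                                corr = ifelse(lab > 0L, amax, NA_real_),
                                gfp = g)
  attr(seg, "corrMatrix") <- A
  seg
}

#' Temporal smoothing of frame labels by windowed-vote rescoring
#'
#' For every assigned frame, each state s receives the evidence score
#' (GFP_t * r_s(t))^2 plus \code{smoothnessWeight} times the number of
#' frames labeled s inside the sliding window of \code{2 * halfWidth + 1}
#' frames centered on t; the frame is relabeled to the top-scoring state
#' whose |correlation| clears \code{minCorr}. Sweeps run left to right and
#' repeat until no label changes (cap 50 sweeps). Unassigned frames never
#' gain a label.
#'
#' @param segmentation a \linkS4class{MicrostateSegmentation} from
#'   \code{\link{labelFrames}}.
#' @param corrMatrix K x frames matrix of |spatial correlations|; taken from
#'   the segmentation's \code{"corrMatrix"} attribute when NULL.
#' @param halfWidth window half-width in frames (default 5, window size 11).
#' @param smoothnessWeight weight of the window vote (default 15; 0 leaves
#'   labels unchanged).
#' @param minCorr assignment threshold (default 0.5).
#' @return The smoothed \linkS4class{MicrostateSegmentation}.
#' @export
smoothLabels <- function(segmentation, corrMatrix = NULL, halfWidth = 5,
                         smoothnessWeight = 15, minCorr = 0.5) {
  if (is.null(corrMatrix)) corrMatrix <- attr(segmentation, "corrMatrix")
  if (is.null(corrMatrix))
    stop("per-frame correlation matrix required for smoothing")
  lab <- frameLabels(segmentation)
  K <- nStates(segmentation)
  n <- length(lab)
  if (smoothnessWeight == 0 || n == 0) return(segmentation)
  g <- segmentation@gfp
  if (!length(g)) g <- rep(1, n)
  evidence <- (matrix(g, K, n, byrow = TRUE) * corrMatrix)^2
  eligible <- corrMatrix >= minCorr
  assigned <- which(lab > 0L)
  for (sweep in seq_len(50)) {
    changed <- FALSE
    counts <- matrix(0L, K, n)
    for (s in seq_len(K)) {
      ind <- as.integer(lab == s)
      cs <- cumsum(ind)
      lo <- pmax(seq_len(n) - halfWidth, 1L)
      hi <- pmin(seq_len(n) + halfWidth, n)
      counts[s, ] <- cs[hi] - cs[lo] + ind[lo]
    }
    for (t in assigned) {
      score <- evidence[, t] + smoothnessWeight * counts[, t]
      score[!eligible[, t]] <- -Inf
      newLab <- which.max(score)
      if (is.finite(score[newLab]) && newLab != lab[t]) {
        counts[lab[t], max(1, t - halfWidth):min(n, t + halfWidth)] <-
          counts[lab[t], max(1, t - halfWidth):min(n, t + halfWidth)] - 1L
        counts[newLab, max(1, t - halfWidth):min(n, t + halfWidth)] <-
          counts[newLab, max(1, t - halfWidth):min(n, t + halfWidth)] + 1L
        lab[t] <- newLab
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- MicrostateSegmentation(lab, K, samplingRate(segmentation),
                                corr = ifelse(lab > 0L,
                                              corrMatrix[cbind(pmax(lab, 1L),
                                                               seq_len(n))],
                                              NA_real_),
                                gfp = segmentation@gfp)
  attr(out, "corrMatrix") <- corrMatrix
  out
}

#' Rejection of short segments by split-in-half absorption
#'
#' Segments of length at most \code{minSegmentFrames} are rejected and split
#' in half: the first floor(n/2) frames join the preceding segment, the
#' remaining ceil(n/2) frames join the following one. A short segment at a
#' sequence boundary (or flanked by an unassigned gap on one side) is
#' absorbed entirely by its single neighbor; with no labeled neighbor at all
#' it becomes unassigned. Because absorption can merge two runs of the same
#' state into a longer one, the rule is re-applied until a fixed point is
#' reached.
#'
#' @param segmentation a \linkS4class{MicrostateSegmentation}.
#' @param minSegmentFrames segments with length <= this are rejected
#'   (default 5).
#' @return The cleaned \linkS4class{MicrostateSegmentation}; the number of
#'   passes is stored in attribute \code{"passes"}.
#' @export
rejectSmallSegments <- function(segmentation, minSegmentFrames = 5) {
  lab <- frameLabels(segmentation)
  n <- length(lab)
  passes <- 0L
  ## every absorption strictly reduces the number of labeled runs, so the
  ## initial run count bounds the pass count
  maxPasses <- length(rle(lab)$values) + 1L
  repeat {
    passes <- passes + 1L
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    short <- which(r$values != 0L & r$lengths <= minSegmentFrames)
    if (!length(short) || passes > maxPasses) break
    ## process the shortest run first; one change per pass keeps the
    ## absorption deterministic and order-independent
    i <- short[which.min(r$lengths[short])]
    prevLab <- if (i > 1 && r$values[i - 1] != 0L) r$values[i - 1] else NA
    nextLab <- if (i < length(r$values) && r$values[i + 1] != 0L)
      r$values[i + 1] else NA
    len <- r$lengths[i]
    idx <- starts[i]:ends[i]
    if (!is.na(prevLab) && !is.na(nextLab)) {
      firstHalf <- idx[seq_len(len %/% 2)]
      secondHalf <- setdiff(idx, firstHalf)
      lab[firstHalf] <- prevLab
      lab[secondHalf] <- nextLab
    } else if (!is.na(prevLab)) {
      lab[idx] <- prevLab
    } else if (!is.na(nextLab)) {
      lab[idx] <- nextLab
    } else {
      lab[idx] <- 0L
    }
  }
  corr <- frameCorr(segmentation)
  if (length(corr)) corr[lab == 0L] <- NA_real_
  cm <- attr(segmentation, "corrMatrix")
  if (!is.null(cm) && length(corr)) {
    ok <- lab > 0L
    corr[ok] <- cm[cbind(lab[ok], which(ok))]
  }
  out <- MicrostateSegmentation(lab, nStates(segmentation),
                                samplingRate(segmentation), corr = corr,
                                gfp = segmentation@gfp)
  attr(out, "corrMatrix") <- cm
  attr(out, "passes") <- passes
  out
}

#' Full backfitting stage for one subject
#'
#' Labels every frame with the group maps (winner-takes-all), smooths the
#' labels temporally, and rejects short segments — in that order. Per-frame
#' winning correlations are retained for the source-imaging correlation
#' gate.
#'
#' @param recording a preprocessed \linkS4class{EEGRecording}.
#' @param groupMaps the group-level \linkS4class{MicrostateMapSet}.
#' @param minCorr assignment threshold (default 0.5).
#' @param halfWidth smoothing window half-width in frames (default 5).
#' @param smoothnessWeight window-vote weight (default 15).
#' @param minSegmentFrames short-segment threshold (default 5).
#' @return A \linkS4class{MicrostateSegmentation}.
#' @export
backfitSubject <- function(recording, groupMaps, minCorr = 0.5,
                           halfWidth = 5, smoothnessWeight = 15,
                           minSegmentFrames = 5) {
  seg <- labelFrames(recording, groupMaps, minCorr = minCorr)
  seg <- smoothLabels(seg, halfWidth = halfWidth,
                      smoothnessWeight = smoothnessWeight, minCorr = minCorr)
  rejectSmallSegments(seg, minSegmentFrames = minSegmentFrames)
}
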