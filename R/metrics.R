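## Per-subject, per-state temporal parameters: mean duration, occurrence
## rate, time coverage, and global explained variance. "Labeled time" is the
## total of frames carrying any state label; unassigned frames enter only
## the GEV denominator (whose weight is total GFP^2 over all frames).

#' Mean segment duration of one state
#'
#' Mean length of that state's segments, in milliseconds. Returns NA when
#' the state never occurs (missing, not zero, to avoid biasing group means).
#'
#' @param segmentation a \linkS4class{MicrostateSegmentation}.
#' @param state state index.
#' @return Duration in ms, or NA.
#' @export
stateDuration <- function(segmentation, state) {
  runs <- segmentTable(segmentation)
  lens <- runs$length[runs$state == state]
  if (!length(lens)) return(NA_real_)
  mean(lens) * 1000 / samplingRate(segmentation)
}

#' Occurrence rate of one state
#'
#' Number of that state's segments divided by the total labeled duration in
#' seconds (labeled frames of all states).
#'
#' @inheritParams stateDuration
#' @return Occurrences per second (0 for an absent state).
#' @export
stateOccurrence <- function(segmentation, state) {
  lab <- frameLabels(segmentation)
  labeled <- sum(lab > 0L)
  if (labeled == 0) stop("no labeled frames: occurrence is undefined")
  runs <- segmentTable(segmentation)
  sum(runs$state == state) / (labeled / samplingRate(segmentation))
}

#' Time coverage of one state
#'
#' Percentage of the labeled time carried by that state.
#'
#' @inheritParams stateDuration
#' @return Coverage in percent (0 for an absent state).
#' @export
stateCoverage <- function(segmentation, state) {
  lab <- frameLabels(segmentation)
  labeled <- sum(lab > 0L)
  if (labeled == 0) stop("no labeled frames: coverage is undefined")
  100 * sum(lab == state) / labeled
}

#' Global explained variance of one state, in percent
#'
#' 100 times the sum over frames labeled with the state of
#' (GFP_t * r_t)^2, divided by the sum of GFP_t^2 over all frames (assigned
#' or not).
#'
#' @param recording the backfitted \linkS4class{EEGRecording} (used for GFP
#'   when the segmentation does not carry it).
#' @param segmentation a \linkS4class{MicrostateSegmentation} with per-frame
#'   winning correlations.
#' @param state state index.
#' @return GEV in percent.
#' @export
stateGev <- function(segmentation, state, recording = NULL) {
  g <- segmentation@gfp
  if (!length(g)) {
    if (is.null(recording)) return(NA_real_)   # no signal: GEV undefined
    g <- gfp(recording)
  }
  tot <- sum(g^2)
  if (tot == 0) stop("all-zero GFP")
  lab <- frameLabels(segmentation)
  corr <- frameCorr(segmentation)
  idx <- which(lab == state)
  if (!length(idx)) return(0)
  100 * sum((g[idx] * corr[idx])^2) / tot
}

#' Per-subject, per-state metrics table
#'
#' Tidy table with one row per (subject, state): GEV (%), mean duration
#' (ms), coverage (% of labeled time) and occurrence (segments per labeled
#' second). Absent states get NA duration and zero occurrence/coverage/GEV.
#'
#' @param segmentations named list of \linkS4class{MicrostateSegmentation},
#'   one per subject.
#' @param groups character/factor of group membership, one per subject
#'   (optional, NA when absent).
#' @param stateLabels display names of the states (defaults to the state
#'   indices).
#' @return data.frame with columns subject_id, group, state, gev_pct,
#'   duration_ms, coverage_pct, occurrence_per_s.
#' @export
metricsTable <- function(segmentations, groups = NULL, stateLabels = NULL) {
  cols <- c("subject_id", "group", "state", "gev_pct", "duration_ms",
            "coverage_pct", "occurrence_per_s")
  if (!length(segmentations)) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                  cols))
    return(out)
  }
  ids <- names(segmentations)
  if (is.null(ids)) ids <- paste0("S", seq_along(segmentations))
  if (is.null(groups)) groups <- rep(NA_character_, length(segmentations))
  rows <- list()
  for (i in seq_along(segmentations)) {
    seg <- segmentations[[i]]
    K <- nStates(seg)
    labs <- if (is.null(stateLabels)) as.character(seq_len(K)) else stateLabels
    for (s in seq_len(K)) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = ids[i], group = as.character(groups[i]), state = labs[s],
        gev_pct = stateGev(seg, s),
        duration_ms = stateDuration(seg, s),
        coverage_pct = stateCoverage(seg, s),
        occurrence_per_s = stateOccurrence(seg, s),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
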