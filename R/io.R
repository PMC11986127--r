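#' Read / write sensor montages
#'
#' Plain-text montage format: one line per channel, whitespace-delimited
#' \code{name x y z}. Positions are normalized to the unit sphere on read.
#'
#' @param path file path.
#' @return \code{readMontage} returns a \linkS4class{SensorMontage}.
#' @export
readMontage <- function(path) {
  if (!file.exists(path)) stop("montage file not found: ", path)
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("name", "x", "y", "z"))
  SensorMontage(tab$name, as.matrix(tab[, c("x", "y", "z")]))
}

#' @rdname readMontage
#' @param montage a \linkS4class{SensorMontage} to write.
#' @export
writeMontage <- function(montage, path) {
  tab <- data.frame(name = channelNames(montage), montage@positions)
  write.table(format(tab, digits = 17), path, quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a recording from EDF or delimited matrix
#'
#' The matrix format is a TSV of channels x samples with channel names in the
#' first column and the sampling rate given explicitly; the montage sidecar
#' supplies channel positions and the canonical channel order, to which the
#' data rows are reordered once at load. EDF files must carry potentials in
#' microvolts or millivolts (converted); other physical dimensions are
#' rejected.
#'
#' @param path recording file.
#' @param format "edf" or "matrix".
#' @param montagePath montage sidecar file (see \code{\link{readMontage}}).
#' @param samplingRate required for \code{format = "matrix"}.
#' @return An \linkS4class{EEGRecording}.
#' @export
readRecording <- function(path, format = c("matrix", "edf"), montagePath,
                          samplingRate = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("recording file not found: ", path)
  mont <- readMontage(montagePath)
  if (format == "matrix") {
    if (is.null(samplingRate))
      stop("samplingRate is required for matrix-format recordings")
    tab <- read.table(path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE)
    data <- as.matrix(tab[, -1, drop = FALSE])
    dimnames(data) <- list(tab[[1]], NULL)
    storage.mode(data) <- "double"
    EEGRecording(data, samplingRate, mont, history = "read:matrix")
  } else {
    edf <- readEDF(path)
    EEGRecording(edf$data, edf$samplingRate, mont, history = "read:edf")
  }
}

#' @rdname readRecording
#' @param recording an \linkS4class{EEGRecording}.
#' @export
writeRecording <- function(recording, path, format = c("matrix", "edf")) {
  format <- match.arg(format)
  if (format == "matrix") {
    d <- potentials(recording)
    tab <- data.frame(channel = rownames(d),
                      format(d, digits = 17, trim = TRUE, scientific = TRUE))
    write.table(tab, path, quote = FALSE, sep = "\t",
                row.names = FALSE, col.names = FALSE)
  } else {
    writeEDF(potentials(recording), samplingRate(recording), path)
  }
  invisible(path)
}

#' Read / write microstate map sets
#'
#' TSV with a comment header carrying level, labels and fit GEV, then one row
#' per map: label followed by one value per channel.
#'
#' @param path file path.
#' @return \code{readMapSet} returns a \linkS4class{MicrostateMapSet}.
#' @export
readMapSet <- function(path) {
  if (!file.exists(path)) stop("map set file not found: ", path)
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  level <- sub("^#level\\s+", "", grep("^#level", meta, value = TRUE))
  gevLine <- grep("^#fit_gev", meta, value = TRUE)
  fitGev <- if (length(gevLine)) as.numeric(sub("^#fit_gev\\s+", "", gevLine))
            else NA_real_
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (!length(body)) stop("map set file contains no maps")
  parts <- strsplit(body, "\t", fixed = TRUE)
  labels <- vapply(parts, `[[`, "", 1L)
  vals <- lapply(parts, function(p) as.numeric(p[-1]))
  if (length(unique(lengths(vals))) != 1)
    stop("inconsistent channel counts across maps")
  MicrostateMapSet(do.call(rbind, vals), level = level, labels = labels,
                   fitGev = fitGev)
}

#' @rdname readMapSet
#' @param mapset a \linkS4class{MicrostateMapSet}.
#' @export
writeMapSet <- function(mapset, path) {
  if (nrow(maps(mapset)) < 1) stop("refusing to write an empty map set")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("#level", mapset@level),
               paste("#fit_gev", format(mapset@fitGev, digits = 17))), con)
  m <- maps(mapset)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(stateLabels(mapset)[i],
                       format(m[i, ], digits = 17, trim = TRUE)),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read / write segmentations
#'
#' TSV of \code{frame}, \code{label} (0 = unassigned), \code{corr}, with a
#' comment header recording the sampling rate and number of states.
#'
#' @param path file path.
#' @return \code{readSegmentation} returns a
#'   \linkS4class{MicrostateSegmentation}.
#' @export
readSegmentation <- function(path) {
  lines <- readLines(path, n = 5)
  sr <- as.numeric(sub("^#sampling_rate\\s+", "",
                       grep("^#sampling_rate", lines, value = TRUE)))
  k <- as.integer(sub("^#n_states\\s+", "",
                      grep("^#n_states", lines, value = TRUE)))
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    strip.white = TRUE)
  MicrostateSegmentation(tab$label, k, sr, corr = tab$corr)
}

#' @rdname readSegmentation
#' @param segmentation a \linkS4class{MicrostateSegmentation}.
#' @export
writeSegmentation <- function(segmentation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("#sampling_rate",
                     format(samplingRate(segmentation), digits = 17)),
               paste("#n_states", nStates(segmentation))), con)
  corr <- frameCorr(segmentation)
  if (!length(corr)) corr <- rep(NA_real_, length(frameLabels(segmentation)))
  tab <- data.frame(frame = seq_along(frameLabels(segmentation)),
                    label = frameLabels(segmentation),
                    corr = format(corr, digits = 17, trim = TRUE))
  suppressWarnings(write.table(tab, con, quote = FALSE, sep = "\t",
                               row.names = FALSE))
  invisible(path)
}

#' Write / read per-subject, per-state metric tables
#'
#' Delimited text with header; one row per (subject, state). Columns:
#' subject_id, group, state, gev_pct, duration_ms, coverage_pct,
#' occurrence_per_s.
#'
#' @param table a metrics data.frame (see \code{\link{metricsTable}}).
#' @param path file path.
#' @export
writeMetrics <- function(table, path) {
  cols <- c("subject_id", "group", "state", "gev_pct", "duration_ms",
            "coverage_pct", "occurrence_per_s")
  missing <- setdiff(cols, names(table))
  if (length(missing))
    stop("metrics table lacks columns: ", paste(missing, collapse = ", "))
  write.table(table[, cols, drop = FALSE], path, quote = FALSE, sep = "\t",
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeMetrics
#' @export
readMetrics <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
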