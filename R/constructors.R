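#' Create a sensor montage
#'
#' @param channelNames unique channel names.
#' @param positions channels x 3 matrix of head-centered coordinates; rows
#'   are normalized to the unit sphere.
#' @return A \linkS4class{SensorMontage}.
#' @export
SensorMontage <- function(channelNames, positions) {
  positions <- as.matrix(positions)
  r <- sqrt(rowSums(positions^2))
  if (any(r == 0)) stop("montage positions must be nonzero")
  positions <- positions / r
  dimnames(positions) <- list(channelNames, c("x", "y", "z"))
  new("SensorMontage", channelNames = as.character(channelNames),
      positions = positions)
}

#' Create an EEG recording
#'
#' @param data channels x samples numeric matrix (microvolts). Rows are
#'   reordered to the montage channel order using row names when present.
#' @param samplingRate Hz.
#' @param montage a \linkS4class{SensorMontage}.
#' @param badChannels character vector of channel names flagged bad.
#' @param history character vector of processing-step descriptions.
#' @return An \linkS4class{EEGRecording}.
#' @export
EEGRecording <- function(data, samplingRate, montage,
                         badChannels = character(), history = character()) {
  data <- as.matrix(data)
  nm <- channelNames(montage)
  if (!is.null(rownames(data))) {
    missing <- setdiff(nm, rownames(data))
    extra <- setdiff(rownames(data), nm)
    if (length(missing) || length(extra))
      stop("channel mismatch between data and montage: ",
           if (length(missing)) paste0("missing [",
             paste(missing, collapse = ", "), "] ") else "",
           if (length(extra)) paste0("extra [",
             paste(extra, collapse = ", "), "]") else "")
    data <- data[nm, , drop = FALSE]
  } else if (nrow(data) != length(nm)) {
    stop(sprintf("data has %d rows but montage lists %d channels",
                 nrow(data), length(nm)))
  } else rownames(data) <- nm
  new("EEGRecording", data = data, samplingRate = as.numeric(samplingRate),
      montage = montage, badChannels = as.character(badChannels),
      history = as.character(history))
}

#' Create a microstate map set
#'
#' Maps are average-referenced and unit-normalized on construction.
#'
#' @param maps K x channels matrix of topographies.
#' @param level "subject" or "group".
#' @param labels display labels; defaults to M1..MK.
#' @param fitGev global explained variance at fit time (fraction), NA if
#'   unknown.
#' @return A \linkS4class{MicrostateMapSet}.
#' @export
MicrostateMapSet <- function(maps, level = "subject", labels = NULL,
                             fitGev = NA_real_) {
  maps <- as.matrix(maps)
  if (nrow(maps) < 1) stop("map set must contain at least one map")
  maps <- maps - rowMeans(maps)
  nrm <- sqrt(rowSums(maps^2))
  if (any(nrm == 0)) stop("maps must be nonzero after average referencing")
  maps <- maps / nrm
  if (is.null(labels)) labels <- paste0("M", seq_len(nrow(maps)))
  rownames(maps) <- labels
  new("MicrostateMapSet", maps = maps, level = level,
      labels = as.character(labels), fitGev = as.numeric(fitGev))
}

#' Create a per-frame microstate segmentation
#'
#' @param labels integer per-frame state index; 0 marks unassigned frames.
#' @param nStates number of states K.
#' @param samplingRate Hz.
#' @param corr per-frame winning |spatial correlation| (optional).
#' @param gfp per-frame global field power (optional).
#' @return A \linkS4class{MicrostateSegmentation}.
#' @export
MicrostateSegmentation <- function(labels, nStates, samplingRate,
                                   corr = numeric(), gfp = numeric()) {
  new("MicrostateSegmentation", labels = as.integer(labels),
      nStates = as.integer(nStates), samplingRate = as.numeric(samplingRate),
      corr = as.numeric(corr), gfp = as.numeric(gfp))
}

## Maximal runs of identical non-zero labels; unassigned (0) frames break runs.
labelRuns <- function(labels) {
  r <- rle(as.integer(labels))
  start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  keep <- r$values != 0L
  data.frame(state = r$values[keep], start = start[keep],
             length = r$lengths[keep])
}

## Rebuild a label vector from a run table (gaps become unassigned).
runsToLabels <- function(runs, nFrames) {
  labels <- integer(nFrames)
  for (i in seq_len(nrow(runs)))
    labels[seq(runs$start[i], length.out = runs$length[i])] <- runs$state[i]
  labels
}

#' Quasi-uniform spherical EEG montage
#'
#' Places sensors on the upper portion of the unit sphere along a golden-angle
#' (Fibonacci) spiral, mimicking the coverage of an EEG sensor net (scalp cap
#' down to roughly 30 degrees below the equator, sparing neck and face).
#'
#' @param nChannels number of sensors.
#' @param minZ lowest sensor height on the unit sphere (default -0.45).
#' @return A \linkS4class{SensorMontage} with channels E1..En.
#' @export
makeSphericalMontage <- function(nChannels, minZ = -0.45) {
  stopifnot(nChannels >= 4)
  i <- seq_len(nChannels)
  z <- 1 - (i - 0.5) / nChannels * (1 - minZ)
  phi <- (1 + sqrt(5)) / 2
  theta <- 2 * pi * i / phi^2
  rho <- sqrt(pmax(0, 1 - z^2))
  SensorMontage(paste0("E", i), cbind(rho * cos(theta), rho * sin(theta), z))
}
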