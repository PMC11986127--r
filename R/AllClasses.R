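#' @import methods
#' @importFrom stats rnorm runif rgamma rbinom sd var cor aov anova lm pf pt
#'   p.adjust cor.test t.test qt approx fft median quantile complete.cases
#'   dist setNames
#' @importFrom utils head tail read.table write.table modifyList
NULL

.TOL_UNIT <- 1e-6

#' Sensor montage: channel names with 3D head-centered positions
#'
#' A montage pairs EEG channel names with positions on the unit sphere
#' (head-centered coordinates). Positions drive spherical-spline
#' interpolation, spatially smoothed noise generation, template-map synthesis
#' and the spherical forward model.
#'
#' @slot channelNames character vector of unique channel names.
#' @slot positions numeric matrix, one row per channel, columns x, y, z;
#'   each row has unit norm.
#' @export
setClass("SensorMontage",
  representation(channelNames = "character", positions = "matrix"))

setValidity("SensorMontage", function(object) {
  msg <- character()
  n <- length(object@channelNames)
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channel names must be unique")
  if (!is.numeric(object@positions) || ncol(object@positions) != 3)
    msg <- c(msg, "positions must be a numeric matrix with 3 columns")
  else {
    if (nrow(object@positions) != n)
      msg <- c(msg, sprintf("positions has %d rows but there are %d channels",
                            nrow(object@positions), n))
    r <- sqrt(rowSums(object@positions^2))
    if (any(abs(r - 1) > 1e-6))
      msg <- c(msg, "positions must lie on the unit sphere")
  }
  if (length(msg)) msg else TRUE
})

#' Multichannel EEG recording
#'
#' Channels x samples potentials in microvolts, with sampling rate, montage
#' and bookkeeping of bad channels and processing history. Row order of
#' \code{data} always follows the montage channel order.
#'
#' @slot data numeric matrix (channels x samples), microvolts.
#' @slot samplingRate sampling rate in Hz.
#' @slot montage a \linkS4class{SensorMontage}.
#' @slot badChannels character, subset of the channel names.
#' @slot history character, one entry per processing step applied.
#' @export
setClass("EEGRecording",
  representation(data = "matrix", samplingRate = "numeric",
                 montage = "SensorMontage", badChannels = "character",
                 history = "character"))

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@samplingRate) != 1 || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  nm <- object@montage@channelNames
  if (nrow(object@data) != length(nm))
    msg <- c(msg, sprintf("data has %d rows but montage lists %d channels",
                          nrow(object@data), length(nm)))
  if (!all(object@badChannels %in% nm))
    msg <- c(msg, "badChannels must be a subset of the montage channels")
  if (length(msg)) msg else TRUE
})

#' Set of microstate topographies
#'
#' K topographies over the montage channels. Each map is average-referenced
#' (zero channel mean) and unit-norm; polarity is arbitrary by convention.
#'
#' @slot maps numeric matrix, K rows (states) x channels.
#' @slot level "subject" or "group" provenance.
#' @slot labels display names, e.g. A, B, C, D.
#' @slot fitGev global explained variance achieved at fit time (fraction in
#'   [0,1]), NA when unknown.
#' @export
setClass("MicrostateMapSet",
  representation(maps = "matrix", level = "character", labels = "character",
                 fitGev = "numeric"))

setValidity("MicrostateMapSet", function(object) {
  msg <- character()
  k <- nrow(object@maps)
  if (k < 1) msg <- c(msg, "map set must contain at least one map")
  if (length(object@labels) != k)
    msg <- c(msg, "one label per map required")
  if (!object@level %in% c("subject", "group"))
    msg <- c(msg, "level must be 'subject' or 'group'")
  if (k >= 1 && ncol(object@maps) >= 1) {
    cm <- rowMeans(object@maps)
    nrm <- sqrt(rowSums(object@maps^2))
    if (any(abs(cm) > 1e-6 * pmax(nrm, 1)))
      msg <- c(msg, "maps must be average-referenced (zero channel mean)")
    if (any(abs(nrm - 1) > 1e-6))
      msg <- c(msg, "maps must be unit-norm")
  }
  if (!is.na(object@fitGev) &&
      (object@fitGev < 0 || object@fitGev > 1))
    msg <- c(msg, "fitGev must be in [0,1] or NA")
  if (length(msg)) msg else TRUE
})

#' Per-frame microstate labeling of a recording
#'
#' Integer state index per frame, with 0 as the unassigned sentinel, plus the
#' winning spatial correlation per frame (NA where unassigned) and the GFP
#' series used for evidence weighting.
#'
#' @slot labels integer vector, 0 = unassigned, 1..K = state index.
#' @slot nStates number of states K.
#' @slot samplingRate Hz.
#' @slot corr numeric, per-frame winning |spatial correlation| (NA where
#'   unassigned).
#' @slot gfp numeric, per-frame global field power (may be length 0 when not
#'   retained).
#' @export
setClass("MicrostateSegmentation",
  representation(labels = "integer", nStates = "integer",
                 samplingRate = "numeric", corr = "numeric", gfp = "numeric"))

setValidity("MicrostateSegmentation", function(object) {
  msg <- character()
  if (length(object@samplingRate) != 1 || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (any(object@labels < 0L) || any(object@labels > object@nStates))
    msg <- c(msg, "labels must lie in 0..nStates")
  if (length(object@corr) && length(object@corr) != length(object@labels))
    msg <- c(msg, "corr must have one entry per frame")
  if (length(object@gfp) && length(object@gfp) != length(object@labels))
    msg <- c(msg, "gfp must have one entry per frame")
  if (length(msg)) msg else TRUE
})

#' Lead field of a forward head model
#'
#' Linear operator mapping source currents (3 orientations per solution
#' point) to sensor potentials.
#'
#' @slot gain numeric matrix, sensors x (3 * points); columns ordered
#'   (x, y, z) per point.
#' @slot pointCoords numeric matrix, points x 3 solution-point coordinates.
#' @slot modelDesc provenance string.
#' @export
setClass("LeadField",
  representation(gain = "matrix", pointCoords = "matrix",
                 modelDesc = "character"))

setValidity("LeadField", function(object) {
  msg <- character()
  p <- nrow(object@pointCoords)
  if (p < 1) msg <- c(msg, "at least one solution point required")
  if (ncol(object@gain) != 3 * p)
    msg <- c(msg, "gain must have 3 columns per solution point")
  if (!all(is.finite(object@gain)))
    msg <- c(msg, "gain entries must be finite")
  if (length(msg)) msg else TRUE
})

#' Distributed source estimate
#'
#' @slot currentDensity numeric matrix, points x frames; orientation-norm
#'   current density (or its per-point standardization).
#' @slot standardized logical flag: has each point been z-scored across time.
#' @export
setClass("SourceEstimate",
  representation(currentDensity = "matrix", standardized = "logical"))
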