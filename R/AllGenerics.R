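#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("montage", function(x) standardGeneric("montage"))
#' @rdname accessors
#' @export
setGeneric("potentials", function(x) standardGeneric("potentials"))
#' @rdname accessors
#' @export
setGeneric("badChannels", function(x) standardGeneric("badChannels"))
#' @rdname accessors
#' @export
setGeneric("processingHistory", function(x) standardGeneric("processingHistory"))
#' @rdname accessors
#' @export
setGeneric("maps", function(x) standardGeneric("maps"))
#' @rdname accessors
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))
#' @rdname accessors
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))
#' @rdname accessors
#' @export
setGeneric("fitGev", function(x) standardGeneric("fitGev"))
#' @rdname accessors
#' @export
setGeneric("frameLabels", function(x) standardGeneric("frameLabels"))
#' @rdname accessors
#' @export
setGeneric("frameCorr", function(x) standardGeneric("frameCorr"))
#' @rdname accessors
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))
#' @rdname accessors
#' @export
setGeneric("gain", function(x) standardGeneric("gain"))
#' @rdname accessors
#' @export
setGeneric("pointCoords", function(x) standardGeneric("pointCoords"))

#' Accessors for the microstate data classes
#'
#' Read-only accessors for \linkS4class{EEGRecording},
#' \linkS4class{SensorMontage}, \linkS4class{MicrostateMapSet},
#' \linkS4class{MicrostateSegmentation} and \linkS4class{LeadField}.
#'
#' @param x an object of one of the classes above.
#' @return The slot content; \code{segmentTable} returns a data.frame with
#'   columns \code{state}, \code{start}, \code{length} — the maximal runs of
#'   identically-labeled frames (unassigned runs excluded).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@samplingRate)
#' @rdname accessors
#' @export
setMethod("samplingRate", "MicrostateSegmentation", function(x) x@samplingRate)
#' @rdname accessors
#' @export
setMethod("channelNames", "SensorMontage", function(x) x@channelNames)
#' @rdname accessors
#' @export
setMethod("channelNames", "EEGRecording", function(x) x@montage@channelNames)
#' @rdname accessors
#' @export
setMethod("montage", "EEGRecording", function(x) x@montage)
#' @rdname accessors
#' @export
setMethod("potentials", "EEGRecording", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("badChannels", "EEGRecording", function(x) x@badChannels)
#' @rdname accessors
#' @export
setMethod("processingHistory", "EEGRecording", function(x) x@history)
#' @rdname accessors
#' @export
setMethod("maps", "MicrostateMapSet", function(x) x@maps)
#' @rdname accessors
#' @export
setMethod("stateLabels", "MicrostateMapSet", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("nStates", "MicrostateMapSet", function(x) nrow(x@maps))
#' @rdname accessors
#' @export
setMethod("nStates", "MicrostateSegmentation", function(x) as.integer(x@nStates))
#' @rdname accessors
#' @export
setMethod("fitGev", "MicrostateMapSet", function(x) x@fitGev)
#' @rdname accessors
#' @export
setMethod("frameLabels", "MicrostateSegmentation", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("frameCorr", "MicrostateSegmentation", function(x) x@corr)
#' @rdname accessors
#' @export
setMethod("segmentTable", "MicrostateSegmentation", function(x)
  labelRuns(x@labels))
#' @rdname accessors
#' @export
setMethod("gain", "LeadField", function(x) x@gain)
#' @rdname accessors
#' @export
setMethod("pointCoords", "LeadField", function(x) x@pointCoords)

setMethod("show", "SensorMontage", function(object) {
  cat(sprintf("SensorMontage with %d channels (unit sphere)\n",
              length(object@channelNames)))
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@samplingRate,
              ncol(object@data) / object@samplingRate))
  if (length(object@badChannels))
    cat("  bad channels:", paste(object@badChannels, collapse = ", "), "\n")
  if (length(object@history))
    cat("  history:", paste(object@history, collapse = " -> "), "\n")
})

setMethod("show", "MicrostateMapSet", function(object) {
  cat(sprintf("MicrostateMapSet (%s level): %d maps x %d channels",
              object@level, nrow(object@maps), ncol(object@maps)))
  if (!is.na(object@fitGev)) cat(sprintf(", fit GEV %.1f%%", 100 * object@fitGev))
  cat("\n  labels:", paste(object@labels, collapse = ", "), "\n")
})

setMethod("show", "MicrostateSegmentation", function(object) {
  n <- length(object@labels)
  una <- sum(object@labels == 0L)
  cat(sprintf(paste0("MicrostateSegmentation: %d frames @ %g Hz, ",
                     "%d states, %.1f%% unassigned, %d segments\n"),
              n, object@samplingRate, object@nStates,
              if (n) 100 * una / n else 0, nrow(labelRuns(object@labels))))
})

setMethod("show", "LeadField", function(object) {
  cat(sprintf("LeadField: %d sensors x %d solution points (%s)\n",
              nrow(object@gain), nrow(object@pointCoords), object@modelDesc))
})
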