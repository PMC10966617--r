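#' Accessors for EEG containers
#'
#' Small accessor generics for the S4 containers: sampling rate, channel
#' labels and counts, duration, seizure markers, and the per-minute ADR
#' values of an [ADRSeries-class].
#'
#' @param object an [EEGRecording-class], [EpochSet-class] or
#'   [ADRSeries-class] object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("recordingDuration",
           function(object) standardGeneric("recordingDuration"))
#' @rdname accessors
#' @export
setGeneric("seizureMarkers",
           function(object) standardGeneric("seizureMarkers"))
#' @rdname accessors
#' @export
setGeneric("adrValues", function(object) standardGeneric("adrValues"))
#' @rdname accessors
#' @export
setGeneric("minuteIndex", function(object) standardGeneric("minuteIndex"))
#' @rdname accessors
#' @export
setGeneric("nEpochs", function(object) standardGeneric("nEpochs"))
#' @rdname accessors
#' @export
setGeneric("rejectedChannels",
           function(object) standardGeneric("rejectedChannels"))

#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(object) object@fs)
#' @rdname accessors
#' @export
setMethod("channelLabels", "EEGRecording",
          function(object) object@channelLabels)
#' @rdname accessors
#' @export
setMethod("channelLabels", "EpochSet", function(object) object@channelLabels)
#' @rdname accessors
#' @export
setMethod("nChannels", "EEGRecording", function(object) nrow(object@samples))
#' @rdname accessors
#' @export
setMethod("nSamples", "EEGRecording", function(object) ncol(object@samples))
#' @rdname accessors
#' @export
setMethod("recordingDuration", "EEGRecording",
          function(object) ncol(object@samples) / object@fs)
#' @rdname accessors
#' @export
setMethod("seizureMarkers", "EEGRecording", function(object) object@markers)
#' @rdname accessors
#' @export
setMethod("adrValues", "ADRSeries", function(object) object@adr)
#' @rdname accessors
#' @export
setMethod("minuteIndex", "ADRSeries", function(object) object@minute)
#' @rdname accessors
#' @export
setMethod("nEpochs", "EpochSet", function(object) length(object@starts))
#' @rdname accessors
#' @export
setMethod("rejectedChannels", "EpochSet",
          function(object) object@channelLabels[object@rejected])

#' @describeIn accessors sample matrix of a recording (channels x time, uV)
#' @export
eegSamples <- function(object) {
  stopifnot(is(object, "EEGRecording"))
  object@samples
}

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channel(s), %.1f s at %g Hz\n",
              nChannels(object), recordingDuration(object), object@fs))
  cat("  channels:", paste(object@channelLabels, collapse = " "), "\n")
  if (length(object@markers))
    cat("  markers:",
        paste(sprintf("%s=%.2fs", names(object@markers), object@markers),
              collapse = ", "), "\n")
})

setMethod("show", "EpochSet", function(object) {
  cat(sprintf("EpochSet: %d epoch(s) of %g s, %d channel(s), %d rejected\n",
              nEpochs(object), object@epochLength,
              length(object@channelLabels), sum(object@rejected)))
  cat(sprintf("  channel-epoch artifact flags: %d of %d\n",
              sum(object@artifact), length(object@artifact)))
})

setMethod("show", "ADRSeries", function(object) {
  ok <- !is.na(object@adr)
  cat(sprintf("ADRSeries: %d minute bin(s), %d missing\n",
              length(object@minute), sum(!ok)))
  if (any(ok))
    cat(sprintf("  range %.3f .. %.3f (first valid minute %d)\n",
                min(object@adr[ok]), max(object@adr[ok]),
                object@minute[which(ok)[1]]))
})

setMethod("show", "SigmoidFit", function(object) {
  cat("SigmoidFit:",
      if (object@converged) "converged" else "NOT converged", "\n")
  if (object@converged) {
    cat(sprintf("  A = %.3f, lambda = %.2f min, tau = %.2f min, U = %.3f\n",
                object@A, object@lam, object@tau, object@U))
    cat(sprintf("  R^2 = %.3f (%s), T_max = %.2f min%s\n",
                object@rSquared, if (object@qcPass) "QC pass" else "QC fail",
                object@tMax, if (object@boundary) " [boundary]" else ""))
  }
})

#' @describeIn accessors named parameter vector (A, lam, tau, U) of a fit
#' @param fit a [SigmoidFit-class] object.
#' @export
fitParams <- function(fit) {
  stopifnot(is(fit, "SigmoidFit"))
  c(A = fit@A, lam = fit@lam, tau = fit@tau, U = fit@U)
}
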