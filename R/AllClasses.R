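#' @import methods
NULL

#' Multichannel EEG recording
#'
#' Container for a peri-ictal EEG recording: a channels-by-time sample matrix
#' in microvolts, the sampling rate, 10-20 channel labels, and optional
#' seizure onset/offset markers in seconds relative to the recording origin.
#'
#' @slot samples numeric matrix, channels x time, in uV.
#' @slot fs sampling rate in Hz.
#' @slot channelLabels character vector of unique channel names.
#' @slot startTime start time of the first sample in seconds.
#' @slot markers named numeric vector; recognised names are
#'   \code{"onset"} and \code{"offset"} (seizure markers, in seconds).
#'
#' @seealso [EEGRecording()] for the constructor,
#'   [bandpassFilter()], [segmentEpochs()], [detectSuppression()].
#' @export
setClass("EEGRecording",
  representation(
    samples = "matrix",
    fs = "numeric",
    channelLabels = "character",
    startTime = "numeric",
    markers = "numeric"
  ),
  prototype(startTime = 0, markers = numeric(0))
)

setValidity("EEGRecording", function(object) {
  msg <- character(0)
  if (length(object@fs) != 1 || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (nrow(object@samples) != length(object@channelLabels))
    msg <- c(msg, "number of rows of 'samples' must match channelLabels")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channel labels must be unique")
  if (length(object@markers)) {
    if (is.null(names(object@markers)) ||
        !all(names(object@markers) %in% c("onset", "offset")))
      msg <- c(msg, "markers must be named 'onset' and/or 'offset'")
    if (all(c("onset", "offset") %in% names(object@markers)) &&
        object@markers["offset"] <= object@markers["onset"])
      msg <- c(msg, "seizure offset must lie after onset")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param samples channels x time numeric matrix (uV). A vector is treated
#'   as a single channel.
#' @param fs sampling rate (Hz).
#' @param channelLabels channel names; defaults to a 10-20 subset of the
#'   right length.
#' @param startTime time of the first sample (s), default 0.
#' @param markers optional named numeric vector with elements
#'   \code{onset} and/or \code{offset} (s).
#' @return An [EEGRecording-class] object.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(2 * 256), 2), fs = 128)
#' nChannels(rec)
#' @export
EEGRecording <- function(samples, fs, channelLabels = NULL, startTime = 0,
                         markers = numeric(0)) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  if (is.null(channelLabels)) channelLabels <- montage1020(nrow(samples))
  new("EEGRecording", samples = samples, fs = fs,
      channelLabels = channelLabels, startTime = startTime,
      markers = markers)
}

#' Standard 10-20 montage labels
#'
#' Returns the first \code{n} labels of the 12-electrode reduced 10-20
#' montage (extended towards the 20-electrode layout when \code{n > 12}).
#'
#' @param n number of channels.
#' @return Character vector of length \code{n}.
#' @export
montage1020 <- function(n) {
  base <- c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4",
            "O1", "O2", "T3", "T4", "F7", "F8", "T5", "T6",
            "Fz", "Pz", "A1", "A2")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, paste0("EEG", seq_len(n - length(base))))
}

#' Epoch grid with artifact flags
#'
#' A contiguous grid of fixed-length epochs cut from an [EEGRecording-class],
#' together with per-channel artifact flags and the set of wholly rejected
#' channels.
#'
#' @slot starts epoch start times in seconds (relative to the recording
#'   origin); the grid is contiguous with spacing \code{epochLength}.
#' @slot epochLength epoch duration in seconds (5 by default).
#' @slot artifact logical matrix, channels x epochs; TRUE marks a
#'   channel-epoch contaminated by artifact.
#' @slot rejected logical vector per channel; TRUE marks channels excluded
#'   wholesale (flagged in more than half of the epochs).
#' @slot channelLabels channel names, matching the parent recording.
#' @export
setClass("EpochSet",
  representation(
    starts = "numeric",
    epochLength = "numeric",
    artifact = "matrix",
    rejected = "logical",
    channelLabels = "character"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character(0)
  if (length(object@epochLength) != 1 || object@epochLength <= 0)
    msg <- c(msg, "epochLength must be a single positive number")
  if (ncol(object@artifact) != length(object@starts))
    msg <- c(msg, "artifact matrix must have one column per epoch")
  if (nrow(object@artifact) != length(object@channelLabels))
    msg <- c(msg, "artifact matrix must have one row per channel")
  if (length(object@rejected) != length(object@channelLabels))
    msg <- c(msg, "rejected flags must match channels")
  if (length(object@starts) > 1 &&
      any(diff(object@starts) <= 0))
    msg <- c(msg, "epoch starts must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Per-minute normalized alpha-delta ratio series
#'
#' The recovery trajectory of one postictal recording: one normalized
#' alpha-delta ratio (ADR) value per minute since seizure offset, with the
#' number of valid Welch windows that entered each minute bin. Minutes with
#' fewer than half of the nominal windows valid are missing (NA).
#'
#' @slot minute integer minute index since seizure offset (bin k covers
#'   [k, k+1) minutes), strictly increasing, starting at 0.
#' @slot adr ADR per minute, in [-1, 1], NA where too few valid windows.
#' @slot nWindows number of valid windows per minute bin.
#' @export
setClass("ADRSeries",
  representation(
    minute = "integer",
    adr = "numeric",
    nWindows = "integer"
  )
)

setValidity("ADRSeries", function(object) {
  msg <- character(0)
  n <- length(object@minute)
  if (length(object@adr) != n || length(object@nWindows) != n)
    msg <- c(msg, "minute, adr and nWindows must have equal length")
  if (n && (any(object@minute < 0) || any(diff(object@minute) <= 0)))
    msg <- c(msg, "minute indices must be nonnegative and strictly increasing")
  ok <- is.na(object@adr) | (object@adr >= -1 - 1e-9 & object@adr <= 1 + 1e-9)
  if (!all(ok))
    msg <- c(msg, "adr values must lie in [-1, 1] or be NA")
  if (length(msg)) msg else TRUE
})

#' Construct an ADRSeries
#'
#' @param minute integer minute indices since seizure offset.
#' @param adr ADR value per minute (NA allowed).
#' @param nWindows valid window count per minute (defaults to NA counts).
#' @return An [ADRSeries-class] object.
#' @export
ADRSeries <- function(minute, adr, nWindows = rep(NA_integer_, length(minute))) {
  new("ADRSeries", minute = as.integer(minute), adr = as.numeric(adr),
      nWindows = as.integer(nWindows))
}

#' Fitted sigmoidal recovery model
#'
#' Result of fitting the lag-parameterised sigmoid to an [ADRSeries-class]:
#' the recovery amplitude A, initial lag lambda, time constant tau, upper
#' asymptote U, goodness of fit, and the derived time of fastest recovery
#' \code{tMax = lambda + tau}.
#'
#' @slot A recovery amplitude (distance from the upper level to the lower
#'   asymptote), in ADR units; positive.
#' @slot lam initial lag (min).
#' @slot tau time constant (min); positive.
#' @slot U upper asymptote (ADR units).
#' @slot rSquared coefficient of determination of the fit.
#' @slot converged TRUE if the optimiser succeeded for at least one start.
#' @slot tMax time of maximum recovery rate (min), capped at D.
#' @slot maxSlope maximum of the fitted derivative (ADR/min).
#' @slot D fitted span: last observed minute (min).
#' @slot qcPass TRUE if converged and rSquared >= the quality gate (0.7).
#' @slot boundary TRUE if the derivative argmax fell on the boundary of
#'   [0, D] (lambda + tau outside the observed span).
#' @export
setClass("SigmoidFit",
  representation(
    A = "numeric", lam = "numeric", tau = "numeric", U = "numeric",
    rSquared = "numeric", converged = "logical",
    tMax = "numeric", maxSlope = "numeric", D = "numeric",
    qcPass = "logical", boundary = "logical"
  )
)

setValidity("SigmoidFit", function(object) {
  msg <- character(0)
  if (isTRUE(object@converged)) {
    if (object@A <= 0) msg <- c(msg, "A must be positive")
    if (object@tau <= 0) msg <- c(msg, "tau must be positive")
    if (object@lam < 0) msg <- c(msg, "lam must be nonnegative")
    if (!is.na(object@rSquared) && object@rSquared > 1 + 1e-9)
      msg <- c(msg, "rSquared cannot exceed 1")
  }
  if (length(msg)) msg else TRUE
})
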