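#' Zero-phase Butterworth band-pass filter
#'
#' Applies a first-order Butterworth band-pass (default 0.5-30 Hz) to every
#' channel, forward and backward (zero phase), removing DC drift and content
#' above the upper edge without shifting band-power timing.
#'
#' @param rec an [EEGRecording-class].
#' @param low lower band edge (Hz).
#' @param high upper band edge (Hz).
#' @param order filter order (1 by default; the two-pass application doubles
#'   the effective order).
#' @return A filtered [EEGRecording-class] with unchanged metadata.
#' @examples
#' rec <- EEGRecording(matrix(100, 1, 1280), fs = 128)  # DC only
#' filt <- bandpassFilter(rec)
#' mean(abs(eegSamples(filt)))  # ~0: DC is outside the passband
#' @export
bandpassFilter <- function(rec, low = 0.5, high = 30, order = 1) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- rec@fs
  if (fs <= 2 * high)
    stop("sampling rate (", fs, " Hz) must exceed twice the upper band edge (",
         high, " Hz)")
  if (low <= 0 || high <= low)
    stop("band edges must satisfy 0 < low < high")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  out <- rec@samples
  for (ch in seq_len(nrow(out)))
    out[ch, ] <- signal::filtfilt(bf, rec@samples[ch, ])
  rec@samples <- out
  rec
}

#' Cut a recording into a contiguous epoch grid
#'
#' Segments the recording into fixed-length epochs starting at \code{t0}
#' (typically the seizure offset). A trailing partial epoch is discarded.
#' All artifact flags start FALSE; see [flagArtifacts()].
#'
#' @param rec an [EEGRecording-class].
#' @param t0 grid origin in seconds (relative to the recording origin).
#' @param epochLength epoch duration in seconds (default 5).
#' @return An [EpochSet-class]. Empty (0 epochs) with a warning if the
#'   recording does not span a full epoch past \code{t0}.
#' @export
segmentEpochs <- function(rec, t0 = rec@startTime, epochLength = 5) {
  stopifnot(is(rec, "EEGRecording"), epochLength > 0)
  tEnd <- rec@startTime + recordingDuration(rec)
  n <- max(0L, floor((tEnd - t0) / epochLength))
  if (n == 0L)
    warning("recording does not contain a complete epoch after t0 = ", t0)
  starts <- t0 + epochLength * (seq_len(n) - 1L)
  new("EpochSet",
      starts = starts, epochLength = epochLength,
      artifact = matrix(FALSE, nChannels(rec), n),
      rejected = rep(FALSE, nChannels(rec)),
      channelLabels = rec@channelLabels)
}

#' Flag artifact-contaminated channel-epochs
#'
#' Automated stand-in for visual artifact inspection: a channel-epoch is
#' flagged when its peak absolute amplitude exceeds \code{ampThresh}
#' (movement / electrode pops) or its peak-to-peak amplitude falls below
#' \code{flatThresh} (detached or shorted electrode). Channels flagged in
#' more than half of the epochs are rejected wholesale.
#'
#' @param rec the [EEGRecording-class] the epochs were cut from.
#' @param epochs an [EpochSet-class] from [segmentEpochs()].
#' @param ampThresh amplitude threshold (uV), default 200.
#' @param flatThresh flatline peak-to-peak threshold (uV), default 0.1.
#' @return The [EpochSet-class] with updated artifact and rejection flags.
#' @export
flagArtifacts <- function(rec, epochs, ampThresh = 200, flatThresh = 0.1) {
  stopifnot(is(rec, "EEGRecording"), is(epochs, "EpochSet"))
  fs <- rec@fs
  nEp <- nEpochs(epochs)
  flags <- epochs@artifact
  for (e in seq_len(nEp)) {
    i0 <- round((epochs@starts[e] - rec@startTime) * fs) + 1L
    i1 <- i0 + round(epochs@epochLength * fs) - 1L
    seg <- rec@samples[, i0:i1, drop = FALSE]
    peak <- apply(abs(seg), 1, max)
    p2p <- apply(seg, 1, function(x) diff(range(x)))
    flags[, e] <- flags[, e] | peak > ampThresh | p2p < flatThresh
  }
  epochs@artifact <- flags
  if (nEp > 0) {
    rej <- rowMeans(flags) > 0.5
    if (any(rej & !epochs@rejected))
      message("rejecting channel(s): ",
              paste(epochs@channelLabels[rej & !epochs@rejected],
                    collapse = ", "))
    epochs@rejected <- epochs@rejected | rej
  }
  epochs
}

#' Detect postictal suppression intervals
#'
#' Finds maximal intervals during which the cross-channel amplitude envelope
#' stays below \code{amp} for at least \code{minDur} seconds. The envelope is
#' the RMS amplitude in 0.5-s sliding windows, taken as the median across
#' channels so that suppression must be generalized rather than confined to
#' one electrode. The first such interval after seizure onset proposes the
#' seizure offset.
#'
#' @param rec an [EEGRecording-class].
#' @param amp amplitude threshold (uV), default 10.
#' @param minDur minimum duration (s), default 2.
#' @param windowLength envelope window (s), default 0.5.
#' @param step envelope step (s), default 0.1.
#' @return A data.frame with columns \code{start}, \code{end} (s, half-open
#'   intervals, relative to the recording origin), possibly empty; intervals
#'   are disjoint, sorted, each at least \code{minDur} long.
#' @export
detectSuppression <- function(rec, amp = 10, minDur = 2,
                              windowLength = 0.5, step = 0.1) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- rec@fs
  w <- max(1L, round(windowLength * fs))
  s <- max(1L, round(step * fs))
  n <- nSamples(rec)
  starts <- seq(1L, n - w + 1L, by = s)
  if (!length(starts))
    return(data.frame(start = numeric(0), end = numeric(0)))
  env <- vapply(starts, function(i0) {
    seg <- rec@samples[, i0:(i0 + w - 1L), drop = FALSE]
    stats::median(sqrt(rowMeans(seg^2)))
  }, numeric(1))
  below <- env < amp
  r <- rle(below)
  idxEnd <- cumsum(r$lengths)
  idxStart <- idxEnd - r$lengths + 1L
  out <- data.frame(start = numeric(0), end = numeric(0))
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    t0 <- rec@startTime + (starts[idxStart[k]] - 1L) / fs
    t1 <- rec@startTime + (starts[idxEnd[k]] - 1L + w) / fs
    if (t1 - t0 >= minDur)
      out <- rbind(out, data.frame(start = t0, end = t1))
  }
  out
}

#' Propose seizure offset from suppression
#'
#' Returns the start of the first suppression interval beginning at or after
#' the annotated seizure onset: the onset of generalized postictal
#' suppression. Intended as a fallback proposal when manual offset
#' annotations are absent, never to override them.
#'
#' @param rec an [EEGRecording-class].
#' @param onset seizure onset (s); defaults to the recording's onset marker.
#' @param ... passed to [detectSuppression()].
#' @return Proposed offset time (s), or NA if no suppression is found.
#' @export
proposeSeizureOffset <- function(rec, onset = NULL, ...) {
  if (is.null(onset)) {
    mk <- seizureMarkers(rec)
    if (!"onset" %in% names(mk))
      stop("no seizure onset available (argument or marker)")
    onset <- unname(mk["onset"])
  }
  sup <- detectSuppression(rec, ...)
  sup <- sup[sup$start >= onset - 1e-9, , drop = FALSE]
  if (!nrow(sup)) return(NA_real_)
  sup$start[1]
}

#' Seizure duration from markers
#'
#' @param onset seizure onset (s).
#' @param offset seizure offset (s); must lie strictly after onset.
#' @return Duration in seconds.
#' @examples
#' seizureDuration(0, 58.5)
#' @export
seizureDuration <- function(onset, offset) {
  stopifnot(is.numeric(onset), is.numeric(offset))
  if (any(offset <= onset))
    stop("seizure offset must lie strictly after onset")
  offset - onset
}
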