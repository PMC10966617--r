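#' Welch power spectral densities per overlapping window
#'
#' Computes one Hann-tapered, density-scaled periodogram per channel for
#' every 5-second window advancing by \code{window * (1 - overlap)} seconds
#' across the epoched span: the overlapping windows are the Welch segments.
#' A window is invalid for a channel when the channel is rejected or when
#' any epoch it touches is artifact-flagged for that channel.
#'
#' @param rec a (filtered) [EEGRecording-class].
#' @param epochs the [EpochSet-class] carrying artifact flags.
#' @param window window length (s), default 5.
#' @param overlap fractional overlap between consecutive windows, default 0.5.
#' @return A list with elements \code{freq} (Hz), \code{psd} (array
#'   frequencies x channels x windows, uV^2/Hz), \code{windowStart} (s,
#'   relative to the recording origin), \code{valid} (channels x windows
#'   logical), \code{channelLabels}. Zero windows yields empty members with
#'   a warning.
#' @export
windowPSD <- function(rec, epochs, window = 5, overlap = 0.5) {
  stopifnot(is(rec, "EEGRecording"), is(epochs, "EpochSet"))
  stopifnot(window > 0, overlap >= 0, overlap < 1)
  fs <- rec@fs
  nW <- round(window * fs)
  advance <- window * (1 - overlap)
  if (nEpochs(epochs) == 0L) {
    warning("no epochs: returning empty PSD set")
    return(list(freq = numeric(0),
                psd = array(0, c(0, nChannels(rec), 0)),
                windowStart = numeric(0),
                valid = matrix(FALSE, nChannels(rec), 0),
                channelLabels = rec@channelLabels))
  }
  spanStart <- epochs@starts[1]
  spanEnd <- epochs@starts[nEpochs(epochs)] + epochs@epochLength
  starts <- seq(spanStart, spanEnd - window + 1e-9, by = advance)
  nwin <- length(starts)
  if (!nwin) {
    warning("epoched span shorter than one window")
    return(list(freq = numeric(0),
                psd = array(0, c(0, nChannels(rec), 0)),
                windowStart = numeric(0),
                valid = matrix(FALSE, nChannels(rec), 0),
                channelLabels = rec@channelLabels))
  }
  taper <- hannWindow(nW)
  scale <- 1 / (fs * sum(taper^2))
  nFreq <- nW %/% 2 + 1L
  freq <- (seq_len(nFreq) - 1L) * fs / nW

  i0 <- round((starts - rec@startTime) * fs) + 1L
  segIdx <- outer(0:(nW - 1L), i0, "+")   # nW x nwin sample indices

  # validity: window x epoch overlap (half-open intervals)
  ends <- starts + window
  valid <- matrix(TRUE, nChannels(rec), nwin)
  for (e in seq_len(nEpochs(epochs))) {
    eStart <- epochs@starts[e]
    eEnd <- eStart + epochs@epochLength
    touch <- which(starts < eEnd - 1e-9 & ends > eStart + 1e-9)
    if (length(touch))
      valid[, touch] <- valid[, touch] & !epochs@artifact[, e]
  }
  valid[epochs@rejected, ] <- FALSE

  psd <- array(NA_real_, c(nFreq, nChannels(rec), nwin))
  for (ch in seq_len(nChannels(rec))) {
    segs <- matrix(rec@samples[ch, segIdx], nrow = nW) * taper
    ft <- stats::mvfft(segs)
    p <- (Mod(ft[seq_len(nFreq), , drop = FALSE])^2) * scale
    p[2:(nFreq - 1L), ] <- 2 * p[2:(nFreq - 1L), ]
    psd[, ch, ] <- p
  }
  list(freq = freq, psd = psd, windowStart = starts, valid = valid,
       channelLabels = rec@channelLabels)
}

hannWindow <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

#' Frequency-wise median PSD across valid channels
#'
#' Whole-brain spectral summary: the median across non-rejected,
#' artifact-free channels at each frequency, per window.
#'
#' @param psds result of [windowPSD()].
#' @return A list with \code{freq}, \code{psd} (frequencies x windows; NA
#'   columns where no channel is valid), \code{windowStart},
#'   \code{nChannelsUsed} per window.
#' @export
medianOverChannels <- function(psds) {
  nwin <- length(psds$windowStart)
  nFreq <- length(psds$freq)
  nCh <- nrow(psds$valid)
  nUsed <- colSums(psds$valid)
  if (!nwin || !nFreq)
    return(list(freq = psds$freq, psd = matrix(NA_real_, nFreq, nwin),
                windowStart = psds$windowStart, nChannelsUsed = nUsed))
  # channels x (freq * window) with invalid channel-windows pushed to +Inf,
  # then a vectorised bubble sorting network over the channel dimension;
  # the median picks the order statistics set by each window's valid count
  M <- t(matrix(aperm(psds$psd, c(2, 1, 3)), nrow = nCh))
  invalid <- t(!psds$valid[, rep(seq_len(nwin), each = nFreq), drop = FALSE])
  M[invalid] <- Inf
  for (i in seq_len(nCh - 1L)) {
    for (j in seq_len(nCh - i)) {
      a <- M[, j]
      b <- M[, j + 1L]
      swap <- a > b
      M[swap, j] <- b[swap]
      M[swap, j + 1L] <- a[swap]
    }
  }
  nv <- nUsed[rep(seq_len(nwin), each = nFreq)]
  rows <- seq_len(nFreq * nwin)
  lo <- M[cbind(rows, pmax((nv + 1L) %/% 2L, 1L))]
  hi <- M[cbind(rows, pmax((nv + 2L) %/% 2L, 1L))]
  med <- (lo + hi) / 2
  med[nv == 0L] <- NA_real_
  list(freq = psds$freq, psd = matrix(med, nFreq, nwin),
       windowStart = psds$windowStart, nChannelsUsed = nUsed)
}

#' Band power by trapezoidal integration
#'
#' Integrates a power spectral density over a frequency band on the native
#' frequency grid (no interpolation).
#'
#' @param psd PSD values (uV^2/Hz), a vector on the grid \code{freq}.
#' @param freq frequency grid (Hz).
#' @param lo,hi band edges (Hz), \code{lo < hi}, both within the PSD support.
#' @return Band power in uV^2.
#' @examples
#' freq <- seq(0, 64, by = 0.2)
#' flat <- rep(1, length(freq))
#' bandPower(flat, freq, 8, 13)  # 5 uV^2
#' @export
bandPower <- function(psd, freq, lo, hi) {
  if (lo >= hi) stop("band edges must satisfy lo < hi")
  if (lo < min(freq) - 1e-9 || hi > max(freq) + 1e-9)
    stop("band [", lo, ", ", hi, "] outside PSD support")
  sel <- which(freq >= lo - 1e-9 & freq <= hi + 1e-9)
  if (length(sel) < 2) stop("band too narrow for the frequency grid")
  f <- freq[sel]
  p <- psd[sel]
  sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
}

#' Normalized alpha-delta ratio
#'
#' \code{(pAlpha - pDelta) / (pAlpha + pDelta)}: -1 for pure delta activity,
#' +1 for pure alpha, 0 for balance. Values are clipped to [-1, 1] against
#' rounding; a window where both powers are zero is returned as NA.
#'
#' @param pAlpha alpha-band power (8-13 Hz), uV^2.
#' @param pDelta delta-band power (0.5-4 Hz), uV^2.
#' @return ADR, dimensionless in [-1, 1]; NA where undefined. Vectorised.
#' @examples
#' adr(2, 2)   #  0
#' adr(0, 5)   # -1
#' adr(3, 1)   #  0.5
#' @export
adr <- function(pAlpha, pDelta) {
  stopifnot(all(pAlpha >= 0 | is.na(pAlpha)), all(pDelta >= 0 | is.na(pDelta)))
  tot <- pAlpha + pDelta
  out <- ifelse(!is.na(tot) & tot > 1e-12,
                (pAlpha - pDelta) / tot, NA_real_)
  pmin(1, pmax(-1, out))
}

#' Average window ADRs into a per-minute series
#'
#' Minute bin k covers [k, k+1) minutes after seizure offset; its value is
#' the mean of the window ADRs whose window start falls in the bin. Bins
#' where fewer than half of the nominal windows are valid are missing.
#'
#' @param windowADR ADR per window (NA where invalid).
#' @param windowStart window start times (s).
#' @param seizureOffset time origin (s): the seizure offset.
#' @param duration span to cover (min); defaults to the span of the windows.
#' @param advance window advance (s), default 2.5, used for the nominal
#'   per-minute window count.
#' @return An [ADRSeries-class].
#' @export
minuteSeries <- function(windowADR, windowStart, seizureOffset = 0,
                         duration = NULL, advance = 2.5) {
  stopifnot(length(windowADR) == length(windowStart))
  rel <- windowStart - seizureOffset
  keep <- rel >= -1e-9
  rel <- rel[keep]
  windowADR <- windowADR[keep]
  if (is.null(duration))
    duration <- if (length(rel)) floor(max(rel) / 60) + 1 else 0
  nominal <- 60 / advance
  minute <- seq_len(duration) - 1L
  vals <- rep(NA_real_, duration)
  nWin <- integer(duration)
  bin <- floor(rel / 60)
  for (k in minute) {
    inBin <- bin == k
    ok <- inBin & !is.na(windowADR)
    nWin[k + 1L] <- sum(ok)
    if (sum(ok) >= 0.5 * nominal)
      vals[k + 1L] <- mean(windowADR[ok])
  }
  ADRSeries(minute, vals, nWin)
}

#' Full spectral pipeline: recording to per-minute ADR series
#'
#' Convenience wrapper chaining the stages: band-pass filter, 5-s epoch
#' grid from the seizure offset, artifact flagging, overlapping Welch
#' windows, channel-median PSD, alpha and delta band powers, per-window
#' ADR, per-minute averaging.
#'
#' @param rec an [EEGRecording-class]; its \code{offset} marker (or
#'   \code{t0}) defines minute 0.
#' @param t0 seizure offset (s); defaults to the recording's offset marker,
#'   else the recording start.
#' @param alphaBand,deltaBand band edges (Hz).
#' @param low,high band-pass edges (Hz).
#' @param ampThresh,flatThresh artifact thresholds (uV).
#' @param window,overlap Welch window settings.
#' @return An [ADRSeries-class].
#' @export
computeADRSeries <- function(rec, t0 = NULL,
                             alphaBand = c(8, 13), deltaBand = c(0.5, 4),
                             low = 0.5, high = 30,
                             ampThresh = 200, flatThresh = 0.1,
                             window = 5, overlap = 0.5) {
  if (is.null(t0)) {
    mk <- seizureMarkers(rec)
    t0 <- if ("offset" %in% names(mk)) unname(mk["offset"]) else rec@startTime
  }
  filt <- bandpassFilter(rec, low = low, high = high)
  epochs <- segmentEpochs(filt, t0 = t0, epochLength = window)
  epochs <- flagArtifacts(filt, epochs, ampThresh = ampThresh,
                          flatThresh = flatThresh)
  psds <- windowPSD(filt, epochs, window = window, overlap = overlap)
  med <- medianOverChannels(psds)
  nwin <- length(med$windowStart)
  wadr <- rep(NA_real_, nwin)
  for (wdx in seq_len(nwin)) {
    if (med$nChannelsUsed[wdx] < 1L) next
    pa <- bandPower(med$psd[, wdx], med$freq, alphaBand[1], alphaBand[2])
    pd <- bandPower(med$psd[, wdx], med$freq, deltaBand[1], deltaBand[2])
    wadr[wdx] <- adr(pa, pd)
  }
  minuteSeries(wadr, med$windowStart, seizureOffset = t0,
               advance = window * (1 - overlap))
}
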