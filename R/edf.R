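padField <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = -width)  # left-justified, space padded
}

numField <- function(x, width) {
  s <- formatC(x, width = 1, format = "g", digits = 8)
  if (nchar(s) > width) s <- substr(formatC(x, format = "f", digits = width),
                                    1, width)
  padField(s, width)
}

#' Write a recording to European Data Format (EDF)
#'
#' Standard 16-bit EDF with physical units in microvolts, one-second data
#' records, and per-channel symmetric physical scaling. A trailing partial
#' data record is discarded.
#'
#' @param rec an [EEGRecording-class]; the sampling rate must be an integer
#'   number of samples per one-second record.
#' @param path output file path.
#' @param patientId,recordingId free-text header fields.
#' @return Invisibly, the number of data records written.
#' @export
writeEDF <- function(rec, path, patientId = "X", recordingId = "synthetic") {
  stopifnot(is(rec, "EEGRecording"))
  fs <- rec@fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("writeEDF requires an integer sampling rate")
  spr <- as.integer(round(fs))
  ns <- nChannels(rec)
  nRec <- nSamples(rec) %/% spr
  if (nRec < 1) stop("recording shorter than one data record")
  if (nSamples(rec) %% spr != 0)
    warning("discarding trailing partial data record")

  physMax <- pmax(apply(abs(rec@samples), 1, max), 1)
  digMax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    padField("0", 8), padField(patientId, 80), padField(recordingId, 80),
    padField("01.01.00", 8), padField("00.00.00", 8),
    padField(256 * (ns + 1), 8), padField("", 44),
    padField(nRec, 8), padField(1, 8), padField(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    vapply(rec@channelLabels, function(l) padField(paste("EEG", l), 16), ""),
    rep(padField("AgAgCl cup electrode", 80), ns),
    rep(padField("uV", 8), ns),
    vapply(-physMax, numField, "", width = 8),
    vapply(physMax, numField, "", width = 8),
    rep(padField(-digMax, 8), ns),
    rep(padField(digMax, 8), ns),
    rep(padField("BP 0.5-30Hz", 80), ns),
    rep(padField(spr, 8), ns),
    rep(padField("", 32), ns))
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)

  scale <- physMax / digMax
  for (r in seq_len(nRec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- as.integer(pmin(pmax(round(rec@samples[ch, idx] / scale[ch]),
                                  -digMax), digMax))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(nRec)
}

readHeaderField <- function(con, width, offset, what = "character") {
  raw <- readChar(con, width, useBytes = TRUE)
  if (nchar(raw, type = "bytes") < width)
    stop("corrupt EDF header: truncated at byte offset ", offset)
  trimws(raw)
}

#' Read a European Data Format (EDF) file
#'
#' Parses the EDF header and 16-bit data records, rescales samples to
#' physical units, converts millivolt or volt channels to microvolts with
#' a warning, normalises \code{"EEG Fp1"}-style labels to bare 10-20 names,
#' and drops channels whose physical dimension is not voltage (logged).
#'
#' @param path EDF file path.
#' @return An [EEGRecording-class] in microvolts.
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- readHeaderField(con, 8, 0)
  if (version != "0")
    stop("corrupt EDF header: bad version field at byte offset 0")
  readHeaderField(con, 80, 8)    # patient
  readHeaderField(con, 80, 88)   # recording
  readHeaderField(con, 8, 168)   # date
  readHeaderField(con, 8, 176)   # time
  hdrBytes <- as.integer(readHeaderField(con, 8, 184))
  readHeaderField(con, 44, 192)
  nRec <- as.integer(readHeaderField(con, 8, 236))
  recDur <- as.numeric(readHeaderField(con, 8, 244))
  ns <- as.integer(readHeaderField(con, 4, 252))
  if (is.na(ns) || ns < 1 || is.na(nRec) || nRec < 1)
    stop("corrupt EDF header: bad record counts at byte offset 236")
  if (hdrBytes != 256 * (ns + 1))
    stop("corrupt EDF header: header size field at byte offset 184")

  rd <- function(width, base) vapply(seq_len(ns), function(i)
    readHeaderField(con, width, base + (i - 1) * width), "")
  labels <- rd(16, 256)
  rd(80, 256 + ns * 16)
  dims <- rd(8, 256 + ns * 96)
  physMin <- as.numeric(rd(8, 256 + ns * 104))
  physMax <- as.numeric(rd(8, 256 + ns * 112))
  digMin <- as.numeric(rd(8, 256 + ns * 120))
  digMax <- as.numeric(rd(8, 256 + ns * 128))
  rd(80, 256 + ns * 136)
  spr <- as.integer(rd(8, 256 + ns * 216))
  rd(32, 256 + ns * 224)
  if (any(spr != spr[1]))
    stop("channels with differing sampling rates are not supported")

  dat <- matrix(0, ns, nRec * spr[1])
  for (r in seq_len(nRec)) {
    for (ch in seq_len(ns)) {
      v <- readBin(con, integer(), n = spr[ch], size = 2, signed = TRUE,
                   endian = "little")
      if (length(v) < spr[ch])
        stop("corrupt EDF data: truncated in record ", r)
      idx <- ((r - 1) * spr[ch] + 1):(r * spr[ch])
      dat[ch, idx] <- v
    }
  }
  for (ch in seq_len(ns)) {
    dat[ch, ] <- (dat[ch, ] - digMin[ch]) *
      (physMax[ch] - physMin[ch]) / (digMax[ch] - digMin[ch]) + physMin[ch]
  }
  unitScale <- vapply(dims, function(d) switch(tolower(d),
    "uv" = 1, "µv" = 1, "mv" = 1000, "v" = 1e6, NA_real_), numeric(1))
  keep <- !is.na(unitScale)
  if (any(!keep))
    message("dropping non-voltage channel(s): ",
            paste(labels[!keep], collapse = ", "))
  if (any(unitScale[keep] != 1))
    warning("rescaling ", sum(unitScale[keep] != 1),
            " channel(s) to microvolts")
  dat <- dat[keep, , drop = FALSE] * unitScale[keep]
  labels <- sub("^EEG ?", "", labels[keep])
  fs <- spr[1] / recDur
  EEGRecording(dat, fs = fs, channelLabels = labels)
}
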