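# Recording containers: a plain-text array format (inspectable, bit-exact
# round trip) and a minimal EDF reader/writer for interchange.

#' Write a recording to the plain-text array container
#'
#' One JSON header line (shape, rate, channel names, labels, ratings)
#' followed by one line of full-precision samples per trial and channel.
#' Reading the file back reproduces the arrays bit-exactly.
#'
#' @param rec An [eeg_recording()].
#' @param path Output path (conventionally `.eegr`).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  d <- dim(rec$data)
  header <- jsonlite::toJSON(list(
    format = "eegemo-recording", version = 1L,
    n_trials = d[1], n_channels = d[2], n_samples = d[3],
    sampling_rate = rec$sampling_rate,
    channel_names = rec$channel_names,
    baseline_seconds = rec$baseline_seconds,
    subject_id = rec$subject_id,
    labels = rec$labels,
    ratings = rec$ratings
  ), auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  for (tr in seq_len(d[1]))
    for (ch in seq_len(d[2]))
      writeLines(paste(sprintf("%.17g", rec$data[tr, ch, ]), collapse = " "), con)
  invisible(path)
}

read_eegr <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty recording file: ", path)
  hd <- tryCatch(jsonlite::fromJSON(lines[1]),
                 error = function(e) stop("parse error in header of ", path,
                                          ": ", conditionMessage(e)))
  if (!identical(hd$format, "eegemo-recording"))
    stop("not an eegemo recording file: ", path)
  need <- hd$n_trials * hd$n_channels
  if (length(lines) < need + 1L)
    stop(sprintf("truncated recording file %s: expected %d data lines, found %d",
                 path, need, length(lines) - 1L))
  data <- array(0, dim = c(hd$n_trials, hd$n_channels, hd$n_samples))
  k <- 1L
  for (tr in seq_len(hd$n_trials))
    for (ch in seq_len(hd$n_channels)) {
      v <- as.numeric(strsplit(lines[k + 1L], " ", fixed = TRUE)[[1]])
      if (length(v) != hd$n_samples)
        stop(sprintf("corrupt record at data line %d of %s: expected %d samples, found %d",
                     k, path, hd$n_samples, length(v)))
      data[tr, ch, ] <- v
      k <- k + 1L
    }
  eeg_recording(data, hd$sampling_rate, hd$channel_names,
                labels = hd$labels,
                ratings = if (is.null(hd$ratings)) NULL else as.data.frame(hd$ratings),
                baseline_seconds = hd$baseline_seconds %||% 0,
                subject_id = hd$subject_id %||% 1L)
}

#' Read a recording file
#'
#' Dispatches on `format`: the package's text container (`eegr`), an EDF file
#' (`edf`), or sniffing the file contents (`auto`).
#'
#' @param path Input file.
#' @param format `"auto"`, `"eegr"` or `"edf"`.
#' @param ... Passed to the format-specific reader (e.g. `as_trials` for EDF).
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "eegr", "edf"), ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readChar(path, 8L, useBytes = TRUE)
    format <- if (startsWith(first, "{")) "eegr" else "edf"
  }
  switch(format, eegr = read_eegr(path), edf = read_edf(path, ...))
}

# ---- minimal EDF support ------------------------------------------------

edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

#' Write a recording as an EDF file
#'
#' Minimal continuous EDF export: one data record per trial, 16-bit samples
#' scaled to each channel's physical range. EDF quantizes amplitudes to 16
#' bits, so the round trip through [read_edf()] is close but not bit-exact;
#' labels and ratings are not representable in EDF and are dropped.
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  d <- dim(rec$data)
  ns <- d[2]
  n_rec <- d[1]
  spr <- d[3]
  dur <- spr / rec$sampling_rate
  pmin_ <- apply(rec$data, 2, min); pmax_ <- apply(rec$data, 2, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmax_[flat] <- pmin_[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_field(x, width), con, eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256L + ns * 256L, 8); wr("", 44); wr(n_rec, 8)
  wr(format(dur, digits = 8), 8); wr(ns, 4)
  for (ch in rec$channel_names) wr(ch, 16)
  for (i in seq_len(ns)) wr("EEG", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(format(pmin_[i], digits = 7), 8)
  for (i in seq_len(ns)) wr(format(pmax_[i], digits = 7), 8)
  for (i in seq_len(ns)) wr(-32768L, 8)
  for (i in seq_len(ns)) wr(32767L, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(spr, 8)
  for (i in seq_len(ns)) wr("", 32)
  scale <- (pmax_ - pmin_) / 65535
  for (tr in seq_len(n_rec))
    for (ch in seq_len(ns)) {
      dig <- round((rec$data[tr, ch, ] - pmin_[ch]) / scale[ch]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
               size = 2L, endian = "little")
    }
  invisible(path)
}

#' Read an EDF file
#'
#' Minimal reader for continuous EDF: parses the fixed-width ASCII header and
#' the 16-bit little-endian sample records, rescaling to physical units.
#'
#' @param path Input file.
#' @param as_trials Treat each data record as one trial (the convention
#'   [write_edf()] uses); otherwise all records are concatenated into a
#'   single continuous trial.
#' @return An [eeg_recording()] (without labels; EDF does not carry them).
#' @export
read_edf <- function(path, as_trials = FALSE) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    if (sz < seek(con) + width) stop("truncated EDF header in ", path)
    trimws(readChar(con, width, useBytes = TRUE))
  }
  ver <- rd(8)
  if (ver != "0") stop("unsupported EDF version field: ", ver)
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF: bad signal count")
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("mixed per-signal sampling rates are not supported")
  expected <- header_bytes + 2 * n_rec * sum(spr)
  if (sz < expected)
    stop(sprintf("truncated EDF %s: expected %d bytes, file has %d (record area starts at byte %d)",
                 path, expected, sz, header_bytes))
  scale <- (pmax_ - pmin_) / (dmax_ - dmin_)
  data <- array(0, dim = c(n_rec, ns, spr[1]))
  for (r in seq_len(n_rec))
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2L, signed = TRUE,
                     endian = "little")
      data[r, ch, ] <- scale[ch] * (dig - dmin_[ch]) + pmin_[ch]
    }
  fs <- spr[1] / dur
  if (!as_trials) {
    cont <- array(aperm(data, c(3, 1, 2)), dim = c(1, n_rec * spr[1], ns))
    data <- aperm(cont, c(1, 3, 2))
  }
  eeg_recording(data, fs, labels, baseline_seconds = 0, subject_id = 1L)
}

#' Normalize a DEAP-shaped array into a recording
#'
#' Takes a per-subject array of 40 trials x 40 channels x samples (the
#' benchmark layout, where the first 32 channels are EEG and the remainder
#' peripheral signals) plus the trials x ratings matrix, keeps the 32 EEG
#' channels, attaches the standard montage names and the 3-s baseline.
#'
#' @param data Array `trials x 40 x samples`.
#' @param ratings Matrix/data.frame with one row per trial; the first two
#'   columns are interpreted as valence and arousal (1-9).
#' @param sampling_rate Default 128 Hz.
#' @param dimension Which rating drives the binary label (`"valence"` or
#'   `"arousal"`).
#' @param subject_id Subject identifier.
#' @return An [eeg_recording()] with 32 channels and binarized labels.
#' @export
as_deap_recording <- function(data, ratings = NULL, sampling_rate = 128,
                              dimension = c("valence", "arousal"),
                              subject_id = 1L) {
  dimension <- match.arg(dimension)
  if (length(dim(data)) != 3L || dim(data)[2] < 32L)
    stop("expected a trials x 40 (>=32) channels x samples array")
  data <- data[, 1:32, , drop = FALSE]
  labels <- NULL; rt <- NULL
  if (!is.null(ratings)) {
    ratings <- as.matrix(ratings)
    if (nrow(ratings) != dim(data)[1])
      stop("ratings must have one row per trial")
    rt <- data.frame(valence = ratings[, 1],
                     arousal = if (ncol(ratings) >= 2) ratings[, 2] else NA_real_)
    labels <- binarize_ratings(rt[[dimension]])
  }
  eeg_recording(data, sampling_rate, DEAP_CHANNELS, labels = labels,
                ratings = rt, baseline_seconds = 3, subject_id = subject_id)
}
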