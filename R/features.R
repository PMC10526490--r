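#' Discard the pre-stimulus baseline from a recording
#'
#' Removes the leading `baseline_seconds` of every trial, keeping only the
#' stimulus period. No baseline subtraction is performed; the baseline samples
#' are simply dropped.
#'
#' @param rec An [eeg_recording()].
#' @return A new `eeg_recording` with `baseline_seconds = 0` and shorter trials.
#' @examples
#' rec <- generate_recording(synth_spec(n_trials_per_subject = 1,
#'                                      trial_seconds = 5, seed = 1))
#' dim(strip_baseline(rec)$data)[3] # (5 - 3) * 128
#' @export
strip_baseline <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  n_base <- as.integer(round(rec$baseline_seconds * fs))
  n_samp <- dim(rec$data)[3]
  if (n_base == 0L) return(rec)
  if (n_samp < n_base + fs)
    stop(sprintf("trial too short: %d samples cover less than baseline (%d) + one 1-s window",
                 n_samp, n_base))
  out <- rec
  out$data <- rec$data[, , (n_base + 1L):n_samp, drop = FALSE]
  out$baseline_seconds <- 0
  out
}

#' Cut trials into fixed-length windows
#'
#' Slides a window of `window_s` seconds with step `step_s` over every trial
#' (defaults 1 s / 1 s: non-overlapping windows). Each window inherits the
#' label of its trial. The number of windows per trial is
#' `floor((trial_s - window_s) / step_s) + 1`.
#'
#' @param rec An [eeg_recording()] (strip the baseline first if present).
#' @param window_s Window length in seconds; `window_s * sampling_rate` must be
#'   an integer.
#' @param step_s Step between window starts in seconds.
#' @return An object of class `eeg_segments`: list with `data`
#'   (`n_segments x channels x window_samples` array), `meta` (data.frame with
#'   `subject`, `trial`, `segment`, `label`), `sampling_rate`, `channel_names`.
#' @export
segment_trials <- function(rec, window_s = 1, step_s = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  check_number(window_s, "window_s", 0, strict = TRUE)
  check_number(step_s, "step_s", 0, strict = TRUE)
  fs <- rec$sampling_rate
  win <- window_s * fs
  stp <- step_s * fs
  if (abs(win - round(win)) > 1e-9)
    stop(sprintf("window_s * sampling_rate = %g is not an integer number of samples", win))
  if (abs(stp - round(stp)) > 1e-9)
    stop(sprintf("step_s * sampling_rate = %g is not an integer number of samples", stp))
  win <- as.integer(round(win)); stp <- as.integer(round(stp))
  d <- dim(rec$data)
  if (win > d[3]) stop("window is longer than the trial")
  n_per_trial <- (d[3] - win) %/% stp + 1L
  starts <- (seq_len(n_per_trial) - 1L) * stp + 1L

  n_seg <- d[1] * n_per_trial
  data <- array(0, dim = c(n_seg, d[2], win))
  k <- 0L
  for (tr in seq_len(d[1])) {
    for (s in starts) {
      k <- k + 1L
      data[k, , ] <- rec$data[tr, , s:(s + win - 1L)]
    }
  }
  meta <- data.frame(
    subject = rep(rec$subject_id, n_seg),
    trial = rep(seq_len(d[1]), each = n_per_trial),
    segment = rep(seq_len(n_per_trial), times = d[1]),
    label = if (is.null(rec$labels)) NA_integer_
            else rep(rec$labels, each = n_per_trial)
  )
  structure(list(data = data, meta = meta, sampling_rate = fs,
                 channel_names = rec$channel_names),
            class = "eeg_segments")
}

#' @export
print.eeg_segments <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_segments> %d segments x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sampling_rate))
  invisible(x)
}

# column-wise zero-phase filtering (samples x K matrix)
filtfilt_mat <- function(bf, X) {
  n <- nrow(X)
  pad <- 3L * (max(length(bf$a), length(bf$b)) - 1L)
  if (n <= pad)
    stop(sprintf("signal too short for zero-phase filtering: %d samples, need > %d", n, pad))
  pre <- 2 * X[rep(1L, pad), , drop = FALSE] - X[(pad + 1L):2L, , drop = FALSE]
  post <- 2 * X[rep(n, pad), , drop = FALSE] - X[(n - 1L):(n - pad), , drop = FALSE]
  Y <- rbind(pre, X, post)
  Y <- iir_filter_mat(bf, Y)
  Y <- iir_filter_mat(bf, Y[nrow(Y):1L, , drop = FALSE])
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  Y[(pad + 1L):(pad + n), , drop = FALSE]
}

iir_filter_mat <- function(bf, X) {
  b <- bf$b; a <- bf$a
  nb <- length(b); n <- nrow(X)
  Z <- stats::filter(rbind(matrix(0, nb - 1L, ncol(X)), X), b,
                     method = "convolution", sides = 1)
  Z <- matrix(as.numeric(Z), ncol = ncol(X))[nb:(nb + n - 1L), , drop = FALSE]
  if (length(a) > 1)
    Z <- matrix(as.numeric(stats::filter(Z, -a[-1], method = "recursive")),
                ncol = ncol(X))
  Z
}

#' Split a segment into frequency-band components
#'
#' Applies a zero-phase Butterworth bandpass filter per band. For a single
#' segment (channels x samples matrix) a named list of filtered matrices is
#' returned; for an `eeg_segments` batch, a named list of filtered
#' `eeg_segments`.
#'
#' @param seg A channels x samples matrix or an `eeg_segments` object.
#' @param bands Band table as from [default_bands()].
#' @param sampling_rate Required when `seg` is a bare matrix.
#' @return Named list (one entry per band) of objects matching the input type.
#' @export
bandpass_decompose <- function(seg, bands = default_bands(),
                               sampling_rate = NULL) {
  if (inherits(seg, "eeg_segments")) {
    fs <- seg$sampling_rate
    validate_bands(bands, fs)
    d <- dim(seg$data)
    X <- matrix(aperm(seg$data, c(3, 2, 1)), nrow = d[3]) # samples x (ch*seg)
    out <- lapply(seq_len(nrow(bands)), function(b) {
      bf <- butter_bandpass(bands$low_hz[b], bands$high_hz[b], fs,
                            bands$filter_order[b])
      Y <- filtfilt_mat(bf, X)
      res <- seg
      res$data <- aperm(array(Y, dim = c(d[3], d[2], d[1])), c(3, 2, 1))
      res
    })
    names(out) <- bands$name
    return(out)
  }
  stopifnot(is.matrix(seg))
  if (is.null(sampling_rate))
    stop("'sampling_rate' is required when filtering a bare matrix")
  validate_bands(bands, sampling_rate)
  out <- lapply(seq_len(nrow(bands)), function(b) {
    bf <- butter_bandpass(bands$low_hz[b], bands$high_hz[b], sampling_rate,
                          bands$filter_order[b])
    t(filtfilt_mat(bf, t(seg)))
  })
  names(out) <- bands$name
  out
}

#' Differential entropy of a band-limited window
#'
#' Under the Gaussian approximation a signal window with variance
#' \eqn{\sigma^2} has differential entropy
#' \eqn{\tfrac12 \ln(2 \pi e \sigma^2)} (natural log, nats). The sample
#' variance of the window is plugged in; this equals the log band energy up to
#' an affine transform, which is what makes it a stable spectral feature.
#'
#' @param x Numeric vector with at least 2 samples.
#' @return Differential entropy in nats.
#' @examples
#' set.seed(1)
#' differential_entropy(rnorm(10000)) # ~ 0.5 * log(2 * pi * exp(1)) = 1.4189
#' @export
differential_entropy <- function(x) {
  if (length(x) < 2L) stop("need at least 2 samples")
  v <- stats::var(x)
  if (!is.finite(v) || v <= 0)
    stop("zero-variance (constant) signal: differential entropy is undefined here")
  0.5 * log(2 * pi * exp(1) * v)
}

#' Differential-entropy features for a batch of segments
#'
#' Filters every segment into the given bands and computes the per-channel,
#' per-band differential entropy, producing the feature matrices that are
#' placed on the scalp grid.
#'
#' @param segments An `eeg_segments` object.
#' @param bands Band table as from [default_bands()].
#' @return Object of class `de_segments`: list with `values`
#'   (`n_segments x channels x n_bands` array), `meta`, `band_names`,
#'   `channel_names`.
#' @export
de_transform <- function(segments, bands = default_bands()) {
  stopifnot(inherits(segments, "eeg_segments"))
  fs <- segments$sampling_rate
  validate_bands(bands, fs)
  d <- dim(segments$data)
  X <- matrix(aperm(segments$data, c(3, 2, 1)), nrow = d[3])
  vals <- array(0, dim = c(d[1], d[2], nrow(bands)))
  n <- d[3]
  for (b in seq_len(nrow(bands))) {
    bf <- butter_bandpass(bands$low_hz[b], bands$high_hz[b], fs,
                          bands$filter_order[b])
    Y <- filtfilt_mat(bf, X)
    v <- (colSums(Y^2) - colSums(Y)^2 / n) / (n - 1)
    if (any(v <= 0))
      stop("zero-variance band-filtered window encountered; differential entropy undefined")
    vals[, , b] <- t(matrix(0.5 * log(2 * pi * exp(1) * v), nrow = d[2]))
  }
  structure(list(values = vals, meta = segments$meta,
                 band_names = bands$name,
                 channel_names = segments$channel_names),
            class = "de_segments")
}

#' The packaged 9x9 scalp grid layout
#'
#' Reads the versioned layout file shipped with the package, which places the
#' 32 channels of the standard montage on a 9x9 grid according to their scalp
#' topology (row 0 = frontal edge).
#'
#' @param path Optional path to a user-supplied layout file with columns
#'   `channel`, `row`, `col` (tab-separated, 0-based coordinates).
#' @return A data.frame with columns `channel`, `row`, `col`.
#' @export
deap_9x9_layout <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "layout_deap9x9.tsv", package = "eegemo")
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Map channel names to scalp-grid cells
#'
#' @param channel_names Ordered character vector of channel names.
#' @param layout Layout table (see [deap_9x9_layout()]).
#' @param h,w Grid dimensions (default 9 x 9).
#' @return Object of class `electrode_map`: list with `placements` (data.frame
#'   `channel`, `row`, `col` in input order), `h`, `w`.
#' @export
build_electrode_map <- function(channel_names, layout = deap_9x9_layout(),
                                h = 9L, w = 9L) {
  channel_names <- as.character(channel_names)
  if (anyDuplicated(channel_names))
    stop("duplicate channel name(s): ",
         paste(unique(channel_names[duplicated(channel_names)]), collapse = ", "))
  unknown <- setdiff(channel_names, layout$channel)
  if (length(unknown))
    stop("unknown channel name(s): ", paste(unknown, collapse = ", "))
  idx <- match(channel_names, layout$channel)
  pl <- layout[idx, c("channel", "row", "col")]
  rownames(pl) <- NULL
  if (nrow(pl)) {
    if (any(pl$row < 0 | pl$row >= h | pl$col < 0 | pl$col >= w))
      stop("layout places a channel outside the grid")
    if (anyDuplicated(pl[c("row", "col")]))
      stop("layout places two channels in the same cell")
  }
  structure(list(placements = pl, h = as.integer(h), w = as.integer(w)),
            class = "electrode_map")
}

#' Place differential-entropy values on the scalp grid
#'
#' Builds the h x w x d feature tensor: each channel's per-band values go to
#' its grid cell, cells without an electrode stay structurally zero, and a
#' boolean occupancy mask marks which cells hold data.
#'
#' @param de A channels x bands matrix (one segment), or a `de_segments`
#'   batch.
#' @param map An [build_electrode_map()] result covering every channel.
#' @return For a single segment, a list with `grid` (h x w x d array) and
#'   `mask` (h x w logical). For a batch, an object of class `de_tensors`:
#'   list with `grid` (`n_segments x h x w x d`), `mask`, `meta`,
#'   `band_names`.
#' @export
assemble_feature_tensor <- function(de, map) {
  stopifnot(inherits(map, "electrode_map"))
  pl <- map$placements
  if (inherits(de, "de_segments")) {
    missing_ch <- setdiff(de$channel_names, pl$channel)
    if (length(missing_ch))
      stop("channel(s) missing from electrode map: ",
           paste(missing_ch, collapse = ", "))
    ord <- match(de$channel_names, pl$channel)
    d <- dim(de$values)
    grid <- array(0, dim = c(d[1], map$h, map$w, d[3]))
    mask <- matrix(FALSE, map$h, map$w)
    for (i in seq_along(ord)) {
      r <- pl$row[ord[i]] + 1L; c <- pl$col[ord[i]] + 1L
      mask[r, c] <- TRUE
      grid[, r, c, ] <- de$values[, i, ]
    }
    return(structure(list(grid = grid, mask = mask, meta = de$meta,
                          band_names = de$band_names),
                     class = "de_tensors"))
  }
  stopifnot(is.matrix(de))
  ch <- rownames(de)
  if (is.null(ch))
    stop("matrix input needs channel names as rownames")
  missing_ch <- setdiff(ch, pl$channel)
  if (length(missing_ch))
    stop("channel(s) missing from electrode map: ",
         paste(missing_ch, collapse = ", "))
  grid <- array(0, dim = c(map$h, map$w, ncol(de)))
  mask <- matrix(FALSE, map$h, map$w)
  for (i in seq_along(ch)) {
    j <- match(ch[i], pl$channel)
    r <- pl$row[j] + 1L; c <- pl$col[j] + 1L
    mask[r, c] <- TRUE
    grid[r, c, ] <- de[i, ]
  }
  list(grid = grid, mask = mask)
}

#' Full featurization pipeline for one recording
#'
#' Convenience wrapper: strip baseline, cut 1-s windows, extract
#' differential-entropy features, and place them on the 9x9 grid.
#'
#' @param rec An [eeg_recording()].
#' @param window_s,step_s Windowing parameters (default 1 s / 1 s).
#' @param bands Band table.
#' @param layout Scalp layout table.
#' @return A `de_tensors` object.
#' @export
featurize_recording <- function(rec, window_s = 1, step_s = 1,
                                bands = default_bands(),
                                layout = deap_9x9_layout()) {
  rec <- strip_baseline(rec)
  segs <- segment_trials(rec, window_s, step_s)
  de <- de_transform(segs, bands)
  map <- build_electrode_map(rec$channel_names, layout)
  assemble_feature_tensor(de, map)
}

#' Serialize feature tensors to a plain-text container
#'
#' Writes a one-line JSON header (dimensions, band names, mask, metadata)
#' followed by one line of full-precision values per segment. The round trip
#' through [read_feature_tensors()] is bit-exact.
#'
#' @param x A `de_tensors` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_tensors <- function(x, path) {
  stopifnot(inherits(x, "de_tensors"))
  d <- dim(x$grid)
  header <- jsonlite::toJSON(list(
    format = "eegemo-detensors", version = 1L,
    n_segments = d[1], h = d[2], w = d[3], d = d[4],
    band_names = x$band_names,
    mask = which(t(x$mask)) - 1L,  # row-major linear indices of occupied cells
    meta = x$meta
  ), auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  for (i in seq_len(d[1]))
    writeLines(paste(sprintf("%.17g", as.vector(x$grid[i, , , ])),
                     collapse = " "), con)
  invisible(path)
}

#' Read feature tensors written by [write_feature_tensors()]
#'
#' @param path Input file path.
#' @return A `de_tensors` object.
#' @export
read_feature_tensors <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty feature-tensor file: ", path)
  hd <- jsonlite::fromJSON(lines[1])
  if (!identical(hd$format, "eegemo-detensors"))
    stop("not an eegemo feature-tensor file: ", path)
  n <- hd$n_segments
  if (length(lines) < n + 1L)
    stop(sprintf("truncated feature-tensor file: expected %d data lines, found %d",
                 n, length(lines) - 1L))
  grid <- array(0, dim = c(n, hd$h, hd$w, hd$d))
  for (i in seq_len(n)) {
    v <- as.numeric(strsplit(lines[i + 1L], " ", fixed = TRUE)[[1]])
    if (length(v) != hd$h * hd$w * hd$d)
      stop(sprintf("corrupt record %d: expected %d values, found %d",
                   i, hd$h * hd$w * hd$d, length(v)))
    grid[i, , , ] <- array(v, dim = c(hd$h, hd$w, hd$d))
  }
  mask <- matrix(FALSE, hd$h, hd$w)
  mask[cbind((hd$mask %/% hd$w) + 1L, (hd$mask %% hd$w) + 1L)] <- TRUE
  structure(list(grid = grid, mask = mask,
                 meta = as.data.frame(hd$meta),
                 band_names = hd$band_names),
            class = "de_tensors")
}
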