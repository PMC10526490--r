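#' Specification of a synthetic EEG study
#'
#' Describes a study of band-limited synthetic EEG trials whose per-band power
#' depends on a latent emotion class, mirroring the shape of benchmark emotion
#' datasets (by default 128 Hz, 32 channels, 63-s trials of which the first 3 s
#' are a pre-stimulus baseline).
#'
#' Each class is characterized by a row of `band_power_map`: the standard
#' deviation of the class's signal in each of the four canonical bands (theta,
#' alpha, beta, gamma). Trials additionally carry broadband Gaussian noise of
#' standard deviation `noise_sd`. All amplitudes are in arbitrary units
#' (microvolt-like scale).
#'
#' @param n_subjects Number of subjects.
#' @param n_trials_per_subject Trials recorded per subject.
#' @param n_channels Number of EEG channels (default 32; up to 32 channels the
#'   standard montage names are attached so the scalp-grid mapping works).
#' @param sampling_rate Sampling rate in Hz (default 128). Must exceed twice
#'   the highest band edge (45 Hz).
#' @param trial_seconds Total trial duration in seconds (default 63).
#' @param baseline_seconds Pre-stimulus baseline at the start of each trial
#'   (default 3); downstream processing discards it.
#' @param class_scheme `"binary"` (two classes, mimicking high/low valence
#'   ratings on a 1-9 scale) or `"ternary"` (three categorical classes,
#'   mimicking negative/neutral/positive).
#' @param band_power_map Numeric matrix, one row per class and one column per
#'   band (theta, alpha, beta, gamma), giving the per-band signal standard
#'   deviation for that class. Rows must differ between classes. A default
#'   with moderate separation is supplied per scheme.
#' @param noise_sd Standard deviation of the broadband noise (default 1).
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An object of class `synth_spec`.
#' @seealso [generate_recording()]
#' @export
synth_spec <- function(n_subjects = 1L,
                       n_trials_per_subject = 40L,
                       n_channels = 32L,
                       sampling_rate = 128,
                       trial_seconds = 63,
                       baseline_seconds = 3,
                       class_scheme = c("binary", "ternary"),
                       band_power_map = NULL,
                       noise_sd = 1,
                       seed = 1L) {
  class_scheme <- match.arg(class_scheme)
  n_classes <- if (class_scheme == "binary") 2L else 3L
  if (is.null(band_power_map)) {
    band_power_map <- if (class_scheme == "binary") {
      rbind(low  = c(theta = 1.2, alpha = 1.5, beta = 0.8, gamma = 0.5),
            high = c(theta = 0.8, alpha = 0.7, beta = 1.5, gamma = 1.0))
    } else {
      rbind(negative = c(theta = 1.4, alpha = 0.7, beta = 1.2, gamma = 0.9),
            neutral  = c(theta = 1.0, alpha = 1.2, beta = 0.8, gamma = 0.5),
            positive = c(theta = 0.7, alpha = 1.5, beta = 1.3, gamma = 1.1))
    }
  }
  band_power_map <- as.matrix(band_power_map)

  spec <- structure(list(
    n_subjects = check_count(n_subjects, "n_subjects"),
    n_trials_per_subject = check_count(n_trials_per_subject, "n_trials_per_subject"),
    n_channels = check_count(n_channels, "n_channels"),
    sampling_rate = check_number(sampling_rate, "sampling_rate", 0, strict = TRUE),
    trial_seconds = check_number(trial_seconds, "trial_seconds", 0, strict = TRUE),
    baseline_seconds = check_number(baseline_seconds, "baseline_seconds", 0),
    class_scheme = class_scheme,
    n_classes = n_classes,
    band_power_map = band_power_map,
    noise_sd = check_number(noise_sd, "noise_sd", 0),
    seed = check_count(seed, "seed", min = 0L)
  ), class = "synth_spec")
  validate_synth_spec(spec)
}

validate_synth_spec <- function(spec) {
  bpm <- spec$band_power_map
  if (nrow(bpm) != spec$n_classes)
    stop(sprintf("'band_power_map' must have %d rows (one per class), got %d",
                 spec$n_classes, nrow(bpm)), call. = FALSE)
  if (ncol(bpm) != 4L)
    stop("'band_power_map' must have 4 columns (theta, alpha, beta, gamma)",
         call. = FALSE)
  if (any(bpm < 0) || any(!is.finite(bpm)))
    stop("'band_power_map' entries must be finite and non-negative", call. = FALSE)
  if (spec$sampling_rate <= 2 * 45)
    stop("'sampling_rate' must exceed twice the highest band edge (45 Hz)",
         call. = FALSE)
  if (spec$baseline_seconds >= spec$trial_seconds)
    stop("'baseline_seconds' must be smaller than 'trial_seconds'", call. = FALSE)
  dup <- duplicated(apply(bpm, 1, paste, collapse = ","))
  if (any(dup))
    stop("'band_power_map' rows must differ between classes", call. = FALSE)
  spec
}

# DEAP 32-channel montage order (international 10/20 extended labels)
DEAP_CHANNELS <- c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7",
                   "CP5", "CP1", "P3", "P7", "PO3", "O1", "Oz", "Pz",
                   "Fp2", "AF4", "Fz", "F4", "F8", "FC6", "FC2", "Cz",
                   "C4", "T8", "CP6", "CP2", "P4", "P8", "PO4", "O2")

default_channel_names <- function(n) {
  if (n <= length(DEAP_CHANNELS)) DEAP_CHANNELS[seq_len(n)]
  else c(DEAP_CHANNELS, sprintf("X%02d", seq_len(n - length(DEAP_CHANNELS))))
}

#' Construct a raw EEG recording object
#'
#' Container for one subject's EEG: a trials x channels x samples array plus
#' sampling rate, channel names, per-trial labels and (optionally) continuous
#' 1-9 ratings.
#'
#' @param data Numeric array `trials x channels x samples`.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_names Character vector, one name per channel.
#' @param labels Integer class labels per trial (0-based), or `NULL`.
#' @param ratings Optional data.frame of per-trial continuous ratings.
#' @param baseline_seconds Leading baseline duration in seconds (default 0).
#' @param subject_id Identifier for the subject.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sampling_rate, channel_names,
                          labels = NULL, ratings = NULL,
                          baseline_seconds = 0, subject_id = 1L) {
  if (length(dim(data)) != 3L)
    stop("'data' must be a 3-d array (trials x channels x samples)")
  if (length(channel_names) != dim(data)[2])
    stop(sprintf("channel_names length (%d) != channel axis length (%d)",
                 length(channel_names), dim(data)[2]))
  if (dim(data)[3] < baseline_seconds * sampling_rate)
    stop("trials are shorter than the stated baseline")
  if (!is.null(labels) && length(labels) != dim(data)[1])
    stop("labels length must equal the number of trials")
  structure(list(
    data = data,
    sampling_rate = as.numeric(sampling_rate),
    channel_names = as.character(channel_names),
    labels = if (is.null(labels)) NULL else as.integer(labels),
    ratings = ratings,
    baseline_seconds = as.numeric(baseline_seconds),
    subject_id = subject_id
  ), class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_recording> subject %s: %d trials x %d channels x %d samples @ %g Hz\n",
              x$subject_id, d[1], d[2], d[3], x$sampling_rate))
  if (!is.null(x$labels))
    cat("  labels:", paste(utils::head(x$labels, 10), collapse = " "),
        if (length(x$labels) > 10) "..." else "", "\n")
  invisible(x)
}

#' Generate synthetic EEG recordings with known class structure
#'
#' Each trial draws a class label; its signal is a sum of four band-limited
#' components (white Gaussian noise filtered with the same Butterworth
#' bandpass filters used downstream, rescaled so the in-band standard
#' deviation equals the class's `band_power_map` entry) plus broadband
#' Gaussian noise. For the binary scheme a per-trial continuous rating in
#' 1-9 is also drawn, above 5 for the "high" class and at or below 5
#' otherwise.
#'
#' @param spec A [synth_spec()].
#' @return For `n_subjects == 1` a single [eeg_recording()]; otherwise a list
#'   of recordings (class `eeg_study`), one per subject.
#' @examples
#' rec <- generate_recording(synth_spec(n_trials_per_subject = 2,
#'                                      trial_seconds = 5, seed = 7))
#' dim(rec$data) # 2 x 32 x 640
#' @export
generate_recording <- function(spec) {
  spec <- validate_synth_spec(spec)
  recs <- lapply(seq_len(spec$n_subjects), function(s) {
    with_seed(derive_seed(spec$seed, s), generate_one_subject(spec, s))
  })
  if (spec$n_subjects == 1L) recs[[1]]
  else structure(recs, class = "eeg_study")
}

generate_one_subject <- function(spec, subject_id) {
  fs <- spec$sampling_rate
  n_samp <- as.integer(round(spec$trial_seconds * fs))
  n_tr <- spec$n_trials_per_subject
  n_ch <- spec$n_channels
  bands <- default_bands()
  filters <- lapply(seq_len(nrow(bands)), function(b)
    butter_bandpass(bands$low_hz[b], bands$high_hz[b], fs,
                    bands$filter_order[b]))

  # balanced class assignment, shuffled
  labels <- sample(rep_len(seq_len(spec$n_classes) - 1L, n_tr))
  data <- array(0, dim = c(n_tr, n_ch, n_samp))
  for (tr in seq_len(n_tr)) {
    pow <- spec$band_power_map[labels[tr] + 1L, ]
    for (ch in seq_len(n_ch)) {
      sig <- numeric(n_samp)
      for (b in seq_along(filters)) {
        if (pow[b] > 0) {
          comp <- filtfilt(filters[[b]], stats::rnorm(n_samp))
          s <- stats::sd(comp)
          if (s > 0) sig <- sig + pow[b] * comp / s
        }
      }
      if (spec$noise_sd > 0) sig <- sig + spec$noise_sd * stats::rnorm(n_samp)
      data[tr, ch, ] <- sig
    }
  }

  ratings <- if (spec$class_scheme == "binary") {
    v <- ifelse(labels == 1L, stats::runif(n_tr, 5 + 1e-6, 9),
                stats::runif(n_tr, 1, 5))
    data.frame(valence = v)
  } else NULL

  eeg_recording(data, fs, default_channel_names(n_ch),
                labels = labels, ratings = ratings,
                baseline_seconds = spec$baseline_seconds,
                subject_id = subject_id)
}
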