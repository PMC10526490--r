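# shared fixtures, all generated in code

# a small but non-trivial synthetic study: 2 classes, clear band separation
easy_spec <- function(seed = 20L, n_subjects = 2L, n_trials = 10L,
                      trial_seconds = 12) {
  synth_spec(
    n_subjects = n_subjects,
    n_trials_per_subject = n_trials,
    trial_seconds = trial_seconds,
    band_power_map = rbind(low = c(2, 2, 0.3, 0.3),
                           high = c(0.3, 0.3, 2, 2)),
    noise_sd = 1,
    seed = seed
  )
}

# featurized study: returns list(grid, labels, meta)
featurized_study <- function(spec) {
  study <- generate_recording(spec)
  if (inherits(study, "eeg_recording")) study <- list(study)
  merged <- merge_tensors(lapply(study, featurize_recording))
  merged
}

# a deliberately small network configuration for fast tests
tiny_cfg <- function(...) {
  model_config(widths = c(4L, 6L, 8L, 10L), blocks_per_stage = 1L,
               lateral_channels = 6L, gru_hidden = 5L, seed = 3L, ...)
}

rel_err <- function(a, b) max(abs(a - b)) / max(1e-8, max(abs(a) + abs(b)))
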