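# preprocessing: baseline, segmentation, differential entropy, scalp grid

make_rec <- function(n_trials = 1, n_channels = 2, seconds = 5, fs = 128,
                     baseline = 0, seed = 1) {
  set.seed(seed)
  n <- as.integer(seconds * fs)
  eeg_recording(array(rnorm(n_trials * n_channels * n),
                      c(n_trials, n_channels, n)),
                fs, paste0("Ch", seq_len(n_channels)),
                labels = rep(0L, n_trials), baseline_seconds = baseline)
}

test_that("strip_baseline drops exactly the baseline samples", {
  rec <- make_rec(seconds = 63, baseline = 3)
  out <- strip_baseline(rec)
  expect_equal(dim(out$data)[3], 7680L)  # 60 s at 128 Hz
  expect_equal(out$data[1, 1, 1], rec$data[1, 1, 3 * 128 + 1])
  expect_equal(out$baseline_seconds, 0)
  # baseline 0 is the identity
  rec0 <- make_rec(seconds = 2, baseline = 0)
  expect_identical(strip_baseline(rec0), rec0)
  # too-short trial errors
  rec_short <- make_rec(seconds = 3.5, baseline = 3)
  expect_error(strip_baseline(rec_short), "short")
})

test_that("segment counts follow the windowing formula", {
  rec <- make_rec(seconds = 60)
  segs <- segment_trials(rec, 1, 1)
  expect_equal(dim(segs$data), c(60L, 2L, 128L))
  # window == trial length -> a single segment equal to the trial
  one <- segment_trials(rec, 60, 60)
  expect_equal(dim(one$data)[1], 1L)
  expect_equal(one$data[1, , ], rec$data[1, , ])
  # non-integer window
  expect_error(segment_trials(rec, 1 / 3, 1), "integer")
})

test_that("segment counting matches brute-force window enumeration", {
  set.seed(99)
  for (i in 1:20) {
    fs <- 8
    trial_s <- sample(3:12, 1)
    window_s <- sample(seq_len(trial_s), 1)
    step_s <- sample(1:3, 1)
    rec <- make_rec(seconds = trial_s, fs = fs, seed = i)
    segs <- segment_trials(rec, window_s, step_s)
    # oracle: enumerate admissible start samples directly
    starts <- seq(1, trial_s * fs, by = step_s * fs)
    n_expected <- sum(starts + window_s * fs - 1 <= trial_s * fs)
    expect_equal(dim(segs$data)[1], n_expected,
                 info = sprintf("trial %ds window %ds step %ds",
                                trial_s, window_s, step_s))
  }
})

test_that("segments inherit trial labels in temporal order", {
  rec <- make_rec(n_trials = 3, seconds = 4)
  rec$labels <- c(1L, 0L, 1L)
  segs <- segment_trials(rec, 1, 1)
  expect_equal(segs$meta$label, rep(c(1L, 0L, 1L), each = 4))
  expect_equal(segs$meta$segment, rep(1:4, times = 3))
  expect_equal(segs$data[6, , ], rec$data[2, , 129:256])
})

test_that("differential entropy matches the Gaussian closed form", {
  # oracle: numerically integrate -f log f for the standard normal
  de_oracle <- integrate(function(x) {
    f <- dnorm(x); ifelse(f > 0, -f * log(f), 0)
  }, -Inf, Inf)$value
  expect_equal(de_oracle, 0.5 * log(2 * pi * exp(1)), tolerance = 1e-8)
  set.seed(123)
  x <- rnorm(12800)
  expect_lt(abs(differential_entropy(x) - de_oracle), 0.05)
  # scaling identity DE(c x) - DE(x) = log|c|, exactly
  for (c_ in c(0.5, 2, 10))
    expect_equal(differential_entropy(c_ * x) - differential_entropy(x),
                 log(c_), tolerance = 1e-12)
  expect_error(differential_entropy(rep(1, 100)), "zero-variance")
  expect_error(differential_entropy(3), "2 samples")
})

test_that("bandpass_decompose returns one same-shaped copy per band", {
  set.seed(7)
  seg <- matrix(rnorm(32 * 128), 32, 128)
  out <- bandpass_decompose(seg, sampling_rate = 128)
  expect_named(out, c("theta", "alpha", "beta", "gamma"))
  for (b in out) expect_equal(dim(b), c(32L, 128L))
  # zero in, zero out
  z <- bandpass_decompose(matrix(0, 4, 128), sampling_rate = 128)
  expect_true(all(vapply(z, function(m) all(m == 0), TRUE)))
})

test_that("the packaged layout places the 32 channels on 32 distinct cells", {
  map <- build_electrode_map(eegemo:::DEAP_CHANNELS)
  expect_equal(nrow(map$placements), 32L)
  expect_equal(map$h, 9L)
  expect_equal(map$w, 9L)
  expect_equal(nrow(unique(map$placements[c("row", "col")])), 32L)
  expect_true(all(map$placements$row >= 0 & map$placements$row < 9))
  # frontal channels on the top edge
  expect_equal(map$placements$row[map$placements$channel == "Fp1"], 0)
  expect_equal(map$placements$row[map$placements$channel == "O2"], 8)
  # empty and invalid input
  expect_equal(nrow(build_electrode_map(character(0))$placements), 0L)
  expect_error(build_electrode_map(c("Fp1", "XX99")), "XX99")
  expect_error(build_electrode_map(c("Fp1", "Fp1")), "duplicate")
})

test_that("feature tensors have structural zeros off the mask", {
  de <- matrix(rnorm(32 * 4), 32, 4,
               dimnames = list(eegemo:::DEAP_CHANNELS, NULL))
  map <- build_electrode_map(eegemo:::DEAP_CHANNELS)
  ft <- assemble_feature_tensor(de, map)
  expect_equal(dim(ft$grid), c(9L, 9L, 4L))
  expect_equal(sum(ft$mask), 32L)          # conservation: one cell per channel
  for (b in 1:4) {
    expect_true(all(ft$grid[, , b][!ft$mask] == 0))
    expect_equal(sum(ft$grid[, , b][ft$mask]), sum(de[, b]))
  }
  # all-zero DE values leave the mask intact
  ft0 <- assemble_feature_tensor(de * 0, map)
  expect_true(all(ft0$grid == 0))
  expect_identical(ft0$mask, ft$mask)
  # unknown channel rejected by name
  de_bad <- rbind(de, Q9 = rnorm(4))
  expect_error(assemble_feature_tensor(de_bad, map), "Q9")
})

test_that("injected band power raises DE in that band's grid cells only", {
  levels <- c(0.6, 1.2, 2.4)
  mean_de <- sapply(levels, function(pw) {
    spec <- synth_spec(n_trials_per_subject = 2L, trial_seconds = 6,
                       baseline_seconds = 0,
                       band_power_map = rbind(c(1, 1, pw, 1), c(1, 1, 1, 1)),
                       noise_sd = 0.1, seed = 31L)
    ft <- featurize_recording(generate_recording(spec))
    sel <- which(ft$meta$label == 0L)
    msk <- as.vector(ft$mask)
    vapply(1:4, function(b)
      mean(matrix(ft$grid[sel, , , b], length(sel))[, msk]), 1)
  })
  # beta band strictly increasing with the injected power
  expect_true(all(diff(mean_de[3, ]) > 0))
  # other bands stay flat within noise
  for (b in c(1, 2, 4))
    expect_lt(max(mean_de[b, ]) - min(mean_de[b, ]), 0.15)
})

test_that("feature tensors round-trip through the text container bit-exactly", {
  spec <- easy_spec(n_subjects = 1L, n_trials = 2L, trial_seconds = 5)
  ft <- featurize_recording(generate_recording(spec))
  path <- withr::local_tempfile()
  write_feature_tensors(ft, path)
  back <- read_feature_tensors(path)
  expect_identical(back$grid, ft$grid)
  expect_identical(back$mask, ft$mask)
  expect_equal(back$meta$label, ft$meta$label)
})
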