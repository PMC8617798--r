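make_rec <- function(m, fs = 256, labels = NULL, gender = "female") {
  labels <- labels %||% paste0("ch", seq_len(nrow(m)))
  erpdecode::recording(m, labels, fs, "t01", gender)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("band-pass keeps a 10 Hz sine, kills DC, and maps zero to zero", {
  fs <- 256
  t <- seq_len(60 * fs) / fs
  x <- sin(2 * pi * 10 * t)
  rec <- make_rec(rbind(x, 0))
  out <- bandpass_filter(rec, preprocess_config())
  mid <- (20 * fs):(40 * fs)
  expect_gte(max(out$data[1, mid]), 0.95)          # in-band amplitude retained
  expect_equal(out$data[2, ], rep(0, ncol(out$data)))  # linearity: zero -> zero

  # analytic response: DC far below the 0.01 Hz corner is suppressed
  expect_lt(filter_response(preprocess_config(), 1e-4, fs), 1e-4)
})

test_that("filter magnitude response has half-amplitude cutoffs and 24 dB/oct roll-off", {
  cfg <- preprocess_config()
  r <- filter_response(cfg, c(0.01, 30), fs = 256)
  expect_equal(r[1], 0.5, tolerance = 1e-6)
  expect_equal(r[2], 0.5, tolerance = 1e-3)
  # asymptotic slope above the low-pass corner, in dB per octave
  r2 <- filter_response(cfg, c(60, 120), fs = 256)
  expect_gte(20 * log10(r2[1] / r2[2]), 24)
  # and below the high-pass corner
  r3 <- filter_response(cfg, c(0.0025, 0.00125), fs = 256)
  expect_gte(20 * log10(r3[1] / r3[2]), 24)
})

test_that("filtered sine amplitudes agree with the analytic response", {
  fs <- 256
  t <- seq_len(120 * fs) / fs
  cfg <- preprocess_config()
  for (f in c(5, 30, 45)) {
    rec <- make_rec(matrix(sin(2 * pi * f * t), 1))
    out <- bandpass_filter(rec, cfg)
    mid <- (40 * fs):(80 * fs)
    meas <- max(abs(out$data[1, mid]))
    expect_equal(meas, filter_response(cfg, f, fs), tolerance = 0.02)
  }
})

test_that("PCA blink correction removes an injected frontal blink and little else", {
  set.seed(11)
  fs <- 256
  n <- 40 * fs
  labels <- c("Fp1", "Fp2", "Cz", "Pz", "O1")
  topo <- c(1, 0.95, 0.25, 0.05, 0.01)          # stereotyped blink mixing
  base <- matrix(rnorm(5 * n, sd = 2), 5)
  blink_ts <- rep(0, n)
  blink_at <- as.integer(seq(2 * fs, n - 2 * fs, length.out = 16))
  for (c0 in blink_at) {
    idx <- (c0 - 30):(c0 + 30)
    blink_ts[idx] <- blink_ts[idx] + 150 * exp(-((idx - c0)^2) / (2 * 12^2))
  }
  blink_mask <- blink_ts > 5
  rec <- make_rec(base + outer(topo, blink_ts), labels = labels)
  out <- correct_blinks_pca(rec, preprocess_config())

  rms <- function(x) sqrt(mean(x^2))
  # blink energy (departure from the known clean signal) in frontal
  # channels drops by more than half over blink intervals
  for (ch in 1:2) {
    expect_lt(rms(out$data[ch, blink_mask] - base[ch, blink_mask]),
              0.5 * rms(rec$data[ch, blink_mask] - base[ch, blink_mask]))
  }
  # posterior channels: away from blinks the correction leaves only a DC
  # shift (the blink's mean, removed later by baseline correction) plus a
  # fluctuation under 10% of the clean signal
  for (ch in 4:5) {
    err <- out$data[ch, !blink_mask] - base[ch, !blink_mask]
    expect_lt(rms(err - mean(err)) / rms(base[ch, !blink_mask]), 0.1)
  }
})

test_that("blink correction edge cases: identity at 0 components, missing reference errors", {
  rec <- make_rec(matrix(rnorm(3 * 512), 3), labels = c("Fp1", "Fp2", "Cz"))
  cfg0 <- preprocess_config(blink_components = 0)
  expect_identical(correct_blinks_pca(rec, cfg0)$data, rec$data)
  cfg_bad <- preprocess_config(blink_reference_channels = c("Fp1", "AF7"))
  expect_error(correct_blinks_pca(rec, cfg_bad), "AF7")
})

test_that("epoch grid reproduces the study's 281 timepoints and window conventions", {
  expect_length(epoch_grid_indices(c(-100, 1000), 256), 281)
  expect_identical(epoch_grid_indices(c(-100, 1000), 256), -25:255)
  expect_identical(epoch_grid_indices(c(0, 1000), 256), 0:255)
  expect_identical(epoch_grid_indices(c(0, 0), 256), 0:0)
})

test_that("epoching extracts onset-locked windows and drops edge events with a warning", {
  fs <- 256
  sig <- matrix(seq_len(3 * fs), 1)              # ramp encodes sample index
  rec <- make_rec(sig, fs)
  ev <- event_table(c(10L, 400L), c("standard", "target"))
  expect_warning(ep <- epoch_recording(rec, ev, preprocess_config()),
                 "dropped")
  expect_equal(dim(ep$data), c(1, 1, 281))
  expect_equal(ep$data[1, 1, ], 400 + (-25:255))  # exact sample indices
  expect_equal(ep$times, (-25:255) * 1000 / fs)
  expect_true(0 %in% ep$times)
  expect_error(epoch_recording(rec, event_table(integer(0), character(0))),
               "empty")
})

test_that("artifact rejection is strict at +/-75 uV", {
  ep <- structure(list(
    data = array(0, dim = c(3, 1, 281)),
    times = study_times(),
    categories = factor(rep("standard", 3), levels = c("standard", "target")),
    keep_mask = rep(TRUE, 3)), class = "epoch_set")
  ep$data[1, 1, 50] <- 80       # over threshold -> rejected
  ep$data[2, 1, 50] <- 74.9     # below -> kept
  ep$data[3, 1, 50] <- -75      # exactly at threshold -> kept ("over" is strict)
  out <- reject_artifacts(ep, preprocess_config())
  expect_identical(out$keep_mask, c(FALSE, TRUE, TRUE))
})

test_that("baseline correction and detrending behave on crafted epochs", {
  times <- study_times()
  tp <- length(times)
  mk <- function(x) {
    a <- aperm(array(x, dim = c(tp, 1, 2)), c(3, 2, 1))  # 2 trials x 1 ch x tp
    structure(list(
      data = a, times = times,
      categories = factor(rep("target", 2), levels = c("standard", "target")),
      keep_mask = rep(TRUE, 2)), class = "epoch_set")
  }

  cfg <- preprocess_config()
  # constant epoch -> all zeros
  out <- baseline_and_detrend(mk(rep(7, tp)), cfg)
  expect_lt(max(abs(out$data)), 1e-9)
  # pure linear ramp -> ~zeros after detrend, baseline mean ~0 exactly
  out <- baseline_and_detrend(mk(seq(-3, 3, length.out = tp)), cfg)
  expect_lt(max(abs(out$data)), 1e-9)
  expect_lt(abs(mean(out$data[1, 1, 1:25])), 1e-9)
  # offset + ramp + centred P3-like bump: peak-to-baseline amplitude
  # preserved within 1% (the intercept shift cancels in the difference)
  bump <- exp(-(times - 450)^2 / (2 * 30^2))
  x <- 10 + 0.01 * seq_len(tp) + bump
  out <- baseline_and_detrend(mk(x), cfg)
  peak_idx <- which.max(bump)
  expect_equal(out$data[1, 1, peak_idx] - mean(out$data[1, 1, 1:25]),
               1, tolerance = 0.01)
  # baseline mean stays small despite the bump's pull on the trend fit
  expect_lt(abs(mean(out$data[1, 1, 1:25])), 0.1)
})

test_that("category averaging and difference waveform follow their algebra", {
  times <- study_times()
  tp <- length(times)
  epd <- array(0, dim = c(4, 2, tp))
  epd[1, , ] <- 1; epd[2, , ] <- 3          # targets: mean 2
  epd[3, , ] <- 5                           # standard kept
  epd[4, , ] <- 99                          # standard, will be masked out
  ep <- structure(list(
    data = epd, times = times,
    categories = factor(c("target", "target", "standard", "standard"),
                        levels = c("standard", "target")),
    keep_mask = c(TRUE, TRUE, TRUE, FALSE)), class = "epoch_set")
  tgt <- average_by_category(ep, "target")
  std <- average_by_category(ep, "standard")
  expect_equal(tgt$n_trials, 2)
  expect_equal(std$n_trials, 1)
  expect_true(all(tgt$data == 2))
  expect_true(all(std$data == 5))

  diff <- difference_waveform(tgt, std, "p1", "female")
  expect_true(all(diff$data == -3))
  expect_equal(unname(attr(diff, "n_trials")), c(2, 1))

  # mean of +x and -x epochs is the zero waveform
  ep2 <- ep
  ep2$data[1, , ] <- 4; ep2$data[2, , ] <- -4
  expect_true(all(average_by_category(ep2, "target")$data == 0))

  # zero kept epochs of a category is an error
  ep3 <- ep
  ep3$keep_mask <- c(FALSE, FALSE, TRUE, TRUE)
  expect_error(average_by_category(ep3, "target"), "unusable")
})

test_that("rejection happens before baseline correction in the chain", {
  # an epoch whose large offset would fall under the threshold after
  # baseline subtraction: the pipeline order (reject first) must drop it
  times <- study_times()
  tp <- length(times)
  a <- array(0, dim = c(2, 1, tp))
  a[1, 1, ] <- 100                          # constant 100 uV offset
  a[2, 1, ] <- 1
  ep <- structure(list(
    data = a, times = times,
    categories = factor(c("target", "target"),
                        levels = c("standard", "target")),
    keep_mask = c(TRUE, TRUE)), class = "epoch_set")
  cfg <- preprocess_config()
  reject_first <- baseline_and_detrend(reject_artifacts(ep, cfg), cfg)
  baseline_first <- reject_artifacts(baseline_and_detrend(ep, cfg), cfg)
  expect_identical(reject_first$keep_mask, c(FALSE, TRUE))
  expect_identical(baseline_first$keep_mask, c(TRUE, TRUE))  # order matters
})

test_that("the full preprocessing chain is deterministic and study-shaped", {
  cfg <- tiny_sim_cfg(n_persons = 1L, n_female = 1L)
  ev <- oddball_sequence(cfg, seed = 3)
  rec <- simulate_recording(cfg, ev, "female", "p1", seed = 3)
  e1 <- preprocess_person(rec, ev, preprocess_config())
  e2 <- preprocess_person(rec, ev, preprocess_config())
  expect_identical(e1$data, e2$data)        # bit-identical rerun
  expect_equal(dim(e1$data), c(32, 281))
  expect_gte(min(attr(e1, "n_trials")), 1)
})

test_that("configuration validation names the broken constraint", {
  expect_error(preprocess_config(low_hz = 30, high_hz = 0.01), "low_hz")
  expect_error(preprocess_config(reject_threshold_uv = -1), "positive")
  expect_error(preprocess_config(epoch_window_ms = c(100, 1000)), "onset")
  rec <- recording(matrix(0, 1, 512), "Cz", 256, "x", "male")
  expect_error(bandpass_filter(rec, preprocess_config(high_hz = 200)),
               "Nyquist")
})
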