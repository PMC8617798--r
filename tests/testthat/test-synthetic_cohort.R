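test_that("oddball sequences have exact category counts for any seed", {
  cfg <- sim_config()
  for (seed in c(1, 7, 123)) {
    ev <- oddball_sequence(cfg, seed = seed)
    expect_equal(nrow(ev), 300)
    expect_equal(sum(ev$category == "target"), 60)
    expect_equal(sum(ev$category == "standard"), 240)
    expect_true(all(diff(ev$onset_sample) ==
                      round(1.15 * cfg$fs)))     # 150 ms stim + 1000 ms ISI
  }
  # determinism and seed sensitivity
  expect_identical(oddball_sequence(cfg, seed = 9), oddball_sequence(cfg, seed = 9))
  expect_false(identical(as.character(oddball_sequence(cfg, seed = 1)$category),
                         as.character(oddball_sequence(cfg, seed = 2)$category)))

  expect_equal(sum(oddball_sequence(sim_config(p_target = 0),
                                    seed = 1)$category == "target"), 0)
  expect_error(oddball_sequence(sim_config(n_stimuli = 301L), seed = 1),
               "integer")
})

test_that("templates are sums of placed bumps with the configured effects", {
  cfg <- sim_config()
  cfg_plain <- sim_config(gender_effects = list())
  # zero-amplitude components (and no effects) give the zero template
  comp0 <- default_components()
  comp0$amplitude_uv <- 0
  t0 <- erp_template(cfg_plain, "target", "female", components = comp0)
  expect_true(all(t0 == 0))

  # a single P3 bump peaks at the sample nearest its configured latency
  comp <- default_components()
  comp <- comp[comp$name == "P3", ]
  comp$latency_ms <- 400
  t1 <- erp_template(cfg_plain, "target", "male", components = comp)
  times <- attr(t1, "times")
  expect_equal(times[which.max(t1["Pz", ])],
               times[which.min(abs(times - 400))])

  # gender effect: female-male target difference is the boxcar delta
  tf <- erp_template(cfg, "target", "female")
  tm <- erp_template(cfg, "target", "male")
  d <- tf - tm
  late <- times >= 650 & times < 700
  early <- times >= 300 & times < 350
  expect_equal(unname(d["Pz", late]), rep(2, sum(late)))
  expect_equal(unname(d["Pz", early]), rep(-2, sum(early)))  # male-favoured window
  expect_true(all(abs(d["Pz", !(late | early)]) < 1e-12))
  expect_true(all(d["Fp1", ] == 0))               # effect is parietal only

  # standards carry the attenuated P3 and no gender effect
  sf <- erp_template(cfg, "standard", "female")
  sm <- erp_template(cfg, "standard", "male")
  expect_equal(sf, sm)

  # an effect window outside the epoch errors
  bad <- sim_config(gender_effects = list(list(window_ms = c(1100, 1200),
                                               channels = "Pz", delta_uv = 1,
                                               gender = "female")))
  expect_error(erp_template(bad, "target", "female"), "outside")
})

test_that("a clean single-event recording reproduces the template through epoching", {
  cfg <- sim_config(noise_sd_uv = 0, drift_sd_uv = 0, blink_rate_per_min = 0,
                    artifact_prob = 0, n_stimuli = 5L, pad_s = 5)
  ev <- oddball_sequence(cfg, seed = 1)
  rec <- simulate_recording(cfg, ev, "female", "p1", seed = 1)
  ep <- epoch_recording(rec, ev, preprocess_config())
  tmpl <- erp_template(cfg, "target", "female")
  j <- which(ev$category == "target")[1]
  expect_equal(ep$data[j, , ], unclass(tmpl), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("simulated recordings are seed-deterministic and blink-free when disabled", {
  cfg <- tiny_sim_cfg(1L, 1L)
  ev <- oddball_sequence(cfg, seed = 4)
  r1 <- simulate_recording(cfg, ev, "male", "p", seed = 11)
  r2 <- simulate_recording(cfg, ev, "male", "p", seed = 11)
  expect_identical(r1$data, r2$data)

  quiet <- sim_config(n_stimuli = 20L, pad_s = 5, noise_sd_uv = 0,
                      drift_sd_uv = 0, artifact_prob = 0,
                      blink_rate_per_min = 0)
  rec <- simulate_recording(quiet, oddball_sequence(quiet, seed = 2),
                            "female", "p", seed = 2)
  # frontal channels show only the (small) evoked activity, no 100 uV blinks
  expect_lt(max(abs(rec$data["Fp1", ])), 10)
})

test_that("cohorts have the configured composition and are reproducible", {
  cfg <- tiny_sim_cfg(4L, 2L)
  c1 <- simulate_cohort(cfg, seed = 3)
  expect_length(c1, 4)
  g <- vapply(c1, `[[`, "", "gender")
  expect_equal(sum(g == "female"), 2)
  expect_identical(c1[[2]]$recording$data,
                   simulate_cohort(cfg, seed = 3)[[2]]$recording$data)
  ids <- vapply(c1, function(m) m$recording$person_id, "")
  expect_equal(ids, c("s01", "s02", "s03", "s04"))
})

test_that("trial dropout is calibrated to the reported kept-trial counts", {
  # study conditions; modest person count to keep runtime in check
  cfg <- sim_config(n_persons = 6L, n_female = 3L)
  raw <- simulate_cohort(cfg, seed = 20)
  coh <- preprocess_cohort(raw)
  kept <- t(vapply(unclass(coh), function(e) attr(e, "n_trials"), c(0, 0)))
  expect_gt(mean(kept[, "target"]), 40 - 8)
  expect_lt(mean(kept[, "target"]), 40 + 8)
  expect_gt(mean(kept[, "standard"]), 160 - 32)
  expect_lt(mean(kept[, "standard"]), 160 + 32)
})

test_that("difference-level cohorts are deterministic and carry the effect", {
  cfg <- sim_config()
  c1 <- simulate_erp_cohort(cfg, seed = 5)
  c2 <- simulate_erp_cohort(cfg, seed = 5)
  expect_identical(unclass(c1)[[1]]$data, unclass(c2)[[1]]$data)
  expect_equal(length(c1), 20)
  expect_equal(ncol(unclass(c1)[[1]]$data), 281)

  # the injected late effect separates the gender means around 650-700 ms
  # (averaged over the parietal set to beat the residual noise)
  times <- unclass(c1)[[1]]$times
  g <- cohort_genders(c1)
  late <- times >= 650 & times < 700
  parietal <- c("CP1", "CP2", "P3", "Pz", "P4", "POz")
  pz <- vapply(unclass(c1), function(e) mean(e$data[parietal, late]), 0)
  expect_gt(mean(pz[g == "female"]) - mean(pz[g == "male"]), 1)
})

test_that("a stronger injected effect never hurts decoding (monotonicity)", {
  deltas <- c(0, 2, 6)
  reps <- 5L
  acc <- matrix(NA_real_, length(deltas), reps)
  for (i in seq_along(deltas)) {
    fx <- default_gender_effects()
    fx[[2]]$delta_uv <- deltas[i]
    fx[[1]]$delta_uv <- 0                       # isolate the late window
    cfg <- sim_config(gender_effects = fx)
    for (r in seq_len(reps)) {
      coh <- simulate_erp_cohort(cfg, seed = 100 + r)
      acc[i, r] <- loo_segment_eval(coh, classifier_spec("gnb"), 16)$accuracy
    }
  }
  m <- rowMeans(acc)
  se <- apply(acc, 1, sd) / sqrt(reps)
  # non-decreasing within Monte-Carlo slack of one standard error
  expect_gte(m[2], m[1] - (se[1] + se[2]))
  expect_gte(m[3], m[2] - (se[2] + se[3]))
})
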