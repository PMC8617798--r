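#' Simulation configuration for a synthetic oddball cohort
#'
#' The generative model mirrors the study conditions: 20 persons (10
#' female / 10 male), 32-channel extended 10/20 montage, 256 Hz, 300
#' stimuli per run (20% targets) with 150 ms duration and 1000 ms
#' inter-stimulus interval, and roughly 30 s of padding before the first
#' and after the last stimulus.
#'
#' Each evoked response is a sum of Gaussian-shaped components (N1, P2,
#' N2, P3) with fixed scalp topographies; targets carry the full P3 while
#' standards carry an attenuated one. Gender effects are additive boxcar
#' amplitude offsets applied to the target template of one gender inside a
#' latency window on a channel subset; the defaults follow the reported
#' direction of the effect (higher amplitude in men at 300-350 ms, higher
#' in women at 650-700 ms, parietal sites). Background activity is 1/f
#' (pink) noise plus slow drift; stereotyped frontal blinks occur at a
#' Poisson rate; independent high-amplitude artifact bursts hit a random
#' channel on about a third of trials, calibrated so that roughly 40 of
#' 60 target and 160 of 240 standard epochs survive the +/-75 uV
#' rejection.
#'
#' @param n_persons Cohort size.
#' @param n_female Number of female persons (the rest are male).
#' @param channels Channel labels (montage).
#' @param fs Sampling rate, Hz.
#' @param n_stimuli Stimuli per run.
#' @param p_target Target probability; `n_stimuli * p_target` must be an
#'   integer.
#' @param stim_duration_ms,isi_ms Stimulus duration and inter-stimulus
#'   interval, ms.
#' @param pad_s Padding before the first / after the last stimulus, s.
#' @param components Data frame with columns `name`, `latency_ms`,
#'   `width_ms`, `amplitude_uv`, `topography` (one of `frontal`,
#'   `central`, `parietal`, `occipital`).
#' @param p3_standard_scale P3 attenuation factor for standard stimuli.
#' @param gender_effects List of effects, each a list with `window_ms`
#'   (length 2), `channels` (labels), `delta_uv`, and `gender` (who gets
#'   the extra amplitude).
#' @param noise_sd_uv Background noise standard deviation, microvolts.
#' @param noise_exponent Spectral exponent of the 1/f^a background.
#' @param drift_sd_uv Slow drift amplitude, microvolts.
#' @param blink_rate_per_min Poisson blink rate.
#' @param blink_amplitude_uv Blink peak amplitude at Fp1/Fp2.
#' @param artifact_prob Per-trial probability of an injected
#'   high-amplitude artifact burst (drives trial dropout).
#' @param artifact_amplitude_uv Artifact burst peak amplitude.
#' @param amplitude_jitter_sd Per-person multiplicative component
#'   amplitude variability (lognormal sd on the log scale).
#' @param latency_jitter_sd_ms Per-person component latency variability.
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(n_persons = 20L, n_female = 10L,
                       channels = montage_32(), fs = 256,
                       n_stimuli = 300L, p_target = 0.2,
                       stim_duration_ms = 150, isi_ms = 1000, pad_s = 30,
                       components = default_components(),
                       p3_standard_scale = 0.25,
                       gender_effects = default_gender_effects(),
                       noise_sd_uv = 9, noise_exponent = 1,
                       drift_sd_uv = 3,
                       blink_rate_per_min = 10, blink_amplitude_uv = 110,
                       artifact_prob = 1 / 3, artifact_amplitude_uv = 120,
                       amplitude_jitter_sd = 0.15,
                       latency_jitter_sd_ms = 10) {
  if (p_target < 0 || p_target > 1) stop("p_target must be in [0, 1]", call. = FALSE)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  if (n_female < 0 || n_female > n_persons) {
    stop("n_female must be between 0 and n_persons", call. = FALSE)
  }
  structure(
    list(n_persons = as.integer(n_persons), n_female = as.integer(n_female),
         channels = channels, fs = fs, n_stimuli = as.integer(n_stimuli),
         p_target = p_target, stim_duration_ms = stim_duration_ms,
         isi_ms = isi_ms, pad_s = pad_s, components = components,
         p3_standard_scale = p3_standard_scale,
         gender_effects = gender_effects, noise_sd_uv = noise_sd_uv,
         noise_exponent = noise_exponent, drift_sd_uv = drift_sd_uv,
         blink_rate_per_min = blink_rate_per_min,
         blink_amplitude_uv = blink_amplitude_uv,
         artifact_prob = artifact_prob,
         artifact_amplitude_uv = artifact_amplitude_uv,
         amplitude_jitter_sd = amplitude_jitter_sd,
         latency_jitter_sd_ms = latency_jitter_sd_ms),
    class = "sim_config"
  )
}

#' Default evoked-component table
#'
#' Canonical visual oddball components: occipital N1 (~110 ms),
#' fronto-central P2 (~190 ms) and N2 (~250 ms), and a broad parietal P3
#' peaking around 420 ms.
#'
#' @return Data frame with one row per component.
#' @export
default_components <- function() {
  data.frame(
    name = c("N1", "P2", "N2", "P3"),
    latency_ms = c(110, 190, 250, 420),
    width_ms = c(20, 25, 30, 120),
    amplitude_uv = c(-4, 3, -3, 6),
    topography = c("occipital", "central", "central", "parietal")
  )
}

#' Default gender effects
#'
#' Two parietal boxcar amplitude offsets on the target response: +2 uV for
#' men at 300-350 ms and +2 uV for women at 650-700 ms (the reported
#' direction of the gender difference in the P3 window).
#'
#' @return List of effect descriptions.
#' @export
default_gender_effects <- function() {
  parietal <- c("CP1", "CP2", "P3", "Pz", "P4", "POz")
  list(
    list(window_ms = c(300, 350), channels = parietal, delta_uv = 2,
         gender = "male"),
    list(window_ms = c(650, 700), channels = parietal, delta_uv = 2,
         gender = "female")
  )
}

# smooth scalp weighting for a named topography, peaking at 1
.topography_weights <- function(channels, topography) {
  groups <- .channel_groups(channels)
  w <- stats::setNames(rep(0.05, length(channels)), channels)
  core <- groups[[topography]]
  w[core] <- 1
  neighbour <- switch(topography,
                      frontal = groups$central, central = unique(c(groups$frontal, groups$parietal)),
                      parietal = unique(c(groups$central, groups$occipital)),
                      occipital = groups$parietal)
  w[setdiff(neighbour, core)] <- 0.4
  w
}

#' Randomized oddball stimulus sequence
#'
#' Exactly `n_stimuli * p_target` target events and the remainder standard
#' events, in seeded random order, with onsets spaced by the stimulus
#' duration plus the inter-stimulus interval.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return An [event_table()].
#' @export
#' @examples
#' ev <- oddball_sequence(sim_config(), seed = 1)
#' table(ev$category)  # 240 standard, 60 target
oddball_sequence <- function(cfg = sim_config(), seed = 1L) {
  n_target <- cfg$n_stimuli * cfg$p_target
  if (abs(n_target - round(n_target)) > 1e-9) {
    stop("n_stimuli * p_target must be an integer", call. = FALSE)
  }
  n_target <- as.integer(round(n_target))
  set.seed(seed)
  cats <- sample(rep(c("target", "standard"),
                     c(n_target, cfg$n_stimuli - n_target)))
  spacing <- round((cfg$stim_duration_ms + cfg$isi_ms) / 1000 * cfg$fs)
  onsets <- round(cfg$pad_s * cfg$fs) + spacing * (seq_len(cfg$n_stimuli) - 1L) + 1L
  event_table(onsets, cats,
              stim_duration_ms = cfg$stim_duration_ms, isi_ms = cfg$isi_ms)
}

#' Evoked-response template for one category and gender
#'
#' Sum of Gaussian bumps `amplitude * topography * exp(-(t - latency)^2 /
#' (2 width^2))` over the components, evaluated on the epoch grid.
#' Standard stimuli carry an attenuated P3; gender effects (boxcar
#' amplitude offsets) are applied to the target template of the matching
#' gender.
#'
#' @param cfg A [sim_config()].
#' @param category `"standard"` or `"target"`.
#' @param gender `"female"` or `"male"`.
#' @param components Optional per-person jittered component table
#'   (defaults to `cfg$components`).
#' @param epoch_window_ms Grid window, ms.
#' @return Channels x timepoints matrix (microvolts) with the epoch grid
#'   times as attribute `"times"`.
#' @export
erp_template <- function(cfg = sim_config(), category = "target",
                         gender = "female", components = NULL,
                         epoch_window_ms = c(-100, 1000)) {
  category <- match.arg(category, c("standard", "target"))
  .assert_gender(gender)
  comp <- components %||% cfg$components
  grid <- epoch_grid_indices(epoch_window_ms, cfg$fs)
  times <- grid * 1000 / cfg$fs
  d <- length(cfg$channels)
  out <- matrix(0, d, length(times), dimnames = list(cfg$channels, NULL))
  for (i in seq_len(nrow(comp))) {
    amp <- comp$amplitude_uv[i]
    if (comp$name[i] == "P3" && category == "standard") {
      amp <- amp * cfg$p3_standard_scale
    }
    bump <- amp * exp(-(times - comp$latency_ms[i])^2 / (2 * comp$width_ms[i]^2))
    w <- .topography_weights(cfg$channels, comp$topography[i])
    out <- out + outer(w, bump)
  }
  if (category == "target") {
    for (eff in cfg$gender_effects) {
      if (!all(eff$window_ms >= epoch_window_ms[1] &
               eff$window_ms <= epoch_window_ms[2])) {
        stop("gender effect window outside the epoch window", call. = FALSE)
      }
      if (eff$gender == gender) {
        sel <- times >= eff$window_ms[1] & times < eff$window_ms[2]
        ch <- intersect(eff$channels, cfg$channels)
        out[ch, sel] <- out[ch, sel] + eff$delta_uv
      }
    }
  }
  attr(out, "times") <- times
  out
}

# 1/f^a noise, one channel per row, scaled to sd target_sd; all channels
# synthesized with one column-wise inverse FFT (random phases, shaped
# amplitude spectrum, Hermitian symmetry)
.pink_noise <- function(n_channels, n_samples, exponent, target_sd, fs) {
  nf <- as.integer(floor((n_samples - 1) / 2))   # bins strictly below Nyquist
  freqs <- seq_len(nf)
  shape <- (freqs / n_samples * fs)^(-exponent / 2)
  ph <- matrix(stats::runif(nf * n_channels, 0, 2 * pi), nf)
  re <- shape * cos(ph)                  # shape recycles down the columns
  im <- shape * sin(ph)
  full <- matrix(0 + 0i, n_samples, n_channels)
  full[freqs + 1L, ] <- complex(real = re, imaginary = im)
  full[n_samples + 1L - freqs, ] <- complex(real = re, imaginary = -im)
  x <- Re(stats::mvfft(full, inverse = TRUE))
  sds <- sqrt(pmax(colMeans(x * x) - colMeans(x)^2, .Machine$double.eps))
  t(x) * (target_sd / sds)               # rows = channels, scaled per channel
}

# gaussian bump patch: list(idx, patch) to add onto a channels x samples
# matrix (applied by the caller so the addition stays in place)
.bump_patch <- function(n, center, width_samples, amplitude, weights) {
  lo <- max(1L, as.integer(floor(center - 4 * width_samples)))
  hi <- min(n, as.integer(ceiling(center + 4 * width_samples)))
  if (lo > hi) return(NULL)
  idx <- lo:hi
  bump <- amplitude * exp(-(idx - center)^2 / (2 * width_samples^2))
  list(idx = idx, patch = outer(weights, bump))
}

#' Simulate one continuous oddball EEG recording
#'
#' Places the per-category evoked templates at the event onsets and adds
#' 1/f background noise, slow drift, Poisson-timed stereotyped frontal
#' blinks, and per-trial high-amplitude artifact bursts (the trial
#' dropout mechanism). The recording length is padded to whole seconds.
#'
#' @param cfg A [sim_config()].
#' @param events An [event_table()] (e.g. from [oddball_sequence()]).
#' @param gender Person gender (selects the effect-carrying template).
#' @param person_id Identifier for the output recording.
#' @param seed Integer seed.
#' @param components Optional per-person jittered component table.
#' @return A [recording()].
#' @export
simulate_recording <- function(cfg = sim_config(), events, gender = "female",
                               person_id = "sim", seed = 1L,
                               components = NULL) {
  set.seed(seed)
  d <- length(cfg$channels)
  fs <- cfg$fs
  last <- max(events$onset_sample)
  n <- as.integer(ceiling((last + fs + cfg$pad_s * fs) / fs) * fs)
  grid <- epoch_grid_indices(c(-100, 1000), fs)

  tmpl <- list(
    standard = erp_template(cfg, "standard", gender, components),
    target = erp_template(cfg, "target", gender, components)
  )
  data <- matrix(0, d, n, dimnames = list(cfg$channels, NULL))
  for (j in seq_len(nrow(events))) {
    idx <- events$onset_sample[j] + grid
    keep <- idx >= 1L & idx <= n
    data[, idx[keep]] <- data[, idx[keep]] +
      tmpl[[as.character(events$category[j])]][, keep, drop = FALSE]
  }

  if (cfg$noise_sd_uv > 0) {
    data <- data + .pink_noise(d, n, cfg$noise_exponent, cfg$noise_sd_uv, fs)
  }
  if (cfg$drift_sd_uv > 0) {
    # slow drift: few very-low-frequency sinusoids per channel
    tt <- seq_len(n) / fs
    for (ch in seq_len(d)) {
      f1 <- stats::runif(1, 0.003, 0.02)
      f2 <- stats::runif(1, 0.003, 0.02)
      data[ch, ] <- data[ch, ] + cfg$drift_sd_uv *
        (sin(2 * pi * f1 * tt + stats::runif(1, 0, 2 * pi)) +
         0.5 * sin(2 * pi * f2 * tt + stats::runif(1, 0, 2 * pi)))
    }
  }
  if (cfg$blink_rate_per_min > 0 && cfg$blink_amplitude_uv != 0) {
    n_blinks <- stats::rpois(1, cfg$blink_rate_per_min * n / fs / 60)
    blink_w <- stats::setNames(rep(0, d), cfg$channels)
    blink_w[intersect(c("Fp1", "Fpz", "Fp2"), cfg$channels)] <- 1
    blink_w[intersect(c("F7", "F3", "Fz", "F4", "F8"), cfg$channels)] <- 0.45
    blink_w[intersect(c("FC5", "FC1", "FC2", "FC6"), cfg$channels)] <- 0.15
    width <- 0.06 * fs                     # ~60 ms
    for (b in seq_len(n_blinks)) {
      center <- stats::runif(1, 1, n)
      amp <- cfg$blink_amplitude_uv * stats::runif(1, 0.7, 1.3)
      bp <- .bump_patch(n, center, width, amp, blink_w)
      if (!is.null(bp)) data[, bp$idx] <- data[, bp$idx] + bp$patch
    }
  }
  if (cfg$artifact_prob > 0) {
    hit <- stats::runif(nrow(events)) < cfg$artifact_prob
    width <- 0.06 * fs
    for (j in which(hit)) {
      ch <- sample.int(d, 1)
      w <- rep(0, d)
      w[ch] <- 1
      center <- events$onset_sample[j] + stats::runif(1, 0.05, 0.85) * fs
      amp <- sample(c(-1, 1), 1) * cfg$artifact_amplitude_uv *
        stats::runif(1, 1, 1.4)
      bp <- .bump_patch(n, center, width, amp, w)
      if (!is.null(bp)) data[, bp$idx] <- data[, bp$idx] + bp$patch
    }
  }
  recording(data, cfg$channels, fs, person_id, gender)
}

# per-person jittered copy of the component table
.jitter_components <- function(cfg) {
  comp <- cfg$components
  comp$amplitude_uv <- comp$amplitude_uv *
    exp(stats::rnorm(nrow(comp), 0, cfg$amplitude_jitter_sd))
  comp$latency_ms <- comp$latency_ms +
    stats::rnorm(nrow(comp), 0, cfg$latency_jitter_sd_ms)
  comp
}

#' Simulate a full cohort of raw recordings
#'
#' Generates `n_persons` recordings with per-person random component
#' amplitude/latency jitter (individual differences) and the configured
#' gender effects. Per-person seeds are derived deterministically from the
#' master seed, so the whole cohort is reproducible.
#'
#' @param cfg A [sim_config()].
#' @param seed Master integer seed.
#' @return List of per-person lists with elements `recording`, `events`,
#'   `gender`.
#' @export
simulate_cohort <- function(cfg = sim_config(), seed = 1L) {
  set.seed(seed)
  person_seeds <- sample.int(2^31 - 2, 2L * cfg$n_persons)
  genders <- rep(c("female", "male"), c(cfg$n_female, cfg$n_persons - cfg$n_female))
  ids <- sprintf("s%02d", seq_len(cfg$n_persons))
  lapply(seq_len(cfg$n_persons), function(p) {
    events <- oddball_sequence(cfg, seed = person_seeds[2L * p - 1L])
    set.seed(person_seeds[2L * p])
    comp <- .jitter_components(cfg)
    rec <- simulate_recording(cfg, events, gender = genders[p],
                              person_id = ids[p],
                              seed = person_seeds[2L * p], components = comp)
    list(recording = rec, events = events, gender = genders[p])
  })
}

#' Preprocess a simulated cohort into difference waveforms
#'
#' Convenience wrapper: [preprocess_person()] applied to every member of a
#' [simulate_cohort()] result.
#'
#' @param raw_cohort A [simulate_cohort()] result.
#' @param cfg A [preprocess_config()].
#' @param verbose Forwarded to [preprocess_person()].
#' @return An [cohort_dataset()].
#' @export
preprocess_cohort <- function(raw_cohort, cfg = preprocess_config(),
                              verbose = FALSE) {
  cohort_dataset(lapply(raw_cohort, function(m) {
    preprocess_person(m$recording, m$events, cfg, verbose = verbose)
  }))
}

#' Simulate a cohort directly at the difference-waveform level
#'
#' Fast generative shortcut that emulates the output of the preprocessing
#' chain: for each person, the target minus standard template difference
#' (with per-person component jitter and gender effects) plus band-limited
#' 1/f residual noise at the level expected after averaging about 40
#' target and 160 standard trials. Useful for calibration studies of the
#' classification stack where the continuous stage is not under test.
#'
#' @param cfg A [sim_config()].
#' @param seed Master integer seed.
#' @param n_target,n_standard Trial counts assumed for the residual-noise
#'   level (`sd = noise_sd_uv * sqrt(1/n_target + 1/n_standard)`).
#' @return An [cohort_dataset()].
#' @export
simulate_erp_cohort <- function(cfg = sim_config(), seed = 1L,
                                n_target = 40, n_standard = 160) {
  set.seed(seed)
  person_seeds <- sample.int(2^31 - 2, cfg$n_persons)
  genders <- rep(c("female", "male"), c(cfg$n_female, cfg$n_persons - cfg$n_female))
  ids <- sprintf("s%02d", seq_len(cfg$n_persons))
  resid_sd <- cfg$noise_sd_uv * sqrt(1 / n_target + 1 / n_standard)
  cohort_dataset(lapply(seq_len(cfg$n_persons), function(p) {
    set.seed(person_seeds[p])
    comp <- .jitter_components(cfg)
    tgt <- erp_template(cfg, "target", genders[p], comp)
    std <- erp_template(cfg, "standard", genders[p], comp)
    times <- attr(tgt, "times")
    diffm <- tgt - std +
      .pink_noise(nrow(tgt), ncol(tgt), cfg$noise_exponent, resid_sd, cfg$fs)
    difference_erp(diffm, times, ids[p], genders[p])
  }))
}
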