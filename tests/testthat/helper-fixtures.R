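# Shared fixtures and brute-force oracles, built in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

study_times <- function() (-25:255) * 1000 / 256

# tiny simulation configuration for fast plumbing tests (NOT the study
# conditions; calibration tests use sim_config() defaults)
tiny_sim_cfg <- function(n_persons = 4L, n_female = 2L, ...) {
  sim_config(n_persons = n_persons, n_female = n_female,
             n_stimuli = 60L, pad_s = 5, ...)
}

# cohort of difference waveforms with a large, clean gender separation
# (constant offset on every channel), trivially decodable
separable_cohort <- function(n_per_gender = 3L, d = 6L, offset = 10) {
  times <- study_times()
  erps <- list()
  idx <- 1L
  for (g in c("female", "male")) {
    s <- if (g == "female") offset else -offset
    for (j in seq_len(n_per_gender)) {
      erps[[idx]] <- difference_erp(
        matrix(s, d, length(times)) + matrix(rnorm(d * length(times), 0, 0.01),
                                             d),
        times, sprintf("%s%02d", substr(g, 1, 1), j), g)
      idx <- idx + 1L
    }
  }
  cohort_dataset(erps)
}

# random difference-ERP cohort with NO gender structure
noise_cohort <- function(n_per_gender = 3L, d = 4L, sd = 1) {
  times <- study_times()
  erps <- list()
  idx <- 1L
  for (g in c("female", "male")) {
    for (j in seq_len(n_per_gender)) {
      erps[[idx]] <- difference_erp(matrix(rnorm(d * length(times), 0, sd), d),
                                    times, sprintf("%s%02d", substr(g, 1, 1), j),
                                    g)
      idx <- idx + 1L
    }
  }
  cohort_dataset(erps)
}

# brute-force oracles for the vote aggregation layer
oracle_vote <- function(labels, tie_break = "female") {
  nf <- sum(labels == "female")
  nm <- sum(labels == "male")
  if (nf > nm) "female" else if (nm > nf) "male" else tie_break
}

oracle_rate <- function(labels, truth) sum(labels == truth) / length(labels)

# permute the gender labels of a cohort (balance preserved)
permute_genders <- function(cohort) {
  erps <- unclass(cohort)
  g <- sample(vapply(erps, `[[`, "", "gender"))
  cohort_dataset(lapply(seq_along(erps), function(i) {
    e <- erps[[i]]
    difference_erp(e$data, e$times, e$person_id, g[i])
  }))
}
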