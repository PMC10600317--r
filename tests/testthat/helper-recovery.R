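# Shared parameter-recovery harness: simulate modest cohorts with known
# coefficients and no random effects, fit each observation family with the
# generating design, and report Wald 95% interval coverage indicators.

recovery_config <- function() {
  sim_config(
    n_participants = 20L,
    rhythms = test_rhythm_set(12L),
    n_sets = 4L,
    repetitions = 2L,
    beta_prob = c(
      intercept = -1.2, cue = 2,
      proj_cent = 0.4, "cue:proj_cent" = -0.2,
      markov2 = 0.3, "cue:markov2" = -0.27
    ),
    sd_participant = 0, sd_rhythm = 0,
    sd_participant_cue = 0, sd_rhythm_cue = 0,
    vel_participant_sd = 0,
    vel_mean = 85, vel_sd = 25, vel_cue = 2,
    delta_mean_cued = -9, delta_mean_uncued = 4.8, delta_sd = 40,
    p_double = 0
  )
}

# Build the joined observation table for one simulated cohort (window
# assignment only; the accuracy metric is not needed for recovery).
recovery_observations <- function(cfg, seed) {
  sim <- simulate_cohort(cfg, seed = seed)
  taps <- sim$taps
  rmap <- stats::setNames(cfg$rhythms, vapply(cfg$rhythms, function(r) r$id, character(1)))
  key <- interaction(taps$participant, taps$rhythm_id, taps$perf_num, drop = TRUE)
  obs <- do.call(rbind, lapply(levels(key), function(kk) {
    sub <- taps[key == kk, , drop = FALSE]
    r <- rmap[[as.character(sub$rhythm_id[1L])]]
    a <- assign_taps_to_pulses(sub$t_ms, sub$velocity, cfg$n_slots, cfg$ioi_ms)
    slot_n <- (sub$start_cue[1L] + a$slot) %% r$n_pulses
    data.frame(
      participant = sub$participant[1L], rhythm_id = sub$rhythm_id[1L],
      perf_num = sub$perf_num[1L], n = slot_n,
      cued = r$indicator[slot_n + 1L],
      tapped = a$tapped, velocity = a$velocity, delta = a$delta,
      stringsAsFactors = FALSE
    )
  }))
  pf <- pulse_features(cfg$rhythms)
  list(
    obs = merge(obs, pf, by = c("rhythm_id", "n"), sort = FALSE),
    truth = sim$truth
  )
}

# covered: |estimate - truth| <= 1.96 se, per coefficient
wald_covered <- function(fit, true_coefs) {
  nm <- names(true_coefs)
  abs(fit$coefficients[nm] - true_coefs) <= 1.96 * fit$se[nm]
}

recover_binomial <- function(cfg, seed) {
  ro <- recovery_observations(cfg, seed)
  obs <- ro$obs
  counts <- stats::aggregate(
    list(tap_num = obs$tapped, n_pulses = rep(1L, nrow(obs))),
    by = obs[, c("participant", "rhythm_id", "perf_num", "n")],
    FUN = sum
  )
  counts <- merge(counts, pulse_features(cfg$rhythms),
    by = c("rhythm_id", "n"), sort = FALSE
  )
  design <- build_design(counts,
    response = c("tap_num", "n_pulses"),
    pulse_predictors = c("proj_cent", "markov2"),
    standardization = ro$truth$feature_standardization
  )
  fit <- fit_binomial_logit(design)
  truth <- ro$truth$beta_prob
  names(truth)[names(truth) == "intercept"] <- "intercept"
  wald_covered(fit, truth)
}

recover_censored <- function(cfg, seed) {
  ro <- recovery_observations(cfg, seed)
  tapped <- ro$obs[ro$obs$tapped == 1L, ]
  tapped$tap_vel <- tapped$velocity
  design <- build_design(tapped,
    response = "tap_vel",
    pulse_predictors = character(0), cue = "cue"
  )
  fit <- fit_censored_normal(design)
  sc <- design$response_scale
  truth <- c(intercept = cfg$vel_mean / sc, cue = cfg$vel_cue / sc)
  wald_covered(fit, truth)
}

recover_truncated <- function(cfg, seed) {
  ro <- recovery_observations(cfg, seed)
  tapped <- ro$obs[ro$obs$tapped == 1L, ]
  tapped$tap_delta <- tapped$delta
  design <- build_design(tapped,
    response = "tap_delta",
    pulse_predictors = character(0), cue = "cue"
  )
  fit <- fit_truncated_normal(design)
  sc <- design$response_scale
  truth <- c(
    intercept = cfg$delta_mean_uncued / sc,
    cue = (cfg$delta_mean_cued - cfg$delta_mean_uncued) / sc
  )
  wald_covered(fit, truth)
}

# Beta-family recovery simulates directly from the beta GLM.
recover_beta <- function(seed, n = 400L) {
  set.seed(seed)
  true_beta <- c(intercept = 0.5, x1 = 0.3, x2 = -0.2)
  phi <- 30
  dat <- data.frame(x1 = stats::rnorm(n), x2 = stats::rnorm(n))
  # standardized columns as build_design will produce them
  z1 <- (dat$x1 - mean(dat$x1)) / stats::sd(dat$x1)
  z2 <- (dat$x2 - mean(dat$x2)) / stats::sd(dat$x2)
  mu <- stats::plogis(true_beta[1] + true_beta[2] * z1 + true_beta[3] * z2)
  dat$tap_acc <- stats::rbeta(n, mu * phi, (1 - mu) * phi)
  design <- build_design(dat,
    response = "tap_acc",
    predictors = c("x1", "x2"), cue = NULL
  )
  fit <- fit_beta_accuracy(design)
  wald_covered(fit, true_beta)
}
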