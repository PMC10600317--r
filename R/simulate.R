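#' Simulation configuration for synthetic tapping cohorts
#'
#' Builds the configuration for [simulate_cohort()] /
#' [simulate_performance()]. The defaults mirror the design of the tapping
#' experiment the package models: 111 participants, the 91-rhythm universe
#' split into four disjoint sets (23, 23, 23, 22), each participant assigned
#' one set and performing every rhythm in it twice (in two blocks, random
#' order within block), 30-s performances of 129 pulses at a 234-ms
#' interonset interval, a randomized starting cue, MIDI velocities censored
#' at 127, and occasional double taps about 15 or 60 ms after a genuine tap.
#'
#' Tap occurrence follows a logistic model on standardized pulse/rhythm
#' features: `logit P(tap) = beta . x + u_participant + u_rhythm +
#' (v_participant + v_rhythm) * cue`. Coefficient defaults are illustrative
#' of the regimes reported for real tapping (cue around 2 on the log-odds
#' scale, modest feature effects), not estimates. Given a tap, the signed
#' asynchrony is normal truncated to half a window each side with a cued
#' mean of -9 ms and an uncued mean of +4.8 ms, and the velocity is normal,
#' rounded, and censored to the MIDI range 1-127.
#'
#' @param n_participants cohort size (default 111).
#' @param rhythms rhythm universe (default [enumerate_wf_rhythms()]).
#' @param n_sets number of disjoint rhythm sets (default 4).
#' @param repetitions performances of each assigned rhythm (default 2).
#' @param beta_prob named log-odds coefficients for tap probability. Names:
#'   `intercept`, `cue`, any pulse/rhythm feature column of
#'   [pulse_features()] / [rhythm_features()], and `cue:<feature>`
#'   interactions. Features are standardized over the cohort's pulse table.
#' @param sd_participant,sd_rhythm random-intercept SDs (log-odds).
#' @param sd_participant_cue,sd_rhythm_cue random cue-effect SDs (log-odds).
#' @param vel_mean,vel_sd velocity mean and SD in MIDI units; `vel_cue`
#'   added on cued pulses; `vel_participant_sd` between-participant SD.
#' @param delta_mean_cued,delta_mean_uncued,delta_sd asynchrony model in ms.
#' @param p_double probability a kept tap spawns a double tap.
#' @param double_offsets_ms candidate double-tap offsets (default 15 and 60).
#' @param n_slots,ioi_ms performance geometry (129 pulses, 234 ms).
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_participants = 111L,
                       rhythms = enumerate_wf_rhythms(),
                       n_sets = 4L,
                       repetitions = 2L,
                       beta_prob = c(
                         intercept = -1.2, cue = 2,
                         proj_cent = 0.4, "cue:proj_cent" = -0.2,
                         markov2 = 0.3, "cue:markov2" = -0.27
                       ),
                       sd_participant = 0.5,
                       sd_rhythm = 0.5,
                       sd_participant_cue = 0.78,
                       sd_rhythm_cue = 0.96,
                       vel_mean = 85,
                       vel_sd = 25,
                       vel_cue = 2,
                       vel_participant_sd = 21.7,
                       delta_mean_cued = -9,
                       delta_mean_uncued = 4.8,
                       delta_sd = 40,
                       p_double = 0.034,
                       double_offsets_ms = c(15, 60),
                       n_slots = 129L,
                       ioi_ms = 234) {
  stopifnot(
    n_participants >= 1L, length(rhythms) >= 1L,
    p_double >= 0, p_double <= 1,
    sd_participant >= 0, sd_rhythm >= 0,
    sd_participant_cue >= 0, sd_rhythm_cue >= 0,
    vel_sd >= 0, delta_sd >= 0
  )
  if (!("intercept" %in% names(beta_prob))) {
    stop("beta_prob must name an 'intercept' coefficient", call. = FALSE)
  }
  cfg <- list(
    n_participants = as.integer(n_participants),
    rhythms = rhythms,
    n_sets = as.integer(n_sets),
    repetitions = as.integer(repetitions),
    beta_prob = beta_prob,
    sd_participant = sd_participant,
    sd_rhythm = sd_rhythm,
    sd_participant_cue = sd_participant_cue,
    sd_rhythm_cue = sd_rhythm_cue,
    vel_mean = vel_mean, vel_sd = vel_sd, vel_cue = vel_cue,
    vel_participant_sd = vel_participant_sd,
    delta_mean_cued = delta_mean_cued,
    delta_mean_uncued = delta_mean_uncued,
    delta_sd = delta_sd,
    p_double = p_double,
    double_offsets_ms = double_offsets_ms,
    n_slots = as.integer(n_slots),
    ioi_ms = ioi_ms
  )
  class(cfg) <- "sim_config"
  cfg
}

# standardized pulse-level design for the simulator: one row per
# (rhythm, pulse) with the linear-predictor features standardized across the
# table (binary cue left as is). Returns list(eta_parts, std).
sim_linear_predictor <- function(cfg) {
  pf <- pulse_features(cfg$rhythms)
  rf <- rhythm_features(cfg$rhythms)
  tab <- merge(pf, rf, by.x = "rhythm_id", by.y = "id", sort = FALSE)
  tab <- tab[order(match(tab$rhythm_id, vapply(cfg$rhythms, function(r) r$id, character(1))), tab$n), ]
  nm <- names(cfg$beta_prob)
  feats <- setdiff(nm, "intercept")
  base_feats <- unique(sub("^cue:", "", feats))
  std <- list()
  eta <- rep(cfg$beta_prob[["intercept"]], nrow(tab))
  for (f in base_feats) {
    if (f == "cue") {
      x <- tab$cue
    } else {
      if (!f %in% names(tab)) stop("unknown simulator feature: ", f, call. = FALSE)
      x <- tab[[f]]
      if (!all(x %in% c(0, 1))) {
        mu <- mean(x)
        sd_ <- stats::sd(x)
        std[[f]] <- c(center = mu, scale = sd_)
        x <- (x - mu) / sd_
      }
    }
    if (f %in% nm) eta <- eta + cfg$beta_prob[[f]] * x
    intn <- paste0("cue:", f)
    if (intn %in% nm && f != "cue") eta <- eta + cfg$beta_prob[[intn]] * (tab$cue * x)
  }
  list(tab = tab, eta = eta, std = std)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(
    n,
    stats::pnorm(lo, mean, sd),
    stats::pnorm(hi, mean, sd)
  )
  stats::qnorm(u, mean, sd)
}

#' Simulate one tapping performance
#'
#' Generates the taps of one participant's 30-s rendition of one rhythm
#' under the configured observation model. Uses the current RNG state; seed
#' management belongs to the caller (see [simulate_cohort()]).
#'
#' @param cfg a [sim_config()].
#' @param rhythm a [rhythm()] from `cfg$rhythms`.
#' @param start_cue pulse index of the first sounded cue, or `NULL` to pick
#'   one of the rhythm's cues at random.
#' @param u_intercept,u_cue participant/rhythm random-effect offsets added to
#'   the intercept and the cue effect (default 0).
#' @param vel_offset participant velocity offset in MIDI units (default 0).
#' @param eta optional precomputed per-pulse log-odds for this rhythm
#'   (length `N`, from the cohort-level standardization); when `NULL` the
#'   features are standardized over this rhythm alone.
#' @return a data.frame of taps with columns `t_ms` and `velocity`, plus
#'   attributes `start_cue` and `n_double` (injected double taps).
#' @export
simulate_performance <- function(cfg, rhythm, start_cue = NULL,
                                 u_intercept = 0, u_cue = 0,
                                 vel_offset = 0, eta = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(rhythm, "rhythm"))
  n <- rhythm$n_pulses
  cues <- cue_positions(rhythm)
  if (is.null(start_cue)) {
    start_cue <- cues[sample.int(length(cues), 1L)]
  }
  if (!rhythm$indicator[start_cue + 1L]) {
    stop("start_cue must index a cued pulse", call. = FALSE)
  }
  if (is.null(eta)) {
    one <- cfg
    one$rhythms <- list(rhythm)
    eta <- sim_linear_predictor(one)$eta
  }
  slots <- seq_len(cfg$n_slots) - 1L
  pos <- (start_cue + slots) %% n
  cued <- rhythm$indicator[pos + 1L]
  lp <- eta[pos + 1L] + u_intercept + u_cue * cued
  tapped <- stats::runif(cfg$n_slots) < stats::plogis(lp)
  idx <- which(tapped)
  if (length(idx) == 0L) {
    out <- data.frame(t_ms = numeric(0), velocity = numeric(0))
    attr(out, "start_cue") <- start_cue
    attr(out, "n_double") <- 0L
    return(out)
  }
  half <- cfg$ioi_ms / 2
  mu_d <- ifelse(cued[idx] == 1L, cfg$delta_mean_cued, cfg$delta_mean_uncued)
  delta <- rtruncnorm1(length(idx), mu_d, cfg$delta_sd, -half, half)
  t_ms <- (idx - 1L) * cfg$ioi_ms + delta
  vel_mu <- cfg$vel_mean + vel_offset + cfg$vel_cue * cued[idx]
  vel <- round(stats::rnorm(length(idx), vel_mu, cfg$vel_sd))
  vel <- pmin(pmax(vel, 1), 127)
  dbl <- stats::runif(length(idx)) < cfg$p_double
  n_dbl <- sum(dbl)
  if (n_dbl > 0L) {
    off <- sample(cfg$double_offsets_ms, n_dbl, replace = TRUE)
    t2 <- t_ms[dbl] + off
    v2 <- pmin(pmax(round(vel[dbl] * stats::runif(n_dbl, 0.3, 0.7)), 1), 127)
    t_ms <- c(t_ms, t2)
    vel <- c(vel, v2)
  }
  ord <- order(t_ms)
  out <- data.frame(t_ms = t_ms[ord], velocity = vel[ord])
  attr(out, "start_cue") <- start_cue
  attr(out, "n_double") <- n_dbl
  out
}

#' Simulate a full tapping cohort
#'
#' Assigns each participant to one of the disjoint rhythm sets, draws the
#' participant/rhythm random effects, and simulates every performance
#' (each assigned rhythm `repetitions` times, block order randomized as in
#' the experimental procedure). A single seeded generator drives the whole
#' cohort, so the same `seed` and configuration reproduce the output
#' exactly.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return a list with `taps` (tap-log data.frame: `participant`,
#'   `rhythm_id`, `perf_num`, `repetition`, `start_cue`, `t_ms`, `velocity`)
#'   and `truth` (the generating parameters: the config scalars, the
#'   standardized-scale coefficient vector, the feature standardization
#'   record, per-participant and per-rhythm random effects, and the total
#'   injected double-tap count).
#' @export
simulate_cohort <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  ids <- vapply(cfg$rhythms, function(r) r$id, character(1))
  sets <- split(seq_along(ids), rep(seq_len(cfg$n_sets), length.out = length(ids)))
  lp <- sim_linear_predictor(cfg)
  eta_by_rhythm <- split(lp$eta, lp$tab$rhythm_id)[ids]
  names(eta_by_rhythm) <- ids

  u_p <- stats::rnorm(cfg$n_participants, 0, cfg$sd_participant)
  v_p <- stats::rnorm(cfg$n_participants, 0, cfg$sd_participant_cue)
  u_r <- stats::rnorm(length(ids), 0, cfg$sd_rhythm)
  v_r <- stats::rnorm(length(ids), 0, cfg$sd_rhythm_cue)
  w_p <- stats::rnorm(cfg$n_participants, 0, cfg$vel_participant_sd)

  rows <- vector("list", cfg$n_participants)
  n_double <- 0L
  for (p in seq_len(cfg$n_participants)) {
    set_id <- ((p - 1L) %% cfg$n_sets) + 1L
    assigned <- sets[[set_id]]
    perf <- 0L
    prows <- list()
    for (rep_i in seq_len(cfg$repetitions)) {
      order_i <- sample(assigned) # random order within each block pass
      for (ri in order_i) {
        perf <- perf + 1L
        r <- cfg$rhythms[[ri]]
        tp <- simulate_performance(
          cfg, r,
          u_intercept = u_p[p] + u_r[ri],
          u_cue = v_p[p] + v_r[ri],
          vel_offset = w_p[p],
          eta = eta_by_rhythm[[r$id]]
        )
        n_double <- n_double + attr(tp, "n_double")
        if (nrow(tp) > 0L) {
          prows[[length(prows) + 1L]] <- data.frame(
            participant = p,
            rhythm_id = r$id,
            perf_num = perf,
            repetition = rep_i,
            start_cue = attr(tp, "start_cue"),
            t_ms = tp$t_ms,
            velocity = tp$velocity,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    rows[[p]] <- do.call(rbind, prows)
  }
  taps <- do.call(rbind, rows)
  rownames(taps) <- NULL
  truth <- list(
    seed = seed,
    beta_prob = cfg$beta_prob,
    feature_standardization = lp$std,
    sd_participant = cfg$sd_participant,
    sd_rhythm = cfg$sd_rhythm,
    sd_participant_cue = cfg$sd_participant_cue,
    sd_rhythm_cue = cfg$sd_rhythm_cue,
    vel_mean = cfg$vel_mean, vel_sd = cfg$vel_sd, vel_cue = cfg$vel_cue,
    delta_mean_cued = cfg$delta_mean_cued,
    delta_mean_uncued = cfg$delta_mean_uncued,
    delta_sd = cfg$delta_sd,
    p_double = cfg$p_double,
    n_double = n_double,
    u_participant = u_p, u_rhythm = u_r,
    v_participant = v_p, v_rhythm = v_r,
    vel_offsets = w_p
  )
  list(taps = taps, truth = truth)
}
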