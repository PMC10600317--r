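#' Tap-performance scoring
#'
#' Converts raw tap logs (tap times in ms and MIDI velocities) into the four
#' dependent variables of the tapping analysis: a performance-level accuracy
#' score, and per-pulse tap occurrence, velocity and signed asynchrony.
#'
#' A performance presents `n_pulses` isochronous pulses at a fixed
#' interonset interval (234 ms, 129 pulses for a 30-s rendition). Each tap
#' belongs to the pulse whose centred window (half an interval each side)
#' contains it; the windows tile time, so every tap inside the performance
#' span lands in exactly one window.
#'
#' @name tap-metrics
NULL

#' Assign taps to pulse windows
#'
#' Assigns every tap to the pulse whose 234-ms window (from halfway to the
#' previous pulse to halfway to the next) contains it. When a window holds
#' several taps, the one with the most accurate timing (smallest absolute
#' asynchrony, ties to the earlier tap) is kept and the rest are discarded.
#' Taps before the first window or after the last are dropped and counted.
#'
#' @param t_ms tap times in ms from the first pulse (numeric).
#' @param velocity tap velocities (same length as `t_ms`), MIDI 1-127.
#' @param n_slots number of pulses sounded (default 129, a 30-s performance).
#' @param ioi_ms pulse interonset interval in ms (default 234).
#' @return a data.frame with one row per pulse slot `i = 0..n_slots-1`:
#'   `slot`, `tapped` (0/1), `velocity` (NA when untapped), `delta` (signed
#'   asynchrony in ms, NA when untapped), `tap_lag1` (whether the previous
#'   slot was tapped). Attributes `n_discarded` (extra taps dropped from
#'   multiply-hit windows) and `n_out_of_range` record losses.
#' @export
assign_taps_to_pulses <- function(t_ms, velocity, n_slots = 129L,
                                  ioi_ms = 234) {
  stopifnot(length(t_ms) == length(velocity))
  half <- ioi_ms / 2
  slot <- floor((t_ms + half) / ioi_ms)
  in_range <- slot >= 0 & slot < n_slots
  n_out <- sum(!in_range)
  t_ms <- t_ms[in_range]
  velocity <- velocity[in_range]
  slot <- slot[in_range]
  delta <- t_ms - slot * ioi_ms

  tapped <- integer(n_slots)
  vel <- rep(NA_real_, n_slots)
  del <- rep(NA_real_, n_slots)
  n_disc <- 0L
  if (length(slot) > 0L) {
    # earlier taps first so that ties in |delta| keep the earlier tap
    ord <- order(slot, abs(delta), t_ms)
    keep <- !duplicated(slot[ord])
    kept <- ord[keep]
    n_disc <- length(slot) - length(kept)
    tapped[slot[kept] + 1L] <- 1L
    vel[slot[kept] + 1L] <- velocity[kept]
    del[slot[kept] + 1L] <- delta[kept]
  }
  out <- data.frame(
    slot = seq_len(n_slots) - 1L,
    tapped = tapped,
    velocity = vel,
    delta = del,
    tap_lag1 = c(0L, tapped[-n_slots])
  )
  attr(out, "n_discarded") <- n_disc
  attr(out, "n_out_of_range") <- n_out
  out
}

# Gaussian smoothing of a regularly sampled series (zero-padded, linear).
gauss_smooth <- function(x, sigma, resolution = 1) {
  hw <- max(1L, ceiling(8 * sigma / resolution))
  tt <- seq(-hw, hw) * resolution
  kern <- exp(-tt^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  n <- length(x)
  padded <- c(numeric(hw), x, numeric(hw))
  sm <- stats::filter(padded, kern, sides = 2)
  as.numeric(sm[(hw + 1L):(hw + n)])
}

#' Performance tap accuracy
#'
#' The cosine similarity between Gaussian-smoothed indicator time series of
#' the taps and of the cues, both at 1-ms resolution with a 10-ms smoothing
#' standard deviation. The score lives in `[0, 1]`: it is 1 when every cue
#' is tapped exactly on time and nothing else is tapped, and it penalizes
#' missed cues, spurious taps and mistimed taps alike, including a constant
#' asynchrony. With `factor_out_offset = TRUE` the score is maximized over a
#' constant shift of the tap train (grid search over one window width at the
#' metric's resolution).
#'
#' @param tap_ms tap times in ms (may be empty: accuracy is then 0).
#' @param cue_ms cue times in ms (nonempty).
#' @param sigma_ms smoothing standard deviation in ms (default 10).
#' @param resolution_ms sampling resolution in ms (default 1).
#' @param factor_out_offset maximize over a constant tap-train shift
#'   (default `FALSE`).
#' @return a single number in `[0, 1]`.
#' @export
tap_accuracy <- function(tap_ms, cue_ms, sigma_ms = 10, resolution_ms = 1,
                         factor_out_offset = FALSE) {
  stopifnot(length(cue_ms) > 0L)
  if (length(tap_ms) == 0L) return(0)
  pad <- ceiling(8 * sigma_ms) + 117
  t0 <- min(c(tap_ms, cue_ms)) - pad
  t1 <- max(c(tap_ms, cue_ms)) + pad
  grid <- seq(t0, t1, by = resolution_ms)
  nbin <- length(grid)
  bin <- function(t) {
    idx <- round((t - t0) / resolution_ms) + 1L
    tabulate(idx[idx >= 1L & idx <= nbin], nbins = nbin)
  }
  taps <- gauss_smooth(bin(tap_ms), sigma_ms, resolution_ms)
  cues <- gauss_smooth(bin(cue_ms), sigma_ms, resolution_ms)
  cosine <- function(a, b) {
    den <- sqrt(sum(a^2) * sum(b^2))
    if (den == 0) 0 else sum(a * b) / den
  }
  if (!factor_out_offset) {
    return(cosine(taps, cues))
  }
  shifts <- seq(-117, 117, by = resolution_ms) / resolution_ms
  best <- 0
  for (s in shifts) {
    if (s >= 0) {
      num <- sum(taps[seq_len(nbin - s)] * cues[seq_len(nbin - s) + s])
    } else {
      num <- sum(taps[seq_len(nbin + s) - s] * cues[seq_len(nbin + s)])
    }
    val <- num / sqrt(sum(taps^2) * sum(cues^2))
    if (val > best) best <- val
  }
  best
}

#' Aggregate pulse observations to binomial counts
#'
#' Collapses per-slot observations of one performance onto the rhythm's `N`
#' pulse classes: `tap_num` counts the tapped cycles of each pulse and
#' `n_pulses` the number of times that pulse occurred in the performance
#' (e.g. 16 for every pulse of an 8-pulse rhythm over 30 s, since
#' `30 / (8 * 0.234)` is about 16).
#'
#' @param obs a data.frame from [assign_taps_to_pulses()].
#' @param rhythm_n the rhythm's cycle length `N`.
#' @param start_cue pulse index (0-based) sounded at slot 0.
#' @return a data.frame with one row per pulse `n = 0..N-1`: `n`, `tap_num`,
#'   `n_pulses`.
#' @export
pulse_aggregate <- function(obs, rhythm_n, start_cue = 0L) {
  n_class <- (start_cue + obs$slot) %% rhythm_n
  tap_num <- rowsum(obs$tapped, n_class)
  n_pulses <- rowsum(rep(1L, nrow(obs)), n_class)
  data.frame(
    n = as.integer(rownames(tap_num)),
    tap_num = as.integer(tap_num[, 1L]),
    n_pulses = as.integer(n_pulses[, 1L])
  )
}

#' Smoothed velocity profile over the rhythm cycle
#'
#' Velocity-weighted tap-time histogram modulo the rhythm period, circularly
#' convolved with a Gaussian kernel (10-ms standard deviation by default)
#' and normalized to unit mass. This is the quantity behind circular
#' velocity-distribution plots: mass near the cycle end wraps around to the
#' start.
#'
#' @param tap_ms tap times in ms.
#' @param velocity tap velocities.
#' @param period_ms rhythm period in ms (`N * 234`).
#' @param sigma_ms smoothing standard deviation in ms (default 10).
#' @param resolution_ms sampling resolution in ms (default 1).
#' @return a data.frame with columns `t_ms` (cycle time, `0..period_ms-1`)
#'   and `density` (sums to 1 when any tap is present).
#' @export
smooth_velocity_profile <- function(tap_ms, velocity, period_ms,
                                    sigma_ms = 10, resolution_ms = 1) {
  stopifnot(length(tap_ms) == length(velocity))
  nbin <- round(period_ms / resolution_ms)
  phase <- (tap_ms %% period_ms) / resolution_ms
  idx <- (round(phase) %% nbin) + 1L
  hist <- numeric(nbin)
  for (j in seq_along(idx)) hist[idx[j]] <- hist[idx[j]] + velocity[j]
  hw <- max(1L, ceiling(5 * sigma_ms / resolution_ms))
  tt <- seq(-hw, hw) * resolution_ms
  kern <- exp(-tt^2 / (2 * sigma_ms^2))
  kern <- kern / sum(kern)
  sm <- numeric(nbin)
  for (j in seq_along(tt)) {
    sm <- sm + kern[j] * hist[((seq_len(nbin) - 1L + (j - hw - 1L)) %% nbin) + 1L]
  }
  if (sum(sm) > 0) sm <- sm / (sum(sm) * 1)
  data.frame(t_ms = (seq_len(nbin) - 1L) * resolution_ms, density = sm)
}

#' Score a tap-log table
#'
#' Computes per-performance accuracy scores and per-slot pulse observations
#' for a full tap-log table (the schema written by [simulate_cohort()] or
#' read by [read_tap_log()]).
#'
#' @param taps a tap-log data.frame with columns `participant`, `rhythm_id`,
#'   `perf_num`, `repetition`, `start_cue`, `t_ms`, `velocity`.
#' @param rhythms a list of [rhythm()] objects covering every `rhythm_id`.
#' @param n_slots,ioi_ms performance geometry (defaults 129 slots, 234 ms).
#' @param sigma_ms accuracy smoothing SD in ms.
#' @param factor_out_offset also compute the offset-corrected accuracy.
#' @return a list with `scores` (one row per performance: ids, `tap_acc`,
#'   optionally `tap_acc_offset`, `n_discarded`) and `observations` (one row
#'   per performance x slot with `n`, `cycle`, `cued`, `tapped`, `velocity`,
#'   `delta`, `tap_lag1`).
#' @export
score_performances <- function(taps, rhythms, n_slots = 129L, ioi_ms = 234,
                               sigma_ms = 10, factor_out_offset = FALSE) {
  rmap <- stats::setNames(rhythms, vapply(rhythms, function(r) r$id, character(1)))
  key <- interaction(taps$participant, taps$rhythm_id, taps$perf_num, drop = TRUE)
  score_rows <- list()
  obs_rows <- list()
  for (kk in levels(key)) {
    sub <- taps[key == kk, , drop = FALSE]
    r <- rmap[[as.character(sub$rhythm_id[1L])]]
    if (is.null(r)) stop("unknown rhythm_id: ", sub$rhythm_id[1L], call. = FALSE)
    start_cue <- sub$start_cue[1L]
    obs <- assign_taps_to_pulses(sub$t_ms, sub$velocity, n_slots, ioi_ms)
    slot_n <- (start_cue + obs$slot) %% r$n_pulses
    cue_slots <- which(r$indicator[slot_n + 1L] == 1L) - 1L
    cue_ms <- cue_slots * ioi_ms
    acc <- tap_accuracy(sub$t_ms, cue_ms, sigma_ms = sigma_ms)
    row <- data.frame(
      participant = sub$participant[1L],
      rhythm_id = sub$rhythm_id[1L],
      perf_num = sub$perf_num[1L],
      repetition = sub$repetition[1L],
      start_cue = start_cue,
      tap_acc = acc,
      n_discarded = attr(obs, "n_discarded"),
      stringsAsFactors = FALSE
    )
    if (factor_out_offset) {
      row$tap_acc_offset <- tap_accuracy(sub$t_ms, cue_ms,
        sigma_ms = sigma_ms, factor_out_offset = TRUE
      )
    }
    score_rows[[kk]] <- row
    obs_rows[[kk]] <- data.frame(
      participant = sub$participant[1L],
      rhythm_id = sub$rhythm_id[1L],
      perf_num = sub$perf_num[1L],
      repetition = sub$repetition[1L],
      n = slot_n,
      cycle = (start_cue + obs$slot) %/% r$n_pulses,
      cued = r$indicator[slot_n + 1L],
      tapped = obs$tapped,
      velocity = obs$velocity,
      delta = obs$delta,
      tap_lag1 = obs$tap_lag1,
      stringsAsFactors = FALSE
    )
  }
  list(
    scores = do.call(rbind, score_rows),
    observations = do.call(rbind, obs_rows)
  )
}
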