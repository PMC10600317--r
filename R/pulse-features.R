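#' Pulse-level structural predictors
#'
#' Every pulse of a rhythm — cued or uncued — gets a value from each of these
#' predictors. All of them are equivariant under rotation: rotating the
#' rhythm rotates the profile by the same amount.
#'
#' @name pulse-features
NULL

# signed circular distance mapped to [-N/2, N/2)
circular_dist <- function(d, n) ((d + n / 2) %% n) - n / 2

#' Markov cue probability of order k
#'
#' The optimal order-`k` Markov predictor for the cue sequence: at each pulse
#' `n`, the proportion of the `N` cyclic positions sharing the length-`k`
#' context `indicator[n-k .. n-1]` that are followed by a cue. Because the
#' contexts are read off the rhythm itself, every pulse's context occurs at
#' least once.
#'
#' @param r a [rhythm()].
#' @param k context length (the study uses 2, 3 and 4); must satisfy `k < N`.
#' @return numeric vector of length `N`, values in `[0, 1]`.
#' @examples
#' markov_cue_prob(rhythm("10010010"), 2) # 1/3 0 1/3 1 0 1/3 1 0
#' @export
markov_cue_prob <- function(r, k = 2L) {
  n <- r$n_pulses
  stopifnot(k >= 1L, k < n)
  ind <- r$indicator
  ctx <- vapply(seq_len(n) - 1L, function(m) {
    paste(ind[((m - k):(m - 1L)) %% n + 1L], collapse = "")
  }, character(1))
  vapply(seq_len(n), function(i) mean(ind[ctx == ctx[i]]), numeric(1))
}

#' Edge-detection profile
#'
#' Detects the boundaries of cue clusters and of gaps by convolving the
#' indicator, placed as unit impulses on the pulse circle, with a
#' derivative-of-Gaussian kernel, and taking magnitudes at pulse positions.
#' The kernel carries a small phase shift, so the trailing edge of a cluster
#' responds slightly more strongly than its leading edge (the second cue of a
#' two-cue cluster gets the larger value). The default scale, shift and gain
#' were calibrated once against the worked six-pulse example
#' `(0 0 1 1 0 0) -> (0.00, 0.22, 0.15, 0.27, 0.20, 0.00)` and are not meant
#' to be tuned per rhythm. Swapping cued and uncued pulses flips the sign of
#' the convolution up to a small constant, so edge profiles of a rhythm and
#' its complement agree closely (exactly, were the kernel unshifted).
#'
#' @param r a [rhythm()].
#' @param sigma kernel scale in pulses.
#' @param shift kernel phase shift in pulses.
#' @param gain output scaling.
#' @return numeric vector of length `N`, values `>= 0`.
#' @examples
#' round(edge_profile(rhythm("001100")), 2)
#' @export
edge_profile <- function(r, sigma = 0.36048, shift = -0.0071177,
                         gain = 1.27829) {
  stopifnot(sigma > 0)
  n <- r$n_pulses
  cues <- cue_positions(r)
  vapply(seq_len(n) - 1L, function(p) {
    t <- circular_dist(p - cues, n) - shift
    gain * abs(sum(-t / sigma^2 * exp(-t^2 / (2 * sigma^2))))
  }, numeric(1))
}

#' Normalized mean temporal offset
#'
#' For each pulse, the sum of forward circular distances to all cues minus
#' the sum of backward circular distances, normalized by `K * N` so values
#' lie in `[-1, 1]`. Pulses near the end of a cue cluster score high (the
#' cues just passed sit close behind while the next cluster is far ahead),
#' pulses near the start of a cluster score low.
#'
#' @param r a [rhythm()].
#' @return numeric vector of length `N` in `[-1, 1]`.
#' @export
mean_offset <- function(r) {
  n <- r$n_pulses
  cues <- cue_positions(r)
  k <- length(cues)
  vapply(seq_len(n) - 1L, function(p) {
    fwd <- (cues - p) %% n
    bwd <- (p - cues) %% n
    sum(fwd - bwd) / (k * n)
  }, numeric(1))
}

#' Projected centroid
#'
#' The rhythm's cue centroid projected onto the diameter through each pulse:
#' `|c| * cos(theta_n - arg(c))`, positive toward the centroid, negative
#' opposite. All zeros when the rhythm is perfectly balanced; bounded by the
#' centroid magnitude `1 - balance(r)`.
#'
#' @param r a [rhythm()].
#' @return numeric vector of length `N` in `[-1, 1]`.
#' @export
proj_cent <- function(r) {
  n <- r$n_pulses
  cen <- rhythm_centroid(r)
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  Re(cen * exp(-1i * theta))
}

#' Autocorrelation phase matrix salience
#'
#' Column sums of a circular autocorrelation phase matrix: for each lag `k`
#' in `lags`, a pulse `n` accumulates the mean autocorrelation mass
#' `x(n + i*k) * x(n + (i+1)*k)` along its whole cyclic orbit under steps of
#' `k` (the circular phase class of `n` at that lag); its value is the mean
#' of those per-lag entries. Pulses in phase with strong isochronous beats
#' induced by the cues score high; defining the phase classes on the cyclic
#' orbit keeps the profile rotation-equivariant for every lag, including
#' lags that do not divide `N`.
#'
#' @param r a [rhythm()] with `N >= 2`.
#' @param lags integer lags to accumulate (default `1:floor(N/2)`).
#' @return numeric vector of length `N` in `[0, 1]`.
#' @export
apm_profile <- function(r, lags = NULL) {
  n <- r$n_pulses
  stopifnot(n >= 2L)
  if (is.null(lags)) lags <- seq_len(n %/% 2L)
  ind <- r$indicator
  acc <- numeric(n)
  for (k in lags) {
    orbit_len <- n / gcd2(n, k)
    prod_k <- ind * ind[(seq_len(n) - 1L + k) %% n + 1L]
    val <- vapply(seq_len(n) - 1L, function(p) {
      mean(prod_k[(p + k * (seq_len(orbit_len) - 1L)) %% n + 1L])
    }, numeric(1))
    acc <- acc + val
  }
  acc / length(lags)
}

#' Sequential expectation
#'
#' Rewards the pulse that would continue a run of isochronous cues. Every
#' maximal run of `m >= 2` cues linked by a constant interonset interval `d`
#' ending at cue `p` contributes `(1 - run_gain^(m-1)) * ioi_decay^(d-1)` to
#' pulse `(p + d) mod N`; a pulse's value is the sum of its contributions.
#' Contributions grow with run length and shrink with interval size. When
#' all IOIs are equal, the run wraps the full cycle and every cue's
#' continuation pulse receives the full-length contribution.
#'
#' @param r a [rhythm()].
#' @param run_gain geometric run-length gain in `(0, 1)` (default 0.5).
#' @param ioi_decay geometric decay per extra pulse of IOI in `(0, 1)`
#'   (default 0.5).
#' @return numeric vector of length `N`, values `>= 0`.
#' @export
seq_exp <- function(r, run_gain = 0.5, ioi_decay = 0.5) {
  if (is.null(run_gain) || is.null(ioi_decay)) {
    stop("seq_exp needs its two shape constants (run_gain, ioi_decay)",
      call. = FALSE
    )
  }
  stopifnot(run_gain > 0, run_gain < 1, ioi_decay > 0, ioi_decay < 1)
  n <- r$n_pulses
  cues <- cue_positions(r)
  k <- length(cues)
  out <- numeric(n)
  contrib <- function(m, d) (1 - run_gain^(m - 1)) * ioi_decay^(d - 1)
  if (k == 1L) return(out)
  io <- ioi_sequence(r)
  if (length(unique(io)) == 1L) {
    d <- io[1L]
    for (p in cues) out[(p + d) %% n + 1L] <- out[(p + d) %% n + 1L] + contrib(k, d)
    return(out)
  }
  # maximal runs of equal consecutive IOIs on the circular IOI sequence
  j <- 1L
  starts <- which(io != io[c(k, seq_len(k - 1L))]) # run starts (IOI differs from previous)
  for (s in starts) {
    len <- 1L
    while (io[(s - 1L + len) %% k + 1L] == io[s]) len <- len + 1L
    d <- io[s]
    p_end <- cues[(s - 1L + len) %% k + 1L] # cue ending the run
    m <- len + 1L # cues in the run = IOIs + 1
    out[(p_end + d) %% n + 1L] <- out[(p_end + d) %% n + 1L] + contrib(m, d)
  }
  out
}

#' Povel accent indicators
#'
#' Three binary accent markers per pulse, following the grouping-accent
#' criteria for cue clusters: `iso_accent` marks an isolated cue (uncued
#' neighbours on both sides), `end_accent` the last cue of a run of two or
#' more consecutive cues, `start_accent` the first cue of a run of three or
#' more; all circular.
#'
#' @param r a [rhythm()].
#' @return a data.frame with columns `iso_accent`, `start_accent`,
#'   `end_accent` (length-`N` binaries).
#' @export
povel_accents <- function(r) {
  n <- r$n_pulses
  ind <- r$indicator
  prev <- ind[c(n, seq_len(n - 1L))]
  nxt <- ind[c(seq_len(n - 1L) + 1L, 1L)]
  nxt2 <- ind[c(seq_len(n - 2L) + 2L, 1L, 2L)[seq_len(n)]]
  iso <- as.integer(ind == 1L & prev == 0L & nxt == 0L)
  end <- as.integer(ind == 1L & prev == 1L & nxt == 0L)
  start <- as.integer(ind == 1L & prev == 0L & nxt == 1L & nxt2 == 1L)
  data.frame(iso_accent = iso, start_accent = start, end_accent = end)
}

#' Pulse-level feature table
#'
#' One row per pulse per rhythm, with the full set of pulse-level predictors
#' under their canonical column names.
#'
#' @param rhythms a list of [rhythm()] objects (or a single rhythm).
#' @param edge_args,seq_exp_args,apm_lags optional parameter overrides passed
#'   to [edge_profile()], [seq_exp()] and [apm_profile()].
#' @return a data.frame with columns `rhythm_id`, `n`, `cue`, `apm`,
#'   `seq_exp`, `edge`, `mean_offset`, `proj_cent`, `markov2`, `markov3`,
#'   `markov4`, `iso_accent`, `start_accent`, `end_accent`.
#' @export
pulse_features <- function(rhythms, edge_args = list(),
                           seq_exp_args = list(), apm_lags = NULL) {
  if (inherits(rhythms, "rhythm")) rhythms <- list(rhythms)
  do.call(rbind, lapply(rhythms, function(r) {
    n <- r$n_pulses
    acc <- povel_accents(r)
    data.frame(
      rhythm_id = r$id,
      n = seq_len(n) - 1L,
      cue = r$indicator,
      apm = apm_profile(r, lags = apm_lags),
      seq_exp = do.call(seq_exp, c(list(r), seq_exp_args)),
      edge = do.call(edge_profile, c(list(r), edge_args)),
      mean_offset = mean_offset(r),
      proj_cent = proj_cent(r),
      markov2 = if (n > 2L) markov_cue_prob(r, 2L) else NA_real_,
      markov3 = if (n > 3L) markov_cue_prob(r, 3L) else NA_real_,
      markov4 = if (n > 4L) markov_cue_prob(r, 4L) else NA_real_,
      iso_accent = acc$iso_accent,
      start_accent = acc$start_accent,
      end_accent = acc$end_accent,
      stringsAsFactors = FALSE
    )
  }))
}
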