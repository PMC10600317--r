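# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities from first principles by different code paths than
# the package implementation.

# Myhill's property by tabulating all K*(K-1) directed cue pairs explicitly.
oracle_myhill <- function(ind) {
  n <- length(ind)
  cues <- which(ind == 1L) - 1L
  k <- length(cues)
  if (k < 2L || k >= n) return(FALSE)
  pairs <- expand.grid(a = seq_len(k), b = seq_len(k))
  pairs <- pairs[pairs$a != pairs$b, ]
  generic <- (pairs$b - pairs$a) %% k
  specific <- (cues[pairs$b] - cues[pairs$a]) %% n
  all(vapply(
    seq_len(k - 1L),
    function(g) length(unique(specific[generic == g])) == 2L,
    logical(1)
  ))
}

# Coherence failures by scanning every unordered pair of directed intervals.
oracle_coherence_failures <- function(ind) {
  n <- length(ind)
  cues <- which(ind == 1L) - 1L
  k <- length(cues)
  ivals <- do.call(rbind, lapply(seq_len(k), function(a) {
    do.call(rbind, lapply(setdiff(seq_len(k), a), function(b) {
      c(g = (b - a) %% k, s = (cues[b] - cues[a]) %% n)
    }))
  }))
  count <- 0L
  m <- nrow(ivals)
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      gi <- ivals[i, "g"]; gj <- ivals[j, "g"]
      si <- ivals[i, "s"]; sj <- ivals[j, "s"]
      if ((gi < gj && si > sj) || (gj < gi && sj > si)) count <- count + 1L
    }
  }
  count
}

# Tap accuracy by direct summation of untruncated Gaussians on the same
# 1-ms grid the metric uses (no filter(), no kernel truncation).
oracle_tap_accuracy <- function(tap_ms, cue_ms, sigma_ms = 10,
                                resolution_ms = 1) {
  pad <- ceiling(8 * sigma_ms) + 117
  t0 <- min(c(tap_ms, cue_ms)) - pad
  t1 <- max(c(tap_ms, cue_ms)) + pad
  grid <- seq(t0, t1, by = resolution_ms)
  smooth_at <- function(times) {
    binned <- t0 + (round((times - t0) / resolution_ms)) * resolution_ms
    rowSums(vapply(
      binned,
      function(tc) exp(-(grid - tc)^2 / (2 * sigma_ms^2)),
      numeric(length(grid))
    ))
  }
  a <- smooth_at(tap_ms)
  b <- smooth_at(cue_ms)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# A small fixed rhythm set spanning different N and K, for cohort-level
# property tests.
test_rhythm_set <- function(n = 12L) {
  u <- enumerate_wf_rhythms()
  u[round(seq(1, length(u), length.out = n))]
}
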