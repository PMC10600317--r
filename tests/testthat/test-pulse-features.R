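test_that("markov predictor reproduces the tresillo vector and simple cases", {
  expect_equal(
    markov_cue_prob(rhythm("10010010"), 2),
    c(1 / 3, 0, 1 / 3, 1, 0, 1 / 3, 1, 0)
  )
  expect_equal(markov_cue_prob(rhythm("1111"), 2), c(1, 1, 1, 1))
  expect_equal(markov_cue_prob(rhythm("1010"), 2), c(1, 0, 1, 0))
})

test_that("markov probabilities obey the law of total probability", {
  # averaging the per-pulse predictions over all N positions must give the
  # overall cue rate K/N, for every order
  for (r in test_rhythm_set(8L)) {
    for (k in 2:4) {
      if (r$n_pulses <= k) next
      expect_equal(
        mean(markov_cue_prob(r, k)),
        r$n_cues / r$n_pulses,
        info = paste(r$id, k)
      )
    }
  }
})

test_that("edge profile matches the worked six-pulse vector at 2 dp", {
  expect_equal(
    round(edge_profile(rhythm("001100")), 2),
    c(0.00, 0.22, 0.15, 0.27, 0.20, 0.00)
  )
  # second cue of a two-cue cluster gets the larger value
  e <- edge_profile(rhythm("001100"))
  expect_gt(e[4], e[3])
})

test_that("edge profile is flat and small on isochronous rhythms", {
  # a constant signal has no edges: the profile is flat, equal at every
  # pulse, and no larger than the kernel's small constant response
  e <- edge_profile(rhythm("1111"))
  expect_equal(diff(range(e)), 0, tolerance = 1e-12)
  expect_lt(max(e), 0.06)
  # alternating pattern vs its complement: same profile up to that constant
  expect_lt(
    max(abs(edge_profile(rhythm("101010")) - edge_profile(rhythm("010101")))),
    0.06
  )
})

test_that("edge profiles of a rhythm and its complement agree closely", {
  # the calibrated kernel has a small nonzero response to a constant signal,
  # so complement invariance is exact only up to that constant (about 0.05)
  u <- enumerate_wf_rhythms()
  for (r in u) {
    expect_lt(
      max(abs(edge_profile(r) - edge_profile(complement_rhythm(r)))),
      0.06
    )
  }
})

test_that("mean_offset ranks cluster ends above cluster starts", {
  v <- mean_offset(rhythm("11110000"))
  expect_gt(v[4], v[1]) # pulse 3 (cluster end) above pulse 0 (start)
  # isochronous: identical at every pulse
  expect_equal(diff(range(mean_offset(rhythm("101010")))), 0)
  # direct summation oracle for (1 1 0 0)
  oracle <- vapply(0:3, function(p) {
    cues <- c(0, 1)
    sum(((cues - p) %% 4) - ((p - cues) %% 4)) / (2 * 4)
  }, numeric(1))
  expect_equal(mean_offset(rhythm("1100")), oracle)
  expect_equal(oracle, c(-0.25, 0.25, 0.25, -0.25))
})

test_that("projected centroid is zero when balanced and signed along the centroid", {
  expect_equal(proj_cent(rhythm("1010")), rep(0, 4))
  v <- proj_cent(rhythm("1000"))
  expect_equal(v[1], 1) # pulse at the centroid of a one-cue rhythm
  v6 <- proj_cent(rhythm("100000"))
  expect_equal(v6[4], -1) # antipodal pulse: phase reversed
  for (r in test_rhythm_set(8L)) {
    expect_true(all(abs(proj_cent(r)) <= (1 - balance(r)) + 1e-12))
  }
})

test_that("apm salience is uniform when isochronous and higher on alternating cues", {
  expect_equal(diff(range(apm_profile(rhythm("1111")))), 0)
  v <- apm_profile(rhythm("10101010"))
  expect_true(all(v[c(1, 3, 5, 7)] > v[c(2, 4, 6, 8)]))
  expect_equal(length(unique(round(v[c(1, 3, 5, 7)], 12))), 1L)
})

test_that("sequential expectation rewards continuation, longer runs, smaller IOIs", {
  v <- seq_exp(rhythm("111000"))
  expect_equal(which.max(v), 4L) # pulse 3 continues the run
  cfun <- function(m, d, g = 0.5, dec = 0.5) (1 - g^(m - 1)) * dec^(d - 1)
  expect_gt(cfun(3, 1), cfun(2, 1))
  expect_gt(cfun(2, 1), cfun(2, 3))
  expect_error(seq_exp(rhythm("1100"), run_gain = NULL), "shape constants")
})

test_that("povel accents mark isolated cues and run boundaries", {
  a <- povel_accents(rhythm("010"))
  expect_equal(a$iso_accent, c(0L, 1L, 0L))
  a <- povel_accents(rhythm("1100"))
  expect_equal(a$end_accent, c(0L, 1L, 0L, 0L))
  expect_equal(a$start_accent, rep(0L, 4L)) # run of 2 < 3
  a <- povel_accents(rhythm("1110"))
  expect_equal(a$start_accent, c(1L, 0L, 0L, 0L))
  expect_equal(a$end_accent, c(0L, 0L, 1L, 0L))
})

test_that("all pulse features are rotation equivariant", {
  set.seed(7)
  feature_funs <- list(
    markov2 = function(r) markov_cue_prob(r, 2),
    edge = edge_profile,
    mean_offset = mean_offset,
    proj_cent = proj_cent,
    apm = apm_profile,
    seq_exp = seq_exp,
    iso = function(r) povel_accents(r)$iso_accent,
    start = function(r) povel_accents(r)$start_accent,
    end = function(r) povel_accents(r)$end_accent
  )
  for (r in test_rhythm_set(6L)) {
    n <- r$n_pulses
    s <- sample.int(n - 1L, 1L)
    rr <- rotate_rhythm(r, s)
    for (nm in names(feature_funs)) {
      f <- feature_funs[[nm]]
      expected <- f(r)[((seq_len(n) - 1L - s) %% n) + 1L]
      expect_equal(f(rr), expected,
        info = paste(r$id, nm, s), tolerance = 1e-12
      )
    }
  }
})

test_that("pulse feature table has the canonical columns and cue flags", {
  u <- test_rhythm_set(4L)
  pf <- pulse_features(u)
  expect_named(pf, c(
    "rhythm_id", "n", "cue", "apm", "seq_exp", "edge", "mean_offset",
    "proj_cent", "markov2", "markov3", "markov4", "iso_accent",
    "start_accent", "end_accent"
  ))
  expect_equal(nrow(pf), sum(vapply(u, function(r) r$n_pulses, integer(1))))
  for (r in u) {
    expect_equal(pf$cue[pf$rhythm_id == r$id], r$indicator)
  }
})
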