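#' Rhythm-level structural predictors
#'
#' Eight scalar descriptors of a cyclic rhythm, all invariant under rotation.
#' They quantify complementary aspects of structure: how evenly the cues are
#' spread ([evenness()]), how far their circular centre of mass sits from the
#' centre ([balance()]), the unpredictability of the interonset-interval
#' distribution ([ioi_entropy()]) and of the full inter-cue interval
#' distribution ([interval_entropy()]), how consistently larger generic
#' intervals span more pulses ([coherence_quotient()]), how few specific
#' sizes each generic interval takes ([sameness_quotient()]), whether the
#' cycle length is divisible by 2 or 3 ([duple_triple()]), and the mean
#' interonset interval `N/K` ([mean_ioi()]).
#'
#' @name rhythm-features
NULL

#' Evenness of a rhythm
#'
#' Similarity of the cue set to a perfectly even `K`-point set on the cycle:
#' the magnitude of the mean, over cues `j = 0..K-1` in temporal order at
#' pulses `t_j`, of unit vectors at angle `2*pi*t_j/N - 2*pi*j/K`. Equals 1
#' exactly when the cues are equally spaced, and is invariant to rotation and
#' to which cue is labelled first.
#'
#' @param r a [rhythm()] with `K >= 2`.
#' @return a number in `[0, 1]`.
#' @examples
#' evenness(rhythm("110"))  # 0.866
#' evenness(rhythm("1100")) # 0.707
#' @export
evenness <- function(r) {
  cues <- cue_positions(r)
  k <- length(cues)
  if (k < 2L) stop("evenness needs at least 2 cues", call. = FALSE)
  j <- seq_len(k) - 1L
  Mod(mean(exp(2i * pi * (cues / r$n_pulses - j / k))))
}

#' Balance of a rhythm
#'
#' One minus the distance of the rhythm's circular centre of mass from the
#' circle centre; 1 means perfectly balanced (centroid at the centre),
#' 0 means all cues coincide on the circumference. Balance is one minus the
#' mean resultant length of the cue angles, i.e. the circular variance.
#'
#' @param r a [rhythm()].
#' @return a number in `[0, 1]`.
#' @export
balance <- function(r) {
  1 - Mod(rhythm_centroid(r))
}

# Cue centroid as a complex number (mean of unit vectors at cue angles).
rhythm_centroid <- function(r) {
  cues <- cue_positions(r)
  mean(exp(2i * pi * cues / r$n_pulses))
}

shannon_bits <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Interonset-interval entropy
#'
#' Shannon entropy (bits) of the empirical distribution of the `K`
#' consecutive-cue interonset intervals. Zero for isochronous rhythms.
#'
#' @param r a [rhythm()].
#' @return entropy in bits, `>= 0`.
#' @examples
#' ioi_entropy(rhythm("10010")) # 1 bit: IOIs (3, 2)
#' @export
ioi_entropy <- function(r) {
  shannon_bits(table(ioi_sequence(r)))
}

#' Inter-cue interval entropy
#'
#' Shannon entropy (bits) of the multiset of all `K*(K-1)` directed intervals
#' between distinct cues, taken modulo the period. Considers every pair of
#' cues, not just consecutive ones.
#'
#' @param r a [rhythm()] with `K >= 2`.
#' @return entropy in bits, `>= 0`.
#' @export
interval_entropy <- function(r) {
  shannon_bits(table(interval_multiset(r)))
}

#' All directed inter-cue intervals modulo the period
#'
#' @param r a [rhythm()] with `K >= 2`.
#' @return integer vector of length `K*(K-1)` of pulse distances in `1..N-1`.
#' @export
interval_multiset <- function(r) {
  cues <- cue_positions(r)
  if (length(cues) < 2L) stop("needs at least 2 cues", call. = FALSE)
  d <- outer(cues, cues, function(a, b) (b - a) %% r$n_pulses)
  as.integer(d[row(d) != col(d)])
}

# Directed cue-pair intervals with their generic distances: a data.frame with
# one row per ordered cue pair (j -> j+g), columns generic (1..K-1) and
# specific (pulses).
directed_intervals <- function(r) {
  sizes <- specific_sizes(r)
  k <- r$n_cues
  data.frame(
    generic = rep(seq_len(k - 1L), each = k),
    specific = as.integer(sizes)
  )
}

count_coherence_failures <- function(r) {
  d <- directed_intervals(r)
  g <- d$generic
  s <- d$specific
  # unordered pairs of directed intervals with generic(a) < generic(b) and
  # specific(a) > specific(b)
  sum(outer(g, g, "<") & outer(s, s, ">"))
}

sq_numerator <- function(r) {
  sizes <- specific_sizes(r)
  sum(apply(sizes, 2L, function(s) length(unique(s)) - 1L))
}

# Worst-case (maximal) coherence-failure count for a K-cue rhythm, by
# exhaustive search over all cue patterns with up to `max_n` pulses (one cue
# fixed at pulse 0; the count is rotation-invariant). Cached per (K, max_n).
.norm_cache <- new.env(parent = emptyenv())

max_coherence_failures <- function(k, max_n = 13L) {
  key <- sprintf("K%d_N%d", k, max_n)
  if (!is.null(.norm_cache[[key]])) return(.norm_cache[[key]])
  max_cq <- 0L
  for (n in seq.int(k + 1L, max_n)) {
    combs <- utils::combn(n - 1L, k - 1L)
    for (j in seq_len(ncol(combs))) {
      ind <- integer(n)
      ind[c(1L, combs[, j] + 1L)] <- 1L
      max_cq <- max(max_cq, count_coherence_failures(rhythm(ind)))
    }
  }
  .norm_cache[[key]] <- max_cq
  max_cq
}

#' Coherence quotient
#'
#' Quantifies how consistently larger generic intervals (cue-step distances)
#' span more pulses. A *coherence failure* is an unordered pair of directed
#' cue-pair intervals where the interval with the smaller generic distance
#' spans strictly more pulses. The quotient is one minus the failure count
#' divided by the worst-case failure count for a `K`-cue rhythm (obtained by
#' exhaustive search over all cue patterns with up to `max_n` pulses, cached).
#'
#' @param r a [rhythm()]; undefined (returns `NA`) for `K < 3`.
#' @param max_n pulse-count bound for the worst-case normalizer search
#'   (default 13, the largest cycle in the rhythm universe).
#' @return a number in `[0, 1]`, or `NA` when `K < 3`.
#' @export
coherence_quotient <- function(r, max_n = 13L) {
  if (r$n_cues < 3L) return(NA_real_)
  1 - count_coherence_failures(r) / max_coherence_failures(r$n_cues, max_n)
}

#' Sameness quotient
#'
#' Counts, for every generic interval `g = 1..K-1`, the number of distinct
#' specific sizes beyond the first, sums them, and normalizes by the
#' combinatorial maximum for a `K`-cue pattern: each generic interval is
#' realized by `K` cyclic cue pairs, so it can take at most `K` distinct
#' sizes, i.e. `K - 1` beyond the first, giving a normalizer of
#' `(K - 1)^2`. One minus that ratio: 1 for an isochronous rhythm (one size
#' per generic interval). Every nondegenerate well-formed rhythm contributes
#' exactly one extra size per generic interval (Myhill's property), so
#' across the enumerated universe the quotient is `(K - 2)/(K - 1)`, an
#' increasing function of `K` alone.
#'
#' @param r a [rhythm()] with `K >= 2`.
#' @return a number in `[0, 1]`.
#' @export
sameness_quotient <- function(r) {
  k <- r$n_cues
  if (k < 2L) stop("sameness quotient needs at least 2 cues", call. = FALSE)
  1 - sq_numerator(r) / (k - 1L)^2
}

#' Duple/triple indicator
#'
#' 1 when the cycle length `N` is divisible by 2 or by 3 (the rhythm can be
#' metrically chunked in twos or threes without inflating the period), else 0.
#'
#' @param r a [rhythm()].
#' @return 0 or 1.
#' @export
duple_triple <- function(r) {
  as.integer(r$n_pulses %% 2L == 0L || r$n_pulses %% 3L == 0L)
}

#' Mean interonset interval
#'
#' `N / K`, in pulses; equals the mean of the IOI sequence.
#'
#' @param r a [rhythm()].
#' @return a positive number.
#' @export
mean_ioi <- function(r) {
  r$n_pulses / r$n_cues
}

#' Rhythm-level feature table
#'
#' Computes all eight rhythm-level predictors for a list of rhythms.
#'
#' @param rhythms a list of [rhythm()] objects (default: the enumerated
#'   91-rhythm universe).
#' @return a data.frame with one row per rhythm: `id`, `n_pulses`, `n_cues`,
#'   `mean_ioi`, `evenness`, `balance`, `ioi_ent`, `int_ent`, `cq`, `sq`,
#'   `duple_triple`.
#' @export
rhythm_features <- function(rhythms = enumerate_wf_rhythms()) {
  if (inherits(rhythms, "rhythm")) rhythms <- list(rhythms)
  data.frame(
    id = vapply(rhythms, function(r) r$id, character(1)),
    n_pulses = vapply(rhythms, function(r) r$n_pulses, integer(1)),
    n_cues = vapply(rhythms, function(r) r$n_cues, integer(1)),
    mean_ioi = vapply(rhythms, mean_ioi, numeric(1)),
    evenness = vapply(rhythms, evenness, numeric(1)),
    balance = vapply(rhythms, balance, numeric(1)),
    ioi_ent = vapply(rhythms, ioi_entropy, numeric(1)),
    int_ent = vapply(rhythms, interval_entropy, numeric(1)),
    cq = vapply(rhythms, coherence_quotient, numeric(1)),
    sq = vapply(rhythms, sameness_quotient, numeric(1)),
    duple_triple = vapply(rhythms, duple_triple, integer(1)),
    stringsAsFactors = FALSE
  )
}
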