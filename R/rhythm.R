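#' Cyclic rhythms as binary cue patterns
#'
#' A rhythm is a cyclic pattern of `N` isochronous pulses of which `K` are
#' *cued* (sounded as targets to tap). It is represented as a length-`N`
#' 0/1 indicator vector; pulse indices run from 0 to `N - 1` and all interval
#' arithmetic is modulo `N`. Within a cycle, pulse `n` occurs at time
#' `n * 234` ms (the pulse interonset interval used throughout).
#'
#' @param indicator integer vector of 0/1 (or a string such as `"10110"`),
#'   length at least 3, with at least one cue.
#' @param id optional stable text label; generated labels look like `"N8K5a"`.
#' @return An object of class `"rhythm"`: a list with elements `n_pulses`,
#'   `n_cues`, `indicator` and `id`.
#' @examples
#' r <- rhythm("10101101")
#' ioi_sequence(r)
#' @export
rhythm <- function(indicator, id = NULL) {
  if (is.character(indicator) && length(indicator) == 1L) {
    indicator <- as.integer(strsplit(indicator, "")[[1L]])
  }
  indicator <- as.integer(indicator)
  if (length(indicator) < 3L) {
    stop("a rhythm needs at least 3 pulses", call. = FALSE)
  }
  if (!all(indicator %in% c(0L, 1L))) {
    stop("indicator must contain only 0 and 1", call. = FALSE)
  }
  if (sum(indicator) < 1L) {
    stop("empty rhythm", call. = FALSE)
  }
  structure(
    list(
      n_pulses = length(indicator),
      n_cues = sum(indicator),
      indicator = indicator,
      id = if (is.null(id)) paste(indicator, collapse = "") else id
    ),
    class = "rhythm"
  )
}

#' @export
print.rhythm <- function(x, ...) {
  cat(sprintf(
    "<rhythm %s> N = %d, K = %d, indicator (%s), IOIs (%s)\n",
    x$id, x$n_pulses, x$n_cues,
    paste(x$indicator, collapse = " "),
    paste(ioi_sequence(x), collapse = " ")
  ))
  invisible(x)
}

#' @export
format.rhythm <- function(x, ...) paste(x$indicator, collapse = "")

#' Cue positions of a rhythm
#'
#' @param r a [rhythm()].
#' @return 0-based pulse indices of the cues, in temporal order.
#' @export
cue_positions <- function(r) {
  stopifnot(inherits(r, "rhythm"))
  which(r$indicator == 1L) - 1L
}

#' Interonset-interval sequence
#'
#' Circular gaps (in pulses) from each cue to the next, starting at the first
#' cue at or after pulse 0. The gaps always sum to `N`.
#'
#' @param r a [rhythm()].
#' @return integer vector of length `K`.
#' @examples
#' ioi_sequence(rhythm("10101101")) # 2 2 1 2 1
#' @export
ioi_sequence <- function(r) {
  cues <- cue_positions(r)
  k <- length(cues)
  if (k == 0L) stop("empty rhythm", call. = FALSE)
  if (k == 1L) return(r$n_pulses)
  (cues[c(seq_len(k - 1L) + 1L, 1L)] - cues) %% r$n_pulses
}

#' Rotate a rhythm
#'
#' Shifts the pattern forward in time by `s` pulses: the rotated indicator at
#' pulse `n` equals the original at `(n - s) mod N`.
#'
#' @param r a [rhythm()].
#' @param s integer shift (any sign).
#' @return a rotated [rhythm()].
#' @export
rotate_rhythm <- function(r, s) {
  n <- r$n_pulses
  idx <- ((seq_len(n) - 1L - s) %% n) + 1L
  rhythm(r$indicator[idx], id = r$id)
}

#' Complement rhythm
#'
#' Swaps cued and uncued pulses. `complement_rhythm(complement_rhythm(r))`
#' equals `r`.
#'
#' @param r a [rhythm()] with `1 <= K <= N - 1`.
#' @return the complemented [rhythm()].
#' @export
complement_rhythm <- function(r) {
  if (r$n_cues >= r$n_pulses) {
    stop("complement of an all-cued rhythm has no cues", call. = FALSE)
  }
  rhythm(1L - r$indicator, id = paste0(r$id, "'"))
}

# Specific sizes (pulse counts) of all directed cue pairs at generic distance
# g (number of cue steps forward), for g in 1..K-1. Returns a K x (K-1)
# matrix; column g holds the K specific sizes at generic g.
specific_sizes <- function(r) {
  cues <- cue_positions(r)
  k <- length(cues)
  n <- r$n_pulses
  vapply(seq_len(k - 1L), function(g) {
    (cues[((seq_len(k) - 1L + g) %% k) + 1L] - cues) %% n
  }, numeric(k))
}

#' Test nondegenerate well-formedness
#'
#' A cyclic rhythm is nondegenerate well-formed when its two interonset
#' intervals are distributed as evenly as possible, which is equivalent to
#' Myhill's property: every generic interval (cue-step distance `g` in
#' `1..K-1`) is realized in exactly two specific sizes (pulse counts).
#' In addition the rhythm must be *primitive*: its IOI sizes must not share a
#' common factor, since otherwise every cue lies on a proper sublattice of
#' the pulse cycle and the pattern is merely a pulse-magnified copy of a
#' shorter rhythm (equivalently, no generator of the cue set is coprime with
#' `N`). Set `require_primitive = FALSE` to test Myhill's property alone.
#'
#' @param r a [rhythm()] with `2 <= K < N`.
#' @param require_primitive also require the IOI sizes to be coprime
#'   (default `TRUE`).
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_wellformed(rhythm("10101101")) # TRUE
#' is_wellformed(rhythm("1111"))     # FALSE (isochronous, degenerate)
#' @export
is_wellformed <- function(r, require_primitive = TRUE) {
  if (r$n_cues < 2L || r$n_cues >= r$n_pulses) return(FALSE)
  sizes <- specific_sizes(r)
  myhill <- all(apply(sizes, 2L, function(s) length(unique(s)) == 2L))
  if (!myhill) return(FALSE)
  if (require_primitive) {
    io <- unique(ioi_sequence(r))
    if (Reduce(gcd2, io) > 1L) return(FALSE)
  }
  TRUE
}

gcd2 <- function(a, b) {
  while (b != 0L) {
    t <- a %% b
    a <- b
    b <- t
  }
  a
}

#' Canonical rotation
#'
#' Rotates a rhythm so that pulse 0 falls on a cue and, among all rotations
#' starting on a cue, the IOI sequence places the small IOIs as close to the
#' end as possible; operationally this is the rotation whose IOI sequence is
#' lexicographically largest (ties between symmetric rotations are broken by
#' taking the first such cue).
#'
#' @param r a [rhythm()].
#' @return the canonically rotated [rhythm()].
#' @examples
#' format(canonical_rotation(rhythm("01011010"))) # "10101101"
#' @export
canonical_rotation <- function(r) {
  cues <- cue_positions(r)
  io <- ioi_sequence(r)
  k <- length(cues)
  best <- 1L
  for (j in seq_len(k)[-1L]) {
    if (lex_greater(rot_vec(io, j), rot_vec(io, best))) best <- j
  }
  rotate_rhythm(r, -cues[best])
}

rot_vec <- function(x, j) x[((seq_along(x) - 1L + j - 1L) %% length(x)) + 1L]

lex_greater <- function(a, b) {
  d <- a - b
  i <- which(d != 0L)
  length(i) > 0L && d[i[1L]] > 0L
}

#' Enumerate the well-formed rhythm universe
#'
#' Enumerates all rotation-distinct nondegenerate well-formed rhythms with
#' pulse counts in `n_range`, cue counts in `k_range` and no interonset
#' interval exceeding `max_ioi` pulses. Each rhythm is returned in canonical
#' rotation; ordering is deterministic by `(N, K, IOI sequence)`. With the
#' defaults this yields the 91-rhythm universe used in the tapping
#' experiments.
#'
#' @param n_range pulse counts to consider (default `3:13`).
#' @param k_range cue counts to consider (default `2:11`).
#' @param max_ioi largest admissible interonset interval in pulses
#'   (default 5).
#' @return a list of [rhythm()] objects with ids of the form `"N8K5a"`.
#' @examples
#' length(enumerate_wf_rhythms()) # 91
#' @export
enumerate_wf_rhythms <- function(n_range = 3:13, k_range = 2:11,
                                 max_ioi = 5) {
  stopifnot(length(n_range) > 0L, length(k_range) > 0L)
  out <- list()
  for (n in sort(unique(as.integer(n_range)))) {
    for (k in sort(unique(as.integer(k_range)))) {
      if (k < 2L || k >= n) next
      found <- list()
      keys <- character(0)
      combs <- utils::combn(n - 1L, k - 1L)
      for (j in seq_len(ncol(combs))) {
        cues <- c(0L, combs[, j]) # fix a cue at 0: covers every rotation class
        ind <- integer(n)
        ind[cues + 1L] <- 1L
        r <- rhythm(ind)
        io <- ioi_sequence(r)
        if (max(io) > max_ioi) next
        if (!is_wellformed(r)) next
        canon <- canonical_rotation(r)
        key <- format(canon)
        if (!(key %in% keys)) {
          keys <- c(keys, key)
          found[[length(found) + 1L]] <- canon
        }
      }
      if (length(found) > 0L) {
        ord <- order(vapply(
          found,
          function(r) paste(sprintf("%02d", ioi_sequence(r)), collapse = ""),
          character(1)
        ), decreasing = TRUE)
        found <- found[ord]
        for (i in seq_along(found)) {
          found[[i]]$id <- sprintf("N%dK%d%s", n, k, letters[i])
          out[[length(out) + 1L]] <- found[[i]]
        }
      }
    }
  }
  out
}

#' Tabulate a rhythm set as a catalog
#'
#' @param rhythms a list of [rhythm()] objects, e.g. from
#'   [enumerate_wf_rhythms()].
#' @return a data.frame with columns `id`, `n_pulses`, `n_cues`, `indicator`
#'   (as a "10110" string), `ioi_sequence` (space separated) and `canonical`
#'   (whether the stored rotation is the canonical one).
#' @export
rhythm_catalog <- function(rhythms = enumerate_wf_rhythms()) {
  data.frame(
    id = vapply(rhythms, function(r) r$id, character(1)),
    n_pulses = vapply(rhythms, function(r) r$n_pulses, integer(1)),
    n_cues = vapply(rhythms, function(r) r$n_cues, integer(1)),
    indicator = vapply(rhythms, format, character(1)),
    ioi_sequence = vapply(
      rhythms, function(r) paste(ioi_sequence(r), collapse = " "), character(1)
    ),
    canonical = vapply(
      rhythms, function(r) identical(format(canonical_rotation(r)), format(r)),
      logical(1)
    ),
    stringsAsFactors = FALSE
  )
}
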