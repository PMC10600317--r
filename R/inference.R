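#' Regression families for tapping observations
#'
#' Four maximum-likelihood observation families cover the four dependent
#' variables: binomial-logit for per-pulse tap counts, upper-censored normal
#' for MIDI velocities (values recorded at the 127 ceiling mean "at least
#' this hard"), two-sided truncated normal for signed asynchronies (taps
#' outside half a window are assigned to the neighbouring pulse, so the data
#' cannot contain them), and beta regression for performance accuracies in
#' the unit interval. Every pulse-level predictor interacts with `cue`, so
#' each fit decomposes per predictor into an uncued (bias) effect, a cued
#' effect, and their difference — the discriminability effect — with the
#' exact identity `cued = uncued + discriminability`.
#'
#' @name inference
NULL

#' Build a standardized model design
#'
#' Assembles the model matrix for one observation family: intercept,
#' performance-, rhythm- and pulse-level predictors, and `cue x predictor`
#' interactions for every pulse-level predictor. Continuous inputs are
#' standardized to mean 0, SD 1; binary (0/1) inputs are left dummy-coded;
#' proportions listed in `keep_scale` are left untouched. Responses named
#' `tap_vel` or `tap_delta` are divided by their SD but not centred; the
#' standardization record is stored so the same transform can be re-applied.
#'
#' @param data a data.frame holding the response and all predictor columns.
#' @param response response column name, or `c("tap_num", "n_pulses")` for
#'   the binomial family.
#' @param predictors non-interacting predictor column names.
#' @param pulse_predictors pulse-level predictor names; each enters both as
#'   a main effect and interacted with `cue`.
#' @param cue name of the cue indicator column (default `"cue"`; set `NULL`
#'   for designs without cue interactions).
#' @param keep_scale predictor names to leave unstandardized (e.g. a
#'   `tap_lag1` proportion).
#' @param standardization optional standardization record from a previous
#'   design (list of `c(center, scale)` per column) to re-apply instead of
#'   estimating from `data`.
#' @return an object of class `"tap_design"`: list with `x` (model matrix),
#'   `y` (response vector or two-column count matrix), `standardization`,
#'   `response_scale` (SD divisor applied to the response, 1 if none).
#' @export
build_design <- function(data, response, predictors = character(0),
                         pulse_predictors = character(0), cue = "cue",
                         keep_scale = character(0),
                         standardization = NULL) {
  n <- nrow(data)
  cols <- list(intercept = rep(1, n))
  std <- list()
  std_col <- function(name, x) {
    if (all(x %in% c(0, 1)) || name %in% keep_scale) {
      return(x)
    }
    if (!is.null(standardization) && !is.null(standardization[[name]])) {
      rec <- standardization[[name]]
    } else {
      rec <- c(center = mean(x), scale = stats::sd(x))
      if (rec[["scale"]] == 0) {
        stop("predictor '", name, "' is constant", call. = FALSE)
      }
    }
    std[[name]] <<- rec
    (x - rec[["center"]]) / rec[["scale"]]
  }
  for (p in predictors) {
    if (!p %in% names(data)) stop("missing predictor column: ", p, call. = FALSE)
    cols[[p]] <- std_col(p, data[[p]])
  }
  if (!is.null(cue) && (length(pulse_predictors) > 0L || cue %in% names(data))) {
    cue_x <- data[[cue]]
    cols[[cue]] <- cue_x
  }
  for (p in pulse_predictors) {
    if (!p %in% names(data)) stop("missing predictor column: ", p, call. = FALSE)
    x <- std_col(p, data[[p]])
    cols[[p]] <- x
    if (!is.null(cue)) cols[[paste0(cue, ":", p)]] <- data[[cue]] * x
  }
  x <- do.call(cbind, cols)
  colnames(x) <- names(cols)
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    aliased <- colnames(x)[qrx$pivot[(qrx$rank + 1L):ncol(x)]]
    stop(
      "design is rank deficient; aliased columns: ",
      paste(aliased, collapse = ", "),
      call. = FALSE
    )
  }
  response_scale <- 1
  if (length(response) == 2L) {
    y <- as.matrix(data[, response])
  } else {
    y <- data[[response]]
    if (response %in% c("tap_vel", "tap_delta")) {
      response_scale <- stats::sd(y)
      y <- y / response_scale
    }
  }
  structure(
    list(
      x = x, y = y,
      standardization = std,
      response = response,
      response_scale = response_scale
    ),
    class = "tap_design"
  )
}

# Student-t(df, 0, scale) log density penalty summed over coefficients
# (intercept excluded).
t_penalty <- function(beta, df = 3, scale = 1) {
  b <- beta[names(beta) != "intercept"]
  sum(stats::dt(b / scale, df = df, log = TRUE) - log(scale))
}

fit_ml <- function(design, nll, n_aux = 0L, aux_names = character(0),
                   family, extra = list()) {
  p <- ncol(design$x)
  par0 <- numeric(p + n_aux)
  opt <- stats::optim(par0, nll,
    method = "BFGS",
    control = list(maxit = 500, reltol = 1e-12), hessian = TRUE
  )
  grad_norm <- sqrt(sum(numerical_grad(nll, opt$par)^2))
  vc <- tryCatch(solve(opt$hessian), error = function(e) {
    matrix(NA_real_, length(opt$par), length(opt$par))
  })
  nm <- c(colnames(design$x), aux_names)
  coefs <- stats::setNames(opt$par, nm)
  se <- stats::setNames(sqrt(pmax(diag(vc), 0)), nm)
  dimnames(vc) <- list(nm, nm)
  out <- c(
    list(
      family = family,
      coefficients = coefs,
      se = se,
      vcov = vc,
      loglik = -opt$value,
      converged = opt$convergence == 0L,
      grad_norm = grad_norm,
      design = design
    ),
    extra
  )
  class(out) <- "tap_fit"
  out
}

numerical_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x))
    e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

#' @export
print.tap_fit <- function(x, ...) {
  cat(sprintf(
    "<tap_fit %s> logLik %.3f, %sconverged (|grad| %.2e)\n",
    x$family, x$loglik, if (x$converged) "" else "NOT ", x$grad_norm
  ))
  tab <- data.frame(
    estimate = x$coefficients,
    se = x$se,
    z = x$coefficients / x$se
  )
  if (x$family == "binomial-logit") tab$odds_ratio <- exp(x$coefficients)
  print(round(tab, 4))
  invisible(x)
}

#' Binomial-logit fit for tap counts
#'
#' Maximum (optionally penalized) likelihood for per-pulse binomial tap
#' counts with a logit link: response rows are `(tap_num, n_pulses)` pairs.
#' Coefficients are log odds ratios; `exp(coefficient)` is the odds ratio.
#' The optional penalty is the Student-t(3, 0, 1) log density on every
#' non-intercept coefficient, a weakly informative shrinkage toward small
#' to medium effects on the standardized scale.
#'
#' @param design a [build_design()] result with a two-column count response.
#' @param penalty `"none"` (default) or `"student_t"`.
#' @return a `"tap_fit"` with an `odds_ratios` element.
#' @export
fit_binomial_logit <- function(design, penalty = c("none", "student_t")) {
  penalty <- match.arg(penalty)
  x <- design$x
  succ <- design$y[, 1L]
  size <- design$y[, 2L]
  stopifnot(all(succ >= 0), all(succ <= size))
  ln_choose <- lchoose(size, succ)
  nll <- function(par) {
    eta <- drop(x %*% par)
    log1pe <- pmax(eta, 0) + log1p(exp(-abs(eta))) # stable log(1 + e^eta)
    ll <- sum(ln_choose + succ * eta - size * log1pe)
    if (penalty == "student_t") {
      ll <- ll + t_penalty(stats::setNames(par, colnames(x)))
    }
    -ll
  }
  fit <- fit_ml(design, nll, family = "binomial-logit")
  fit$odds_ratios <- exp(fit$coefficients)
  fit$penalty <- penalty
  fit
}

#' Upper-censored normal fit for tap velocities
#'
#' Gaussian regression where responses at or above `ceiling` are treated as
#' censored (recorded as the ceiling but meaning "at least this much"):
#' censored rows contribute the upper-tail mass, uncensored rows the normal
#' density. With no censored rows the estimates coincide with ordinary
#' least squares.
#'
#' @param design a [build_design()] result; the response is the (scaled)
#'   velocity on tapped rows.
#' @param ceiling censoring point on the response scale (default `127`
#'   divided by the design's response scale).
#' @return a `"tap_fit"`; the auxiliary coefficient `log_sigma` is the log
#'   residual SD.
#' @export
fit_censored_normal <- function(design, ceiling = NULL) {
  if (is.null(ceiling)) ceiling <- 127 / design$response_scale
  x <- design$x
  y <- design$y
  cens <- y >= ceiling
  if (all(cens)) stop("all observations are censored", call. = FALSE)
  nll <- function(par) {
    beta <- par[seq_len(ncol(x))]
    sigma <- exp(par[ncol(x) + 1L])
    eta <- drop(x %*% beta)
    ll <- sum(stats::dnorm(y[!cens], eta[!cens], sigma, log = TRUE))
    if (any(cens)) {
      ll <- ll + sum(stats::pnorm(ceiling, eta[cens], sigma,
        lower.tail = FALSE, log.p = TRUE
      ))
    }
    -ll
  }
  fit <- fit_ml(design, nll,
    n_aux = 1L, aux_names = "log_sigma",
    family = "censored-normal", extra = list(ceiling = ceiling)
  )
  fit
}

#' Two-sided truncated normal fit for tap asynchronies
#'
#' Gaussian regression where the response is only observable inside
#' `bounds` (taps further from a pulse belong to the neighbouring pulse, so
#' such values cannot occur): the normal density is renormalized to the
#' window. As the bounds recede to infinity the fit coincides with ordinary
#' Gaussian regression.
#'
#' @param design a [build_design()] result; the response is the (scaled)
#'   signed asynchrony on tapped rows.
#' @param bounds length-2 truncation window on the response scale (default
#'   `c(-117, 117)` divided by the design's response scale).
#' @return a `"tap_fit"` with auxiliary coefficient `log_sigma`.
#' @export
fit_truncated_normal <- function(design, bounds = NULL) {
  if (is.null(bounds)) bounds <- c(-117, 117) / design$response_scale
  stopifnot(length(bounds) == 2L, bounds[1L] < bounds[2L])
  x <- design$x
  y <- design$y
  if (any(y < bounds[1L] | y > bounds[2L])) {
    stop("responses outside the truncation bounds", call. = FALSE)
  }
  nll <- function(par) {
    beta <- par[seq_len(ncol(x))]
    sigma <- exp(par[ncol(x) + 1L])
    eta <- drop(x %*% beta)
    denom <- stats::pnorm(bounds[2L], eta, sigma) -
      stats::pnorm(bounds[1L], eta, sigma)
    -sum(stats::dnorm(y, eta, sigma, log = TRUE) - log(denom))
  }
  fit_ml(design, nll,
    n_aux = 1L, aux_names = "log_sigma",
    family = "truncated-normal", extra = list(bounds = bounds)
  )
}

#' Beta regression for performance accuracy
#'
#' Maximum likelihood beta regression with a logit mean link and a common
#' precision: the accuracy score lies in the unit interval, so fitted means
#' are always in (0, 1). Responses exactly 0 or 1 are nudged inward by a
#' machine-epsilon-scale shrinkage.
#'
#' @param design a [build_design()] result with a response in `[0, 1]`.
#' @return a `"tap_fit"` with auxiliary coefficient `log_phi` (log
#'   precision).
#' @export
fit_beta_accuracy <- function(design) {
  x <- design$x
  y <- design$y
  stopifnot(all(y >= 0), all(y <= 1))
  if (stats::sd(y) == 0) stop("degenerate constant response", call. = FALSE)
  eps <- .Machine$double.eps^0.5
  y <- pmin(pmax(y, eps), 1 - eps)
  nll <- function(par) {
    beta <- par[seq_len(ncol(x))]
    phi <- exp(par[ncol(x) + 1L])
    mu <- stats::plogis(drop(x %*% beta))
    -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  fit_ml(design, nll,
    n_aux = 1L, aux_names = "log_phi",
    family = "beta"
  )
}

#' Signal-detection decomposition of cue interactions
#'
#' For every predictor `x` with a `cue:x` interaction in the fit, reports
#' the effect of `x` at uncued pulses (the main effect, a bias effect), the
#' effect at cued pulses (main effect plus interaction), and their
#' difference (the interaction, the discriminability effect), with standard
#' errors propagated through the coefficient covariance (the cued-effect
#' variance includes the covariance term). The identity
#' `cued = uncued + discriminability` holds exactly.
#'
#' @param fit a `"tap_fit"` from a design with cue interactions.
#' @param cue name of the cue column (default `"cue"`).
#' @return a data.frame with one row per interacting predictor: `predictor`,
#'   `uncued`, `uncued_se`, `cued`, `cued_se`, `discriminability`,
#'   `discriminability_se`.
#' @export
sdt_decompose <- function(fit, cue = "cue") {
  nm <- names(fit$coefficients)
  ints <- grep(paste0("^", cue, ":"), nm, value = TRUE)
  if (length(ints) == 0L) {
    stop("fit has no ", cue, " interactions to decompose", call. = FALSE)
  }
  preds <- sub(paste0("^", cue, ":"), "", ints)
  missing <- setdiff(preds, nm)
  if (length(missing) > 0L) {
    stop(
      "interaction without matching main effect: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  b <- fit$coefficients
  v <- fit$vcov
  data.frame(
    predictor = preds,
    uncued = unname(b[preds]),
    uncued_se = unname(fit$se[preds]),
    cued = unname(b[preds] + b[ints]),
    cued_se = sqrt(unname(
      v[cbind(preds, preds)] + v[cbind(ints, ints)] +
        2 * v[cbind(preds, ints)]
    )),
    discriminability = unname(b[ints]),
    discriminability_se = unname(fit$se[ints]),
    stringsAsFactors = FALSE
  )
}

#' Variance inflation factors
#'
#' `1 / (1 - R^2)` for each column of a predictor matrix regressed on the
#' others (no intercept column; one is added internally).
#'
#' @param x numeric predictor matrix (columns named).
#' @return named numeric vector of VIFs (`Inf` for aliased columns).
#' @export
vif <- function(x) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (p < 2L) return(stats::setNames(rep(1, p), colnames(x)))
  v <- vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    res <- sum(fit$residuals^2)
    tot <- sum((x[, j] - mean(x[, j]))^2)
    # VIF = 1 / (1 - R^2) = total SS / residual SS
    if (res <= tot * 1e-12) Inf else tot / res
  }, numeric(1))
  stats::setNames(v, colnames(x))
}

#' VIF-guarded forward selection
#'
#' Adds candidate predictors in the supplied (externally ranked) order,
#' skipping any whose addition would push any column's variance inflation
#' factor above `vif_max`; previously added predictors are never removed.
#' `vif_max = 10` corresponds to refusing any predictor expressible from
#' the others with `R^2 > 0.9`.
#'
#' @param candidates predictor names in decreasing priority order.
#' @param data data.frame holding the candidate columns.
#' @param vif_max inflation threshold (default 10).
#' @return character vector of selected predictor names.
#' @export
vif_forward_select <- function(candidates, data, vif_max = 10) {
  selected <- character(0)
  for (cand in candidates) {
    trial <- c(selected, cand)
    v <- vif(as.matrix(data[, trial, drop = FALSE]))
    if (all(v <= vif_max)) selected <- trial
  }
  selected
}
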