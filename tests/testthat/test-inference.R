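toy_design <- function(n = 60L, seed = 1L, response = "y") {
  set.seed(seed)
  dat <- data.frame(
    cue = rep(c(0L, 1L), length.out = n),
    x = rnorm(n)
  )
  dat$y <- rnorm(n, 1 + 0.5 * dat$cue + 0.3 * dat$x, 1)
  dat
}

test_that("build_design standardizes, dummy-codes, and adds cue interactions", {
  dat <- toy_design()
  dat$perf_num <- rep(1:6, each = 10)
  d <- build_design(dat,
    response = "y", predictors = "perf_num",
    pulse_predictors = "x"
  )
  expect_identical(colnames(d$x), c("intercept", "perf_num", "cue", "x", "cue:x"))
  expect_equal(mean(d$x[, "perf_num"]), 0, tolerance = 1e-10)
  expect_equal(sd(d$x[, "perf_num"]), 1, tolerance = 1e-10)
  expect_true(all(d$x[, "cue"] %in% c(0, 1))) # binary left dummy-coded
  expect_equal(d$x[, "cue:x"], d$x[, "cue"] * d$x[, "x"])
})

test_that("scale-only responses are divided by SD but not centred", {
  dat <- toy_design()
  dat$tap_vel <- dat$y * 10 + 100
  d <- build_design(dat, response = "tap_vel", pulse_predictors = "x")
  expect_equal(sd(d$y), 1, tolerance = 1e-12)
  expect_gt(mean(d$y), 1) # not centred
  expect_equal(d$response_scale, sd(dat$tap_vel))
})

test_that("rank-deficient designs fail with the aliased columns named", {
  dat <- toy_design()
  dat$x2 <- 2 * dat$x
  expect_error(
    build_design(dat, response = "y", predictors = c("x", "x2")),
    "rank deficient.*x2"
  )
})

test_that("binomial logit matches glm and converts effects to odds ratios", {
  set.seed(8)
  n <- 300L
  dat <- data.frame(cue = rbinom(n, 1, 0.5), x = rnorm(n), n_pulses = 16L)
  eta <- -0.5 + 1.5 * dat$cue + 0.4 * scale(dat$x)[, 1] -
    0.3 * dat$cue * scale(dat$x)[, 1]
  dat$tap_num <- rbinom(n, 16L, plogis(eta))
  d <- build_design(dat,
    response = c("tap_num", "n_pulses"),
    pulse_predictors = "x"
  )
  fit <- fit_binomial_logit(d)
  ref <- glm(
    cbind(tap_num, n_pulses - tap_num) ~ d$x[, -1],
    family = binomial(), data = dat
  )
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-5)
  expect_equal(
    unname(fit$se), unname(sqrt(diag(vcov(ref)))),
    tolerance = 1e-3
  )
  expect_equal(fit$odds_ratios, exp(fit$coefficients))
  # log-likelihood equals the closed-form binomial density sum
  p_hat <- plogis(drop(d$x %*% fit$coefficients))
  expect_equal(
    fit$loglik,
    sum(dbinom(dat$tap_num, 16L, p_hat, log = TRUE)),
    tolerance = 1e-8
  )
})

test_that("the student-t penalty shrinks coefficients toward zero", {
  set.seed(12)
  n <- 40L
  dat <- data.frame(cue = rbinom(n, 1, 0.5), x = rnorm(n), n_pulses = 4L)
  dat$tap_num <- rbinom(n, 4L, plogis(2 * dat$cue))
  d <- build_design(dat, response = c("tap_num", "n_pulses"), pulse_predictors = "x")
  free <- fit_binomial_logit(d)
  pen <- fit_binomial_logit(d, penalty = "student_t")
  expect_lt(abs(pen$coefficients["cue"]), abs(free$coefficients["cue"]))
})

test_that("censored normal equals OLS without censoring and matches survreg", {
  dat <- toy_design(n = 200L, seed = 3L)
  dat$tap_vel <- dat$y
  d <- build_design(dat, response = "tap_vel", pulse_predictors = "x")
  fit <- fit_censored_normal(d, ceiling = Inf)
  ols <- lm(d$y ~ d$x[, -1])
  expect_equal(
    unname(fit$coefficients[1:4]), unname(coef(ols)),
    tolerance = 1e-6
  )

  skip_if_not_installed("survival")
  # censor the top fifth and compare with the survreg tobit likelihood
  cens_point <- quantile(d$y, 0.8)
  y_obs <- pmin(d$y, cens_point)
  dat2 <- dat
  dat2$tap_vel <- y_obs * sd(dat$tap_vel) # undo scale so build_design rescales
  d2 <- build_design(dat2, response = "tap_vel", pulse_predictors = "x")
  fit2 <- fit_censored_normal(d2, ceiling = cens_point * sd(dat$tap_vel) / d2$response_scale)
  sv <- survival::survreg(
    survival::Surv(d2$y, d2$y < cens_point * sd(dat$tap_vel) / d2$response_scale,
      type = "right"
    ) ~ d2$x[, -1],
    dist = "gaussian"
  )
  expect_equal(unname(fit2$coefficients[1:4]), unname(coef(sv)), tolerance = 1e-4)
  expect_equal(
    unname(exp(fit2$coefficients["log_sigma"])), sv$scale,
    tolerance = 1e-4
  )
})

test_that("censored fit is unbiased where naive OLS is biased downward", {
  set.seed(44)
  n <- 2000L
  x <- rnorm(n)
  y_star <- 10 + 2 * x + rnorm(n, 0, 3)
  ceiling_v <- quantile(y_star, 0.8)
  dat <- data.frame(x = x, y = pmin(y_star, ceiling_v))
  d <- build_design(dat, response = "y", predictors = "x")
  fit <- fit_censored_normal(d, ceiling = ceiling_v)
  ols <- lm(y ~ scale(x), data = dat)
  expect_lt(coef(ols)[2], 2 * sd(x)) # attenuated
  expect_lt(
    abs(fit$coefficients[["x"]] - 2 * sd(x)),
    3 * fit$se[["x"]]
  )
})

test_that("truncated normal recovers the untruncated limit and quadrature loglik", {
  dat <- toy_design(n = 150L, seed = 5L)
  d <- build_design(dat, response = "y", pulse_predictors = "x")
  wide <- fit_truncated_normal(d, bounds = c(-1e6, 1e6))
  ols <- lm(d$y ~ d$x[, -1])
  expect_equal(unname(wide$coefficients[1:4]), unname(coef(ols)), tolerance = 1e-5)

  # 10-row toy table: loglik at the optimum equals brute-force numerical
  # renormalization of the window density
  toy <- dat[1:10, ]
  toy$y <- pmin(pmax(toy$y, -2), 2)
  d10 <- build_design(toy, response = "y", pulse_predictors = "x")
  fit <- fit_truncated_normal(d10, bounds = c(-2.5, 2.5))
  beta <- fit$coefficients[1:4]
  sigma <- exp(fit$coefficients["log_sigma"])
  eta <- drop(d10$x %*% beta)
  ll_oracle <- sum(vapply(seq_len(10L), function(i) {
    z <- stats::integrate(
      function(u) dnorm(u, eta[i], sigma),
      -2.5, 2.5,
      rel.tol = 1e-12
    )$value
    dnorm(d10$y[i], eta[i], sigma, log = TRUE) - log(z)
  }, numeric(1)))
  expect_equal(fit$loglik, ll_oracle, tolerance = 1e-8)
  expect_error(
    fit_truncated_normal(d10, bounds = c(-0.5, 0.5)),
    "outside the truncation bounds"
  )
})

test_that("censored loglik matches quadrature tail mass on a toy table", {
  dat <- toy_design(n = 10L, seed = 6L)
  d <- build_design(dat, response = "y", pulse_predictors = "x")
  cpoint <- median(d$y)
  dat$y2 <- pmin(d$y, cpoint)
  d2 <- build_design(dat, response = "y2", pulse_predictors = "x")
  fit <- fit_censored_normal(d2, ceiling = cpoint)
  beta <- fit$coefficients[1:4]
  sigma <- exp(fit$coefficients["log_sigma"])
  eta <- drop(d2$x %*% beta)
  cens <- d2$y >= cpoint
  ll_oracle <- sum(dnorm(d2$y[!cens], eta[!cens], sigma, log = TRUE)) +
    sum(vapply(which(cens), function(i) {
      log(stats::integrate(function(u) dnorm(u, eta[i], sigma),
        cpoint, Inf,
        rel.tol = 1e-12
      )$value)
    }, numeric(1)))
  expect_equal(fit$loglik, ll_oracle, tolerance = 1e-8)
})

test_that("beta regression keeps fitted means in (0,1) and handles constants", {
  set.seed(10)
  n <- 200L
  dat <- data.frame(x = rnorm(n))
  mu <- plogis(0.8 + 0.5 * scale(dat$x)[, 1])
  dat$tap_acc <- rbeta(n, mu * 20, (1 - mu) * 20)
  d <- build_design(dat, response = "tap_acc", predictors = "x", cue = NULL)
  fit <- fit_beta_accuracy(d)
  mu_hat <- plogis(drop(d$x %*% fit$coefficients[1:2]))
  expect_true(all(mu_hat > 0 & mu_hat < 1))
  expect_lt(abs(fit$coefficients[["x"]] - 0.5), 3 * fit$se[["x"]])
  # loglik matches a normalizing-constant quadrature oracle on 10 rows
  toy <- dat[1:10, , drop = FALSE]
  d10 <- build_design(toy, response = "tap_acc", predictors = "x", cue = NULL)
  f10 <- fit_beta_accuracy(d10)
  phi <- exp(f10$coefficients["log_phi"])
  mu10 <- plogis(drop(d10$x %*% f10$coefficients[1:2]))
  ll_oracle <- sum(vapply(seq_len(10L), function(i) {
    a <- mu10[i] * phi
    b <- (1 - mu10[i]) * phi
    z <- stats::integrate(function(u) u^(a - 1) * (1 - u)^(b - 1), 0, 1,
      rel.tol = 1e-13
    )$value
    (a - 1) * log(d10$y[i]) + (b - 1) * log(1 - d10$y[i]) - log(z)
  }, numeric(1)))
  expect_equal(f10$loglik, ll_oracle, tolerance = 1e-7)

  dat$tap_acc <- 0.7
  expect_error(
    fit_beta_accuracy(build_design(dat, response = "tap_acc", predictors = "x", cue = NULL)),
    "degenerate"
  )
})

test_that("sdt decomposition satisfies cued = uncued + discriminability exactly", {
  set.seed(15)
  n <- 400L
  dat <- data.frame(cue = rbinom(n, 1, 0.5), x = rnorm(n), z = rnorm(n), n_pulses = 12L)
  eta <- 0.2 + 1 * dat$cue + 0.30 * dat$x - 0.27 * dat$cue * dat$x + 0.1 * dat$z
  dat$tap_num <- rbinom(n, 12L, plogis(eta))
  d <- build_design(dat,
    response = c("tap_num", "n_pulses"),
    pulse_predictors = c("x", "z")
  )
  fit <- fit_binomial_logit(d)
  dec <- sdt_decompose(fit)
  expect_setequal(dec$predictor, c("x", "z"))
  expect_equal(dec$cued, dec$uncued + dec$discriminability, tolerance = 1e-12)
  # cued-effect variance includes the covariance term
  i <- which(dec$predictor == "x")
  v <- fit$vcov
  expect_equal(
    dec$cued_se[i],
    sqrt(v["x", "x"] + v["cue:x", "cue:x"] + 2 * v["x", "cue:x"])
  )
  d0 <- build_design(dat, response = c("tap_num", "n_pulses"), predictors = "x")
  expect_error(sdt_decompose(fit_binomial_logit(d0)), "no cue interactions")
})

test_that("worked decomposition arithmetic: OR conversion and effect sum", {
  # both numbers are printed at 2 dp, so they agree to half a unit in
  # the last place: exp(0.17) = 1.185
  expect_lt(abs(exp(0.17) - 1.18), 0.01)
  expect_equal(0.30 + (-0.27), 0.03)
})

test_that("null simulated discriminability is near zero", {
  set.seed(33)
  n <- 4000L
  dat <- data.frame(cue = rbinom(n, 1, 0.5), x = rnorm(n), n_pulses = 10L)
  dat$tap_num <- rbinom(n, 10L, plogis(0.4 * dat$x)) # p_hit = p_fa
  d <- build_design(dat, response = c("tap_num", "n_pulses"), pulse_predictors = "x")
  dec <- sdt_decompose(fit_binomial_logit(d))
  expect_lt(
    abs(dec$discriminability), 3 * dec$discriminability_se
  )
})

test_that("VIF selection skips collinear candidates and keeps orthogonal ones", {
  set.seed(20)
  n <- 100L
  dat <- data.frame(a = rnorm(n))
  dat$b <- dat$a # perfectly collinear
  dat$c <- rnorm(n)
  sel <- vif_forward_select(c("a", "b", "c"), dat)
  expect_identical(sel, c("a", "c"))
  # orthogonal designs have VIF 1
  q <- qr.Q(qr(matrix(rnorm(300), 100, 3)))
  colnames(q) <- c("q1", "q2", "q3")
  expect_equal(unname(vif(q)), rep(1, 3), tolerance = 1e-3)
  # VIF 10 corresponds to R^2 = 0.9 on the same regression
  x1 <- rnorm(n)
  e <- residuals(lm(rnorm(n) ~ x1))
  x2 <- x1 * sqrt(0.9) / sd(x1) + e * sqrt(0.1) / sd(e)
  v <- vif(cbind(x1 = x1, x2 = x2))
  r2 <- summary(lm(x2 ~ x1))$r.squared
  expect_equal(unname(v["x2"]), 1 / (1 - r2), tolerance = 1e-10)
})

test_that("odds ratios are strictly increasing in coefficients", {
  b <- sort(rnorm(20))
  expect_true(all(diff(exp(b)) > 0))
  expect_equal(exp(0), 1)
})
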