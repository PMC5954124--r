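# Generate a phenotype-level mediation dataset directly from the structural
# model: exposure score Z ~ N(0,1), binary mediator from a logistic model,
# outcome from the configured family.
make_mediation_data <- function(n, b0 = -1, b1 = 1, t0 = 0, t1 = 1, t2 = 2,
                                t3 = 0, sigma = 2, family = "linear",
                                seed = 1) {
  withr::with_seed(seed, {
    z <- rnorm(n)
    a <- dichotomize_exposure(z)
    m <- rbinom(n, 1, plogis(b0 + b1 * z))
    lp <- t0 + t1 * z + t2 * m + t3 * z * m
    y <- if (family == "linear") lp + sigma * rnorm(n)
         else rbinom(n, 1, plogis(lp))
    data.frame(z = z, a = a, m = m, y = y)
  })
}

test_that("quartile dichotomisation keeps the extremes and drops the middle", {
  a <- dichotomize_exposure(1:8)
  expect_equal(a[7:8], c(1, 1), ignore_attr = TRUE)
  expect_equal(a[1:2], c(0, 0), ignore_attr = TRUE)
  expect_true(all(is.na(a[4:5])))
  expect_error(dichotomize_exposure(rep(2, 20)), "degenerate")
  expect_error(dichotomize_exposure(1:5), "at least 8")
  u <- withr::with_seed(3, runif(383))
  au <- dichotomize_exposure(u)
  expect_lt(abs(sum(!is.na(au)) - 383 / 2), 10)
})

test_that("natural effects match hand computation and null structure", {
  mfit <- list(b0 = 0, b1 = 1, b2 = numeric(0))
  ofit <- list(t0 = 0, t1 = 2, t2 = 3, t3 = 0, t4 = numeric(0),
               family = "linear")
  est <- estimate_effects(mfit, ofit)
  expect_equal(est$nde, 2)
  expect_equal(est$nie, 3 * (plogis(1) - 0.5), tolerance = 1e-10)
  expect_equal(round(est$nie, 4), 0.6932)
  expect_equal(round(est$proportion_mediated, 4), 0.2574)
  # no mediator pathway: NIE and PM vanish whatever the mediator model
  ofit0 <- modifyList(ofit, list(t2 = 0))
  est0 <- estimate_effects(list(b0 = 2, b1 = -3, b2 = numeric(0)), ofit0)
  expect_equal(est0$nie, 0)
  expect_equal(est0$proportion_mediated, 0)
})

test_that("point estimates agree with the Monte-Carlo counterfactual oracle", {
  withr::with_seed(11, {
    for (i in 1:6) {
      mfit <- list(b0 = runif(1, -1, 1), b1 = runif(1, -1.5, 1.5),
                   b2 = numeric(0))
      interaction <- i %% 2 == 0
      family <- if (i <= 3) "linear" else "logistic"
      t0 <- if (family == "logistic") runif(1, -6, -4) else runif(1, -1, 1)
      ofit <- list(t0 = t0, t1 = runif(1, -1, 1), t2 = runif(1, -1, 1),
                   t3 = if (interaction) runif(1, -0.5, 0.5) else 0,
                   t4 = numeric(0), family = family)
      est <- estimate_effects(mfit, ofit)
      mc <- oracle_mediation_mc(mfit, ofit, n_draws = 2e5)
      slack <- if (family == "logistic")
        0.02 * (abs(est$nde) + abs(est$nie)) else 0
      expect_lt(abs(est$nde - mc$nde), 3 * mc$se_nde + slack + 1e-10)
      expect_lt(abs(est$nie - mc$nie), 3 * mc$se_nie + slack + 1e-10)
    }
  })
})

test_that("linear-family effects always decompose additively", {
  withr::with_seed(13, {
    for (i in 1:10) {
      mfit <- list(b0 = rnorm(1), b1 = rnorm(1), b2 = rnorm(2))
      ofit <- list(t0 = rnorm(1), t1 = rnorm(1), t2 = rnorm(1),
                   t3 = rnorm(1), t4 = rnorm(2), family = "linear")
      est <- estimate_effects(mfit, ofit, c = rnorm(2))
      expect_equal(est$total, est$nde + est$nie, tolerance = 1e-12)
    }
  })
})

test_that("without interaction the direct effect ignores the mediator model", {
  ofit <- list(t0 = 1, t1 = 1.7, t2 = 2, t3 = 0, t4 = numeric(0),
               family = "linear")
  e1 <- estimate_effects(list(b0 = 0, b1 = 1, b2 = numeric(0)), ofit)
  e2 <- estimate_effects(list(b0 = -3, b1 = 0.1, b2 = numeric(0)), ofit)
  expect_equal(e1$nde, 1.7)
  expect_equal(e2$nde, 1.7)
})

test_that("fitting recovers generating coefficients and handles errors", {
  # mediator and outcome driven directly by the binary exposure, so the
  # fitted coefficients estimate the generating ones
  d <- withr::with_seed(17, {
    a <- rep(c(0, 1), each = 2000)
    m <- rbinom(4000, 1, plogis(-1 + 1 * a))
    y <- 0.5 + 1 * a + 2 * m + 2 * rnorm(4000)
    data.frame(a = a, m = m, y = y)
  })
  est <- fit_and_estimate(d, "y", "m", "a")
  expect_equal(est$mfit$b1, 1, tolerance = 0.3)
  expect_equal(est$ofit$t1, 1, tolerance = 0.3)
  expect_equal(est$ofit$t2, 2, tolerance = 0.15)
  d_const <- d; d_const$m <- 1
  expect_error(fit_and_estimate(d_const, "y", "m", "a"), "constant")
  expect_error(fit_and_estimate(d, "y", "m", "missing_col"), "not found")
})

test_that("an interaction term on interaction-free data barely moves the estimates", {
  d <- make_mediation_data(3000, t3 = 0, seed = 19)
  e_plain <- fit_and_estimate(d, "y", "m", "a", interaction = FALSE)
  e_int <- fit_and_estimate(d, "y", "m", "a", interaction = TRUE)
  # within half a bootstrap-scale SE, proxied by the outcome-model noise
  scale <- 2 / sqrt(nrow(d) / 2)
  expect_lt(abs(e_plain$nde - e_int$nde), 0.5 * scale * 5)
  expect_lt(abs(e_plain$nie - e_int$nie), 0.5 * scale * 5)
})

test_that("bias-corrected intervals are deterministic and cover degenerate cases", {
  expect_equal(erpmed:::bc_interval(rep(2.5, 100), 2.5), c(2.5, 2.5))
  d <- make_mediation_data(600, seed = 23)
  b1 <- bootstrap_bcci(d, "y", "m", "a", n_boot = 60, seed = 5)
  b2 <- bootstrap_bcci(d, "y", "m", "a", n_boot = 60, seed = 5)
  expect_identical(b1$ci_nde, b2$ci_nde)
  expect_identical(b1$ci_nie, b2$ci_nie)
  expect_true(b1$ci_nie[1] <= b1$nie && b1$nie <= b1$ci_nie[2])
  expect_error(bootstrap_bcci(d, "y", "m", "a", n_boot = 10), "at least 50")
})

test_that("a null exposure-mediator path gives NIE intervals covering zero", {
  # 200 bootstrap draws (the method default): fewer draws estimate the 2.5%
  # tails too coarsely for a fair coverage check
  covered <- vapply(1:20, function(s) {
    d <- make_mediation_data(500, b1 = 0, seed = 100 + s)
    b <- bootstrap_bcci(d, "y", "m", "a", n_boot = 200, seed = s)
    b$ci_nie[1] <= 0 && 0 <= b$ci_nie[2]
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("zero-strength sensitivity reproduces the unadjusted estimates exactly", {
  d <- make_mediation_data(500, seed = 29)
  base <- fit_and_estimate(d, "y", "m", "a")
  sens <- sensitivity_unmeasured(d, "y", "m", "a",
                                 strengths = cbind(0, 0), n_draws = 3,
                                 seed = 1)
  expect_equal(sens$nde, base$nde)
  expect_equal(sens$nie, base$nie)
  expect_equal(sens$proportion_mediated, base$proportion_mediated)
})

test_that("sensitivity analysis attenuates the indirect effect as confounding grows", {
  d <- make_mediation_data(800, seed = 31)
  sens <- sensitivity_unmeasured(d, "y", "m", "a",
                                 strengths = cbind(r_mu = c(0, 0.3, 0.5),
                                                   r_yu = c(0, 0.3, 0.5)),
                                 n_draws = 30, seed = 2)
  expect_true(all(diff(abs(sens$nie)) < 0))
  expect_error(
    sensitivity_unmeasured(d, "y", "m", "a", strengths = cbind(0.9, -0.9),
                           n_draws = 2, seed = 3),
    "infeasible")
})

test_that("adjusting for the planted confounder strength moves the estimate toward truth", {
  # data generated WITH a real confounder U at correlation ~0.3 with both
  # mediator liability and outcome
  better <- vapply(1:10, function(s) {
    d <- withr::with_seed(200 + s, {
      n <- 800
      z <- rnorm(n)
      u <- rnorm(n)
      m <- rbinom(n, 1, plogis(-1 + z + 0.8 * u))
      y <- 1 * z + 2 * m + 1.5 * u + 2 * rnorm(n)
      data.frame(z = z, a = dichotomize_exposure(z), m = m, y = y)
    })
    truth <- fit_and_estimate(transform(d, u_true = withr::with_seed(
      200 + s, {z <- rnorm(800); u <- rnorm(800); u})),
      "y", "m", "a", covariates = "u_true")$nie
    unadj <- fit_and_estimate(d, "y", "m", "a")$nie
    adj <- sensitivity_unmeasured(d, "y", "m", "a",
                                  strengths = cbind(0.3, 0.3),
                                  n_draws = 20, seed = s)$nie
    abs(adj - truth) < abs(unadj - truth)
  }, logical(1))
  expect_gte(mean(better), 0.7)
})
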