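#' Dichotomise a polygenic score into quartile extremes
#'
#' The mediation exposure contrasts the top against the bottom quartile of a
#' score: samples at or above the 75th percentile get A = 1, samples at or
#' below the 25th percentile get A = 0, and the middle half is excluded
#' (NA). Quantiles are empirical with linear interpolation; ties at a
#' boundary keep the sample in the extreme group.
#'
#' @param scores Numeric score vector (optionally named by sample id).
#' @return Numeric vector of 1 / 0 / NA, same length and names as
#'   \code{scores}.
#' @export
dichotomize_exposure <- function(scores) {
  if (length(scores) < 8) stopf("need at least 8 samples to form quartiles")
  qs <- stats::quantile(scores, c(0.25, 0.75), type = 7, names = FALSE)
  if (qs[1] == qs[2]) stopf("degenerate score distribution: quartiles equal")
  a <- rep(NA_real_, length(scores))
  a[scores >= qs[2]] <- 1
  a[scores <= qs[1]] <- 0
  names(a) <- names(scores)
  a
}

#' Natural direct and indirect effects from fitted model coefficients
#'
#' Regression-based counterfactual mediation for a binary mediator M, binary
#' exposure contrast \code{a} vs \code{a_star}, and a continuous (linear) or
#' binary (logistic, rare-outcome approximation) outcome, with optional
#' exposure-mediator interaction.
#'
#' With mediator model \code{logit P(M = 1 | A, C) = b0 + b1 A + b2' C},
#' outcome model \code{E[Y | A, M, C] = t0 + t1 A + t2 M + t3 A M + t4' C}
#' (linear) or the same linear predictor on the logit scale (logistic), and
#' \code{LP(a) = b0 + b1 a + b2' c}:
#' \itemize{
#'   \item linear: \code{NDE = (t1 + t3 expit(LP(a*))) (a - a*)},
#'     \code{NIE = (t2 + t3 a) (expit(LP(a)) - expit(LP(a*)))}, total =
#'     NDE + NIE, proportion mediated = NIE / total;
#'   \item logistic (rare outcome): odds-ratio expressions for the natural
#'     direct and indirect effects, reported as log odds ratios, with the
#'     proportion mediated computed on the odds-ratio scale as
#'     \code{OR_NDE (OR_NIE - 1) / (OR_NDE OR_NIE - 1)}.
#' }
#'
#' @param mfit List with \code{b0}, \code{b1}, \code{b2} (vector, may be
#'   empty): mediator-model coefficients.
#' @param ofit List with \code{t0}, \code{t1}, \code{t2}, \code{t3},
#'   \code{t4} (vector, may be empty) and \code{family} ("linear" or
#'   "logistic").
#' @param a,a_star Exposed and reference exposure levels.
#' @param c Covariate values at which effects are evaluated (defaults to
#'   none).
#' @return List of class \code{mediation_estimates}: \code{nde}, \code{nie},
#'   \code{total}, \code{proportion_mediated}, \code{family},
#'   \code{pm_defined}.
#' @export
estimate_effects <- function(mfit, ofit, a = 1, a_star = 0, c = numeric(0)) {
  b2c <- if (length(c)) sum(mfit$b2 * c) else 0
  lp <- function(x) mfit$b0 + mfit$b1 * x + b2c
  t1 <- ofit$t1; t2 <- ofit$t2; t3 <- ofit$t3 %||% 0
  family <- ofit$family %||% "linear"
  if (family == "linear") {
    nde <- (t1 + t3 * expit(lp(a_star))) * (a - a_star)
    nie <- (t2 + t3 * a) * (expit(lp(a)) - expit(lp(a_star)))
    total <- nde + nie
    pm_defined <- abs(total) > .Machine$double.eps^0.5
    pm <- if (pm_defined) nie / total else NA_real_
  } else if (family == "logistic") {
    or_nde <- exp(t1 * (a - a_star)) *
      (1 + exp(t2 + t3 * a + lp(a_star))) /
      (1 + exp(t2 + t3 * a_star + lp(a_star)))
    or_nie <- ((1 + exp(lp(a_star))) * (1 + exp(t2 + t3 * a + lp(a)))) /
      ((1 + exp(lp(a))) * (1 + exp(t2 + t3 * a + lp(a_star))))
    nde <- log(or_nde)
    nie <- log(or_nie)
    total <- nde + nie
    denom <- or_nde * or_nie - 1
    pm_defined <- abs(denom) > .Machine$double.eps^0.5
    pm <- if (pm_defined) or_nde * (or_nie - 1) / denom else NA_real_
  } else stopf("unknown outcome family '%s'", family)
  structure(list(nde = nde, nie = nie, total = total,
                 proportion_mediated = pm, pm_defined = pm_defined,
                 family = family),
            class = "mediation_estimates")
}

# Fit the mediator (logistic) and outcome (linear or logistic) models on an
# analysis table and return coefficient lists in estimate_effects() form.
fit_mediation_models <- function(data, outcome, mediator, exposure,
                                 covariates, interaction, family) {
  m <- data[[mediator]]
  a <- data[[exposure]]
  if (length(unique(m)) < 2) stopf("mediator is constant in the subset")
  C <- if (length(covariates))
    as.matrix(data[, covariates, drop = FALSE]) else
      matrix(0, nrow(data), 0)
  Xm <- cbind(intercept = 1, a = a, C)
  med <- logistic_fit(m, Xm)
  Xo <- if (interaction) cbind(intercept = 1, a = a, m = m, am = a * m, C)
        else cbind(intercept = 1, a = a, m = m, C)
  y <- data[[outcome]]
  if (family == "linear") {
    out <- ols_fit(y, Xo)
  } else {
    out <- logistic_fit(y, Xo)
  }
  k <- length(covariates)
  oc <- out$coefficients
  list(mfit = list(b0 = unname(med$coefficients[1]),
                   b1 = unname(med$coefficients[2]),
                   b2 = if (k) unname(med$coefficients[2 + seq_len(k)])
                        else numeric(0)),
       ofit = list(t0 = unname(oc[1]), t1 = unname(oc[2]),
                   t2 = unname(oc[3]),
                   t3 = if (interaction) unname(oc[4]) else 0,
                   t4 = if (k) unname(oc[length(oc) - k + seq_len(k)])
                        else numeric(0),
                   family = family))
}

#' Fit mediation models and estimate natural effects
#'
#' Restricts to complete cases on outcome, mediator, exposure and
#' covariates; fits a logistic mediator model and a linear or logistic
#' outcome model; and evaluates \code{\link{estimate_effects}} at the
#' covariate means of the analysis subset for the contrast \code{a = 1} vs
#' \code{a_star = 0}.
#'
#' @param data Data frame holding all variables.
#' @param outcome Name of the outcome column.
#' @param mediator Name of the binary mediator column.
#' @param exposure Name of the binary exposure column (1/0/NA; NA rows are
#'   excluded).
#' @param covariates Character vector of covariate column names.
#' @param interaction Include an exposure-mediator interaction term?
#' @param family \code{"linear"} or \code{"logistic"}; if NULL, inferred
#'   from the outcome (binary 0/1 -> logistic).
#' @return A \code{mediation_estimates} list augmented with \code{n} (the
#'   analysis-subset size), the fitted coefficient lists and the covariate
#'   evaluation point.
#' @export
fit_and_estimate <- function(data, outcome, mediator, exposure,
                             covariates = character(), interaction = FALSE,
                             family = NULL) {
  vars <- c(outcome, mediator, exposure, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stopf("columns not found: %s", paste(missing_cols, collapse = ", "))
  cc <- stats::complete.cases(data[, vars, drop = FALSE])
  d <- data[cc, , drop = FALSE]
  if (nrow(d) < length(vars) + 2) stopf("too few complete cases")
  if (is.null(family))
    family <- if (all(d[[outcome]] %in% c(0, 1))) "logistic" else "linear"
  fits <- fit_mediation_models(d, outcome, mediator, exposure, covariates,
                               interaction, family)
  cbar <- if (length(covariates))
    colMeans(d[, covariates, drop = FALSE]) else numeric(0)
  est <- estimate_effects(fits$mfit, fits$ofit, a = 1, a_star = 0, c = cbar)
  est$n <- nrow(d)
  est$mfit <- fits$mfit
  est$ofit <- fits$ofit
  est$covariate_values <- cbar
  est$interaction <- interaction
  est
}

# Fieller-type interval for the proportion mediated: the set of candidate
# proportions p for which the bias-corrected interval of NIE - p * total
# covers zero. The raw ratio NIE/total has a wrapped, heavy-tailed bootstrap
# distribution whenever the total effect is weakly identified (draws cross
# zero), where percentile intervals are defective; the linear-combination
# formulation avoids the ratio entirely and can legitimately return very
# wide (or unbounded) intervals when the total effect is indistinguishable
# from zero.
fieller_pm_interval <- function(boot_nie, boot_total, point_nie,
                                point_total, conf = 0.95,
                                grid = seq(-25, 25, by = 0.01)) {
  ok <- is.finite(boot_nie) & is.finite(boot_total)
  boot_nie <- boot_nie[ok]
  boot_total <- boot_total[ok]
  if (!length(boot_nie)) return(c(NA_real_, NA_real_))
  covered <- vapply(grid, function(p) {
    ci <- bc_interval(boot_nie - p * boot_total,
                      point_nie - p * point_total, conf)
    !anyNA(ci) && ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  if (!any(covered)) return(c(NA_real_, NA_real_))
  lo <- grid[which(covered)[1]]
  hi <- grid[rev(which(covered))[1]]
  if (lo == grid[1]) lo <- -Inf
  if (hi == grid[length(grid)]) hi <- Inf
  c(lo, hi)
}

# One bias-corrected percentile interval.
bc_interval <- function(boot, point, conf = 0.95) {
  boot <- boot[is.finite(boot)]
  if (!length(boot)) return(c(NA_real_, NA_real_))
  if (max(boot) - min(boot) < 1e-12)
    return(c(point, point))
  frac <- mean(boot < point)
  frac <- min(max(frac, 1 / (2 * length(boot))), 1 - 1 / (2 * length(boot)))
  z0 <- stats::qnorm(frac)
  zc <- stats::qnorm(1 - (1 - conf) / 2)
  probs <- stats::pnorm(c(2 * z0 - zc, 2 * z0 + zc))
  unname(stats::quantile(boot, probs, type = 7))
}

#' Bias-corrected bootstrap intervals for mediation effects
#'
#' Resamples individuals with replacement within the analysis subset,
#' re-fits both models and re-estimates the natural effects, and forms 95
#' percent bias-corrected percentile intervals (bias correction z0 from the
#' fraction of bootstrap estimates below the point estimate; no acceleration
#' term) for the direct, indirect and total effects. The proportion mediated
#' is a ratio whose bootstrap distribution wraps through infinity whenever
#' the total effect is weakly identified, so its interval is computed by a
#' Fieller-type inversion of the bias-corrected interval of
#' \code{NIE - p * total} (unbounded when the total effect is
#' indistinguishable from zero).
#'
#' @inheritParams fit_and_estimate
#' @param n_boot Number of bootstrap replications (>= 50).
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return The \code{\link{fit_and_estimate}} result augmented with
#'   \code{ci_nde}, \code{ci_nie}, \code{ci_total}, \code{ci_pm},
#'   \code{n_boot}, \code{n_failed}, \code{seed}.
#' @export
bootstrap_bcci <- function(data, outcome, mediator, exposure,
                           covariates = character(), interaction = FALSE,
                           family = NULL, n_boot = 200L, seed = 1L,
                           conf = 0.95) {
  if (n_boot < 50) stopf("n_boot must be at least 50")
  point <- fit_and_estimate(data, outcome, mediator, exposure, covariates,
                            interaction, family)
  vars <- c(outcome, mediator, exposure, covariates)
  cc <- stats::complete.cases(data[, vars, drop = FALSE])
  d <- data[cc, , drop = FALSE]
  boot <- with_seed(substream_seed(seed, "bootstrap"), {
    replicate(n_boot, {
      idx <- sample.int(nrow(d), replace = TRUE)
      est <- tryCatch(
        fit_and_estimate(d[idx, , drop = FALSE], outcome, mediator,
                         exposure, covariates, interaction, family),
        error = function(e) NULL)
      if (is.null(est)) c(NA_real_, NA_real_, NA_real_, NA_real_)
      else c(est$nde, est$nie, est$total, est$proportion_mediated)
    })
  })
  n_failed <- sum(is.na(boot[1, ]))
  if (n_failed > 0.2 * n_boot)
    stopf("bootstrap failure rate too high: %d of %d replicates failed",
          n_failed, n_boot)
  point$ci_nde <- bc_interval(boot[1, ], point$nde, conf)
  point$ci_nie <- bc_interval(boot[2, ], point$nie, conf)
  point$ci_total <- bc_interval(boot[3, ], point$total, conf)
  point$ci_pm <- fieller_pm_interval(boot[2, ], boot[3, ], point$nie,
                                     point$total, conf)
  point$n_boot <- n_boot
  point$n_failed <- n_failed
  point$seed <- seed
  point
}

#' Sensitivity of mediation estimates to unmeasured confounding
#'
#' For each requested confounder strength pair \code{(r_MU, r_YU)}, a
#' standard-normal confounder U is simulated to have (in expectation) the
#' target correlations with the standardised mediator indicator and the
#' standardised outcome, both models are refitted including U, the natural
#' effects are re-estimated, and results are averaged over \code{n_draws}
#' seeded draws of U. The zero-strength setting returns the unadjusted
#' estimates exactly.
#'
#' U is built by the conditional-Gaussian construction
#' \code{U = c1 ZM + c2 ZY + s e}, where \code{(c1, c2)} solve the 2 x 2
#' system fixing \code{cor(U, ZM) = r_MU} and \code{cor(U, ZY) = r_YU} given
#' the observed \code{cor(ZM, ZY)}; jointly infeasible targets (non-positive
#' residual variance) raise an error.
#'
#' @inheritParams fit_and_estimate
#' @param strengths Two-column matrix (or data frame) of \code{(r_MU, r_YU)}
#'   pairs in (-1, 1).
#' @param n_draws Number of confounder draws averaged per grid point.
#' @param seed Integer seed.
#' @return Data frame: r_mu, r_yu, nde, nie, total, proportion_mediated.
#' @export
sensitivity_unmeasured <- function(data, outcome, mediator, exposure,
                                   covariates = character(),
                                   interaction = FALSE, family = NULL,
                                   strengths = cbind(r_mu = c(0, 0.1, 0.2, 0.3),
                                                     r_yu = c(0, 0.1, 0.2, 0.3)),
                                   n_draws = 100L, seed = 1L) {
  strengths <- as.matrix(strengths)
  if (any(abs(strengths) >= 1)) stopf("strengths must lie in (-1, 1)")
  vars <- c(outcome, mediator, exposure, covariates)
  cc <- stats::complete.cases(data[, vars, drop = FALSE])
  d <- data[cc, , drop = FALSE]
  base <- fit_and_estimate(d, outcome, mediator, exposure, covariates,
                           interaction, family)
  zm <- as.numeric(scale(d[[mediator]]))
  zy <- as.numeric(scale(d[[outcome]]))
  rho <- stats::cor(zm, zy)
  rows <- lapply(seq_len(nrow(strengths)), function(r) {
    r_mu <- strengths[r, 1]; r_yu <- strengths[r, 2]
    if (r_mu == 0 && r_yu == 0)
      return(data.frame(r_mu = 0, r_yu = 0, nde = base$nde, nie = base$nie,
                        total = base$total,
                        proportion_mediated = base$proportion_mediated))
    S <- matrix(c(1, rho, rho, 1), 2)
    cvec <- solve(S, c(r_mu, r_yu))
    s2 <- 1 - drop(crossprod(cvec, S %*% cvec))
    if (s2 <= 0)
      stopf("requested correlations (%.2f, %.2f) jointly infeasible",
            r_mu, r_yu)
    ests <- with_seed(substream_seed(seed + r, "sensitivity"), {
      replicate(n_draws, {
        u <- cvec[1] * zm + cvec[2] * zy +
          sqrt(s2) * stats::rnorm(nrow(d))
        d2 <- d
        d2$.u_confounder <- u
        est <- tryCatch(
          fit_and_estimate(d2, outcome, mediator, exposure,
                           c(covariates, ".u_confounder"), interaction,
                           family),
          error = function(e) NULL)
        if (is.null(est)) c(NA_real_, NA_real_, NA_real_, NA_real_)
        else c(est$nde, est$nie, est$total, est$proportion_mediated)
      })
    })
    m <- rowMeans(ests, na.rm = TRUE)
    data.frame(r_mu = r_mu, r_yu = r_yu, nde = m[1], nie = m[2],
               total = m[3], proportion_mediated = m[4])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
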