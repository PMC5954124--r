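#' Logistic regression fit (maximum likelihood)
#'
#' Fits a binomial GLM with logit link by iteratively reweighted least
#' squares and returns the pieces downstream code needs: coefficient vector,
#' asymptotic covariance, and the maximised log-likelihood. Perfect
#' separation and rank deficiency are detected and raised as errors naming
#' the offending column.
#'
#' @param y Binary response vector (0/1).
#' @param X Design matrix including the intercept column.
#' @return List with \code{coefficients}, \code{covariance},
#'   \code{log_likelihood}, \code{fitted}.
#' @export
logistic_fit <- function(y, X) {
  X <- as.matrix(X)
  if (!all(y %in% c(0, 1))) stopf("response must be binary 0/1")
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    bad <- colnames(X)[qr_$pivot[(qr_$rank + 1):ncol(X)]]
    stopf("design matrix is rank deficient (collinear: %s)",
          paste(bad, collapse = ", "))
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(epsilon = 1e-10, maxit = 100)))
  mu <- fit$fitted.values
  # (quasi-)separation: the MLE diverges, so the fit perfectly reproduces y
  # or the coefficients run away without convergence
  separated <- all(abs(y - mu) < 1e-6) ||
    (!fit$converged && max(abs(fit$coefficients)) > 15)
  if (separated) {
    big <- which.max(abs(fit$coefficients[-1]))
    stopf("perfect separation detected (column %s)",
          colnames(X)[-1][big] %||% "unknown")
  }
  w <- mu * (1 - mu)
  xtwx <- crossprod(X * w, X)
  covar <- solve(xtwx)
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  list(coefficients = stats::setNames(fit$coefficients, colnames(X)),
       covariance = covar, log_likelihood = ll, fitted = mu)
}

#' Nagelkerke pseudo R-squared
#'
#' Cox-Snell \code{1 - exp(2 (ll0 - ll1) / n)} rescaled by its maximum
#' \code{1 - exp(2 ll0 / n)} so that a saturated fit reaches 1.
#'
#' @param ll_null Log-likelihood of the null (reference) model.
#' @param ll_full Log-likelihood of the full model.
#' @param n Number of observations.
#' @return Nagelkerke R-squared in \[0, 1\].
#' @export
nagelkerke_r2 <- function(ll_null, ll_full, n) {
  if (n <= 0) stopf("n must be positive")
  if (ll_full < ll_null - 1e-8)
    stopf("full-model log-likelihood below null-model log-likelihood")
  cox_snell <- 1 - exp(2 * (ll_null - ll_full) / n)
  max_r2 <- 1 - exp(2 * ll_null / n)
  if (max_r2 <= 0) return(0)
  min(max(cox_snell / max_r2, 0), 1)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up q-values \code{q_(i) = min_{j >= i} p_(j) m / j}, returned in the
#' input order.
#'
#' @param p Vector of P values in (0, 1].
#' @return q-values in input order.
#' @export
fdr_adjust <- function(p) {
  if (any(p <= 0 | p > 1 | !is.finite(p)))
    stopf("P values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' PRS-phenotype association with ancestry adjustment
#'
#' For each trait-by-threshold score, fits
#' \code{GI ~ score + PC1 + ... + PCk} by logistic regression, reports the
#' Wald P for the score coefficient, and the Nagelkerke R-squared increment
#' of the score over the covariate-only model (floored at 0). FDR q-values
#' are computed across all rows of the subset with
#' \code{\link{fdr_adjust}}.
#'
#' @param prs A \code{prs_result} table (possibly several traits row-bound).
#' @param gi_flag Named binary vector (names = sample ids): globally impaired
#'   indicator.
#' @param pcs An \code{ancestry_pcs} object, or a matrix with rownames.
#' @param subset \code{"all"} or \code{"cases"}; recorded in the output.
#' @param sample_ids Optional character vector restricting the analysis (for
#'   the cases-only subset).
#' @param incremental If FALSE, reports the full-model Nagelkerke R-squared
#'   instead of the increment over covariates.
#' @return Data frame: trait, p_threshold, n, beta, se, wald_p,
#'   nagelkerke_r2, q_value, subset.
#' @export
prs_association <- function(prs, gi_flag, pcs, subset = "all",
                            sample_ids = NULL, incremental = TRUE) {
  if (inherits(pcs, "ancestry_pcs")) {
    scores_mat <- pcs$scores
    pc_ids <- pcs$sample_ids
  } else {
    scores_mat <- as.matrix(pcs)
    pc_ids <- rownames(scores_mat)
  }
  ids <- intersect(names(gi_flag), pc_ids)
  if (!is.null(sample_ids)) ids <- intersect(ids, sample_ids)
  if (length(unique(gi_flag[ids])) < 2)
    stopf("subset has a single outcome class")
  combos <- unique(prs[, c("trait", "p_threshold")])
  rows <- lapply(seq_len(nrow(combos)), function(r) {
    tr <- combos$trait[r]; pt <- combos$p_threshold[r]
    sc <- prs[prs$trait == tr & prs$p_threshold == pt, ]
    s <- stats::setNames(sc$score, sc$sample_id)[ids]
    y <- gi_flag[ids]
    P <- scores_mat[match(ids, pc_ids), , drop = FALSE]
    if (stats::sd(s) == 0) {
      # a constant score carries no information: no increment by definition
      return(data.frame(trait = tr, p_threshold = pt, n = length(y),
                        beta = 0, se = NA_real_, wald_p = 1,
                        nagelkerke_r2 = 0, subset = subset,
                        stringsAsFactors = FALSE))
    }
    X_full <- cbind(intercept = 1, score = s, P)
    X_null <- cbind(intercept = 1, P)
    full <- logistic_fit(y, X_full)
    null <- logistic_fit(y, X_null)
    ll00 <- sum(y) * log(mean(y)) + sum(1 - y) * log(1 - mean(y))
    r2_full <- nagelkerke_r2(ll00, full$log_likelihood, length(y))
    r2_null <- nagelkerke_r2(ll00, null$log_likelihood, length(y))
    r2 <- if (incremental) max(r2_full - r2_null, 0) else r2_full
    beta <- full$coefficients["score"]
    se <- sqrt(full$covariance["score", "score"])
    data.frame(trait = tr, p_threshold = pt, n = length(y),
               beta = unname(beta), se = se,
               wald_p = 2 * stats::pnorm(-abs(beta / se)),
               nagelkerke_r2 = r2, subset = subset,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- fdr_adjust(out$wald_p)
  rownames(out) <- NULL
  out
}

#' Two-sample t test from summary statistics
#'
#' Pooled-variance two-sample t test for equal means, computed from group
#' means, standard deviations and sizes.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @return List: statistic, df, p, kind = "t".
#' @export
two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    if (mean1 == mean2) return(list(statistic = 0, df = df, p = 1,
                                    kind = "t"))
    stopf("zero pooled variance with unequal means")
  }
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(statistic = t, df = df, p = 2 * stats::pt(-abs(t), df), kind = "t")
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson chi-square without continuity correction,
#' \code{df = (r - 1)(c - 1)}, upper-tail P.
#'
#' @param table Matrix of non-negative integer counts, at least 2 x 2.
#' @return List: statistic, df, p, kind = "chi2".
#' @export
pearson_chi2 <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stopf("counts must be non-negative integers")
  if (nrow(table) < 2 || ncol(table) < 2)
    stopf("table must be at least 2 x 2")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stopf("zero row or column margin")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, kind = "chi2")
}

#' Ordinary least squares fit
#'
#' Least-squares coefficients with classical covariance and two-sided
#' t-based p-values. Rank deficiency raises an error naming the collinear
#' columns.
#'
#' @param y Response vector.
#' @param X Design matrix including the intercept.
#' @return List: coefficients, covariance, p_values, sigma2, df_residual.
#' @export
ols_fit <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y)
  if (n <= ncol(X)) stopf("need more observations than columns")
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    bad <- colnames(X)[qr_$pivot[(qr_$rank + 1):ncol(X)]]
    stopf("design matrix is rank deficient (collinear: %s)",
          paste(bad, collapse = ", "))
  }
  fit <- stats::lm.fit(X, y)
  df <- n - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  covar <- sigma2 * solve(crossprod(X))
  dimnames(covar) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(covar))
  tstat <- fit$coefficients / se
  list(coefficients = stats::setNames(fit$coefficients, colnames(X)),
       covariance = covar,
       p_values = 2 * stats::pt(-abs(tstat), df),
       sigma2 = sigma2, df_residual = df)
}
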