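# Independent oracles used across the test files. These deliberately take
# different computational routes than the package implementation.

# Exact Hardy-Weinberg probabilities by direct conditional enumeration:
# P(het = h | n, nA) built from binomial coefficients rather than the
# multinomial factorial form used in the package.
oracle_hwe_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n - nA
  if (nA == 0 || na == 0) return(1)
  rare <- min(nA, na)
  hets <- seq(rare %% 2, rare, by = 2)
  logw <- vapply(hets, function(h) {
    lchoose(n, h) + lchoose(n - h, (rare - h) / 2) + h * log(2) -
      lchoose(2 * n, rare)
  }, numeric(1))
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  obs <- w[match(n_Aa, hets)]
  sum(w[w <= obs * (1 + 1e-12)])
}

# Globally optimal k=2 partition by exhaustive enumeration (<= 20 points).
oracle_kmeans2_inertia <- function(x) {
  n <- nrow(x)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    grp <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    if (!any(grp) || all(grp)) next
    ss <- 0
    for (g in list(grp, !grp)) {
      cen <- colMeans(x[g, , drop = FALSE])
      ss <- ss + sum(sweep(x[g, , drop = FALSE], 2, cen, `-`)^2)
    }
    best <- min(best, ss)
  }
  best
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Monte-Carlo counterfactual oracle for mediation point estimates:
# simulates M under one exposure level and evaluates the outcome model under
# another, directly from the counterfactual definition E[Y(a, M(a_star))].
# Monte-Carlo standard errors come from 100 batch means.
oracle_mediation_mc <- function(mfit, ofit, a = 1, a_star = 0,
                                c = numeric(0), n_draws = 1e6) {
  b2c <- if (length(c)) sum(mfit$b2 * c) else 0
  t4c <- if (length(c)) sum(ofit$t4 * c) else 0
  pm_at <- function(x) plogis(mfit$b0 + mfit$b1 * x + b2c)
  mean_y <- function(aa, m) {
    lp <- ofit$t0 + ofit$t1 * aa + ofit$t2 * m +
      (ofit$t3 %||% 0) * aa * m + t4c
    if (identical(ofit$family, "logistic")) plogis(lp) else lp
  }
  m_astar <- stats::rbinom(n_draws, 1, pm_at(a_star))
  m_a <- stats::rbinom(n_draws, 1, pm_at(a))
  y_a_mastar <- mean_y(a, m_astar)
  y_astar_mastar <- mean_y(a_star, m_astar)
  y_a_ma <- mean_y(a, m_a)
  n_batch <- 100
  batch <- rep(seq_len(n_batch), length.out = n_draws)
  stat <- function(sel) {
    if (identical(ofit$family, "logistic")) {
      odds <- function(p) p / (1 - p)
      c(nde = log(odds(mean(y_a_mastar[sel])) /
                    odds(mean(y_astar_mastar[sel]))),
        nie = log(odds(mean(y_a_ma[sel])) / odds(mean(y_a_mastar[sel]))))
    } else {
      c(nde = mean(y_a_mastar[sel]) - mean(y_astar_mastar[sel]),
        nie = mean(y_a_ma[sel]) - mean(y_a_mastar[sel]))
    }
  }
  full <- stat(rep(TRUE, n_draws))
  per_batch <- vapply(seq_len(n_batch), function(b) stat(batch == b),
                      numeric(2))
  se <- apply(per_batch, 1, stats::sd) / sqrt(n_batch)
  list(nde = unname(full["nde"]), nie = unname(full["nie"]),
       se_nde = unname(se["nde"]), se_nie = unname(se["nie"]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
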