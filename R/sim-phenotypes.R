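#' Simulate phenotypes and covariates on top of simulated genotypes
#'
#' Encodes the causal chain the downstream analysis is built to detect:
#' \enumerate{
#'   \item the true polygenic score \code{Z} is the dosage-weighted sum of the
#'     generating (true) effects, standardised to zero mean and unit variance;
#'   \item membership in the globally impaired ERP cluster is Bernoulli with
#'     \code{logit P(M = 1) = cluster_logit[1] + cluster_logit[2] * Z}; the
#'     remaining subjects split between the intermediate and high-functioning
#'     clusters with probabilities \code{nonimpaired_split};
#'   \item the six ERP measures are drawn from the member cluster's normal
#'     distributions (\code{cluster_means}, \code{cluster_sds});
#'   \item diagnosis (SCZ / BPD / control) is multinomial conditional on
#'     cluster (\code{diag_probs});
#'   \item the PANSS positive total follows the generating outcome model
#'     \code{t0 + t1*A + t2*M + t3*A*M + sigma*e}, observed for a
#'     \code{panss_fraction} of eligible subjects (cases by default), missing
#'     completely at random. The generating exposure \code{A} is the
#'     score-quartile class of \code{Z} (1 for the top quartile, 0 for the
#'     bottom, 0.5 for the middle half), i.e. the direct effect is applied
#'     on the same top-vs-bottom-quartile contrast the downstream mediation
#'     analysis estimates, so \code{t1} is the generating natural direct
#'     effect of that contrast;
#'   \item age and smoking are cluster-conditional, sex is Bernoulli, and
#'     chlorpromazine-equivalent dose is lognormal for cases.
#' }
#'
#' @param genotypes A \code{\link{genotype_matrix}}.
#' @param sumstats Summary statistics from \code{\link{simulate_summary_stats}}
#'   carrying the \code{true_effect} column used to form the true score.
#' @param config A \code{\link{sim_config}}.
#' @return A data frame with one row per sample: \code{sample_id},
#'   \code{diagnosis}, the six ERP measures, \code{panss_positive},
#'   \code{age}, \code{sex}, \code{smoker}, \code{cpz_dose},
#'   \code{true_cluster} (latent label retained for recovery tests) and
#'   \code{true_prs} (the standardised generating score).
#' @export
simulate_phenotypes <- function(genotypes, sumstats, config) {
  validate_sim_config(config)
  if (is.null(sumstats$true_effect))
    stopf("sumstats must carry the generating true_effect column")
  idx <- match(sumstats$id, genotypes$variants$id)
  if (anyNA(idx))
    stopf("sumstats and genotypes are dimensionally inconsistent")
  n <- length(genotypes$sample_ids)
  with_seed(substream_seed(config$seed, "phenotypes"), {
    dos <- genotypes$dosages[, idx, drop = FALSE]
    freq <- colMeans(dos, na.rm = TRUE)
    dos[is.na(dos)] <- rep(freq, each = n)[is.na(dos)]
    raw <- drop(dos %*% sumstats$true_effect)
    z <- if (stats::sd(raw) > 0) as.numeric(scale(raw)) else raw * 0

    p_gi <- expit(config$cluster_logit[1] + config$cluster_logit[2] * z)
    gi <- stats::rbinom(n, 1, p_gi)
    cl <- ifelse(gi == 1, 1L,
                 ifelse(stats::runif(n) < config$nonimpaired_split[1], 2L, 3L))

    erp <- matrix(NA_real_, n, 6, dimnames = list(NULL, erp_measures))
    for (k in 1:3) {
      sel <- cl == k
      if (!any(sel)) next
      erp[sel, ] <- matrix(stats::rnorm(sum(sel) * 6,
                                        mean = rep(config$cluster_means[k, ],
                                                   each = sum(sel)),
                                        sd = rep(config$cluster_sds[k, ],
                                                 each = sum(sel))),
                           sum(sel), 6)
    }
    erp[, "p50_ratio"] <- pmax(erp[, "p50_ratio"], 0)

    dp <- config$diag_probs
    diag_row <- ifelse(cl == 1L, 1L, 2L)
    u <- stats::runif(n)
    cum1 <- dp[, 1]
    cum2 <- dp[, 1] + dp[, 2]
    diagnosis <- ifelse(u < cum1[diag_row], "SCZ",
                        ifelse(u < cum2[diag_row], "BPD", "control"))
    is_case <- diagnosis != "control"

    cs <- config$covariate_spec
    imp <- cl == 1L
    age <- ifelse(imp,
                  stats::rnorm(n, cs$age$mean_impaired, cs$age$sd_impaired),
                  stats::rnorm(n, cs$age$mean_other, cs$age$sd_other))
    age <- pmin(pmax(age, cs$age$min), cs$age$max)
    sex <- ifelse(stats::runif(n) < cs$sex$p_female, "F", "M")
    smoker <- ifelse(stats::runif(n) <
                       ifelse(imp, cs$smoking$p_impaired, cs$smoking$p_other),
                     "yes", "no")
    cpz <- ifelse(is_case,
                  stats::rlnorm(n, cs$cpz$meanlog, cs$cpz$sdlog), NA_real_)

    mt <- config$mediation_truth
    qz <- stats::quantile(z, c(0.25, 0.75), type = 7, names = FALSE)
    a_cls <- ifelse(z >= qz[2], 1, ifelse(z <= qz[1], 0, 0.5))
    panss <- mt$t0 + mt$t1 * a_cls + mt$t2 * gi + mt$t3 * a_cls * gi +
      mt$sigma * stats::rnorm(n)
    panss <- pmax(panss, 0)
    eligible <- if (config$panss_cases_only) is_case else rep(TRUE, n)
    observed <- eligible & stats::runif(n) < config$panss_fraction
    panss[!observed] <- NA_real_

    data.frame(sample_id = genotypes$sample_ids,
               diagnosis = diagnosis,
               erp,
               panss_positive = panss,
               age = age, sex = sex, smoker = smoker, cpz_dose = cpz,
               true_cluster = cl, true_prs = z,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running \code{\link{simulate_genotypes}},
#' \code{\link{simulate_summary_stats}} for the requested traits and
#' \code{\link{simulate_phenotypes}} (phenotypes are driven by the first
#' trait's generating effects).
#'
#' @param config A \code{\link{sim_config}}.
#' @param traits Character vector of discovery traits to simulate.
#' @return List with elements \code{genotypes}, \code{sumstats} (named list of
#'   summary-statistic tables) and \code{phenotypes}.
#' @export
simulate_cohort <- function(config = sim_config(),
                            traits = c("scz", "bpd", "college",
                                       "intelligence")) {
  g <- simulate_genotypes(config)
  ss <- lapply(traits, function(tr) simulate_summary_stats(config, g, tr))
  names(ss) <- traits
  ph <- simulate_phenotypes(g, ss[[1]], config)
  list(genotypes = g, sumstats = ss, phenotypes = ph)
}
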