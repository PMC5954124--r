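#' Names of the six ERP measures used throughout the package
#'
#' P50 sensory gating ratio (percent, (S2/S1) x 100), S1 response amplitude
#' (uV), N1 amplitude magnitude (uV), P2 amplitude (uV), P3 amplitude (uV) and
#' P3 latency (ms).
#'
#' @export
erp_measures <- c("p50_ratio", "s1_amplitude", "n1_amplitude",
                  "p2_amplitude", "p3_amplitude", "p3_latency")

#' Default impairment directions for the six ERP measures
#'
#' +1 means higher values reflect worse function (P50 ratio, P3 latency);
#' -1 means lower values reflect worse function (reduced S1, N1, P2 and P3
#' amplitudes; N1 is operationalised on its magnitude, so a smaller value is a
#' weaker negative-going component).
#'
#' @export
default_impairment_directions <- c(p50_ratio = 1, s1_amplitude = -1,
                                   n1_amplitude = -1, p2_amplitude = -1,
                                   p3_amplitude = -1, p3_latency = 1)

#' Simulation configuration for the synthetic cohort generator
#'
#' Builds the full parameter set that drives \code{\link{simulate_genotypes}},
#' \code{\link{simulate_summary_stats}} and \code{\link{simulate_phenotypes}}.
#' The defaults emulate the study design the package targets: 383
#' European-ancestry subjects (136 schizophrenia, 122 psychotic bipolar, 125
#' controls before quality control), a three-cluster latent structure over six
#' ERP measures in which roughly 60 subjects fall into a cluster impaired on
#' all six, a polygenic-score effect on membership in that cluster, and a
#' configurable mediation chain from the score through cluster membership to
#' the PANSS positive-symptom total.
#'
#' @param n_samples Number of subjects.
#' @param n_variants Number of autosomal variants to simulate.
#' @param ld_block_size Variants per linkage-disequilibrium block.
#' @param within_block_r Latent haplotype correlation between adjacent variants
#'   within a block (AR(1) Gaussian copula), in \[0, 1).
#' @param maf_range Interval within (0, 0.5] from which per-variant minor
#'   allele frequencies are drawn uniformly.
#' @param n_causal Number of causal variants per simulated discovery trait.
#' @param causal_effect_sd Standard deviation of the zero-mean normal from
#'   which causal effect sizes are drawn (log-odds-ratio scale).
#' @param discovery_n Effective discovery-GWAS sample size; controls the
#'   standard error \code{1/sqrt(2 N p (1-p))} of reported effects.
#' @param cluster_means 3 x 6 matrix of ERP means (rows: globally impaired,
#'   intermediate, high-functioning; columns \code{\link{erp_measures}}).
#' @param cluster_sds 3 x 6 matrix of within-cluster standard deviations.
#' @param cluster_logit Length-2 vector \code{c(intercept, prs_coefficient)}
#'   of the logistic model for membership in the globally impaired cluster,
#'   with the true polygenic score standardised to unit variance.
#' @param nonimpaired_split Probabilities of the intermediate vs
#'   high-functioning cluster conditional on not being globally impaired.
#' @param diag_probs 2 x 3 matrix of diagnosis probabilities (SCZ, BPD,
#'   control) conditional on cluster (rows: impaired, non-impaired).
#' @param mediation_truth List of generating coefficients for the outcome
#'   model \code{panss = t0 + t1*A + t2*M + t3*A*M + sigma*e}, where M is the
#'   impaired-cluster indicator and A is the score-quartile class of the
#'   standardised true polygenic score (1 top quartile / 0 bottom / 0.5
#'   middle), so \code{t1} is the generating direct effect of the
#'   top-vs-bottom-quartile exposure contrast the mediation stage estimates.
#' @param covariate_spec List of distributions for age, sex, smoking and
#'   chlorpromazine-equivalent dose; see Details.
#' @param panss_fraction Fraction of eligible subjects with an observed PANSS
#'   positive total (missing completely at random).
#' @param panss_cases_only If TRUE (default) PANSS is generated for cases only.
#' @param missing_rate Genotype missingness rate in \[0, 1).
#' @param seed Master seed; per-stage substreams are derived from it so stages
#'   can be regenerated independently.
#'
#' @details Age and smoking are generated conditionally on cluster so that the
#' demographic contrasts of the target design (the globally impaired cluster
#' older and more often smokers) hold in expectation. Chlorpromazine-equivalent
#' dose is lognormal and generated for cases only. Diagnosis probabilities per
#' cluster default to the target design's margins (impaired: 48.3/43.3/8.3
#' percent SCZ/BPD/control; non-impaired: 33.1/29.7/37.2 percent).
#'
#' @return An object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_samples = 383L,
                       n_variants = 20000L,
                       ld_block_size = 50L,
                       within_block_r = 0.8,
                       maf_range = c(0.05, 0.5),
                       n_causal = 50L,
                       causal_effect_sd = 0.1,
                       discovery_n = 5e4,
                       cluster_means = default_cluster_means(),
                       cluster_sds = default_cluster_sds(),
                       cluster_logit = c(intercept = -1.75, prs = 0.5),
                       nonimpaired_split = c(intermediate = 0.5, high = 0.5),
                       diag_probs = default_diag_probs(),
                       mediation_truth = list(t0 = 16, t1 = 0.5, t2 = 3.75,
                                              t3 = 0, sigma = 7),
                       covariate_spec = default_covariate_spec(),
                       panss_fraction = 161 / 258,
                       panss_cases_only = TRUE,
                       missing_rate = 0.005,
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_variants = as.integer(n_variants),
              ld_block_size = as.integer(ld_block_size),
              within_block_r = within_block_r,
              maf_range = maf_range,
              n_causal = as.integer(n_causal),
              causal_effect_sd = causal_effect_sd,
              discovery_n = discovery_n,
              cluster_means = cluster_means,
              cluster_sds = cluster_sds,
              cluster_logit = cluster_logit,
              nonimpaired_split = nonimpaired_split / sum(nonimpaired_split),
              diag_probs = diag_probs,
              mediation_truth = mediation_truth,
              covariate_spec = covariate_spec,
              panss_fraction = panss_fraction,
              panss_cases_only = isTRUE(panss_cases_only),
              missing_rate = missing_rate,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_cluster_means <- function() {
  m <- rbind(impaired     = c(85, 0.8, 3.0, 1.5, 2.0, 400),
             intermediate = c(55, 1.8, 6.0, 3.0, 4.5, 355),
             high         = c(25, 2.8, 9.0, 4.5, 7.0, 310))
  colnames(m) <- erp_measures
  m
}

#' @rdname sim_config
#' @export
default_cluster_sds <- function() {
  m <- rbind(impaired     = c(15, 0.5, 1.5, 0.75, 1.25, 22.5),
             intermediate = c(15, 0.5, 1.5, 0.75, 1.25, 22.5),
             high         = c(15, 0.5, 1.5, 0.75, 1.25, 22.5))
  colnames(m) <- erp_measures
  m
}

#' @rdname sim_config
#' @export
default_diag_probs <- function() {
  m <- rbind(impaired     = c(SCZ = 0.483, BPD = 0.433, control = 0.083),
             nonimpaired  = c(SCZ = 0.331, BPD = 0.297, control = 0.372))
  m / rowSums(m)
}

#' @rdname sim_config
#' @export
default_covariate_spec <- function() {
  list(age = list(mean_impaired = 43.58, sd_impaired = 14.68,
                  mean_other = 38.41, sd_other = 13.25,
                  min = 18, max = 65),
       sex = list(p_female = 0.52),
       smoking = list(p_impaired = 0.421, p_other = 0.242),
       cpz = list(meanlog = 5.4, sdlog = 1.0))
}

validate_sim_config <- function(cfg) {
  for (fld in c("n_samples", "n_variants", "ld_block_size", "n_causal"))
    if (!is_count(cfg[[fld]]))
      stopf("configuration error: %s must be a positive count", fld)
  if (cfg$n_causal > cfg$n_variants)
    stopf("configuration error: n_causal exceeds n_variants")
  if (!(cfg$within_block_r >= 0 && cfg$within_block_r < 1))
    stopf("configuration error: within_block_r must lie in [0, 1)")
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2])
    stopf("configuration error: maf_range must be an interval within (0, 0.5]")
  if (!(cfg$missing_rate >= 0 && cfg$missing_rate < 1))
    stopf("configuration error: missing_rate must lie in [0, 1)")
  if (!all(dim(cfg$cluster_means) == c(3, 6)))
    stopf("configuration error: cluster_means must be 3 x 6")
  if (!all(dim(cfg$cluster_sds) == c(3, 6)) || any(cfg$cluster_sds <= 0))
    stopf("configuration error: cluster_sds must be 3 x 6 and positive")
  # the impaired row must be strictly worse than both others on every measure
  dir <- default_impairment_directions
  aligned <- sweep(cfg$cluster_means, 2, dir, `*`)
  if (!all(aligned[1, ] > aligned[2, ] & aligned[1, ] > aligned[3, ]))
    stopf(paste("configuration error: impaired cluster means must be worse",
                "than both other clusters on every measure"))
  if (length(cfg$cluster_logit) != 2)
    stopf("configuration error: cluster_logit must be c(intercept, prs)")
  if (!(cfg$panss_fraction >= 0 && cfg$panss_fraction <= 1))
    stopf("configuration error: panss_fraction must lie in [0, 1]")
  invisible(cfg)
}
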