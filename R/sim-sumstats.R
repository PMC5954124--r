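#' Simulate discovery GWAS summary statistics
#'
#' Emulates a large discovery genome-wide association study for one trait on
#' the simulated variant panel. \code{n_causal} variants (chosen uniformly at
#' random per trait) receive true effects drawn from
#' \code{N(0, causal_effect_sd^2)}; all other true effects are zero. The
#' reported effect adds estimation noise with standard error
#' \code{se = 1/sqrt(2 * discovery_n * maf * (1 - maf))}, and the P value is
#' the two-sided normal tail of \code{effect/se}.
#'
#' The effect allele is the simulated alt allele, so effects are on the
#' alt-dosage scale (log odds ratio or beta, depending on how the trait is
#' read downstream).
#'
#' @param config A \code{\link{sim_config}}.
#' @param genotypes The \code{\link{genotype_matrix}} the panel refers to.
#' @param trait Trait label; one of \code{"scz"}, \code{"bpd"},
#'   \code{"college"}, \code{"intelligence"}.
#' @return A \code{summary_stats} data frame with columns \code{chrom},
#'   \code{pos}, \code{id}, \code{effect_allele}, \code{other_allele},
#'   \code{effect}, \code{se}, \code{p} and (for simulation-truth checks) a
#'   \code{true_effect} column.
#' @export
simulate_summary_stats <- function(config, genotypes,
                                   trait = c("scz", "bpd", "college",
                                             "intelligence")) {
  validate_sim_config(config)
  trait <- tryCatch(match.arg(trait),
                    error = function(e)
                      stopf("configuration error: unknown trait label '%s'",
                            paste(trait, collapse = ",")))
  v <- genotypes$variants
  m <- nrow(v)
  if (config$n_causal > m)
    stopf("configuration error: n_causal exceeds the variant panel size")
  trait_offset <- match(trait, c("scz", "bpd", "college", "intelligence"))
  with_seed(substream_seed(config$seed + trait_offset, "effects"), {
    maf <- pmin(pmax(colMeans(genotypes$dosages, na.rm = TRUE) / 2, 1e-4),
                1 - 1e-4)
    se <- 1 / sqrt(2 * config$discovery_n * maf * (1 - maf))
    true_effect <- numeric(m)
    causal <- sample.int(m, config$n_causal)
    true_effect[causal] <- stats::rnorm(config$n_causal,
                                        sd = config$causal_effect_sd)
    effect <- true_effect + se * stats::rnorm(m)
    z <- effect / se
    p <- 2 * stats::pnorm(-abs(z))
    p[p == 0] <- .Machine$double.xmin
    out <- data.frame(chrom = v$chrom, pos = v$pos, id = v$id,
                      effect_allele = v$alt, other_allele = v$ref,
                      effect = effect, se = unname(se), p = p,
                      true_effect = true_effect,
                      stringsAsFactors = FALSE)
    class(out) <- c("summary_stats", "data.frame")
    out
  })
}

validate_summary_stats <- function(ss) {
  req <- c("chrom", "pos", "id", "effect_allele", "other_allele",
           "effect", "se", "p")
  miss <- setdiff(req, names(ss))
  if (length(miss))
    stopf("summary statistics lack columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(ss$id)) stopf("summary statistics variant ids must be unique")
  if (any(!is.finite(ss$effect))) stopf("summary statistics effects must be finite")
  if (any(ss$se <= 0)) stopf("summary statistics standard errors must be positive")
  if (any(ss$p <= 0 | ss$p > 1)) stopf("summary statistics P values must lie in (0, 1]")
  invisible(ss)
}
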