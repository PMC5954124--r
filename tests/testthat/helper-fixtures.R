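# Small synthetic fixtures built in code at test time.

tiny_config <- function(seed = 1L, ...) {
  sim_config(n_samples = 200L, n_variants = 600L, ld_block_size = 20L,
             missing_rate = 0.01, seed = seed, ...)
}

# A bare genotype_matrix with independent variants at given frequencies.
make_genotypes <- function(n, freqs, seed = 1L, chrom = NULL, pos = NULL) {
  m <- length(freqs)
  dos <- withr::with_seed(seed, {
    matrix(stats::rbinom(n * m, 2, rep(freqs, each = n)), n, m)
  })
  genotype_matrix(
    dos,
    data.frame(chrom = chrom %||% rep("1", m),
               pos = pos %||% (seq_len(m) * 1000L),
               id = sprintf("v%03d", seq_len(m)),
               ref = rep("A", m), alt = rep("C", m),
               stringsAsFactors = FALSE),
    sprintf("S%03d", seq_len(n)))
}

# ERP profiles drawn from the generator's cluster model without genotypes.
make_erp_profiles <- function(n, seed = 1L, weights = c(0.16, 0.42, 0.42),
                              means = default_cluster_means(),
                              sds = default_cluster_sds()) {
  withr::with_seed(seed, {
    cl <- sample.int(3, n, replace = TRUE, prob = weights)
    x <- matrix(stats::rnorm(n * 6, mean = t(means)[, cl],
                             sd = t(sds)[, cl]),
                n, 6, byrow = TRUE)
    colnames(x) <- erp_measures
    list(profiles = as.data.frame(x), cluster = cl)
  })
}
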