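test_that("identical configuration gives bit-identical cohorts", {
  cfg <- tiny_config(seed = 11)
  a <- simulate_cohort(cfg, traits = c("scz", "college"))
  b <- simulate_cohort(cfg, traits = c("scz", "college"))
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$sumstats, b$sumstats)
  expect_identical(a$phenotypes, b$phenotypes)
})

test_that("generated data satisfy downstream preconditions", {
  co <- simulate_cohort(tiny_config(seed = 3), traits = "scz")
  g <- co$genotypes
  expect_true(all(g$dosages %in% c(0, 1, 2) | is.na(g$dosages)))
  expect_false(anyDuplicated(g$variants$id) > 0)
  for (ch in unique(g$variants$chrom))
    expect_false(is.unsorted(g$variants$pos[g$variants$chrom == ch],
                             strictly = TRUE))
  ss <- co$sumstats$scz
  expect_true(all(ss$p > 0 & ss$p <= 1))
  expect_true(all(ss$se > 0))
  expect_true(all(is.finite(ss$effect)))
  ph <- co$phenotypes
  expect_true(all(is.finite(as.matrix(ph[, erp_measures]))))
  expect_true(all(ph$diagnosis %in% c("SCZ", "BPD", "control")))
  expect_true(all(is.na(ph$panss_positive) |
                    ph$diagnosis != "control"))
})

test_that("allele frequencies match the configured MAF", {
  cfg <- sim_config(n_samples = 10000L, n_variants = 60L,
                    ld_block_size = 10L, maf_range = c(0.3, 0.3),
                    missing_rate = 0, seed = 5)
  g <- simulate_genotypes(cfg)
  freq <- colMeans(g$dosages) / 2
  expect_true(all(freq > 0.29 & freq < 0.31))
})

test_that("zero within-block correlation gives independent variants", {
  cfg <- sim_config(n_samples = 5000L, n_variants = 30L,
                    ld_block_size = 10L, within_block_r = 0,
                    n_causal = 10L, missing_rate = 0, seed = 7)
  g <- simulate_genotypes(cfg)
  cm <- cor(g$dosages)
  r2 <- cm[upper.tri(cm)]^2
  expect_lt(max(r2), 0.01)
})

test_that("block LD structure appears within but not across blocks", {
  cfg <- sim_config(n_samples = 3000L, n_variants = 40L,
                    ld_block_size = 10L, within_block_r = 0.8,
                    n_causal = 10L, missing_rate = 0, seed = 9)
  g <- simulate_genotypes(cfg)
  cm <- cor(g$dosages)^2
  within_adjacent <- mean(sapply(c(1:9, 11:19), function(j) cm[j, j + 1]))
  across <- mean(cm[1:10, 21:30])
  expect_gt(within_adjacent, 0.2)
  expect_lt(across, 0.02)
})

test_that("genotype counts are in Hardy-Weinberg proportions", {
  cfg <- sim_config(n_samples = 500L, n_variants = 1000L,
                    ld_block_size = 25L, missing_rate = 0, seed = 13)
  g <- simulate_genotypes(cfg)
  pvals <- apply(g$dosages, 2, function(x)
    hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2)))
  expect_gte(mean(pvals > 1e-6), 0.99)
})

test_that("summary statistics P values follow from the z-score", {
  co <- simulate_cohort(tiny_config(seed = 17), traits = "bpd")
  ss <- co$sumstats$bpd
  expect_equal(ss$p, 2 * pnorm(-abs(ss$effect / ss$se)), tolerance = 1e-12)
})

test_that("null variants have uniform P values", {
  cfg <- sim_config(n_samples = 50L, n_variants = 10000L,
                    ld_block_size = 1L, within_block_r = 0,
                    n_causal = 1L, missing_rate = 0, seed = 19)
  g <- simulate_genotypes(cfg)
  ss <- simulate_summary_stats(cfg, g, "scz")
  p_null <- ss$p[ss$true_effect == 0]
  ks <- suppressWarnings(ks.test(p_null, "punif"))
  # 1% critical value of the one-sample KS statistic
  expect_lt(unname(ks$statistic), 1.63 / sqrt(length(p_null)))
})

test_that("reported effects track true effects more closely at larger discovery n", {
  base <- list(n_samples = 300L, n_variants = 2000L, ld_block_size = 10L,
               n_causal = 200L, missing_rate = 0, seed = 23)
  cfg_small <- do.call(sim_config, c(base, discovery_n = 1e3))
  cfg_big <- do.call(sim_config, c(base, discovery_n = 1e5))
  g <- simulate_genotypes(cfg_small)
  r_small <- cor(simulate_summary_stats(cfg_small, g, "scz")$effect,
                 simulate_summary_stats(cfg_small, g, "scz")$true_effect)
  r_big <- cor(simulate_summary_stats(cfg_big, g, "scz")$effect,
               simulate_summary_stats(cfg_big, g, "scz")$true_effect)
  expect_gt(r_big, r_small)
})

test_that("cluster-wise ERP means match the generating means", {
  cfg <- sim_config(n_samples = 3000L, n_variants = 400L,
                    ld_block_size = 20L, seed = 29)
  co <- simulate_cohort(cfg, traits = "scz")
  ph <- co$phenotypes
  for (k in 1:3) {
    sel <- ph$true_cluster == k
    for (j in seq_along(erp_measures)) {
      mmeas <- erp_measures[j]
      se <- cfg$cluster_sds[k, j] / sqrt(sum(sel))
      expect_lt(abs(mean(ph[[mmeas]][sel]) - cfg$cluster_means[k, j]),
                3 * se + 1e-9)
    }
  }
})

test_that("a zero PRS coefficient yields a null membership slope", {
  cfg <- sim_config(n_samples = 2000L, n_variants = 400L,
                    ld_block_size = 20L,
                    cluster_logit = c(intercept = -1.68, prs = 0),
                    seed = 31)
  co <- simulate_cohort(cfg, traits = "scz")
  ph <- co$phenotypes
  fit <- glm((true_cluster == 1) ~ true_prs, data = ph, family = binomial())
  est <- summary(fit)$coefficients["true_prs", ]
  expect_lt(abs(est["Estimate"]), 2 * est["Std. Error"])
})

test_that("defaults give an impaired-cluster size near 60 of 383", {
  sizes <- vapply(1:10, function(s) {
    cfg <- sim_config(n_variants = 400L, ld_block_size = 20L, seed = s)
    co <- simulate_cohort(cfg, traits = "scz")
    sum(co$phenotypes$true_cluster == 1)
  }, numeric(1))
  # marginal P(impaired) for the default logit, by numerical integration
  cfg <- sim_config(n_variants = 400L)
  p_marg <- integrate(function(z)
    dnorm(z) / (1 + exp(-(cfg$cluster_logit[1] + cfg$cluster_logit[2] * z))),
    -8, 8)$value
  expect_lt(abs(p_marg - 60 / 383), 0.02)
  expect_lt(abs(mean(sizes) - 383 * p_marg),
            3 * sqrt(383 * p_marg * (1 - p_marg) / 10))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_samples = 0), "positive count")
  expect_error(sim_config(maf_range = c(0, 0.6)), "maf_range")
  expect_error(sim_config(within_block_r = 1), "within_block_r")
  expect_error(sim_config(n_causal = 100, n_variants = 50), "n_causal")
  bad_means <- default_cluster_means()
  bad_means[1, 1] <- 0   # impaired no longer worst on P50
  expect_error(sim_config(cluster_means = bad_means), "worse")
  co <- simulate_cohort(tiny_config(seed = 1), traits = "scz")
  expect_error(simulate_summary_stats(tiny_config(seed = 1), co$genotypes,
                                      "nonsense"), "unknown trait")
})
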