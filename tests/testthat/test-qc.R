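test_that("Hardy-Weinberg exact test matches known cases and the enumeration oracle", {
  expect_equal(hwe_exact_test(100, 0, 0), 1)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-6)
  expect_gte(hwe_exact_test(25, 50, 25), 0.5)
  # random genotype configurations against an independently written oracle
  withr::with_seed(42, {
    for (i in 1:25) {
      n <- sample(20:200, 1)
      p <- runif(1, 0.05, 0.5)
      x <- rbinom(n, 2, p)
      counts <- c(sum(x == 0), sum(x == 1), sum(x == 2))
      expect_equal(hwe_exact_test(counts[1], counts[2], counts[3]),
                   oracle_hwe_p(counts[1], counts[2], counts[3]),
                   tolerance = 1e-10)
    }
  })
  expect_error(hwe_exact_test(-1, 0, 2), "non-negative")
})

test_that("variant QC removes exactly the planted failures with the right reasons", {
  g <- make_genotypes(400, rep(0.3, 100), seed = 5)
  d <- g$dosages
  v <- g$variants
  # plant: 2 sex-chromosome, 3 low-MAF, 3 low call rate, 2 HWE failures
  v$chrom[1:2] <- c("X", "Y")
  d[, 3:5] <- rbinom(400 * 3, 2, 0.02)
  d[1:20, 6:8] <- NA       # call rate 95%
  d[, 9] <- rep(c(0, 2), each = 200)  # no hets at p = 0.5
  d[, 10] <- 1             # all hets
  g2 <- genotype_matrix(d, v, g$sample_ids)
  res <- variant_qc(g2, qc_thresholds())
  planted <- sprintf("v%03d", 1:10)
  expect_setequal(res$report$removed_variants$id, planted)
  got <- res$report$removed_variants
  expect_setequal(got$reason[match(sprintf("v%03d", 1:2), got$id)],
                  "sex_chromosome")
  expect_setequal(got$reason[match(sprintf("v%03d", 3:5), got$id)], "maf")
  expect_setequal(got$reason[match(sprintf("v%03d", 6:8), got$id)],
                  "call_rate")
  expect_setequal(got$reason[match(sprintf("v%03d", 9:10), got$id)], "hwe")
  # surviving order preserved and counts reconcile
  expect_identical(res$genotypes$variants$id,
                   setdiff(g2$variants$id, planted))
  expect_equal(res$report$n_before[["variants"]],
               ncol(res$genotypes$dosages) +
                 nrow(res$report$removed_variants))
})

test_that("variant QC boundary cases: MAF 0.04 and 97% call rate are removed", {
  g <- make_genotypes(1000, c(0.04, 0.3, 0.3), seed = 7)
  d <- g$dosages
  d[1:30, 2] <- NA
  g2 <- genotype_matrix(d, g$variants, g$sample_ids)
  res <- variant_qc(g2)
  expect_equal(res$report$removed_variants$reason[
    res$report$removed_variants$id == "v001"], "maf")
  expect_equal(res$report$removed_variants$reason[
    res$report$removed_variants$id == "v002"], "call_rate")
  expect_equal(res$genotypes$variants$id, "v003")
  # nothing left after filtering is an explicit error
  g_rare <- make_genotypes(1000, c(0.01, 0.02), seed = 8)
  expect_error(variant_qc(g_rare), "no variants survive")
})

test_that("sample QC removes high-missingness and heterozygosity outliers", {
  g <- make_genotypes(500, rep(0.3, 400), seed = 9)
  d <- g$dosages
  d[1, 1:24] <- NA                 # 6% missing
  het_target <- mean(d[-1, ] == 1, na.rm = TRUE)
  d[2, ] <- rbinom(400, 1, 0.999)  # het rate ~1, way above +5 SD
  g2 <- genotype_matrix(d, g$variants, g$sample_ids)
  res <- sample_qc(g2)
  rem <- res$report$removed_samples
  expect_equal(rem$reason[rem$id == "S001"], "missingness")
  expect_equal(rem$reason[rem$id == "S002"], "heterozygosity")
  # idempotence: a second pass removes nothing further
  res2 <- sample_qc(res$genotypes)
  expect_equal(nrow(res2$report$removed_samples), 0)
  expect_identical(res2$genotypes$dosages, res$genotypes$dosages)
})

test_that("identical heterozygosity rates disable the outlier filter", {
  d <- matrix(rep(c(0, 1, 2, 1), each = 25), nrow = 5)
  g <- genotype_matrix(d,
                       data.frame(chrom = "1", pos = seq_len(20) * 100,
                                  id = sprintf("v%03d", 1:20),
                                  ref = "A", alt = "G"),
                       sprintf("S%03d", 1:5))
  res <- sample_qc(g)
  expect_equal(nrow(res$report$removed_samples), 0)
})

test_that("relatedness recovers duplicates, unrelated pairs and parent-offspring", {
  freqs <- withr::with_seed(1, runif(800, 0.1, 0.5))
  g <- make_genotypes(60, freqs, seed = 11)
  d <- g$dosages
  d[2, ] <- d[1, ]                       # duplicate
  # parent-offspring: one haplotype from sample 3, one random
  withr::with_seed(12, {
    from_parent <- rbinom(800, 1, d[3, ] / 2)
    random_hap <- rbinom(800, 1, freqs)
    d[4, ] <- from_parent + random_hap
  })
  g2 <- genotype_matrix(d, g$variants, g$sample_ids)
  rel <- estimate_relatedness(g2)
  key <- function(i, j) rel$pi_hat[rel$sample_i == i & rel$sample_j == j]
  expect_lt(abs(key("S001", "S002") - 1), 0.02)
  expect_lt(abs(key("S003", "S004") - 0.5), 0.07)
  unrelated <- rel$pi_hat[!(rel$sample_i %in% c("S001", "S002", "S003", "S004") |
                              rel$sample_j %in% c("S001", "S002", "S003", "S004"))]
  expect_lt(mean(unrelated), 0.05)
  expect_lt(abs(key("S001", "S002") - key("S001", "S002")), 1e-12)
  # flagged duplicate resolves to one removal
  drop <- related_removals(g2, rel)
  expect_true(any(c("S001", "S002") %in% drop))
})

test_that("principal components separate simulated subpopulations", {
  n <- 400; m <- 2000
  withr::with_seed(21, {
    pop <- rep(c(0, 1), each = n / 2)
    p1 <- runif(m, 0.1, 0.5)
    # Balding-Nichols-style divergence
    fst <- 0.05
    p2 <- rbeta(m, p1 * (1 - fst) / fst, (1 - p1) * (1 - fst) / fst)
    dos <- matrix(NA_real_, n, m)
    dos[pop == 0, ] <- rbinom(n / 2 * m, 2, rep(p1, each = n / 2))
    dos[pop == 1, ] <- rbinom(n / 2 * m, 2, rep(p2, each = n / 2))
  })
  g <- genotype_matrix(dos,
                       data.frame(chrom = "1", pos = seq_len(m) * 100,
                                  id = sprintf("v%05d", seq_len(m)),
                                  ref = "A", alt = "G"),
                       sprintf("S%04d", seq_len(n)))
  pcs <- compute_pcs(g, 3)
  acc <- max(mean((pcs$scores[, 1] > 0) == (pop == 1)),
             mean((pcs$scores[, 1] > 0) == (pop == 0)))
  expect_gte(acc, 0.95)
  expect_true(all(diff(pcs$eigenvalues) <= 1e-8))
})

test_that("top PC matches a brute-force eigendecomposition on a small instance", {
  g <- make_genotypes(20, withr::with_seed(3, runif(50, 0.2, 0.5)), seed = 31)
  pcs <- compute_pcs(g, 2)
  # independent oracle: eigen-decomposition of the sample covariance of the
  # standardized genotype matrix
  dos <- g$dosages
  freq <- colMeans(dos) / 2
  std <- sweep(dos, 2, 2 * freq, `-`)
  std <- sweep(std, 2, sqrt(2 * freq * (1 - freq)), `/`)
  ev <- eigen(tcrossprod(std) / 1)   # sample-by-sample covariance kernel
  oracle_pc1 <- ev$vectors[, 1] * sqrt(ev$values[1])
  flip <- sign(sum(oracle_pc1 * pcs$scores[, 1]))
  expect_lt(max(abs(pcs$scores[, 1] - flip * oracle_pc1)), 1e-8)
})

test_that("variant QC is idempotent and reports reconcile", {
  co <- simulate_cohort(tiny_config(seed = 41), traits = "scz")
  r1 <- variant_qc(co$genotypes)
  r2 <- variant_qc(r1$genotypes)
  expect_equal(nrow(r2$report$removed_variants), 0)
  expect_identical(r1$genotypes$variants, r2$genotypes$variants)
  expect_equal(r1$report$n_after[["variants"]],
               r1$report$n_before[["variants"]] -
                 nrow(r1$report$removed_variants))
})
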