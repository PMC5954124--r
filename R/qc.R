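#' Quality-control thresholds
#'
#' Default thresholds: minor allele frequency >= 0.05, variant call rate
#' >= 0.98, Hardy-Weinberg exact P >= 1e-6, sample missingness <= 0.05,
#' heterozygosity within 3 SD of the sample mean, pairwise PI-HAT <= 0.125,
#' and 3 ancestry principal components.
#'
#' @param maf_min Minimum minor allele frequency.
#' @param call_rate_min Minimum variant call rate.
#' @param hwe_p_min Minimum Hardy-Weinberg exact-test P value.
#' @param sample_missing_max Maximum per-sample missing genotype fraction.
#' @param het_sd Heterozygosity outlier cut in standard deviations.
#' @param relatedness_max Maximum tolerated PI-HAT.
#' @param n_pcs Number of ancestry principal components.
#' @return A list of class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(maf_min = 0.05, call_rate_min = 0.98,
                          hwe_p_min = 1e-6, sample_missing_max = 0.05,
                          het_sd = 3, relatedness_max = 0.125, n_pcs = 3L) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, call_rate_min > 0,
            call_rate_min <= 1, hwe_p_min >= 0, hwe_p_min <= 1,
            sample_missing_max >= 0, sample_missing_max < 1,
            het_sd > 0, relatedness_max > 0, relatedness_max <= 1,
            is_count(n_pcs))
  structure(list(maf_min = maf_min, call_rate_min = call_rate_min,
                 hwe_p_min = hwe_p_min,
                 sample_missing_max = sample_missing_max,
                 het_sd = het_sd, relatedness_max = relatedness_max,
                 n_pcs = as.integer(n_pcs)),
            class = "qc_thresholds")
}

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditioning on the observed allele counts: over all
#' heterozygote counts compatible with the allele counts, sums the
#' probabilities of those configurations no more probable than the observed
#' one. A monomorphic variant returns 1 (no test possible).
#'
#' @param n_AA,n_Aa,n_aa Genotype counts.
#' @return Exact two-sided P value.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0) || sum(n_AA, n_Aa, n_aa) == 0)
    stopf("genotype counts must be non-negative and not all zero")
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  rare <- min(nA, na)
  # heterozygote count shares the parity of the rare-allele count
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    hom_rare <- (rare - h) / 2
    hom_comm <- (max(nA, na) - h) / 2
    lfactorial(n) - lfactorial(h) - lfactorial(hom_rare) -
      lfactorial(hom_comm) + h * log(2) +
      lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- match(n_Aa, hets)
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

new_qc_report <- function(removed_variants, removed_samples, n_before,
                          n_after) {
  structure(list(removed_variants = removed_variants,
                 removed_samples = removed_samples,
                 n_before = n_before, n_after = n_after),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> variants %d -> %d; samples %d -> %d\n",
              x$n_before["variants"], x$n_after["variants"],
              x$n_before["samples"], x$n_after["samples"]))
  if (nrow(x$removed_variants))
    print(table(x$removed_variants$reason))
  if (nrow(x$removed_samples))
    print(table(x$removed_samples$reason))
  invisible(x)
}

#' Variant-level quality control
#'
#' Removes, in order: variants on the X or Y chromosome, variants with call
#' rate below \code{call_rate_min}, minor allele frequency below
#' \code{maf_min}, and Hardy-Weinberg exact-test P below \code{hwe_p_min}.
#' Each variant is reported once with the first reason that applied; the
#' order of surviving variants is preserved.
#'
#' @param g A \code{\link{genotype_matrix}}.
#' @param t A \code{\link{qc_thresholds}}.
#' @return List with elements \code{genotypes} (filtered) and \code{report}.
#' @export
variant_qc <- function(g, t = qc_thresholds()) {
  if (ncol(g$dosages) == 0) stopf("empty genotype matrix")
  dos <- g$dosages
  n <- nrow(dos)
  chrom <- toupper(as.character(g$variants$chrom))
  call_rate <- colMeans(!is.na(dos))
  freq <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  reason <- rep(NA_character_, ncol(dos))
  reason[is.na(reason) & chrom %in% c("X", "Y", "23", "24", "CHRX", "CHRY")] <-
    "sex_chromosome"
  reason[is.na(reason) & call_rate < t$call_rate_min] <- "call_rate"
  reason[is.na(reason) & maf < t$maf_min] <- "maf"
  need_hwe <- which(is.na(reason))
  if (length(need_hwe)) {
    hwe_p <- vapply(need_hwe, function(j) {
      x <- dos[, j]
      hwe_exact_test(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                     sum(x == 2, na.rm = TRUE))
    }, numeric(1))
    reason[need_hwe[hwe_p < t$hwe_p_min]] <- "hwe"
  }
  keep <- is.na(reason)
  if (!any(keep)) stopf("no variants survive quality control")
  removed <- data.frame(id = g$variants$id[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  out <- subset_genotypes(g, variants = which(keep))
  report <- new_qc_report(
    removed, data.frame(id = character(), reason = character()),
    c(variants = ncol(dos), samples = n),
    c(variants = sum(keep), samples = n))
  list(genotypes = out, report = report)
}

#' Sample-level quality control
#'
#' Removes samples with missing genotype fraction above
#' \code{sample_missing_max} or with heterozygosity rate (fraction of
#' non-missing genotypes equal to 1) more than \code{het_sd} standard
#' deviations from the mean. The heterozygosity cut is iterated to a fixed
#' point (mean and SD recomputed on the retained samples until no further
#' outlier appears), which makes the filter idempotent. A zero
#' heterozygosity SD disables the outlier filter rather than flagging
#' everyone.
#'
#' @inheritParams variant_qc
#' @return List with elements \code{genotypes} and \code{report}.
#' @export
sample_qc <- function(g, t = qc_thresholds()) {
  dos <- g$dosages
  if (nrow(dos) < 3) stopf("sample QC needs at least 3 samples")
  missing <- rowMeans(is.na(dos))
  het <- rowMeans(dos == 1, na.rm = TRUE)
  reason <- rep(NA_character_, nrow(dos))
  reason[missing > t$sample_missing_max] <- "missingness"
  repeat {
    ok <- is.na(reason)
    if (sum(ok) < 3) break
    het_mu <- mean(het[ok])
    het_s <- stats::sd(het[ok])
    if (het_s == 0) break
    out <- ok & abs(het - het_mu) > t$het_sd * het_s
    if (!any(out)) break
    reason[out] <- "heterozygosity"
  }
  keep <- is.na(reason)
  if (!any(keep)) stopf("no samples survive quality control")
  removed <- data.frame(id = g$sample_ids[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  out <- subset_genotypes(g, samples = which(keep))
  report <- new_qc_report(
    data.frame(id = character(), reason = character()),
    removed,
    c(variants = ncol(dos), samples = nrow(dos)),
    c(variants = ncol(dos), samples = sum(keep)))
  list(genotypes = out, report = report)
}

#' Greedy LD pruning
#'
#' Slides a window of \code{window} variants; within a window, of any pair
#' with squared dosage correlation above \code{r2_max} the later variant is
#' dropped. Used to obtain a quasi-independent variant set for relatedness
#' estimation.
#'
#' @param g A \code{\link{genotype_matrix}}.
#' @param window Window size in variants.
#' @param r2_max Maximum tolerated squared correlation.
#' @return Integer indices of retained variants.
#' @export
ld_prune <- function(g, window = 100L, r2_max = 0.2) {
  dos <- g$dosages
  m <- ncol(dos)
  n <- nrow(dos)
  freq <- colMeans(dos, na.rm = TRUE)
  idx_na <- which(is.na(dos))
  if (length(idx_na))
    dos[idx_na] <- freq[((idx_na - 1) %/% n) + 1]
  dos <- sweep(dos, 2, colMeans(dos), `-`)
  nrm <- sqrt(colSums(dos^2))
  zero_var <- nrm == 0
  nrm[zero_var] <- 1
  dos <- sweep(dos, 2, nrm, `/`)   # unit-norm columns: r = crossprod
  keep <- !zero_var
  for (j in seq_len(m)) {
    if (!keep[j]) next
    upper <- min(m, j + window - 1L)
    if (upper <= j) next
    cand <- which(keep[(j + 1L):upper]) + j
    if (!length(cand)) next
    r <- drop(crossprod(dos[, cand, drop = FALSE], dos[, j]))
    keep[cand[r^2 > r2_max]] <- FALSE
  }
  which(keep)
}

#' Method-of-moments relatedness (PI-HAT)
#'
#' For each sample pair, computes identity-by-state (IBS) counts over
#' non-missing variants and solves the method-of-moments equations for the
#' probabilities \code{Z0, Z1, Z2} of sharing 0, 1 or 2 alleles identical by
#' descent, using allele-frequency-based expectations of IBS given IBD.
#' Returns \code{pi_hat = Z2 + Z1/2}, clamped to \[0, 1\].
#'
#' Variants should be LD-pruned first (\code{\link{ld_prune}}); fewer than 50
#' informative variants triggers a low-confidence warning.
#'
#' @param g A \code{\link{genotype_matrix}} (post-QC, pruned).
#' @param relatedness_max Pairs with \code{pi_hat} above this value are
#'   flagged.
#' @return Data frame with columns \code{sample_i}, \code{sample_j},
#'   \code{pi_hat}, \code{flagged}.
#' @export
estimate_relatedness <- function(g, relatedness_max = 0.125) {
  dos <- g$dosages
  n <- nrow(dos)
  if (n < 2) stopf("relatedness needs at least 2 samples")
  m <- ncol(dos)
  if (m < 50)
    warning("fewer than 50 informative variants; ",
            "relatedness estimates are low-confidence")
  # unbiased factorial-moment estimators of p^2 q^2, p^3 q + p q^3 and
  # p^2 q + p q^2 from the sample allele counts (finite-sample correction)
  n_ok_var <- colSums(!is.na(dos))
  w <- 2 * n_ok_var                       # alleles observed per variant
  nA <- colSums(dos, na.rm = TRUE)        # alt-allele count
  na_ <- w - nA
  f <- function(x, k) {
    out <- rep(1, length(x))
    for (i in seq_len(k) - 1) out <- out * pmax(x - i, 0)
    out
  }
  denom4 <- f(w, 4)
  p2q2 <- ifelse(denom4 > 0, f(nA, 2) * f(na_, 2) / denom4, 0)
  p3q <- ifelse(denom4 > 0, f(nA, 3) * f(na_, 1) / denom4, 0)
  pq3 <- ifelse(denom4 > 0, f(nA, 1) * f(na_, 3) / denom4, 0)
  denom3 <- f(w, 3)
  p2q <- ifelse(denom3 > 0, f(nA, 2) * f(na_, 1) / denom3, 0)
  pq2 <- ifelse(denom3 > 0, f(nA, 1) * f(na_, 2) / denom3, 0)
  e0_ibs0 <- 2 * p2q2
  e0_ibs1 <- 4 * p3q + 4 * pq3
  e1_ibs1 <- 2 * p2q + 2 * pq2
  # indicator matrices per genotype class; IBS counts via cross-products
  I0 <- (!is.na(dos)) & dos == 0; I0[is.na(dos)] <- FALSE
  I1 <- (!is.na(dos)) & dos == 1; I1[is.na(dos)] <- FALSE
  I2 <- (!is.na(dos)) & dos == 2; I2[is.na(dos)] <- FALSE
  V <- !is.na(dos)
  storage.mode(I0) <- storage.mode(I1) <- storage.mode(I2) <-
    storage.mode(V) <- "double"
  obs0 <- tcrossprod(I0, I2); obs0 <- obs0 + t(obs0)
  obs1 <- tcrossprod(I1, I0 + I2)
  obs1 <- obs1 + t(obs1)
  E00 <- tcrossprod(V * rep(e0_ibs0, each = n), V)
  E10 <- tcrossprod(V * rep(e0_ibs1, each = n), V)
  E11 <- tcrossprod(V * rep(e1_ibs1, each = n), V)
  z0 <- ifelse(E00 > 0, obs0 / E00, 0)
  z1 <- ifelse(E11 > 0, (obs1 - z0 * E10) / E11, 0)
  z0 <- pmin(pmax(z0, 0), 1)
  z1 <- pmin(pmax(z1, 0), 1 - z0)
  z2 <- 1 - z0 - z1
  pihat <- pmin(pmax(z2 + z1 / 2, 0), 1)
  pairs <- utils::combn(n, 2)
  ph <- pihat[cbind(pairs[1, ], pairs[2, ])]
  data.frame(sample_i = g$sample_ids[pairs[1, ]],
             sample_j = g$sample_ids[pairs[2, ]],
             pi_hat = ph,
             flagged = ph > relatedness_max,
             stringsAsFactors = FALSE)
}

#' Resolve related pairs into a removal list
#'
#' Within each flagged pair the sample with the higher missingness is removed
#' (ties broken by lexicographically larger id), iterating until no flagged
#' pair remains among retained samples.
#'
#' @param g A \code{\link{genotype_matrix}}.
#' @param rel Output of \code{\link{estimate_relatedness}}.
#' @return Character vector of sample ids to remove.
#' @export
related_removals <- function(g, rel) {
  flagged <- rel[rel$flagged & !is.na(rel$pi_hat), , drop = FALSE]
  if (!nrow(flagged)) return(character())
  missing <- rowMeans(is.na(g$dosages))
  names(missing) <- g$sample_ids
  drop <- character()
  flagged <- flagged[order(-flagged$pi_hat), , drop = FALSE]
  for (r in seq_len(nrow(flagged))) {
    i <- flagged$sample_i[r]; j <- flagged$sample_j[r]
    if (i %in% drop || j %in% drop) next
    worse <- if (missing[i] > missing[j]) i
             else if (missing[j] > missing[i]) j
             else max(i, j)
    drop <- c(drop, worse)
  }
  drop
}

#' Ancestry principal components
#'
#' Mean-imputes missing dosages, centers each variant at twice its allele
#' frequency and scales by \code{sqrt(2 p (1 - p))}, then takes the top
#' \code{n_pcs} left singular directions of the standardised matrix as sample
#' coordinates. Zero-variance variants are excluded with a warning.
#'
#' @param g A post-QC \code{\link{genotype_matrix}}.
#' @param n_pcs Number of components.
#' @return List of class \code{ancestry_pcs}: \code{scores} (samples x
#'   \code{n_pcs}), \code{eigenvalues} (non-increasing), \code{sample_ids}.
#' @export
compute_pcs <- function(g, n_pcs = 3L) {
  dos <- g$dosages
  n <- nrow(dos)
  if (n_pcs >= min(dim(dos)))
    stopf("n_pcs must be smaller than both dimensions")
  freq <- colMeans(dos, na.rm = TRUE) / 2
  keep <- freq > 0 & freq < 1
  if (!all(keep)) {
    warning(sprintf("%d zero-variance variants excluded from PCA",
                    sum(!keep)))
    dos <- dos[, keep, drop = FALSE]
    freq <- freq[keep]
  }
  for (j in seq_len(ncol(dos)))
    dos[is.na(dos[, j]), j] <- 2 * freq[j]
  std <- sweep(dos, 2, 2 * freq, `-`)
  std <- sweep(std, 2, sqrt(2 * freq * (1 - freq)), `/`)
  sv <- svd(std, nu = n_pcs, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  structure(list(scores = scores,
                 eigenvalues = sv$d^2 / (n - 1),
                 sample_ids = g$sample_ids),
            class = "ancestry_pcs")
}

#' Run the full genotype QC chain
#'
#' Variant filters (sex chromosomes, call rate, MAF, Hardy-Weinberg), then
#' sample filters (missingness, heterozygosity), then relatedness removal on
#' an LD-pruned panel, then ancestry PCA.
#'
#' @param g A \code{\link{genotype_matrix}}.
#' @param t A \code{\link{qc_thresholds}}.
#' @return List with \code{genotypes}, \code{pcs}, \code{report}.
#' @export
run_qc <- function(g, t = qc_thresholds()) {
  v <- variant_qc(g, t)
  s <- sample_qc(v$genotypes, t)
  pruned <- ld_prune(s$genotypes)
  rel <- estimate_relatedness(
    subset_genotypes(s$genotypes, variants = pruned), t$relatedness_max)
  rel_drop <- related_removals(s$genotypes, rel)
  g2 <- if (length(rel_drop))
    subset_genotypes(s$genotypes,
                     samples = which(!s$genotypes$sample_ids %in% rel_drop))
  else s$genotypes
  removed_samples <- rbind(
    s$report$removed_samples,
    data.frame(id = rel_drop,
               reason = rep("relatedness", length(rel_drop)),
               stringsAsFactors = FALSE))
  report <- new_qc_report(
    v$report$removed_variants, removed_samples,
    c(variants = ncol(g$dosages), samples = nrow(g$dosages)),
    c(variants = ncol(g2$dosages), samples = nrow(g2$dosages)))
  pcs <- compute_pcs(g2, t$n_pcs)
  list(genotypes = g2, pcs = pcs, report = report, relatedness = rel)
}
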