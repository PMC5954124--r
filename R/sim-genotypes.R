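#' Construct a genotype matrix container
#'
#' Bundles a samples-by-variants dosage matrix (alt-allele counts 0/1/2 or NA)
#' with its variant metadata table. All QC, PCA, clumping and scoring
#' functions operate on this container.
#'
#' @param dosages Numeric matrix, samples in rows, variants in columns; values
#'   in \{0, 1, 2, NA\}.
#' @param variants Data frame with columns \code{chrom}, \code{pos},
#'   \code{id}, \code{ref}, \code{alt}.
#' @param sample_ids Character vector of sample identifiers.
#' @return An object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(dosages, variants, sample_ids) {
  dosages <- as.matrix(dosages)
  if (nrow(variants) != ncol(dosages))
    stopf("variant table (%d rows) does not match dosage columns (%d)",
          nrow(variants), ncol(dosages))
  if (length(sample_ids) != nrow(dosages))
    stopf("sample_ids length (%d) does not match dosage rows (%d)",
          length(sample_ids), nrow(dosages))
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok))
    stopf("dosages must be 0, 1, 2 or missing")
  if (anyDuplicated(variants$id))
    stopf("variant ids must be unique")
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stopf("positions must be strictly increasing within chromosome %s", ch)
  }
  rownames(dosages) <- sample_ids
  colnames(dosages) <- variants$id
  structure(list(dosages = dosages,
                 variants = as.data.frame(variants),
                 sample_ids = as.character(sample_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants (%.2f%% missing)\n",
              length(x$sample_ids), nrow(x$variants),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

# Subset a genotype matrix by sample and/or variant index.
subset_genotypes <- function(g, samples = NULL, variants = NULL) {
  d <- g$dosages
  v <- g$variants
  s <- g$sample_ids
  if (!is.null(variants)) {
    d <- d[, variants, drop = FALSE]
    v <- v[variants, , drop = FALSE]
    rownames(v) <- NULL
  }
  if (!is.null(samples)) {
    d <- d[samples, , drop = FALSE]
    s <- s[samples]
  }
  genotype_matrix(d, v, s)
}

#' Simulate genotypes with block linkage disequilibrium
#'
#' Draws per-variant minor allele frequencies uniformly from
#' \code{maf_range}, then generates two haplotypes per subject from a
#' Gaussian copula: within each block of \code{ld_block_size} consecutive
#' variants, latent normals follow an AR(1) process with lag-one correlation
#' \code{within_block_r}; blocks are independent. Each latent value is
#' thresholded at the allele-frequency quantile to give an allele, and the
#' genotype is the sum of the two haplotypes. Missingness is applied uniformly
#' at random at \code{missing_rate}.
#'
#' Variants are laid out on chromosomes 1-22 in equal contiguous stretches,
#' one block never straddling a chromosome boundary concern because positions
#' are only used for windowing (5 kb spacing).
#'
#' @param config A \code{\link{sim_config}}.
#' @return A \code{\link{genotype_matrix}}.
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  n <- config$n_samples
  m <- config$n_variants
  with_seed(substream_seed(config$seed, "genotypes"), {
    maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    thr <- stats::qnorm(maf)
    r <- config$within_block_r
    block <- rep(seq_len(ceiling(m / config$ld_block_size)),
                 each = config$ld_block_size)[seq_len(m)]
    new_block <- c(TRUE, diff(block) != 0)
    hap_latent <- function() {
      z <- matrix(stats::rnorm(n * m), n, m)
      if (r > 0 && m > 1) {
        for (j in 2:m) {
          if (!new_block[j])
            z[, j] <- r * z[, j - 1] + sqrt(1 - r^2) * z[, j]
        }
      }
      z
    }
    h1 <- sweep(hap_latent(), 2, thr, `<`)
    h2 <- sweep(hap_latent(), 2, thr, `<`)
    dos <- h1 + h2
    storage.mode(dos) <- "double"
    if (config$missing_rate > 0) {
      miss <- stats::runif(n * m) < config$missing_rate
      dos[miss] <- NA_real_
    }
    chrom <- rep(1:22, length.out = 22)[
      cut(seq_len(m), breaks = 22, labels = FALSE)]
    pos <- integer(m)
    for (ch in unique(chrom))
      pos[chrom == ch] <- seq_len(sum(chrom == ch)) * 5000L
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
    variants <- data.frame(chrom = as.character(chrom), pos = pos,
                           id = sprintf("rs%06d", seq_len(m)),
                           ref = ref, alt = unname(alt),
                           stringsAsFactors = FALSE)
    genotype_matrix(dos, variants,
                    sprintf("S%04d", seq_len(n)))
  })
}
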