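#' Clumping and scoring configuration
#'
#' Defaults follow the standard clump-and-threshold recipe: a 250 kb window
#' (interpreted as +/- 250 kb around the index variant), an r-squared
#' ceiling of 0.1, exclusion of the extended MHC region (chromosome 6,
#' 26-33 Mb, 1-based inclusive), and five P-value thresholds.
#'
#' @param window_kb Clumping window half-width in kb.
#' @param r2_max LD r-squared above which neighbours of an index variant are
#'   removed.
#' @param exclude_mhc Whether to drop the MHC region before clumping.
#' @param mhc_region List with \code{chrom}, \code{start}, \code{end}.
#' @param thresholds P-value thresholds used to select index variants.
#' @return A list of class \code{clump_config}.
#' @export
clump_config <- function(window_kb = 250, r2_max = 0.1, exclude_mhc = TRUE,
                         mhc_region = list(chrom = "6", start = 26e6,
                                           end = 33e6),
                         thresholds = c(0.001, 0.01, 0.05, 0.1, 0.5)) {
  stopifnot(window_kb > 0, r2_max > 0, r2_max < 1,
            all(thresholds > 0), all(thresholds <= 1))
  structure(list(window_kb = window_kb, r2_max = r2_max,
                 exclude_mhc = isTRUE(exclude_mhc), mhc_region = mhc_region,
                 thresholds = sort(thresholds)),
            class = "clump_config")
}

#' Harmonise summary statistics to a target genotype panel
#'
#' Matches variants by chromosome and position. When the effect allele is
#' the target's alt allele (and the other allele its ref) the effect is kept;
#' when the alleles are swapped the effect sign is flipped so that all
#' effects are on the target alt-dosage scale. Strand-ambiguous A/T and C/G
#' variants and variants with incompatible alleles are dropped. A drop report
#' is attached as attribute \code{"harmonization"}.
#'
#' @param sumstats Summary-statistics data frame (see
#'   \code{\link{simulate_summary_stats}} for the column contract).
#' @param g A \code{\link{genotype_matrix}}.
#' @return The harmonised subset of \code{sumstats}, in target variant order,
#'   with an extra column \code{target_id}.
#' @export
harmonize_alleles <- function(sumstats, g) {
  validate_summary_stats(sumstats)
  v <- g$variants
  key_s <- paste(sumstats$chrom, sumstats$pos)
  key_g <- paste(v$chrom, v$pos)
  idx <- match(key_s, key_g)
  matched <- !is.na(idx)
  drops <- data.frame(id = character(), reason = character(),
                      stringsAsFactors = FALSE)
  if (any(!matched))
    drops <- rbind(drops, data.frame(id = sumstats$id[!matched],
                                     reason = "unmatched"))
  ss <- sumstats[matched, , drop = FALSE]
  tv <- v[idx[matched], , drop = FALSE]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ambiguous <- ss$effect_allele == comp[ss$other_allele]
  if (any(ambiguous))
    drops <- rbind(drops, data.frame(id = ss$id[ambiguous],
                                     reason = "ambiguous"))
  ss <- ss[!ambiguous, , drop = FALSE]
  tv <- tv[!ambiguous, , drop = FALSE]
  same <- ss$effect_allele == tv$alt & ss$other_allele == tv$ref
  flipped <- ss$effect_allele == tv$ref & ss$other_allele == tv$alt
  mismatch <- !(same | flipped)
  if (any(mismatch))
    drops <- rbind(drops, data.frame(id = ss$id[mismatch],
                                     reason = "allele_mismatch"))
  ss <- ss[!mismatch, , drop = FALSE]
  tv <- tv[!mismatch, , drop = FALSE]
  flipped <- flipped[!mismatch]
  if (nrow(ss) == 0) stopf("zero overlapping variants after harmonisation")
  ss$effect[flipped] <- -ss$effect[flipped]
  tmp <- ss$effect_allele[flipped]
  ss$effect_allele[flipped] <- ss$other_allele[flipped]
  ss$other_allele[flipped] <- tmp
  ss$target_id <- tv$id
  ord <- order(match(ss$target_id, v$id))
  ss <- ss[ord, , drop = FALSE]
  rownames(ss) <- NULL
  attr(ss, "harmonization") <- drops
  ss
}

#' Greedy LD clumping of summary statistics
#'
#' Removes MHC variants (if configured), then visits variants in ascending
#' P value (ties broken by chromosome then position); each visited variant
#' not already removed becomes an index variant, and all not-yet-retained
#' variants within \code{window_kb} kb on the same chromosome whose dosage
#' correlation with the index exceeds \code{sqrt(r2_max)} in absolute value
#' are removed. The retained set is returned in the original variant order.
#'
#' r-squared is computed on mean-imputed, centred dosages of the target
#' sample, which thereby acts as its own LD reference.
#'
#' @param sumstats Harmonised summary statistics
#'   (\code{\link{harmonize_alleles}}).
#' @param g The target \code{\link{genotype_matrix}} (LD reference).
#' @param cfg A \code{\link{clump_config}}.
#' @return The clumped subset of \code{sumstats}.
#' @export
ld_clump <- function(sumstats, g, cfg = clump_config()) {
  if (is.null(sumstats$target_id))
    sumstats$target_id <- sumstats$id
  if (anyNA(sumstats$pos)) stopf("summary statistics lack positions")
  ss <- sumstats
  if (cfg$exclude_mhc) {
    mhc <- as.character(ss$chrom) == as.character(cfg$mhc_region$chrom) &
      ss$pos >= cfg$mhc_region$start & ss$pos <= cfg$mhc_region$end
    ss <- ss[!mhc, , drop = FALSE]
  }
  if (nrow(ss) == 0) stopf("no variants left to clump")
  gi <- match(ss$target_id, g$variants$id)
  if (anyNA(gi)) stopf("clump input contains variants absent from the panel")
  dos <- g$dosages[, gi, drop = FALSE]
  freq <- colMeans(dos, na.rm = TRUE)
  for (j in seq_len(ncol(dos)))
    dos[is.na(dos[, j]), j] <- freq[j]
  dos <- sweep(dos, 2, colMeans(dos), `-`)
  norm <- sqrt(colSums(dos^2))
  m <- nrow(ss)
  visit <- order(ss$p, as.character(ss$chrom), ss$pos)
  state <- rep("free", m)            # free / index / removed
  win <- cfg$window_kb * 1000
  for (i in visit) {
    if (state[i] != "free") next
    state[i] <- "index"
    near <- which(state == "free" &
                    as.character(ss$chrom) == as.character(ss$chrom[i]) &
                    abs(ss$pos - ss$pos[i]) <= win)
    if (!length(near)) next
    if (norm[i] == 0) next
    r <- (drop(crossprod(dos[, near, drop = FALSE], dos[, i])) /
            (norm[near] * norm[i]))
    r[!is.finite(r)] <- 1
    state[near[r^2 > cfg$r2_max]] <- "removed"
  }
  out <- ss[state == "index", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compute clump-and-threshold polygenic scores
#'
#' For each P-value threshold, the index variants with \code{p <= threshold}
#' contribute \code{dosage * effect} to each sample's score; missing dosages
#' are replaced by twice the effect-allele frequency observed in the target
#' sample.
#'
#' @param g The target \code{\link{genotype_matrix}}.
#' @param clumped Clumped, harmonised summary statistics.
#' @param cfg A \code{\link{clump_config}} (supplies the thresholds).
#' @param trait Trait label recorded in the result.
#' @return Long-format data frame of class \code{prs_result}: columns
#'   \code{sample_id}, \code{trait}, \code{p_threshold}, \code{score},
#'   \code{n_snps}.
#' @export
compute_prs <- function(g, clumped, cfg = clump_config(), trait = "trait") {
  if (is.null(clumped$target_id)) clumped$target_id <- clumped$id
  gi <- match(clumped$target_id, g$variants$id)
  if (anyNA(gi)) stopf("scored variants absent from the panel")
  dos <- g$dosages[, gi, drop = FALSE]
  freq <- colMeans(dos, na.rm = TRUE)
  for (j in seq_len(ncol(dos)))
    dos[is.na(dos[, j]), j] <- freq[j]
  res <- lapply(cfg$thresholds, function(pt) {
    sel <- clumped$p <= pt
    if (!any(sel)) {
      warning(sprintf("no index variants at threshold %g; score set to 0",
                      pt))
      score <- rep(0, nrow(dos))
    } else {
      score <- drop(dos[, sel, drop = FALSE] %*% clumped$effect[sel])
    }
    data.frame(sample_id = g$sample_ids, trait = trait, p_threshold = pt,
               score = score, n_snps = sum(sel), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("prs_result", "data.frame")
  out
}
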