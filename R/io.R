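#' Write a genotype matrix as an unphased VCF
#'
#' Minimal VCFv4.2 writer emitting GT fields (0/0, 0/1, 1/1, ./.) from
#' alt-allele dosages.
#'
#' @param g A \code{\link{genotype_matrix}}.
#' @param path Output file path (plain text).
#' @return The path, invisibly.
#' @export
write_vcf <- function(g, path) {
  v <- g$variants
  gt_codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##source=erpmed",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", g$sample_ids), collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(j) {
    d <- g$dosages[, j]
    gt <- ifelse(is.na(d), "./.", gt_codes[as.character(d)])
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j], ".", "PASS",
            ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Uses \pkg{vcfR} to parse the file and converts GT fields to alt-allele
#' dosages.
#'
#' @param path VCF file path.
#' @return A \code{\link{genotype_matrix}}.
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stopf("reading VCF requires the vcfR package")
  vc <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vc, element = "GT")
  alt_count <- function(x) {
    ifelse(is.na(x) | x %in% c("./.", "."), NA_real_,
           vapply(strsplit(x, "[/|]"), function(a)
             sum(a != "." & a != "0"), numeric(1)))
  }
  dos <- t(apply(gt, 1, alt_count))
  fix <- as.data.frame(vc@fix, stringsAsFactors = FALSE)
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         id = fix$ID, ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  genotype_matrix(t(dos), variants, colnames(gt))
}

#' Write genotypes as a PLINK-1 binary triplet
#'
#' Writes \code{.bed} (SNP-major, magic bytes 0x6c 0x1b 0x01), \code{.bim}
#' and \code{.fam} files. Dosages count the alt allele, stored as PLINK A1.
#'
#' @param g A \code{\link{genotype_matrix}}.
#' @param prefix Path prefix (without extension).
#' @return The prefix, invisibly.
#' @export
write_plink <- function(g, prefix) {
  v <- g$variants
  n <- length(g$sample_ids)
  bim <- data.frame(v$chrom, v$id, 0, v$pos, v$alt, v$ref)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(g$sample_ids, g$sample_ids, 0, 0, 0, -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  # 2-bit codes, A1 = alt: 00 hom A1 (dosage 2), 10 het, 11 hom A2, 01 missing
  code <- function(d) {
    ifelse(is.na(d), 1L, ifelse(d == 2, 0L, ifelse(d == 1, 2L, 3L)))
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  bytes_per_var <- ceiling(n / 4)
  for (j in seq_len(ncol(g$dosages))) {
    cd <- code(g$dosages[, j])
    cd <- c(cd, rep(3L, bytes_per_var * 4 - n))  # pad with hom A2
    idx <- matrix(cd, nrow = 4)
    byte <- idx[1, ] + idx[2, ] * 4L + idx[3, ] * 16L + idx[4, ] * 64L
    writeBin(as.raw(byte), con)
  }
  invisible(prefix)
}

#' Read genotypes from a PLINK-1 binary triplet
#'
#' @param prefix Path prefix of the \code{.bed}/\code{.bim}/\code{.fam}
#'   triplet.
#' @return A \code{\link{genotype_matrix}} (dosages count A1 = alt).
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"),
                           col.names = c("chrom", "id", "cm", "pos",
                                         "a1", "a2"),
                           colClasses = c("character", "character",
                                          "numeric", "integer", "character",
                                          "character"))
  fam <- utils::read.table(paste0(prefix, ".fam"), colClasses = "character")
  n <- nrow(fam)
  m <- nrow(bim)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    stopf("not a SNP-major PLINK-1 bed file")
  bytes_per_var <- ceiling(n / 4)
  raw <- readBin(con, "raw", bytes_per_var * m)
  bits <- matrix(as.integer(rawToBits(raw)), nrow = 8)
  # each byte holds 4 samples, 2 bits each, low bits first
  two_bit <- bits[c(TRUE, FALSE), ] + 2L * bits[c(FALSE, TRUE), ]
  codes <- matrix(as.vector(two_bit), nrow = bytes_per_var * 4)[seq_len(n), ,
                                                                drop = FALSE]
  dos <- matrix(NA_real_, n, m)
  dos[codes == 0L] <- 2
  dos[codes == 2L] <- 1
  dos[codes == 3L] <- 0
  variants <- data.frame(chrom = bim$chrom, pos = bim$pos, id = bim$id,
                         ref = bim$a2, alt = bim$a1,
                         stringsAsFactors = FALSE)
  genotype_matrix(dos, variants, fam[[2]])
}

#' Read or write GWAS summary statistics as TSV
#'
#' Column layout: CHR, POS, SNP, A1 (effect allele), A2, EFFECT, SE, P.
#'
#' @param ss Summary-statistics data frame.
#' @param path File path.
#' @return \code{read_sumstats}: a summary-statistics data frame.
#' @export
write_sumstats <- function(ss, path) {
  out <- data.frame(CHR = ss$chrom, POS = ss$pos, SNP = ss$id,
                    A1 = ss$effect_allele, A2 = ss$other_allele,
                    EFFECT = ss$effect, SE = ss$se, P = ss$p)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c(CHR = "character"))
  out <- data.frame(chrom = x$CHR, pos = x$POS, id = x$SNP,
                    effect_allele = x$A1, other_allele = x$A2,
                    effect = x$EFFECT, se = x$SE, p = x$P,
                    stringsAsFactors = FALSE)
  validate_summary_stats(out)
  out
}

#' Read or write a genotype dosage table as TSV
#'
#' Wide layout: columns chrom, pos, id, ref, alt, then one column per sample.
#'
#' @param g A \code{\link{genotype_matrix}}.
#' @param path File path.
#' @return \code{read_dosage_tsv}: a \code{\link{genotype_matrix}}.
#' @export
write_dosage_tsv <- function(g, path) {
  out <- cbind(g$variants, as.data.frame(t(g$dosages)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE,
                         colClasses = c(chrom = "character"))
  meta <- c("chrom", "pos", "id", "ref", "alt")
  samples <- setdiff(names(x), meta)
  genotype_matrix(t(as.matrix(x[, samples, drop = FALSE])),
                  x[, meta], samples)
}
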