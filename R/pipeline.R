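#' Pipeline configuration
#'
#' Bundles either a \code{\link{sim_config}} (synthetic run) or paths to
#' genotype, summary-statistics and phenotype files (real-data run) with the
#' stage parameters and a global seed.
#'
#' @param sim A \code{\link{sim_config}}, or NULL when file inputs are given.
#' @param geno_path,sumstats_paths,pheno_path Input file paths
#'   (\code{sumstats_paths}: named list, one TSV per trait). Ignored when
#'   \code{sim} is given; exactly one of the two input modes must be used.
#' @param qc A \code{\link{qc_thresholds}}.
#' @param clump A \code{\link{clump_config}}.
#' @param k Number of ERP clusters, or \code{"auto"} for V-fold selection.
#' @param k_range Candidate k values when \code{k = "auto"}.
#' @param folds Folds for V-fold selection.
#' @param mediation_specs List of lists with elements \code{exposure}
#'   (trait), \code{p_threshold}, \code{mediator}, \code{outcome},
#'   \code{interaction}; \code{mediator}/\code{outcome} name pipeline
#'   variables (\code{"gi"}, \code{"panss_positive"}, \code{"case"}).
#' @param n_boot Bootstrap replications for mediation intervals.
#' @param out_dir Output directory for stage TSVs, or NULL to skip writing.
#' @param seed Global seed.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(sim = sim_config(),
                            geno_path = NULL, sumstats_paths = NULL,
                            pheno_path = NULL,
                            qc = qc_thresholds(),
                            clump = clump_config(),
                            k = "auto", k_range = 2:5, folds = 10L,
                            mediation_specs = list(
                              list(exposure = "scz", p_threshold = 0.001,
                                   mediator = "gi",
                                   outcome = "panss_positive",
                                   interaction = FALSE)),
                            n_boot = 200L, out_dir = NULL, seed = 1L) {
  has_sim <- !is.null(sim)
  has_files <- !is.null(geno_path)
  if (has_sim == has_files)
    stopf("provide exactly one of a simulation config or input file paths")
  if (has_files) {
    for (p in c(geno_path, unlist(sumstats_paths), pheno_path))
      if (!file.exists(p)) stopf("input path does not exist: %s", p)
  }
  structure(list(sim = sim, geno_path = geno_path,
                 sumstats_paths = sumstats_paths, pheno_path = pheno_path,
                 qc = qc, clump = clump, k = k, k_range = k_range,
                 folds = as.integer(folds),
                 mediation_specs = mediation_specs,
                 n_boot = as.integer(n_boot), out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

pipeline_stage <- function(report, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  report$stages[[name]] <- list(wall_time = proc.time()[["elapsed"]] - t0)
  list(report = report, value = value)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (if configured), genotype QC with ancestry PCs, ERP
#' clustering with globally-impaired labelling, per-trait clumping and
#' polygenic scoring, PRS-phenotype association with FDR adjustment (all
#' subjects and cases only), a demographic comparison block, and the
#' configured mediation analyses. All stages derive their seeds from the
#' global seed, so a rerun with the same configuration reproduces identical
#' numbers.
#'
#' @param cfg A \code{\link{pipeline_config}}.
#' @return A \code{run_report} list with per-stage records and the three
#'   result blocks (\code{table1}, \code{associations}, \code{mediation}).
#' @export
run_pipeline <- function(cfg) {
  report <- list(config = cfg, seed = cfg$seed, stages = list())

  if (!is.null(cfg$sim)) {
    st <- pipeline_stage(report, "simulate", simulate_cohort(cfg$sim))
    report <- st$report
    cohort <- st$value
    geno <- cohort$genotypes
    sumstats <- cohort$sumstats
    pheno <- cohort$phenotypes
  } else {
    geno <- switch(tools::file_ext(cfg$geno_path),
                   vcf = read_vcf(cfg$geno_path),
                   bed = read_plink(sub("\\.bed$", "", cfg$geno_path)),
                   read_dosage_tsv(cfg$geno_path))
    sumstats <- lapply(cfg$sumstats_paths, read_sumstats)
    pheno <- utils::read.table(cfg$pheno_path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  }

  st <- pipeline_stage(report, "qc", run_qc(geno, cfg$qc))
  report <- st$report
  qc_out <- st$value
  geno_qc <- qc_out$genotypes
  keep <- pheno$sample_id %in% geno_qc$sample_ids
  pheno <- pheno[keep, , drop = FALSE]

  st <- pipeline_stage(report, "cluster", {
    profiles <- pheno[, erp_measures]
    ksel <- NULL
    k <- cfg$k
    if (identical(k, "auto")) {
      ksel <- select_k_vfold(profiles, cfg$k_range, cfg$folds,
                             seed = cfg$seed)
      k <- ksel$chosen_k
    }
    model <- label_globally_impaired(
      fit_kmeans(profiles, k, seed = cfg$seed))
    list(model = model, ksel = ksel)
  })
  report <- st$report
  model <- st$value$model
  report$k_selection <- st$value$ksel
  gi <- stats::setNames(model$gi_flag, pheno$sample_id)

  st <- pipeline_stage(report, "score", {
    res <- lapply(names(sumstats), function(tr) {
      h <- harmonize_alleles(sumstats[[tr]], geno_qc)
      cl <- ld_clump(h, geno_qc, cfg$clump)
      compute_prs(geno_qc, cl, cfg$clump, trait = tr)
    })
    do.call(rbind, res)
  })
  report <- st$report
  prs <- st$value

  st <- pipeline_stage(report, "assoc", {
    case_ids <- pheno$sample_id[pheno$diagnosis != "control"]
    all_res <- prs_association(prs, gi, qc_out$pcs, subset = "all")
    case_res <- tryCatch(
      prs_association(prs, gi, qc_out$pcs, subset = "cases",
                      sample_ids = case_ids),
      error = function(e) NULL)
    rbind(all_res, case_res)
  })
  report <- st$report
  report$associations <- st$value

  report$table1 <- demographic_block(pheno, gi)

  st <- pipeline_stage(report, "mediate", {
    lapply(cfg$mediation_specs, function(spec) {
      sc <- prs[prs$trait == spec$exposure &
                  prs$p_threshold == spec$p_threshold, ]
      a <- dichotomize_exposure(stats::setNames(sc$score, sc$sample_id))
      d <- pheno
      d$gi <- gi[d$sample_id]
      d$case <- as.integer(d$diagnosis != "control")
      d$exposure <- a[d$sample_id]
      d$sex_m <- as.integer(d$sex == "M")
      d$smoker_yes <- as.integer(d$smoker == "yes")
      pcs_m <- qc_out$pcs$scores[match(d$sample_id,
                                       qc_out$pcs$sample_ids), ,
                                 drop = FALSE]
      d <- cbind(d, pcs_m)
      covars <- c(colnames(pcs_m), "age", "sex_m", "smoker_yes")
      if (identical(spec$outcome, "panss_positive"))
        covars <- c(covars, "cpz_dose")
      est <- bootstrap_bcci(d, spec$outcome, spec$mediator, "exposure",
                            covars,
                            interaction = isTRUE(spec$interaction),
                            n_boot = cfg$n_boot, seed = cfg$seed)
      est$spec <- spec
      est
    })
  })
  report <- st$report
  report$mediation <- st$value
  report$qc_report <- qc_out$report
  report$cluster_model <- model
  report$gi <- gi
  report$prs <- prs
  report$pcs <- qc_out$pcs
  report$phenotypes <- pheno

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) utils::write.table(
      x, file.path(cfg$out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(report$associations, "associations.tsv")
    wt(data.frame(sample_id = names(gi), cluster = model$assignments,
                  gi_flag = unname(gi)), "clusters.tsv")
    wt(prs, "scores.tsv")
    med_tab <- do.call(rbind, lapply(report$mediation, function(m)
      data.frame(exposure = m$spec$exposure,
                 p_threshold = m$spec$p_threshold,
                 mediator = m$spec$mediator, outcome = m$spec$outcome,
                 nde = m$nde, nie = m$nie, total = m$total,
                 proportion_mediated = m$proportion_mediated,
                 nde_lo = m$ci_nde[1], nde_hi = m$ci_nde[2],
                 nie_lo = m$ci_nie[1], nie_hi = m$ci_nie[2],
                 n = m$n, n_boot = m$n_boot, seed = m$seed)))
    wt(med_tab, "mediation.tsv")
    writeLines(render_report(report), file.path(cfg$out_dir, "report.md"))
  }
  class(report) <- "run_report"
  report
}

fmt_p <- function(p) {
  ifelse(p < 0.001, sprintf("%.2e", p), sprintf("%.3f", p))
}

demographic_block <- function(pheno, gi) {
  gi_v <- gi[pheno$sample_id]
  blocks <- list()
  tab_diag <- table(factor(pheno$diagnosis,
                           levels = c("SCZ", "BPD", "control")),
                    factor(gi_v, levels = c(1, 0)))
  blocks$diagnosis <- tryCatch(pearson_chi2(t(as.matrix(tab_diag))),
                               error = function(e) NULL)
  blocks$diagnosis_table <- tab_diag
  tab_sex <- table(pheno$sex, factor(gi_v, levels = c(1, 0)))
  blocks$sex <- tryCatch(pearson_chi2(as.matrix(tab_sex)),
                         error = function(e) NULL)
  tab_smoke <- table(pheno$smoker, factor(gi_v, levels = c(1, 0)))
  blocks$smoking <- tryCatch(pearson_chi2(as.matrix(tab_smoke)),
                             error = function(e) NULL)
  for (v in c("age", "panss_positive")) {
    x1 <- pheno[[v]][gi_v == 1]
    x0 <- pheno[[v]][gi_v == 0]
    x1 <- x1[!is.na(x1)]; x0 <- x0[!is.na(x0)]
    blocks[[v]] <- if (length(x1) >= 2 && length(x0) >= 2)
      two_sample_t(mean(x1), stats::sd(x1), length(x1),
                   mean(x0), stats::sd(x0), length(x0)) else NULL
  }
  blocks$gi_case_pct <- 100 * mean(pheno$diagnosis[gi_v == 1] != "control")
  blocks
}

#' Render a run report as markdown
#'
#' Formats the demographic comparison, association and mediation blocks at
#' conventional printed precision (statistics to 2 decimal places, P values
#' to 2-3 significant figures).
#'
#' @param report A \code{run_report} from \code{\link{run_pipeline}}.
#' @return Character vector of markdown lines.
#' @export
render_report <- function(report) {
  out <- c("# Pipeline run report", "",
           sprintf("Seed: %d", report$seed), "")
  t1 <- report$table1
  out <- c(out, "## Demographics (globally impaired vs non-impaired)", "")
  if (!is.null(t1)) {
    if (!is.null(t1$diagnosis))
      out <- c(out, sprintf("- Diagnosis: X2 = %.2f, P = %s",
                            t1$diagnosis$statistic, fmt_p(t1$diagnosis$p)))
    if (!is.null(t1$sex))
      out <- c(out, sprintf("- Sex: X2 = %.2f, P = %s",
                            t1$sex$statistic, fmt_p(t1$sex$p)))
    if (!is.null(t1$smoking))
      out <- c(out, sprintf("- Current smoker: X2 = %.2f, P = %s",
                            t1$smoking$statistic, fmt_p(t1$smoking$p)))
    if (!is.null(t1$age))
      out <- c(out, sprintf("- Age: t = %.2f, P = %s",
                            t1$age$statistic, fmt_p(t1$age$p)))
    if (!is.null(t1$panss_positive))
      out <- c(out, sprintf("- PANSS positive: t = %.2f, P = %s",
                            t1$panss_positive$statistic,
                            fmt_p(t1$panss_positive$p)))
    out <- c(out, sprintf("- Cases in impaired cluster: %.1f%%",
                          t1$gi_case_pct))
  }
  out <- c(out, "", "## PRS associations (Nagelkerke incremental R2)", "")
  a <- report$associations
  if (!is.null(a) && nrow(a)) {
    for (r in seq_len(nrow(a))) {
      stars <- if (a$q_value[r] < 0.05) "**"
               else if (a$wald_p[r] < 0.05) "*" else ""
      out <- c(out, sprintf(
        "- %s [%s] PT=%g: dR2 = %.2f%%, P = %s, q = %s %s",
        a$trait[r], a$subset[r], a$p_threshold[r],
        100 * a$nagelkerke_r2[r], fmt_p(a$wald_p[r]),
        fmt_p(a$q_value[r]), stars))
    }
  }
  out <- c(out, "", "## Mediation", "")
  if (length(report$mediation) == 0) {
    out <- c(out, "not run")
  } else {
    for (m in report$mediation) {
      out <- c(out, sprintf(
        paste0("- %s (PT=%g) -> %s -> %s: NDE = %.2f (%.2f, %.2f), ",
               "NIE = %.2f (%.2f, %.2f), total = %.2f, PM = %.1f%%, ",
               "n = %d"),
        m$spec$exposure, m$spec$p_threshold, m$spec$mediator,
        m$spec$outcome, m$nde, m$ci_nde[1], m$ci_nde[2],
        m$nie, m$ci_nie[1], m$ci_nie[2], m$total,
        100 * m$proportion_mediated, m$n))
    }
  }
  out
}
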