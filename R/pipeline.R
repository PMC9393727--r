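#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline. The defaults are the
#' thresholds of the study design this package models: DEGs at
#' `|log2FC| > 1` and `FDR < 0.05`; DEPs at linear `|FC| > 1.5` and
#' `q < 0.05`; differential-response screen at `|delta| > 1`; replicate
#' correlation flagged below 0.866; top 20 enriched terms. Overrides of any
#' default are echoed to the run log.
#'
#' @param data_dir Directory of input TSVs (as written by
#'   [write_dataset()]); `NULL` (default) simulates a dataset from `sim`.
#' @param sim A [sim_config()] used when `data_dir` is `NULL`.
#' @param control_genotype,treatment_genotype Genotype labels; the two
#'   within-genotype contrasts are `24h vs 0h` for each.
#' @param timepoints Baseline and treatment timepoint labels.
#' @param rna_lfc,rna_alpha RNA calling thresholds (default 1, 0.05).
#' @param protein_fc,protein_alpha Protein calling thresholds
#'   (default 1.5, 0.05).
#' @param delta_threshold Screen threshold on |delta| (default 1).
#' @param correlation_threshold Replicate QC threshold (default 0.866).
#' @param top_n Number of top enriched terms to report (default 20).
#' @param pseudocount RNA pseudocount (default 1).
#' @param protein_var_equal Student (TRUE, default) or Welch protein test.
#' @param pool Screen candidate pool, `"quadrant37"` or `"all"`.
#' @param seed Seed used when simulating.
#' @param outdir Output directory for artifacts and the run log.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(data_dir = NULL,
                            sim = sim_config(),
                            control_genotype = "WT",
                            treatment_genotype = "OX",
                            timepoints = c("0h", "24h"),
                            rna_lfc = 1, rna_alpha = 0.05,
                            protein_fc = 1.5, protein_alpha = 0.05,
                            delta_threshold = 1,
                            correlation_threshold = 0.866,
                            top_n = 20,
                            pseudocount = 1,
                            protein_var_equal = TRUE,
                            pool = c("quadrant37", "all"),
                            seed = 1L,
                            outdir = tempfile("dualomics_run")) {
  cfg <- list(
    data_dir = data_dir, sim = sim,
    control_genotype = control_genotype,
    treatment_genotype = treatment_genotype,
    timepoints = timepoints,
    rna_lfc = rna_lfc, rna_alpha = rna_alpha,
    protein_fc = protein_fc, protein_alpha = protein_alpha,
    delta_threshold = delta_threshold,
    correlation_threshold = correlation_threshold,
    top_n = top_n, pseudocount = pseudocount,
    protein_var_equal = protein_var_equal,
    pool = match.arg(pool), seed = as.integer(seed),
    outdir = outdir
  )
  defaults <- c(rna_lfc = 1, rna_alpha = 0.05, protein_fc = 1.5,
                protein_alpha = 0.05, delta_threshold = 1,
                correlation_threshold = 0.866, top_n = 20)
  cfg$overridden <- names(defaults)[
    vapply(names(defaults), function(nm) !identical(as.numeric(cfg[[nm]]),
                                                    unname(defaults[nm])),
           logical(1))
  ]
  structure(cfg, class = "pipeline_config")
}

## hash of the scientific configuration; output location excluded so the
## same analysis run into two directories carries the same provenance
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$outdir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' Executes every stage in order — simulate (or load) the dataset, replicate
#' QC, RNA and protein differential expression for the two within-genotype
#' contrasts, DEG/DEP Venn accounting, nine-quadrant association per
#' comparison, the differential-response screen, and term enrichment of the
#' screen hits — writing each stage's artifact as a TSV with a provenance
#' header (package version, configuration hash) and a run log. Given the
#' same seed the numeric outputs are identical across runs. Any stage
#' failure halts with the stage named.
#'
#' @param config A [pipeline_config()] object.
#' @return Invisibly, a list with all in-memory stage results plus
#'   `outdir` and `files`.
#' @export
run_all <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("config must be created by pipeline_config()")
  }
  if (!dir.exists(config$outdir)) dir.create(config$outdir, recursive = TRUE)
  log_path <- file.path(config$outdir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con))
  logmsg <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    writeLines(msg, log_con)
    message(msg)
  }
  version <- as.character(utils::packageVersion("dualomics"))
  hash <- config_hash(config)
  prov <- c(paste0("dualomics ", version), paste0("config ", hash))
  logmsg("dualomics ", version, ", config hash ", hash)
  if (length(config$overridden) > 0) {
    logmsg("threshold overrides: ", paste(config$overridden, collapse = ", "))
  }

  stage <- function(name, expr) {
    logmsg("stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  emit <- function(x, name, ...) {
    path <- file.path(config$outdir, name)
    write_table(x, path, header_lines = prov, ...)
    path
  }
  files <- character(0)

  data <- stage("data", {
    if (is.null(config$data_dir)) {
      simulate_experiment(config$sim)
    } else {
      read_dataset(config$data_dir)
    }
  })

  tp0 <- config$timepoints[1]; tp1 <- config$timepoints[2]
  grp <- function(geno, tp) paste(geno, tp, sep = "_")
  ctrl <- config$control_genotype; trt <- config$treatment_genotype

  qc <- stage("replicate_qc", {
    fpkm_mat <- fpkm(data$counts, data$lengths)
    rbind(
      cbind(layer = "rna",
            replicate_correlation(log2(fpkm_mat + 1), data$samples,
                                  threshold = config$correlation_threshold)),
      cbind(layer = "protein",
            replicate_correlation(log2(data$protein), data$samples,
                                  threshold = config$correlation_threshold))
    )
  })
  files["replicate_qc"] <- emit(qc, "replicate_qc.tsv")

  rna_ctrl <- stage("rna_de_control", de_test_rna(
    data$counts, data$samples, c(grp(ctrl, tp1), grp(ctrl, tp0)),
    pseudocount = config$pseudocount, lfc_threshold = config$rna_lfc,
    alpha = config$rna_alpha))
  rna_trt <- stage("rna_de_treatment", de_test_rna(
    data$counts, data$samples, c(grp(trt, tp1), grp(trt, tp0)),
    pseudocount = config$pseudocount, lfc_threshold = config$rna_lfc,
    alpha = config$rna_alpha))
  prot_ctrl <- stage("protein_de_control", de_test_protein(
    data$protein, data$samples, c(grp(ctrl, tp1), grp(ctrl, tp0)),
    fc_threshold = config$protein_fc, alpha = config$protein_alpha,
    var_equal = config$protein_var_equal))
  prot_trt <- stage("protein_de_treatment", de_test_protein(
    data$protein, data$samples, c(grp(trt, tp1), grp(trt, tp0)),
    fc_threshold = config$protein_fc, alpha = config$protein_alpha,
    var_equal = config$protein_var_equal))
  files["rna_de_control"] <- emit(rna_ctrl, "rna_de_control.tsv")
  files["rna_de_treatment"] <- emit(rna_trt, "rna_de_treatment.tsv")
  files["protein_de_control"] <- emit(prot_ctrl, "protein_de_control.tsv")
  files["protein_de_treatment"] <- emit(prot_trt, "protein_de_treatment.tsv")

  venn <- stage("venn", {
    deg <- venn_overlap(rna_ctrl$feature[rna_ctrl$status != "ns"],
                        rna_trt$feature[rna_trt$status != "ns"])
    dep <- venn_overlap(
      prot_ctrl$feature[prot_ctrl$status %in% c("up", "down")],
      prot_trt$feature[prot_trt$status %in% c("up", "down")])
    data.frame(layer = c("rna", "protein"),
               n_control = c(deg$n_a, dep$n_a),
               n_treatment = c(deg$n_b, dep$n_b),
               n_common = c(deg$n_common, dep$n_common),
               pct_common = c(deg$pct_common, dep$pct_common))
  })
  files["venn"] <- emit(venn, "venn_summary.tsv")

  assoc_ctrl <- stage("associate_control", associate_omics(
    rna_ctrl, prot_ctrl, data$gene2protein,
    rna_thr = config$rna_lfc, prot_thr = log2(config$protein_fc)))
  assoc_trt <- stage("associate_treatment", associate_omics(
    rna_trt, prot_trt, data$gene2protein,
    rna_thr = config$rna_lfc, prot_thr = log2(config$protein_fc)))
  files["association_control"] <- emit(assoc_ctrl$records,
                                       "association_control.tsv")
  files["association_treatment"] <- emit(assoc_trt$records,
                                         "association_treatment.tsv")
  files["quadrant_counts"] <- emit(
    rbind(cbind(comparison = "control", assoc_ctrl$counts),
          cbind(comparison = "treatment", assoc_trt$counts)),
    "quadrant_counts.tsv")

  screen <- stage("screen", build_screen_report(
    rna_ctrl, rna_trt, prot_ctrl, prot_trt, data$gene2protein,
    pool = config$pool, assoc_control = assoc_ctrl,
    assoc_treatment = assoc_trt,
    delta_threshold = config$delta_threshold))
  passing <- screen_genes(screen, config$delta_threshold)
  files["screen"] <- emit(screen, "screen_report.tsv")
  files["screen_passing"] <- emit(passing, "screen_passing.tsv")

  enrichment <- stage("enrichment", {
    if (nrow(passing) == 0 || is.null(data$annotation)) {
      NULL
    } else {
      background <- rna_ctrl$feature
      direction <- stats::setNames(
        ifelse(!is.na(passing$delta_rna) & passing$delta_rna >= 0,
               "up", "down"),
        passing$gene)
      enrich(passing$gene, background, data$annotation,
             direction = direction)
    }
  })
  if (!is.null(enrichment)) {
    files["enrichment"] <- emit(enrichment, "enrichment.tsv")
    files["top_terms"] <- emit(top_terms(enrichment, config$top_n),
                               "top_terms.tsv")
  }
  logmsg("done: ", length(files), " artifacts in ", config$outdir)

  invisible(list(
    data = data, qc = qc,
    rna_control = rna_ctrl, rna_treatment = rna_trt,
    protein_control = prot_ctrl, protein_treatment = prot_trt,
    venn = venn, association_control = assoc_ctrl,
    association_treatment = assoc_trt,
    screen = screen, screen_passing = passing,
    enrichment = enrichment,
    outdir = config$outdir, files = files
  ))
}
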