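#' Cross-genotype differential-response statistic
#'
#' For one omics layer, the log2 ratio between the treatment-induced fold
#' change in the genotype of interest and in the control genotype:
#' `delta = log2(fc_treatment / fc_control)`. A gene responding identically
#' in both genotypes has `delta = 0`; `|delta| > 1` means the responses
#' differ by more than two-fold. Missing or non-positive fold changes give
#' `NA` (recorded, not an error), so the screen can fall back to the other
#' omics layer.
#'
#' @param fc_control Fold change (treatment/baseline) in the control
#'   genotype, linear scale.
#' @param fc_treatment Fold change in the genotype of interest.
#' @return Numeric vector of deltas (`NA` where undefined).
#' @examples
#' differential_response(2.91, 6.27) # 1.107 -> reported as 1.11
#' @export
differential_response <- function(fc_control, fc_treatment) {
  out <- rep(NA_real_, length(fc_treatment))
  ok <- !is.na(fc_control) & !is.na(fc_treatment) &
    fc_control > 0 & fc_treatment > 0 &
    is.finite(fc_control) & is.finite(fc_treatment)
  out[ok] <- log2(fc_treatment[ok] / fc_control[ok])
  out
}

#' Build screen records from a fold-change table
#'
#' Takes a table with the four fold-change columns of the screen layout
#' (`fc1` = RNA treatment/baseline in the control genotype, `fc2` = same at
#' the genotype of interest, `fc3`/`fc4` the protein counterparts), computes
#' `delta_rna = log2(fc2/fc1)` and `delta_prot = log2(fc4/fc3)` and the pass
#' flags `|delta| > threshold` per layer (strict, on unrounded deltas;
#' a missing layer simply cannot contribute a pass).
#'
#' @param fc_table Data frame with columns `gene` (or `gene_id`), `fc1`,
#'   `fc2`, `fc3`, `fc4`; additional columns are carried through.
#' @param delta_threshold Screen threshold on |delta| (default 1).
#' @return Data frame of screen records: the inputs plus `delta_rna`,
#'   `delta_prot`, `pass_rna`, `pass_prot`, `pass_any`.
#' @export
screen_records <- function(fc_table, delta_threshold = 1) {
  df <- as.data.frame(fc_table, stringsAsFactors = FALSE)
  if ("gene_id" %in% names(df) && !"gene" %in% names(df)) {
    names(df)[names(df) == "gene_id"] <- "gene"
  }
  need <- c("gene", "fc1", "fc2", "fc3", "fc4")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("fc_table lacks column(s): ", paste(missing, collapse = ", "))
  }
  df$delta_rna <- differential_response(df$fc1, df$fc2)
  df$delta_prot <- differential_response(df$fc3, df$fc4)
  df$pass_rna <- !is.na(df$delta_rna) & abs(df$delta_rna) > delta_threshold
  df$pass_prot <- !is.na(df$delta_prot) & abs(df$delta_prot) > delta_threshold
  df$pass_any <- df$pass_rna | df$pass_prot
  df
}

#' Filter screen records to the passing subset
#'
#' Re-evaluates the pass flags at the given threshold and returns the
#' records passing at the RNA or protein level, ordered by gene ID.
#'
#' @param records Data frame from [screen_records()] or
#'   [build_screen_report()].
#' @param delta_threshold Screen threshold on |delta| (default 1).
#' @return The passing subset, stably ordered by gene ID.
#' @export
screen_genes <- function(records, delta_threshold = 1) {
  pass_rna <- !is.na(records$delta_rna) &
    abs(records$delta_rna) > delta_threshold
  pass_prot <- !is.na(records$delta_prot) &
    abs(records$delta_prot) > delta_threshold
  out <- records[pass_rna | pass_prot, , drop = FALSE]
  out$pass_rna <- pass_rna[pass_rna | pass_prot]
  out$pass_prot <- pass_prot[pass_rna | pass_prot]
  out$pass_any <- rep(TRUE, nrow(out))
  out[order(out$gene), , drop = FALSE]
}

#' Assemble the differential-response screen report from pipeline results
#'
#' Combines the four per-contrast results (RNA and protein, each
#' treatment-vs-baseline in the control genotype and in the genotype of
#' interest) into one record per candidate gene, with the four fold changes,
#' the per-layer deltas and pass flags. The candidate pool is either the
#' union, over the two comparisons, of genes falling in the concordant
#' quadrants 3 and 7 with full significance in both layers (`"quadrant37"`,
#' the default) or every gene measured at the RNA level (`"all"`).
#'
#' @param rna_control,rna_treatment RNA results from [de_test_rna()] for the
#'   control genotype and the genotype of interest (same gene universe).
#' @param prot_control,prot_treatment Protein results from
#'   [de_test_protein()] (same protein universe).
#' @param gene2protein Gene-to-protein mapping data frame.
#' @param pool Candidate-pool mode, `"quadrant37"` or `"all"`.
#' @param assoc_control,assoc_treatment [associate_omics()] results for the
#'   two comparisons; required for the `"quadrant37"` pool and computed from
#'   the supplied results when omitted.
#' @param delta_threshold Screen threshold on |delta| (default 1).
#' @param metadata Optional data frame with a `gene` column (e.g. gene name,
#'   description) merged onto the report.
#' @return Data frame of screen records (see [screen_records()]), ordered by
#'   gene ID.
#' @export
build_screen_report <- function(rna_control, rna_treatment,
                                prot_control, prot_treatment,
                                gene2protein,
                                pool = c("quadrant37", "all"),
                                assoc_control = NULL, assoc_treatment = NULL,
                                delta_threshold = 1, metadata = NULL) {
  pool <- match.arg(pool)
  if (!setequal(rna_control$feature, rna_treatment$feature)) {
    stop("RNA results cover different gene universes")
  }
  if (!setequal(prot_control$feature, prot_treatment$feature)) {
    stop("protein results cover different protein universes")
  }
  if (pool == "quadrant37") {
    if (is.null(assoc_control)) {
      assoc_control <- associate_omics(rna_control, prot_control, gene2protein)
    }
    if (is.null(assoc_treatment)) {
      assoc_treatment <- associate_omics(rna_treatment, prot_treatment,
                                         gene2protein)
    }
    pick <- function(a) {
      r <- a$records
      r$gene[r$quadrant %in% c(3L, 7L) &
               r$rna_significant & r$prot_significant]
    }
    candidates <- sort(union(pick(assoc_control), pick(assoc_treatment)))
  } else {
    candidates <- sort(rna_control$feature)
  }
  if (length(candidates) == 0) {
    empty <- screen_records(data.frame(gene = character(0), fc1 = numeric(0),
                                       fc2 = numeric(0), fc3 = numeric(0),
                                       fc4 = numeric(0)), delta_threshold)
    return(empty)
  }
  map <- unique(gene2protein[, c("gene", "protein")])
  prot_of <- stats::setNames(map$protein, map$gene)
  fc_of <- function(res, ids) res$fc[match(ids, res$feature)]
  unquant <- function(res, ids) {
    st <- res$status[match(ids, res$feature)]
    is.na(st) | st == "unquantified"
  }
  prot_ids <- unname(prot_of[candidates])
  fc3 <- fc_of(prot_control, prot_ids)
  fc4 <- fc_of(prot_treatment, prot_ids)
  fc3[unquant(prot_control, prot_ids)] <- NA_real_
  fc4[unquant(prot_treatment, prot_ids)] <- NA_real_
  tab <- data.frame(
    gene = candidates,
    fc1 = fc_of(rna_control, candidates),
    fc2 = fc_of(rna_treatment, candidates),
    fc3 = fc3, fc4 = fc4,
    stringsAsFactors = FALSE
  )
  if (!is.null(metadata)) {
    tab <- merge(tab, metadata, by = "gene", all.x = TRUE, sort = FALSE)
  }
  out <- screen_records(tab, delta_threshold)
  out[order(out$gene), , drop = FALSE]
}

#' Published 36-gene fold-change table
#'
#' Loads the fold-change table bundled with the package: 36 genes reported
#' in a published salt-stress experiment comparing wild-type and
#' ZmPDI-overexpressing *Zoysia matrella*, with RNA (`fc1`, `fc2`) and
#' protein (`fc3`, `fc4`) fold changes for the 24h-vs-0h response in each
#' genotype, the published rounded delta columns (`printed_delta_rna`,
#' `printed_delta_prot`), gene names, descriptions, and a `highlighted`
#' flag for the five genes singled out in that study (TUBB2, PXG4, PLDa2,
#' PFK4, 4CL1). Cells the source printed as "\\" (no measurement) are `NA`;
#' one gene lacks an RNA fold change and can only pass the screen at the
#' protein level.
#'
#' @return Data frame with 36 rows.
#' @examples
#' tab <- zmpdi_screen()
#' nrow(screen_genes(screen_records(tab)))
#' @export
zmpdi_screen <- function() {
  path <- system.file("extdata", "zmpdi_salt_screen.tsv",
                      package = "dualomics", mustWork = TRUE)
  read_fc_table(path)
}
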