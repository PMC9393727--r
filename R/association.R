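#' Nine-quadrant assignment
#'
#' Classifies genes by joint transcript (x axis) and protein (y axis) log2
#' fold change into a 3x3 grid. Columns are left (`rna < -rna_thr`), middle,
#' right (`rna > rna_thr`); rows are top (`prot > prot_thr`), middle, bottom
#' (`prot < -prot_thr`). Cells are numbered row-major from the top left:
#'
#' ```
#'           RNA down   RNA ns   RNA up
#' prot up       1         2        3
#' prot ns       4         5        6
#' prot down     7         8        9
#' ```
#'
#' so quadrant 3 is concordant-up, 7 is concordant-down and 5 is unchanged
#' in both layers. Inequalities are strict: a value exactly at a threshold
#' falls to the middle band.
#'
#' @param rna_log2fc,prot_log2fc Numeric vectors of log2 fold changes
#'   (no missing values; callers filter genes lacking a measurement).
#' @param rna_thr RNA threshold on |log2FC| (default 1).
#' @param prot_thr Protein threshold on |log2FC| (default `log2(1.5)`).
#' @return Integer vector of quadrants in 1..9.
#' @examples
#' assign_quadrant(c(2, -2, 0.1), c(1, -1, 0.05)) # 3 7 5
#' @export
assign_quadrant <- function(rna_log2fc, prot_log2fc,
                            rna_thr = 1, prot_thr = log2(1.5)) {
  if (length(rna_log2fc) != length(prot_log2fc)) {
    stop("rna_log2fc and prot_log2fc must have equal length")
  }
  if (anyNA(rna_log2fc) || anyNA(prot_log2fc)) {
    stop("undefined log2 fold change: filter missing values before assignment")
  }
  col <- ifelse(rna_log2fc < -rna_thr, 1L, ifelse(rna_log2fc > rna_thr, 3L, 2L))
  row <- ifelse(prot_log2fc > prot_thr, 1L,
                ifelse(prot_log2fc < -prot_thr, 3L, 2L))
  (row - 1L) * 3L + col
}

#' Cross RNA and protein results for one contrast
#'
#' Matches genes to proteins, keeps genes quantified in both layers, assigns
#' each a quadrant from its two log2 fold changes, and tallies per-quadrant
#' totals split by significance (a gene is counted as significant when it
#' meets the full DEG criteria at the RNA level AND the full DEP criteria at
#' the protein level, i.e. both statuses are `up` or `down`). Genes without
#' a protein measurement are excluded rather than forced into quadrant 5.
#'
#' @param rna_results RNA results from [de_test_rna()].
#' @param prot_results Protein results from [de_test_protein()].
#' @param gene2protein Data frame with columns `gene` and `protein`.
#'   Duplicated rows are dropped with a warning; a gene mapped to several
#'   proteins (or vice versa) is an error.
#' @param rna_thr,prot_thr Quadrant thresholds, as in [assign_quadrant()].
#' @return List of class `"omics_association"`: `records` (one row per
#'   matched gene: `gene`, `protein`, `rna_log2fc`, `rna_significant`,
#'   `prot_log2fc`, `prot_significant`, `quadrant`) and `counts` (per
#'   quadrant: `n`, `n_significant`).
#' @export
associate_omics <- function(rna_results, prot_results, gene2protein,
                            rna_thr = 1, prot_thr = log2(1.5)) {
  map <- gene2protein[, c("gene", "protein")]
  if (anyDuplicated(map)) {
    warning("dropping duplicated gene-protein mapping rows")
    map <- unique(map)
  }
  if (anyDuplicated(map$gene) || anyDuplicated(map$protein)) {
    stop("conflicting gene-protein mappings: mapping must be one-to-one")
  }
  rna <- rna_results[match(map$gene, rna_results$feature), ]
  prot <- prot_results[match(map$protein, prot_results$feature), ]
  keep <- !is.na(rna$feature) & !is.na(prot$feature) &
    !is.na(rna$log2fc) & !is.na(prot$log2fc) &
    prot$status != "unquantified"
  records <- data.frame(
    gene = map$gene[keep],
    protein = map$protein[keep],
    rna_log2fc = rna$log2fc[keep],
    rna_significant = rna$status[keep] != "ns",
    prot_log2fc = prot$log2fc[keep],
    prot_significant = prot$status[keep] != "ns",
    stringsAsFactors = FALSE
  )
  records$quadrant <- if (nrow(records) > 0) {
    assign_quadrant(records$rna_log2fc, records$prot_log2fc,
                    rna_thr = rna_thr, prot_thr = prot_thr)
  } else integer(0)
  sig <- records$rna_significant & records$prot_significant
  counts <- data.frame(
    quadrant = 1:9,
    n = as.integer(table(factor(records$quadrant, levels = 1:9))),
    n_significant = as.integer(table(factor(records$quadrant[sig],
                                            levels = 1:9)))
  )
  structure(list(records = records, counts = counts),
            class = "omics_association")
}

#' Overlap summary of two feature sets
#'
#' @param set_a,set_b Character vectors of feature IDs (duplicates ignored).
#' @return List with `n_a`, `n_b`, `n_common` and `pct_common`, the shared
#'   percentage of the union `100 * |A intersect B| / |A union B|` rounded
#'   to 2 decimals.
#' @examples
#' venn_overlap(letters[1:4], letters[3:6])$pct_common # 33.33
#' @export
venn_overlap <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  n_common <- length(intersect(a, b))
  n_union <- length(a) + length(b) - n_common
  list(
    n_a = length(a), n_b = length(b), n_common = n_common,
    pct_common = if (n_union == 0) NA_real_ else
      round(100 * n_common / n_union, 2)
  )
}

#' Overlap percentage from printed set sizes
#'
#' The same shared-percentage arithmetic as [venn_overlap()] for the case
#' where only the set sizes and intersection size are known (e.g. figures in
#' a publication).
#'
#' @param n_a,n_b,n_common Set sizes and intersection size.
#' @return Shared percentage of the union, 2 decimals.
#' @export
venn_pct <- function(n_a, n_b, n_common) {
  if (n_common > min(n_a, n_b)) stop("intersection larger than a set")
  round(100 * n_common / (n_a + n_b - n_common), 2)
}

#' Nine-quadrant scatter plot
#'
#' @param assoc An `"omics_association"` object.
#' @param rna_thr,prot_thr Threshold lines to draw.
#' @return A ggplot object.
#' @export
plot_quadrants <- function(assoc, rna_thr = 1, prot_thr = log2(1.5)) {
  rec <- assoc$records
  rec$significant <- rec$rna_significant & rec$prot_significant
  ggplot2::ggplot(rec, ggplot2::aes(x = rna_log2fc, y = prot_log2fc,
                                    colour = significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-rna_thr, rna_thr), linetype = 2) +
    ggplot2::geom_hline(yintercept = c(-prot_thr, prot_thr), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "RNA log2 fold change", y = "protein log2 fold change",
                  colour = "significant in both") +
    ggplot2::theme_bw()
}
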