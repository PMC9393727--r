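#' Protein differential-abundance test
#'
#' Per-protein two-sample t-test (Student's equal-variance by default,
#' Welch optionally) on log2 intensities, with the fold change computed as
#' the ratio of linear-scale group means. The adjusted value ("q") is
#' Benjamini-Hochberg. Proteins are called `up` when `FC > fc_threshold`
#' and `q < alpha`, `down` when `FC < 1/fc_threshold` and `q < alpha`
#' (defaults 1.5 and 0.05, strict comparisons). A protein with fewer than
#' two quantified (non-missing) values in either group is flagged
#' `unquantified` and excluded from testing and adjustment.
#'
#' @param intensities Proteins x samples intensity matrix; missing values as
#'   `NA`, quantified values must be positive.
#' @param samples Sample sheet with columns `sample` and `group`.
#' @param contrast `c(treatment_group, control_group)`.
#' @param fc_threshold Linear fold-change threshold (default 1.5).
#' @param alpha Adjusted-value threshold (default 0.05).
#' @param var_equal `TRUE` (default) for Student's pooled-variance test,
#'   `FALSE` for Welch.
#' @return Data frame with one row per protein: `feature`, `fc`, `log2fc`,
#'   `p`, `q`, `status` (one of `up`, `down`, `ns`, `unquantified`).
#' @export
de_test_protein <- function(intensities, samples, contrast,
                            fc_threshold = 1.5, alpha = 0.05,
                            var_equal = TRUE) {
  intensities <- as.matrix(intensities)
  if (any(intensities <= 0, na.rm = TRUE)) {
    stop("intensities must be positive where quantified")
  }
  grp <- resolve_contrast(samples, contrast)
  if (length(grp$b) < 2 || length(grp$a) < 2) {
    stop("each contrast group needs at least 2 replicates")
  }
  B <- intensities[, grp$b, drop = FALSE]
  A <- intensities[, grp$a, drop = FALSE]
  ok <- rowSums(!is.na(B)) >= 2 & rowSums(!is.na(A)) >= 2

  n <- nrow(intensities)
  fc <- log2fc <- p <- q <- rep(NA_real_, n)
  status <- rep("unquantified", n)

  if (any(ok)) {
    Bq <- B[ok, , drop = FALSE]
    Aq <- A[ok, , drop = FALSE]
    mB <- rowMeans(Bq, na.rm = TRUE)
    mA <- rowMeans(Aq, na.rm = TRUE)
    fc[ok] <- mB / mA
    log2fc[ok] <- log2(fc[ok])
    if (anyNA(Bq) || anyNA(Aq)) {
      ## uneven quantification: fall back to per-row tests on observed values
      pv <- vapply(seq_len(nrow(Bq)), function(i) {
        x <- Bq[i, !is.na(Bq[i, ])]
        y <- Aq[i, !is.na(Aq[i, ])]
        res <- tryCatch(
          stats::t.test(log2(x), log2(y), var.equal = var_equal)$p.value,
          error = function(e) if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
        )
        res
      }, numeric(1))
      p[ok] <- pv
    } else {
      p[ok] <- row_t_test(log2(Bq), log2(Aq), var_equal = var_equal)$p
    }
    q[ok] <- bh_adjust(p[ok])
    st <- rep("ns", sum(ok))
    sig <- q[ok] < alpha
    st[sig & fc[ok] > fc_threshold] <- "up"
    st[sig & fc[ok] < 1 / fc_threshold] <- "down"
    status[ok] <- st
  }

  data.frame(
    feature = rownames(intensities), fc = fc, log2fc = log2fc,
    p = p, q = q, status = status,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Peptide-support summary of a proteome
#'
#' Counts unique peptides and proteins in a peptide-to-protein mapping and
#' the share of proteins supported by more than one distinct peptide.
#' Duplicated mapping rows and row order do not affect the result.
#'
#' @param peptide2protein Data frame with columns `peptide` and `protein`.
#' @return List with `n_peptides`, `n_proteins`, `n_multi_peptide` and
#'   `pct_multi_peptide` (percentage, 2 decimals).
#' @examples
#' m <- data.frame(peptide = c("a", "b", "c"), protein = c("P1", "P1", "P2"))
#' summarize_peptide_support(m)$pct_multi_peptide # 50
#' @export
summarize_peptide_support <- function(peptide2protein) {
  if (nrow(peptide2protein) == 0) stop("peptide-to-protein mapping is empty")
  m <- unique(peptide2protein[, c("peptide", "protein")])
  per_protein <- table(m$protein)
  n_proteins <- length(per_protein)
  n_multi <- sum(per_protein > 1)
  list(
    n_peptides = length(unique(m$peptide)),
    n_proteins = n_proteins,
    n_multi_peptide = n_multi,
    pct_multi_peptide = round(100 * n_multi / n_proteins, 2)
  )
}

#' Annotation coverage across databases
#'
#' Given per-protein boolean annotation flags (one column per database),
#' reports how many proteins are annotated in at least one database.
#'
#' @param flags Logical matrix or data frame, proteins x databases.
#' @return List with `n_proteins`, `n_annotated` and `pct_annotated`
#'   (percentage, 2 decimals).
#' @export
annotation_coverage <- function(flags) {
  flags <- as.matrix(flags)
  if (!is.logical(flags)) stop("flags must be logical")
  n <- nrow(flags)
  if (n == 0) stop("no proteins supplied")
  n_annot <- sum(rowSums(flags, na.rm = TRUE) > 0)
  list(
    n_proteins = n,
    n_annotated = n_annot,
    pct_annotated = round(100 * n_annot / n, 2)
  )
}
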