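#' FPKM quantification
#'
#' Fragments per kilobase of transcript per million mapped reads:
#' `FPKM[g, s] = counts[g, s] * 1e9 / (lengths[g] * mapped_totals[s])`.
#'
#' @param counts Genes x samples count matrix.
#' @param lengths Per-gene transcript lengths in bp (recycled by position, or
#'   matched by name when named).
#' @param mapped_totals Per-sample mapped-read totals; defaults to the column
#'   sums of `counts`.
#' @return Matrix of FPKM values with the dimnames of `counts`.
#' @examples
#' fpkm(matrix(10, 1, 1), lengths = 1000, mapped_totals = 1e6) # 10
#' @export
fpkm <- function(counts, lengths, mapped_totals = colSums(counts)) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
    lengths <- lengths[rownames(counts)]
  }
  if (length(lengths) != nrow(counts)) {
    stop("lengths must have one entry per gene")
  }
  if (length(mapped_totals) != ncol(counts)) {
    stop("mapped_totals must have one entry per sample")
  }
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  if (any(mapped_totals <= 0)) stop("mapped totals must be positive")
  counts * 1e9 / outer(as.numeric(lengths), as.numeric(mapped_totals))
}

#' Counts per million
#'
#' Depth normalisation used by the differential-expression engine (FPKM is
#' kept for reporting; testing uses CPM so gene length cancels out of the
#' within-gene contrast).
#'
#' @param counts Genes x samples count matrix.
#' @return CPM matrix.
#' @export
cpm_normalize <- function(counts) {
  counts <- as.matrix(counts)
  totals <- colSums(counts)
  if (any(totals <= 0)) stop("every sample must have a positive total count")
  sweep(counts, 2, totals, "/") * 1e6
}

#' Within-group replicate correlation
#'
#' Computes all pairwise Pearson (or Spearman) correlations between replicate
#' columns within each sample group and reports the per-group minimum,
#' flagging groups whose minimum falls below a repeatability threshold. A
#' constant replicate (zero variance) makes the correlation undefined; such
#' pairs are reported as `NA` and flag the group rather than propagating.
#'
#' @param mat Features x samples numeric matrix (typically log-scale
#'   expression).
#' @param samples Sample sheet with columns `sample` and `group`.
#' @param threshold Minimum acceptable within-group correlation
#'   (default 0.866).
#' @param method Correlation method, `"pearson"` or `"spearman"`.
#' @return Data frame with one row per group: `group`, `n_pairs`, `min_r`,
#'   `ok` (`min_r` defined and above threshold). The per-pair correlations
#'   are attached as attribute `"pairs"`.
#' @export
replicate_correlation <- function(mat, samples, threshold = 0.866,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  samples <- samples[samples$sample %in% colnames(mat), , drop = FALSE]
  groups <- unique(samples$group)
  pair_rows <- list()
  out <- data.frame(group = groups, n_pairs = 0L, min_r = NA_real_,
                    ok = NA, stringsAsFactors = FALSE)
  for (gi in seq_along(groups)) {
    cols <- samples$sample[samples$group == groups[gi]]
    if (length(cols) < 2) {
      stop("group '", groups[gi], "' has fewer than 2 replicates")
    }
    cmb <- utils::combn(cols, 2)
    r <- numeric(ncol(cmb))
    for (k in seq_len(ncol(cmb))) {
      x <- mat[, cmb[1, k]]
      y <- mat[, cmb[2, k]]
      r[k] <- if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        NA_real_
      } else {
        stats::cor(x, y, method = method)
      }
    }
    pair_rows[[gi]] <- data.frame(
      group = groups[gi], sample_a = cmb[1, ], sample_b = cmb[2, ],
      r = r, stringsAsFactors = FALSE
    )
    out$n_pairs[gi] <- length(r)
    out$min_r[gi] <- if (anyNA(r)) NA_real_ else min(r)
    out$ok[gi] <- !anyNA(r) && min(r) >= threshold
  }
  attr(out, "pairs") <- do.call(rbind, pair_rows)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (wraps [stats::p.adjust()] after validating the input range).
#'
#' @param p Numeric vector of p-values in \[0, 1\] (`NA` allowed and
#'   propagated).
#' @return Adjusted values in \[0, 1\], same order as the input.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    stop("p-values outside [0, 1] at positions: ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }
  stats::p.adjust(p, method = "BH")
}

## Vectorised two-sample t statistics, one test per row.
## var_equal = FALSE -> Welch (Satterthwaite df); TRUE -> Student pooled.
## Degenerate rows (both groups zero-variance) get p = 1 when the means are
## equal (no evidence) and p = 0 when they differ (perfect separation).
row_t_test <- function(B, A, var_equal = FALSE) {
  B <- as.matrix(B); A <- as.matrix(A)
  nB <- ncol(B); nA <- ncol(A)
  if (nB < 2 || nA < 2) stop("each group needs at least 2 samples")
  mB <- rowMeans(B); mA <- rowMeans(A)
  vB <- rowSums((B - mB)^2) / (nB - 1)
  vA <- rowSums((A - mA)^2) / (nA - 1)
  if (var_equal) {
    sp2 <- ((nB - 1) * vB + (nA - 1) * vA) / (nB + nA - 2)
    se2 <- sp2 * (1 / nB + 1 / nA)
    df <- rep(nB + nA - 2, length(mB))
  } else {
    se2 <- vB / nB + vA / nA
    df <- se2^2 / ((vB / nB)^2 / (nB - 1) + (vA / nA)^2 / (nA - 1))
  }
  tstat <- (mB - mA) / sqrt(se2)
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    p[degenerate] <- ifelse(mB[degenerate] == mA[degenerate], 1, 0)
    tstat[degenerate] <- ifelse(mB[degenerate] == mA[degenerate], 0, Inf)
    df[degenerate] <- NA_real_
  }
  list(statistic = tstat, df = df, p = p, mean_b = mB, mean_a = mA)
}

#' Differential-expression status call
#'
#' Applies the fold-change and adjusted-value thresholds: `up` when
#' `log2fc > lfc_threshold` and `adjusted < alpha`, `down` symmetrically,
#' otherwise `ns`. All comparisons are strict, so values exactly at a
#' threshold are not called.
#'
#' @param log2fc Log2 fold changes.
#' @param adjusted Adjusted p-values (FDR/q).
#' @param lfc_threshold Absolute log2 fold-change threshold (default 1).
#' @param alpha Adjusted-value threshold (default 0.05).
#' @return Character vector in `{"up", "down", "ns"}`.
#' @export
de_status <- function(log2fc, adjusted, lfc_threshold = 1, alpha = 0.05) {
  status <- rep("ns", length(log2fc))
  sig <- !is.na(adjusted) & adjusted < alpha & !is.na(log2fc)
  status[sig & log2fc > lfc_threshold] <- "up"
  status[sig & log2fc < -lfc_threshold] <- "down"
  status
}

resolve_contrast <- function(samples, contrast) {
  if (length(contrast) != 2) {
    stop("contrast must name two groups: c(treatment, control)")
  }
  missing <- setdiff(contrast, samples$group)
  if (length(missing) > 0) {
    stop("unknown sample group(s): ", paste(missing, collapse = ", "))
  }
  list(b = samples$sample[samples$group == contrast[1]],
       a = samples$sample[samples$group == contrast[2]])
}

#' RNA differential-expression test
#'
#' A deliberately simple, deterministic engine: counts are depth-normalised
#' to CPM, a pseudocount is added, and a per-gene Welch t-test is run on the
#' log2 values. Fold change is the ratio of group means of normalised counts
#' (plus pseudocount), the FDR is Benjamini-Hochberg, and genes are called
#' `up`/`down` with strict `|log2FC| > lfc_threshold` and
#' `FDR < alpha` (defaults 1 and 0.05).
#'
#' @param counts Genes x samples count matrix.
#' @param samples Sample sheet with columns `sample` and `group`.
#' @param contrast Character vector `c(treatment_group, control_group)`; fold
#'   changes are treatment over control.
#' @param pseudocount Added to normalised values before ratios and logs so
#'   zero-count genes have defined fold changes (default 1).
#' @param lfc_threshold,alpha Calling thresholds (defaults 1 and 0.05).
#' @param normalize `"cpm"` (default) or `"none"` to test the matrix as
#'   given.
#' @return Data frame with one row per gene: `feature`, `fc`, `log2fc`,
#'   `p`, `fdr`, `status`.
#' @export
de_test_rna <- function(counts, samples, contrast, pseudocount = 1,
                        lfc_threshold = 1, alpha = 0.05,
                        normalize = c("cpm", "none")) {
  normalize <- match.arg(normalize)
  counts <- as.matrix(counts)
  grp <- resolve_contrast(samples, contrast)
  if (length(grp$b) < 2 || length(grp$a) < 2) {
    stop("each contrast group needs at least 2 samples")
  }
  norm <- if (normalize == "cpm") cpm_normalize(counts) else counts
  B <- norm[, grp$b, drop = FALSE]
  A <- norm[, grp$a, drop = FALSE]
  tt <- row_t_test(log2(B + pseudocount), log2(A + pseudocount),
                   var_equal = FALSE)
  fc <- (rowMeans(B) + pseudocount) / (rowMeans(A) + pseudocount)
  log2fc <- log2(fc)
  fdr <- bh_adjust(tt$p)
  data.frame(
    feature = rownames(counts), fc = fc, log2fc = log2fc,
    p = tt$p, fdr = fdr,
    status = de_status(log2fc, fdr, lfc_threshold, alpha),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
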