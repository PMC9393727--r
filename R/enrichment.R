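#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`:
#' the chance of drawing at least `k` annotated features when `n` features
#' are drawn without replacement from a background of `N` features of which
#' `K` carry the annotation. Equivalent to a one-sided Fisher exact test.
#'
#' @param k Observed hits in the drawn set.
#' @param K Annotated features in the background.
#' @param n Size of the drawn set.
#' @param N Background size.
#' @return Upper-tail p-value in (0, 1]. Vectorised over all arguments.
#' @examples
#' hypergeometric_test(3, 5, 5, 20) # 1126/15504
#' @export
hypergeometric_test <- function(k, K, n, N) {
  bad <- k < 0 | K < 0 | n < 0 | N < 0 | k > K | k > n | K > N | n > N
  if (any(bad)) stop("invalid urn: need 0 <= k <= min(K, n), K <= N, n <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term over-representation for a feature set
#'
#' Tests each annotation term with at least one hit in `feature_set` for
#' over-representation against `background` using the one-sided
#' hypergeometric test, adjusts across terms with Benjamini-Hochberg and
#' flags significance at `adjusted <= alpha`. When direction labels are
#' supplied, each term also gets the directional z-score
#' `(n_up - n_down) / n` over its labelled set members, a value in
#' \[-1, 1\] (1 = all members upregulated).
#'
#' @param feature_set Character vector of features of interest; must be a
#'   subset of `background` (anything else would silently inflate p-values).
#' @param background Character vector: all features measured in the relevant
#'   omics layer.
#' @param annotation Data frame with columns `term` and `gene` (features
#'   outside the background are ignored).
#' @param direction Optional named character vector over (a subset of)
#'   `feature_set` with values `"up"`/`"down"`.
#' @param alpha Significance threshold on the adjusted value (default 0.05,
#'   non-strict).
#' @return Data frame with one row per term with >= 1 hit: `term`, `k`, `K`,
#'   `n`, `N`, `p`, `adjusted`, `z_score`, `significant`.
#' @export
enrich <- function(feature_set, background, annotation, direction = NULL,
                   alpha = 0.05) {
  feature_set <- unique(feature_set)
  background <- unique(background)
  outside <- setdiff(feature_set, background)
  if (length(outside) > 0) {
    stop("feature_set contains features missing from the background, e.g. ",
         outside[1])
  }
  ann <- annotation[annotation$gene %in% background, c("term", "gene")]
  ann <- unique(ann)
  if (nrow(ann) == 0) {
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      adjusted = numeric(0), z_score = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  }
  K_tab <- table(ann$term)
  hits <- ann[ann$gene %in% feature_set, ]
  k_tab <- table(hits$term)
  terms <- sort(names(k_tab))
  k <- as.integer(k_tab[terms])
  K <- as.integer(K_tab[terms])
  n <- length(feature_set)
  N <- length(background)
  p <- hypergeometric_test(k, K, n, N)
  adjusted <- bh_adjust(p)
  z <- rep(NA_real_, length(terms))
  if (!is.null(direction)) {
    for (i in seq_along(terms)) {
      members <- hits$gene[hits$term == terms[i]]
      d <- direction[members[members %in% names(direction)]]
      d <- d[!is.na(d)]
      if (length(d) > 0) {
        z[i] <- (sum(d == "up") - sum(d == "down")) / length(d)
      }
    }
  }
  data.frame(
    term = terms, k = k, K = K, n = n, N = N, p = p, adjusted = adjusted,
    z_score = z, significant = adjusted <= alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Top enriched terms
#'
#' Orders enrichment results by ascending adjusted value, breaking ties by
#' ascending raw p and then lexical term ID (deterministic), and returns the
#' first `n`.
#'
#' @param results Data frame from [enrich()].
#' @param n Number of terms to keep (default 20).
#' @return Ordered subset of `results`.
#' @export
top_terms <- function(results, n = 20) {
  ord <- order(results$adjusted, results$p, results$term)
  results[ord[seq_len(min(n, nrow(results)))], , drop = FALSE]
}

#' Bar plot of top enriched terms
#'
#' @param results Data frame from [enrich()].
#' @param n Number of terms to show (default 20).
#' @param alpha Significance line to mark (default 0.05).
#' @return A ggplot object.
#' @export
plot_top_terms <- function(results, n = 20, alpha = 0.05) {
  top <- top_terms(results, n)
  top$term <- factor(top$term, levels = rev(top$term))
  ggplot2::ggplot(top, ggplot2::aes(x = term, y = -log10(adjusted))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = -log10(alpha), colour = "goldenrod",
                        linewidth = 1) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "-log10 adjusted p") +
    ggplot2::theme_bw()
}
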