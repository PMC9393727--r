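#' Configuration for the paired-omics simulator
#'
#' Builds a validated configuration object for [simulate_experiment()]. The
#' defaults emulate a 2 genotype (WT, OX) x 2 timepoint (0h, 24h) x 3
#' replicate root stress experiment: negative-binomial RNA counts at roughly
#' one million reads per sample, log-normal protein intensities for about a
#' fifth of the genes, ~15% / ~18% of genes responding to treatment in the
#' two genotypes with a high overlap between the responding sets, and a small
#' planted set of genes whose treatment response differs between genotypes by
#' more than one log2 unit (the quantity the downstream screen recovers).
#'
#' @param n_genes Number of genes to simulate.
#' @param protein_fraction Fraction of genes with a measured protein, in
#'   (0, 1]. Genes without a protein emulate transcripts lacking DIA
#'   evidence.
#' @param replicates Biological replicates per genotype x timepoint group
#'   (minimum 2; differential tests are undefined below that).
#' @param nb_dispersion Negative-binomial dispersion of RNA counts
#'   (variance = mu + dispersion * mu^2).
#' @param protein_cv Coefficient of variation of the log-normal protein
#'   intensity noise.
#' @param frac_de_wt,frac_de_ox Fraction of genes differentially expressed at
#'   24h vs 0h in the wild-type and overexpression genotype respectively.
#' @param de_overlap Fraction of the OX-responsive gene set drawn from the
#'   WT-responsive set (controls the Venn overlap of the two DEG sets).
#' @param planted_log2fc_range Interval of absolute planted log2
#'   fold changes for responsive genes.
#' @param frac_diff_response Fraction of genes given a planted
#'   between-genotype response difference (|delta| > 1 by construction).
#' @param diff_response_delta_range Interval of absolute planted deltas for
#'   those genes; the lower bound exceeds the screen threshold of 1 by at
#'   least 0.5 so recovery is not boundary-dominated.
#' @param concordant_fraction,null_protein_fraction Among genes with a
#'   protein, fraction whose protein effect equals the RNA effect and
#'   fraction with no protein-level effect; the remainder get the opposite
#'   sign (populates the discordant quadrants).
#' @param n_terms Size of the synthetic annotation-term universe.
#' @param term_size_range Interval of genes per term.
#' @param frac_enriched_terms Fraction of terms planted onto the true
#'   differential-response genes.
#' @param planted_term_purity Fraction of a planted term's members drawn from
#'   the true differential-response set.
#' @param mean_peptides Mean number of extra peptides per protein beyond the
#'   first (Poisson); the default reproduces a realistic share of
#'   multi-peptide proteins.
#' @param library_size Target mean sequencing depth per sample, in counts.
#' @param seed Integer seed; fixing it fixes every simulated value.
#'
#' @return A list of class `"sim_config"`.
#' @seealso [simulate_experiment()]
#' @export
sim_config <- function(n_genes = 2000,
                       protein_fraction = 0.2,
                       replicates = 3,
                       nb_dispersion = 0.1,
                       protein_cv = 0.2,
                       frac_de_wt = 0.15,
                       frac_de_ox = 0.18,
                       de_overlap = 0.8,
                       planted_log2fc_range = c(1.5, 4),
                       frac_diff_response = 0.02,
                       diff_response_delta_range = c(1.5, 2.5),
                       concordant_fraction = 0.7,
                       null_protein_fraction = 0.15,
                       n_terms = 100,
                       term_size_range = c(10, 50),
                       frac_enriched_terms = 0.05,
                       planted_term_purity = 0.7,
                       mean_peptides = 1.33,
                       library_size = 1e6,
                       seed = 1L) {
  cfg <- list(
    n_genes = n_genes, protein_fraction = protein_fraction,
    replicates = replicates, nb_dispersion = nb_dispersion,
    protein_cv = protein_cv, frac_de_wt = frac_de_wt,
    frac_de_ox = frac_de_ox, de_overlap = de_overlap,
    planted_log2fc_range = planted_log2fc_range,
    frac_diff_response = frac_diff_response,
    diff_response_delta_range = diff_response_delta_range,
    concordant_fraction = concordant_fraction,
    null_protein_fraction = null_protein_fraction,
    n_terms = n_terms, term_size_range = term_size_range,
    frac_enriched_terms = frac_enriched_terms,
    planted_term_purity = planted_term_purity,
    mean_peptides = mean_peptides,
    library_size = library_size, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(is.numeric(cfg$n_genes), length(cfg$n_genes) == 1)
  if (cfg$n_genes < 1) stop("n_genes must be a positive integer")
  if (cfg$replicates < 2) {
    stop("replicates must be >= 2: differential tests are undefined with a single replicate")
  }
  fracs <- c(
    protein_fraction = cfg$protein_fraction,
    frac_de_wt = cfg$frac_de_wt, frac_de_ox = cfg$frac_de_ox,
    de_overlap = cfg$de_overlap,
    frac_diff_response = cfg$frac_diff_response,
    concordant_fraction = cfg$concordant_fraction,
    null_protein_fraction = cfg$null_protein_fraction,
    frac_enriched_terms = cfg$frac_enriched_terms,
    planted_term_purity = cfg$planted_term_purity
  )
  bad <- fracs < 0 | fracs > 1
  if (any(bad)) {
    stop("fractions must lie in [0, 1]: ", paste(names(fracs)[bad], collapse = ", "))
  }
  if (cfg$protein_fraction == 0) stop("protein_fraction must be in (0, 1]")
  if (cfg$concordant_fraction + cfg$null_protein_fraction > 1) {
    stop("concordant_fraction + null_protein_fraction must not exceed 1")
  }
  if (cfg$planted_log2fc_range[1] < 0 ||
      diff(cfg$planted_log2fc_range) < 0) {
    stop("planted_log2fc_range must be a non-decreasing interval with lower bound >= 0")
  }
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (cfg$protein_cv <= 0) stop("protein_cv must be positive")
  if (cfg$library_size <= 0) stop("library_size must be positive")
  if (cfg$n_terms < 1) stop("n_terms must be positive")
  invisible(cfg)
}

#' Simulate a paired RNA/protein stress experiment with known ground truth
#'
#' Generates an RNA count matrix (negative binomial), a protein intensity
#' matrix (log-normal) for a subset of genes, a peptide-to-protein mapping, a
#' synthetic term annotation with planted enriched terms, a sample sheet for
#' the 2 genotype x 2 timepoint x replicate design, and a truth table holding
#' every planted effect, so that each downstream stage has a recoverable
#' answer key.
#'
#' The planted structure, per gene: a treatment (24h vs 0h) log2 fold change
#' for each genotype at the RNA level; a protein-level effect that is equal,
#' absent, or sign-flipped relative to the RNA effect; and, for a small set,
#' a between-genotype response difference whose absolute value exceeds the
#' screen threshold. The truth table's `screen_true` flag is always
#' recomputed from the planted effects as
#' `|log2FC_OX - log2FC_WT| > 1` at the RNA or protein level.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `"omics_sim"` with elements `counts` (genes x
#'   samples integer matrix), `protein` (proteins x samples matrix),
#'   `lengths` (named gene lengths, bp), `samples` (sample sheet data frame
#'   with columns sample, genotype, timepoint, replicate, group),
#'   `gene2protein`, `peptide2protein`, `annotation` (term, gene),
#'   `truth` (per-gene planted effects and flags), `planted_terms`
#'   (character vector of enriched term IDs), and `config`.
#' @examples
#' sim <- simulate_experiment(sim_config(n_genes = 200, seed = 42))
#' dim(sim$counts)
#' head(sim$truth)
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("config must be created by sim_config()")
  }
  validate_sim_config(config)
  set.seed(config$seed)
  n <- as.integer(config$n_genes)
  reps <- as.integer(config$replicates)
  genes <- sprintf("g%05d", seq_len(n))

  lengths <- stats::setNames(sample(500:5000, n, replace = TRUE), genes)

  ## baseline expression weights; scaled so a sample sums to ~library_size
  w <- stats::rlnorm(n, meanlog = log(50), sdlog = 1)
  mu0 <- config$library_size * w / sum(w)

  rng <- config$planted_log2fc_range
  draw_lfc <- function(m) {
    if (m == 0) return(numeric(0))
    sample(c(-1, 1), m, replace = TRUE) * stats::runif(m, rng[1], rng[2])
  }

  lfc_wt <- numeric(n)
  n_wt <- round(config$frac_de_wt * n)
  de_wt <- if (n_wt > 0) sample(n, n_wt) else integer(0)
  lfc_wt[de_wt] <- draw_lfc(n_wt)

  lfc_ox <- numeric(n)
  n_ox <- round(config$frac_de_ox * n)
  n_shared <- min(round(config$de_overlap * n_wt), n_ox, n_wt)
  shared <- if (n_shared > 0) sample(de_wt, n_shared) else integer(0)
  ox_only <- if (n_ox - n_shared > 0) {
    sample(setdiff(seq_len(n), de_wt), n_ox - n_shared)
  } else integer(0)
  ## shared responders keep nearly the same effect in both genotypes
  lfc_ox[shared] <- lfc_wt[shared] + stats::runif(n_shared, -0.4, 0.4)
  lfc_ox[ox_only] <- draw_lfc(length(ox_only))

  ## dedicated differential-response genes: planted delta beyond the screen
  ## threshold; drawn away from genes that are already asymmetric
  n_dr <- round(config$frac_diff_response * n)
  symmetric_pool <- setdiff(seq_len(n), c(ox_only, setdiff(de_wt, shared)))
  n_dr <- min(n_dr, length(symmetric_pool))
  dr <- if (n_dr > 0) sample(symmetric_pool, n_dr) else integer(0)
  if (n_dr > 0) {
    drr <- config$diff_response_delta_range
    delta <- sample(c(-1, 1), n_dr, replace = TRUE) * stats::runif(n_dr, drr[1], drr[2])
    lfc_ox[dr] <- lfc_wt[dr] + delta
  }

  ## protein layer: equal, absent or opposite effect relative to RNA
  np <- round(config$protein_fraction * n)
  np <- max(np, 1L)
  prot_idx <- sort(sample(n, np))
  p_opp <- 1 - config$concordant_fraction - config$null_protein_fraction
  mode <- sample(c(1, 0, -1), n, replace = TRUE,
                 prob = c(config$concordant_fraction,
                          config$null_protein_fraction, p_opp))
  plfc_wt <- mode * lfc_wt
  plfc_ox <- mode * lfc_ox

  samples <- expand.grid(
    replicate = seq_len(reps), timepoint = c("0h", "24h"),
    genotype = c("WT", "OX"), KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )
  samples <- samples[, c("genotype", "timepoint", "replicate")]
  samples$sample <- sprintf("%s_%s_r%d", samples$genotype,
                            samples$timepoint, samples$replicate)
  samples$group <- paste(samples$genotype, samples$timepoint, sep = "_")
  samples <- samples[, c("sample", "genotype", "timepoint", "replicate", "group")]

  counts <- matrix(0L, nrow = n, ncol = nrow(samples),
                   dimnames = list(genes, samples$sample))
  size <- 1 / config$nb_dispersion
  for (j in seq_len(nrow(samples))) {
    lfc <- if (samples$genotype[j] == "WT") lfc_wt else lfc_ox
    mu <- mu0 * 2^(lfc * (samples$timepoint[j] == "24h"))
    counts[, j] <- stats::rnbinom(n, mu = mu, size = size)
  }
  storage.mode(counts) <- "integer"

  proteins <- sub("^g", "p", genes[prot_idx])
  base_p <- stats::rlnorm(np, meanlog = log(1e5), sdlog = 1)
  sdlog <- sqrt(log(1 + config$protein_cv^2))
  protein <- matrix(0, nrow = np, ncol = nrow(samples),
                    dimnames = list(proteins, samples$sample))
  for (j in seq_len(nrow(samples))) {
    plfc <- if (samples$genotype[j] == "WT") plfc_wt else plfc_ox
    ml <- log(base_p) + log(2) * plfc[prot_idx] *
      (samples$timepoint[j] == "24h") - sdlog^2 / 2
    protein[, j] <- stats::rlnorm(np, meanlog = ml, sdlog = sdlog)
  }

  gene2protein <- data.frame(gene = genes[prot_idx], protein = proteins,
                             stringsAsFactors = FALSE)
  n_pep <- 1L + stats::rpois(np, config$mean_peptides)
  peptide2protein <- data.frame(
    peptide = sprintf("pep%06d", seq_len(sum(n_pep))),
    protein = rep(proteins, n_pep),
    stringsAsFactors = FALSE
  )

  ## truth: planted effects and derived flags
  delta_rna <- lfc_ox - lfc_wt
  delta_prot <- ifelse(seq_len(n) %in% prot_idx, plfc_ox - plfc_wt, NA_real_)
  has_protein <- seq_len(n) %in% prot_idx
  screen_true <- abs(delta_rna) > 1 |
    (!is.na(delta_prot) & abs(delta_prot) > 1)
  truth <- data.frame(
    gene = genes,
    has_protein = has_protein,
    lfc_rna_wt = lfc_wt, lfc_rna_ox = lfc_ox,
    lfc_prot_wt = ifelse(has_protein, plfc_wt, NA_real_),
    lfc_prot_ox = ifelse(has_protein, plfc_ox, NA_real_),
    de_rna_wt = abs(lfc_wt) > 1, de_rna_ox = abs(lfc_ox) > 1,
    de_prot_wt = has_protein & abs(plfc_wt) > 1,
    de_prot_ox = has_protein & abs(plfc_ox) > 1,
    delta_rna = delta_rna, delta_prot = delta_prot,
    screen_true = screen_true,
    diff_response_planted = seq_len(n) %in% dr,
    stringsAsFactors = FALSE
  )
  truth$quadrant_wt <- ifelse(
    has_protein, assign_quadrant(lfc_wt, ifelse(has_protein, plfc_wt, 0)),
    NA_integer_
  )
  truth$quadrant_ox <- ifelse(
    has_protein, assign_quadrant(lfc_ox, ifelse(has_protein, plfc_ox, 0)),
    NA_integer_
  )

  ## annotation: random terms plus terms planted on the screen-true genes
  n_terms <- config$n_terms
  terms <- sprintf("term%03d", seq_len(n_terms))
  n_planted <- round(config$frac_enriched_terms * n_terms)
  planted <- if (n_planted > 0) sample(terms, n_planted) else character(0)
  sizes <- sample(config$term_size_range[1]:config$term_size_range[2],
                  n_terms, replace = TRUE)
  sizes <- pmin(sizes, n)
  screen_set <- which(screen_true)
  members <- vector("list", n_terms)
  for (i in seq_len(n_terms)) {
    if (terms[i] %in% planted && length(screen_set) > 0) {
      k_in <- min(round(config$planted_term_purity * sizes[i]),
                  length(screen_set))
      inset <- sample(screen_set, k_in)
      rest <- sample(setdiff(seq_len(n), inset), sizes[i] - k_in)
      members[[i]] <- sort(c(inset, rest))
    } else {
      members[[i]] <- sort(sample(n, sizes[i]))
    }
  }
  annotation <- data.frame(
    term = rep(terms, lengths(members)),
    gene = genes[unlist(members)],
    stringsAsFactors = FALSE
  )

  structure(
    list(counts = counts, protein = protein, lengths = lengths,
         samples = samples, gene2protein = gene2protein,
         peptide2protein = peptide2protein, annotation = annotation,
         truth = truth, planted_terms = sort(planted), config = config),
    class = "omics_sim"
  )
}

#' Write a simulated dataset to tab-separated files
#'
#' Serialises every component of an [simulate_experiment()] result to
#' UTF-8 TSV files with a header row, named `counts.tsv`, `protein.tsv`,
#' `lengths.tsv`, `samples.tsv`, `gene2protein.tsv`, `peptide2protein.tsv`,
#' `terms.tsv` and `truth.tsv`. Files round-trip losslessly through
#' [read_dataset()].
#'
#' @param sim An `"omics_sim"` object.
#' @param dir Output directory (created if absent).
#' @return Named character vector of file paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  if (!inherits(sim, "omics_sim")) stop("sim must be an 'omics_sim' object")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    protein = file.path(dir, "protein.tsv"),
    lengths = file.path(dir, "lengths.tsv"),
    samples = file.path(dir, "samples.tsv"),
    gene2protein = file.path(dir, "gene2protein.tsv"),
    peptide2protein = file.path(dir, "peptide2protein.tsv"),
    terms = file.path(dir, "terms.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_table(sim$counts, paths["counts"], id_column = "gene")
  write_table(sim$protein, paths["protein"], id_column = "protein")
  write_table(data.frame(gene = names(sim$lengths), length = sim$lengths),
              paths["lengths"])
  write_table(sim$samples, paths["samples"])
  write_table(sim$gene2protein, paths["gene2protein"])
  write_table(sim$peptide2protein, paths["peptide2protein"])
  write_table(sim$annotation, paths["terms"])
  write_table(sim$truth, paths["truth"])
  invisible(paths)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing the TSV files.
#' @return A list with the same data components as an `"omics_sim"` object
#'   (`counts`, `protein`, `lengths`, `samples`, `gene2protein`,
#'   `peptide2protein`, `annotation`, `truth`).
#' @export
read_dataset <- function(dir) {
  counts_m <- read_matrix(file.path(dir, "counts.tsv"))
  storage.mode(counts_m) <- "integer"
  len <- utils::read.delim(file.path(dir, "lengths.tsv"),
                           stringsAsFactors = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  list(
    counts = counts_m,
    protein = read_matrix(file.path(dir, "protein.tsv")),
    lengths = stats::setNames(len$length, len$gene),
    samples = read_sample_sheet(file.path(dir, "samples.tsv")),
    gene2protein = utils::read.delim(file.path(dir, "gene2protein.tsv"),
                                     stringsAsFactors = FALSE),
    peptide2protein = utils::read.delim(file.path(dir, "peptide2protein.tsv"),
                                        stringsAsFactors = FALSE),
    annotation = read_term_annotation(file.path(dir, "terms.tsv")),
    truth = if (file.exists(truth_path)) {
      utils::read.delim(truth_path, stringsAsFactors = FALSE)
    } else NULL
  )
}
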