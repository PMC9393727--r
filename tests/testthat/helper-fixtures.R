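# Shared fixtures: a small simulated experiment and hand-built comparison
# results for the association/screen stages.

small_sim <- function(seed = 1, n_genes = 300, ...) {
  simulate_experiment(sim_config(n_genes = n_genes, seed = seed, ...))
}

run_four_contrasts <- function(sim) {
  s <- sim$samples
  list(
    rna_wt = de_test_rna(sim$counts, s, c("WT_24h", "WT_0h")),
    rna_ox = de_test_rna(sim$counts, s, c("OX_24h", "OX_0h")),
    prot_wt = de_test_protein(sim$protein, s, c("WT_24h", "WT_0h")),
    prot_ox = de_test_protein(sim$protein, s, c("OX_24h", "OX_0h"))
  )
}

# Minimal comparison-result data frames for direct association tests.
toy_rna_result <- function(genes, log2fc, sig) {
  data.frame(feature = genes, fc = 2^log2fc, log2fc = log2fc,
             p = ifelse(sig, 1e-4, 0.5), fdr = ifelse(sig, 1e-3, 0.8),
             status = ifelse(sig, ifelse(log2fc > 0, "up", "down"), "ns"),
             stringsAsFactors = FALSE)
}

toy_prot_result <- function(proteins, log2fc, sig) {
  data.frame(feature = proteins, fc = 2^log2fc, log2fc = log2fc,
             p = ifelse(sig, 1e-4, 0.5), q = ifelse(sig, 1e-3, 0.8),
             status = ifelse(sig, ifelse(log2fc > 0, "up", "down"), "ns"),
             stringsAsFactors = FALSE)
}
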