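---
title: "Methods: paired transcriptome-proteome differential expression, concordance and differential-response screening"
author: "dualomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired transcriptome-proteome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualomics)
```

## The analysis problem

An overexpression line (OX) and its wild type (WT) are profiled at two
timepoints (0h, 24h after treatment) at both the transcript and the protein
level, with a small number of biological replicates per group. Three
questions structure the analysis:

1. Which genes/proteins respond to treatment within each genotype
   (differential expression)?
2. Where do the transcript and protein responses agree (nine-quadrant
   concordance)?
3. Which genes respond *differently* in the two genotypes (the
   differential-response screen) — the genes most likely to sit downstream
   of the transgene?

This vignette records the models, parameter choices and numerical
conventions behind each stage, and what the synthetic-data tests do and do
not establish about real data.

## Differential expression: a declared simple engine

Count-based RNA-seq differential expression is usually fitted with
negative-binomial GLMs and shared dispersion estimation. This package
deliberately uses a simpler, fully deterministic engine instead: counts are
normalised to CPM, a pseudocount of 1 is added, and each gene gets a Welch
t-test on the log2 values; proteins get a Student (pooled-variance) t-test
on log2 intensities, matching the convention of DIA processing software
(Welch is available via `var_equal = FALSE`). The rationale: the package's
own contribution is the downstream concordance and screening logic, which
is agnostic to the DE engine; a transparent engine makes every downstream
number auditable by hand and keeps the test suite's oracles independent.

Consequences to be aware of:

- At three replicates Welch's t is conservative (measured type-I rate
  ≈ 0.03 at nominal 0.05 on null simulations); calibration is within the
  Monte-Carlo band from about five replicates upward. The property test
  therefore asserts two-sided calibration at six replicates and
  conservativeness at three.
- No dispersion shrinkage means less power at n = 3 than DESeq2/edgeR
  would give; DEG counts on simulated data are accordingly conservative.

Calling rules, all strict at the boundary (a value exactly at a threshold
is **not** called): DEGs need `|log2FC| > 1` and `FDR < 0.05`; DEPs need
linear `FC > 1.5` or `FC < 1/1.5` and `q < 0.05`. The "q-value" is a
Benjamini-Hochberg adjusted p — no distinct q-value estimator is implied —
and the same BH procedure is used wherever an adjusted value appears,
including enrichment. Fold changes are ratios of group means: of
pseudocounted CPM means for RNA (so zero-count genes have defined, shrunken
fold changes) and of linear intensity means for protein. The protein
fold-change threshold of 1.5 is interpreted on the linear scale; a value
like 1.5 is only meaningful there.

A protein with fewer than two quantified values in either group is flagged
`unquantified`, excluded from testing and from the BH family, and excluded
from the association stage.

## Nine-quadrant concordance

Genes measured in both layers are placed on a 3×3 grid by
(RNA log2FC, protein log2FC) with thresholds 1 and log2(1.5) — the same
fold-change cutoffs as the calling rules. The numbering convention is fixed
by the two anchored cells — 3 = concordant-up, 7 = concordant-down — and
filled row-major from the top left:

```
            RNA down   RNA ns   RNA up
protein up      1         2        3
protein ns      4         5        6
protein down    7         8        9
```

Boundary values fall to the middle band, consistent with the strict
thresholds elsewhere. Genes without a protein measurement are excluded
rather than placed in quadrant 5: "unchanged at the protein level" and
"not measured at the protein level" are different statements.

Whether the quadrant grid should use pure fold-change bands or full
significance criteria is genuinely open; the package reports both readings
at once — every quadrant count is split into a total (fold-change bands
only) and a "significant in both layers" subtotal — so either convention is
recoverable from the same output.

## The differential-response screen

Per layer, the screen statistic is the log2 ratio of the two genotypes'
treatment fold changes, `delta = log2(FC_OX / FC_WT)`; a gene passes when
`|delta| > 1` at the RNA or protein level. Conventions:

- Strict inequality at 1. The bundled published table contains a row
  (PXG4) whose RNA delta, recomputed from the printed rounded fold
  changes, is exactly −1.00; it passes through its protein delta of −1.13.
  The strict rule keeps that row's routing faithful.
- Deltas are computed from unrounded pipeline fold changes; report columns
  are rounded to 2 decimals for display only. When the screen runs on an
  external table of already-rounded fold changes, recomputed deltas can
  differ from the table's own printed deltas by more than rounding
  distance wherever the printed fold changes are tiny (0.03–0.05) — there
  the fold changes' own rounding dominates the ratio. Tests assert exact
  2-decimal agreement only for rows whose printed delta is consistent with
  its rounded fold changes.
- A missing level contributes nothing: the screen is evaluated on whatever
  levels are defined, and a gene missing both is never a candidate.
- The candidate pool is configurable: `"quadrant37"` (default) takes the
  union over the two comparisons of genes in quadrants 3/7 meeting both
  significance criteria, mirroring a workflow that screens only
  concordantly-responding genes; `"all"` applies the delta statistic to
  every measured gene. The two pools answer slightly different questions
  and neither is asserted as canonical; recovery statistics in the tests
  use `"all"` because the planted truth is defined over all genes.

Antisymmetry under genotype swap (all deltas negate, pass flags are
preserved) is enforced by construction and by property test.

## Enrichment

One-sided hypergeometric over-representation (equivalently Fisher's exact
upper tail), with the background fixed to the features measured in the
relevant layer — not the genome — to guard against detection bias. Terms
are ranked by BH-adjusted p with deterministic tie-breaking (raw p, then
lexical term ID); significance is flagged at adjusted ≤ 0.05 (non-strict,
matching the convention that a printed threshold of 0.05 includes 0.05).
The directional z-score per term is (n_up − n_down)/n over the term's
labelled differential members, a value in [−1, 1]. Term semantics (GO
graph structure, pathway topology) are out of scope: annotations are flat
term→gene tables (TSV or GMT).

## The synthetic-data generator

`simulate_experiment()` emulates the 2×2×3 design with:

- **RNA**: negative-binomial counts, gene-level baseline means drawn
  log-normal (sdlog 1 around a mean of ~500 counts at the default 2000
  genes × 1e6 depth), dispersion 0.1 — typical bulk RNA-seq values. The
  depth is arbitrary in the sense that no depth was specified for the
  modelled design; one million counts per sample is a realistic bulk
  figure and is fixed as the default.
- **Protein**: log-normal intensities with CV 0.2 around the baseline
  times 2^(planted effect), mean-corrected so the expectation equals the
  target; about 20% of genes carry a protein, matching the usual
  DIA-vs-transcriptome detection ratio.
- **Planted effects**: 15% of genes respond in WT and 18% in OX, with 80%
  of the OX set drawn from the WT set at nearly equal effect (|jitter| ≤
  0.4) — proportions rescaled from the modelled experiment's DEG counts
  and Venn overlap. Effects are uniform in ±[1.5, 4]. A dedicated 2% of
  genes get a planted between-genotype delta in ±[1.5, 2.5]; genes
  responding in only one genotype are *also* true screen positives (their
  planted delta is ≥ 1.5 automatically), and the truth table's
  `screen_true` flag is always recomputed from the planted effects as
  |Δ| > 1 at either layer, so construction and truth cannot disagree.
- **Protein concordance**: per gene, the protein effect equals the RNA
  effect (70%), is absent (15%), or has the opposite sign (15%),
  populating the concordant and discordant quadrants.
- **Annotation**: 100 terms of 10–50 genes; 5% are planted with 70% of
  their members drawn from the true screen positives.
- One global seed drives every draw; a fixed seed gives byte-identical
  output.

What passing tests show: the pipeline recovers planted differential
responses (sensitivity ≈ 0.97, specificity ≈ 0.92 at the design size,
against bounds of 0.8/0.9) and planted terms rank top in ≥ 9/10 seeds.
What they do not show: robustness to features the generator omits —
library-size imbalance and composition effects, batch structure,
missing-not-at-random protein dropout, correlated genes, dispersion trends
— so real-data performance claims need real data.

## Numerical choices and degenerate inputs

- Degenerate t-tests (both groups zero-variance) give p = 1 when means are
  equal and p = 0 otherwise, instead of NaN.
- An undefined replicate correlation (constant column) is reported as `NA`
  and flags the group rather than propagating.
- Fold-change tables ingested from external sources have unicode minus
  normalised to ASCII and `\` cells read as missing.
- Report columns mirror 2-decimal display conventions; machine-readable
  TSVs keep full precision. All percentages are rounded to 2 decimals at
  computation, as they are conventionally printed.
- Problem sizes in the test suite: most unit tests run at 120–1000 genes;
  the recovery and calibration properties run at 2000 genes × 10 seeds,
  the size at which the Monte-Carlo bands quoted above were set.

## Known limitations

- The DE engine is not a substitute for count-GLM methods when maximal
  power at n = 3 matters.
- The enrichment stage assumes a flat, complete annotation; propagation
  over an ontology graph must happen upstream.
- The screen compares point estimates of fold changes; it carries no
  uncertainty on delta, so genes near the threshold flip between seeds —
  the motivation for the strict, pre-registered |Δ| > 1 rule rather than a
  ranked list.
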