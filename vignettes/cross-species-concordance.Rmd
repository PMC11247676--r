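---
title: "Scoring mouse models of late-onset Alzheimer's disease against human transcriptomic signatures"
author: "concordAD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring mouse models of late-onset Alzheimer's disease against human transcriptomic signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Genome-wide association studies nominate many candidate risk variants for
late-onset Alzheimer's disease (LOAD), but a variant knocked into a mouse
only matters if it pushes the mouse brain transcriptome in the same
direction that disease pushes the human brain transcriptome. concordAD
implements a complete, testable version of the analysis chain used to ask
that question with panel-based (NanoString-style) expression data:

1. normalize panel counts per lane by the geometric mean of designated
   housekeeping genes, log2-transform, and remove lane batch effects with
   empirical-Bayes location/scale adjustment (ComBat);
2. fit, per gene and per age cohort, the additive model
   \(\log_2 \mathrm{expr} = \beta_0 + \beta_{male} + \sum_i \beta_i +
   \varepsilon\), where the \(\beta_i\) are 0/1 genotype indicators arranged
   in a nested control hierarchy: the B6J strain is the baseline, the 5xFAD
   and LOAD1 (humanized APOE4 + Trem2*R47H) models are contrasted against
   B6J, and each candidate-variant strain carries both its own indicator and
   the LOAD1 indicator, so its coefficient estimates the deviation from the
   sensitized background it was built on;
3. score each perturbation's human relevance as the Pearson correlation
   (`cor.test`) between its per-gene coefficient vector \(\beta\) and human
   log2 fold changes (AD or LOAD-subtype versus control), either restricted
   to each of 30 human brain co-expression modules (annotated with consensus
   clusters A–E) or spanning the whole homolog-mapped panel;
4. characterize the drivers with preranked gene-set enrichment (weighted
   Kolmogorov–Smirnov running sum over coefficient-ranked genes, with a
   gene-permutation null), directional-coherence gene extraction
   (sign(mouse \(\beta\)) = sign(human log2FC)), hypergeometric
   overrepresentation, and Benjamini–Hochberg FDR control.

Because the original mouse and human datasets live behind controlled-access
portals, the package ships a first-class synthetic-data module that
generates the whole study — counts, metadata, modules, signatures, homolog
map — with known ground truth, so every stage of the chain is exercised and
validated end to end without any download.

## The synthetic generator

`simulate_experiment()` draws counts from a negative binomial whose log2
mean is `baseline + design effects + sex effect + lane batch shift`. The
defaults encode the study conditions the analysis assumes:

| parameter | default | meaning |
|---|---|---|
| `n_genes` / `n_housekeeping` | 770 / 10 | panel size and designated stable genes |
| `genotype_factors` | 13 factors | 5xFAD, LOAD1, and 11 variant factors on the LOAD1 background |
| `animals_per_group_per_sex` | 6 | animals per (strain, sex, age) cell |
| `ages` | 4, 12 months | age cohorts; an 8-month cohort can be generated but is not in the defaults because the comparative analyses use 4 and 12 months |
| `n_batches` | 4 | lane/run batches, assigned at random within each age cohort |
| `effect_sparsity` / `effect_scale` | 0.1 / 0.5 log2 | fraction of genes affected per factor, and the SD of planted effects (symmetric around zero, since both up- and down-regulated modules occur in practice) |
| `batch_shift_scale` | 0.25 log2 | SD of per-gene lane shifts |
| `dispersion` | 0.02 | NB dispersion (variance \( \mu + 0.02\mu^2 \)); a replicate CV of ~14%, reflecting the low biological variability of inbred mice under controlled housing |
| `baseline_log2_mean_range` | [5, 10] | per-gene baseline abundance |

Housekeeping genes receive zero genotype, sex, and batch effects by
construction, so their expected cross-group ratios are 1 and the
housekeeping divisor is unbiased. All generators are pure functions of
(config, seed): the RNG state is isolated and restored, and identical
inputs give bitwise-identical outputs.

`plant_human_signature()` is the generative inverse of the concordance
measurement: for each module it emits human log2 fold changes
\(h = a\,\beta + e\) with \(e \sim N(0, \sigma^2)\) and the gain \(a\)
calibrated so the *expected* Pearson correlation with the mouse truth
vector equals the requested target; the realized correlation of any single
draw varies with sampling, which is exactly what the recovery tests
measure. Genes outside all modules get pure noise; genes shared between
overlapping modules keep the first module's value. `|target| = 1` plants an
exact sign-matched copy; `|target| < 1` requires positive noise.

What the generator does **not** emulate: probe chemistry, background
counts, positive/negative spike-in controls, gene–gene correlation beyond
what the shared design induces, count-level outliers, and litter or cage
structure. Passing tests therefore demonstrate that the chain recovers
truth under its own statistical assumptions — additive log-scale effects
with NB noise — not that it is robust to every artifact of real panel data.

## Numerical and design choices

- **Log base 2** throughout, so mouse coefficients are directly comparable
  to human log2 fold changes.
- **Pseudocount policy**: the default pseudocount 1 is added to raw counts
  *before* the housekeeping division, and the log2 is taken of the ratio
  directly. Adding a pseudocount after division would destroy
  log-linearity, because housekeeping-normalized ratios are order 1.
- **Batch correction** uses the parametric empirical-Bayes location/scale
  model, applied independently within each age cohort (mirroring the
  per-age regressions) with the sex + genotype design preserved. Whether
  the original analyses preserved biological covariates during correction
  is not stated anywhere we could verify, so preservation is exposed as a
  toggle (`correct_batch`, `preserve`) rather than hard-wired; preserving
  the modeled factors is the default because removing them risks deleting
  signal when genotype is unevenly spread over lanes. A single batch is a
  no-op; a singleton batch or a batch aliased with a preserved covariate is
  an error.
- **One joint fit, not pairwise contrasts**: the nested indicator encoding
  reproduces the stated contrasts (variant vs LOAD1, LOAD1/5xFAD vs B6J) in
  a single design per age, sharing one residual variance per gene. Plain
  OLS, two-sided t-based p-values, no variance moderation — moderation
  (as in limma) is a possible extension but is deliberately not applied so
  coefficients remain plain group contrasts.
- **Sex coding**: male indicator, female reference.
- **Minimum module overlap** for a correlation: 5 homolog-mapped genes with
  a fitted effect and a human fold change; below that the module row is
  reported with a missing `r` and reason code `insufficient_overlap` rather
  than dropped. Genes are removed pairwise when either side is missing, and
  `n_genes` records the final count.
- **No multiple-testing correction across perturbation–context pairs** in
  the concordance tables: the convention in this analysis style is to frame
  raw p < 0.05 in the dot plot; `bh_adjust()` is available for users who
  want an FDR column.
- **Homolog policy**: only one-to-one human–mouse pairs are kept (dropped
  rows are counted in a warning); matching is case-insensitive with case
  preserved on output. This avoids arbitrary aggregation of paralog fold
  changes at the cost of discarding genuinely informative many-to-many
  families.
- **GSEA**: exponent 1 by default (the cited method's weighting), exponent
  0 retained because the unweighted statistic has an exact brute-force
  oracle. The null permutes gene labels (preranked data have no sample
  phenotypes to permute); p-values and NES use the same-signed null with
  the +1 correction, so p ≥ 1/(nperm+1). Ties in coefficients are broken
  by gene symbol order and recorded, making rankings reproducible.
  `nperm` defaults to 10,000 for analyses; tests use 300–5,000.
- **Known property of the enrichment score**: with exponent 0 the running
  sum ends at zero, so the maximal positive and maximal negative deviations
  can tie in magnitude; the score then takes whichever extreme is reached
  first. For hit patterns that are their own mirror image (palindromic),
  the reversed list has the identical profile, so reversing a ranked list
  preserves |ES| always but cannot flip the sign in those degenerate cases.
  Uniformly sampled short lists hit such cases at a measurable rate (about
  12–16% at length ≤ 12); the acceptance report quantifies it as
  `es_reversal_violation_rate`.
- **Dot plot conventions**: circle *area* and color intensity proportional
  to |r| (area, not radius, is the perceptually honest encoding), blue for
  positive, red for negative, black frame iff p < threshold, columns
  grouped by consensus cluster. SVG output is drawn without raster
  elements, so identical inputs give byte-identical files.

## Problem sizes and what the tests show

The suite validates each stage against independent oracles (closed-form
Pearson t-formula, brute-force running-sum enumeration, exact
hypergeometric combinatorics, `lm()` on small designs, an established GSEA
implementation for the weighted score) and then checks recovery at the
study scale: a 770-gene panel with 14 strains x 2 sexes x 6 animals x 2
ages (672 samples) for effect recovery; 500 null genes for regression
calibration; 30 disjoint modules of 20–50 genes with planted correlations
-0.6/0/0.6 over 100 planting seeds for concordance recovery; 50 random
sets at 500 permutations for GSEA null calibration; and a full two-run
pipeline comparison for byte-level reproducibility. These sizes were
chosen as the smallest that leave the Monte-Carlo bands meaningful.

## Limitations

- Effect estimates feed the concordance step as point values; estimation
  noise in \(\hat\beta\) attenuates measured correlations below the
  planted target when module effects are sparse (visible in the analysis
  scripts, where the planted r = 0.6 factor measures ~0.4 through the full
  chain). The calibration tests therefore measure against the truth
  vectors, and the end-to-end run documents the attenuation rather than
  hiding it.
- The GO/pathway side is format-level only: gene sets are plain GMT
  inputs; there is no ontology graph traversal, term ancestry propagation,
  or term-hierarchy reduction.
- No mixed effects: litter, cage, and batch random effects are out of
  scope; batch is handled once, upstream, by empirical Bayes.
- No RCC (instrument file) parsing and no portal download client; readers
  accept plain TSV/GMT.
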