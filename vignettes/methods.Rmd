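---
title: "Methods: benchmarking single-cell protocols with scpbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking single-cell protocols with scpbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scpbench)
```

## The problem

When the same tissue is profiled by single-cell RNA-seq under two
sample-processing protocols — say freshly dissociated versus fixed material —
the question is whether the protocol changes what the assay sees: library
complexity, the quality-control landscape, transcriptome-wide expression,
cell-type composition, and the burden of dissociation-stress artifacts.
`scpbench` implements the statistical machinery of that comparison as a
tested pipeline, together with a molecule-level synthetic generator so every
statistic can be validated against known ground truth.

## Synthetic libraries

A `synthetic_spec()` describes a two-protocol experiment. Protocol "A" is
the stressed (fresh-analogue) arm, "B" the protected arm.

* **Gene abundance.** Per-gene base rates are log-normal
  (`base_rate_log_mean = 0`, `base_rate_log_sd = 1`), perturbed per cell
  type by independent log-normal multipliers (`type_effect_sd = 0.4`). No
  gene–gene correlation is modelled: every statistic in scope (means,
  ranks, set scores, proportions) depends only on marginal gene behaviour,
  so this simplification is adequate here but means the generator cannot
  exercise co-expression-based methods.
* **Cells.** Default four cell types with 75 cells per type per protocol
  (300 cells per arm) over 2000 genes; per-cell totals are log-normal with
  median 2500 UMIs (`library_size_log_sd = 0.35`) — a typical droplet
  library after barcode filtering.
* **Stress.** A designated gene set (default 20 genes) has its rates
  multiplied by `stress_fold` in arm A only; `stress_fold = 1` is the
  exchangeable null used for all calibration checks.
* **Reads.** Each molecule carries `1 + NB(mu = amplification_mean - 1,
  size = amplification_dispersion)` reads (defaults 4 and 1). The shift
  guarantees at least one read per molecule; the negative binomial is the
  standard over-dispersed stand-in for PCR amplification. Real read-count
  distributions were not available to fit, so these are generative choices,
  not estimates.
* **Low-quality cells.** Optionally a fraction of barcodes is rewritten to
  have a mitochondrial fraction boosted by `lowq_mt_boost` (capped at 95%)
  and totals below the 5th percentile of intact cells — exactly the cells
  the QC stage should remove.
* **Determinism.** One master seed; every stage draws from a child seed
  derived by a fixed affine map, so stages can be re-run independently and
  two runs with the same spec are byte-identical. UMI tokens are sequential
  within each (barcode, gene) pair, which makes them unique by construction.

Because the generator is the test bed, passing tests demonstrate the
*statistics* behave correctly under a known model; they do not certify any
claim about a particular real tissue, where ambient RNA, doublets, batch
structure and gene–gene correlation all exist and are deliberately out of
scope here.

## Library complexity and saturation

`downsample_reads()` draws exactly `n` of the library's reads without
replacement, jointly across molecules — a multivariate hypergeometric draw
implemented by sampling read indices, so the kept total is exact and each
molecule's survival probability matches exhaustive enumeration (checked on
small instances in the tests). Bernoulli thinning was rejected because it
does not fix the total.

`saturation_curve()` evaluates detected genes and surviving molecules on a
depth grid (default ten equal steps — fixed multi-million-read steps are
meaningless at simulation scale but any explicit grid can be supplied), one
independent draw per depth, with the full-depth point always appended. A
nested mode (single read permutation, prefix depths) exists for monotone
coupling checks only. `fit_depth_model()` then fits ordinary least squares
of the detected count on depth with the t-based 95% CI of the slope
(`n - 2` df), and `ci_overlap_test()` declares two libraries different only
when the closed intervals are disjoint — ties count as overlap, the
conservative reading. Under exchangeable pairs this verdict fires well
under 10% of the time because non-overlap of two 95% intervals is stricter
than a 5% test; the saturation curve's concavity further inflates the
residual variance and hence the intervals.

`cumulative_gene_curve()` averages, over 100 repetitions, the distinct
genes found in `n` randomly drawn cells for `n` = 1 to 100 in steps of 2
(configurable). Within a repetition the draws are coupled through one cell
permutation: each `n` is a prefix, so every repetition's curve is monotone
while each `n` keeps the exact uniform-subset marginal.

## Quality control and normalization

`compute_qc()` reports library size, complexity and mitochondrial/ribosomal
percentages. `filter_cells()` supports plain bounds and the two-pass colon
scheme: a permissive mitochondrial ceiling first (75% mouse, 85% human),
then lineage-specific ceilings on the survivors (60% epithelial; 50% mouse /
25% human non-epithelial), available as the `"mouse_colon"` and
`"human_colon"` presets. Lineage labels must be supplied (ground-truth
labels for synthetic data); the clustering that produced them in real
analyses is out of scope. Thresholds for "very low" UMI/gene counts are
configuration with documented defaults, not fixed constants, since no
universal values exist.

Normalization is `ln(1 + 10^4 · count / cell_total)`, preserving zeros and
within-cell ranks. HVG selection is vst-style: a loess trend of log10
variance on log10 mean (span 0.3, widened automatically when fewer than ~30
variable genes are available, and replaced by a direct variance ranking
below 10), standardized counts clipped at `sqrt(n_cells)`, genes ranked by
the clipped standardized variance with ties broken by gene id.
`hvg_overlap()` is the shared fraction of the two arms' top-n lists.

## Comparison statistics

*Pseudo-bulk correlation* (`pseudobulk_correlation()`): profiles are
per-gene means of log-normalized expression over cells; a cell type is
compared only with more than 100 cells overall and more than 20 per
condition, and the larger condition is first subsampled to the smaller.
Pearson correlation is computed over genes expressed in either profile
(genes zero in both would inflate agreement), and a comparison is "strong"
when r² > 0.9 with p < 0.05. Whether real analyses use the union or
intersection support is not standardized; the union of expressed genes is
used here and recorded as such.

*Composition* (`composition_compare()`): per-protocol proportions, log2
ratio with a 0.5 pseudo-count on zero cell counts, and a percentile
bootstrap 95% CI resampling cells within protocol. This is deliberately
descriptive — a replacement for Bayesian compositional modelling, which is
out of scope — and its output never claims "credible" changes.

*Differential expression* (`differential_expression()`): per-gene two-sided
Wilcoxon rank-sum on log-normalized values, after excluding genes present
in fewer than 10% of cells in both groups. The fold change de-logs the
means (`expm1`) and adds `eps = 1/mean(group size)` to both numerator and
denominator. BH adjustment runs over tested genes; significance requires
|log2FC| > 1, adjusted p < 0.05 and the presence rule. The rank-sum test
replaces a hurdle-model fit: the contribution being tested is the filter
rule, and the rank-sum test is distribution-free, dependency-light and
reproducible; the substitution is recorded in the result metadata.

## Signature scoring

`score_signature()` is the Mann–Whitney-U–based per-cell score: within each
cell, genes are ranked by decreasing expression (average ranks on ties);
ranks beyond `r_max = 1500` (the reference implementation's default,
configurable) and unexpressed or absent genes take the ceiling `r_max + 1`;
`U = Σ rank − n_s(n_s+1)/2` and `score = clamp(1 − U/(n_s r_max), 0, 1)`.
The score is a function of within-cell ranks only, hence exactly invariant
under monotone transforms — asserted in the tests, along with the closed
forms for a top-ranked and a fully unexpressed signature.

`compare_scores()` caps each (cell type × protocol) stratum at 250 cells by
seeded subsampling and applies the two-sided Wilcoxon *rank-sum* test. The
protocol arms are unpaired groups, so a signed-rank (paired) test is not
applicable by default; a `paired` option exists for genuinely paired
designs.

## Pre-ranked enrichment

`enrichment_score()` implements the weighted running sum (hits add
`|stat|^p / Σ_hits |stat|^p`, default `p = 1`; misses subtract
`1/(N − n_hits)`), with the signed extremum as the score; exact ±ties
prefer the positive extremum, a measure-zero tie-break documented so the
test oracle can share it. Internally the extremum is evaluated only at hit
boundaries (an O(set size) identity of the piecewise-linear running sum),
which is what makes a permutation null affordable.

`preranked_gsea()` filters sets to an in-universe size of 10–300 and builds
a per-set null from random same-size gene sets: with pre-ranked statistics
there are no sample labels left to permute, so gene permutation is the only
available null. The p-value is conditional on the observed sign —
`(1 + #{matching-sign null ≥ |es|}) / (1 + #matching-sign null)` — which is
uniform under the null (verified by a KS check in the tests); dividing by
the total permutation count instead would compress p-values into (0, ½].
NES divides by the mean |null| of matching sign. Significance requires
BH-adjusted p < 0.05, more than 5 set genes in the universe, and those
covering more than 15% of the set; "overlap" here means in-universe set
size, with leading-edge size a possible additional report, since the filter
predates any particular edge definition.

## Pipeline and reproducibility

`bench_config()` collects the generative spec, stage toggles and every
stage parameter; `run_benchmark()` executes the stages in dependency order,
writes each stage's table under the output directory, and emits
`report.json` with the verdicts, the substitution notes and the full
configuration echo. The report contains no timestamps, so a config + seed
pair reproduces it byte-identically — that is the pipeline's determinism
contract and is asserted in the tests. Any stage error aborts the run with
the stage name.

Depth equalization follows the aggregation convention of droplet pipelines:
libraries are brought to the same *mean reads per barcode* (not total
reads), anchored by the shallowest library, which is returned unchanged.
It is exposed as an explicit optional stage since its ordering relative to
barcode filtering is an analysis choice.

## Problem sizes and numerical choices

Test and default problem sizes are chosen so the full suite exercises the
study conditions at simulation scale: 300 cells and 2000 genes per arm for
DE recovery and pseudo-bulk calibration, 250 cells per arm and 30-gene
signatures for the score power/size checks, 50 exchangeable pairs for the
CI-overlap calibration, and 200 random sets × 500 permutations for the
enrichment null. Degenerate inputs are handled explicitly: zero-variance
predictors yield flagged fits with undefined slope rather than numbers;
all-zero cells are flagged in QC and must be removed before normalization;
constant matrices refuse HVG selection; sets that never intersect the
ranked universe are errors, and whole-universe sets score exactly 1.

## Known limitations

The generator omits ambient RNA, doublets, batch effects, UMI collisions,
sequencing errors and gene–gene correlation; conclusions from passing tests
transfer to real data only for the rank- and mean-based statistics whose
assumptions those features would not break. The composition comparison is
descriptive, not a compositional model. The DE test ignores covariates.
Enrichment uses a gene-permutation null, which treats genes as
exchangeable and can be anti-conservative under strong inter-gene
correlation in real data.
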