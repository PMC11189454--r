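---
title: "Methods: paired ligand-activity inference for segmented-ROI spatial transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired ligand-activity inference for segmented-ROI spatial transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roicrosstalk)
```

## Data model

The pipeline operates on a gene × ROI matrix of non-negative integer
counts plus a per-ROI annotation carrying three things: the
tissue-microarray **core** the ROI was drawn from, its **compartment**
(tumour, stroma or immune-infiltrated tumour), and sequencing QC
metrics. Cores are the adjacency unit: the tumour and stroma ROIs of
one core were segmented from the same tissue circle, so they are
physically adjacent, while ROIs from different cores are not. All joins
between tables are by exact string identifier; column order is never
assumed meaningful.

## QC rules

`filter_rois()` keeps an ROI only if **all** of the following hold:

| rule | default | direction |
|---|---|---|
| raw reads | 1000 | `>=` ("minimum") |
| sequencing saturation | 50 % | strict `>` |
| aligned / trimmed / stitched reads | 80 % | strict `>` |
| fraction of genes detected | 10 % | `>=` (ROIs *below* 10 % removed) |

`filter_genes()` then keeps a gene iff it is detected (count ≥ 1; the
detection limit is configurable, there being no limit-of-quantitation
model in scope) in **strictly more than** 10 % of the kept ROIs. The
gene rule is deliberately read as removing *rarely* detected genes:
keeping genes detected in more than the threshold fraction is the only
direction under which the filter retains a plausible minority of a
whole-transcriptome panel. The ROI detection rule is evaluated against
the full pre-filter gene panel; this is configurable because either
order can be argued.

Every exclusion is enumerated with the rule(s) that caused it; the
pipeline logs one structured line per dropped ROI, gene, core or
ligand so that data loss is always accounted for.

## Q3 normalisation

Each ROI *j* is scaled by its 75th percentile `q3_j` of counts over
retained genes, anchored so the scale is preserved:

`normalized_ij = count_ij * gm(q3) / q3_j`,

where `gm` is the geometric mean over ROIs. Percentiles use the
linear-interpolation definition (R `quantile` type 7); the convention
matters at small gene counts and is therefore fixed and stated. After
normalisation every ROI's Q3 equals the common geometric mean (the test
suite asserts equality to 1e−9 relative). An ROI with zero third
quartile is an error, not a silent NaN — such an ROI should have failed
QC. Log2 transform adds a pseudo-count of 1 (in normalized-count
units).

## Differential expression

Two-group comparison on log2 expression with empirical-Bayes variance
moderation. Per gene, the pooled residual variance `s²` on
`d = n_a + n_b − 2` df is shrunk towards a prior `(d0, s0²)` fitted
across genes by method of moments on `log s²` under the scaled-F
marginal — the same closed-form moment matching the reference
implementation of the moderated t uses, which the test suite verifies
against `limma` to 1e−6/1e−8. The moderated statistic uses `d0 + d`
degrees of freedom; `d0 = 0` recovers the ordinary pooled t exactly.
Genes with zero residual variance are floored to the smallest positive
`s²` and flagged rather than yielding infinite statistics — a case that
arises routinely in small synthetic fixtures. Multiple testing uses
Benjamini–Hochberg; the default significance threshold is adjusted
p < 0.05. The design is a simple two-group contrast; donor blocking is
a possible extension but every ROI is treated as an independent
replicate, matching the source analysis convention.

## Deconvolution

Per-ROI non-negative least squares of linear normalized expression on a
cell-profile signature matrix, with proportions `β / Σβ` and the
residual norm reported. The self-contained Lawson–Hanson active-set
solver is exact at these problem sizes. This is a deliberate
simplification of log-normal-regression deconvolution tools: only the
output proportions are consumed downstream, and the estimator sits
behind a single interface so it can be swapped. Signature genes default
to the top 50 genes per cell type by fold difference over the mean of
the other types, computed from the profile matrix itself; pass
`signature_genes = NA` to use all shared genes. No background term is
modelled (no negative-probe data in scope).

## Ligand activity

The package's central statistic. For sender compartment *s* and
receiver *r*:

1. **Pairing** (`build_pairs`): each core with ≥ 1 *s*-ROI and ≥ 1
   *r*-ROI contributes one pair; multiple ROIs of a compartment in a
   core are averaged (arithmetic mean of log2 values). Cores lacking
   either compartment are skipped and logged. At least 3 pairs are
   required for any correlation.
2. **Prior restriction** (`restrict_prior`): ligand–target pairs are
   kept when both genes are measured; per ligand the top-K targets by
   regulatory potential are retained (default K = 200, ties broken by
   target symbol; `K = Inf` reproduces the literal "all pairs present
   in the dataset" reading) and ligands with fewer than 5 surviving
   targets are dropped.
3. **Scoring** (`ligand_activity`): activity = arithmetic mean over
   targets of the Pearson correlation between the ligand's sender
   profile and the target's receiver profile across pairs. Active ⇔
   activity ≥ 0.2. Zero-variance targets are skipped and counted;
   a zero-variance ligand is reported as not-evaluable rather than
   dropped.

Correlations are computed on **log2** normalized expression: downstream
analysis is log2 throughout and variance stabilisation makes Pearson
correlation meaningful; this is a documented choice, as the source
convention is not stated. No multiple-testing correction is applied to
activity scores — the threshold is a fixed effect-size rule — but
`activity_permutation_null()` provides a seeded permutation null
(receiver profiles shuffled across pairs) for calibrating the
false-call rate; the test suite verifies ≤ 10 % of null ligands reach
0.2 at 30 pairs over 200 replicates.

Ligand **origin** is attributed by correlating each active ligand's
per-ROI expression with each deconvolved cell-type proportion; edges
with r strictly above 0.2 are reported (the activity call itself uses
≥ 0.2; the two conventions follow their respective stated rules).

## Path inference

Given a layered weighted network (`ligand_receptor`, `signalling`,
`gene_regulatory` edges with weights in (0, 1]), `infer_path()` returns
the path from ligand to target maximising the product of edge weights
among paths of at most 6 edges whose first hop is a ligand→receptor
edge. This is equivalent to a shortest path under cost `−log(weight)`
and is implemented as dynamic programming over path length, which makes
the bound and the tie-breaks (fewer edges, then lexicographic node
sequence) deterministic; because weights never exceed 1, cycles cannot
improve a product and the optimum is a simple path. This transparent
optimal-path criterion replaces diffusion-based path weighting — the
inferred route is a qualitative hypothesis, and an exactly defined
optimum is easier to reason about and to test (the suite checks it
against exhaustive enumeration).

## Subtyping

Nearest-centroid classification of each ROI against pluggable subtype
centroids (the six consensus muscle-invasive bladder cancer labels are
the motivating case) by Pearson correlation over shared genes (≥ 20
required). The call is the argmax centroid if its correlation reaches
`min_corr` (default 0.2), else `undefined`; the separation (best minus
second-best correlation) is reported for diagnostics. The undefined
rule of the original consensus classifier is not public, so this
transparent threshold stands in; exact reproduction of published
undefined fractions is therefore not guaranteed.

## Synthetic data: what it emulates, and what a green test means

`generate_dataset()` draws a cohort whose defaults state the emulated
world: 55 cores with compartment presence probabilities
(0.85, 0.60, 0.35) giving ≈ 98 expected ROIs in roughly a 47/32/19
tumour/stroma/immune split; log-normal library sizes
(meanlog = log(2e5), sdlog = 0.35); negative-binomial counts with
dispersion 0.2 (overdispersed, standard for sequencing counts — the
noise model is a package choice, not a measured one). Cell-type
composition per compartment is Dirichlet with qualitative patterns
(tumour malignant-dominated; stroma MyoCAF-led; immune B-cell/
macrophage-led), not fitted values.

Planted ligand couplings act multiplicatively on receiver target means:
on the log2 scale a target's planted component is
`coupling · z + ε` with `z` the core-level sender latent and
`ε ~ N(0,1)`, so the pre-measurement population correlation is
`coupling / sqrt(coupling² + 1)` and the generator is parameterised
directly by the desired population r (`active_target_r`, default 0.6);
count noise attenuates realised correlations slightly below this.
Subtype signatures use the same construction (`subtype_r`). QC-failure
plants corrupt exactly one named rule per designated ROI. All
randomness flows from one mandatory seed; identical configs and seeds
give byte-identical outputs.

What the simulator does **not** emulate: real gene-level expression
distributions, probe-level effects, spatial coordinates beyond core
co-membership, donor-level correlation structure, or batch effects. A
green recovery test therefore establishes that the estimators are
correct under the stated generative model — not that they are robust to
everything real tissue does.

Two simulation-scale choices are made for test-runtime reasons and
stated here: unit tests use down-scaled configs (≈ 900–1100 genes,
30 cores) rather than whole-transcriptome size, and the planted-DE
fixture uses residual sd 0.5 on the log2 scale (typical for expression
data; at much larger noise the planted ranking outcome stops being a
property of the method and becomes a coin flip of the draw).

## Numerical choices and degenerate inputs

- Percentile definition: type-7 linear interpolation, fixed above.
- BH adjustment: standard step-up, `pmin(1, cummin(...))` on the
  reverse-sorted p-values.
- NNLS: active-set with dual tolerance 1e−10; an all-zero solution
  (non-decomposable ROI) is an error, not a zero row.
- Zero-variance genes/targets/ligands: floored and flagged (DE),
  skipped and counted (targets), reported not-evaluable (ligands).
- Ties: top-K prior restriction by weight then target symbol; path
  search by score, then edge count, then node sequence; subtype argmax
  by lexicographic label, flagged.
- Validation errors carry a dedicated condition class
  (`roicrosstalk_validation_error`) and name the offending identifiers.

## Known limitations

- The empirical-Bayes fit uses the closed-form moment-matching
  estimator only (no robust/winsorised variant, no trend on abundance).
- Deconvolution assumes the signature matrix spans the tissue's cell
  types; no background/unknown-content term.
- Activity inference treats cores as exchangeable pairs; it does not
  model donor effects, and with one ROI per compartment per core the
  within-core aggregation is a no-op.
- The pipeline has no survival analysis, pathway knowledge base, or
  image handling; the ligand-target prior and subtype centroids are
  inputs, not derived products.
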