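---
title: "Z-ratio differential expression: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Z-ratio differential expression: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zratioDE)
```

## The statistical model

zratioDE analyzes probe-by-sample intensity matrices from multi-group
expression studies — the reference design is four groups (sham control,
drug-only, injury, injury + drug) with five arrays each. The chain is:

1. **Log transform.** `log_transform()` applies
   `log_base(max(x, floor))`. The base (default 10) cancels entirely in
   the Z-scores, because standardization is invariant to affine maps; the
   floor (default 1 scanner unit) only guards zeros. Neither choice
   affects inference.

2. **Per-array Z-score normalization.** Each array column is standardized
   to mean 0, sd 1 (denominator *n* − 1) over its non-missing probes.
   This is the normalization step of the method: any per-array *affine*
   transformation of the log intensities — additive background offset,
   multiplicative gain on the log scale — is removed exactly, which the
   test suite asserts to 1e-9. What it does *not* remove: intensity-
   dependent (non-linear) distortions, which would require loess-type
   normalization that is deliberately out of scope.

3. **Z-ratio.** For comparison A vs B, each probe's difference of
   group-mean Z-scores is divided by the sd (denominator *n* − 1) of
   those differences across all probes in the comparison. Two
   consequences used by the tests: the Z-ratio vector has sd exactly 1 by
   construction, and `zratio(A,B) = -zratio(B,A)` exactly. If every probe
   has a zero group-mean difference, all Z-ratios are defined as 0.

4. **Five-criterion selection.** A probe is significant only if all hold
   simultaneously (`selection_thresholds()` defaults): z-test p ≤ 0.05,
   |Z-ratio| ≥ 1.5, BH FDR ≤ 0.30, average Z-score over the compared
   samples ≥ 0, one-way ANOVA p ≤ 0.05 across *all* design groups.

The per-probe z-test treats the Z-ratio as a standard normal deviate,
which the construction enforces marginally across probes under the null;
under a global null simulation the fraction of probes with p ≤ 0.05 sits
at 0.05 within binomial error, which the acceptance checks verify.

### Interpretation choices that were genuinely open

- **"Average Z-score not negative."** We read this as: the mean Z-score
  over all samples of the two compared groups must be ≥ 0 — i.e. the
  probe is expressed at or above the array median on average. It is an
  *expression filter*, not an effect-size criterion, and it is switchable
  (`require_nonneg_avg_z = FALSE`). The alternative reading (averaging
  Z-ratios across comparisons) would make the criterion depend on which
  other comparisons were run, which we rejected for locality.
- **FDR procedure.** No specific estimator is mandated by the method's
  description; we use Benjamini–Hochberg on the comparison's z-test
  p-values — the default, monotone, assumption-light choice. Ties in p
  receive identical q.
- **z-test.** Defined as the two-sided normal tail of the Z-ratio; this
  is the only test consistent with a per-probe z statistic after the
  sd-1 normalization.
- **ANOVA scope.** Computed on Z-scores across all design groups (not
  only the compared pair), so the criterion asks whether the probe varies
  anywhere in the design. It is computed row-wise in closed form
  (per-group sums and sums of squares, then the F tail probability); the
  suite cross-checks it against `stats::oneway.test(var.equal = TRUE)`
  probe by probe.
- **Fold change.** Ratio of raw group-mean intensities in the signed
  convention (+r for r ≥ 1, −1/r otherwise), computed on the raw scale
  as reported figures usually are. Note that raw-scale folds are *not*
  protected by the normalization, so under per-array effects they
  scatter around the planted truth; the Z-ratio carries the inference.
- **Missing values.** Any probe missing a value in a compared group is
  excluded from that comparison and reported in an attribute — no
  imputation, because no imputation rule is part of the method.

## PAGE enrichment

`page_enrichment()` scores a gene set of *m* members with data as
`Z = (Sm − μ)√m / δ`, with μ and δ computed once per comparison over the
full Z-ratio vector (intersection semantics: set members absent from the
array are ignored). The default `min_size = 10` reflects where the
central-limit normal approximation for a set mean becomes acceptable;
below that the p-values are anticonservative. q-values are BH across the
scored sets of the comparison. `geometric_average_change()` summarizes
signed fold changes as the geometric mean of magnitudes signed by the
mean signed log-magnitude, returning +1 in the perfectly balanced case
(no net change).

## Venn partitioning and reversal genes

`partition_signed()` partitions exactly three signed gene lists into the
seven disjoint Venn regions, separately for up- and down-regulated genes;
a gene up in one comparison and down in another legitimately appears in
both direction-specific diagrams, which is why the up and down tallies
are reported as separate paired counts. `reversal_genes()` returns
`(a.up ∩ b.down) ∪ (a.down ∩ b.up)` — the "treatment reverses injury"
signature. Counts are gene-level when the matrix has been collapsed with
`collapse_to_genes()` (per gene, the probe with the highest mean log
intensity — a deterministic standard rule); otherwise probe-level.

## qPCR (Pfaffl) and behavior

`pfaffl_ratio()` implements `R = E_t^ΔCt_t / E_ref^ΔCt_ref` with ΔCt
defined as control mean minus treated mean, so R > 1 means up-regulation
in the treated group. Efficiencies default to 2.0 (perfect doubling) when
no standard curve is supplied, and `efficiency_from_dilution()` converts
a standard-curve slope when one is. With E = 2 for both genes the ratio
reduces exactly to 2^(−ΔΔCt). SEM is computed over per-sample ratios
(each sample against the control-group mean Ct), and the group test is an
unpaired Student t-test (equal variances) on per-sample log-ratios —
log because Ct noise is additive in cycles, hence multiplicative in
expression.

`preference_index()` is `(t_novel − t_familiar)/(t_novel + t_familiar)`;
trials with zero total exploration are flagged `NA` rather than dropped
silently. `group_anova_lsd()` runs the omnibus one-way ANOVA and Fisher
LSD pairwise tests from the pooled MSE with N − k df, unadjusted, gated
by default on a significant omnibus (Fisher's protected procedure,
overridable) — LSD p-values therefore are never above their Bonferroni
counterparts, which the suite asserts.

## What the synthetic generator emulates — and what it does not

`simulate_expression()` draws raw intensities as
`10^(offset_j + gain_j·(baseline_i + log10(fold_ig) + noise_ij))`:

| parameter | default | meaning |
|---|---|---|
| `n_probes` | 25000 | array size of the emulated BeadChip design |
| `groups` | 4 × 5 | sham / PHEN / mTBI / mTBI_PHEN, n = 5 |
| `baseline_mean`, `baseline_sd` | 2.5, 0.5 (log10) | log-normal intensity spectrum centred near a few hundred units |
| `array_offset_sd` | 0.1 (log10) | per-array additive offset ≈ ±26% intensity scaling |
| `array_scale_sd` | 0.05 | per-array gain on the log scale (dynamic-range distortion) |
| `noise_sd` | 0.1 (log10) | within-group biological + technical noise |

Array effects are affine in log space *by design*: they are exactly the
distortions per-array Z-scoring exists to remove, so null simulations
with them present prove the normalization does its job. Planted effects
are specified as per-group fold changes; an optional `baseline` column
pins a planted probe's abundance. Recovery studies pin planted probes at
baseline 3.0 (mean + 1 sd, i.e. clearly expressed transcripts): the
non-negative average-Z criterion is an expression filter that discards
low-abundance probes *by design*, so sensitivity is a property of the
detection chain only over expressed probes — planting effects at random
abundances would measure the expression filter instead.

Not emulated: bead-level Illumina noise, detection p-values,
intensity-dependent (non-affine) array distortions, probe-specific
variance heterogeneity, and correlated probe blocks. Passing recovery
tests therefore show the chain is correct and calibrated under its own
assumptions; they do not certify behavior under real-array artifacts the
model excludes.

`simulate_qpcr()` shifts treated Cts by −log_E(ratio) so the Pfaffl
arithmetic recovers planted ratios exactly at zero noise;
`simulate_behavior()` draws indices per group and back-converts to
exploration times at fixed total time, so the index is recovered exactly.

## Numerical and degenerate-input conventions

- sd uses denominator *n* − 1 everywhere.
- Zero-variance array → error naming the sample; all-zero group-mean
  differences → all Z-ratios 0; all-identical behavioral values → ANOVA
  flagged degenerate (exact zero within-group sum of squares, tested on
  the raw values, not the aov rounding).
- BH ties get identical q; region and reversal outputs are sorted for
  determinism; reruns of `run_pipeline()` are byte-identical (no RNG).
- qPCR efficiencies are validated to (1, 2]; a zero mean intensity in a
  fold-change denominator yields `NA`, not an error.

## Problem sizes used by the checks

The calibration and recovery studies run at 5,000 probes × 20 arrays
over 20 seeds (null level, five-criterion null behavior, recovery of 100
planted two-fold probes), 10,000 random size-20 sets for the PAGE null,
and 20-probe fixtures for the brute-force oracle comparisons. These sizes
give binomial/CLT error bars comfortably inside the asserted bands while
keeping a full run in seconds.

## Known limitations

- With the FDR ceiling at 0.30, Benjamini–Hochberg itself implies a
  ≈ 0.3 probability of at least one (single-probe) false discovery per
  comparison under a *global* null — "zero discoveries on null data" is
  therefore true only on average, not per run; the null behavior to
  expect is a tiny discovery *rate*, not a guaranteed empty list.
- The z-test assumes the Z-ratio is standard normal per probe; this is a
  marginal, not per-probe, property, and heavy probe-variance
  heterogeneity would distort per-probe calibration (no moderated
  variance estimation is attempted, by scope).
- Raw-scale fold changes are unprotected against array effects (above).
- PAGE p-values assume set members are exchangeable draws from the
  Z-ratio vector; correlated gene sets inflate |Z|.
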