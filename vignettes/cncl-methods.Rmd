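---
title: "Methods: signature derivation, stemness scoring and downstream analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature derivation, stemness scoring and downstream analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cncl)
```

## The problem

Breast cancer cell populations contain cells along an axis from an
epithelial, non-stem-like state (NS/E) to a mesenchymal, cancer-stem-cell-like
state (CS/M). The two states differ in drug sensitivity and in prognosis, and
cells move between them (epithelial-mesenchymal transition and its reverse),
notably under therapy pressure. `cncl` implements a transcriptomic toolkit
around this axis:

1. **Signature derivation** — a small directional gene list separating the two
   states, built from two independently labeled expression datasets.
2. **Categorical classification** — complete-linkage hierarchical clustering
   of samples on the signature genes.
3. **Continuous stemness score** — per-sample Pearson correlations to median
   phenotype centroids; the score is their difference.
4. **Plasticity tracing** — phenotype switches in paired (e.g. pre/post
   therapy) designs.
5. **Drug response** — a six-model logistic ensemble producing IC50 and
   activity-area summaries, plus a phenotype-differential drug screen.
6. **Survival** — a multiple-cutoff log-rank scan (LRMC) for dichotomizing
   the score, and multivariate Cox regression.

All inputs can be simulated with planted ground truth, so every stage is
testable without external downloads.

## Signature derivation

Given two log2-scale expression matrices with CS/M / NS/E labels,
`derive_signature()` runs, per dataset, gene-wise Welch t-tests and keeps the
`top_n = 200` most significant genes at `initial_p = 0.05`, ranked by p-value
(the ranking key is configurable to absolute fold change; the choice matters
only near the list boundary). The two lists are intersected, keeping features
whose direction of change agrees in both datasets; survivors must then show a
linear fold change of at least `min_fold = 3` **and** `p < max_p = 2e-4` in
*both* datasets. Fold change is computed on anti-logged group means of the
log2 data, `2^|mean difference|` — a geometric-mean fold, the natural choice
on RMA-style data.

Finally a coherence screen: within each direction arm, a gene is retained only
if its mean absolute pairwise Pearson correlation with the other retained
same-direction genes is at least `min_intercorr = 0.5` in both datasets. This
operationalizes the requirement that signature genes move together; 0.5 is a
conventional "moderate-to-strong" threshold, and single-gene arms pass
vacuously. The screen is applied once (not iterated to a fixed point): with a
planted co-varying signature one pass removes exactly the incoherent tail, and
iteration would make membership depend on removal order.

The fold/p filters are applied per dataset (both must pass) rather than on
pooled statistics; pooling across cohorts with different platforms would mix
unequal variances into one test.

```{r derive}
simA <- generate_expression(expression_sim_config(seed = 11))
simB <- generate_expression(expression_sim_config(seed = 22))
sig <- derive_signature(simA$matrix, simA$labels, simB$matrix, simB$labels)
sig[, c("feature_id", "direction", "fold_a", "p_a")]
```

## Classification by clustering

`hcluster()` z-scores each signature gene across samples, computes Euclidean
distances between samples and applies complete-linkage agglomeration
(`stats::hclust`), cut into `k` flat clusters. Per-gene standardization
precedes clustering so that no single high-variance gene dominates the
distance; it can be disabled. `label_clusters()` orders the clusters by mean
*polarity* — mean standardized expression of the up-in-CS/M genes minus the
up-in-NS/E genes — and labels the top cluster CS/M and the bottom NS/E.

Two routes to an intermediary (I) call are offered, because visual
two-cluster heatmap classification has no canonical rule for borderline
samples: either cut at `k = 3` and label the middle-polarity cluster I, or
use the score-based band of `call_from_score()`. Both are explicit options;
neither is applied silently.

Exactly tied cluster polarity means (e.g. all-identical samples) raise a
typed error rather than an arbitrary label. Equal-height merge ties inside
the agglomeration are resolved by `stats::hclust`'s deterministic order, so
results are reproducible across platforms; flat partitions and merge heights
are what downstream code consumes, and both are tie-order invariant for
generic (continuous) data.

## The stemness score

`build_centroids()` standardizes each signature gene across the reference
cohort and takes the per-group median, giving a CS/M and an NS/E centroid
vector. "Standardization" here is a full z-score (center and scale). Scaling
is required, not cosmetic: the score correlates *across genes* within one
sample, so genes must be on a common scale for the centroid medians to be
comparable; a center-only mode is provided for data already on a common
scale.

`score_sample()` computes Pearson correlations of a sample's standardized
signature vector with both centroids — the sample-as-vector orientation, the
only one in which "correlate a sample to a reference matrix" is defined — and
the stemness score is

$$SS = \Delta(r) = r_{CS/M} - r_{NS/E} \in [-2, 2],$$

negative values indicating a more epithelial phenotype. The bound of 2 is
structural (each correlation lies in $[-1, 1]$) and is asserted at run time.
The default categorical cutoff is 0; cohort-specific cutoffs should come from
the LRMC scan below, not be hand-picked. At the cutoff boundary the call is
NS/E (a sample must *exceed* the cutoff to be called CS/M); a band of
half-width `b` around the cutoff yields I calls.

Test cohorts are standardized against their own per-gene means and standard
deviations by default. An alternative would be anchoring to the reference
cohort's distribution; self-standardization was chosen as the default because
cross-platform intensity scales are not comparable, and the anchored mode is
available by standardizing externally and calling `score_samples()` with
`standardize = FALSE`.

For qPCR-derived data, use $-\Delta C_t$ values (reference-gene–subtracted,
sign-flipped so larger means more expressed) as the expression scale before
standardization; `delta_delta_ct()` provides the standard relative
quantification $2^{-\Delta\Delta C_t}$.

`trace_plasticity()` joins paired pre/post score tables and flags call
changes; pairs with an I call are excluded from the switch flag by default
(an indeterminate call cannot evidence a switch).

## Dose-response ensemble

All six models are the four-parameter logistic

$$v(d) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
{1 + (d/\mathrm{IC}_{50})^{h}}$$

with constraints: the "3-parameter" family fixes the Hill slope at $h = 1$,
and each family comes unconstrained, with top fixed at 100%, or with bottom
fixed at 0%. The naming follows screening convention even though, e.g., the
"4-parameter Top 100" model has three free parameters — the "4" counts the
logistic's parameters, not the free ones. Each model is fitted by
Levenberg-Marquardt least squares with the midpoint parameterized as
$\log_{10} \mathrm{IC}_{50}$, initialized from the data (bottom/top from the
observed range, midpoint from the half-range crossing) with a three-point
multi-start over the Hill slope. The selected model minimizes the residual
standard error $\sqrt{RSS/(n-p)}$; dividing by residual degrees of freedom
penalizes free parameters, which makes the comparison meaningful across
models of different complexity. The reported IC50 is the fitted curve
midpoint (relative IC50). When the fitted asymptote span collapses or the
midpoint falls beyond the highest tested dose, the IC50 is reported as a
right-censored "> max dose" sentinel.

The activity area is the mean per-dose inhibition
$AA = \tfrac1n \sum_d \max(0, 1 - v_d/100) \in [0, 1]$ over the distinct
tested doses (replicates averaged first); a trapezoid-on-log-dose variant is
available. The mean-over-doses convention was chosen as the default because
it is exact for hand-checkable cases and insensitive to dose-grid spacing
when the grid is log-uniform.

**Identifiability limitation.** For shallow curves ($h \approx 0.5$) the
asymptotes, slope and midpoint trade off against each other: with a 10-dose
half-log series, quadruplicate wells and 2% viability noise, the ensemble's
IC50 estimate has a median sampling error of roughly 6% (the single-parameter
floor, all other parameters known, is about 2.5%). There is no model in the
six with both asymptotes fixed and the slope free, so this gap is inherent to
the ensemble. Steeper curves ($h \ge 1$) recover IC50 to 2-3% under the same
conditions. Users screening shallow-response drugs should widen the dose
range or increase replication.

`screen_differential_drugs()` compares a sensitivity metric between CS/M and
NS/E cell lines per drug with Welch t-tests. Direction ("more sensitive
phenotype") honors the metric's sense: higher activity area but *lower* IC50
means more sensitive.

## Survival analyses

`lrmc_scan()` dichotomizes the score at candidate cutoffs — score percentiles
from the 10th to the 90th in steps of 5 by default — subject to both groups
retaining at least 10% of the cohort, and runs a two-group log-rank test at
each. The reported best cutoff minimizes p. Scanning cutoffs is a
multiple-testing procedure and the naive minimum p is anti-conservative, so a
permutation adjustment is offered (scores permuted against the survival
columns; the adjusted p is the fraction of permutation minima at or below the
observed minimum, with the +1 correction). Both the naive and adjusted values
are reported side by side. The percentile grid with a group-size guard was
chosen over a fixed numeric grid so the scan adapts to each cohort's score
distribution and never tests cutoffs that isolate a handful of patients.

`cox_multivariate()` wraps `survival::coxph` for the score-derived group plus
clinical covariates, returning hazard ratios with confidence intervals;
non-convergence and separation surface as typed errors rather than silent
warnings. Endpoints are generic `(time, event)` pairs — endpoint semantics
(overall vs relapse-free survival) are the caller's configuration.

## The synthetic-data generators

`generate_expression()` emulates the structure the pipeline assumes: log2
RMA-like intensities (per-gene baselines around 8 ± 1.5), two sample groups,
a planted directional signature (defaults: 8 genes up in CS/M, 7 up in NS/E)
shifted by `log2_effect` between groups, additive Gaussian noise on the log2
scale, and same-arm co-expression through one shared standard-normal latent
factor per arm and sample with weight `w` (`within_arm_corr`); gene noise is
$w z_{arm} + \sqrt{1-w^2}\,\varepsilon$, so total noise variance is
`noise_sd`² and the pairwise within-arm gene correlation is $w^2$ (0.49 at
the default $w = 0.7$). Defaults — `log2_effect = 3`, `noise_sd = 0.25`, 20
samples per group — represent a cleanly separable cell-line panel: the
derivation filters require a 3-fold linear change, and an 8-fold planted
effect with small noise sits above that filter the way genuinely
signature-worthy genes do. `generate_paired_switch()` redraws each sample at
the second timepoint from its (possibly switched) group's model, holding the
per-gene baselines fixed, so pre/post differences carry both resampling noise
and any planted switch.

`generate_dose_response()` samples the 4PL curve with Gaussian well noise,
truncated to [-10, 130]% viability to mimic plate artifacts — fitted curves
must cope with slightly out-of-range data, as real assays produce.
`generate_survival()` draws exponential event times under proportional
hazards with independent exponential censoring.

What the generators do **not** emulate: probe-level microarray physics, batch
and lab effects, RNA-seq count overdispersion, correlated censoring, or
signature genes whose effect sizes differ gene-to-gene. Passing tests on this
synthetic data therefore demonstrate the correctness of the computations and
the internal consistency of the pipeline — not that any particular real
cohort separates as cleanly.

## Numerical and testing choices

Degenerate inputs have defined behavior throughout: zero-variance groups in
the Welch test give $p = 1$ (equal means) or the smallest representable
positive p (unequal); constant sample vectors or centroids are refused rather
than yielding NaN correlations; tied cluster polarity is an error; a cohort
with no events refuses survival testing. Expression files are validated
cell-by-cell with errors naming the offending row and column, and missing
values in the signature submatrix are an error — a 15-gene Pearson
correlation cannot absorb silent gaps.

The test suite checks the implementation against independent oracles:
complete linkage against exhaustive pair enumeration (n ≤ 6), Pearson/median
against textbook formulas, the Welch test against its closed form, the
log-rank statistic against the O−E/variance sums, and the dose-response
ensemble against a grid-search-plus-polish refit. Simulation-based checks use
cohorts of 40 samples (500 per group for mean-convergence checks), 200
replicates for type-I error, and 200 patients for cutoff recovery — sizes at
which the planted effects are decisively detectable while the whole suite
runs in well under a minute.
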