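# cncl

Derivation and application of a two-phenotype stemness signature for breast
cancer transcriptomics: separate **CS/M** (cancer-stem-cell-like,
mesenchymal) from **NS/E** (non-stem-cell-like, epithelial) samples, score
them continuously, and carry the score through drug-response and survival
analyses.

The package is for computational biologists working with bulk (or
pseudo-bulked single-cell) expression matrices who need:

- a **directional gene signature** derived from two independently labeled
  cohorts (per-gene Welch t-tests, top-200 intersection with direction
  concordance, fold ≥ 3 and p < 2×10⁻⁴ in both cohorts, within-arm
  co-expression screen);
- **categorical phenotype calls** by complete-linkage hierarchical clustering
  on the signature genes (Euclidean distance, per-gene z-scores);
- a **continuous stemness score** per sample,
  *SS = Δ(r) = r<sub>CS/M</sub> − r<sub>NS/E</sub>*, the difference of
  Pearson correlations between the sample's standardized signature profile
  and the median CS/M and NS/E centroids of a reference cohort
  (Δ(r) ∈ [−2, 2]; negative = more epithelial);
- **plasticity tracing** of phenotype switches in paired pre/post designs;
- **dose-response fitting** with the six-model logistic ensemble (3/4
  parameter × unconstrained / top = 100 / bottom = 0, lowest residual
  standard error wins) yielding IC50 and activity area, plus a
  phenotype-differential drug screen;
- **survival tools**: a multiple-cutoff log-rank scan (LRMC) with optional
  permutation adjustment, and multivariate Cox regression.

Synthetic-data generators with planted ground truth
(`generate_expression()`, `generate_paired_switch()`,
`generate_dose_response()`, `generate_survival()`) make the full pipeline
reproducible and testable offline.

## Worked example

```r
library(cncl)

# two labeled cohorts with a planted 8-up/7-down signature
simA <- generate_expression(expression_sim_config(seed = 11))
simB <- generate_expression(expression_sim_config(seed = 22))

sig <- derive_signature(simA$matrix, simA$labels, simB$matrix, simB$labels)
nrow(sig); table(sig$direction)
#> [1] 15
#>
#> up_in_CS/M up_in_NS/E
#>          8          7

# classify an independent cohort by clustering, then score it
simC <- generate_expression(expression_sim_config(log2_effect = 2,
                                                  noise_sd = 0.5, seed = 33))
calls <- classify_phenotype(simC$matrix, sig)
cen <- build_centroids(simA$matrix, simA$labels, sig)
scores <- score_samples(simC$matrix, cen)
head(scores, 3)
#>   sample_id     csm_r      nse_r  delta_r call
#> 1      S001 0.9725922 -0.9717237 1.944316 CS/M
#> 2      S002 0.9728960 -0.9719185 1.944814 CS/M
#> 3      S003 0.9722080 -0.9672574 1.939465 CS/M
mean(scores$call == simC$labels[scores$sample_id])   # accuracy vs truth
#> [1] 1

# dose-response: six-model ensemble fit
tbl <- generate_dose_response(dose_response_sim_config(ic50 = 1, noise_sd = 5,
                                                       seed = 44))
fit_dose_response(tbl$dose_uM, tbl$viability_pct)
#> Dose-response fit
#>   model:        3P_bottom0
#>   IC50 (uM):   1.06698
#>   activity area: 0.3781
#>   residual SE:  5.408

# survival: planted hazard ratio of 3 for CS/M
sv <- generate_survival(survival_sim_config(n_per_group = 200,
                                            hazard_ratio = 3, seed = 55))
sv$csm <- as.integer(sv$group == "CS/M")
cox_multivariate(sv, "csm")
#>   term       hr ci_lower ci_upper      p_value
#> 1  csm 2.905996 2.314215 3.649105 4.223061e-20
```

The signature table recovers exactly the 15 planted genes with correct
directions; the score-based calls match the planted labels; the ensemble
recovers the planted IC50 of 1 µM within ~7% at 5% well noise; and the Cox
hazard ratio estimate brackets the planted value of 3.

See `vignettes/cncl-methods.Rmd` for the model details, parameter defaults
and their rationale, and known limitations.

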