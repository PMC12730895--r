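# motiscore

A transparent multi-omics tumor immunogenicity score for immune checkpoint
inhibitor (ICI) outcome prediction.

Immunotherapy response correlates with many molecular properties — tumor
mutation burden (TMB), neoantigen load, T-cell infiltration, antigen
presentation integrity, immune gene expression — but no single biomarker is
reliable on its own, and black-box multi-omics models are hard to act on in
a molecular tumor board. `motiscore` implements the opposite design point: a
composite score whose every term is inspectable. For users with paired
tumor/normal WES and bulk RNA-Seq call sets (variant/CNV tables, TCR
clonotype reports, neoantigen candidate lists, HLA genotypes, count
matrices), the package derives eight candidate biomarkers per sample,
selects the informative ones on a RECIST-labeled discovery cohort, and
scores samples as a weighted sum of z-scores:

```
score(x) = Σ_b  w_b · (x_b − μ_b) / σ_b ,    w_b = −log10(p_b) / Σ_c −log10(p_c)
```

Candidates are screened by two-sided Mann–Whitney U (continuous) or
Fisher's exact (categorical) tests at α = 0.05, pruned for mutual Spearman
correlation |ρ| > 0.5 (the weaker effect loses), and weighted by their
normalized −log10 selection p-values. A Youden-index cutoff on the
discovery ROC curve dichotomizes the score into high/low for survival
analysis (Kaplan–Meier, univariate Cox with Breslow ties).

The package is tidyverse-native: functions take data frames and return
tibbles, fitted models have `tidy()`/`glance()` methods, and result objects
have `autoplot()` methods.

## Worked example

Fit the score on a synthetic discovery cohort (the generator plants a
melanoma-like design: n = 225, 98 responders, correlated TMB/neoantigen
burden, moderate planted effects), then score new samples:

```r
library(motiscore)

cohort <- simulate_panels(sim_config(seed = 42))
fit <- fit_motiscore(cohort, seed = 42)
fit
#> Immunogenicity score fit
#>   discovery n = 225 (98 responders), AUC = 0.775
#> Multi-omics immunogenicity score model
#>   4 selected biomarker(s); cutoff = 0.127
#> # A tibble: 4 × 5
#>   biomarker     weight    p_value   mean     sd
#>   <chr>          <dbl>      <dbl>  <dbl>  <dbl>
#> 1 tmb            0.233 0.000132   10.5   16.6
#> 2 tcr_entropy    0.307 0.00000795  4.43   1.53
#> 3 response_flag  0.178 0.00109     0.129  0.336
#> 4 pdl1_cpm       0.282 0.0000208  14.2   17.3
```

Four of the eight candidates survive selection; the neoantigen burden is
dropped as the weaker member of its ρ ≈ 0.9 pair with TMB, and each weight
is the normalized −log10 of the biomarker's selection p-value (TCR
repertoire entropy, with the smallest p, carries the largest weight). The
means and SDs are the discovery-cohort standardization constants, and the
cutoff is the Youden-optimal threshold on the discovery ROC.

```r
new_panels <- simulate_panels(sim_config(n_samples = 4, responder_fraction = 0.5, seed = 99))
score_samples(new_panels, fit$model)
#> # A tibble: 4 × 3
#>   sample_id  score score_class
#>   <chr>      <dbl> <fct>
#> 1 S001       1.38  high
#> 2 S002      -0.149 low
#> 3 S003      -0.295 low
#> 4 S004      -0.324 low
```

A score is the weighted sum of the sample's biomarker z-scores (0 = exactly
at the discovery means); `score_class` compares it against the fitted
cutoff (ties classify low). Models serialize to diffable JSON with
`save_model()` / `load_model()`.

Biomarkers are derived from raw call sets with the `compute_tmb()`,
`neoantigen_burden()`, `tcr_entropy()`, `resistance_flag()`,
`response_flag()`, `hed()`, `expression_markers()` family and assembled per
sample with `build_panel()`; QC lives in `sample_qc()`, `variant_qc()`,
`cnv_qc()` and the target-region functions. Evaluation tools are
`roc_curve()`/`youden_cutoff()`, `kaplan_meier()`, `cox_univariate()` and
`stratified_response_table()`. A thin CLI (`exec/motiscore`) exposes
`fit`/`score`/`evaluate`/`simulate` over panel and clinical TSVs.

See `vignettes/motiscore-methods.Rmd` for the full model description,
parameter defaults and the design decisions behind them.

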