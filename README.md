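# texsurv

Filtration-histogram CT texture analysis with cutoff-based survival
inference, for imaging researchers who want to test whether first-order
tumor heterogeneity on contrast-enhanced CT stratifies overall survival —
and for methodologists who want the whole chain (including its known
pitfalls, such as cutoff-optimization optimism) reproducible on synthetic
data.

## What it computes

**Texture.** A Laplacian-of-Gaussian band-pass filter highlights image
structure of radius SSF mm (SSF 0 = no filtration; 2 = fine … 6 = coarse),

```
LoG(r) = -1/(πσ⁴) (1 - r²/2σ²) exp(-r²/2σ²),   σ = SSF/√2,
```

sampled per pixel, truncated at 4σ and shifted to zero sum (zero DC gain).
After filtering the full image (FFT, reflection padding), six first-order
statistics are taken over the ROI: mean, sample SD, MPP (mean of pixels
> 0), entropy (−Σ pᵢ log₂ pᵢ over 1-HU bins), skewness g₁ = m₃/m₂^{3/2}
and excess kurtosis g₂ = m₄/m₂² − 3.

**Survival.** Features are compared between survivors and non-survivors
(Mann-Whitney U; exact p by enumeration for n₁+n₂ ≤ 12), dichotomized at
the ROC cutoff maximizing Youden's J for the rule "value < cutoff ⇒
death", and carried into Kaplan-Meier curves, log-rank tests, and Cox
proportional-hazards models (Efron ties, Wald 95% CIs) — univariate and
bivariate (feature + M stage). Spearman matrices screen feature
collinearity; two-way random-effects absolute-agreement ICCs with
qualitative bands quantify reader agreement.

**Synthetic data.** Tumor phantoms (enhancing rim, optional necrotic
core, Gaussian noise) and Weibull proportional-hazards cohorts with known
log-hazard effects and censoring provide ground truth for every stage.

## Worked example

```r
library(texsurv)

# a full synthetic study: cohort -> phantoms -> features -> survival tables
cfg <- run_config(seed = 11, n_subjects = 150, scales = c(0, 2, 6),
                  features = c("mean", "mpp"))
study <- run_all(cfg)

study$survival$cutoffs
#> # A tibble: 2 × 9
#>   feature cutoff   auc youden_j sensitivity specificity direction n_events n_nonevents
#>   <chr>    <dbl> <dbl>    <dbl>       <dbl>       <dbl> <chr>        <int>       <int>
#> 1 mean      76.0 0.560    0.210       0.473       0.737 lower           55          95
#> 2 mpp       98.1 0.546    0.216       0.564       0.653 lower           55          95

dplyr::filter(study$survival$bivariate_cox, feature == "mpp", !is.na(hazard_ratio))
#> # A tibble: 2 × 9
#>   feature term    level      n hazard_ratio conf_low conf_high    p_value note
#>   <chr>   <chr>   <chr>  <int>        <dbl>    <dbl>     <dbl>      <dbl> <chr>
#> 1 mpp     m_stage 1         64         3.67     2.03      6.64 0.0000172  NA
#> 2 mpp     group   <98.05    64         3.74     2.11      6.66 0.00000690 NA
```

The cutoff table shows, per feature, the ROC-optimal threshold (in
feature units), its AUC for predicting death, and the attained Youden J.
The bivariate Cox table reads like a standard survival table: subjects
whose unfiltered MPP fell below 98.1 HU carried a 3.7-fold death hazard
(95% CI 2.11–6.66), independent of M stage — recovering the threefold
low-MPP hazard built into this simulated cohort through the estimated
cutoff. `autoplot(km_curve(...))` draws the corresponding KM
curves, and `run_agreement()` produces the ICC table between two readers.

A thin command-line interface over the same functions lives at
`inst/cli/texsurv.R` (subcommands `simulate-phantoms`, `simulate-cohort`,
`extract`, `survive`, `agreement`, `run-all`, all driven by a YAML config
plus `--seed`/`--out` overrides).

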