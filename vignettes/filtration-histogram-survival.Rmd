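---
title: "Filtration-histogram CT texture analysis and cutoff-based survival inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filtration-histogram CT texture analysis and cutoff-based survival inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(texsurv)
```

## The problem

Aggressive tumors such as inflammatory breast cancer are routinely staged
with contrast-enhanced chest CT, but their diffuse growth makes them
non-measurable under diameter-based response criteria. First-order texture
analysis offers a simple imaging biomarker instead: quantify the
heterogeneity of the tumor's attenuation histogram and ask whether it
stratifies overall survival (OS). `texsurv` implements this chain end to
end — band-pass filtration, histogram statistics, ROC-derived
dichotomization, Kaplan-Meier / log-rank / Cox inference, and
intraclass-correlation reliability — together with synthetic generators
that make every stage testable without patient data.

## The filtration-histogram model

The texture half follows the filtration-histogram technique. A
Laplacian-of-Gaussian (LoG) band-pass kernel highlights blob-like image
structure of a characteristic radius, the *spatial scale filter* (SSF) in
mm; SSF 0 denotes no filtration, SSF 2 "fine" through SSF 6 "coarse"
texture. The continuous kernel is

$$\mathrm{LoG}(r) = -\frac{1}{\pi\sigma^4}
  \Bigl(1 - \frac{r^2}{2\sigma^2}\Bigr)\,e^{-r^2/(2\sigma^2)},$$

sampled at pixel centres, truncated at $4\sigma$, and shifted to sum to
exactly zero (zero DC gain), so constant images filter to zero and all
filtered statistics are invariant to HU offsets.

**SSF-to-σ mapping.** The scale parameter is defined only as "the radius
in mm of the highlighted features"; the proprietary software's exact
mapping is unpublished. We fix the natural geometric convention: the
kernel's zero-crossing radius equals the SSF value, i.e.
$\sigma = \mathrm{SSF}/\sqrt{2}$. Numeric equality with any particular
commercial implementation is therefore not claimed — feature *rankings*
and downstream inference, not absolute filtered values, are the object of
interest.

The whole image is filtered (FFT convolution, symmetric reflection padding
at the borders) before the ROI mask is applied, so ROI statistics carry no
artificial edge response from the ROI boundary. Responses smaller than
$10^{-10}$ of the input scale are snapped to zero so the zero-DC property
holds literally in floating point; this matters because the
mean-of-positive-pixels statistic tests strict positivity.

Within the ROI (at least 9 pixels), six statistics are computed per scale:
mean; sample SD ($n-1$); MPP (mean of pixels strictly $> 0$, `NA`-flagged
when no pixel is positive); first-order entropy
$-\sum_i p_i \log_2 p_i$ over 1-HU-wide bins (values rounded to the
nearest bin centre, empty bins excluded; the bin width is exposed as
`bin_width` because the commercial binning is unpublished); skewness
$g_1 = m_3/m_2^{3/2}$ and excess kurtosis $g_2 = m_4/m_2^2 - 3$ from
population central moments, `NA`-flagged when $m_2 = 0$. Undefined values
are always flagged, never silently zeroed. Pixel spacing must be isotropic
in-plane; anisotropic rasters are rejected rather than silently resampled.
Analysis is single-slice 2D, mirroring manual ROI placement at the
tumor's largest cross-section.

```{r features}
ph <- generate_phantom(phantom_spec(noise_sd = 10, core_fraction = 0.4, seed = 1))
texture_features(ph, scales = c(0, 2, 6))
```

## Survival inference

Features are compared between survivors and non-survivors with the
Mann-Whitney U test (midranks for ties; exact p by full enumeration when
$n_1+n_2 \le 12$, else the tie-corrected normal approximation without
continuity correction), after a mean-centred Levene check of variance
homogeneity. Each candidate feature is then dichotomized at the ROC-optimal
cutoff: every observed value is scanned as a threshold for the rule
"value < cutoff predicts death", and the cutoff maximizing Youden's
$J = \text{sensitivity} + \text{specificity} - 1$ is chosen, ties broken
toward the larger cutoff (the more inclusive low group). The "lower value
predicts death" orientation is the prognostic direction for post-contrast
attenuation (necrotic, hypo-enhancing tumors do worse); it can be flipped
per feature. Youden maximization is one standard reading of "ROC-optimal";
the criterion sits behind `optimal_cutoff()` so alternatives can be
swapped in.

Groups are compared with Kaplan-Meier curves and the unweighted log-rank
test, and effect sizes come from Cox proportional-hazards models (Efron
tie correction, Newton-Raphson with up to 100 iterations; Wald 95% CIs and
p-values). Because the six features are strongly collinear (screened with
Spearman rank correlations), multivariable adjustment is deliberately
limited to *bivariate* models — one dichotomized feature plus M stage —
rather than a joint model over all features. Significance is $\alpha =
0.05$ with no multiplicity correction by default, reproducing the
single-study analysis convention; a Holm flag (`p_adjust = "holm"`) is
available. Subjects with undefined feature values are excluded listwise
per analysis with logged counts. Monotone likelihood (a group with no
events) and non-convergence are flagged, never returned silently.

Reliability between two readings is the two-way random-effects,
absolute-agreement, single-measure ICC computed from the ANOVA mean
squares; the consistency form is available via `type = "consistency"`.
ICC values map to the conventional qualitative bands (1 perfect,
0.81–0.99 almost perfect, 0.61–0.80 substantial, 0.41–0.60 moderate,
0.21–0.40 fair, ≤ 0.20 slight). The printed bands do not tile the whole
interval, so gap values (e.g. 0.995) are assigned to the nearest lower
band.

## What the synthetic generators emulate

`generate_phantom()` renders a post-contrast tumor slice as an enhancing
disc (default 100 HU) with an optional concentric hypodense necrotic core
(default 20 HU over 40% of the radius), additive Gaussian noise truncated
to the signed 16-bit raster range, and a uniform background; the ROI is
the exact tumor disc. This reproduces the two features the texture chain
must detect — central necrosis lowering mean/MPP, and noise raising
SD/entropy — and nothing else: no anatomy, no contrast kinetics, no
partial-volume blur, no ROI-placement ambiguity. Phantom-based tests
therefore validate the *measurement chain*, not the clinical
discriminability of real tumors, whose within-group feature spread is far
larger.

`generate_cohort()` draws survival from a Weibull proportional-hazards
model with two binary risk factors: a latent low/high texture group (log
HR `log(3)` by default) and M stage (log HR `log(3.5)`, prevalence 0.39).
A Weibull (rather than exponential) baseline was chosen so shape
misspecification can be probed; shape 1 recovers the exponential case.
Censoring is the minimum of an exponential time (rate 1/48 per month) and
an administrative horizon (157 months). The defaults — baseline scale 150
months, shape 1.2 — were calibrated once against the published profile of
an aggressive breast-cancer cohort: roughly 40% deaths and a median OS
among the deceased near 20 months:

```{r cohort}
cohort <- generate_cohort(cohort_spec(n_subjects = 2000, seed = 1))
c(death_fraction = mean(cohort$event),
  median_os_deceased = median(cohort$os_months[cohort$event == 1]))
```

Each subject also carries a continuous MPP-like `feature` drawn from
group-specific normal distributions (defaults follow published
survivor/non-survivor summaries of post-contrast tumor attenuation,
$N(60.7, 14.9^2)$ vs $N(74.3, 20.8^2)$), for cohort-only exercises of the
cutoff chain. Note the substantial overlap of those distributions: a
dichotomized proxy recovered from this feature is a noisy surrogate of the
latent group, so hazard ratios estimated through it are attenuated — an
intentional, realistic property. For end-to-end recovery experiments the
pipeline instead links phantom appearance to the latent group
(`core_fraction` 0.55 for the low group vs 0.15 otherwise in
`simulate_phantoms()`), giving the cleanly separated features a
measurement-chain test needs. All randomness flows from one explicit seed
per call; no global RNG state is consumed.

## Numerical and design choices

* **Convolution**: FFT with symmetric (edge-including) reflection
  padding; brute-force spatial convolution is used as the test oracle,
  with agreement at $10^{-6}$ on random images.
* **Exact Mann-Whitney**: full enumeration of all
  $\binom{n_1+n_2}{n_1}$ labelings of the pooled midranks when
  $n_1 + n_2 \le 12$; two-sided p is the probability of a U at least as
  far from $n_1 n_2 / 2$ as observed.
* **Cutoff tie-break**: strict `<` defines the low group, and J ties
  resolve to the larger cutoff, so the boundary value always falls in the
  "high" reference group.
* **Cox estimation**: delegated to the `survival` package (Efron ties);
  correctness is pinned by a brute-force partial-likelihood grid search
  and by the exact identity between the log-rank chi-square and the Cox
  score test on tie-free data.
* **Degenerate inputs**: empty dichotomization groups, constant
  covariates, zero between-subject ICC variance, and all-identical ROIs
  are flagged or rejected explicitly.
* **Problem sizes**: simulation-based checks use 100–1000 replicates at
  n = 60–500 (coverage, permutation size, power), sizes at which
  binomial noise on the checked rates is small relative to the asserted
  margins.

## Known limitations

* The SSF↔σ convention, entropy binning, and raw-vs-rescaled filtered
  statistics of commercial texture software are unpublished; numeric
  equality with such software is not claimed.
* Phantoms are radially symmetric and noise is white; spatially
  correlated CT noise and reconstruction-kernel effects are out of scope.
* Cutoff optimization genuinely inflates the type-I error of the
  subsequent log-rank test. On null cohorts (n = 98, ~40% deaths) the
  package's own simulations measure a rejection rate of roughly 14–18% at
  nominal 5%, while a fixed median split holds exactly 5%. Cutoffs should
  be validated on independent data; the package reports the optimism
  rather than hiding it.
* ICC confidence intervals, Bland-Altman analysis, competing risks,
  time-varying covariates, and proportional-hazards diagnostics are not
  implemented.
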