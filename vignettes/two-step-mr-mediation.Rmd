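---
title: "Two-step MR mediation: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step MR mediation: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The problem

Gut-microbiome abundance GWAS, plasma-proteome pQTL panels and disease
GWAS are measured in different cohorts, so causal questions linking them —
*does taxon X raise disease risk, and does it do so by changing the level
of protein M?* — must be answered from summary statistics alone.
`mrmediate` implements the two-sample Mendelian randomization (MR)
machinery for that question end to end: instrument selection,
harmonization, causal-effect estimation, robustness diagnostics, and the
two-step mediation decomposition with its retention gates, plus a
simulator that generates the whole three-trait system with known truth so
every stage can be validated.

## Model and assumptions

For a variant $j$ with exposure association $\hat\gamma_j$ (SE
$\sigma_{x j}$) and outcome association $\hat\Gamma_j$ (SE
$\sigma_{y j}$), the Wald ratio $b_j = \hat\Gamma_j / \hat\gamma_j$
estimates the causal effect of the exposure on the outcome under the
instrumental-variable assumptions (relevance, independence, exclusion
restriction). The package's estimators combine the $b_j$:

* **IVW** — precision-weighted mean
  $\hat\beta = \sum w_j b_j / \sum w_j$ with
  $w_j = \sigma_{y j}^{-2}\hat\gamma_j^{2}$ (first-order weights). The
  default error model is multiplicative random effects: the fixed-effect
  SE $(\sum w_j)^{-1/2}$ is inflated by $\sqrt{\max(Q/(n-1), 1)}$, never
  deflated, so it is at least as conservative as the fixed-effect model.
* **MR-Egger** — weighted regression
  $\hat\Gamma_j = \beta_0 + \beta_1 \hat\gamma_j$ with weights
  $\sigma_{y j}^{-2}$ after orienting every variant to
  $\hat\gamma_j \ge 0$. The slope is robust to directional pleiotropy
  under the InSIDE assumption; the intercept estimates the average
  pleiotropic effect, and its t-test (df $n-2$) is the pleiotropy
  diagnostic. Coefficient SEs carry multiplicative overdispersion floored
  at 1.
* **Weighted median** — ratios sorted ascending with standardized
  cumulative weights $p_j = (S_j - w_j/2)/S_n$, linearly interpolated at
  $p = 0.5$; consistent when valid instruments carry at least half the
  weight.
* **Simple / weighted mode** — argmax of a normal-kernel density of the
  ratios with bandwidth
  $h = \phi \cdot 0.9\,\min(\mathrm{sd}(b), \mathrm{MAD}(b)/0.6745)\,n^{-1/5}$,
  evaluated on a 512-point grid spanning $[\min b - 3h, \max b + 3h]$;
  consistent when the largest cluster of instruments is valid.

Median and mode SEs come from a parametric bootstrap
($b_j^\ast \sim N(b_j, s_j)$, default 1000 replicates, seed mandatory).

**Heterogeneity** is assessed with Cochran's
$Q = \sum_j w_j (b_j - \hat\beta_{\mathrm{IVW,fixed}})^2 \sim \chi^2_{n-1}$,
always centred on the fixed-effect estimate; **sensitivity** with
leave-one-out IVW.

### Mediation decomposition

With IVW estimates $\hat\beta_1$ (exposure → mediator, path a),
$\hat\beta_2$ (mediator → outcome, path b) and $\hat\beta_{all}$
(exposure → outcome, total effect), the product-of-coefficients
decomposition is

$$\hat\beta_{12} = \hat\beta_1\hat\beta_2, \qquad
  \hat\beta_{dir} = \hat\beta_{all} - \hat\beta_{12}, \qquad
  P = \hat\beta_{12}/\hat\beta_{all},$$

with the Sobel delta-method SE
$\mathrm{se}_{12} = \sqrt{\hat\beta_1^2\mathrm{se}_2^2 + \hat\beta_2^2\mathrm{se}_1^2}$
and a two-sided normal test of the indirect effect. The proportion's CI
uses the delta method on the ratio with the legs treated as independent
(they come from three non-overlapping cohorts):
$\mathrm{var}(P) \approx \mathrm{se}_{12}^2/\hat\beta_{all}^2 +
\hat\beta_{12}^2\mathrm{se}_{all}^2/\hat\beta_{all}^4$. A seeded
parametric bootstrap is available as an alternative through the
configuration. A pathway is *retained* when the p-value is below 0.05,
the proportion exceeds 10%, and the indirect and total effects share a
(nonzero) sign. The pathway p-value is the Sobel test of the indirect
effect: published mediation tables attach a single p to a pathway without
defining it, and the indirect-effect test is the natural reading; the
retention gate accepts an externally supplied p-value when the user
prefers leg-wise inference.

When $|P| > 1$ (inconsistent mediation, direct and indirect effects of
opposing sign) the result is flagged rather than truncated, and a zero
total effect leaves the proportion undefined.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `p_threshold_exposure` | 5e-6 | instrument p threshold for polygenic exposures (microbial taxa) |
| `p_threshold_pqtl` | 5e-8 | genome-wide threshold for protein mediators |
| `window_kb` | 10,000 | clumping window (kb, inclusive, same chromosome) |
| `r2_cutoff` | 0.1 | variants with r² ≥ cutoff to a better index are clumped |
| `min_f` | 10 | minimum instrument F-statistic `(beta/se)²` |
| `alpha` | 0.05 | leg significance and diagnostic exclusion level |
| `min_proportion` | 0.10 | retention gate on the mediation proportion |
| `palindrome_eaf_window` | 0.08 | palindromic variants with either allele frequency in [0.42, 0.58] (or missing) are dropped |
| `re_mode` | multiplicative_random | IVW error model |
| `n_boot`, `phi` | 1000, 1 | bootstrap replicates; mode bandwidth multiplier |

Numerical conventions: confidence intervals are
$\hat\beta \mp 1.959964\,\mathrm{se}$; p-values are two-sided (normal for
ratio-based estimators, t with $n-2$ df for Egger) and floored at the
smallest positive double so they stay in (0, 1]; equal p-values during
clumping break ties by lexicographic variant id; the mode's argmax
resolves grid plateaus to the smallest grid value; the clumping boundary
removes at r² = `r2_cutoff` exactly (retention requires strictly smaller
r², the stricter reading of an "r² below threshold" rule); duplicate
variant ids within one table keep the smallest-p row (a deliberate,
documented choice — source GWAS rarely state theirs). Missing LD pairs
within the window are treated as r² = 0 and counted, which is
conservative toward keeping instruments; a `missing_ld = "drop"` policy
is available. The per-variant F-statistic uses `(beta/se)²` rather than
the variance-explained form because allele frequency and sample size may
be missing; the two agree to first order.

## What the simulator emulates — and what it does not

`simulate_summary()` draws a three-trait system X → M → Y with direct
effect `theta_dir`, paths `theta_a`, `theta_b`, per-SNP exposure effects
`gamma`, optional horizontal pleiotropy
$\pi_j \sim N(\mu_\pi, \sigma_\pi^2)$, allele frequencies uniform in
`maf_range`, observed effects $\hat\beta \sim N(\beta, \mathrm{se}^2)$
with $\mathrm{se} = (2\,\mathrm{maf}(1-\mathrm{maf})\,n)^{-1/2}$, and LD
identity by default (block-diagonal on request).

Two design points deserve emphasis:

* **The mediator has instruments of its own.** A generator in which the
  mediator's only genetic signal is the one induced through the exposure
  ($\alpha_j = \theta_a\gamma_j$) cannot support two-step mediation: the
  mediator-to-outcome leg would be estimated from the exposure's SNPs,
  and its Wald ratios identify $(\theta_{dir} + \theta_a\theta_b)/\theta_a$
  rather than $\theta_b$. Real analyses instrument the protein with its
  own (typically cis) pQTLs, so the generator gives the mediator
  `n_snp_med` SNPs with effects `delta` drawn from the strong cis-pQTL
  regime (0.15–0.5); the exposure's SNPs retain the induced
  $\theta_a\gamma_j$ signal, which occasionally crosses the genome-wide
  threshold in a large mediator cohort and contaminates the
  mediator-to-outcome leg — a faithful analogue of correlated pleiotropy
  in real two-step MR.
* **Cohort scales are the emulated studies'.** Defaults are 5,959
  (microbiome GWAS), 35,559 (pQTL panel) and 51,340 for the outcome —
  the *effective* sample size $4 n_{case} n_{ctrl} / n$ of a
  ~13,000-case binary GWAS, because the simulated outcome is continuous
  and matching the precision of log-odds associations requires the
  effective n rather than the raw 400,000.

`simulate_individual()` generates genotypes in three non-overlapping
cohorts and regresses trait on genotype per SNP, providing an
individual-level two-stage least-squares oracle against which the
summary-level pipeline is tested.

The simulator does **not** model: microbiome compositionality (CLR
transforms, zero inflation), binary outcomes (the MR algebra under test
is identical on the linear scale; odds ratios are a reporting transform),
sample overlap (a knob exists but defaults to off), fine-scale LD from
reference panels, or winner's-curse-free instrument discovery in an
independent cohort. Passing tests therefore demonstrate the correctness
of the statistical machinery under its stated assumptions, not robustness
to every artefact of real GWAS.

## Validation design and problem sizes

The test suite validates each estimator against an independent oracle
(weighted least squares through the origin for IVW; a generic weighted
regression for Egger; grid search over weighted absolute deviation for
the median — the interpolated median and the WAD minimizer bracket the
same half-weight crossing, so they can differ by at most one order
statistic; a dense 4096-point grid for the mode), and the pipeline
against simulations with known truth:

* **Size under the null** — 2,000 replicates of a 20-SNP null system:
  the IVW rejection rate at $\alpha = 0.05$ must lie in [0.035, 0.065]
  (the multiplicative random-effects floor makes the test slightly
  conservative, about 0.04), and Cochran's Q p-values must pass a
  Kolmogorov–Smirnov uniformity check at the 1% level.
* **Recovery** — 500 replicates at the headline parameterization
  ($\theta_a = -0.125$, $\theta_b = -0.223$, $\theta_{dir} = 0.140125$,
  30 + 30 SNPs, cohorts 50,000 / 20,000 / 50,000): the median estimated
  mediation proportion must land within 2 percentage points of the true
  16.6%, and the delta-method CI must cover the truth with frequency in
  [0.92, 0.975]. The mediator cohort of 20,000 keeps the induced
  exposure-to-mediator signal (|z| ≲ 3.2) below the genome-wide
  instrument threshold, so the recovery check isolates estimator
  correctness from the contamination phenomenon described above.
* **Screening** — seven replicate 3 × 2 × 1 scenarios with one planted
  pathway ($\theta_a = -0.05$, $\theta_b = -0.3$, $\theta_{dir} = 0.06$,
  true proportion 20%, cohorts of 50,000). Each screen applies six
  nominal-level diagnostic exclusions across the three legs, so even a
  correct implementation drops the planted pathway in roughly a quarter
  of replicates; the suite therefore asserts that no false pathway is
  *ever* retained, that the planted one is retained in the majority of
  replicates, and that permuting the manifest never changes the result —
  properties of the logic rather than of one seed's luck.
* **Determinism** — identical configuration and seed reproduce
  byte-identical output tables; all bootstrap and simulation streams
  derive from a single master seed via a fixed multiplicative
  congruential scheme, so components drawing in different orders remain
  reproducible.

These sizes keep the complete suite under a few minutes on one core
while leaving Monte-Carlo error well inside each acceptance band.

## Interfaces

The package's functions are its interface: `screen()` consumes a
`screen_manifest()` of summary-statistic tables (in memory or as TSV
paths) plus LD, and `write_screen()` emits the audit tables and a JSON
run report; `load_config()`/`dump_config()` round-trip the YAML
configuration; `scripts/acceptance.R` re-runs the validation suite from
the command line. Single steps (`clump`, `harmonize`, `mr_ivw`,
`mediate_decompose`, `simulate_summary`, ...) are exported for
interactive use.

## Known limitations

Leg estimates are combined assuming independent samples; no correction
for sample overlap is applied. No MR-PRESSO outlier removal, Steiger
directionality filtering, multivariable MR or SIMEX correction is
provided. Significance gates use raw p-values with no multiple-testing
correction — matching the screening convention the package implements —
but the run report always records the number of tests performed so users
can judge the multiplicity themselves. The proportion CI assumes
asymptotic normality of a ratio; for weak total effects the bootstrap
alternative is preferable.
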