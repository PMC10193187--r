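---
title: "Two-sample Mendelian randomization with mrpipe: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

## The model

Two-sample Mendelian randomization (MR) treats genetic variants as
instrumental variables for a modifiable exposure. For variant $j$ we observe,
from two non-overlapping GWAS samples, the variant–exposure association
$\hat\beta_{Xj}$ with standard error $\sigma_{Xj}$ and the variant–outcome
association $\hat\beta_{Yj}$ with standard error $\sigma_{Yj}$ (log-odds
scale for a case-control outcome). Under the instrumental-variable
assumptions — the variant is associated with the exposure, independent of
confounders, and affects the outcome only through the exposure — each variant
supplies a Wald ratio $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$
estimating the same causal effect $\theta$, the change in outcome log odds
per unit of exposure.

The estimator suite in `mr_fit()`:

* **IVW** (the primary analysis): the precision-weighted mean of the Wald
  ratios with weights $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$, identical to a
  zero-intercept weighted regression of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$
  with weights $1/\sigma_{Yj}^2$. Both identities are kept as tested
  invariants. Cochran's $Q=\sum_j w_j(\hat\theta_j-\hat\theta)^2$ measures
  heterogeneity.
* **MR-Egger**: the same regression with a free intercept. The slope is a
  pleiotropy-adjusted causal estimate; the intercept estimates the average
  directional (horizontal) pleiotropic effect, valid under the InSIDE
  assumption that instrument strength is independent of the direct effects.
* **Weighted median**: the interpolated weighted median of the ratio
  estimates; consistent when instruments carrying at least half the weight
  are valid. Its SE comes from a parametric bootstrap.
* **MR-PRESSO** (`mr_presso()`): a simulation-based global heterogeneity
  test on the leave-one-out weighted residual sum of squares, a per-variant
  outlier test, an outlier-corrected IVW estimate and a distortion test
  comparing raw and corrected estimates.
* **Multivariable MR** (`mr_mvmr()`): zero-intercept weighted multiple
  regression of outcome effects on several exposures' effect vectors,
  giving each exposure's direct effect conditional on the others. This is
  the tool for correlated exposures such as lipid fractions, where
  univariable estimates mix direct and mediated paths.

## Instrument selection and harmonization

Instruments are selected at genome-wide significance with a strict
inequality ($P < 5\times10^{-8}$), then pruned for linkage disequilibrium by
greedy clumping: keep the smallest-$p$ remaining variant (ties broken by
variant id for determinism), drop everything correlated above the $r^2$
threshold, repeat. `clump()` operates on a caller-supplied $r^2$ matrix:
reference-panel handling is deliberately outside this package, so the
source-GWAS thresholds (0.001, 0.05, 0.1) are applied against whatever LD
information the caller trusts, and the synthetic generator can emit a block
matrix for testing. A consequence worth stating: without the original
panels, published instrument counts cannot be reproduced exactly.

`harmonize()` aligns outcome records to the exposure's effect allele
(directly, by allele swap with a sign flip, or after strand complement) and
**excludes all palindromic variants** (A/T and C/G pairs). The exclusion is
unconditional by default because allele labels alone cannot resolve strand
for these variants; the common frequency-based rescue (both frequencies
decisive relative to a 0.3 window) is available behind
`palindrome_rescue = TRUE` for users who want it. Effect-allele-frequency
discordance is a warning, never an exclusion, since frequency filters are a
separate analytic choice. Every exclusion carries a machine-readable reason
(`palindromic`, `not_in_outcome`, `not_in_exposure`, `allele_mismatch`);
variants missing from the outcome are dropped, not proxied.

For multivariable MR the instrument set is the union of variants reaching
significance for at least one exposure, harmonized to the first exposure's
orientation across all tables — standard practice, and the choice that uses
the available instruments maximally.

## Tunable parameters and their defaults

* **IVW model**: multiplicative random effects by default — the fixed-effect
  SE scaled by $\sqrt{\max(1, Q/(n-1))}$, never narrower than fixed.
  Large instrument sets for complex traits essentially always carry excess
  heterogeneity; `model = "fe"` is available and the method label in every
  output records which was used.
* **Wald-ratio SE**: first-order delta method $\sigma_{Yj}/|\hat\beta_{Xj}|$
  by default, appropriate for strong instruments; `second_order = TRUE` adds
  the exposure-side term $\hat\beta_{Yj}^2\sigma_{Xj}^2/\hat\beta_{Xj}^4$.
* **Weighted-median bootstrap**: 1,000 draws; the seed is a required
  argument so pipeline runs are reproducible. `n_boot = 0` skips the
  bootstrap in simulation loops where only the point estimate matters.
* **MR-Egger orientation**: instruments are recoded so
  $\hat\beta_{Xj}\ge 0$ before fitting. This makes the slope invariant to
  allele coding and gives the intercept its interpretation as a mean
  pleiotropic effect per exposure-increasing allele.
* **CI multiplier**: normal, 1.959964, as is conventional for summary-data
  MR; at the instrument counts involved the difference from a $t$ quantile
  is negligible.
* **MR-PRESSO**: `n_sim = 1000` replicates and `outlier_alpha = 0.05` on
  Bonferroni-adjusted empirical p-values. Empirical p-values follow the
  add-one rule, so their floor is $1/(n_{\rm sim}+1)$ and the Bonferroni
  floor is $n/(n_{\rm sim}+1)$: with 50 variants, `n_sim = 1000` is the
  smallest round count at which any variant can be flagged at 0.05, and the
  audit table marks floor values (report them as "< 1/(n_sim+1)").
  The distortion-test null is built by removing random pseudo-outlier sets
  of the observed outlier count.
* **FDR**: Benjamini–Hochberg within each (method, outcome data set)
  stratum across exposures, never pooled across methods — the correction
  matches how the results are read, one forest of exposures per method.

## Effect scaling, odds ratios and power

Estimates are reported as odds ratios per unit increase of the exposure:
per SD for continuous traits, per 10 mm Hg for blood pressure (a unit
multiplier of 10 applied to effects per mm Hg), per year of education, ever
vs never for smoking initiation, and per unit log odds for a binary
exposure such as diabetes — no liability-scale conversion is attempted.
`scale_and_convert()` multiplies the log-odds effect and SE by the unit
multiplier before exponentiating.

Per-instrument variance explained uses
$\beta^2 \cdot 2\,\mathrm{MAF}(1-\mathrm{MAF})$ for an SD-scaled trait;
values sum to the instrument set's $R^2$.

Statistical power for a binary outcome uses the standard noncentrality
approximation: the IVW estimate of $b$ has approximate standard error
$1/\sqrt{N R^2 \phi(1-\phi)}$ with $N$ the outcome sample size, $\phi$ the
case fraction and $R^2$ the instrument variance explained, so two-sided
power at level $\alpha$ is
$\Phi(\sqrt{N R^2 \phi(1-\phi)}\,|b| - z_{1-\alpha/2}) +
 \Phi(-\sqrt{N R^2 \phi(1-\phi)}\,|b| - z_{1-\alpha/2})$.
`min_detectable_effect()` inverts this numerically (root-finding to
tolerance $10^{-12}$; the forward power at the returned minimum matches the
target to $10^{-6}$, a tested invariant) and reports the per-exposure curve;
the study-level "minimum detectable change in log odds" is the smallest
value across exposures, attained at the largest $R^2$. With 39,106 cases,
401,577 controls and instrument $R^2$ values between 0.7% and 19%:

```{r power}
curve <- min_detectable_effect(39106, 401577,
                               r2 = c(0.077, 0.103, 0.092, 0.119, 0.101,
                                      0.12, 0.06, 0.023, 0.007, 0.057,
                                      0.053, 0.19))
round(min(curve$pct_change))
```

## What the synthetic generator emulates — and what it does not

`simulate_two_sample()` draws summary statistics directly, with no
individual-level genotypes: true per-allele effects
$\beta_j \sim N(\mu_\beta, \sigma_\beta^2)$, exposure estimates with the
analytic SE $1/\sqrt{2N_{\rm exp}\,\mathrm{maf}_j(1-\mathrm{maf}_j)}$ for an
SD-scaled trait, and outcome effects
$\theta\beta_j + \alpha_j + \varepsilon_j$ with the log-odds SE
$1/\sqrt{N\phi(1-\phi)\,2\,\mathrm{maf}_j(1-\mathrm{maf}_j)}$. Defaults
emulate the study regime this package is built around: a biobank-scale
exposure GWAS (400,000 participants) against an outcome sample of 39,106
cases and 401,577 controls; a shipped scenario file
(`inst/extdata/scenario-hdl-like-synthetic.yaml`, clearly labelled
synthetic) mimics a lipoprotein-like exposure with 534 instruments
explaining about 12% of trait variance.

Pleiotropy modes set the direct effects $\alpha_j$: `balanced` (zero mean),
`directional` (nonzero mean), `inside_violating` (magnitude scaling with
instrument strength). Two calibrations deserve explanation:

* **Balanced pleiotropy defaults to sd 0.001** on the log-odds scale,
  roughly an eighth of a typical outcome SE at these sample sizes. The
  choice is a forward calculation, not a fit: the MR-PRESSO global test
  compares the observed residual dispersion with a parametric null that
  contains sampling error only, so any true extra-dispersion $\lambda =
  \sigma_\alpha^2/\sigma_Y^2$ shifts its size above nominal by roughly
  $P(\chi^2_{n-1} > q_{0.95}/(1+\lambda)) - 0.05$. At sd 0.001
  ($\lambda \approx 0.013$ at a typical SE of 0.0087) both IVW (with its
  multiplicative random-effects inflation) and the global test keep
  approximately nominal 5% size, which is what "weak ubiquitous pleiotropy
  dominated by sampling error" should mean at this scale.
* **Directional pleiotropy is planted in the frame of the
  exposure-increasing allele** ($\alpha_j$ carries $\mathrm{sign}(\beta_j)$).
  A directional mean only exists relative to an allele orientation, and
  MR-Egger estimates it after recoding instruments to $\beta_{Xj}\ge 0$;
  planting it in any other frame makes the parameter unidentifiable. For
  the same reason, the scenario used to check intercept recovery draws
  instruments exposure-increasing and bounded away from zero
  (per-allele mean 0.03, sd 0.007): with sign-symmetric effects centred at
  zero, near-null instruments get re-oriented by their noise sign and drag
  the intercept towards zero — a property of the orientation convention,
  not an estimator defect.
* **The planted "gross" outlier** used in the robustness checks is a strong
  instrument (per-allele effect 0.05, at the upper end of the strength
  distribution) with Wald ratio 1.0 against a causal effect of 0.1 and an
  outcome SE of 0.005. An outlier planted on a weak instrument is not gross:
  its induced IVW bias is comparable to IVW sampling noise and removing it
  cannot systematically reduce the error.

`simulate_mv_exposures()` draws per-variant effect vectors jointly normal
with a chosen cross-exposure correlation and builds the outcome from direct
effects only, so the univariable-vs-multivariable contrast has a known
truth.

### The proxy-outcome model

`simulate_proxy_pair()` is the one place an individual-level model is used,
because GWAS-by-proxy bias operates through parental genotype and cannot be
expressed purely at summary level. For each of 20,000 respondent–parent
pairs: the parent's genotype is drawn at the panel frequencies and one
allele is transmitted to the respondent (genotype correlation 0.5);
parental disease follows a logistic model in the parental exposure with the
true effect $\theta$; and the respondent *reports* the disease with a
probability that depends on the respondent's own exposure through
`reporting_effect`. The proxy case is a reported diseased parent.
Per-variant log-odds associations use the logistic score approximation
$\mathrm{cov}(g, y)/(\mathrm{var}(g)\,\bar p(1-\bar p))$, adequate for the
small per-variant effects involved.

The default calibration ($\theta = -0.18$ per exposure SD, prevalence 0.15,
reporting baseline 0.5, `reporting_effect = 0.5`) comes from a channel
calculation: the diluted protective channel contributes roughly
$0.5\,\theta\,p_D(1-p_D)\bar R/(\bar p(1-\bar p)) \approx -0.08$ per unit
$\beta_j$ and the reporting channel
$\rho\,r(1-r)\bar D/(\bar p(1-\bar p)) \approx +0.27\rho$, so a reporting
effect of 0.5 makes the upward channel about twice the protective one and
the proxy-based estimate reverses sign while the diagnosed-based estimate
stays negative. With `reporting_effect = 0`, only dilution remains: the
proxy estimate is attenuated towards zero but keeps its sign.

What the generator does **not** emulate: realistic genome-wide LD,
population stratification, sample overlap between exposure and outcome
GWAS, assortative mating, or selection into the biobank. Passing tests
therefore show that the estimators behave correctly under their own
assumptions and under the specific violations modelled — not that real-data
estimates are unbiased.

## Numerical choices and degenerate inputs

* Clumping ties on p-values break by variant id; output order follows the
  input table.
* A single instrument degenerates IVW to the Wald ratio; an empty set is an
  error. MR-Egger and the weighted median require 3 instruments, MR-PRESSO
  4, multivariable MR one more than the number of exposures.
* A rank-deficient exposure matrix in MVMR is an error naming the most
  correlated pair — the multicollinearity that motivates restricting
  adjustment sets among lipid traits rather than conditioning on everything.
* Generator p-values are floored at $10^{-300}$ so extreme associations
  never underflow the record invariant $p \in (0, 1]$.
* All generators and simulation-based tests restore the ambient RNG state;
  results are pure functions of (config, seed).

## Problem sizes used in the checked claims

The shipped verification suite runs at the scale its claims name: 1,000
null replicates for test size (50 instruments each; MR-PRESSO at 1,000
simulations), 500 replicates for parameter recovery (100 instruments), 200
replicates each for the robustness orderings and the multivariable
contrast, 100 replicates for the proxy sign-reversal, and 100 random
instrument sets for the closed-form oracle comparisons. The trio model uses
20,000 families per replicate.

## Known limitations

* No LD-reference handling: clumping trusts the caller's $r^2$ matrix.
* No proxy-variant lookup for instruments missing in the outcome GWAS.
* No CAUSE-style correlated-pleiotropy model and no LD-score-regression
  correction for sample overlap; the estimators here assume non-overlapping
  samples.
* Binary exposures are analysed per unit log odds without liability-scale
  conversion.
* The power approximation ignores instrument-selection winner's curse and
  weak-instrument bias; it matches the standard tool's behaviour, which is
  the point, but both caveats apply to it equally.
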