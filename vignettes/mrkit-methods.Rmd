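---
title: "Two-sample Mendelian randomization with mrkit: models, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrkit)
```

## The causal model

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure $X$ (here, a circulating metabolite measured in SD units) on an
outcome $Y$ (here, disease liability on the log-odds scale) using $K$
genetic variants as instrumental variables, with the SNP-exposure and
SNP-outcome associations taken from two non-overlapping GWAS. For SNP $k$
let $(\hat\beta_{Xk}, \sigma_{Xk})$ and $(\hat\beta_{Yk}, \sigma_{Yk})$ be
the estimated per-allele effects and standard errors. If SNP $k$ is a valid
instrument — associated with $X$, affecting $Y$ only through $X$, and
unconfounded — then $\beta_{Yk} = \theta\,\beta_{Xk}$ and every SNP
identifies the same slope $\theta$ via the Wald ratio

$$\hat\theta_k = \hat\beta_{Yk}/\hat\beta_{Xk}, \qquad
  \mathrm{se}(\hat\theta_k) = \sigma_{Yk}/|\hat\beta_{Xk}|.$$

The standard error is first-order and conditions on the SNP-exposure
estimates (the NOME assumption: no measurement error on the exposure side).
We take the absolute value in the denominator — the ratio itself may be
negative, its standard error may not.

### Pooled estimators

**Inverse-variance weighted (IVW).** The precision-weighted average of the
Wald ratios, equivalently weighted regression of $\hat\beta_{Yk}$ on
$\hat\beta_{Xk}$ through the origin with weights $\sigma_{Yk}^{-2}$:

$$\hat\theta_{IVW}
  = \frac{\sum_k \hat\beta_{Xk}\hat\beta_{Yk}\sigma_{Yk}^{-2}}
         {\sum_k \hat\beta_{Xk}^2\sigma_{Yk}^{-2}}, \qquad
  \hat\sigma_{IVW} = \Big(\sum_k \hat\beta_{Xk}^2\sigma_{Yk}^{-2}\Big)^{-1/2}.$$

`mr_ivw()` implements two SE conventions with an identical point estimate:
the fixed-effect closed form above, and a multiplicative random-effects
variant that inflates it by $\max\{1, \sqrt{Q/(K-1)}\}$ where $Q$ is
Cochran's statistic. Published MR analyses rarely state which convention
produced their intervals, so the pipeline reports both side by side; the
odds ratio itself cannot differ between them. P-values are two-sided
normal.

**Weighted median.** The ratios $\hat\theta_k$ are weighted by their
inverse variances, sorted, and the weighted empirical distribution is
linearly interpolated at probability one half through the cumulative-weight
midpoints $p_j = (S_j - w_j/2)/S_K$. The estimator is consistent whenever
more than half of the total weight comes from valid instruments, which
makes it the standard guard against a minority of pleiotropic SNPs. Its
standard error comes from a parametric bootstrap: exposure and outcome
betas are redrawn from $N(\hat\beta, \mathrm{se}^2)$ and the weighted
median recomputed. Defaults are 5,000 replicates under a caller-supplied
seed; the bootstrap restores the caller's RNG state, and a fixed seed makes
the SE bit-reproducible. Point estimates never depend on the bootstrap.

**MR-Egger.** Weighted least squares of $\hat\beta_{Yk}$ on
$\hat\beta_{Xk}$ with a free intercept, after orienting each instrument so
$\hat\beta_{Xk} \ge 0$ (the fit is not invariant to allele coding unless
the orientation is fixed; the joint sign flip leaves ratio information
unchanged). Under the InSIDE assumption — instrument strengths independent
of direct effects — the intercept estimates the average directional
pleiotropic effect and the slope is a pleiotropy-adjusted causal estimate.
Both are tested with $t_{K-2}$. The coefficient standard errors floor the
residual scale at 1 (the analogue of the multiplicative random-effects IVW
convention), so under-dispersed instrument sets do not produce
anti-conservative intervals.

All slopes are reported as odds ratios per one SD of exposure,
$\mathrm{OR} = e^{\hat\theta}$, with normal-quantile confidence bounds
$e^{\hat\theta \pm z\,\mathrm{se}}$.

### Diagnostics

`cochran_q()` measures ratio heterogeneity around the fixed-effect IVW
center, $Q = \sum_k ((\hat\theta_k - \hat\theta_{IVW})/\mathrm{se}(\hat\theta_k))^2
\sim \chi^2_{K-1}$ under validity. The IVW center (not the Egger fit) is
used because Q is reported alongside the IVW row in results tables.
`leave_one_out()` recomputes IVW excluding each SNP in turn;
`single_snp_forest()` and `scatter_data()` emit the numeric content of the
standard forest and scatter displays, keeping rendering out of the
computational layer so everything is testable headlessly.

## Harmonization

The outcome association must be expressed on the exposure's effect allele
before any ratio is meaningful. `harmonize_pair()` resolves, in order:
exact allele match (kept), swapped effect/other alleles (outcome beta
negated, EAF complemented), match after strand complement (strand flip,
then the swap rule), and otherwise incompatibility. Indels and multi-base
alleles are dropped: the estimators here are defined for biallelic SNPs.

Palindromic SNPs (A/T, C/G) are the one genuinely ambiguous case: the
allele labels cannot reveal a strand flip. The policy is conservative and
configurable: orient by effect-allele frequency when both studies report an
EAF outside $0.5 \pm w$ (default window $w = 0.08$), treating
opposite-side frequencies as a hidden strand flip; drop the SNP whenever
either EAF is missing or uninformative. Published analyses rarely disclose
their palindromic handling, which is precisely why `harmonize_sets()`
attaches a per-SNP audit (kept / flipped / dropped, with one entry per
input instrument including those absent from the outcome GWAS): the
instrument count entering each analysis should be explainable, not
asserted.

Matching is by rsID rather than chromosome/position, since curated
instrument tables routinely mix genome builds across sources. LD proxies
are consumed from a user-supplied substitution table with an $r^2 \ge 0.8$
acceptance rule (`apply_proxy_map()`); LD computation against a reference
panel is deliberately out of scope, as is LD clumping — instruments are
taken as pre-selected, the way curated MR instrument tables provide them.
When several proxy candidates qualify, the first map entry is used and the
alternatives are logged, since no principled ranking survives without the
reference panel itself.

## The synthetic generator

`sim_scenario()` / `simulate_instruments()` generate paired summary
statistics under the model the estimators target:

* true strengths $\gamma_k \sim U(0.05, 0.15)$ in exposure-SD units —
  deliberately bounded away from zero so that estimator tests are not
  confounded by weak-instrument artifacts (a weak-instrument range can be
  requested explicitly);
* direct effects $\alpha_k$ for a fraction `prop_invalid` of instruments,
  drawn with mean 0 (balanced) or mean $\mu_\alpha$ (directional) and sd
  $\tau$, independent of $\gamma_k$ so InSIDE holds;
* observed $\hat\beta_{Xk} \sim N(\gamma_k, \sigma_X^2)$ and
  $\hat\beta_{Yk} \sim N(\theta\gamma_k + \alpha_k, \sigma_Y^2)$ with
  $\sigma_X = 0.01$, $\sigma_Y = 0.02$ by default, magnitudes typical of
  well-powered metabolite and disease GWAS. Setting a $\sigma$ to zero is
  a degenerate switch used by exact-recovery tests (the stored SE column
  then carries unit weights).

Exposure-side noise is generated for realism even though the estimators
ignore it (NOME); with the default parameters the induced regression-
dilution bias in IVW is below one percent of $\theta$. All randomness
flows from the single scenario seed; `estimator_benchmark()` splits
per-replicate sub-seeds deterministically from it, so the full benchmark
table is reproducible and the weighted-median bootstrap inside each
replicate is independently seeded.

What the generator does *not* emulate: LD between instruments, allele
frequencies and harmonization hazards (simulated sets are born
harmonized), case-control ascertainment, sample overlap between the two
GWAS, and winner's curse from instrument discovery. Passing benchmarks
therefore validate the estimators under their stated model, not the
robustness of any particular real-data analysis to those additional
complications.

## Relative power of the pleiotropy diagnostics

A point worth making explicit, because it is measured by
`estimator_benchmark()` and the acceptance script: under directional
pleiotropy with InSIDE holding and a common outcome SE, Cochran's Q is by
far the most powerful of the three pleiotropy signals, the weighted
median's null rejection is intermediate, and the Egger-intercept test is
the weakest at realistic instrument counts. The reason is structural. Each
invalid SNP contributes roughly $(\alpha/\sigma_Y)^2$ to Q's
noncentrality, so Q accumulates $K\,p(1-p)(\alpha/\sigma_Y)^2$ against a
detection threshold growing only like $\sqrt{K}$. The Egger intercept is a
single extrapolated parameter with standard error inflated by
$\sqrt{1 + \bar\gamma^2/\mathrm{var}(\gamma)}$ — for strengths uniform on
(0.05, 0.15) that factor is $\sqrt{13} \approx 3.6$ — giving a z-statistic
of order $\sqrt{K}\,p\,(\alpha/\sigma_Y)/3.6$. The intercept test only
overtakes Q for $K$ in the thousands. With 20 instruments, 30% invalid and
$\mu_\alpha = 0.05$, the benchmark measures Q power near 0.95, weighted-
median rejection near 0.25 and Egger-intercept power below 0.15. The
Egger intercept remains the right *estimator* of the average directional
effect (its estimate centers on $p\,\mu_\alpha$, and the benchmark
verifies the slope is nearly unbiased when IVW is badly biased); it is
simply not the most sensitive *detector*.

## Significance tiers

With $E$ exposures and $O$ outcomes the family comprises $E \times O$
primary IVW tests; `bonferroni_threshold(0.05, 9)` gives $0.05/9 \approx
0.0056$ for a 3-by-3 design. `classify_tier()` labels a p-value
*significant* below the corrected threshold, *suggestive* between the
corrected threshold and the nominal 0.05, and *null* otherwise — the
three-tier convention used in multi-pair MR reports. The tier is a pure
function of the p-value and the two thresholds, and the pipeline applies
it only to the headline IVW row; sensitivity estimators are judged by
directional consistency, not re-tested.

## Numerical and design choices

* **Degenerate inputs.** A zero exposure beta is a degenerate instrument
  (ratio undefined) and errors rather than propagating infinities; a
  single instrument reduces IVW exactly to the Wald ratio and makes the
  random-effects variant fall back to fixed with a warning; Egger and the
  weighted median require $K \ge 3$; zero variance in oriented exposure
  betas makes Egger unidentified and errors.
* **Ties in the weighted median.** When the interpolation point lands
  exactly on a cumulative midpoint the corresponding ratio is returned;
  outside the midpoint range the extreme ratio is returned.
* **Rounding.** Machine precision is kept internally; the formatted
  results table rounds ORs/CIs to 3 decimals and p-values to 3 significant
  figures, the convention of published MR tables.
* **Reproducibility.** Every stochastic component (bootstrap, simulation,
  benchmark) takes an explicit seed and restores the caller's RNG state.
  Re-running a configured pipeline with the same config yields
  byte-identical result tables.
* **Problem sizes.** The test suite and acceptance script use 20-instrument
  scenarios with 300-1,000 replicates and bootstraps of 100-200 inside
  benchmarks (5,000 when a single analysis is run); these sizes give
  Monte-Carlo error well below the effect sizes being checked while
  keeping the full suite fast.

## Known limitations

Binary-outcome GWAS betas are treated as log-odds ratios, inheriting the
usual non-collapsibility caveats; no correction for sample overlap or
winner's curse; no MR-PRESSO-style outlier removal, mode-based estimators,
multivariable MR, or reverse-direction analyses; proxy substitution trusts
the supplied $r^2$ values and carries the original instrument's exposure
statistics under the proxy's identity. The weighted-median p-value relies
on a normal approximation with a bootstrap SE, which can be optimistic for
very small $K$.
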