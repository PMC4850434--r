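---
title: "From genotype counts to a causal estimate: methods behind mmtsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From genotype counts to a causal estimate: methods behind mmtsa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmtsa)
library(dplyr)
```

## The scientific question

Observational studies associate elevated plasma homocysteine (Hcy) with the
risk of multiple myeloma (MM), but such associations are vulnerable to
confounding and reverse causation. Mendelian randomization (MR) sidesteps
both by using a genetic variant as an instrumental variable: the *MTHFR*
C677T polymorphism raises plasma Hcy (roughly 0.158 SD of ln-Hcy per T
allele, from a GWAS meta-analysis of 44,147 individuals), and genotypes are
fixed at conception, so a genotype-MM association can only arise through
the pathway the variant perturbs (granting the usual instrumental-variable
assumptions).

`mmtsa` implements the complete inference chain for this design on summary
genotype counts:

1. validation and Hardy-Weinberg testing of per-study case-control
   genotype tables;
2. meta-analysis of the genotype-disease association under five genetic
   contrasts, with heterogeneity-driven fixed/random selection,
   leave-one-out sensitivity analysis and publication-bias diagnostics;
3. trial sequential analysis (TSA) of the cumulative evidence;
4. a Wald-ratio MR estimate of the causal effect of Hcy on MM, with
   analytic power.

The packaged dataset (`mthfr_mm_studies()`) holds the nine case-control
studies (2,092 cases, 4,954 controls) on which the published analysis this
package reproduces was run; every number below is computed, not
transcribed.

## Study-level effects

Each study contributes CC/CT/TT counts for cases and controls. A genetic
model collapses them to a 2x2 table: the allele model counts alleles (T =
CT + 2·TT per arm, margins twice the subject totals), the dominant and
recessive models pool carriers, and the homozygous/heterozygous models drop
the excluded genotype from both arms. The per-study effect is the log odds
ratio with the Woolf standard error,

$$\hat\theta_i = \log\frac{a_i d_i}{b_i c_i},\qquad
  \mathrm{se}_i = \sqrt{\tfrac1{a_i}+\tfrac1{b_i}+\tfrac1{c_i}+\tfrac1{d_i}}.$$

A continuity correction of 0.5 is added to all four cells of a table only
when that table contains a zero (none occurs in the packaged data); the
all-cells convention keeps synthetic edge cases deterministic.

Hardy-Weinberg equilibrium in each control arm is tested with the Pearson
one-degree-of-freedom chi-square against expectations from the sample
allele frequency, *without* Yates' continuity correction: the uncorrected
test is what reproduces the per-study HWE p-values the source studies
report (e.g. 0.08 for the largest Korean control arm), and is the standard
choice at these sample sizes. A monomorphic sample is defined to have
`chi2 = 0, p = 1`. Studies whose controls violate HWE (p < 0.05) are a
sensitivity-analysis concern; the packaged data contain none, and the
package flags rather than excludes.

## Pooling

Heterogeneity uses Cochran's Q on inverse-variance weights,
$I^2 = \max(0, (Q - \mathrm{df})/Q)$, and the DerSimonian-Laird moment
estimator for the between-study variance $\tau^2$. Random-effects pooling
is inverse-variance with weights $1/(\mathrm{se}_i^2 + \tau^2)$ and Wald
(normal) confidence intervals -- not Knapp-Hartung, matching the
conventions of the software era this analysis reproduces.

Fixed-effect pooling defaults to **Mantel-Haenszel** on the 2x2 cells with
the Robins-Breslow-Greenland variance. This is a deliberate design choice:
MH is the fixed-effect default of the standard meta-analysis tooling for
sparse-ish count data, and it -- not inverse-variance pooling of Woolf log
ORs -- reproduces the published fixed-effect rows (TT vs CC 1.16 (0.98,
1.37); TT vs CT+CC 1.13 (0.98, 1.32)). Classical inverse-variance fixed
pooling remains available (`weights = "iv"`), and `pool_random(tau2 = 0)`
reduces to it exactly.

The fixed/random choice follows the heterogeneity: random effects when
Q's p-value is below 0.10 **or** I² exceeds 50%. Stated prose for such
rules often reads "and", but the disjunction is what the published model
column actually encodes (the allele model, I² = 47 < 50 yet
p(Q) = 0.058 < 0.10, is pooled random), and it is the conservative
reading: either signal of heterogeneity is allowed to widen the interval.

Presentation rounding follows the published layout: ORs and CI bounds to
two decimals, I² to the nearest integer.

## Publication-bias diagnostics

`egger_test()` is Egger's classical unweighted regression of the
standardized effect $\hat\theta_i/\mathrm{se}_i$ on precision
$1/\mathrm{se}_i$; the intercept's t statistic has $k-2$ degrees of
freedom. The weighted variant of the test yields different t values and is
not what the published recessive-model diagnostic (t = 1.53, 7 df) comes
from, so it is not offered. `begg_test()` is the Begg-Mazumdar rank
correlation between variance-standardized deviates and variances, with the
continuity-corrected normal approximation; ties count for neither side.
`funnel_coordinates()`/`plot_funnel()` expose the (log OR, se) geometry
with the pooled estimate as reference.

## Trial sequential analysis

A meta-analysis updated study by study is an interim-analysed experiment,
so nominal 5% testing at every update inflates the type-I error. TSA
treats the accumulating subjects as information and applies
group-sequential monitoring:

* **Diversity.** $D^2 = (v_R - v_F)/v_R$, the relative variance inflation
  from random-effects weighting ($v_F$, $v_R$ are the variances of the
  fixed and random pooled estimates). $D^2 \ge I^2$ on the same data; on
  the packaged allele-model effects it is 66.7%, agreeing with the 67%
  used in the published design.
* **Required information size.**
  $\mathrm{IS} = \lceil (z_{1-\alpha/2}+z_{\beta})^2\, 2\bar p(1-\bar p)
  /\delta^2 \cdot 1/(1-D^2) \rceil$ with $p_e = p_c(1+\mathrm{rri})$,
  $\bar p$ the mean of the two event proportions and $\delta$ their
  difference. With the published design inputs ($p_c$ = 38.02%, rri =
  16.81%, $D^2$ = 67%) this gives 2,822 subjects. Note the constant: the
  conventional *total two-arm* sample-size constant is twice this
  ($4\bar p(1-\bar p)$, here 5,644); the per-group-style constant is the
  one the published information size uses, and the other is available as
  `variant = "total"`. Two defaults are derived from the data when not
  supplied: the control event proportion is the pooled control T-allele
  frequency (38.02%), and rri is the pooled random-effects OR minus one
  (1.1681 yields exactly the published 16.81%).
* **Boundaries.** Lan-DeMets alpha-spending of the O'Brien-Fleming type,
  $\alpha(t) = \min\{\alpha,\, 4(1-\Phi(z_{1-\alpha/4}/\sqrt t))\}$, which
  spends almost nothing early and exactly $\alpha$ at $t = 1$. Boundary
  z values solve the sequential crossing equations by the standard
  recursive numerical integration of the non-crossing sub-density on a
  512-point trapezoidal grid; accuracy is well below $10^{-3}$ on the z
  scale (validated in the tests against a Monte-Carlo Brownian-motion
  oracle). Looks whose alpha increment is numerically zero are capped at
  z = 8.5. Looks are placed at each study's cumulative subject count
  divided by the required size, capped at 1; information is counted in
  subjects even for the allele contrast, matching how the published
  design states both the information size and the event proportion.
* **Z-curve.** Studies enter in ascending publication year (ties broken
  alphabetically -- the standard cumulative meta-analysis convention; the
  accrual order is not part of the published description), and after each
  addition the DerSimonian-Laird pooled z is recorded.
* **Adjusted interval.** The conventional CI half-width is inflated by the
  ratio of the final-look boundary to $z_{1-\alpha/2}$. Once the accrued
  information reaches the required size the final fraction is 1, the
  boundary is $z_{1-\alpha/2}$ (to ~$10^{-4}$), and the adjusted interval
  coincides with the conventional one -- on the packaged data,
  (1.02, 1.34). The published adjusted interval, 0.99 to 1.38, is wider;
  it implies a final critical value near 2.37, which no alpha-spending
  construction yields at full information. We attribute it to internals
  of the original TSA desktop software that its description does not
  specify, and deliberately keep the transparent boundary-ratio
  definition rather than emulate an unspecified algorithm.

## Mendelian randomization

The Wald ratio divides the gene-outcome effect by the gene-exposure
effect:

$$\log\mathrm{OR}_{\mathrm{MM/Hcy}}
  = \frac{\log\mathrm{OR}_{\mathrm{MM/allele}}}{\beta_{\mathrm{Hcy/allele}}},
\qquad
\mathrm{se} = \frac{\mathrm{se}_{\mathrm{MM/allele}}}{|\beta|},$$

the first-order delta method; dividing estimate and SE by the same
constant leaves z and p unchanged, so the MR p-value equals the
gene-outcome p-value. When an instrument SE is supplied the second-order
term $\log\mathrm{OR}^2\,\mathrm{se}_\beta^2/\beta^4$ is added.

The default $\beta$ = 0.158 SD ln-Hcy per T allele is the GWAS-reported
per-allele effect, and with it the packaged data give OR 2.67 per SD
ln-Hcy (95% CI 1.12-6.37, p = 0.026). `infer_beta()` inverts the ratio
for reconstruction from rounded headline numbers (1.17 and 2.67 imply
0.160 -- the rounding, not a different instrument).

Analytic power for a binary outcome uses the standard approximation
$\Phi\!\big(\sqrt{N R^2 p(1-p)}\,|\log\mathrm{OR}| - z_{1-\alpha/2}\big)$
with $R^2$ the exposure variance explained by the instrument (0.01 here);
at the packaged totals and the estimated causal OR it returns 96.5%.

## The synthetic generator

`simulate_studies()` draws the world the meta-analysis assumes: a control
T-allele frequency $q$ uniform on a configured range, control genotypes
multinomial under HWE, case genotypes from the exponentially tilted HWE
distribution (probability $\propto$ HWE $\times\, e^{\theta_i k}$ for $k$
T alleles -- the exact generative counterpart of a logistic disease model
with per-allele log OR $\theta_i$), and $\theta_i \sim N(\theta, \tau^2)$.
Defaults mirror the packaged dataset's observed conditions: nine studies,
$\theta = \log 1.17$, $\tau^2 = 0.0175$ (the DL estimate on the packaged
allele-model effects, I² near 47%), frequencies 0.28-0.45, and arm sizes
spanning 26-1264 cases and 79-1797 controls. A seed in the config makes a
run byte-identical.

What the generator deliberately does **not** emulate -- and hence what
passing recovery tests do not certify about real data: genotyping error
and HWE violation in controls, ethnicity or control-source structure,
correlated or selectively published studies, and any individual-level
exposure; the pipeline, like the design it implements, sees only summary
counts.

Simulation scales are chosen to keep the default test run fast while
leaving Monte-Carlo error well inside the asserted bands: 2,000 replicates
for bias/coverage of the pooled estimate (bias below 0.02 on the log-OR
scale, coverage 95% +/- 3 points), 5,000 simulated control arms for the
HWE rejection rate, 5,000 replicates for the null crossing rate over five
looks, and 4x10^5 Brownian paths for the boundary oracle.

## Known limitations

* Single-instrument MR cannot separate the instrument's effect through
  Hcy from pleiotropic paths; the design itself carries that caveat.
* The Wald CI ignores instrument uncertainty unless an instrument SE is
  supplied.
* TSA results are conditional on the design inputs (event proportion,
  rri, $D^2$); the package derives data-driven defaults but accepts the
  published values as configuration.
* The adjusted-CI definition is the transparent boundary-ratio one, not a
  re-implementation of any particular desktop TSA build (see above).
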