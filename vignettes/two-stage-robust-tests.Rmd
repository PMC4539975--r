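---
title: "Model-robust association testing across a two-stage case-control design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-robust association testing across a two-stage case-control design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(robrep)
```

## Data model and notation

A biallelic marker with alleles A and B has genotypes
$G_0 = AA, G_1 = AB, G_2 = BB$. A case-control study observes counts
$(r_0, r_1, r_2)$ among $r$ cases and $(s_0, s_1, s_2)$ among $s$
controls; $n_i = r_i + s_i$, $n = r + s$. Writing $f_i = P(\text{disease}
\mid G_i)$ for the penetrances and $K$ for prevalence, the genotype
relative risks are $\lambda_1 = f_1/f_0$ and $\lambda_2 = f_2/f_0$; the
null of no association is $\lambda_1 = \lambda_2 = 1$. The classical
genetic models constrain $\lambda_1$: recessive $\lambda_1 = 1$, additive
$\lambda_1 = (1+\lambda_2)/2$, multiplicative $\lambda_1 =
\sqrt{\lambda_2}$, dominant $\lambda_1 = \lambda_2$.

## Single-stage tests

`catt(counts, x)` is the Cochran-Armitage trend statistic with scores
$(0, x, 1)$, standard normal under the null, positive when allele B is
over-represented in cases; $x = 0, 1/2, 1$ are the model-optimal scores.
`pearson_chi2()` is the 2-df genotype test and `abt()` the allele-count
z-test (whose normal null requires Hardy-Weinberg equilibrium — it is
provided for completeness and comparison, not recommended for analysis).

`hwdtt()` estimates the Hardy-Weinberg disequilibrium coefficients
$\hat\Delta_p = \hat p_2 - (\hat p_2 + \hat p_1/2)^2$ in cases and
$\hat\Delta_q$ in controls and standardises their difference:

$$Z_H = \sqrt{rs/n}\,\frac{\hat\Delta_p - \hat\Delta_q}
      {(1-\tilde p)\tilde p},$$

with $\tilde p$ the pooled B-allele frequency. Under a recessive
architecture cases show excess BB homozygosity ($\Delta_p > 0$), under a
dominant one a deficit, so the sign of $Z_H$ is informative about the
genetic model while being asymptotically uncorrelated with $Z_{1/2}$
under HWE. The denominator is the asymptotic standard deviation
$\tilde p(1-\tilde p)$ of $\sqrt{n}\hat\Delta$ under the null; we
verified the unit variance and 0.05-level calibration of this form by
simulation before adopting it.

## The robust procedures and their selection-adjusted p-values

- **MAX3** $= \max(|Z_0|, |Z_{1/2}|, |Z_1|)$. Its default p-value is a
  parametric bootstrap from multinomials at the pooled genotype
  frequencies (add-one estimator, default $B = 10^5$); an asymptotic
  mode evaluates the survival function of the limiting Gaussian maximum
  deterministically (below).
- **MIN2** $= \min(P_{\chi^2}, P_{1/2})$, adjusted through its joint
  asymptotic null in which the 2-df statistic decomposes as
  $Z_{1/2}^2$ plus an independent 1-df chi-square. `min2_pvalue()`
  evaluates the resulting one-dimensional integral; the output always
  lies in $[m, 2m]$ (Bonferroni/monotonicity bracket).
- **GMS** uses $Z_H$ to select the model at level $\alpha_H$ (default
  0.05, threshold $c = \Phi^{-1}(1-\alpha_H)$): $Z_0$ if $Z_H > c$,
  $Z_1$ if $Z_H < -c$, else $Z_{1/2}$. The sign of $Z_{1/2}$ identifies
  the risk allele; when $Z_{1/2} \le 0$ the components are negated and
  the recessive/dominant roles swap.
- **GME** replaces the extreme components by
  $Z^*_x = (Z_x + Z_{1/2})/\sqrt{2(1+\hat\rho_{x,1/2})}$ — rather than
  committing to the extreme model, it merely excludes the implausible
  one. $Z^*_{1/2} = Z_{1/2}$.

### The rank-2 reduction

The selection-adjusted p-values need the joint null law of
$(Z_0, Z_{1/2}, Z_1, Z_H)$. All four statistics are, to first order,
linear functionals of the two free genotype-proportion contrasts (the
trend statistics by construction; $Z_H$ after the delta-method
linearisation that also supplies its plug-in correlations in
`estimate_correlations()`). The joint law is therefore a *rank-2*
Gaussian: writing $e_1$ for the $Z_H$ direction, every statistic $S$
decomposes as $S = \rho_{SH} e_1 + \tau_S e_2$ with
$\tau_S = \pm\sqrt{1-\rho_{SH}^2}$, the sign fixed by
$\mathrm{Corr}(S, Z_{1/2})$. Region probabilities such as
$\Pr(Z_H > c, Z_{1/2} > 0, Z_0 > t)$ then collapse to a single adaptive
quadrature over $e_1$ with closed-form normal interval probabilities
inside. This is exact for the plug-in correlation matrix (which is
singular positive semi-definite by construction), is far better
conditioned than nested three-dimensional quadrature, and costs well
under a millisecond per p-value — which is what makes large simulation
studies of GMS/GME feasible.

The full selection-adjusted p-value is

$$p(t) = 2\left[\Pr(Z_H > c, Z_{1/2} > 0, C_0 > t)
  + \Pr(Z_H < -c, Z_{1/2} > 0, C_1 > t)
  + \Pr(|Z_H| \le c, Z_{1/2} > \max(t, 0))\right]$$

with $(C_0, C_1)$ the recessive/dominant components (starred for GME).
The factor 2 is exact, not an approximation: a global sign flip of the
Gaussian field maps the branches in which the other allele is the risk
allele onto the ones written out, whatever the correlations. So $p(t) =
\Pr(\text{aligned selected statistic} > t)$, one-sided in the aligned
statistic but two-sided in allele direction. All three formulas (MIN2,
GMS, GME) are validated in the test suite against independent
Monte-Carlo oracles that draw the four-variate field by eigen
decomposition and apply the verbal selection rule.

Numerical settings: adaptive quadrature at relative tolerance $10^{-9}$
(absolute $10^{-13}$) for single-marker use, relaxed to $10^{-7}$ inside
simulations; normal tails truncated at $|z| = 8.5$ (mass $<10^{-16}$).
Exact ties in MAX3/MIN2 component selection go to the additive
component, the most robust default. `sign(0)` is taken as $+1$
everywhere a direction is needed. Degenerate (monomorphic) tables raise
a typed error; the CLI reports such markers as NA rows instead of
aborting a batch.

## Replication-stage inheritance

The replication sample is analysed with the method, the selected model,
and the risk-allele direction fixed by discovery: for a trend component
$x$, $P^{(2)}_x = 1 - \Phi(\mathrm{sign}(Z^{(1)}_x) Z^{(2)}_x)$. MAX3
replicates the score with the smallest discovery p-value; MIN2
replicates the winning component (Pearson's p is inherently one-sided);
GMS/GME replicate the component fixed by the discovery $Z_H$ region,
with roles swapped when $Z^{(1)}_{1/2} \le 0$. For GME the replication
standardisation uses the replication-stage correlation estimate — each
stage standardises with its own data. Because the discovery direction is
$\pm$ with probability $1/2$ under the null and each selection region
has fixed probability ($\alpha_H$, $\alpha_H$, $1-2\alpha_H$), the
stage-2 p-value is conditionally uniform and the two stages' p-values
are independent under the null — verified by simulation in the tests.

`stage1_record()` captures exactly the information the replication stage
consumes and serialises losslessly (`as.data.frame()` /
`stage1_from_row()`), so a summary-statistics workflow reproduces the
counts-based one bit for bit.

## Conditional combined tests

Selection at $\alpha_D$ makes the naive combination anticonservative, so
both combinations are referred to their conditional null,
$\Pr(P^{(1)} < \alpha_D,\ \text{statistic} > \text{observed})$.

For Fisher's combination the closed forms are implemented as printed
(equal-weight branch taken when $|w_1 - w_2| < 10^{-9}$, where the
unequal form is singular); at $\alpha_D = 1$ the equal-weight form is
the classical 4-df chi-square tail, a limit the tests check. Natural
logarithms throughout — the published worked examples only reproduce
with $\ln$.

For the inverse-normal combination one subtlety was genuinely open: the
discovery probit $\Phi^{-1}(1 - P^{(1)}/2)$ of a two-sided p-value is
*half*-normal under the null (density $2\phi$ on the positive axis), so
an integral written with density $\phi$ equals only half of
$\Pr(P^{(1)} < \alpha_D, Z_{LC} > z)$ and a threshold calibrated from it
would reject twice too often. `lc_pvalue()` therefore uses the
half-normal density, with ceiling $\alpha_D$. Two observations support
this choice: the package's Monte-Carlo oracle of the defining
probability (uniform $P^{(1)}$, standard-normal replication probit)
matches the half-normal form at all tested points, and the two-stage
null simulation calibrates at the nominal per-marker level with it
(empirically $\approx 0.005$ against nominal $0.005$; the $\phi$ variant
gave $\approx 0.010$).

Weights: equal Fisher weights are the default (`combine_config()`), the
scheme consistent with the published worked examples; sample-size
weights $w_1 = 2\pi_s$, $w_2 = 2(1-\pi_s)$ are available. The
inverse-normal combination uses $\sqrt{\pi_s}, \sqrt{1-\pi_s}$ when
$\pi_s$ is supplied, equal otherwise.

## The simulator and what it does (not) emulate

`simulation_scenario()` fixes the study conditions; its defaults are the
published null design this package is benchmarked against: prevalence
$K = 0.1$, MAF 0.3, HWE ($F = 0$), 1500 cases + 1500 controls split
evenly across stages ($\pi_s = 0.5$), $M = 10$ independent markers,
genome-wide $\alpha = 0.05$ with Bonferroni, $\alpha_D = 0.05$. Genotype
frequencies follow the inbreeding parametrisation
$g_2 = p^2 + Fp(1-p)$ etc., whose implied HWD coefficient is
$Fp(1-p)$ (identity tested). Penetrances are solved from
$(\text{model}, \lambda_2, K)$ and inverted by Bayes' rule to case and
control genotype probabilities; between-stage effect heterogeneity
(e.g. $\lambda_2 = 1.6$ then $1.4$) re-solves the penetrances per stage.
Sampling is multinomial per group per stage.

`run_scenario()` applies three decision strategies per test, all
calibrated to the per-marker level $\alpha/M$:

- **REP**: $P^{(1)} < \alpha_D$ and $P^{(2)} < (\alpha/M)/\alpha_D$ —
  stage independence makes the product rule exact, and it is the unique
  product-form rule hitting the target rate for every $\alpha_D$;
- **FC** and **LC**: $P^{(1)} < \alpha_D$ and the combination statistic
  above its conditional threshold (`fc_threshold()` / `lc_threshold()`),
  computed once per scenario.

Stage-1 p-values inside the engine are exact for the trend and Pearson
tests; MIN2 selection is inverted once into a critical value of the raw
minimum; MAX3 uses the deterministic asymptotic path; GMS/GME use the
selection-adjusted quadrature per table, preceded by the conservative
screen $p \ge 2\Phi(-t) - 2\alpha_H$ (and $p_{\text{MAX3}} \ge
2\Phi(-t)$) that skips tables which cannot reach $\alpha_D$. The engine
draws all replicates in one vectorised stream per scenario seed; a
20,000-replicate, 10-marker null run of the trend-test pipeline takes a
few seconds, and the quadrature-based tests run 5,000 replicates in
under a minute on one core. Those are the problem sizes the test suite
and acceptance script use: 20,000 replicates for the trend/Pearson/MIN2
calibration cells, 5,000 for MAX3/GMS/GME, 2,000 for the power
comparisons (1,000+1,000 samples, additive effects 1.4/1.4 and 1.6/1.4)
— large enough that three binomial standard errors at the 0.005
per-marker level distinguish real miscalibration from noise.

What passing simulations do *not* show: the generator draws independent
markers from clean multinomials at a single MAF. It has no linkage
disequilibrium, no population stratification, no genotyping error or
missingness, no covariates, and both stages sample the same population
(apart from deliberate GRR heterogeneity). Calibration and power results
transfer to real data only to the extent those complications are absent
or handled upstream.

## Known limitations

- All p-values are asymptotic (or bootstrap); no exact small-sample
  versions. Very sparse tables (expected cell counts of a few) will
  stress the normal approximations, particularly for $Z_H$.
- The allele-based test is included for comparison only; its null
  distribution requires HWE.
- Two stages only; multi-stage extensions of the replication logic are
  out of scope.
- The X chromosome, covariate adjustment, imputation and meta-analytic
  effect-size pooling are out of scope.
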