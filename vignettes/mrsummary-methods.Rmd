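---
title: "Methods: likelihood-based Mendelian randomization from summarized data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: likelihood-based Mendelian randomization from summarized data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsummary)
```

## The model

Mendelian randomization treats genetic variants as instrumental
variables for a risk factor. A variant is a valid instrument when it is
(i) associated with the risk factor, (ii) independent of confounders of
the risk factor–outcome relationship, and (iii) associated with the
outcome only through the risk factor. Under these assumptions, and
assuming a linear risk factor–outcome relationship, the per-variant
association estimates identify a single causal slope.

The package works entirely from summarized data: for variant
$k = 1, \dots, K$, the estimated association with the exposure
$X_k$ (standard error $\sigma_{Xk}$) and with the outcome $Y_k$
(standard error $\sigma_{Yk}$), both per copy of a common effect
allele. For a binary outcome $Y_k$ is a log odds ratio and the causal
effect is on the log-odds scale.

Two estimators are provided.

**IVW.** The inverse-variance weighted estimate is the
precision-weighted average of the per-variant ratio estimates
$Y_k / X_k$, equivalently the zero-intercept weighted least-squares
slope of $Y$ on $X$ with weights $\sigma_{Yk}^{-2}$. It is the right
tool when the exposure associations are precisely estimated and the
variants are uncorrelated. Its standard error treats the $X_k$ as
fixed, so when $\sigma_{Xk}$ is non-negligible its intervals are
over-precise; and when variants are correlated it counts overlapping
information twice, again overstating precision.

**Likelihood-based.** The measurement-error model
$$X_k \sim N(\xi_k, \sigma_{Xk}^2), \qquad
  Y_k \sim N(\beta\,\xi_k, \sigma_{Yk}^2)$$
treats both coordinates as noisy measurements of an underlying linear
relation through the origin with slope $\beta$; the $\xi_k$ are
nuisance means. Correlated variants (linkage disequilibrium, LD) enter
through multivariate-normal blocks
$\Sigma_{Xij} = \sigma_{Xi}\sigma_{Xj}\rho_{ij}$,
$\Sigma_{Yij} = \sigma_{Yi}\sigma_{Yj}\rho_{ij}$, where $\rho_{ij}$ is
the correlation between variants $i$ and $j$. Overlap between the
exposure and outcome samples makes $X$ and $Y$ dependent; this is
modelled by a joint $2K$-normal with cross-covariance
$\Sigma_{XYij} = \theta\,\sigma_{Xi}\sigma_{Yj}\rho_{ij}$, where
$\theta$ is the induced correlation between the two sets of
coefficients ($\theta = 0$ in a strict two-sample design). Since
$\theta$ is rarely estimable from summarized data, `mr_theta_scan()`
refits across a user-chosen grid of plausible values as a sensitivity
analysis.

`mr_loglik()` evaluates this joint density exactly (via a Cholesky
factorization of the fixed $2K \times 2K$ covariance); with
$\rho = I$ and $\theta = 0$ it reduces, by construction and by test, to
the sum of $2K$ univariate normal log densities.

## Fitting

**Profile maximum likelihood (`mr_ml`).** For fixed $\beta$ the
optimal nuisance means have a closed form (independent case) or solve
one generalized least-squares system (correlated/overlap case), so the
problem collapses to a one-dimensional profile likelihood in $\beta$.
The profile is maximized by golden-section/parabolic search on a
bracket initialized at the IVW estimate $\pm$ 10 IVW standard errors
and doubled until the maximum is interior (the IVW estimate is a cheap
consistent starting point; up to eight doublings before declaring
non-convergence).

The primary 95% interval inverts the profile likelihood at a drop of
$\chi^2_{1,0.95}/2 \approx 1.92$ from the maximum, found by root
search with geometric bracket expansion on each side. Profile
intervals, unlike Wald intervals, respect the asymmetry that appears
when the exposure-side uncertainty matters — which is the main reason
to prefer the likelihood-based method over IVW in the first place. A
Wald standard error from the numerical curvature at the maximum is
always recorded in the diagnostics, and used as a fallback if the
inversion fails to bracket (`diagnostics$ci_method` says which one the
interval is). No small-sample degrees-of-freedom correction is applied
anywhere; all intervals use normal/chi-squared asymptotics, matching
the asymptotic derivation of the estimators themselves.

**Bayesian fit (`mr_bayes`).** The same likelihood with vague normal
priors, $\beta \sim N(0, 100^2)$ and $\xi_k \sim N(0, 100^2)$ —
effectively flat on any plausible per-allele association scale, and
user-overridable. Because the likelihood is conditionally Gaussian in
$\beta$ given $\xi$ and in $\xi$ given $\beta$, the sampler is a
conjugate Gibbs scheme drawing from the exact full conditionals: no
proposal tuning, no rejections, and rapid mixing. Defaults are 4
chains of 5000 iterations with 1000 warmup, overdispersed initial
values around the IVW estimate, and a mandatory seed. Convergence is
monitored by the split-chain potential scale reduction factor
(warning above 1.05, error above 1.1) and a crude autocorrelation-based
effective sample size. The reported point estimate is the posterior
median (robust to the skew that appears with weak instruments); the
mean and SD are in the diagnostics. Credible intervals are
equal-tailed.

## Heterogeneity (overidentification) test

If every variant is a valid instrument for the same linear effect, the
points $(X_k, Y_k)$ are consistent with one line through the origin.
`mr_heterogeneity()` tests this by a likelihood ratio: twice the gap
between the saturated log-likelihood — means set to the observations
themselves, $\xi_k = X_k$ and $Y$-means $= Y_k$ — and the maximized
common-$\beta$ log-likelihood, referred to $\chi^2_{K-1}$. The
saturated term is evaluated analytically (all residuals vanish, so only
the normalizing constant survives), not by optimization: exact and
instant. In the correlated case the same covariance is used in both
terms, so the normalizing constants cancel and the statistic is the
GLS quadratic form at the constrained optimum; the statistic is
clamped at zero against roundoff. The companion diagnostic is the
scatter of $Y_k$ on $X_k$ with $\pm 1.96$-SE bars on both axes and the
fitted origin line (`plot()` on any fit, `mr_plot_file()` to render to
PNG/SVG).

## Data handling choices

**Harmonization.** The outcome coefficient must refer to the
exposure's effect allele. Matching alleles are kept; swapped
effect/other alleles flip the sign of $Y_k$ (and complement the allele
frequency); irreconcilable pairs are excluded. Palindromic variants
(A/T, C/G) are strand-ambiguous: without frequency evidence they are
excluded by default (a `keep_palindromic` flag overrides), because an
undetected strand flip silently negates $Y_k$. With allele frequencies
on both sides, palindromic variants are resolved only when both
frequencies are at least 0.08 away from 0.5 and on the same or
opposite sides — near 0.5 the frequency carries no strand information.
The 0.08 margin is a conservative convention; variants near it are
cheap to drop relative to the cost of a sign error.

**Variant order.** The exposure file defines the canonical variant
order; the outcome table and the LD matrix are reordered to it. One
canonical ordering prevents silent misalignment between the vectors
and the matrix.

**LD matrix validation.** Input correlation matrices must be symmetric
(asymmetries below 1e-6 are averaged away, larger ones are errors),
unit-diagonal, within $[-1, 1]$, and positive semi-definite with
smallest eigenvalue $\ge -10^{-8}$ — the correlated likelihood needs
an invertible covariance, and a materially indefinite "correlation"
matrix indicates corrupted input rather than roundoff. Condition
numbers above $10^8$ trigger a warning with two remedies: prune
near-duplicate variants, or ridge-regularize
$\rho \to (1-\lambda)\rho + \lambda I$ (off by default).

## Instrument screening

Screening regresses each *standardized covariate on the variant
dosage* (plus adjustment columns such as age, sex, centre), so
coefficients are SD differences in the covariate per allele — the
direction that asks "does this instrument move things it should not?".
Both per-variant and allele-score modes are provided, because a score
can hide the pleiotropy of an individual variant. Instrument sets
follow a min-p rule with two pre-specified thresholds: a conservative
set (every covariate p-value above 0.01) for the primary analysis and
a liberal set (above the Bonferroni level $0.05/V$ for $V$ covariates)
for a secondary analysis. Min-p against fixed thresholds is used
rather than FDR-style corrections, which can be over-conservative here
because covariates (and variants) are themselves correlated. With the
defaults the conservative set is nested in the liberal one whenever
$V \ge 5$; for smaller $V$ the code recomputes the nesting direction
from the thresholds instead of assuming it.

Allele-score weights derived from the data under analysis trigger a
warning: internally derived weights overfit and produce weak-instrument
bias in one-sample settings. The score is affinely calibrated so that
a unit increase corresponds to a stated change in the risk factor
(e.g. 1 SD), by regressing the risk factor on the raw score.
`mr_mediation_check()` reports the variant–covariate coefficient
before and after adjusting for the risk factor; the attenuation ratio
is reported without a pass/fail threshold, since attenuation is rarely
complete (risk-factor measurement error, confounding between risk
factor and covariate).

## The simulator

`mr_simulate()` generates the structural model the instrumental-variable
assumptions describe: dosages $g_{ik} \in \{0,1,2\}$; a single standard
normal confounder $U$ (one confounder suffices to induce every bias
pattern of interest); exposure
$x = g^\top a + c_x U + \varepsilon_x$; outcome
$y = \beta x + c_y U + g^\top p + \varepsilon_y$ with optional direct
(pleiotropic) effects $p$, or a logistic analogue for binary outcomes
(no case-control ascertainment). The exposure and outcome samples are
drawn from one population with a configurable overlap fraction: 0 is
two-sample, 1 one-sample, intermediate values subsample designs.
`mr_summarize_study()` then produces exactly what a consortium would
publish: per-variant univariate regression estimates from each sample
(logistic for binary outcomes), dropping monomorphic variants with a
warning.

**LD generation.** Correlated dosages come from a Gaussian copula at
the haplotype level: two latent $N(0, R)$ draws thresholded at the
MAF quantiles and summed. Thresholding attenuates correlation, so
using the target matrix as the latent $R$ directly would miss the
requested dosage correlations by far more than sampling noise (at
$\rho = 0.5$, MAF 0.3, the realized dosage correlation would be about
0.34). The latent correlation for each pair is therefore *calibrated*:
the bivariate orthant probability is computed by univariate numerical
integration and inverted with a root search so that the realized
dosage correlation matches the requested one up to copula
approximation error and sampling noise (the empirical check in the
test suite allows 0.05 in the realized matrix at n = 10000). If no
latent correlation in $(-0.999, 0.999)$ achieves the request — e.g.
extreme correlation between variants with very different MAFs — or the
calibrated matrix is not positive definite, the configuration is
rejected as infeasible.

**Defaults as study conditions.** The generator defaults describe a
well-powered two-sample biomarker study: $K = 10$ common variants
(MAF 0.30) in linkage equilibrium, per-allele exposure effects of 0.1
residual SD (per-variant $F \approx 40$ at $n = 5000$), causal effect
0.2, moderate positive confounding ($c_x = c_y = 0.3$), and
$n = 5000$ per sample. The summary-level generator
(`mr_simulate_summary()`) defaults to $K = 17$ variants with exposure
means spread over 0.02–0.10, exposure-side standard errors of 0.02 (a
cross-sectional sample of a few thousand) and outcome-side standard
errors of 0.005 (a large meta-analysis) with true $\beta = 0.2$ —
the regime in which a single gene region with many variants is
informative, and in which exposure-side uncertainty is small but not
negligible.

**What passing tests do and do not show.** The calibration studies
(parameter recovery, interval coverage, type-I error of the
heterogeneity test, bias directions) simulate from the assumed model:
normal association estimates, correctly specified standard errors, a
single linear causal pathway, one confounder, and within-population
sampling. They demonstrate internal correctness — the estimators
recover what the model says they should — not robustness to what real
data add: population stratification, non-linear effects, multiple
correlated confounders, winner's-curse-selected instruments,
mis-specified LD from external reference panels, or case-control
ascertainment. The replication sizes used (500 replicates for recovery
and coverage and for each bias design, 1000 for test size, at most a
few thousand simulated individuals per study) were chosen so the
whole suite re-runs in well under a minute while leaving Monte Carlo
error far smaller than the effects being demonstrated; the acceptance
script recomputes all of them from a single seed.

## Known limitations

* Pleiotropy-robust estimators (median-, mode-based, regression with
  an intercept) are out of scope; the heterogeneity test flags, but
  does not correct, pleiotropy.
* Multivariable MR (several correlated risk factors in one model) and
  hierarchical multi-study models are not implemented.
* The binary-outcome path interprets log odds ratios as the causal
  scale without non-collapsibility corrections.
* $\theta$ (sample overlap) is a sensitivity parameter, not an
  estimated quantity; estimating it requires individual-level data.
* Proxy-variant lookup, genome-build liftover and reference-panel LD
  estimation are deliberately excluded: the package consumes, rather
  than constructs, summary statistics and LD matrices.
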