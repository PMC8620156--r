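---
title: "Diagnosing zero-inflated count mixed models with randomized quantile residuals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing zero-inflated count mixed models with randomized quantile residuals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model-checking problem

Sequencing count data — microbiome OTU counts being the motivating case —
are routinely modelled with negative binomial (NB) regression, often with a
zero-inflation component and with random effects for clustering (families,
repeated measurements).  Downstream inference, in particular FDR control in
differential-abundance screens, assumes the postulated model is adequate:
misspecification distorts the null distribution of p-values and inflates
false discoveries.  Checking adequacy is therefore not optional, but the
standard residuals are of little use for counts: Pearson and deviance
residuals of a *correct* count model are far from normal and cluster on
curves, so neither plots nor normality tests on them are informative.

`rqrdiag` implements the randomized quantile residual (RQR, also known as
the Dunn–Smyth residual) solution for six count mixed-model families and
provides the machinery to verify, by simulation, that goodness-of-fit (GOF)
tests built on RQRs are calibrated and powerful for this class of models.

## Model families

All families are built from a base count distribution \(g(y)\): Poisson
with mean \(\mu_i\), or NB with mean \(\mu_i\) and inverse dispersion
\(\theta\) (variance \(\mu_i + \mu_i^2/\theta\); \(\theta \to \infty\)
recovers the Poisson).  Zeros in excess of \(g\) can be handled two ways:

* **Zero-inflated** (ZIP, ZINB): a mixture
  \(f(y) = p_i I(y{=}0) + (1-p_i)\,g(y)\).  The mixture proportion
  \(p_i\) is the probability of a *structural* zero; \(g\) itself still
  produces *sampling* zeros.
* **Zero-modified / hurdle** (ZMP, ZMNB): \(P(y{=}0) = \pi_i\) is modelled
  directly and positive counts follow the zero-truncated base
  distribution \(g(y)/(1 - g(0))\).

The two families coincide exactly when \(\pi_i = p_i + (1-p_i)g(0)\) —
positive counts have the same conditional distribution either way — and the
package tests this identity numerically on a parameter grid.

Covariates enter through
\[
\log \mu_i = \log T_i + X_i\beta + Z_i u, \qquad
\mathrm{logit}\ p_i\ (\text{or } \pi_i) = X_i\tilde\beta + Z_i\tilde u,
\]
with \(\log T_i\) the total-reads offset and \(u, \tilde u\) Gaussian
random effects, one independent variance per grouping factor per model
part.  A general covariance would not be identifiable from the two-level
grouping factors the simulator produces, and diagonal structure matches how
such models are fitted in practice.

## Randomized quantile residuals

For a discrete response the CDF tail probability is randomized across the
probability step at the observed count:
\[
F^*_i = F(y_i - 1) + u_i\, p(y_i), \qquad u_i \sim U[0,1],
\]
and mapped to a normal quantile \(q_i = \Phi^{-1}(F^*_i)\).  Under the true
model with the true parameters \(F^*_i\) is exactly uniform, so the
\(q_i\) are exactly standard normal — which makes overall GOF testing a
normality test.  The package uses Shapiro–Wilk (SW) as the working test;
SW p-values are uniform under the true model and concentrate near zero
under misspecification.

Numerical choices:

* \(F(-1) = 0\) by contract; \(F(y-1)\) is evaluated directly on the
  integer support (all six families have support in the nonnegative
  integers), not as a limit.
* \(F^*\) is clipped to \([10^{-10}, 1 - 10^{-10}]\) before
  \(\Phi^{-1}\); the number of clipped values is recorded on the residual
  object.  The bound is far below any p-value resolution that matters for
  an SW test at the sample sizes involved.
* Residuals are conditional on the random-effect modes:
  \(\hat\mu_i\) includes \(Z_i\hat u\) and the offset.
* The randomization stream is seeded independently of the simulation
  stream, so study results are not coupled to residual draws; the
  (fit, seed) pair reproduces a residual vector bit-for-bit.
* Because RQRs carry randomization noise, applied model checking can
  average the SW p-value over replicated residual draws
  (`replicated_sw_p()`, default 100 replications).  The simulation study
  uses one draw per fit — the two conventions serve different purposes and
  both are exposed.

Pearson residuals \(r_i = (y_i - \hat m_i)/\sqrt{\hat V(y_i)}\) are
provided as the conventional comparator.  The per-observation moments are
computed by exact closed-form algebra on the base moments (zero inflation
scales both raw moments by \(1-p_i\); the hurdle scales them by
\((1-\pi_i)/(1-g(0))\)); a brute-force summation oracle verifies the
algebra in the test suite.  Fitted zero probabilities are nudged off the
boundary by \(10^{-12}\) so that an extreme zero-part predictor yields a
huge (honest) residual rather than an undefined one.

## Fitting and the convergence filter

`fit_model()` estimates all six families by maximum likelihood with
Laplace-approximated integration over the random effects, delegating the
optimization to `glmmTMB`.  The package also carries its own explicit
likelihood route — `joint_nll()`, `laplace_marginal_nll()` and a 20-point
adaptive Gauss–Hermite marginal (`aghq_marginal_nll()`) for one grouping
factor — used to verify the fitted objective independently.  On a toy
model the Laplace and quadrature marginals agree to \(10^{-3}\); the
agreement degrades (to the order of \(5\times10^{-3}\)) when the zero
part combines a large random-effect scale with few observations per
level, which is a known property of the Laplace approximation for
Bernoulli-type likelihoods, not an implementation artefact.

A fit is **converged** only if the optimizer reports success, the
top-level Hessian is positive definite, the log-likelihood is finite and,
for NB families, \(|\log\hat\theta| \le 15\).  The \(\theta\) bound
catches NB fits running off to the Poisson limit — the characteristic
breakdown when an NB model is fitted to equidispersed data — and
non-converged fits are excluded from every rejection-rate denominator;
each study cell reports its own \(N\).

Initialization and optimizer control follow `glmmTMB` defaults, which are
well tested for exactly this model class.

## What the simulator emulates

`simulate_dataset()` produces one taxon's worth of per-observation counts
with the structure of a clustered microbiome design:

* \(n\) observations (default study size 100), each assigned uniformly at
  random to one level of each of 3 three-level fixed factors and 2
  two-level grouping factors.  A balanced layout is not imposed; at these
  sample sizes random assignment is close to balanced in expectation.
* sequencing depth \(T_i \sim\) Poisson(300 000), entering as a
  \(\log T_i\) offset;
* a structural-zero indicator \(H_i\) with
  \(\mathrm{logit}\,P(H_i{=}0)\) given by the zero-part linear predictor;
  when \(H_i = 1\) the count is drawn from the base distribution
  (zero-inflated truth) or its zero-truncated version (hurdle truth).
  Truncated sampling is by vectorized rejection with an inverse-CDF
  fallback when \(g(0) > 0.99\);
* fixed-effect level coefficients \(\sim N(0, 0.1^2)\), random-effect
  level coefficients \(\sim N(0, 2^2)\), drawn independently for the zero
  and count parts; \(\theta \sim \mathrm{unif}(2,3)\) for NB truth.
* four scenarios crossing high/low zero proportion (zero-part intercept
  \(3.5\) vs \(-5.5\)) with high/low counts (count-part intercept
  \(-5.5\)/\(-7.8\) for NB truth, \(-5.7\)/\(-8\) for Poisson truth).

Two points were genuinely open and are fixed here as package policy:
coefficients are **redrawn for every replicate dataset**, which makes
replicates exchangeable draws from the scenario rather than conditional
on one coefficient realization; and the generator indexes **one
coefficient per factor level**, while the fitting side uses treatment
contrasts — the reference-level coefficients are absorbed into the
fitted intercept, which the tests account for when comparing estimates
to truth.

The simulator does **not** emulate several features of real microbiome
data: compositional coupling across taxa, correlated taxon abundances,
longitudinal within-subject structure beyond the grouping factors, or
library-size-dependent zero patterns.  Calibration results on these
synthetic data therefore speak to the residual method's behaviour for the
model class, not to the adequacy of any particular model for a given real
dataset — that is what the diagnostics themselves are for.

## The Monte-Carlo study

`run_study()` repeats (simulate → fit candidate models → one RQR draw per
converged fit → SW test → optionally SW on Pearson residuals) and
aggregates rejection rates over converged fits.  Everything derives from
one master seed; studies are checkpointable and resume after
interruption.  Expected behaviour, which the acceptance runs measure:

* the true model's rejection rate sits near the 5% nominal level
  (type I error);
* Poisson fits to zero-inflated data are rejected essentially always;
  NB fits to zero-inflated Poisson data are rejected at a useful rate
  (the NB's heavy tails absorb some, not all, of the misfit);
* all four zero-handling models stay near 5% under zero-inflated or
  hurdle Poisson truth (they contain, or closely approximate, the truth);
* SW tests on Pearson residuals reject even the true model almost
  always — the negative control that motivates RQRs.

The packaged studies and tests run at reduced scale — 50–200 replicates
of \(n = 100\), against 3000 in a full-scale investigation — chosen so
the whole suite completes on a laptop in minutes.  Monte-Carlo bands in
the tests are computed from each cell's own converged-fit count
(3 binomial standard deviations), so they adapt to the scale of the run.
At high-zero-proportion scenarios roughly half of the hurdle-NB fits fail
the convergence filter at \(n = 100\); this mirrors the instability of
fitting richly parameterized two-part models to ~100 observations of
which most are zeros, and is why denominators are reported per cell.

## Applied preprocessing

For real OTU tables, `truncate_counts()` implements the pragmatic
pre-step of setting small counts (default: below 10; per-taxon overrides)
to zero before fitting zero-handling models, on the view that small
genus-level counts are typically alignment artefacts: without it the data
contain too few zeros for a zero component to be useful, yet the small
counts are not credibly quantitative.  The threshold is a scientific
choice, not a statistical estimate; the function reports how many cells
it changed so the choice stays visible.

## Known limitations

* Only categorical covariates and random intercepts are supported — the
  design space of the study; no random slopes, nested structures or
  continuous covariates.
* The SW test caps at \(n = 5000\) (the statistic's standard validity
  range); larger residual vectors should be subsampled or tested
  otherwise.
* Hurdle and zero-inflated NB models at small \(n\) with extreme zero
  proportions often fail the convergence filter; rejection rates are then
  estimated over few fits and the per-cell \(N\) must be read alongside
  the rate.
* The quadrature cross-check covers one grouping factor; with two
  crossed factors only the Laplace route is available (as in the general
  fitting path).
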