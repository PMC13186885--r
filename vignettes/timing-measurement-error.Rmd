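---
title: "Timing measurement error: models, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timing measurement error: models, methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timerr)
```

## The problem

Timecourse experiments record a *protocol* time — the time a measurement
was supposed to be taken — while the measurement actually happens at some
other, unrecorded time. Fitting a model naively to the protocol times
treats the recorded abscissae as exact. This vignette describes the error
mechanisms the package simulates, the inference machinery it applies, the
corrections it implements, and every numerical choice a user might want to
question.

Two mechanisms cover the cases of interest:

* **Classical**: the observed value scatters about the truth,
  $W = X + U$. The conditional law modelled is $W \mid X$. The canonical
  consequence for a straight line $Y = \beta_0 + \beta_x X + \varepsilon$
  fitted to $(w, y)$ is attenuation: the naive slope converges to
  $\lambda \beta_x$ with reliability ratio
  $\lambda = \sigma_x^2 / (\sigma_x^2 + \sigma_u^2) < 1$.
* **Berkson**: the truth scatters about the recorded value, $X = W + U$,
  the natural model for controlled experiments with preassigned protocol
  times. Linear slopes are unbiased, with inflated variance. Nonlinear
  features are *not* safe: for $Y = a\cos(bX) + \varepsilon$, the
  expected response at a recorded point $w$ is
  $a\,e^{-b^2\sigma_u^2/2}\cos(bw)$, so the fitted amplitude shrinks by
  $e^{-b^2\sigma_u^2/2}$ regardless of the mechanism or design. This
  closed form is used as an independent oracle in the tests.

The error in the equation $\varepsilon$ (scatter of the response about the
deterministic model) is kept conceptually separate from the timing error;
responses in every generator are computed from the *hidden true* time,
never from the recorded one.

## The five case studies and their generators

The generators are first-class, tested code; their defaults *are* the
study conditions, chosen once and not revisited.

| Study | Model | Design | Error defaults |
|---|---|---|---|
| linear | $\beta_0 + \beta_x x$, truth $(0, 1)$ | $n = 50$; non-controlled ($X$ or $W \sim N(0,1)$) or controlled (5 points on $[-2,2]$, 10 replicates) | $\mathrm{var}(U) = \mathrm{var}(\varepsilon) = 0.25$ |
| oscillator | $a\cos(bx)$, truth $(3, 4)$ | $n = 50$; non-controlled ($U(-2,2)$) or 5 protocol points on $[-2,2]$ (Case 1) or on $[-\pi/2,\pi/2]$ (Case 2, spacing $\pi/4$, every point a turning point of $\cos 4x$) | $\mathrm{var}(U) = \mathrm{var}(\varepsilon) = 0.05$ |
| parasite | $V_0e^{gt} + B_0e^{-kt}$, truth $(0.002, 0.531, 0.02, 0.323)$ | one culture, protocol days $\{0,2,\dots,24\}$, a single observation per day | day-level Berkson $U \sim N(0, 0.25^2)$; multiplicative response error $y = (1+\varepsilon)P(t)$, default $\sigma_\varepsilon = 0$ |
| tumour | Gompertz $K(y_0/K)^{e^{-rt}}$ | six tumours, protocol days $\{0,2,\dots,60\}$; per-tumour $y_0 \sim U(100,120)$, $r \sim N(0.08, 0.02^2)$, $K = 4000$ | sequential delays: each measurement takes a lognormal duration with mean $1/6$ day, SD $0.1$ day; a tumour's delay is the cumulative duration of the measurements up to and including its own, in fixed or daily-reshuffled order |
| GLUT4 | $(P_0 - M)e^{-kt} + M$, truth $(0.1, 0.1, 1)$ | protocol minutes $\{0, 0.5, 1, 2, 5, 10, 15, 20, 25, 30, 45, 60\}$, `n_rep` replicates per time | biased uniform timing error $U \sim U(0, \Delta)$; lognormal response moment-matched to mean $P(\theta,t)$ and variance $\sigma_Y^2$ |

Notes on deliberate design decisions:

* In the linear and oscillator designs the normal error parameters are
  **variances**. The internal cross-checks only cohere under this reading:
  the attenuation factor $1/(1+0.25) = 0.8$ for the linear study and
  $3e^{-8 \cdot 0.05} \approx 2.01$ for the oscillator Case 2 both match
  the replicated estimates. Where a parameter is written as a standard
  deviation (parasite $\sigma_U = 0.25$, tumour $r \sim N(0.08, 0.02^2)$)
  it is honoured as one.
* The GLUT4 plateau $M$ is stored as a **free parameter**, not a
  proportion: although the two-compartment derivation gives
  $M = k_{ex}/(k_{ex}+k_{en}) \le 1$ under conservation $P + S = 1$, the
  study grid deliberately explores $M$ up to 29, so the solution form is
  implemented verbatim and $M \le 1$ is not enforced. The
  $k_{en}/k_{ex}$ decomposition is available but optional.
* Sequential tumour delays **include the measured tumour's own duration**
  (the sum runs up to and including its index), so even the first tumour
  of the day is late. With SD 0 the delays are exactly $T\mu_M$.
* Parasite responses may go negative under large multiplicative error;
  they are kept — no truncation or censoring is applied.
* A mean measurement duration of 4 h (1/6 day) is an intentionally extreme
  value: the point of the tumour study is that even day-scale mistiming
  barely moves pooled growth-rate inference.
* GLUT4 grid axes for $(\Delta, \sigma_Y)$ default to
  $[0,1]$ min $\times$ $[0, 0.3]$ but are plain configuration; no
  particular axis values are privileged.

All generators draw from R's ambient RNG stream; `run_study()` and
`bias_variance_grid()` seed each replicate independently from a root seed,
so tables are reproducible and a shorter run is a prefix of a longer one.

## Naive inference

`fit_least_squares()` minimises the stacked sum of squares with bounded
Levenberg–Marquardt (minpack.lm), with lower bounds enforcing each model's
sign constraints. Numerical policies, in order of application:

* **Starts.** Model-specific defaults (e.g. parasite
  $(0.01, 0.3, 0.01, 0.5)$; data-driven ranges elsewhere), overridable per
  call.
* **Multi-start.** The supplied start *and* the default start are both
  tried and the lower SSR kept. The parasite surface is the motivating
  case: from a start at 1.5× truth, plain LM settles into a local minimum
  with a huge background term, while the default start reaches the global
  optimum; multi-start makes the fit insensitive to that choice.
* **Gauss–Newton polish.** LM's relative-change stopping rules leave
  roughly $10^{-9}$ of parameter error; up to three Newton steps from the
  LM optimum sharpen it (exactly, for models linear in the parameters), so
  the linear fit agrees with closed-form OLS to machine precision.
* **Covariance and intervals.** $\widehat{\mathrm{cov}} = (J^TJ)^{-1}s^2$
  with $J$ the central-difference Jacobian of the fitted values at the
  optimum and $s^2$ the mean squared error; intervals are
  $\hat\theta \pm t_{n-p}\sqrt{\mathrm{diag}}$. A singular $J^TJ$ (the
  ill-identified parasite background when fitted to noise-free data) is
  flagged, not fudged.
* **Ties and degeneracies.** $R^2$ is undefined for a constant response;
  fits with $n \le p$ carry no intervals; non-convergence is a flag on the
  result, never an exception, so replicated studies can count failures.

`kde()` uses a Gaussian kernel with the normal-reference bandwidth —
the default of the common built-in density estimators — so replicated
estimate densities are comparable to the usual displays.

## Bayesian inference by tempered SMC

The GLUT4 study is deliberately naive on the Bayesian side too: the
lognormal likelihood is evaluated at the recorded protocol times and the
timing error is *not* modelled. The sampler is an adaptive
likelihood-tempering SMC, a design owned by this package (the settings are
not inherited from anywhere):

* particles initialise from independent uniform priors; the defaults for
  GLUT4 span twice the true-parameter grid ($P_0, k \in [0, 0.5]$,
  $M \in [0, 58]$);
* each temperature increment is found by bisection so the reweighted
  effective sample size is half the population;
* below that ESS the population is resampled systematically and moved by
  (default) five Metropolis–Hastings random-walk sweeps with proposal
  covariance $2.38^2/d$ times the weighted particle covariance;
* the MAP is defined as the particle maximising prior × likelihood — a
  deterministic function of the particle set, in preference to a KDE mode;
* credibility intervals are equal-tailed weighted marginal quantiles.

The accuracy metrics per parameter are the absolute MAP error, the 95%
interval width, and the distance from the truth to the interval (zero when
contained). The sampler is validated against a conjugate normal posterior
and a flat-likelihood prior-recovery check.

## Corrections

* **Reliability ratio** ($\hat\beta/\lambda$) and **Fuller's method of
  moments** ($S_{wy}/(S_{ww} - \sigma_u^2)$) are exact for linear models
  with known classical error variance; they coincide when $\lambda$ is
  computed from the same moments, an identity the tests assert.
* **Regression calibration** substitutes the best linear
  $E[X \mid W] = \mu_x + \lambda(w - \mu_x)$; under unbiased Berkson error
  $E[X \mid W] = W$ and the imputation is, correctly, a no-op.
* **Orthogonal (Deming) regression** jointly minimises vertical plus
  $\eta$-weighted horizontal distances over the parameters and the $N$
  latent abscissae ($\eta = \sigma_\varepsilon^2/\sigma_u^2$). The joint
  problem is itself a least-squares problem in $p + N$ unknowns and is
  solved by the same LM machinery with warm restarts. The $\eta = 1$
  special case is scale-dependent — rescaling the response changes the
  corrected slope — and ignores the error in the equation; the function
  warns rather than "fixes" this, and a test demonstrates the
  scale-dependence.
* **SIMEX** refits under inflated error $w + \sqrt{\zeta}N(0, \sigma_u^2)$
  over $\zeta \in \{0.5, 1, 1.5, 2\}$ (B = 100 pseudo-datasets per point
  by default), then extrapolates the mean-estimate trajectory to
  $\zeta = -1$. The rational-linear extrapolant $a + b/(c + \zeta)$ is
  exact for the linear-classical attenuation curve
  $\lambda(\zeta) = \sigma_x^2/(\sigma_x^2 + (1+\zeta)\sigma_u^2)$ and is
  fitted by profiling $(a, b)$ and line-searching $c > 1$; failures fall
  back to the quadratic with a warning.
* **Measurement-error likelihoods** marginalise the latent true time out
  of each observation: for Berkson error
  $\int \phi_{Y|X}(y; y(\theta,x))\,\phi_{X|W}(x; w)\,dx$ (no density for
  $X$ needed — the predetermined $w$ carries no information about
  $\theta$); for classical error the integrand additionally carries
  $\phi_{W|X}$ and a density $\phi_X$, evaluated through the
  normal-conditional factorisation.

### Quadrature

Normal latent errors use Gauss–Hermite nodes, uniform Berkson errors
Gauss–Legendre on the support. The default order 21 reproduces adaptive
integration to $10^{-6}$ for smooth integrands (a tested property). It is
*not* sufficient when the observation density is much narrower in $x$ than
the error density: for the oscillator, the model gradient
($|\,\mathrm{d}\,3\cos 4x/\mathrm{d}x\,| \le 12$) against a residual SD of
0.22 makes the integrand a spike of width ~0.02 inside an error
distribution of SD 0.22, and order 21 under-resolves it, leaving a few
percent of residual amplitude bias. The order is a plain argument; the
package's own bias-removal checks use order 101, at which the maximum
likelihood estimate is verified consistent. Rule of thumb: scale the order
with the ratio of the error SD to the width
$\sigma_\varepsilon / \max_x |y'(\theta, x)|$.

### Method selection

`select_correction_method()` encodes the decision logic as a deterministic
rule table over five questions (model class, extra data, variance known,
error mechanism, distribution fully specified) and returns ranked
recommendations with standard references. Validation-data and
replicate-based estimators beyond regression calibration are referenced,
not implemented.

## Problem sizes used by the tests

The shipped checks run at desk scale, a package choice: replicated-density
claims use 1000 replicates (linear, oscillator, tumour) where
10000 would only narrow Monte-Carlo bands already far tighter than the
effects asserted; the parasite grid runs 10×10 cells × 100 replicates over
the same $[0, 0.5]^2$ error ranges (the full version is 20×20×1000); the
SMC heterogeneity study uses 20 seeds × 200 replicates per protocol time
with 400 particles. Monte-Carlo assertions use 3×SE bands computed from
the replicates themselves.

Two measured facts inform how the tumour claims are phrased: the pooled
shared-$(r, K)$ estimator carries a small (~0.5–1% of $r$) positive
finite-cohort bias that is *identical across error scenarios* — it is a
property of pooling heterogeneous growth curves, not of mistiming — so the
tests assert that the estimate density is centred at the true mean growth
rate at the resolution the density supports and that the error scenarios
are statistically indistinguishable from perfect data, which is the
substantive claim.

## What the synthetic studies do and do not show

The generators emulate: protocol-time recording, sequential measurement
delays, biased late dosing, multiplicative response noise, and
between-subject parameter heterogeneity. They do not emulate model
misspecification (the fitted model is always the generating one),
differential errors (error distributions never depend on the response),
multiplicative *timing* error ($W = XU$), censoring or detection limits,
or correlated equation errors. A correction that performs well here
performs well when its assumptions hold; on real data the binding question
is usually whether $\sigma_u^2$ (or the full error distribution) is
actually known, and the method selector makes that dependency explicit.

## Known limitations

* The classical measurement-error likelihood assumes a normal $\phi_X$;
  semiparametric treatments of unknown $X$-distributions are out of scope.
* SIMEX assumes additive normal classical error; its extrapolation step is
  a model-choice risk the trajectory plot (`autoplot()` on the SIMEX
  object) is meant to expose.
* The SMC sampler targets low-dimensional, well-identified posteriors; it
  makes no attempt at multimodal robustness beyond its tempering path.
* Orthogonal regression inherits the documented $\eta$-misspecification
  and scale-dependence caveats; it is included because it is simple and
  widely used, not because it is recommended.
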