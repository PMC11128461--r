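---
title: "Predation-risk surfaces and Bayesian activity-budget models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predation-risk surfaces and Bayesian activity-budget models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elkrisk)
```

## What the package models

`elkrisk` implements a complete analysis chain linking the space use of a
recolonizing wolf population to the behavior of adult female elk observed by
focal instantaneous sampling (one behavioral state per elk per minute).
The chain has three tiers:

1. **Risk surfaces.** Wolf GPS fixes become kernel-density utilization
   distributions (UDs) on a 380 x 450 m grid at four spatial-temporal
   scales: per pack by season and year (`PackSY`), per pack by year using
   the maximum seasonal pack count (`PackYm`), and population-level
   season-year and year surfaces built from the single most-sampled wolf
   per pack (`PopSY`, `PopY`).  Pack UDs are multiplied cell-wise by the
   pack's wolf count and summed where packs overlap.  Two used-available
   logistic selection models complement the UDs: a resource selection
   function (RSF) fit to wolf fixes, and a "risky places" (RP) model fit
   to wolf-killed elk locations.  The three primary risk metrics evaluated
   at an observation are the buffer-mean UD times the RSF score
   (predicted wolf presence), the RP score alone, and the buffer-mean UD
   times the RP score, each at a 200, 800 or 2000 m buffer.  Two secondary
   metrics are canopy openness (open pixels within a moving window) and
   the diel wolf movement rate.

2. **Behavior model.** Session-level compositions over five categories
   (foraging, vigilance, resting/ruminating, traveling, other; nursing and
   drinking are pooled into other) are modeled with Dirichlet regression
   in the mean/precision ("alternative") parameterization:
   `y_i ~ Dirichlet(mu_i * phi)` with a multinomial-logit link,
   `log(mu_ic / mu_i,travel) = x_i' beta_c + b_{herd(i),c}`, and a scalar
   precision `phi`.  Traveling is the reference category.  Because
   boundary proportions have no Dirichlet likelihood, compositions are
   first squeezed into the open simplex with the affine transform
   `y* = (y (n - 1) + 1/C) / n`, `n` the session's classified minutes.

3. **Multitasking model.** Within vigilance minutes, chewing-while-vigilant
   is a Bernoulli mixed model on the logit scale with a random intercept
   per focal observation (session), covariates including maternal period,
   a (possibly log-transformed) risk metric, openness and herd size, and a
   maternal-period-by-risk interaction.

Candidate model sets are compared by expected log pointwise predictive
density (ELPD): grouped 10-fold cross-validation for the Dirichlet models
(herds never straddle folds, because the random effect is herd-level) and
Pareto-smoothed importance-sampling LOO for the multitasking models, with
pseudo-BMA+ weights from a Bayesian bootstrap.  A model is retained when
its ELPD deficit to the top model is under 16; the top model is the *sole*
top model when it leads the runner-up by more than 4 ELPD or carries the
majority (> 0.5) of the weight.

## Priors and sampling

Priors follow a weakly-informative scheme: flat on slopes,
Student-t(3, 0, 2.5) on intercepts, gamma(0.01, 0.01) on the Dirichlet
precision, and half-t(3, 0, 2.5) on random-effect SDs with standard-normal
standardized effects.  "Significance" of a term means its 90% equal-tailed
credible interval excludes zero.

Posteriors are sampled with a Hamiltonian Monte Carlo sampler written for
this package (Rcpp): leapfrog trajectories with jittered path length, a
mass matrix from a Laplace approximation, per-chain step-size adaptation
toward 0.8 acceptance, and a mid-warmup window that rescales the mass
matrix from the chain's own draws.  Two further devices matter for the
hierarchical scales:

* the posterior *mode* of a hierarchical model is degenerate in the
  random-effect-scale direction, so the Laplace step anchors that one
  coordinate with a quadratic penalty (center `log 0.3`, scale 0.5) —
  a preconditioning device only; the sampled posterior is unpenalized;
* each iteration interleaves a one-dimensional slice-sampling refresh of
  the random-effect scale through its centered-parameterization full
  conditional (for a non-centered chain, effects are rescaled so the
  centered effects stay fixed).  This interweaving breaks the classic
  funnel coupling between the scale and the effects.

The Dirichlet model uses the *centered* random-effect parameterization by
default: with hundreds of sessions per herd the likelihood identifies each
herd effect well and the centered geometry mixes better; the multitasking
model defaults to non-centered because a session contributes only a few
Bernoulli observations.  Both are available behind the `centered`
argument.

Convergence is declared when every parameter has split R-hat at most 1.01
and effective sample size above ten times the number of chains; the ratio
`n_eff / N` is reported alongside.  Three presets are provided:
`fast` (4 chains, 200 + 350 iterations, at most 6 leapfrog steps) for
simulation studies where the monitored fixed effects mix quickly;
`thorough` (700 + 1800, 12 steps), which meets the strict convergence flag
on the models in this package including their high-dimensional
random-effect blocks; and `full` (4 chains of 4000 + 4000, matching the
16,000 + 16,000 total-iteration scheme of the original analysis).

## The synthetic world

Every stage is testable without field data through a generator with known
ground truth:

* **Landscapes** are stationary Gaussian random fields (FFT convolution of
  white noise with a Gaussian kernel, sd = range/3 cells) for percent
  canopy, percent vegetation coverage and vegetation height, clamped to
  their physical ranges.  Only the autocorrelation structure matters
  downstream, which is why a full geostatistical simulator is not needed.
* **Wolf tracks** are biased correlated random walks at a 2-h fix
  interval: gamma step lengths whose mean follows a diel speed curve
  (crepuscular-peaked by default), wrapped-Cauchy turning errors, and a
  heading bias toward the territory center; positions reflect at the
  landscape boundary.
* **Kill sites** are drawn cell-wise within each pack's territory (the
  95th-percentile fix radius around the pack centroid) with probability
  proportional to `exp(beta' z)` over standardized landscape covariates,
  so `beta = 0` is exactly uniform.
* **Elk sessions** draw a date inside each maternal-period window, a
  daylight start between civil dawn and dusk (NOAA solar equations at the
  study-area coordinates), a location, herd composition (lognormal herd
  sizes around the observed mean of about 27), and session lengths of
  10-40 minutes (normal 19 +/- 5, truncated).  Given session covariates, a
  session-level composition is drawn from the Dirichlet truth and minutes
  are i.i.d. categorical given that composition — deliberately matching
  the fitted model's exchangeability assumption; within-session Markov
  dependence is an explicit non-goal.  Chewing flags for vigilance
  minutes come from the multitasking truth with a session random effect.
  Small fractions of minutes are recorded unknown (1%) or disturbed
  (0.5%) to exercise the filtering audit.

The default truth reproduces the study's bookkeeping exactly: 709 sessions
in a 103/182/345/79 maternal-period mix and 1052 vigilance minutes in a
164/367/421/100 mix, and its multitasking coefficients encode a risk slope
of +0.9 after parturition (reference LMP) and -0.9 before (PPP), i.e. the
qualitative sign structure of the published interaction.  Default
behavioral coefficients are moderate effects (|beta| 0.1-1 on the logit
scale) chosen once to mirror the published directions: foraging up and
resting down at crepuscular hours, vigilance up with risk and down with
herd size.

What passing tests on this world do *not* show: robustness to GPS fix
failure, observer effects beyond simple minute censoring, within-session
behavioral autocorrelation, territory drift, or mis-specified risk
covariates — the generator draws from the model family being fit
(that is what makes coverage and calibration interpretable).

## Calendar and spatial conventions

* Seasons: winter Jan 1 - Mar 31, spring Apr 1 - Jun 30, monsoon
  Jul 1 - Sep 30, fall the remainder (the cited season scheme is not
  defined in the source; this fixed scheme is configurable).
* Maternal periods: WP Jan 1 - Mar 31; PPP from Apr 1 to the day before
  parturition, or to Julian day 134 when parturition is unknown (mean
  parturition Julian day 152 minus 17.4 days gives 134.6, which is not a
  calendar day; the last full PPP day is 134).  The subtraction is applied
  as a total of 17.4 days as printed.  LMP is the next 45 days; SMP runs
  to Julian day 250 ("first week of September"), configurable.
* Diel periods: morning = civil dawn to dawn + 2.5 h; evening =
  dusk - 2 h to dusk; midday between; sessions spanning a boundary take
  the majority period.  Civil twilight is solar elevation -6 degrees from
  the standard NOAA solar-position equations; nights are out of scope.
* Openness: 500 m / 30 m = 16.7 pixels, rounded to the nearest odd
  integer, fixes the moving window at 17 x 17 pixels (510 m) with maximum
  count 289; edge pixels use the in-bounds window.
* Cover: open when coverage <= 16% and height <= 2 m, cover when
  coverage >= 17% and height > 2 m; the two rules do not exhaust the
  plane, so mixed cases are `unclassified` and treated as open for
  distance-to-cover.
* Buffer extraction: a cell belongs to a buffer when its *center* lies
  inside the circle (common raster semantics, cheap to verify by
  enumeration); at 200 m on the 380 x 450 m grid this usually reduces to
  the containing cell.
* Selection scores enter risk products on the exponential scale without
  the intercept, so a point at the training covariate means scores exactly
  1; whether the original analysis used the exponential or probability
  scale is not stated, and the exponential form is the standard RSF
  convention.
* The most-sampled wolf per pack is tie-broken by the smallest animal id,
  keeping builds deterministic.
* Complete separation in selection models (plausible with few kill sites)
  is flagged and the fit redone with a weak ridge (1e-4) on slopes.
* Zero risk values are log-transformed as `log(x + eps)` with `eps` the
  smallest positive observed value times 1e-3.

## Numerical choices and test design

* KDE bandwidths default to the per-coordinate normal-reference rule
  (none is stated in the source), floored at one cell so that degenerate
  fix clouds remain well defined; UDs are renormalized to sum to exactly 1.
* The k-fold machinery is generic over a fit/log-predictive interface, so
  a conjugate normal-mean model with a closed-form posterior predictive
  serves as an exact oracle: at K = n it must reproduce brute-force
  leave-one-out to machine precision.  PSIS-LOO is checked against the
  same conjugate model's analytic LOO and against exact refit LOO on a
  small Dirichlet fit.  The generalized-Pareto tail fit uses the
  Zhang-Stephens profile estimator with the tail fraction fixed at 20% of
  the draws; held-out herds and sessions in cross-validation get their
  random effects drawn from the prior per posterior draw (they are new
  groups under grouped folds).
* Pseudo-BMA+ applies the softmax per bootstrap replicate and averages
  (the "+" variant), with 1000 replicates by default.
* Recovery and calibration simulations generate compositions from the
  Dirichlet model's own process (session-level Dirichlet draws, large
  session lengths so the boundary squeeze is negligible): that is the
  design under which credible-interval coverage and rank uniformity are
  meaningful.  The generator's extra minute-level multinomial layer is
  kept for pipeline realism but attenuates slopes slightly, which is a
  model-misspecification effect, not an inference bug.
* Problem sizes used by the test suite and the acceptance script:
  100-replicate recovery studies at n = 700 sessions and n = 1000
  vigilance minutes with the `fast` preset, a 40-observation toy for
  exact-LOO equivalence, and a 6 x 6 km demo world for the end-to-end
  pipeline.  These sizes were chosen as the smallest at which the checks
  are statistically informative.

## Known limitations

* The sampler is tuned for the two model families shipped here; it is not
  a general-purpose probabilistic-programming backend.
* With the `fast` preset, weakly-identified per-session random effects in
  the multitasking model can fall short of the strict R-hat 1.01 flag even
  though the monitored fixed effects have effective sizes in the hundreds;
  use `thorough` when the convergence flag itself matters.
* Population-level UDs use one wolf per pack, so within-pack space-use
  heterogeneity is deliberately ignored at those scales.
* The RP model scores landscape-conditioned kill likelihood; it is not an
  estimate of encounter rate or per-capita predation hazard.
* Published posterior summaries from the field data are not reproducible
  from this package (the field data are not shipped); all quantitative
  guarantees are about the method's behavior on data with known truth.
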