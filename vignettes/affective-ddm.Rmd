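---
title: "An affective drift diffusion model of approach-avoidance conflict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An affective drift diffusion model of approach-avoidance conflict}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`aacddm` models two-choice approach-avoidance conflict decisions with a
drift diffusion model (DDM): noisy evidence accumulates between two
absorbing bounds separated by a distance $a$, starting from the relative
point $z \in (0,1)$, with mean rate $v$ (positive toward the upper,
*approach*, bound) and unit diffusion coefficient; the first bound crossed
determines the choice, and the response time is the crossing time plus a
non-decision time $ndt$ for stimulus encoding and the motor response. The
likelihood of a (choice, RT) pair is the Wiener first-passage-time (wfpt)
density.

What makes the model *affective* is that the three decision parameters are
trial-level linear functions of the offer and of trial-by-trial neural
activity in four regions of interest (ROIs):

$$v_t = \beta^v_0 + \beta^v_r \log(\mathrm{reward}_t) + \beta^v_s\,
\mathrm{aversiveness}_t + \beta^v_c\,\mathrm{caudate}_t + \beta^v_p\,
\mathrm{pACC}_t + \beta^v_{rc}\log(\mathrm{reward}_t)\,\mathrm{caudate}_t +
\beta^v_{sp}\,\mathrm{aversiveness}_t\,\mathrm{pACC}_t + \beta^v_d\,
\mathrm{dReward}_t$$

$$a_t = \beta^a_0 + \beta^a_{stn}\,\mathrm{STN}_t + \beta^a_c\,
\mathrm{conflict}_t + \beta^a_{cs}\,\mathrm{conflict}_t\,\mathrm{STN}_t$$

$$z_t = \beta^z_0 + \beta^z_p\,\mathrm{Pav}_t + \beta^z_n\,
\mathrm{NAcc}_t + \beta^z_{np}\,\mathrm{NAcc}_t\,\mathrm{Pav}_t$$

with $ndt$ a subject-level constant. Here *conflict* is the absolute
difference between the raw offered reward and aversiveness; *dReward* flags
zero-reward offers; *Pav* flags trials on which approach required pushing
the joystick (the Pavlovian-congruent mapping). All non-dummy regressors
are z-scored before analysis; the log-reward term is defined as
$\log(\mathrm{reward})$ for positive rewards and $0$ at zero reward, with
the dReward dummy absorbing the zero-offer offset (the log transform alone
is undefined there). The links are identity links: trial parameter values
with $a_t \le 0$ or $z_t \notin (0,1)$ carry zero posterior mass rather
than being squashed through a transform, because the reference posterior
means (e.g. a starting point near 0.54) are on the natural scale.

**Standardization scope.** z-scoring is applied within subject by default.
Single-trial fMRI activation estimates have subject-specific scanner scale,
so within-subject scaling is required for the ROI columns; for coherence
the offer-derived regressors are scaled the same way. `build_design(...,
scope = "pooled")` switches to pooled-sample scaling for sensitivity
analyses.

## Likelihood and simulator

The wfpt density is evaluated with the standard small-time and large-time
series expansions and accuracy-driven term counts (automatic regime
selection; truncation error bounded by `err`, default $10^{-7}$). The
lower-bound (avoid) density follows from the reflection $v \to -v$,
$z \to 1 - z$. For MCMC the log density is floored at $\log(10^{-12})$ so
that stray trials (e.g. RTs at or below a proposed non-decision time)
yield a finite penalty instead of $-\infty$; floor activations are counted
and reported in the fit diagnostics.

The trial simulator integrates the diffusion by Euler-Maruyama with step
`dt` (default 1 ms). Within each step an exact Brownian-bridge crossing
probability is applied between the two interior endpoints, which removes
most of the first-passage discretization bias of the naive scheme; at
`dt = 1e-4` the simulated choice/RT distribution agrees with the analytic
density to a total-variation distance below 0.01 (this is one of the
package's standing validation tests, together with the closed-form upper-
bound absorption probability $(1-e^{-2vza})/(1-e^{-2va})$). Paths that
exceed the 20 s decision-time cap are resampled, with the count reported.

## Synthetic data: what it emulates, and what it does not

`generate_task()` reproduces the task structure: 105 trials over 3 runs;
16 reward levels crossed with 6 aversiveness levels, both equally spaced on
$[0,5]$ (the source material gives counts and range; equal spacing is the
simplest faithful choice); the double-zero offer excluded; offers sampled
uniformly over the 95 admissible cells (the sampling scheme over the grid
is not documented; uniform is assumed, and with 105 trials exact cell
balance is impossible anyway); the Pavlovian mapping dummy randomized and
counterbalanced to within one trial.

`generate_roi_signals()` draws per-trial ROI "activations" as standard
normal noise, optionally linearly coupled to the z-scored offers, then
z-scores each series. It deliberately does **not** simulate BOLD time
series, hemodynamics, or least-squares-separate estimation: trial betas
are generated directly at the statistical level the model consumes.
Passing tests on such data demonstrates that the estimation machinery is
correct; it does not establish robustness to autocorrelated, heavy-tailed
or motion-contaminated single-trial estimates from real scanners.

`generate_dataset()` draws subject-level intercepts
($\beta^a_0, \beta^v_0, \beta^z_0, ndt$) from group means with
between-subject standard deviations, mirroring the estimation model in
which only intercept-type parameters vary by subject. The default sds
(0.3, 0.4, 0.04, 0.1 respectively) are typical between-subject spreads for
unit-diffusion DDM fits of comparable tasks; they matter mainly for how
much shrinkage the hierarchy exhibits. Draws violating $a>0$,
$z \in (0,1)$ or $ndt \ge 0$ are redrawn. Group-mean defaults come from
the published posterior means of the final model
(`reference_coefficients("HC")` / `"MDD"`).

One property worth spelling out: the *mean* approach fraction is **not**
monotone in the generating reward slope under the reference conditions.
With a positive drift intercept (0.665), a steeper reward slope raises
drift on high-reward offers but pushes low-reward offers below zero drift,
and the net effect on the average (computable in closed form from the
absorption probabilities) is a mild decrease. What is monotone — and what
the test suite asserts — is reward *discriminability*: the approach-rate
gap between high- and low-reward offers.

## Hierarchical estimation

Subject-level parameters are drawn from population normals with unknown
mean and sd; slope coefficients are estimated at the group level (they are
poorly identified per subject from ~105 trials of noisy neural
regressors), except in the `"single-population"` grouping used for
classification, where *all* coefficients are subject-level under a single
population distribution so that per-subject estimates exist and are not
shrunk toward diagnosis-specific means.

Default priors (all configurable via `ddm_priors()`): threshold intercept
$\mathcal N(1.5, 0.75^2)$ truncated to $(0,\infty)$; drift intercept
$\mathcal N(0, 2^2)$; starting point intercept $\mathcal N(0.5, 0.25^2)$
truncated to $(0,1)$; non-decision time $\mathcal N(0.4, 0.35^2)$
truncated to $[0,\infty)$; slopes $\mathcal N(0, 10^2)$; between-subject
sds half-normal with scale 1. These are weakly informative on the
unit-diffusion scale; the reference analysis used its toolbox's empirical
priors, which are not printed, so these stand-ins are deliberately
conservative and kept configurable.

**Sampler.** Estimation uses adaptive single-site random-walk
Metropolis-within-Gibbs in compiled code: scalar Metropolis updates for
every coefficient (with per-site proposal scales adapted toward 0.44
acceptance during burn-in only, frozen afterwards, so the post-burn-in
chain is a valid Markov chain), conjugate truncated-normal Gibbs updates
for population means, log-scale Metropolis for population sds, and two
joint "funnel" moves per subject-level coefficient — a multiplicative
rescaling of the subject deviations together with their population sd, and
a joint translation of the mean with all subject values — which decorrelate
the hierarchy when the likelihood identifies subject values only weakly.
Proposals implying any trial with $a_t \le 0$ or $z_t \notin (0,1)$ are
rejected (zero posterior mass). Chains run sequentially from mildly
overdispersed starts; identical seeds give bit-identical draws.

Convergence is monitored with the classic Gelman-Rubin statistic per
parameter (exact-copy chains give $\sqrt{(n-1)/n}$); fits warn when any
group-level parameter reaches 1.1. Model comparison uses
$\mathrm{DIC} = \bar D + p_D$ with $p_D = \bar D - D(\hat\theta)$
evaluated at posterior means, on the same floored likelihood the sampler
uses.

**Protocols.** The reference protocol is 5 chains of 5000 samples with
2500 burn-in. The package's own simulation studies and tests use a
desk-scale profile — typically 2–3 chains of 1000–1500 samples (400–500
burn-in) with 6–24 subjects of 105 trials — at which the recovery and
convergence results in the test suite reproduce stably; the protocol
arguments of `fit_ddm()` accept the full reference settings unchanged.

## Posterior analysis

Group effects are posterior distributions of differences between group
posteriors, summarized by $p(A>B)$ (exact ties counted half, preserving
complementarity) and 95% highest-density intervals (sorted-window method).
Draw sequences of unequal length are paired after resampling the shorter
with replacement; the pairing rule is not documented in the reference
analysis and is irrelevant for independent chains. The posterior
predictive check simulates replicate datasets on the observed designs from
posterior draws and overlays approach proportions and signed RTs (avoid
RTs negative) per offer cell; cells default to the 6 aversiveness levels
by 6 equal-width reward bins, since the exact cell definition of the
reference figure is not printed, and the binning is configurable.
Behavioral group comparisons (approach rate, RT) are hierarchical Bayesian
logistic/linear regressions with subject intercepts, fitted with JAGS.
Test-retest reliability uses the two-way mixed-effects, consistency,
single-measures ICC; the reference analysis says only "two-way", and the
consistency form is the natural choice when session means may shift.

## Classification

Diagnosis is predicted from per-subject posterior means of the
single-population fit (all coefficients, or the behavioral-only subset, or
raw behavioral/ROI summaries for the baseline comparison) with
L2-regularized logistic regression: repeated stratified 10-fold CV on a
70% training portion over a strength grid $10^{-3}\dots10^3$, the
configuration with the highest mean CV AUC refit and evaluated on the 30%
held-out portion, with standardization always computed from training data
only. Ties in CV AUC (e.g. perfectly separable data) break toward the
least-shrunk fit, otherwise perfect separation would be reported with
chance-level thresholded accuracy. Because "iteratively predict" is
ambiguous between one fixed and repeated holdout splits, the default
repeats the whole split 10 times and reports the mean held-out AUC;
`n_splits = 1` reproduces the single-split reading. AUC is computed by
average ranks, which equals brute-force pairwise comparison exactly and
carries the probability interpretation.

Two caveats the simulations make visible: with ~40 subjects the held-out
AUC has large split-to-split variance (the repeated-split mean is the more
stable summary), and leave-one-subject-out on balanced null data is
pessimistically biased below 0.5 (each training fold's majority class is
the one opposite the held-out subject), so LOSO chance levels should be
read against that bias.

## Numerical choices and limitations

* Diffusion coefficient fixed at 1; all coefficient magnitudes are on that
  scale. No inter-trial variability parameters (sv, sz, st).
* wfpt truncation error $10^{-7}$; likelihood floor $10^{-12}$; simulator
  step 1 ms (0.1 ms in validation runs); decision-time cap 20 s.
* The model-comparison simulation generates a Pavlovian starting-point
  shift of 0.06 — a plausible but deliberately detectable effect at 12
  subjects — because a recovery study at the reference effect size (0.018,
  below one posterior sd at this cohort size) would only measure noise.
* Single-site Metropolis mixes adequately at these problem sizes but is
  not gradient-based; very large cohorts would warrant HMC.
* Only the theoretically motivated model ladder is implemented; there is
  no free-form formula interface.
* Clinical-scale regressions and fMRI preprocessing are out of scope;
  ROI betas enter as data.
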