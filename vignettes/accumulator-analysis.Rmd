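---
title: "Modeling pulse-based evidence accumulation with puffddm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling pulse-based evidence accumulation with puffddm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puffddm)
```

## The task and the data model

`puffddm` analyses a two-alternative forced-choice task in which a
head-fixed mouse receives two independent streams of randomly timed air
puffs, one per whisker field, over a cue period (3.8 s on 85% of trials,
1.5 s otherwise), holds the evidence across an 800-ms delay, and then
reports the side with more puffs by licking one of two ports. A trial
record (`trial()`) stores the per-side puff onset times (seconds from cue
onset), the timing structure, an optional optogenetic light window with
its laterality, a guided-trial flag, the first-lick choice and the correct
side. Times during the delay are indexed as `cue_duration + offset`. A
puff's 40-ms width is deliberately not represented: every analysis treats
a puff as an instantaneous event at its onset.

Three analysis branches operate on `trial_set` collections, all using the
same inclusion rules (decision-made trials; the primary 3.8-s cue period;
guided trials excluded everywhere except the dedicated response-capability
summaries):

1. a five-parameter pulse accumulator fitted by maximum likelihood,
2. a logistic regression of choice on temporally binned evidence, and
3. psychometric summaries.

## The accumulator model

The decision variable $a(t)$ starts at 0 at cue onset and evolves as

$$\mathrm{d}a = \sigma_a \mathrm{d}W + \lambda a\,\mathrm{d}t +
\left(\delta_{t,t_R}\,\eta_R - \delta_{t,t_L}\,\eta_L\right),$$

with each puff contributing an i.i.d. increment $\eta \sim N(1,
\sigma_s^2)$, signed positive for right and negative for left. The five
parameters, with units and defaults used in the synthetic study:

| parameter    | meaning                                    | units     | baseline regime |
|--------------|--------------------------------------------|-----------|-----------------|
| $\lambda$    | memory drift: leak ($<0$) or instability ($>0$); $\tau = 1/|\lambda|$ | 1/s | $-1/6.7$ |
| $\sigma_a^2$ | diffusion noise added continuously          | units²/s  | 0.5             |
| $\sigma_s^2$ | noise attached to each single puff          | units²    | 1               |
| bias         | decision-threshold offset on $a$            | units     | 0               |
| lapse        | probability of a random choice              | —         | 0.05            |

The accumulation horizon runs to the end of the delay (the decision
point), so leak acts on the memory across the delay as well as within the
cue period. The choice rule is rightward when $a$ ends above the bias
threshold, degraded by the lapse: $P(\text{right} \mid a > \text{bias}) =
1 - 0.5\,\text{lapse}$. Mass exactly at the threshold splits 50/50, which
makes the left/right mirror symmetry of the model exact (swapping puff
sides and negating the bias maps $P(\text{right})$ to $1 -
P(\text{right})$); this symmetry is enforced by tests.

### Three equivalent evaluation routes

The model has no absorbing bound — exactly the five parameters above are
implemented, with the effectively infinite bound realized as an auto-sized
grid — and an unbounded linear SDE driven by Gaussian pulses has an
exactly Gaussian state distribution. `puffddm` therefore evaluates the
choice probability of a trial in three ways that are cross-checked against
one another:

- **Forward simulation** (`simulate_accumulator()`,
  `simulate_endpoints()`): discrete steps of `dt` (default 15 ms, the
  step used for all simulation-based results). Puffs are applied at the
  start of the step containing their onset; the drift over a step uses
  the exact one-step multiplier $e^{\lambda\,dt}$, whose first-order
  expansion is the Euler rule $1 + \lambda\,dt$. Using the exact
  multiplier costs nothing and makes the noise-free single-pulse response
  match the closed form $e^{\lambda \Delta t}$ to machine precision
  rather than to $O(\lambda^2 dt)$.
- **Grid propagation** (`propagate_distribution()`): the probability
  distribution of $a$ on a uniform grid (spacing 0.02 units by default)
  is propagated step by step — puff kernels $N(\pm 1, \sigma_s^2)$
  integrated over grid cells, mass-conserving two-point redistribution
  along the drift map $x \mapsto e^{\lambda dt}x$, then an integrated
  Gaussian diffusion kernel $N(0, \sigma_a^2 dt)$. Total mass is
  conserved to $10^{-9}$ per trial; mass leaking past the grid edges is
  tracked and raises an error beyond $10^{-8}$ rather than being
  silently truncated. The same puff-at-step-start convention as the
  simulator makes the two discretizations agree exactly in
  distribution, so their comparison is limited only by Monte-Carlo
  error.
- **Closed form** (`ddm_moments()`, the `"closed"` method): mean
  $\sum_j s_j e^{\lambda (T - t_j)}$ and variance $\sigma_s^2 \sum_j
  e^{2\lambda (T - t_j)} + \sigma_a^2 (e^{2\lambda T} - 1)/(2\lambda)$.

Likelihood-based fitting uses the closed form: it is the exact solution
of the same SDE, agrees with the grid to the discretization error
(verified below $5 \times 10^{-3}$ per trial in tests), and is what makes
repetition-heavy fitting protocols tractable in pure R. The grid route
remains the reference implementation of the distribution propagation and
is exercised directly by the test battery (grid vs 50,000-path simulation
on random trial/parameter instances).

### Fitting protocol

`fit_ddm()` follows a subsample-repetition protocol: each repetition
omits a random 20% of trials, draws a random initialization ($\lambda \in
[-5, 5]$, variances in $[0, 20]$, bias in $[-3, 3]$, lapse in $[0, 1]$ —
ranges are configurable), and maximizes the likelihood with BFGS on
unconstrained coordinates (log-variances, logit-lapse) using
central-difference gradients. Because the likelihood has a flat
chance-performance plateau at lapse $\to 1$ that can capture ascent from
very poor starting points, each repetition screens several random
candidates by likelihood and starts from the best; this keeps the
repetitions honest draws of the subsampling distribution while avoiding a
known degenerate attractor. A repetition is accepted only if the
optimizer converged and the numerical Hessian of the negative
log-likelihood at its optimum (natural scale, `pracma::hessian`) is
positive semidefinite to a relative eigenvalue tolerance of $10^{-6}$.
Medians and 2.5/97.5% quantiles across accepted repetitions summarize the
fit; held-out choice-prediction accuracy thresholds $p(R\mid\theta)$ at
0.5 (an exact 0.5 predicts right, a documented tie-break). The full
protocol uses 1000 repetitions; the package defaults to a 50-repetition
profile, and the examples and acceptance script use 10-50 repetitions —
repetition quantiles widen, medians are stable.

Two caveats discovered with the synthetic generator are worth knowing.
First, $\sigma_s^2$ and $\sigma_a^2$ trade off strongly below roughly
$10^4$ trials: datasets exist where most noise is attributed to the wrong
source with almost no likelihood penalty; $\lambda$, bias and held-out
accuracy are unaffected. Second, when the true lapse is small, the
per-subsample lapse estimate piles on the 0 boundary and its repetition
median is biased low by roughly its own standard error; the repetition
mean or the full-data fit is closer to truth. Model comparison uses
$\mathrm{BIC} = \ln L - k \ln n / 2$ — note the sign convention, larger
is better, and `relative_bic()` is positive when the reduced variant
(lapse and/or bias fixed at 0) is favored.

## Choice regression

`fit_choice_regression()` fits $\ln \frac{p}{1-p} = \sum_i \beta_i E_i$
with no intercept, where $E_i$ is the #R − #L puff count in the $i$-th of
three temporally uniform bins of the cue period. Bin edges are computed
in full precision as $i \cdot \text{cue}/n$ (for the 3.8-s cue:
1.2667 and 2.5333 s); bins are half-open on the right, so a puff exactly
at an interior edge belongs to the later bin — a deterministic convention
matching the left-closed time indexing used everywhere. Uncertainty comes
from asymptotic standard errors, 99% confidence intervals (matching the
convention used for significance in this analysis), and a 100-resample
bootstrap. Predictive accuracy uses stratified 3-fold cross-validation.
Near-deterministic synthetic agents can separate the data completely; the
unpenalized fit then raises an instructive error, and a tiny ridge
penalty (`ridge = TRUE`, glmnet) is available by explicit flag only —
never silently.

For sub-cue-period light conditions, `align_weights_to_light()`
re-indexes each condition's weights by lag relative to the light-carrying
bin and averages across conditions wherever a lag exists (e.g. the lag +1
mean combines bin 2 of the first-third condition with bin 3 of the
middle-third condition); per-lag bootstrap SDs are propagated from the
per-condition bootstrap draws. `shuffle_control()` permutes the condition
labels across light-on trials before the per-condition regressions,
destroying any real association between light timing and evidence
weighting.

## Psychometrics

`performance_summary()` reports fraction correct with Jeffreys binomial
intervals (central quantiles of $\mathrm{Beta}(k + \frac12, n - k +
\frac12)$, lower bound 0 at $k = 0$, upper bound 1 at $k = n$), verified
in tests against an independent quadrature-based Beta-quantile oracle to
$10^{-9}$. `fit_psychometric()` fits the four-parameter logistic $y(x) =
y_0 + A/(1 + e^{-(x - x_0)/b})$ to the right-choice fraction versus total
evidence $x = \#R - \#L$, weighted by per-$x$ trial counts (trials
pooled, as in a meta-mouse analysis). The fit uses bounded
Levenberg–Marquardt ($y_0 \in [0, 0.5]$, $A \in [0, 1]$, $b \in [10^{-3},
50]$) because step-like choice data from near-deterministic agents drives
$b$ toward 0 and an unconstrained least-squares fit degenerates there.
Both the parametric curve and the empirical per-$x$ fractions are
retained in the fit object, since either rendering may be wanted.

## The synthetic task generator

The generator is first-class, tested code, and its defaults are the study
conditions — they are not tuned per analysis:

- **Puff trains** are renewal processes with inter-event interval
  $0.2 + \mathrm{Exp}(\text{mean} = 1/2.5 - 0.2)$ s, making the 2.5-Hz
  mean rate and the 200-ms refractory period both exact in expectation
  (the generating process of the original rig is not specified; a renewal
  construction is the simplest process satisfying both stated
  constraints, and the 2.5-Hz figure is taken as the realized mean).
- **Cue durations** are 3.8 s with probability 0.85, else 1.5 s; the
  delay is 0.8 s; tie trials (#R = #L) are regenerated because the
  correct side is undefined for a tie and the task rewards the side with
  more puffs.
- **Light windows** per condition: full cue; first/middle/last third of
  the cue; the full delay or its first 200/500 ms — each a distinct
  condition label. Light-on trials are interleaved uniformly at random at
  a configurable 15-30% fraction.
- **Guided trials** carry a single-sided cue train plus regular 2.5-Hz
  guide puffs through the delay.
- **Agents**: a psychometric agent drawing choices from a curve evaluated
  at the trial's total (or impairment-weighted) evidence, and an
  accumulator agent forward-simulating the model at 15-ms steps. The
  default agent curve (`psychometric_curve()`: $y_0 = 0.05$, $A = 0.9$,
  $x_0 = 0$, $b = 2$) mimics a well-trained mouse with a small symmetric
  lapse floor and realistic overall accuracy; it was fixed once as a
  study condition.
- **Impairment scenarios** (`apply_impairment()`): *sensation* weights
  puffs coinciding with the light window by an attenuation factor
  (default 0.5) before summing effective evidence; *retention* attenuates
  puffs preceding light onset; *action* draws the choice normally and
  flips it with probability $\min(1, \kappa / \Delta t_{\text{lick}})$
  where $\Delta t_{\text{lick}}$ is the time from light offset to the
  decision lick ($\kappa$ defaults to 0.4 s; the proportionality constant
  is not specified by the protocol this emulates, and decision latencies
  are synthesized as a configurable 578-ms lick latency after the delay);
  *lapse_flip* flips a uniformly random fraction (default 25%) of
  choices, which is analytically equivalent to a lapse of twice the flip
  fraction. Effective evidence can be non-integer after attenuation; the
  psychometric curve is simply evaluated at the non-integer value (for a
  parametric curve no interpolation is needed; a user-supplied empirical
  curve should interpolate).

With attenuation 0.5 and a mostly-logistic agent curve, the asymptotic
weight drop of a single attenuated bin is exactly 50%; the retention
scenario attenuates two bins and lands reliably above 50%, while the
sensation scenario's single-bin drop straddles 50% — which is why the
package's qualitative dissociation checks test *depression plus
unchanged-within-CI*, not a strict 50% threshold, on the sensation side.

### What the generator does and does not emulate

It reproduces the stimulus statistics (rates, refractory period, cue/delay
structure, condition interleaving) and choice generation from known
mechanisms, which is exactly what parameter-recovery and signature tests
need. It does not emulate session-to-session drift, motivation and
satiety, lick kinematics, within-session learning, serial choice
dependencies, or the rig's empirical difficulty distribution (the real
per-side puff-count distribution is only approximately matched). Passing
tests therefore demonstrate estimator correctness under the stated
generative assumptions, not robustness to every property of real
behavior.

## Numerical choices

- `dt = 15 ms` (simulation convention) and grid spacing 0.02 units;
  halving both changes grid choice probabilities by less than $10^{-3}$.
- Grid half-width auto-sizes to total puffs $+ 6\sigma_{\text{total}} +
  |\text{bias}| + 1$, inflated by $e^{\lambda T}$ for unstable drift;
  strong instability ($e^{\lambda T} > 100$) errors out rather than
  producing an unreliable grid.
- Gaussian kernels are integrated over grid cells (not point-sampled) and
  renormalized, so convolution conserves mass at any kernel width; a
  zero-variance puff is a pure (fractional-cell) shift.
- Per-trial log-probabilities are floored at `log(.Machine$double.xmin)`.
- Exponential overflow in the closed form is avoided by clamping
  $\lambda$ to $[-50, 50]$ /s inside the likelihood, far outside any
  behaviorally meaningful regime.
- Parameter transforms (log, logit) are exact inverses to $10^{-12}$;
  optimizer: BFGS, `reltol` $10^{-9}$, central differences with relative
  step $10^{-5}$.
- Problem sizes in tests and the acceptance script (4,000-10,000 trials,
  10-50 repetitions) were chosen as the smallest sizes at which the
  recovery properties stabilize.

## Known limitations

- No absorbing decision bound and no reaction-time modeling: the model
  explains choices, not response times.
- No sensory adaptation or pulse-depression dynamics; every puff carries
  the same mean increment.
- Lapse and the noise variances are weakly identified against each other
  below roughly $10^4$ trials (see the fitting caveats above).
- The regression branch fits pooled trials by default; per-subject
  random-effects structure is out of scope (per-subject fits can be run
  by filtering and refitting).
- Analyses are per-condition; hierarchical sharing of parameters across
  light conditions is not implemented.
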