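---
title: "Methods: winter behaviour, phenology and breeding-state dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: winter behaviour, phenology and breeding-state dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models behind `shearwaterCOE`, their
assumptions, the tunable parameters and the numerical choices, in the
order the pipeline runs them. It states no empirical result beyond what
the package's tests and `scripts/acceptance.R` themselves compute.

## 1. The question and the data model

Carry-over effects are influences of one life-history stage on
performance in a later one. For a colonial, trans-equatorial migrant
seabird the chain of interest is: breeding phenology in year $t$ →
at-sea behaviour in the intervening winter → reproductive performance
(RP) in year $t+1$, where RP is a three-level category: raised a chick
(`SUCCESS`), failed during incubation (`FAIL`), or did not lay
(`SKIP`).

Three observation streams feed the analysis:

* an **immersion series** per bird-winter: one wet fraction in $[0,1]$
  per fixed logging block, with a daytime flag;
* a **phenology record** per bird-winter: integer event dates (days
  from a 1 March season anchor) for prior-season lay/hatch/fledge,
  colony departure/arrival and wintering-ground (WG) arrival/departure,
  plus sex and the RP label;
* an **encounter history** per bird: one event per breeding season in
  {not seen, seen successful, seen failed, seen skipping, seen
  state-unknown}.

## 2. Synthetic colony generator

No field data ship with the package; the generator (`sim_config()`,
`simulate_*()`) emulates all three streams with the study's group
structure — 111 logger bird-winters split 64/29/18 across
`SUCCESS`/`FAIL`/`SKIP`, plus 88 history-only birds — so the whole
pipeline is runnable, and so that tests can check estimators against
*known* generating parameters.

Defaults, chosen once as the package's study conditions:

* **Transitions** `default_psi()`: rows give each current state's
  next-year distribution; the SUCCESS column is (0.57, 0.61, 0.79) from
  `SUCCESS`/`FAIL`/`SKIP`, i.e. skipping birds have the highest
  next-year success chance. Survival $\phi = 0.90$ (typical for a
  long-lived procellariiform adult), detection $p = 0.85$, six
  occasions.
* **Phenology** `default_phenology()`: group means shift later by 5
  days from `SUCCESS` to `FAIL` and again to `SKIP` (early birds do
  better), SD 6 days for breeding events and 8 for migration events;
  dates are rounded to whole days and the ordering
  lay < hatch < fledge < departure < WG arrival < WG departure < arrival
  is enforced by rejection (≤ 1000 attempts per bird, then an error
  naming the group).
* **Activity budgets** `default_activity()`: daytime (fly, rest,
  forage) proportions are piecewise-linear in winter day with a common
  node at day 60 (flight ramps up towards spring return), plus Gaussian
  day-level noise (SD 0.03, clipped and renormalised). The skip group
  is hyperactive — more flight, much more foraging, less resting — and
  the success group forages least.
* **Logger sampling**: 10-minute blocks (1440 must be divisible by the
  block length), a fixed 07:00–19:00 daytime mask (positioning from
  light data is out of scope, so day length is configuration, not
  computation), flight emits a dry block (0), resting a wet block (1),
  foraging a uniform draw on (0.2, 0.8) — the intermediate wet/dry
  mixing that is the standard foraging signature.

What the generator does **not** emulate: spatial movement and
environmental covariates; weather-driven autocorrelation in behaviour
(noise is independent across days); missing logger days; age structure;
and any real sex differences (sexes are exchangeable by construction).
Passing tests therefore demonstrate correctness of the estimators under
the stated model, not robustness to every property of field data.

All generators are deterministic given `seed`; the pipeline derives
per-stage child seeds from one global seed.

## 3. Activity classification

`classify_block()` maps a wet fraction to FLY (≤ `dry_max`), REST (≥
`wet_min`) or FORAGE (between). Defaults (0.05, 0.95) tolerate brief
splashes during flight and dry shakes while resting. The published
flight-classification rule for these loggers lives in supplementary
material we do not reproduce; the threshold rule here is the package's
own operationalisation and both thresholds are exposed. Budgets are
computed per calendar day over daytime blocks only (a flag admits night
blocks for exploration); days are bounded by midnight in the logger's
own clock and no timezone conversion is attempted.

## 4. Segmented regression of flight activity

For daily flight proportion $y$ against winter day $x$ the broken-line
model is $y = \beta_0 + \beta_1 x + \sum_{j=1}^{k}\delta_j(x-\tau_j)_+$.
`fit_segmented()` estimates $\tau$ by iterative linearization: the
working model adds step indicators $-\mathbf 1(x>\tau_j)$; each
iteration updates $\tau_j$ by the ratio of the indicator to the hinge
coefficient. Numerical choices:

* convergence when $\max_j|\Delta\tau_j| < 10^{-6}$ winter-days, at most
  50 iterations; a non-converged best iterate is returned flagged;
* breakpoints constrained to $[x_{(3)}, x_{(n-2)}]$ and kept distinct;
* several deterministic quantile-spread initialisations, then
  **bootstrap restarting**: each restart re-estimates $\tau$ on a
  case-resampled copy and uses the result to re-initialise the fit on
  the original data (10 restarts by default), keeping the best-RSS
  solution;
* a final coordinate-wise golden-section polish of each $\tau_j$,
  because the linearized fixed point can sit a fraction of a grid step
  from the RSS minimum;
* standard errors for $\tau_j$ by the delta method,
  $\mathrm{se}(\gamma_j)/|\hat\delta_j|$, from the working model.

The number of breakpoints is chosen by `select_n_breakpoints()` over
$k = 0..k_{\max}$ using BIC by default (the Gaussian criterion with
$2+2k$ regression parameters plus the error variance). BIC rather than
AIC guards against overfitting short winter series; the source analysis
does not state its selection rule, so this is a package decision and
AIC is available. Ties break towards smaller $k$, then smaller first
$\tau$. Fits with $k+1$ breakpoints are warm-started from the
$k$-breakpoint solution (plus one breakpoint in the widest gap), which
guarantees RSS is non-increasing in $k$; an effectively-zero RSS is
floored at $10^{-12}\,\mathrm{TSS}$ so rounding noise on noiseless data
cannot reward spurious extra breakpoints. Degenerate inputs error:
fewer than $2(k+2)$ points, constant $y$, unsorted $x$.

Tests verify exact recovery on noiseless data ($|\hat\tau - \tau| <
10^{-6}$, slopes to $10^{-8}$) and agreement with an exhaustive
grid-search oracle (breakpoints restricted to observed $x$) on noisy
one- and two-break data.

## 5. SAMME multi-class boosting

`train_samme()` implements the multi-class generalisation of AdaBoost.
With $K$ classes and weighted misclassification error
$\mathrm{err}_m$ of the round-$m$ weak learner,

$$\alpha_m = \ln\frac{1-\mathrm{err}_m}{\mathrm{err}_m} + \ln(K-1),$$

misclassified weights are multiplied by $e^{\alpha_m}$ and renormalised;
prediction is $\arg\max_k \sum_m \alpha_m \mathbf 1[h_m = k]$ with ties
broken by class order. At $K=2$ this is classical AdaBoost exactly. A
round with $\mathrm{err}_m \ge (K-1)/K$ (no better than guessing) is
discarded and boosting halts — if that happens on round one the learner
is kept with weight zero so the model remains usable; a perfect round
caps $\alpha$ at $\ln 10^{10}$ and halts. The weak learner is a
depth-capped CART tree (a stump by default; the base learner is not
specified by the source analysis) fitted by `rpart` with case weights,
with competitor and surrogate splits disabled so that feature
importances — $\alpha$-weighted sums of primary-split impurity
improvements, normalised to 1 — are unambiguous.

Supporting machinery:

* `cv_error()`: stratified $k$-fold CV (default 10); classes smaller
  than $k$ simply miss some folds. The pooled error and
  `success_rate = 1 - error_rate` (exactly) are returned.
* `permutation_pvalue()`: labels are permuted **within sex strata** so a
  pure sex-composition signal survives under the null; the add-one
  estimator $p = (1+\#\{\mathrm{err}^\ast \le \mathrm{err}\})/(B+1)$
  bounds the smallest attainable $p$ at $1/(B+1)$. Whether the original
  analysis permuted labels or compared against majority-class chance is
  not stated; permutation is this package's choice.
* `drop_correlated_features()`: greedy — while any $|r| >$ threshold
  (default 0.9), drop from the worst pair the feature with the larger
  mean absolute correlation. Constant features have no defined
  correlation: they are flagged and excluded from the test but kept in
  the data.
* Records with missing selected features are dropped with a message;
  the feature registry is configurable because the full published
  feature list lives in supplementary material.

## 6. Trend decomposition and group contrasts

`decompose_additive()` is the classical additive decomposition:
centred moving-average trend of window `period` (2×MA for even
periods), seasonal as the period-position means of the detrended
series centred to zero, remainder as the residual — so
`observed = trend + seasonal + remainder` holds *exactly everywhere*.
At the edges, where the moving average is undefined, the nearest
defined trend value is carried outward and flagged; seasonal means use
only interior points so edge carry-over cannot leak into the seasonal
term. The default period is 7 days — no cycle is stated by the source
analysis, and weekly artefacts are the only plausible one at daily
resolution; `period = 0` disables the seasonal term. Series shorter
than two windows error.

`group_mean_trend()` aligns winters on days since colony departure
(each logger series starts at departure), truncates to the span common
to all usable birds (avoiding composition bias at the late-winter
edge), and averages trend components pointwise within groups.

Contrasts (`compare_groups()`) are two-sample Kolmogorov–Smirnov tests
— the original analysis does not name its test; KS is this package's
choice — per activity and unordered group pair, with Bonferroni
correction across the whole family (pairs × activities) at family
$\alpha = 0.01$. RP contrasts pool birds' trend values; sex contrasts
use per-bird winter means at raw $\alpha$, because pooling thousands of
autocorrelated bird-days would make any negligible sex difference
"significant". Exact small-sample p-values come from `stats::ks.test`;
for extreme scaled statistics whose asymptotic code overflows to `NA`
the classical Kolmogorov series is evaluated directly. Identical
constant samples are reported as $D = 0$, $p = 1$.

## 7. Multi-event capture–mark–recapture

Latent states are {SUCCESS, FAIL, SKIP, DEAD}; DEAD is absorbing and
emits only `NOT_SEEN`. One step of the chain survives with
$\phi(\text{state}, \text{sex})$, then transitions among live states by
the row-stochastic $\psi$ (state-, sex- and year-dependence switchable;
year effects are fixed occasion effects on $\psi$). Observation of a
live bird succeeds with probability $p$ (optionally by sex); a
successful observation records the true state, or `SEEN_UNKNOWN` with
a fixed configurable probability. The likelihood of a history is the
hidden-Markov forward recursion conditioned on first capture (all study
birds were experienced breeders at entry, so recruitment is not
modelled): the release event fixes the initial state — uniform over
live states for a state-unknown release — and `NOT_SEEN` contributes
$1-p$ for live states and 1 for DEAD. Finite-mixture individual
heterogeneity enters as $C$ latent classes with weights $\pi_c$ and
class-specific $\psi$ (or $\phi$); per-class likelihoods combine as
$\sum_c \pi_c L_c$ before the log, evaluated on the log scale with
per-occasion scaling.

Fitting (`fit_mecmr()`) maximises the joint log-likelihood by BFGS on
link scales (logit for $\phi, p$; multinomial logit with SUCCESS
baseline for $\psi$ rows; logit-simplex for $\pi$) from `n_starts`
jittered initialisations (default 10; the first start is the neutral
point $\phi = 0.85$, $p = 0.8$, uniform $\psi$). Standard errors come
from the numerically differentiated Hessian; a non-invertible Hessian
leaves them `NA` and flagged — typical when a mixture class degenerates
— and link-scale estimates beyond ±9 are flagged as boundary MLEs. A
warning is raised when the parameter count reaches the data's degrees
of freedom. `model_table()` ranks fits on identical data by AIC
($= 2K - 2\ell$).

Derived quantities (`longrun_success()`): the phrase "in the long run"
is ambiguous between one-step and equilibrium readings, so both are
exposed — `next_year` (the SUCCESS column of $\psi$; the default
headline, matching per-state phrasing) and `stationary` (the left
eigenvector of $\psi$ at eigenvalue 1, conditioned on survival;
reducible or periodic chains error with the violation named).
Percentile confidence intervals come from a parametric bootstrap:
multivariate-normal draws of the link-scale MLE through the
transformation. `empirical_transition_matrix()` gives the model-free
counterpart from adjacent observed state pairs, excluding (and
counting) pairs that span unobserved seasons.

## 8. Pipeline, validation and problem sizes

`run_pipeline()` executes the stages in dependency order under one
global seed (child seeds per stage), writes every table with a one-line
provenance header, and returns a JSON-serialised manifest of seeds,
counts and headline statistics; a failed stage is recorded and its
dependents skipped. `validate_inputs()` checks the three CSV dialects
(timestamps parseable, strictly increasing with constant spacing per
bird; wet fractions in $[0,1]$; known event codes; no never-seen
histories) and returns one row per violation. Timestamps are parsed
element-wise across accepted ISO-8601 forms, because a vectorised parse
locks onto the first element's format and silently truncates
date-only midnights.

Test and acceptance problem sizes are the package's own choices,
balancing statistical resolution against a desk-scale run: estimator
calibration uses 100 replicates of 300 birds × 8 occasions at the
documented $(\phi, p, \psi)$; the KS family-wise error check uses 1000
replicates of a 3-group × 3-activity global null at $n = 25$ per group;
path-enumeration cross-checks use histories of length ≤ 5 (where
$4^T$ enumeration is exact and fast); the full pipeline runs at the
default 111/88-bird colony.

## 9. Known limitations

* The activity thresholds and the foraging wet-fraction band are stated
  stand-ins for a published supplementary rule.
* Year effects on $\psi$ are fixed occasion effects; survival is
  time-constant by default. No continuous random effects (finite
  mixtures only), no Bayesian fitting, no goodness-of-fit tests of the
  capture-history model.
* The decomposition's moving-average trend is one of several
  conventions (a loess trend is another); only the moving-average form
  is implemented.
* KS tests on pooled bird-days inherit day-to-day autocorrelation; the
  package mitigates this for the (null) sex contrast but reports the
  pooled convention for RP contrasts.
* Light-based positioning, spatial structure and field-protocol
  questions are out of scope.
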