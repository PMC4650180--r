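# shearwaterCOE

Carry-over effects in a long-lived migratory seabird: does what a bird
did last season — and how it behaved at sea over the winter — predict
whether it breeds successfully next season?

The package implements, as tested and reusable R code, a complete
analysis linking three data streams from a monitored shearwater colony:

1. **Saltwater-immersion logger series** (per-block wet fractions from
   leg-mounted geolocator/immersion loggers), converted into daily
   daytime activity budgets: proportion of blocks spent **flying** (dry),
   **resting on the water** (wet) and **foraging** (intermediate wet/dry
   mixing).
2. **Breeding and migration phenology** (lay, hatch, fledge, colony
   departure/arrival, wintering-ground arrival/departure dates), used as
   features to predict the next season's reproductive-performance (RP)
   category — raised a chick (`SUCCESS`), failed during incubation
   (`FAIL`), or did not lay (`SKIP`).
3. **Multi-year encounter histories** (seen as successful / failed /
   skipping / state unknown / not seen), modelling year-to-year
   breeding-state dynamics with imperfect detection and mortality.

Because the underlying field data are not publicly deposited, a seeded
synthetic-data generator reproduces the *structure* of the study — 111
logger bird-winters split 64/29/18 across RP groups plus 88 additional
history-only birds — so that every stage of the analysis is runnable and
testable end to end.

## Methods at a glance

* **Activity classification.** A block with wet fraction $w$ is FLY if
  $w \le 0.05$, REST if $w \ge 0.95$, FORAGE otherwise; daily budgets
  are daytime block proportions.
* **Segmented regression.** Daily flight proportion vs winter day is
  fitted with piecewise-linear models
  $y = \beta_0 + \beta_1 x + \sum_j \delta_j (x - \tau_j)_+$, the
  breakpoints $\tau_j$ estimated by iterative linearization with
  bootstrap restarting and their number chosen by BIC.
* **SAMME boosting.** Multi-class AdaBoost over depth-capped CART
  stumps: round $m$ with weighted error $\mathrm{err}_m$ contributes
  vote weight
  $\alpha_m = \ln\frac{1-\mathrm{err}_m}{\mathrm{err}_m} + \ln(K-1)$;
  performance is assessed by stratified 10-fold cross-validation, a
  within-sex label-permutation test, and greedy elimination of feature
  pairs with $|r| >$ threshold.
* **Trend contrasts.** Each bird's daily budget is decomposed additively
  (`observed = trend + seasonal + remainder`, centred moving-average
  trend, 7-day seasonal); trends are averaged by RP group, summarised by
  empirical cumulative distributions, and compared pairwise with
  two-sample Kolmogorov–Smirnov tests at the Bonferroni-corrected 1%
  level (sex contrasts at raw $\alpha$ on per-bird winter means).
* **Multi-event capture–mark–recapture.** A hidden-Markov likelihood
  over latent states {SUCCESS, FAIL, SKIP, DEAD} with survival $\phi$,
  row-stochastic transition matrix $\psi$ (state-, sex- and
  year-dependence switchable), detection $p$, an event matrix allowing
  state-unknown sightings, and optional finite-mixture individual
  heterogeneity ($\sum_c \pi_c L_c$). Models are fitted by maximum
  likelihood (BFGS on link scales, multi-start), compared by AIC, and
  summarised by each state's probability of breeding successfully next
  season (or at equilibrium), with parametric-bootstrap intervals.

## Worked example

The analysis is organised as numbered drivers under `analysis/`, each a
thin script over the package functions:

```sh
Rscript analysis/01_simulate.R         # synthetic colony -> results/data/
Rscript analysis/02_activity_budgets.R
Rscript analysis/03_breakpoints.R
Rscript analysis/04_boosting.R
Rscript analysis/05_activity_trends.R
Rscript analysis/06_mecmr.R
```

Output of `01`–`03` (seed 2015):

```
Simulated colony (seed 2015):
  logger bird-seasons : 111 (64 success / 29 fail / 18 skip)
  encounter histories : 199 birds
  immersion blocks    : 2844288
Daily activity budgets:
   19752 bird-days across 111 birds
  mean daytime budget: fly 0.199, rest 0.523, forage 0.278
Flight-activity breakpoints per bird-winter:
 0  1  2
13 96  2
  median first breakpoint: winter day 60.0
```

Most winters show exactly one flight-activity breakpoint, at the winter
day where the generator changes the budgets (day 60) — the segmented
estimator recovers it. The classifier extracts real signal from
phenology:

```
10-fold CV error rate: 23.42%  (success rate 76.58%)
Permutation test (199 label shuffles within sex): p = 0.0050
```

and the winter-activity contrasts separate the RP groups exactly as the
generator encodes them (skipping birds hyperactive — more flight, much
more foraging, less resting):

```
  significant: 9 of 9
  SKIP mean foraging trend exceeds SUCCESS on 100% of days
Sex contrasts on per-bird winter means (raw alpha):
  activity ks_statistic p_value
1      FLY       0.0932   0.944
2     REST       0.1412   0.552
3   FORAGE       0.1601   0.397
```

Finally the capture–mark–recapture stage estimates the year-to-year
state dynamics (the generator's transition matrix gives skipping birds
the highest next-year success probability, 0.79):

```
Observed year-to-year transition frequencies:
        SUCCESS  FAIL  SKIP
SUCCESS   0.637 0.274 0.089
FAIL      0.632 0.257 0.111
SKIP      0.765 0.147 0.088
```

A single call runs everything as one seeded, logged pipeline and returns
a manifest of counts and headline statistics:

```r
library(shearwaterCOE)
man <- run_pipeline(pipeline_config(seed = 1, outdir = "run1"))
man$stages$simulate$logger_bird_seasons   # 111
```

## Repository layout

```
R/                    package code (all computation lives here)
analysis/             numbered narrative drivers (see worked example)
scripts/acceptance.R  headline-quantity recomputation
tests/testthat/       unit, property and end-to-end tests
vignettes/            methods vignette (model details and design notes)
```
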