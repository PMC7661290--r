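---
title: "Models and methods behind fishpass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fishpass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fishpass)
```

## The scientific problem

Upstream-migrating adult salmon pass hydroelectric dams through fishways.
fishpass decomposes that passage into three stages and models each:

1. **Finding** — from first detection in the tailrace to first fishway
   entry; a time-to-event process.
2. **Committing** — whether the fish passes fully through the fishway on
   its first attempt rather than dropping back; a binary outcome.
3. **Fishway transit** — from the last fishway entry to exit into the
   reservoir; a second time-to-event process.

The question of interest is whether conspecific *density* speeds these
stages up (collective navigation) or slows them down (crowding). Density is
not observed directly; daily observer counts at the fish ladder stand in
for it. That proxy is the crux of the whole methodology, because counts are
*produced by passage events*: on days when fish happen to pass quickly more
of them are counted, so a naive regression of passage rate on counts is
contaminated by reverse causality even when density has no causal effect.

## Models

The two time-to-event stages use proportional hazards with time-varying
covariates,

$$\lambda(t \mid X) = \lambda_0(t)\, e^{X(t)\beta},$$

where $t$ is hours since the fish's own stage entry (the subject clock) and
$X(t)$ holds temperature and spillway discharge (daily), a binary diel
(daytime) indicator (hourly), and the daily count. Exposure is encoded in
counting-process form: each fish contributes contiguous `(start, stop]`
intervals split wherever any covariate changes value, with left-continuous
covariates (the value on an interval is the value at its start) and the
event flagged on the terminal interval. `fit_ph()` maximizes the Breslow
partial likelihood (Efron available as an option; times are near-continuous
at the hour scale so ties are rare) by Newton–Raphson with step-halving,
converging when the score max-norm drops below 1e-6 and the relative
log-likelihood change below 1e-10; the covariance is the inverse observed
information. Continuous covariates are standardized to exposure-weighted
mean 0, SD 1 so coefficients are per-SD and comparable; binary covariates
enter unscaled. AICc uses the number of events as the effective sample
size. Committing is a logistic regression on covariates evaluated at the
moment of first fishway entry — the decision point (the evaluation time is
a package choice; nothing in the stage definition forces it).

`breslow_baseline()` recovers the cumulative baseline hazard
($d(t)/\sum_{R(t)} e^{X_j\hat\beta}$ at each event time; exactly
Nelson–Aalen when there are no covariates). For simulation the step
function is linearly interpolated between event times — equivalent to a
piecewise-constant baseline *rate* — and extended beyond the last event at
the mean rate over the final quartile of event times, with each subject's
last covariate values carried forward. Subjects whose exponential draw is
never spent (a zero tail rate) are flagged unresolved rather than silently
dropped. `simulate_event_times()` inverts each subject's cumulative hazard
$\Lambda_i(t) = \int e^{X_i(u)\hat\beta}\, d\Lambda_0(u)$ at an Exp(1) draw
exactly on the piecewise structure; there is no discretization error beyond
the step representation itself.

## The bootstrap test

Fitting the count covariate by partial likelihood and reading off a Wald
p-value is invalid here. The package's central device instead builds the
null distribution by simulation:

1. Select, by AICc among candidate covariate sets *excluding the count*,
   a null model (the threshold indicator `count ≤ 150`, when configured,
   belongs to the null model: it is fitted before testing the linear
   effect).
2. Simulate full event histories from the fitted null model along each
   fish's observed covariate path; attach the *observed* count series
   unchanged. Counts are held fixed because tagged fish are a small subset
   of what observers count — simulated passage of the tagged cohort cannot
   regenerate population counts, and under the null hypothesis there is no
   count→hazard link to regenerate.
3. Refit the full model (null covariates plus count) to each replicate and
   collect the count coefficient.
4. Two-sided p-value by the add-one rule,
   $p = (1 + \#\{|\beta^*_b| \ge |\hat\beta|\})/(B+1)$, so B = 1999 gives a
   floor of $5\times10^{-4}$. Two-sided is the package's choice: signed
   effects in either direction (collective navigation vs crowding) are
   plausible a priori.

Confidence intervals are percentile intervals from a second bootstrap that
simulates from the *full* fitted model (BCa was considered and left out;
percentile is the simplest method consistent with a parametric bootstrap,
and the draws are returned so anything else can be computed). Replicates
whose refit fails to converge are recorded and excluded; more than 5%
failures flags the result unreliable. No multiplicity correction is
applied; the report states the number of tests.

For the logistic commit model the bootstrap redraws only the Bernoulli
outcomes, not event times — the commit covariates are fixed at each fish's
entry moment, so new outcomes are the only randomness the fitted model
defines for them. (Whether one should also resimulate entry times is a
sensitivity question, noted, not resolved, here.)

## Density scenarios

`run_density_scenario()` multiplies the raw count covariate by a factor
(0 = near-extirpation, 2 = doubled run), re-standardizes with the
*original* scaling record — so factor 1 is exactly the fitted model — and
simulates `n_rep` cohorts. The curve reported at each grid time (0–72 h at
0.5 h; passage is essentially complete well before 72 h since the great
majority of fish pass within a day) is the median across replicates of the
fraction passed. Mean and median passage time are both reported because a
"percent change in passage time" is ambiguous between the two; the >24 h
tail fraction counts unresolved fish as exceeding the threshold. When a
threshold indicator is configured, factor 0 puts every day under the cut,
the indicator saturates, and the scenario warns: predictions there ride on
an effect confounded with fishway identity and are unreliable.

## The synthetic world

No real telemetry is shipped; `simulation_truth()` + `simulate_cohort()`
generate cohorts whose structure matches what the analysis assumes, with
known parameters for recovery and calibration studies.

* **Arrivals**: inhomogeneous Poisson with a Gaussian run-timing curve
  (peak mid-season, SD one sixth of the season), uniform within a day.
* **Covariates**: daily temperature is a rising quarter-wave sinusoid plus
  AR(1) noise — water warms monotonically across a late-spring/summer run
  season. (A mid-season-peaking sinusoid would be nearly collinear with
  the run-timing curve and make density and temperature unidentifiable by
  construction — an artefact, not a feature of the system.) Spill declines
  exponentially with multiplicative AR(1) noise; the diel window is
  06:00–18:00 (the day window is nowhere standardized; 12 h centred on
  solar noon is the obvious default).
* **Hazards**: exact piecewise-exponential draws from
  $\lambda_0(t)e^{X\beta}$; defaults $\lambda_0 = 0.10/h$ for finding and
  $0.5/h$ for fishway transit give mean stage durations of a few hours to
  half a day, matching the regime where most fish pass within 24 h.
* **Commit**: Bernoulli from a logistic model; the default intercept
  `qlogis(0.43)` sets the baseline commit probability to 43%.
* **Density, two modes.** In *exogenous* mode the count covariate driving
  the hazard is an attached run-count series — generator and analysis see
  the same variable, which is what recovery, power and coverage studies
  need. In *latent* mode the hazard responds to the instantaneous number
  of fish currently searching the tailrace, simulated by an exact
  event-driven (Gillespie) scheme; the analysis never sees that variable,
  only daily counts derived from passage. This deliberately separates the
  causal variable from its proxy.
* **Counts from passage**: `derive_daily_counts()` tallies each exiting
  fish on the day it passes the mid-ladder window (exit time minus a
  window offset, plus an observer lag; default lag 2 h — the window sits
  mid-ladder, so the delay is short, but no quantitative value exists to
  calibrate against), with negative-binomial observation noise. This is
  the reverse-causality structure the bootstrap must survive.
* **Population vs tagged fish**: `simulate_study()` simulates whole
  populations (~1300 Chinook, ~1100 sockeye per dam), derives counts from
  the *population's* passage, and tags a ~30% subsample for analysis.
  Counts derived from the analyzed cohort itself would make the covariate
  a deterministic function of the analyzed fish's own outcomes — a
  coupling no bootstrap can null out, and one the real data do not have.
* **Latent-scale calibration**: latent occupancy is standardized by its
  typical level and spread under the default arrival regime (centre 11,
  scale 5.5 for the study world), so latent coefficients are per-SD.
  Daily counts cannot see the within-day swing of occupancy, so a latent
  effect attenuates on the count scale; the default Chinook latent effects
  (1.0 finding, 0.7 commit) were chosen so the *fitted count-scale*
  coefficients land in the 0.2–0.5 range reported at study scale for
  these processes. Sockeye carry no density effect.
* **Missingness**: each timestamp can be dropped completely at random
  (`p_missing`); the analysis excludes, never imputes, such fish.
  Observation ends with the covariate season: fish unresolved by the last
  covariate day are recorded as missing, exactly how they are then
  treated downstream.

What the generator does **not** emulate: spatial movement within the
tailrace, hydraulics, between-dam travel, non-random missingness,
between-fish frailty, and any feedback of scenario densities onto counts
(scenarios are open-loop). A green calibration test therefore establishes
that the bootstrap survives the count-derived-from-passage pathology in a
world with the assumed proportional-hazards structure — not that it
survives arbitrary model misspecification.

## Numerical choices and edge cases

* Ties: Breslow by default; hour-scale times make ties rare. Efron is a
  config option and is cross-checked against an independent
  implementation in the tests.
* Simultaneous covariate-change and event boundaries: covariates are
  left-continuous on `(start, stop]` — the value in force just after the
  interval opens governs the whole interval.
* Degenerate inputs: zero-variance continuous covariates, rank-deficient
  designs, single-class outcomes and monotone likelihoods raise classed
  errors (`fp_fit_error`) so bootstrap machinery can count failures
  instead of crashing.
* Percentile CI order statistics: with B draws at level $1-2\alpha$ the
  bounds are the $\lfloor\alpha(B+1)\rfloor$-th and mirrored order
  statistics (50th and 1950th of 1999 at 95%).
* Determinism: every stochastic entry point takes a seed; fixed seeds give
  identical output, including whole pipeline reports.
* Minimum cohort size: models under 100 fish are dropped with a notice —
  comfortably above the size at which a model was conventionally
  discarded (59) and below the smallest fitted one (332).
* Threshold placement: the `count ≤ 150` indicator defaults to the
  *finding* null model (the methods-level statement), but is configurable
  per model because the discussion-level text attaches it to commit.

## Known limitations

* The latent-density mode supports only a constant baseline hazard within
  the event-driven scheme (piecewise baselines would add per-fish break
  events; not needed so far).
* Covariate sets per model are configuration, not defaults mined from any
  source: the original per-model covariate lists are not public.
* The bootstrap's power under reverse causality is unknown in principle
  (only its validity is defended); power statements in the tests use the
  exogenous-density world.
* Natural-scale coefficients are derived by dividing per-SD coefficients
  by the stored SD; they are correct only for covariates that entered
  linearly.
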