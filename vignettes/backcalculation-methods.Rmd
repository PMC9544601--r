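---
title: "Estimating injecting initiation trends from repeated cross-sectional surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating injecting initiation trends from repeated cross-sectional surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(injectcohort)
```

## The problem

Surveillance surveys of people who inject drugs (PWID) — recruited through
needle-and-syringe programmes and similar low-threshold services — are
repeated cross-sections: each survey year samples people *currently*
injecting and records their age, age at first injection, and year of first
injection. Such data answer two families of questions:

1. **How is the population changing?** Trends in the distribution of age,
   age at first injection, and injecting duration by calendar year.
2. **When did people start?** Each survey's distribution of initiation years
   is the historical initiation curve filtered by survivorship: someone who
   started 20 years ago is only observed if they are still injecting.
   Inverting that filter yields an estimate of the annual number of people
   injecting for the first time — the incidence of injecting — decades back
   in time.

`injectcohort` implements both, plus the data cleaning such surveys need and
a synthetic-population generator that makes every stage testable against
known ground truth.

## The cohort model

Let $N(c)$ be the number of people injecting for the first time in calendar
year $c$. People leave the injecting population (through cessation or death)
with a constant hazard, so the probability of still injecting $d$ years
after initiation is

$$S(d) = e^{-d/\mu},$$

with $\mu$ the mean injecting duration. $\mu$ is an *assumption*, not
estimated from the data: the primary analysis uses $\mu = 15$ years, in line
with modelling studies that have assumed mean durations between about 8 and
20 years, and `duration_sensitivity()` re-runs everything over a grid
(default 10–20 years).

A survey in year $t$ that samples $n_t$ people currently injecting observes
cohort $c$ with expectation proportional to $N(c)\,S(t-c)$. The observed
initiation-year histogram $n_t(c)$ therefore estimates the cohort curve up
to scale via

$$\tilde N_t(c) \propto \frac{n_t(c)}{S(t-c)},$$

which `backcalc_single()` computes and normalises. Time is discrete at whole
calendar years throughout: a person initiating in year $c$ with continuous
duration $D$ is currently injecting in survey year $t$ iff $c \le t$ and
$t - c < D$, and survivorship is evaluated as $S(d) = e^{-d/\mu}$ at integer
$d$ (not $(1-1/\mu)^d$). The simulator and the estimator share this one
convention, so the forward map and its inverse are exact mutual inverses —
a property the test suite checks to $10^{-10}$.

### Combining surveys

`combine_surveys()` pools all survey years. For each cohort $c$, the point
estimate is the mean of the per-survey relative estimates
$\tilde N_t(c)$ over all surveys that *inform* $c$ (those with
$0 \le t - c \le d_{\max}$), weighted by survey totals — proportions from
larger surveys are more precise, and total weights avoid the instability of
inverse-variance weights at zero counts. The combined curve is renormalised
to sum to one.

Prediction intervals come from a Monte-Carlo scheme: each replicate redraws
every survey's histogram from a multinomial with the observed total and
proportions, re-inverts and re-combines; the 95% interval is the
2.5th–97.5th percentile of replicates per cohort. This is a reconstruction —
the simplest scheme consistent with combining evidence across survey years —
not a transcription of any particular published implementation, so
interval widths should be read as capturing survey resampling noise only.
Cohorts seen by few surveys (especially the most recent years, which only
the last surveys can observe) get visibly wider intervals; the test suite
asserts both this and the empirical coverage of the intervals (85–100% for
cohorts with at least 5 expected counts over 200 simulated replications;
sparser cohorts under-cover, as expected for percentile intervals on
near-empty cells, and are asserted only above 50%).

Numerical choices:

* **Support truncation.** A survey cannot meaningfully inform cohorts more
  than $d_{\max} = \lceil 5\mu \rceil$ years before it: beyond that
  $S(d) < e^{-5}$ and the inflation factor $1/S$ amplifies single
  observations explosively. Estimates outside every survey's window are
  absent from the output, and `n_surveys_informing` records how many
  surveys back each reported cohort.
* **Zero counts.** A cohort a survey covers but did not observe contributes
  an estimate of 0 from that survey — no smoothing by default, keeping the
  estimator transparent. An add-half pseudo-count is available via
  `smooth = TRUE`.
* **Seeding.** All randomness flows from one integer seed through a
  label-based splitting rule (`child_seed()`); `combine_surveys()` derives
  its stream from (seed, $\mu$), so a sensitivity run over several $\mu$
  values is reproducible per-$\mu$ and adding a value never perturbs the
  others.

### Calibration to absolute numbers

A relative curve fixes only the shape. An external prevalence estimate — the
number of people currently injecting in a reference year $t^*$ (for the UK,
such estimates exist for England in 2011 and Scotland in 2006) — pins the
scale: `calibrate()` multiplies the curve by

$$k = \frac{P}{\sum_{c \le t^*} N(c)\, S(t^* - c)}$$

so the implied number still injecting at $t^*$ equals $P$ exactly (the test
suite checks the identity to $10^{-9}$ relative error). Point estimates and
interval bounds are scaled by the same $k$; if the anchor itself carries an
interval, each Monte-Carlo replicate instead draws a uniform prevalence
between the bounds and receives its own $k$, widening the intervals.

### Sensitivity to $\mu$

Inverting with the wrong duration $\mu'$ multiplies cohort $c$'s estimate by
$e^{d(1/\mu' - 1/\mu)}$ with $d = t - c$ — a closed form the tests verify to
$10^{-8}$. The practical consequence, which `duration_sensitivity()` makes
visible: shorter assumed durations inflate early cohorts relative to recent
ones and longer durations do the opposite, while the *timing* of the peak is
robust. The package asserts this direction property on synthetic data (the
1985:2010 cohort-size ratio is strictly decreasing in $\mu$ over 10, 15,
20 years).

## Cleaning and derived variables

Records carry `survey_year`, `age`, `age_first_inj`, `year_first_inj`,
`duration`, a recency indicator, and a psychoactive-vs-image-and-performance
indicator. `derive_fields()` fills whatever is computable from the
identities `duration = age - age_first_inj` and
`year_first_inj = survey_year - duration`, never overwriting observed
values. `apply_exclusions()` then removes, in a fixed order with each record
counted once at the first rule it violates:

1. not recently injecting (or recency unknown, subject to the mode below);
2. image-and-performance-drugs-only records;
3. records still missing any of the four analysis variables;
4. implausible records: age at first injection exceeding current age,
   initiation year after the survey year, negative duration, or the two
   duration computations disagreeing by more than one year.

The ±1-year slack in rule 4 reflects whole-year reporting granularity: a
person surveyed in 2019 who started in 2000 can truthfully report a duration
of 18 or 19 years depending on survey and initiation months. The fixed
order is a design choice for reproducible single-count accounting — flow
diagrams in the surveillance literature do not dictate one.

Recency rules differ across survey eras, so the mode is explicit:
`"strict"` drops unknowns; `"assume_recent_pre1993"` retains unknowns
through 1992 (questionnaires of that era had no recency item, and adjacent
years show ~90% recent injectors); `"last_inj_year"` uses a
year-of-most-recent-injection question, counting the survey year or the
year before as recent. Sex and region are pass-through strata, never
exclusion criteria.

## Quantile trends

Distributions of age, age at first injection, and duration are summarised
by conditional quartiles against calendar year, fitted by quantile
regression (pinball loss, via `quantreg`) on a quadratic in the centred
year. The quadratic accommodates the U-shaped age trends seen where an
early-1980s wave was followed by a 1990s wave; centring at the midpoint of
the observed years is for numerical conditioning only. Reported values for
a year are the model's fitted quantiles, not raw per-year quantiles, so
thin years borrow strength from the trend. Fitted quartiles are sorted
within each year — quantile crossing is rare but possible with separate
per-$\tau$ fits. Calibration of the fits is asserted via residual sign
proportions ($\tau \pm 2/\sqrt{n}$). Bootstrap confidence intervals
(percentile, 200 resamples by default) are available but secondary: with
tens of thousands of records the quantile estimates are tight, and interest
centres on the distribution itself.

**Age at first injection** is analysed by *year of initiation* rather than
survey year, restricted to participants who started within the past 3
years (`recent_initiates()`; "past 3 years" means gaps 0, 1, 2 — initiation
year 2000 draws on surveys 2000–2002). The restriction avoids survivorship
bias: among people who started long ago, those still injecting — and hence
surveyed — are disproportionately those who started young, if attrition is
age-correlated. The synthetic generator can induce exactly that correlation
(`duration_age_effect < 0`), and the test suite shows the windowed
estimator is then closer to the simulated truth than the all-records
estimator.

## The synthetic generator

`make_scenario()` defines the truth: an initiation-rate curve (constant, or
a Gaussian wave — the default UK-like configuration peaks around 10,000
initiations/year in 1998 with width 5 years, echoing the late-1990s heroin
wave), a drifting mean age at initiation (default drifting from 21 to 30
years over the scenario, normal with SD 5 truncated at 15 — the simplest
shape that reproduces a rising median age of initiation), and exponential
durations. `simulate_surveys()` samples people currently injecting,
uniformly and without replacement, in fixed survey years (defaults of
~2000 participants/year mirror the scale of the UK series), then corrupts
records: item non-response per field, non-recent and
performance-only flags, implausible ages — each independently with
configurable probabilities, mirroring item non-response in self-completed
questionnaires.

What the generator deliberately does **not** emulate: engagement bias
(sampling is uniform among current injectors, whereas real recruitment
through services may under-represent recent initiates), repeat participation
across rounds, regional migration, and secular change in duration. Passing
tests therefore demonstrate that the estimators recover the truth *under
the stated model*, not that the model captures every feature of real
surveillance data — the survivorship model in particular assumes a constant
cessation hazard that mortality and remission dynamics only approximate.

## Problem sizes in the test suite

Validation runs use scenario scales chosen to exercise the statistics
meaningfully while keeping the suite quick: the nation-scale recovery runs
use 30 annual surveys of 2000 participants from a population of ~125,000
simulated injectors with 500 Monte-Carlo replicates; the interval-coverage
study uses 200 independent replications of a smaller two-survey design with
200 replicates each. All are fixed-seed and deterministic.

## Limitations

* $\mu$ is assumed, not estimated; results condition on it, and the
  sensitivity grid is the honest statement of that dependence.
* Prediction intervals capture survey resampling noise only — not anchor
  uncertainty (unless an anchor interval is supplied), model
  misspecification, or selection bias.
* The most recent cohort years are informed by few surveys and their
  estimates are intrinsically imprecise.
* Calibration inherits whatever bias the external prevalence estimate has;
  the relative curve is unaffected.
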