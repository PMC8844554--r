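---
title: "From trial data to lifetime cost-effectiveness: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From trial data to lifetime cost-effectiveness: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialcea)
```

## The analysis in one paragraph

trialcea implements a trial-based cost-utility analysis with lifetime
extrapolation, of the kind used to evaluate adding a glucagon-like
peptide-1 receptor agonist (once-weekly exenatide) to usual care in type 2
diabetes. Within the trial, EQ-5D responses are valued with a tariff,
missing post-baseline utilities and cardiovascular risk factors are
multiply imputed, QALYs are computed by the area-under-the-curve method
with baseline-utility adjustment, and resource use is costed into therapy
versus other costs. Beyond the trial, each patient's end-of-trial risk
profile enters an annual-cycle microsimulation of eight diabetes
complications and death, driven by configurable parametric risk equations,
which accrues discounted costs, life-years and QALYs until death.
Uncertainty is propagated by a patient bootstrap crossed with the
imputations for the within-trial period and by multivariate-normal
coefficient draws for the extrapolated period; paired replicates are added
to give lifetime incremental costs and QALYs, from which the ICER,
percentile confidence intervals, the cost-effectiveness plane and the
acceptability curve follow.

## Within-trial period

**Valuation.** EQ-5D-3L profiles are valued directly under an additive
tariff (per-dimension level decrements plus an optional any-level-3 term,
anchored so that profile 11111 values to exactly 1). EQ-5D-5L responses
are first mapped level-by-level through a deterministic 5L-to-3L
crosswalk. The packaged tariffs and crosswalk are *synthetic
placeholders* — they have the structure and rough magnitudes of published
value sets but are not the official US or UK tariffs, which are licensed
and must be supplied by the user as CSV coefficient tables
(`read_value_set()`, `read_crosswalk()`).

**Missing data.** Baseline gaps are filled deterministically: utility,
height and weight by the sex-stratified mean of observed values, smoking
status by the country mode. Post-baseline utilities and risk factors are
then imputed by chained equations with predictive mean matching (PMM,
5 donors, 10 sweeps), run separately for utilities and for each risk
factor. Predictors per visit are arm, age, sex, diabetes duration, prior
cardiovascular disease, baseline utility (or the factor's baseline value)
and the variable's own previous-visit value — a deliberately compact set
chosen because the generator's missingness depends only on always-observed
baseline fields, which keeps the imputation model correctly specified and
testable. PMM was chosen over normal-theory draws because utilities are
bounded and left-skewed; every imputed value is an observed donor value,
so imputations can never leave the observed range. The default is m = 28
imputations, one per percentage point of missing utility data at the
default 28% missingness. Rubin's pooling rules are deliberately not used
for inference: uncertainty is propagated by the bootstrap-by-imputation
scheme instead.

**QALYs and costs.** QALYs are the integral of the piecewise-linear
utility curve from randomization to the end of follow-up. Death inserts an
explicit `(death_time, 0)` vertex — utility declines linearly from the
last observation to zero at death and contributes nothing thereafter. For
patients censored alive after their last response, the last observed
utility is carried forward flat to the censoring date; a `tail =
"truncate"` flag instead stops the integral at the last observation. We
carry forward because the estimand is utility over the full follow-up
period and dropping the tail would censor informatively against sicker
patients with missed final visits. Discounting within the trial is applied
at annual granularity by year of accrual (year 0 undiscounted);
continuous-time discounting would differ by under half a percent at the
rates used and was rejected for simplicity. Arm QALY means are adjusted
for baseline utility by linear regression on arm and centered baseline —
removing bias from chance baseline imbalance — while costs are compared as
unadjusted means; costs split exactly into therapy (study-drug doses at
the per-dose price plus concomitant diabetes medications) and other costs
(hospitalizations, visits, other medications).

**Prices and rates.** Defaults: 3% annual discounting and a 2017 cost
reference year in the US setting; 3.5% and 2016 in the UK. The US
study-drug price is USD 119.70 per weekly dose, i.e. the wholesale
acquisition price (about USD 155.66) after the 23.1% average Medicaid
discount on brand-name medications; the UK price is GBP 18.94 per dose.
All other unit costs are editable configuration with realistic magnitudes.

## Post-trial extrapolation

Each surviving patient leaves the trial with age and diabetes duration
advanced by their follow-up, risk-factor values at their last visit (from
the across-imputation average of imputed values combined with observed
data), first-event history flags, their last valued utility, and their
last-year study-drug compliance.

**Risk equations.** Annual probabilities of ischaemic heart disease,
myocardial infarction, heart failure, stroke, amputation, blindness, renal
failure, foot ulcer and death come from parametric equations with
exponential, Weibull, Gompertz or logistic forms. The hazard-to-probability
bridge is `p = 1 - exp(-H(t+1) + H(t))` on the diabetes-duration time
scale (for the exponential form this reduces to `1 - exp(-exp(lp))`);
logistic equations return the fitted probability directly. The engine
accepts any coefficient file in the documented schema; the shipped
coefficients are synthetic placeholders with realistic magnitudes, because
the published outcomes-model coefficients are not reprinted here. Tests
therefore target structural correctness (closed forms, nesting of Weibull
shape 1 in the exponential, exhaustive enumeration on small instances),
not fidelity to any published model.

**Cycle mechanics.** Cycles are annual. Patients alive at the start of a
cycle accrue that cycle's costs, life-year and utility (no half-cycle
correction; accrual at cycle start); events are drawn independently within
the year and may co-occur; death is evaluated last and takes effect at the
end of its cycle. Event-history flags are first-event indicators — second
events are out of scope — and feed the next cycle's linear predictors, so
within-year event ordering does not otherwise matter. Utility in a year is
the entry utility minus event-year decrements for this year's events and
ongoing decrements for prior events, floored at a configurable floor
(default 0). In the base case all risk factors other than age, duration
and event history are held constant at end-of-trial levels; linear-drift
and user-table trajectories are available.

**Treatment continuation.** Base case: active-arm patients remain on study
drug at their last-year compliance until death or renal failure; on the
development of renal failure the drug stops in that same year and the
patient accrues the same therapy cost as standard care. Scenario 1 takes
every patient off study drug from the first extrapolation year; scenario 2
stops each on-drug patient with a constant annual probability during the
first ten extrapolation years (default 0.05/year — a placeholder, to be
set to the discontinuation rate observed after the first trial year when
that rate is available).

**Discount clock.** Whether post-trial discounting should continue each
patient's randomization clock or restart at trial exit is genuinely
ambiguous (the two conventions differ by each patient's follow-up length
in the exponent, and published summary tables are not always internally
consistent on this point — in the reference worked example used by the
tests, the US life-year rows do not sum across periods while the UK rows
do). Both conventions are implemented behind `discount_from`; the default
restarts the clock at extrapolation year 0, which makes the zero-hazard
annuity identity exact and keeps post-trial results comparable across
patients with different follow-up.

**Parameter uncertainty.** Coefficient sets are drawn multivariate-normally
around the point estimates (draw 0 is reserved for the point estimate);
the default covariance puts independent 0.05-SD uncertainty on each
equation's intercept, i.e. roughly a 5% proportional standard error on
annual rates, in the absence of an estimated covariance (an estimated one
can be supplied as a matrix file). Event uniforms are drawn from a stream
that depends only on the simulation seed, giving common random numbers
across arms, scenarios and coefficient draws: identical arms cancel
exactly, and scenario contrasts are coupled for variance reduction.

## Uncertainty combination

Within-trial: patients are resampled with replacement, stratified by arm,
B = 800 times per imputation, re-fitting the baseline adjustment inside
every replicate. Post-trial: the B coefficient-draw increments. Replicate
b of imputation i is paired with coefficient draw b (recycled in order if
fewer draws than replicates), and the paired increments are added, so the
identity lifetime = within + post holds exactly row-wise on all m x B
replicates. Percentile intervals use the 2.5th and 97.5th empirical
percentiles of the pooled replicates under the linear-interpolation
(type 7) rule, fixed for reproducibility. The ICER is reported only when
incremental QALYs are positive; otherwise the quadrant label carries the
information, and ICER percentile bounds are reported only when every
replicate lies in the north-east quadrant (ratios are not averaged across
quadrants). The acceptability curve is the fraction of replicates with
positive net monetary benefit over a threshold grid of 0 to 300,000 in
steps of 1,000, covering the commonly cited USD 100,000 and GBP 20,000
references.

## The synthetic cohort generator

No patient-level data from the motivating trial are public, so the package
generates two-arm trial-like cohorts with known ground truth. The
generator emulates the statistical structure the analysis consumes: ~62%
male, mean age ~62, high prior-CVD prevalence; competing exponential
clocks for death (control hazard 0.022/year, active hazard ratio 0.86) and
five non-fatal complications with mild active-arm benefit; staggered
administrative censoring plus 0.04/year dropout calibrated so the median
follow-up is about 3.2 years with a 6.7-year maximum; annual EQ-5D visits
(the visit schedule is configuration, not fixed, since the source design
does not pin it) whose profiles derive from a latent health score
declining in age, prior CVD and glycated hemoglobin; annual resource-use
periods with weekly study-drug dosing at ~84% compliance in the active arm
only; and 28% missing post-baseline utility responses, MCAR or MAR on
baseline age with the marginal rate calibrated by root-finding. Ground
truth (the exact hazards and effects used) is serialized with the data so
recovery tests never re-derive it.

What the generator does *not* emulate: the trial's event-driven stopping,
run-in, real covariate correlation structure, or informative missingness
beyond MAR-on-observables. Passing tests therefore demonstrate that the
machinery is correct and recovers known parameters under the stated
mechanisms — not that any specific published result is reproduced, which
would require the original patient-level data and the published
risk-equation coefficients.

## Numerical choices and degenerate inputs

- AUC integration splits segments at integer years so annual discounting
  is exact; agreement with an independent fine-grid integral is tested to
  1e-6.
- The PMM regression uses a pivoted QR with rank detection, so collinear
  predictors are dropped rather than failing; a variable with no observed
  values at a visit is an error.
- An empty sex stratum in baseline imputation falls back to the overall
  mean with a logged message.
- Coefficient covariance matrices are symmetrized and factored by
  eigendecomposition, accepting positive semi-definite inputs (zero
  variances allowed) and rejecting indefinite ones.
- Percentile bounds, bootstrap resampling and all simulation stages derive
  their seeds deterministically from one master seed (a Lehmer step keeps
  derived seeds within 32-bit range), so a run manifest reproduces every
  artifact.
- Empty subgroups in scenario runs are reported as an NA row with a
  warning, not an error; a single-arm design is always an error.

## Problem sizes used by the packaged demo and checks

The demo pipeline and the acceptance script run at n = 2000 patients,
m = 5 imputations, B = 200 bootstrap replicates and 200 coefficient draws
over a 60-year horizon; closed-form and oracle checks use up to 50,000
simulated patients where Monte-Carlo precision is the point. These sizes
were chosen so the whole suite completes comfortably on one core while
leaving Monte-Carlo error well below the tolerances tested. The base-case
defaults (m = 28, B = 800) remain the configuration defaults.

## Known limitations

- The shipped risk equations, tariffs, crosswalk, unit costs and
  complication tables are synthetic placeholders; scientific use requires
  supplying the real coefficient files.
- Only first events are modelled; hypoglycemia and other adverse events
  are not.
- Post-trial standard errors reflect risk-equation parameter uncertainty
  only (as is conventional), not structural model uncertainty or
  uncertainty in end-of-trial risk-factor values.
- No currency conversion or inflation adjustment between reference years;
  no value-of-information analysis; no equity weighting.
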