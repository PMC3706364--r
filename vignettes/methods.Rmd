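---
title: "Model and methods: tobacco control and cardiovascular mortality microsimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdmicrosim)
```

## The model

`cvdmicrosim` is a discrete-time microsimulation of myocardial
infarction (MI) and stroke mortality in a population aged 20-79,
stratified into 24 cohorts: six 10-year age bands crossed with gender
and urban/rural location. The simulation runs in annual cycles over
2013-2022. Each simulated person carries a risk-factor profile --
systolic blood pressure (mmHg), total cholesterol (mmol/l), diabetes,
coronary heart disease history, cerebrovascular disease history, and a
seven-level tobacco variable (never, passive exposure only, former,
cigarette, bidi, chewing, dual use) -- plus, for former users, a
months-since-quitting clock.

Each year, a person's probability of dying of MI, of stroke, and of
other causes is computed; one competing-risk outcome is drawn;
survivors age one year; 20-year-old entrants join per the census
projection; and simulated deaths are scaled to the projected census of
the person's current age band.

### Hazards and calibration

A person's relative risk (RR) per cause is the product of per-factor
multipliers. Continuous factors contribute `rr^((x - ref)/unit)`
(blood pressure per 10 mmHg above 115, cholesterol per 1 mmol/l above
3.8); binary factors and tobacco categories contribute their per-state
RR. Annual cause probabilities are calibrated to the cohort's input
mortality rate `m`:

p_i = m(year) x RR_i / mean(RR_reference),

with `m(year) = m(2013) (1 + trend)^(year - 2013)`. The normalizing
mean is taken over the *intervention-free* (counterfactual) risk
attributes of the same alive population. This matters: normalizing each
scenario by its own mean RR would force simulated cohort mortality to
equal the input rate under every scenario and nullify all
interventions by construction. With the counterfactual reference, the
baseline run reproduces the input rates exactly (the conservation
identity, tested to 1e-12), while intervention runs accrue a benefit
proportional to the drop in mean RR. Annual rates are small, so the
rate-to-probability conversion is taken as the identity; probabilities
that would reach 1 are clamped at 0.999 with a warning.

Other-cause mortality uses the cohort rate directly, with no individual
RR. Persons aging past 79 keep the 70-79 rates but leave the reported
20-79 tallies.

### Correlated profile sampling

The six risk factors are drawn through a Gaussian copula: one
multivariate standard normal draw per person with the parameter set's
6x6 correlation matrix (tobacco occupies a single latent dimension).
Continuous factors are transformed by mean + sd x z and clamped to
physiologic ranges (60-300 mmHg, 1-15 mmol/l; a clamped fraction above
0.1% triggers a warning); binaries are thresholded at the prevalence
quantile; the tobacco category is assigned by inverse CDF over the
fixed category order. The source material states the correlations but
not a joint-distribution mechanism; the Gaussian copula is this
package's choice, and printed (rounded) correlation matrices that miss
positive semidefiniteness by a little are repaired by eigenvalue
clipping, with repairs beyond Frobenius distance 0.05 treated as data
errors.

Within-band age is uniform at baseline (marginal tables carry no
within-band distribution). Baseline former users get a quit duration uniform on 0-120
months; their residual excess risk follows the same lag curve as
intervention-induced quitting. Dual users carry a smoked-product
sub-flag assigned by the cohort's cigarette:bidi prevalence ratio.

### Interventions

Five tobacco-control measures act on three exposure channels (active
cigarette, active bidi, passive exposure): smoke-free laws (64%
passive-probability reduction, 95% CI 39-89%; 1%, 0-2% on both active
channels), brief cessation advice (1%, 0-3%), mass media campaigns
(5%, 1-11%), an advertising ban (6%, 5-7%), and taxation. The tax
dose-response is mechanistic rather than interpolated:

reduction = min(1, |elasticity| x tax share x increase% / 100)

with tax shares of 38% (cigarettes) and 9% (bidis) and price
elasticities of -0.34/-0.19 (cigarette, rural/urban) and -0.92/-0.85
(bidi, rural/urban), assuming full pass-through. This reproduces all
six published 50/300/500% anchors within 3 percentage points after
location averaging and extends to an 800% increase.

Channel effects combine as the largest effect only (`max_only`),
cumulatively (`1 - prod(1 - e)`), or cumulatively with each individual
effect amplified 25% (`synergy25`).

**Implementation schedules.** Under the baseline schedule, legislation
is enacted immediately at full coverage and its smoking effects phase
in linearly over the decade: the realized effect fraction in year *y*
(0-based) is `(y+1)/10`. Under the delayed schedule, legislative
coverage itself ramps 0 to 80% over five years and holds; each annual
coverage tranche then starts its own decade-long phase-in, so the
realized effect is the convolution of coverage increments with the
linear phase-in (0.016 in year 0 rising to 0.64 in year 9, approaching
0.8 asymptotically). Treating the published delayed coverage curve
directly as the effect fraction would make the delayed schedule
*stronger* than the baseline in every year, contradicting both
schedules' intent; the convolution resolves this, and reduces exactly
to `(y+1)/10` for the baseline step-coverage case.

**Quitting and the lag.** Each person carries pre-drawn channel
uniforms; in year *y* a current user of a channel quits if their
uniform lies below the channel's cumulative target (combined effect x
realized trajectory). This selects quitters without replacement, keeps
trajectories monotone, and makes quitter sets nested across doses and
identical across scenarios sharing a seed. Quitters become former
users (dual users drop the smoked component and keep chewing);
passive-exposed individuals selected on the passive channel lose the
passive excess. Excess risk then decays exponentially with time
constant 19.1 months, hard-floored after 120 months:

RR(t) = floor + (RR_full - floor) exp(-t / 19.1 mo).

The floor is 1 for full cessation and the chewing RR for ex-dual
users. The decay clock is evaluated mid-cycle (six months into each
year). The 19.1-month constant is sometimes paired in the literature
with 15% first-year and 36% three-year risk-decline figures; those are
not consistent with a single exponential on excess RR under any timing
convention we tried, so the exponential-on-excess form is used and
those figures are not. Secondhand-smoke benefit uses the same lag (the
cessation literature does not distinguish channels), and chewing-only
use is not targeted by any measure, so its RR contribution persists.

### Medications

The pharmacological comparator expands access to aspirin,
antihypertensives and statins. Eligibility: aspirin for those with
coronary or cerebrovascular history; statins at total cholesterol >=
5.2 mmol/l or history; antihypertensives at systolic pressure >= 140
mmHg or history (ACE inhibitor + thiazide without history,
beta-blocker added with history, sharing one effect size). Coverage
expands linearly from 15% to 45% over the decade (80% in the
sensitivity preset); adherence is 40% (20-60%) without history and 60%
(40-80%) with history. Coverage and adherence are person-level
Bernoulli draws fixed at assignment -- re-drawing annually would
overstate turnover. On treatment, per-cause RRRs stack additively and
the hazard multiplier is floored at 0.1 because additivity can go
non-physical at extreme configurations. The per-class RRR values
shipped by the synthetic generator are literature-plausible
placeholders (no trial-derived table is bundled) and are
configurable.

### Common random numbers and uncertainty

All randomness derives from one master seed split into named streams
(profile sampling, outcome draws, intervention assignment, medication
assignment, parameter draws, trend incidence). Every deviate a
scenario could consult is pre-drawn per person, so paired runs differ
only through the interventions; identical scenarios are bitwise
identical (tested), and averted-death contrasts are low-variance. One
uniform is drawn per person-year *per cause* with a fixed priority
(MI, stroke, other): with a single stacked uniform, lowering p(MI)
shifts the stroke interval and silently reattributes averted MI deaths
to stroke, biasing cause-specific contrasts; per-cause uniforms remove
that artifact at a collision probability of order p_mi x p_stroke per
person-year (negligible at annual rates).

The Monte Carlo layer draws intervention effects, relative risks,
elasticities, medication RRRs, adherence and census growth from
CI-defined normals (clamped to legal domains), one stream per
parameter family, and reports percentile 2.5/97.5 intervals across
replicates. Profiles are re-drawn each replicate, so both parameter
and sampling uncertainty propagate. Failed replicates are recorded and
excluded; more than 1% failures aborts.

## The synthetic parameter generator

Real WHO/GATS prevalence, correlation, RR and mortality tables are not
redistributable, so
`generate_parameter_set()` emulates their structure: blood pressure
and cholesterol means rising with age and higher in urban cohorts;
diabetes and disease-history prevalences rising with age; tobacco use
highest among urban men, with bidi dominating rural and cigarette
urban male smoking; a positive-definite correlation matrix with
modest metabolic correlations; MI/stroke/other mortality rising
steeply with age (the 60-69 band carries the largest absolute CVD
death burden against the shrinking age pyramid); mild upward secular
trends in metabolic risk factors (diabetes +2%/yr, blood pressure and
cholesterol +0.3%/yr) and in CVD mortality (+1.5%/yr MI, +1%/yr
stroke), consistent with projected risk-factor growth; census growth
+1.2%/yr; and the published intervention-effect, tax and quit-lag
constants attached verbatim. The numeric prevalence levels are
emulation -- not survey estimates -- and absolute death counts from
this generator should not be read as projections for India. What passing tests demonstrate is the correctness of the
machinery (sampling, calibration, intervention algebra, paired
contrasts), plus the structural claims that are robust to plausible
inputs (dose monotonicity, tax-effect linearity, implementation-delay
attenuation) -- not agreement with surveillance data.

Secular tobacco trends default to zero (no published value; scenario
contrasts are against the counterfactual either way). Downward trends
in binary factors are not applied to existing disease (incidence-only
updating through pre-drawn uniforms keeps trend updates
scenario-independent and monotone).

## Numerical and design choices

- Annual cycle; interventions and cessation occur at the start of a
  cycle; quit clocks are evaluated mid-cycle (+6 months).
- Entrants join the 20-29 cohorts each year at `n/10` of the cohort
  sample, scaled by census growth; entry is on by default and
  toggleable via `add_entrants`.
- Population weights are recomputed annually as projected census over
  simulated alive count per current age band, so population growth and
  differential survival are honored.
- Cohort extinction (no survivors) is an error naming cohort and year.
- Degenerate inputs: empty effect lists combine to 0; zero coverage or
  adherence reproduces baseline exactly (tested bitwise).

## Problem sizes

Unit tests run on reduced fixtures (1-4 cohorts, 100-2,500 persons per
cohort); distributional checks use up to 100,000 draws. The
acceptance script pools four paired replicates at 2,500 persons per
cohort across all 24 cohorts, a size at which the pooled
delayed-implementation attenuation is stable to about one percentage
point across seeds. The full reference configuration (10,000 persons
per cohort, 10,000 Monte Carlo replicates) is supported but takes
hours on one CPU.

## Known limitations

- No non-fatal events, case fatality or hospitalization; deaths only.
- No product substitution (e.g., cigarette-to-bidi switching under
  asymmetric taxes), no socioeconomic stratification, no body-mass
  index, no cost-effectiveness.
- The copula's latent-threshold treatment of binaries and the single
  tobacco latent dimension are modeling choices; input tables specify
  pairwise correlations only.
- The quit-lag "15%/36%" figures are unreconciled with the single
  exponential (see above).
- The smoke-free laws' 1% active-smoking effect and the
  cessation-advice effect may overlap in reality; they are treated as
  independent effects under the chosen combination mode.
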