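---
title: "A two-eye Markov model for AMD screening cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-eye Markov model for AMD screening cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the model answers

Age-related macular degeneration (AMD) is a leading cause of blindness in
ageing populations.  Neovascular AMD usually strikes one eye first; because
quality of life is driven mostly by the better-seeing eye, patients often
miss early unilateral disease, and treatment (anti-VEGF injections,
photodynamic therapy) arrives late.  Population screening could detect
prodromal changes and early AMD, but fundus-photograph screening, detailed
examinations and years of prophylaxis and treatment carry real costs.

`amdscreen` implements a first-eye and second-eye combined Markov
state-transition model of this trade-off for a Japanese setting.  It
follows a closed cohort from age 40 to 90 in annual cycles under two
strategies — organized screening (base case: every 5 years from age 50)
versus no screening — and reports clinical effectiveness (reduction in
bilateral blindness) and cost-effectiveness (incremental cost per QALY in
JPY, with the willingness-to-pay reference of 5,000,000 JPY/QALY).

## Model structure

Each **eye** moves through an ordinal scale: normal, prodromal
(drusen-type fundus changes), moderate AMD (visual acuity 0.5–0.9),
severe AMD (0.1–0.4) and blindness (< 0.1).  Blindness of an eye is
absorbing; death is person-level and driven by an age-indexed background
life table, independent of disease state (AMD is not fatal in the model).

The **person** state couples the two eyes with:

* the AMD subtype (typical neovascular AMD 40.8%, polypoidal choroidal
  vasculopathy 54.7%, retinal angiomatous proliferation 4.5%), assigned
  once when the first eye converts and shared by the fellow eye —
  the subtype decides whether PDT accompanies injections;
* detection status ("under medical control") with years since detection;
* per-eye treatment-year counters (the injection schedule and treated
  transition probabilities depend on the year of the current treatment
  line);
* supplement status (never offered / taking / stopped) and presbyopia
  status (the vehicle of coincidental detection);
* an alive flag.

The key two-eye mechanism is **second-eye acceleration**: a prodromal eye
converts to moderate AMD at 0.50%/year (ages 50+) while the fellow eye is
AMD-free, but at 2.59%/year once the fellow eye has AMD.  Utility weights
are indexed by the ordered (better eye, worse eye) stage pair, so the
worse-seeing eye depresses quality of life without dominating it
(e.g. normal/normal 1.00, normal/blind 0.88, blind/blind 0.46).

## The annual event cycle

Within each cycle (age `40 + t`, `t = 0..49`) events run in a fixed
order:

1. **Mortality.**  Decedents accrue no cost and no utility that cycle.
2. **Eye transitions**, simultaneous for the two eyes using
   start-of-cycle states.  Undetected (or dropped-out) persons follow the
   untreated probabilities (moderate→severe 37.49%/yr, severe→blind
   19.07%/yr; no spontaneous improvement).  Detected persons follow the
   treated probabilities: moderate stays with 95% in treatment year 1 and
   worsens with 22%/yr afterwards; severe improves to moderate with
   40.3%, maintains with 54.7% and goes blind with 5% in year 1, and
   maintains 95% / goes blind 5% afterwards.  A treatment line's year
   counter resets whenever the eye changes stage, so a severe eye that
   improves restarts as a year-1 moderate line.
3. **Symptom consultation** (undetected persons): an eye that went blind
   this cycle triggers consultation with certainty; otherwise any
   moderate/severe eye triggers it at the 5%/yr "sensor" rate.
   Prodromal-only persons never self-present.
4. **Screening** in programme years: 60% participate; non-participants
   get an opportunistic ("occasional") screening with 20% probability.
   Screened persons pay 3,000 JPY; disease (any eye ≥ prodromal) tests
   positive with sensitivity 80%, healthy persons false-positive with 5%;
   positives attend the 13,900 JPY detailed examination with 80%
   probability, where true positives come under medical control.
5. **Coincidental consultation**: presbyopia onset is drawn at 3%/yr and
   only in the onset year does a 20% clinic-visit probability apply; the
   clinic examination is taken as fully sensitive for any stage ≥
   prodromal.
6. **Supplements and dropout.**  Detected persons with a prodromal eye
   are offered supplements once (50% uptake) and continue at 90%/yr;
   intake stops for good when no eye is prodromal.  From the first
   anniversary of detection, prodromal-only patients withdraw at 50%
   (first year) / 10% (later), moderate/severe patients at 5%/yr, and
   patients with a blind eye never withdraw.  Withdrawal reverts the
   person to undetected status and untreated dynamics; all three
   detection pathways can re-capture them.
7. **Treatment delivery and costing**: observation visits (4/yr
   prodromal, 12/yr otherwise, 4,420 JPY each), anti-VEGF injections per
   treated eye (6 in treatment year 1, 4 in year 2, 2 thereafter, at
   182,035 JPY), PDT for severe PCV/RAP eyes in treatment year 1 only
   (363,450 JPY one eye, 540,000 JPY both eyes in the same year),
   endophthalmitis at 0.03% per injection (1,052,750 JPY per episode,
   cost only — no stage or utility penalty), and the 51,360 JPY/yr
   supplement cost for takers.
8. **Utility accrual** from the (better, worse) stage pair.

Costs and utilities are accrued at the start-of-cycle discount factor
\((1+r)^{-t}\) with \(r = 3\%\); there is **no half-cycle correction** —
the source conventions are unknowable, and this choice is applied
identically to both strategies so increments are affected far less than
levels.  Detection during a cycle takes effect for treatment delivery in
the same cycle and for transition rules from the next cycle; no events
occur at age 90 itself.

## Two engines, one set of rules

`run_microsim()` is an individual-level simulation (the study design this
model family is usually run with), vectorized over persons, with one
fixed random-number channel per event and cycle.  The fixed channels give
common random numbers across strategies: a disabled programme and an
enabled programme with zero participation produce bit-identical
histories, and paired comparisons are low-variance.

`run_cohort()` is a deterministic companion that propagates exact
probability mass over the enumerated joint state space (6,336 states:
canonical unordered eye pairs coupled with treatment years × subtype ×
detection × supplement × presbyopia).  Every event is a sparse transition
matrix built by the same vectorized rule functions the microsimulation
calls, so the two modes cannot drift apart; occupancy mass is conserved
to machine precision, and the test suite checks that 200,000-person
microsimulation means fall within three Monte-Carlo standard errors of
the cohort expectations.  Cohort mode is what the sensitivity analyses
use: a full parameter build plus both strategy arms costs well under a
second.

## Parameters and sensitivity analysis

`amd_parameters()` returns all ~70 model parameters with the univariate
sensitivity interval attached where one is defined ("±50%" intervals are
resolved multiplicatively around the base value).  `perturb_parameter()`
moves exactly one parameter to a bound — perturbing an AMD subtype
probability rescales the other two so the mix still sums to one.

For the probabilistic sensitivity analysis the source material gives only
ranges, not distributions.  `sample_psa_parameters()` therefore uses
standard health-technology-assessment families, moment-matched so the
base value is the mean and the printed interval approximates a 95%
interval: scaled beta on the interval for probabilities, utilities and
the discount rate (which also guarantees draws respect the interval),
gamma for costs, integer uniform for count parameters.  This is a
modelling choice, not an inherited fact, and PSA fractions should be read
accordingly.

Two wrinkles deserve a note:

* **Utility monotonicity.**  The published univariate ranges of adjacent
  stage pairs overlap (the moderate/moderate high bound, 0.96, exceeds
  the prodromal/moderate base, 0.92).  Independent PSA draws could
  therefore produce a utility surface that *increases* with severity.
  Draws are repaired by clipping each pair to the minimum of its
  less-severe neighbours, restoring monotonicity while leaving in-range
  draws untouched.  One-way perturbations are deliberately *not*
  repaired — the contract there is that only the named parameter moves —
  so strict monotonicity is enforced for the base case and PSA draws
  only.
* **Dropout timing.**  "Withdrawal at 50% in the first year of therapy"
  is applied from the first anniversary of detection: patients receive
  their first treatment year and may then withdraw.  Applying it in the
  detection cycle itself would let half of prodromal patients vanish
  before any therapy, which contradicts withdrawal *from* therapy.

## Synthetic inputs

The original analysis used the 2009 Japan abridged life tables, which are
not bundled here.  `synth_life_table()` generates a Gompertz substitute —
annual death probability \(1 - \exp(-a e^{b\,\mathrm{age}})\) — whose
default coefficients give survival from age 40 to 90 of roughly 38%, in
the vicinity of a contemporary Japanese adult cohort; any real abridged
table can be supplied as a two-column CSV via `read_life_table()`.
`synth_population()` builds reference age structures (uniform, or
stationary-population weights consistent with the life table) for direct
age standardization and population projection.

Because background mortality shifts how many person-years are exposed to
late-age AMD risk, headline levels (prevalence, ICER, blindness
reduction) move with the life table.  Passing tests therefore demonstrate
the model's internal consistency, its exact invariants, and directional
and order-of-magnitude agreement with the published analysis — not
digit-level reproduction, which would require the original life table and
the original tool's event-ordering conventions.

## Problem sizes

Default analysis sizes are chosen for a laptop-class workflow: the
deterministic cohort engine replaces the original 50,000-person
simulation for all sensitivity analyses (it is the exact expectation);
the microsimulation default is 50,000 persons as in the study design; the
bundled acceptance analysis runs the full 160-programme grid and a
500-draw PSA (scaled down from 10,000 draws; the PSA fractions' own
Monte-Carlo standard error at 500 draws is about 1–2 percentage points).

## Known limitations

* No dry-AMD/geographic-atrophy pathway and no visual-acuity continuum —
  stages only, as in the source model.
* Prodromal changes never regress; untreated eyes never improve.
* Mortality does not differ by disease state.
* Only direct medical costs are counted — no long-term-care or indirect
  costs, no inflation adjustment; the bevacizumab scenario needs a
  user-supplied unit price (`scenario_parameters()`), since none is
  published in the source material.
* "Occasional (irregular) screening" is interpreted as an opportunistic
  second screening chance for non-participants in programme years; the
  presbyopia clinic-visit probability applies only in the onset year.
  Both readings are documented choices where the source is ambiguous.
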