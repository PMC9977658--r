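---
title: "From tube settings to a conversation: the dose-to-risk pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From tube settings to a conversation: the dose-to-risk pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paedradrisk)
```

## The problem

Radiographers and radiologists in paediatric imaging are routinely asked
"how much radiation is that, and how dangerous is it?" An effective dose in
millisieverts answers neither question for a lay audience, and on its own
it cannot express risk at all: the lifetime probability of a
radiation-induced cancer from the same dose differs severalfold between a
newborn and an adolescent, and between girls and boys. This package turns
an examination, an age and a sex into a risk statement a clinician can
actually say out loud — "about 1 in 166,000, a minimal risk, the same as
eight days of natural background radiation".

## The pipeline

The computation is a chain of small, individually testable steps.

**1. Age to weight band.** Paediatric exposure charts are weight-banded
(3-7, 8-15, 16-25, 26-40, 41-60, 60+ kg) because body habitus, not age,
determines technique. A growth reference table supplies the sex-specific
median weight at each integer age 0-18; where reference weight-for-age
stops (ages 11-18) it is derived from median BMI and height through the
defining identity `weight = BMI x height^2`. The printed integer band
ranges leave fractional gaps, so membership uses the contiguous half-open
intervals `[3, 7.5), [7.5, 15.5), ..., [60.5, Inf)` — equivalent to
rounding to the nearest kilogram first. Weights below 3 kg are a hard
error, not a clamp: the chart makes no recommendation for them and a
conservative tool should say so.

**2. Band to tube settings and dose.** The exposure chart maps (view,
band) to mAs, with a kVp range per view. Where a chart does not pin the
per-band kVp we interpolate linearly across band index between the range
endpoints, which reproduces the convention that the smallest band uses the
bottom of the range and the largest the top; institutions whose charts are
not linear in between can supply explicit per-band values, which always
win. Effective doses per (examination, band) come from Monte Carlo
dosimetry on weight-matched phantoms and ship as a packaged table; views
outside the phantoms' reach (upper extremities) can be normalised from
published doses by the beam-quantity rule `dose x (mAs ratio) x (kVp
ratio)^2`. That rule corrects tube output only — filtration and geometry
differences are a documented, uncorrected limitation. Doses published only
as "<0.001 mSv" are stored as the bound 0.001 and flagged, and every
derived risk inherits a "less than" qualifier.

**3. Dose to excess risk.** Lifetime-attributable-risk tables give excess
cancer cases per 100,000 persons per 0.1 Gy (100 mSv), on a sparse grid of
ages at exposure, by sex, for incidence and mortality. Two linearities are
assumed, both standard in this setting: linearity in dose (no threshold),
so `excess_per_100k = dose_mSv / 100 x coefficient`, and linearity in age
between grid points. Ages outside the grid clamp to the nearest endpoint
with a warning rather than extrapolating. Incidence is the default
endpoint throughout — it is the larger of the two and therefore the
conservative one to communicate.

All arithmetic is kept unrounded internally. The published worked example
fixes this convention: 1 mSv at age 5 with coefficient 1816 gives 18.16
per 100,000, displayed as 18.2, yet its "1 in N" form is 5507 =
round(100000/18.16), not round(100000/18.2) = 5495. Rounding is applied
once, at the display layer.

**4. Risk to words.** Three communication forms are produced:

* the Calman verbal scale — six categories (Negligible to High) on
  order-of-magnitude probability bins from 1-in-a-million to 1-in-100. The
  published bin boundaries overlap at the powers of ten; we make them
  disjoint by taking each bin's lower probability bound as inclusive and
  the upper as exclusive, so exactly 1-in-1000 reads Moderate. Every
  (1-in-N, category) pair in the packaged dose table is interior to a bin,
  so either convention reproduces them — the choice only fixes behaviour
  at the edges, where determinism matters for regression tests;
* background equivalent radiation time (BERT), `dose / 1.5 mSv-per-year`
  (the Australian natural background rate), rendered in hours under two
  days, days under three months, months beyond, with a 365.25-day year;
* international flight time, `dose / 0.00239 mSv-per-hour`, the rate
  implied by a 0.11 mSv, 46-hour long-haul return flight.

"1 in N" strings follow two conventions: running text rounds N to the
nearest integer (5507); tables round to the nearest hundred below 10,000
and to three significant figures above (9400; 166,000), matching how such
tables are published.

**5. Individual versus institutional use.** `patient_risk()` evaluates the
risk at the patient's own age and sex — personal communication should not
inflate the number. `risk_report()` builds the institutional table and is
deliberately conservative: for each (examination, band) it evaluates every
(age, sex) whose median weight falls in the band and reports the maximum,
recording which member attained it. Ties break to the lowest age, then
female before male, so reports are reproducible. Risks from repeated
examinations add (`cumulative_risk()`): each exposure's risk is unchanged
by the others, and the sum is re-classified on the Calman scale.

## The synthetic-data generator

Genuine growth references and lifetime-risk tables are licensed external
datasets, so the package generates structural stand-ins and treats the
real tables as user-supplied CSVs. The generator emulates exactly the
features the pipeline relies on:

* **growth**: a monotone approach to an adult asymptote,
  `w(age) = 68 - (68 - 3.3) exp(-0.12 age)` kg for boys, scaled by 0.97
  for girls. These values were chosen once so that every weight band
  contains at least one (age, sex) — the band-maximum aggregation is then
  exercised everywhere — all weights stay at or above 3 kg, and the
  18-year-old medians land in the 41-60/60+ bands, as real medians do.
  Ages 11-18 are emitted as (BMI, height) pairs so the derivation path is
  always exercised;
* **coefficients**: exponential decay `c(age) = c0 exp(-0.05 age)` on the
  grid {0, 5, 10, 15, 20, 30}, females 1.35x males, mortality half of
  incidence, anchored so the male incidence value at age 5 is exactly
  1816 per 100,000 per 0.1 Gy — the one published reference value, which
  pins the worked example end to end;
* **charts**: geometric mAs progression across bands with an optional
  fraction of views missing their lightest bands, exercising the
  missing-cell error path.

Everything is a closed form; noise defaults to zero, so a configuration
determines its output byte for byte. What the generator does *not* emulate
— LMS-style growth distributions, the age-by-age irregularities of real
risk tables, grid/no-grid dose discontinuities — bounds what passing tests
show: they validate the pipeline's arithmetic and plumbing, not the
epidemiology of any real population. Absolute risks computed from the
synthetic coefficient table are structurally right and numerically
arbitrary except at the anchored point.

## Numerical choices and degenerate inputs

* Linear interpolation error on an exponentially decaying coefficient
  curve is bounded by roughly `(lambda h)^2 / 8`; at the default decay
  0.05/year and a 5-year grid that is under 1%, which the test suite
  verifies directly, together with convergence under grid refinement.
* Zero dose is valid everywhere and yields zero risk; its "1 in N" form is
  an unbounded sentinel (`Inf`), displayed as a dash, never an exception.
* Zero-length dose lists, mixed endpoints in cumulative sums, unknown
  exams/views/bands, and bands containing no median-weight member are all
  explicit classed errors, so a front end can distinguish "you asked for
  something outside the chart" from "your inputs are malformed".
* Problem sizes in the test suite (1000-age interpolation sweeps, 300-point
  probability sweeps, the 108-row packaged table) were chosen as the
  smallest sets that exercise every branch and boundary; the whole suite
  runs in seconds.

## Known limitations

The dose table is institutional: other departments' exposure charts,
detectors and SIDs will shift doses materially, which is why every loader
accepts user CSVs. Median-weight banding misrepresents children far from
the median — the tool reports typical, not personal, dosimetry. The
beam-quantity normalisation ignores filtration and distance. And the
communication layer inherits every caveat of effective dose itself:
nominal risk coefficients apply to populations, not individuals, so
outputs are for communication and justification support, not individual
risk prediction.
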