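---
title: "A Markov cohort model of colorectal cancer screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model of colorectal cancer screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcscreen)
```

## The decision problem

Most colorectal cancers (CRC) develop from benign adenomas over one to
several decades. Screening can interrupt this sequence twice: by removing
adenomas before they turn malignant (preventing cases) and by detecting
preclinical cancers at an earlier stage (improving survival). `crcscreen`
implements a deterministic Markov state-transition cohort model of this
adenoma–carcinoma sequence and uses it to compare four organized screening
policies for an average-risk population:

* **No screening**
* **FIT** — annual fecal immunochemical test, ages 40–75
* **gFOBT** — annual guaiac-based fecal occult blood test, ages 40–75
* **COL** — colonoscopy every 10 years, ages 50, 60 and 70

A positive stool test is always followed by a confirmatory colonoscopy.
Detected non-advanced adenomas are removed; under a stool-test strategy the
individual then switches to 10-yearly colonoscopy. Detected advanced
adenomas trigger 3-yearly surveillance colonoscopy; a 3-yearly exam without
an advanced finding de-escalates to 5-yearly surveillance, and any advanced
finding re-escalates to the 3-yearly track. No surveillance examination is
performed after age 75.

## Model structure

The state space combines:

* **Living, undiagnosed states** — healthy, non-advanced adenoma, advanced
  adenoma, preclinical cancer UICC I–IV, each crossed with a surveillance
  track (`regular`, `colo10y`, `surv3y`, `surv5y`) and a phase counter
  (years since the last examination on that track). The phase tunnel makes
  surveillance timing exact in a cohort model without individual-level
  memory.
* **Diagnosed cancer states** — UICC stage I–IV × detection mode
  (screen/symptom) × years since diagnosis (annual bands 1–5 plus a
  long-term band). The bands carry year-specific follow-up costs and
  year-specific survival; individuals remain in the diagnosed compartment
  until death.
* **Two absorbing states** — CRC death and other-cause death.

The cycle length is one year. Within a cycle the event order is fixed and
documented: screening examinations first (applied only to living,
undiagnosed states), then other-cause death from the life table, then
natural-history progression (at most one step per year), then symptomatic
detection from the current preclinical stage, then cancer survival for the
diagnosed compartment. Adenomas never regress. The stage at symptomatic
diagnosis is the stage occupied at the moment of detection; no additional
within-cycle progression is applied. Screen-detected cases enter the
year-1 survival band in the cycle of detection; symptom-detected cases
enter it at the end of their detection cycle.

Natural history runs from age 20 so that the age-40 state distribution is
shaped by twenty years of adenoma dynamics; **all outcome accumulation
(life-years, costs, event counts) starts at the decision age of 40**.
Life-years are half-cycle corrected (first and last accumulation cycles
weighted 0.5), and discounting uses `(1 + r)^-(age - 40)` with a 3% base
rate. We anchor discounting at age 40 for every strategy, including COL
whose first examination is at 50; anchoring at first screening age instead
would change COL's discounted results at about the 1% level.

The trace terminates at age 110. The packaged life table leaves a residual
living mass of order 1e-4 there, which is ignored after logging; the
associated life-year loss is below 1e-3 years.

## Parameters

### Test accuracy (per application)

| test | adenoma | advanced adenoma | CRC | specificity |
|---|---|---|---|---|
| FIT | 7.6% | 36.7% | 87.2% | 92.8% |
| gFOBT | 9.5% | 23.9% | 72.2% | 90.0% |
| colonoscopy | 69.0% | 86.7% | 94.7% | 100% (expert assumption) |

The gFOBT adenoma sensitivity is the size-pooled value
`0.603 × 7.5% + 0.397 × 12.4%` and its CRC sensitivity the location-pooled
`0.25 × 62.6% + 0.75 × 75.4%` (`pooled_sensitivity()`). Confirmatory
colonoscopy accuracy is independent of the preceding stool-test result.
CRC sensitivity is stage-invariant. The cumulative sensitivity of `k`
repeated independent tests, `1 - (1 - s)^k`, is exposed as
`ten_year_sensitivity()`.

### Costs (EUR, index year 2017)

Unit costs: colonoscopy 228, polypectomy 64, gFOBT 37, FIT 41, staging 461,
stage-specific inpatient care 13 831/18 699/19 038/24 059 (UICC I–IV),
one-time UICC-IV medication 12 433, follow-up years 1–5
552/367/349/419/237 and 228 per 5 years long-term, complication admission
5250 plus a 20% surgical share at 23 258, end-of-life 55 530 (death at
stage I/II) and 36 492 (stage III). No separate end-of-life cost is
tabulated for stage IV deaths; their excess treatment cost is carried by
the one-time medication item at diagnosis.

Program-level fixed costs (1 950 353 EUR/year for a colonoscopy program,
4 118 142 EUR/year for a stool-based program) are amortized per eligible
person per program-year through a documented divisor (default 2 000 000,
an approximate national eligible population). This allocation is a
reconstruction — the original denominators are not published — and the
divisor is a configuration field, not a model constant.

The complication probability is a single per-colonoscopy admission
parameter (3.75e-4). It was chosen so that the base-case colonoscopy
strategy produces about 1.2 complication-related hospital admissions per
1000 screenees over a lifetime, and corresponds to roughly 0.4 admissions
per 1000 colonoscopies, consistent with registry experience. Complications
are cost-only; complication deaths are not modelled.

### Natural history and calibration

The eleven natural-history parameters (log-linear adenoma onset level and
slope, adenoma→advanced, advanced→preclinical, three preclinical stage
progressions, four stage-specific symptomatic detection probabilities) are
not directly observable. They are fitted by `calibrate()` in three
hierarchical stages:

1. **Stage A** — onset and progression-to-cancer parameters against the
   age-group incidence curve (and cumulative CRC mortality), stage
   dynamics fixed;
2. **Stage B** — stage-progression and symptomatic-detection parameters
   against the UICC stage distribution;
3. **Stage C** — joint Nelder–Mead polish of all parameters inside a
   basin-hopping loop (default 8 hops, perturbation 25% of the box width,
   monotone accept, deterministic given the seed).

The loss is a weighted sum of squared relative deviations: each incidence
group has weight 1, the four stage proportions share one incidence block,
and the cumulative-mortality target — the headline validation quantity —
carries a full incidence block on its own. Zero-valued targets fall back
to absolute deviations. Parameters are optimized on a logit-transformed
box whose bounds encode epidemiological plausibility (adenoma dwell times
of years to decades, preclinical sojourn of a few years, detection hazard
increasing with stage). Infeasible or non-finite excursions of the simplex
are penalized rather than allowed to abort the search.

### The packaged default bundle

The original model's supplementary parameter tables are not publicly
deposited, so the packaged bundle is an explicit reconstruction, labelled
as such in its metadata:

* **Life table** — synthetic Gompertz–Makeham
  (`make_life_table(1.65e-5, 0.099, makeham = 5e-4)`), chosen once to match
  the Austrian 2016 period life table (life expectancy 42.4 years at age
  40, 80.7 at birth). Rates beyond age 100 are extrapolated log-linearly
  (`extrapolate_mortality()`), monotone and capped at 1.
* **Cancer survival** — synthetic stage-specific annual death
  probabilities (five-year survival roughly 89/75/50/9% for UICC I–IV),
  chosen to be consistent with the mid-1990s registry era of the
  cumulative-mortality calibration target. Screen-detected cases apply
  stage-specific detection-mode hazard ratios (0.77/0.80/0.84/0.90) on the
  hazard scale: `p_screen = 1 - (1 - p_symptom)^HR`.
* **Calibration targets** — a synthetic Austrian-style incidence curve
  (15 to 420 per 100 000 across age groups 40–44 … 85+), stage
  distribution 21/27/29/23%, and cumulative CRC mortality at 75 of 1.97%.
* **Natural history** — the result of running `calibrate()` against those
  targets (seed 2019). The fitted bundle reproduces the incidence curve
  within ~15%, the stage distribution within 2 percentage points, and a
  cumulative CRC mortality at 75 of 1.72%, inside the ±15% band around
  the 1.97% target and close to the 1.74% the original model reported
  against the same registry value.

## What the synthetic data do and do not emulate

`make_scenario()` generates complete inputs with known ground truth: a
true natural-history parameter set, targets generated from it by the model
itself (optionally with multiplicative lognormal noise, default sd 0.05,
emulating registry sampling variation), and the synthetic life and
survival tables. This supports parameter-recovery experiments — the
strongest available check of the calibration machinery — and end-to-end
pipeline tests without any download.

Synthetic targets are generated by the same model family that is fitted to
them, so recovery experiments demonstrate that the optimizer can invert
the model, not that the model family is correct for real registries. Real
calibration data bring model misfit, cohort effects, sex and location
heterogeneity, and correlated errors that the generator does not emulate.
Passing tests therefore validate the machinery, not the epidemiology.

## Numerical choices

* Transition rows are built from sequentially composed conditional
  probabilities, so they sum to 1 by construction; any single probability
  outside [0, 1] raises a parameter-inconsistency error rather than being
  renormalized. Row sums are asserted to 1e-12, cohort mass conservation
  to 1e-10 over the 90-cycle horizon.
* The frontier algorithm sorts by discounted effect, removes strong
  dominance, then iteratively removes extended dominance until the ICER
  sequence is increasing. Exact cost/effect ties are kept and flagged,
  with the pairwise ICER undefined. ICERs are computed from unrounded
  internal values; rounding printed tables first can shift a ratio by a
  few tenths of a percent (e.g. 598/0.04 = 14 950 from rounded increments).
* Participation is all-or-none at program entry: strategy outcomes under
  partial participation are participation-weighted mixtures with the
  no-screening cohort. Adherence to confirmatory and surveillance
  colonoscopy remains complete in those scenarios.
* Positive-test counting: every positive stool index test and every
  screening or surveillance colonoscopy with any finding counts once;
  findings of the confirmatory colonoscopy after a positive stool test are
  not double-counted. Diagnostic colonoscopies of symptomatic patients
  count toward colonoscopy volume and complications but not toward
  positive screening tests.
* Problem sizes: unit tests run lifetime cohorts (91 cycles, 204 states)
  in well under a second each; the Monte Carlo cross-check uses 2×10^5
  individuals in the unit suite and 10^6 in the acceptance suite; the
  calibration recovery experiment uses the default optimizer budget
  (roughly 5000 model evaluations, under a minute).

## Known limitations

* Cohort expectations only: no quality-of-life weighting, no individual
  lesion histories, no sex or anatomical-site heterogeneity.
* Stool-test sensitivities of consecutive rounds are independent
  conditional on disease in the base case; dependence is explored only
  through the overall sensitivity multiplier.
* The cost reconstruction (program-cost divisor, complication cost split,
  stage-IV end-of-life convention) is plausible but not unique; absolute
  cost levels should be read with that in mind, while within-model
  comparisons between strategies are unaffected by the shared components.
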