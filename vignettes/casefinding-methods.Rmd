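---
title: "Methods: case-finding and validation for anxiety and depression in primary care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-finding and validation for anxiety and depression in primary care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmdcasefind)
```

## Overview

`cmdcasefind` implements an external-validation design for electronic
health record (EHR) phenotyping of the common mental disorders (CMD)
anxiety and depression. The design compares *primary-care cases* — defined
by boolean algorithms over coded diagnoses, symptoms and psychotropic
prescriptions — against *survey cases* defined by the five-item Mental
Health Inventory (MHI-5) in a linked two-wave community survey, reporting
sensitivity, specificity and positive predictive value per algorithm and
wave. Around the validation core sit descriptive analyses of recording
behaviour (annual incidence of recorded episodes per 1000 person-years at
risk, period prevalence) and a synthetic cohort generator that stands in
for the linked records, which cannot be redistributed.

## The case-finding model

For each survey respondent, events are interpreted relative to a one-year
**current window**: the closed 365-day interval `[d − 182, d + 182]` with
the response date `d` at its midpoint (day 183 of 365). The window is
deliberately wide and symmetric: people may present to their GP before a
diagnosis is made, or delay presenting after symptom onset. Anything
strictly before the window is **historical**, over all available
retrospective data; events after the window end post-date the survey and
are ignored.

Five flags summarise a respondent's record:

| flag | meaning |
|------|---------|
| `D`  | ≥ 1 diagnosis-group event in the window |
| `S`  | ≥ 1 symptom-group event in the window |
| `H`  | ≥ 1 diagnosis-group event strictly before the window |
| `Hs` | ≥ 1 symptom-group event strictly before the window |
| `T`  | ≥ 1 antidepressant / anxiolytic / hypnotic prescription in the window |

The twelve algorithms are pure boolean functions of these flags
(`algorithm_descriptions` lists them). Two reading conventions fix the
ambiguity in their natural-language labels: *"plus"* joins case-defining
clauses as a set union (OR), and *"currently treated"* binds as a
conjunction to its preceding clause. Under this reading the algorithms
form subset chains (3 ⊆ 2 ⊆ 4; 5 ⊆ 4; 1 ⊆ 6; 7 ⊆ 8; 9 ⊆ 10 ⊆ 12;
11 ⊆ 12), which reproduces the monotone ordering of identified-case counts
across definitions and is asserted, over the full 32-row truth table and on
every generated dataset, in the test suite. Algorithm 7's "historical or
current diagnosis" excludes symptom history; algorithm 8's "... or
symptom" adds `Hs` — the distinction is taken from the presence of the
words "or symptom" in the labels.

Codes are classified by exact string match against user-supplied code
lists; there is no hierarchical expansion of the Read-code tree, because
the published study queried explicit lists and the lists are inputs here.
The six clinical categories partition into a diagnosis group
(anxiety/depression diagnoses, mixed anxiety–depression, panic) and a
symptom group (anxiety/depression symptoms). Whether panic *attacks* (as
opposed to panic disorder) belong with diagnoses is not decidable from the
study description; the whole panic category is classed as diagnosis here,
and the grouping is exposed as the `diagnosis_categories` argument of
`load_code_lists()` rather than hard-coded.

### Eligibility

A respondent enters validation only with continuous registration across
the whole current window and age 18–74 at response (the MHI-5 is less
reliable in elderly populations). Continuity is evaluated on merged
registration spells: spells merge when the next starts no later than the
day after the previous ends, so a same-day or next-day practice transfer
leaves no uncovered day and does not break continuity, while any uncovered
day does. Age is computed from birth year alone (`year(d) − birth_year`),
the resolution at which anonymised extracts typically carry dates of
birth.

## MHI-5 scoring and the gold standard

Raw items are 1–5; positively worded items are reversed (`6 − x`) via a
configurable per-item map (`mhi5_reverse_default` marks items 3 and 5),
because SF-36 v2 item coding varies between distributions. With at least
three items present, missing items are imputed with the person-mean of the
present oriented items (the half-scale rule standard for SF-36 subscales);
the oriented sum is transformed linearly to 0–100:
`score = (sum − 5)/20 × 100`, lower scores meaning poorer mental health.
With more than two items missing the score — and hence the case label — is
missing, and the respondent is dropped listwise from validation. A
respondent is a gold-standard case when `score ≤ 60`, boundary inclusive,
compared at full floating precision. The cut-point is the
`cutpoint` argument throughout, defaulting to 60 (chosen in the source
study to minimise misclassification).

## Incidence and prevalence

Annual incidence of recorded CMD is computed for three series — diagnosis,
symptom, and either (pooled) — per 1000 person-years at risk (PYAR):

- **Person-time**: per merged registration run, at-risk time in year `y`
  starts at the later of 1 January and run start + 183 days, and ends at
  the earliest of run end, death and 31 December, in closed-interval day
  arithmetic. The six-month exclusion allows retrospective recording of
  prevalent problems to settle so they are not counted as incident.
  Patients with under 365 cumulative at-risk days across the analysis
  years contribute neither person-time nor episodes.
- **Incident episodes**: an event opens a new episode when no event of the
  same series occurred in the 365 days strictly before it; the lookback
  may reach into pre-study data, which is why generated cohorts carry a
  lookback year before the first analysis year. For the "either" series
  the lookback pools both code groups (a diagnosis blocks a subsequent
  symptom from opening an "either" episode); whether the original analysis
  pooled or kept per-problem lookbacks is not stated, and pooling is the
  implemented reading.
- **Rates**: `episodes / (days/365.25) × 1000`, rounded half-up to 1
  decimal. The 365.25-day divisor is a documented package choice; "six
  months" is fixed as 183 days and "one year" as 365 days because explicit
  day arithmetic is unambiguous and testable, where calendar-month
  arithmetic is not.

Period prevalence uses patients continuously registered (merged runs)
across the whole period as denominator and those with ≥ 1 diagnosis-group
event (optionally also symptom-group) in the period as numerator.

## Validation metrics and rounding

`sensitivity = tp/(tp+fn)`, `specificity = tn/(fp+tn)`, `ppv = tp/(tp+fp)`.
Reported values are rounded **half-up** to 2 decimals (percentages to 1),
computed in exact integer arithmetic on the counts
(`floor((2·a·10^d + b) / (2b)) / 10^d` for `a/b`), because binary floating
point cannot represent decimal halves: 764/800 = 0.955 must report as
0.96, and a naive `round()` on the double can land on either side
depending on representation. Unrounded values are returned alongside for
onward computation. A zero denominator yields a missing metric, never 0.

Misclassified-respondent characterisation summarises false negatives
(treated without diagnosis codes, current symptom codes only, historical
diagnosis untreated, no attendance in the window, comorbidity flags) and
false positives (historical diagnosis, currently treated). Comorbidity
flags come from the generator's patient table; the pain/chronic-disease
code lists behind the published breakdown were not published, so real-data
use would require supplying such lists separately.

## The synthetic generator

The generator emulates the *structure* of the study data — it is the
package's test bed, not an estimate of any population:

- Two survey waves about seven years apart, response dates jittered ±30
  days, latent CMD prevalence 0.32 (wave 1) and 0.33 (wave 2), matching
  the gold-standard case fractions of the study population.
- Latent CMD is *defined* as "true MHI-5 ≤ 60": items are drawn so the
  transformed score is ≤ 60 exactly when the latent flag is set (oriented
  item totals 5–17 vs 18–25), making the gold standard consistent by
  construction and the round trip through `score_survey()` exact.
- **Independent-flag mode** (default): each recording flag is drawn
  independently given the latent state and materialised as dated events —
  current events inside the respondent's own window, historical events
  before the first wave's window. Current-window flags therefore equal the
  drawn flags exactly, and `expected_flag_rates()` gives closed-form
  sensitivity/specificity oracles for the current-window algorithms (1, 2,
  4), used in parameter-recovery tests. Historical flags accumulate across
  waves in the event stream (wave-1 events are wave-2 history), so
  historical algorithms have no closed form — a deliberate trade of oracle
  coverage for a single coherent event stream.
- Default recording probabilities were set once to echo the wave-2
  validation pattern: `p_current_dx_given_cmd = 0.05` (current diagnosis
  alone finds ~5% of cases), `p_historical_dx_given_cmd = 0.30` with
  `p_treatment_given_recorded = 0.80` (so the historical-diagnosis-treated
  route contributes ~0.24 sensitivity on top), low non-CMD recording rates
  (0.01–0.04), and a background treatment rate of 0.08 reflecting
  psychotropic prescribing without CMD recording. The probabilities the
  study does not determine are free knobs, documented as such.
- **Event-stream mode**: staggered entry (70% registered before the study
  opens, providing the lookback year), geometric registration lengths with
  5%/year churn, a 1%/year death hazard, and Poisson event streams at
  ~0.020 diagnoses and ~0.0065 symptoms per person-year, the symptom rate
  multiplied by 1.14 per calendar year. This reproduces the qualitative
  recording-behaviour pattern — symptom incidence roughly trebling over a
  decade while diagnosis incidence stays flat — not any specific published
  rate.

What the generator does **not** emulate: realistic Read-code
vocabularies (the shipped lists are labelled synthetic fixtures),
consultation behaviour, survey non-response, deprivation gradients, or any
correlation between MHI-5 severity and recording beyond the binary latent
state. Passing tests therefore demonstrate the pipeline's logic —
windowing, eligibility, episode definitions, metric arithmetic — not the
real-world accuracy of any algorithm.

## Degenerate inputs and numerical conventions

- Dates are ISO-8601; all intervals are closed on both ends.
- Unknown clinical or drug codes are silently non-cases by design (the
  lists define the phenotype); malformed code lists (unknown category,
  duplicate or empty code) fail loudly with the offending row.
- Empty event streams, empty surveys and all-false flags are valid inputs
  yielding empty or all-negative outputs, not errors; a zero PYAR year is
  flagged with a missing rate rather than a division.
- Registration spells ending before they start are rejected; a spell
  opening after death contributes nothing.
- Survey respondents without a patient record are reported and excluded.
- Single RNG stream seeded from the config; identical config + seed gives
  byte-identical output files.

## Problem sizes

The shipped tests run cohorts of 80–4000 patients, with one
20 000-patient independent-flag cohort for parameter recovery (measured
accuracy of the current-diagnosis algorithm within three binomial standard
errors of its closed-form value) and a 5000-patient event-stream cohort
for the incidence trend; the full suite covers the twelve algorithms
against a frozen independently enumerated truth table, person-time against
day-by-day counting on randomised registration histories, and the
validation metrics against the published confusion counts they must
reproduce exactly.

## Limitations

Exact-match code lists put the scientific burden on the list author;
hierarchical Read semantics, free text and secondary-care data are out of
scope. The validation design inherits the MHI-5's view of CMD (current
state, previous four weeks), so respondents with other mental disorders or
in remission under treatment are counted against algorithms that flag
them. Prescription-based treatment flags cannot distinguish indication —
hypnotics prescribed for unrelated reasons count as treatment, as in the
source design. Incidence rates carry no confidence intervals, matching the
descriptive use they serve here.
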