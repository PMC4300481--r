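---
title: "Screening recommendation and quality audit: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening recommendation and quality audit: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smartscreen)
```

`smartscreen` models a preventive-screening programme end to end: person
records in, screening plans and reminder schedules out, and an audit layer
that measures how appropriately a requisition log used the tests a guideline
indicates. This vignette explains the procedures, the tunable parameters and
the design decisions, in the order a user meets them.

## The recommendation procedure and its assumptions

A `ScreeningRule` is pure data: a test code, a target sex, an age window
`[start_age, stop_age)` in **completed years** (floor of calendar age — the
conventional, deterministic choice), a recurrence interval in whole days, and
optional risk-factor *modifiers* and *eligibility* predicates. A modifier
fires when all its predicates hold against the record; fired modifiers may
lower the start age and/or shorten the interval, and when several apply the
**earliest start and shortest interval win** — the most protective
interpretation of overlapping guidance. Eligibility predicates (used by the
skin-examination rule) are OR-combined: any one qualifies the person.

Predicates form a closed, named vocabulary — `bmi_ge`, `bp_ge`, `smoker`,
`known_disease`, `cancer_history`, and `family_history` with an optional
first-degree restriction and an optional onset-age ceiling. No code ever
lives in a ruleset file, so a configuration can be audited cell by cell and
swapped without touching the package (`load_ruleset(path)` validates the
schema: positive intervals, coherent age windows, at most one rule per
(test, sex) with `any` overlapping both sexes, resolvable message ids).

Due dates are mechanical: a person never tested for an indicated test is due
immediately (and overdue); otherwise the test falls due `interval` days after
the most recent result, and is overdue when that date precedes the evaluation
date. The assumptions worth stating: indication depends on the *record*, not
on prior requisition behaviour; results are trusted as dated evidence of
completion; and age is evaluated at a single `as_of` date rather than
continuously (an annual-examination view — see the audit section).

## The shipped default ruleset

The package ships an editable, versioned default (`defaults-2012.1`) written
as circa-2012 adult screening practice; it is a documented stand-in, not a
reproduction of any particular guideline edition. In brief: fasting glucose
3-yearly from 45 (from 25 with BMI ≥ 25 plus another risk factor, or
sustained BP ≥ 135/80); lipid profile 5-yearly, men from 35 and women from 45
(from 20 with CHD risk factors); colorectal screening 50–75 as annual FOBT
plus 10-yearly endoscopy; Pap smear for women 21–65 3-yearly; mammography
from 40 every 2 years (with breast-cancer family history: annually, starting
10 years before the relative's onset age, floor 30); PSA annually from 50
(45 with first-degree family history) flagged as a shared decision; periodic
skin examination for persons with a skin-cancer risk factor.

One detail is deliberately asymmetric: a first-degree **colorectal** family
history advances *FOBT* to age 40 regardless of the relative's onset age,
while it advances *endoscopy* (to 40, 5-yearly) only when the relative's
onset was before 60. Risk-stratifying invasive endoscopy by the relative's
age at diagnosis mirrors real colorectal guidance, and it lets stool-test and
endoscopy indication rates differ in a cohort — which audited programmes
show they do.

## Clinical calculators

All cut points live in one versioned constants file
(`inst/extdata/clinical_thresholds.yaml`): BMI classes at 18.5/25/30; JNC-7
blood-pressure bands (with the 120–139/80–89 band labelled `high_normal`, and
the overall label the worse of the two components); ATP-III lipid bands
(total cholesterol 200/240, LDL 130/160, triglycerides 150/200, low HDL
< 40/50 mg/dL by sex); fasting glucose 100/126 mg/dL; abdominal obesity as a
strict waist > 102/88 cm; ATP-III metabolic syndrome as ≥ 3 of its five
criteria, with a missing component judged *not met* and reported as not
evaluable rather than guessed.

**Band boundary convention, everywhere:** lower bound inclusive, upper bound
exclusive. A BMI of exactly 25 is overweight; an FPG of exactly 100 is
impaired. One convention, stated once, tested at every boundary.

The Framingham score is the ATP-III sex-specific **point-table** variant for
10-year hard coronary heart disease risk, chosen over the regression-equation
variants because a point table is auditable cell by cell; the tables are
package data (`inst/extdata/framingham_atp3.yaml`), not code. Two open bands
need a numeric representation: "< 1%" is reported as 0.5 and the top band as
30. Risk categories use the usual 10/20% cuts (lower-inclusive).

## Reminders

Each due date yields exactly six events per available channel: 14, 7 and 3
days before, and 3, 7 and 14 days after. "Week" means seven calendar days —
no business-day adjustment — and no event ever falls on the due date itself.
A missing e-mail address or phone number silently disables that channel but
never suppresses the recommendation. Reminders stop after the +14-day event;
completing a test moves the due date at the next plan evaluation, which is
how post-due reminders cease. The ICS export writes minimal all-day VEVENTs
and ships with a re-parser so round-trip integrity is testable.

## The audit layer

`classify_test_events()` puts every sex-applicable person in exactly one cell
of a per-test 2×2 tally: **indication judged once, at the end of the audit
period**, and *requested* meaning any in-period visit listed the test.
Judging indication once keeps the tally well-defined and matches an
annual-examination audit; the alternative (continuous indication over the
period) would make a person both indicated and not indicated as birthdays
pass.

Underuse is underused/indicated; overuse is overused/non-indicated;
inappropriateness is their combined count over a denominator that published
audit reports disagree on — total **cases** (the convention of the reference
tables, and the default) or total **requested** tests (a convention some
methods texts use). Both are supported; the choice is recorded in the report.

Percentages are **truncated** at two decimals by default because printed
audit tables are typically chopped, not rounded (108/261 = 41.379 prints as
41.37; 48/78 = 61.538 as 61.53); `rounding = "round"` is available. Coverage
is truncated to a whole percent for the headline figure. Irregular attendance
counts a participant as irregular when some calendar year of the period has
none of their visits or two consecutive in-period visits are more than
`max_gap` days apart (default 365); the denominator is the whole cohort.

A structural property ties the engine to the auditor: a cohort screened by
`evaluate_rules()` whose plans are written back as requisitions
(`apply_screening_requests()`) audits to **zero underuse and zero overuse
for every test** against the same ruleset — software-assisted screening is
perfectly appropriate by construction. The test suite asserts this over many
seeded cohorts, and the acceptance script re-measures it.

## The synthetic generator: what it emulates, what it does not

`cohort_spec()` defaults describe a mid-size workplace cohort: n = 330, 52%
women, ages 36.4 ± 8.68 within 23–62, with chosen realistic risk-factor
prevalences (20% current smokers, 40% BMI ≥ 25, 12% hypertension, 5%
diabetes, 15% dyslipidaemia, family-history rates of 3–15%) and an
error-prone visit log (70% annual attendance; an indicated test goes
unrequested with probability 0.3, a non-indicated one requested with 0.1).
Ages are drawn from a truncated normal whose underlying parameters are
**moment-matched** so that the floored, truncated ages recover the spec's
mean and SD — naive truncation at 23–62 would bias the mean upward by about
a year, and the acceptance check on demographic recovery would (rightly)
catch that.

The generator does *not* model longitudinal disease progression, correlation
between risk factors beyond what indication forcing requires, or realistic
lab-value distributions; passing tests therefore show the machinery is
correct under controlled conditions, not that the defaults reproduce any
particular real population's joint risk structure.

`generate_tally_matched_cohort()` is constructive, not rejection-sampled: it
builds persons whose ages and risk attributes *force* their indication status
per test under the shipped ruleset (neutral host ages, plus per-test "knob"
attributes such as a diabetes family history with BMI 27 for glucose, a
premature-CHD family history for lipids), then deals out requests to hit
each marginal cell exactly. The construction is specific to the default
ruleset's structure; it always **re-audits its own output** and fails naming
the first mismatching cell rather than return an approximation. Infeasible
marginals (more endoscopy-indicated than FOBT-indicated persons, inconsistent
cohort sizes across tests) are rejected with the unsatisfiable cell named.
`study_fixture()` uses it to regenerate, on demand and deterministically, the
261-person reference cohort (136 women, 125 men) whose manual-era audit
reproduces the bundled reference marginals and whose request log totals 366
tests; `software_era_fixture()` adds a 2012 log totalling 334.

## Numerical choices and degenerate inputs

* Truncation uses `floor(x · 10^d + 1e-9)/10^d`; the epsilon guards against
  binary representation error (41.379999… must truncate to 41.37, not 41.36).
* Zero denominators (no indicated cases, no non-indicated cases, an empty
  cohort) yield `NA` reported as *not applicable*, never an error or a zero.
* Validation is total: `validate_record()` returns findings as data and never
  raises, so one malformed exam cannot hide a second problem. Loading
  validated formats stops with the person id and field on any finding.
* Records without exams or results still screen; their detected conditions
  are marked not evaluable.
* Date arithmetic is whole-day on `Date`; files carry ISO-8601 strings.

## Problem sizes in the test and acceptance runs

The suite exercises the self-audit property on 50 generated cohorts of 200
persons, the tally-conservation and recount-oracle identities on 100 cohorts
of 40, the reminder properties on 1,000 random due dates, and demographic
recovery on cohorts of 4,000 (unit test) and 10,000 (acceptance script) —
sizes chosen so the full suite runs in about a minute on one CPU while the
binomial/moment standard errors are tight enough to make 3-SE recovery checks
meaningful.

## Known limitations

* The default ruleset is a documented stand-in for contemporary practice;
  encode your local guidance and pass it to every entry point.
* The auditor's point-in-time indication means a person ageing into a window
  mid-period is counted as indicated for the whole period.
* Reminder transport (SMTP/SMS) is out of scope by design; the package emits
  events and calendars, with the channel as data.
* The Framingham implementation covers ages 20–79 and the hard-CHD point
  variant only; general-CVD regression variants are not provided.
* Unit handling is mg/dL throughout; `mgdl_to_mmol()`/`mmol_to_mgdl()` cover
  the analytes the calculators use, and nothing more.
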