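# smartscreen

Guideline-driven preventive screening for multi-disease programmes: indicated
tests with due dates, automatic clinical risk calculators, reminder
scheduling, and a screening-quality audit layer.

## Who this is for

Occupational-health and primary-care teams running periodic health
examinations face two recurring quality problems: **underuse** (a test a
guideline indicates for a person's sex, age and risk factors is never
requested) and **overuse** (tests requested for people who do not need them),
compounded by irregular attendance. `smartscreen` implements the full
decision-support loop for such a programme as a tested, configurable R
library plus a batch CLI:

1. **register** person records (demographics, medical/family/smoking history,
   physical exams, dated test results, visit logs) — CSV or JSON;
2. **screen** each record against a declarative ruleset to get indicated
   tests, due dates, detected conditions, specialist referrals and health
   messages;
3. **remind** with the fixed six-shot schedule around each due date
   (−14, −7, −3, +3, +7, +14 days) over e-mail/SMS channels, exportable as
   iCalendar;
4. **audit** a cohort's requisition log against the same (or any) ruleset:
   coverage, irregular attendance, and per-test underuse, overuse and
   inappropriateness proportions.

## The statistics at the core

For each screening test *t*, every sex-applicable person falls in one cell of
a 2×2 tally (indicated × requested) over an audit period. With *U_t* the
indicated-but-not-requested count, *I_t* all indicated cases, *O_t* the
requested-but-not-indicated count and *N_t* all non-indicated cases:

    underuse_t  = 100 · U_t / I_t
    overuse_t   = 100 · O_t / N_t
    inappropriateness_t = 100 · (U_t + O_t) / (I_t + N_t)    [denominator = cases]
                        = 100 · (U_t + O_t) / requested_t    [denominator = requested]

Percentages are **truncated** (not rounded) at two decimals by default,
matching printed audit arithmetic (e.g. 108/261 → 41.37); rounding is a
config option, as is the inappropriateness denominator.

Indication comes from a declarative `ScreeningRule`: target sex, age window
`[start_age, stop_age)` in completed years, recurrence interval in days, and
risk-factor *modifiers* drawn from a closed predicate vocabulary (`bmi_ge`,
`bp_ge`, `smoker`, `known_disease`, `family_history`, `cancer_history`) that
may lower the start age or shorten the interval. The shipped default ruleset
covers fasting glucose, lipid profile, FOBT, sigmoidoscopy/colonoscopy, Pap
smear, mammography, PSA and skin examination. The clinical calculators (BMI,
JNC-7 blood-pressure bands, ATP-III lipid/glucose bands, ATP-III metabolic
syndrome, Framingham 10-year hard-CHD point score) run automatically and feed
detected conditions and referrals into each plan.

## Worked example

```r
library(smartscreen)

p <- person_record(
  "0012345678", birth_date = "1961-06-15", sex = "female",
  name = "A. Example", email = "a@example.org",
  history = medical_history(known_diseases = "hypertension",
                            smoking_status = "current", treated_bp = TRUE),
  exams = list(physical_exam("2011-11-20", systolic = 136, diastolic = 86,
                             height = 160, weight = 78, waist = 95)),
  results = list(
    test_result("FPG", "2011-11-20", 104, "mg/dL"),
    test_result("LIPID_PROFILE", "2011-11-20",
                components = list(total_cholesterol = 230, hdl = 42,
                                  ldl = 150, triglycerides = 180))))

plan <- evaluate_rules(p, load_ruleset(), as_of = "2011-12-31")
print(plan)
```

```
Screening plan for 0012345678 as of 2011-12-31
  [x] FOBT                       due 2011-12-31 (overdue)
  [x] FPG                        due 2014-11-19
  [x] LIPID_PROFILE              due 2016-11-18
  [x] MAMMOGRAPHY                due 2011-12-31 (overdue)
  [x] PAP_SMEAR                  due 2011-12-31 (overdue)
  [x] SIGMOIDOSCOPY_COLONOSCOPY  due 2011-12-31 (overdue)
  [ ] SKIN_EXAM                  not indicated
  conditions: bp_high_normal, abdominal_obesity, impaired_fasting_glucose, borderline_lipids, metabolic_syndrome, framingham_low
  referrals: gastroenterology, gynecology, internal medicine, radiology
```

This 50-year-old smoker with treated hypertension is due (and overdue) for
colorectal, breast and cervical screening; her fresh glucose and lipid
results push those due dates forward; the calculators flag impaired fasting
glucose, borderline lipids and ATP-III metabolic syndrome (waist + blood
pressure + glucose + triglycerides), adding an internal-medicine referral.

Audit a cohort's requisition log:

```r
fx <- study_fixture()   # bundled deterministic 261-person synthetic cohort
rep <- audit(fx$cohort, fx$ruleset, fx$period, eligible_n = 330)
print(rep)
```

```
Screening quality audit, 2009-01-01 to 2011-12-31 (261 persons)
coverage: 79%   irregular attendance: 100%
test                               underuse          overuse inappropriate(case) requested
FOBT                         22/23 (95.65%)    0/238 (0.00%)     8.42%         1
FPG                         59/167 (35.32%)    49/94 (52.12%)    41.37%       157
LIPID_PROFILE               49/145 (33.79%)   59/116 (50.86%)    41.37%       155
MAMMOGRAPHY                  24/44 (54.54%)     2/92 (2.17%)    19.11%        22
PAP_SMEAR                    48/78 (61.53%)     0/58 (0.00%)    35.29%        30
PSA                          13/13 (100.00%)    1/112 (0.89%)    11.20%         1
SIGMOIDOSCOPY_COLONOSCOPY      5/5 (100.00%)    0/256 (0.00%)     1.91%         0
SKIN_EXAM                      0/0 (n/a%)    0/261 (0.00%)     0.00%         0
total requested: 366
```

Each row reads: underused/indicated, overused/non-indicated, the combined
inappropriateness over all cases, and the raw request count (366 tests were
requested in total over the three manual-era years).

The same workflow is available from a shell via the installed `smartscreen`
script (`simulate`, `screen`, `audit`, `remind` subcommands; see
`exec/smartscreen` and `run_cli()`).

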