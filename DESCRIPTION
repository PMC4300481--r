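Package: smartscreen
Title: Guideline-Driven Preventive Screening Recommendations, Reminders and
    Quality Audit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision support for multi-disease preventive screening in a
    workplace or clinic cohort. Evaluates a declarative, editable screening
    ruleset (sex, age window, interval, risk-factor modifiers) against person
    records to produce indicated tests with due dates, specialist referrals and
    health messages; applies standard clinical calculators automatically (BMI,
    JNC-7 blood-pressure bands, ATP-III lipid and fasting-glucose bands,
    ATP-III metabolic syndrome, Framingham 10-year hard-CHD point score);
    generates the fixed six-shot pre/post due-date reminder schedule with
    iCalendar export; and audits screening quality per test (coverage,
    irregular attendance, underuse, overuse, inappropriateness). Includes a
    seeded synthetic-cohort generator and an exact tally-matched fixture
    builder so every component is testable without patient data, plus a
    batch command-line interface (screen, audit, remind, simulate).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
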