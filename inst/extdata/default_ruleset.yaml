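# Default screening ruleset: circa-2012 adult preventive-screening defaults,
# written for this package and editable; not a reproduction of any single
# guideline document. Ages in completed years, intervals in days. A rule
# applies when sex matches, age is in [start_age, stop_age), and the optional
# eligibility predicates (OR) hold. A modifier fires when ALL its `when`
# predicates hold; fired modifiers may lower start_age and/or shorten the
# interval (most protective interpretation wins on ties).
#
# Predicate vocabulary (closed):
#   bmi_ge: {value}                     latest exam BMI >= value
#   bp_ge: {systolic, diastolic}        latest exam BP >= either component
#   smoker: {}                          current smoker
#   known_disease: {code}               coded condition in history
#   family_history: {condition, degree, max_onset_age?}  degree: first|any
#   cancer_history: {site}              personal cancer history
version: "defaults-2012.1"

condition_referrals:
  metabolic_syndrome: "internal medicine"
  diabetic_range_fpg: "internal medicine"
  framingham_high: "cardiology"

rules:
  - test_code: FPG
    target_sex: any
    start_age: 45
    interval_days: 1095           # every 3 years
    messages: [fpg_due]
    modifiers:
      - when: [{name: bmi_ge, value: 25}, {name: smoker}]
        start_age: 25
      - when: [{name: bmi_ge, value: 25}, {name: known_disease, code: hypertension}]
        start_age: 25
      - when: [{name: bmi_ge, value: 25},
               {name: family_history, condition: diabetes, degree: first}]
        start_age: 25
      - when: [{name: bp_ge, systolic: 135, diastolic: 80}]
        start_age: 25

  - test_code: LIPID_PROFILE
    target_sex: male
    start_age: 35
    interval_days: 1825           # every 5 years
    messages: [lipid_due]
    modifiers: &lipid_modifiers
      - when: [{name: smoker}]
        start_age: 20
      - when: [{name: family_history, condition: premature_chd, degree: first}]
        start_age: 20
      - when: [{name: known_disease, code: hypertension}]
        start_age: 20
      - when: [{name: known_disease, code: diabetes}]
        start_age: 20

  - test_code: LIPID_PROFILE
    target_sex: female
    start_age: 45
    interval_days: 1825
    messages: [lipid_due]
    modifiers: *lipid_modifiers

  - test_code: FOBT
    target_sex: any
    start_age: 50
    stop_age: 76                  # through age 75
    interval_days: 365            # annual
    referral_specialty: "gastroenterology"
    messages: [fobt_due]
    modifiers:
      - when: [{name: family_history, condition: colorectal_cancer, degree: first}]
        start_age: 40

  - test_code: SIGMOIDOSCOPY_COLONOSCOPY
    target_sex: any
    start_age: 50
    stop_age: 76
    interval_days: 3650           # every 10 years
    referral_specialty: "gastroenterology"
    messages: [colonoscopy_due]
    modifiers:
      # earlier and 5-yearly endoscopy only for early-onset (<60) first-degree
      # family history; later-onset family history advances stool testing only
      - when: [{name: family_history, condition: colorectal_cancer,
                degree: first, max_onset_age: 59}]
        start_age: 40
        interval_days: 1825

  - test_code: PAP_SMEAR
    target_sex: female
    start_age: 21
    stop_age: 66                  # through age 65
    interval_days: 1095
    referral_specialty: "gynecology"
    messages: [pap_due]

  - test_code: MAMMOGRAPHY
    target_sex: female
    start_age: 40
    interval_days: 730            # every 2 years
    referral_specialty: "radiology"
    messages: [mammography_due]
    modifiers:
      - when: [{name: family_history, condition: breast_cancer, degree: first}]
        start_age_rule: {onset_minus: 10, floor: 30}
        interval_days: 365

  - test_code: PSA
    target_sex: male
    start_age: 50
    interval_days: 365
    referral_specialty: "urology"
    messages: [psa_due, psa_shared_decision]
    modifiers:
      - when: [{name: family_history, condition: prostate_cancer, degree: first}]
        start_age: 45

  - test_code: SKIN_EXAM
    target_sex: any
    start_age: 18
    interval_days: 365
    referral_specialty: "dermatology"
    messages: [skin_due]
    eligibility_any:
      - {name: family_history, condition: melanoma, degree: first}
      - {name: cancer_history, site: skin}
      - {name: known_disease, code: immunosuppression}

message_catalog:
  general_welcome: "Preventive screening summary for {name}."
  general_lifestyle: "General advice: balanced diet, regular physical activity, avoid tobacco."
  fpg_due: "Fasting plasma glucose screening is due on {due_date}."
  lipid_due: "Lipid profile screening is due on {due_date}."
  fobt_due: "Annual fecal occult blood testing is due on {due_date}."
  colonoscopy_due: "Flexible sigmoidoscopy or colonoscopy is due on {due_date}."
  pap_due: "Pap smear is due on {due_date}."
  mammography_due: "Mammography is due on {due_date}."
  psa_due: "Prostate-specific antigen testing is due on {due_date}."
  psa_shared_decision: "PSA screening is a shared decision: discuss benefits and harms with your physician."
  skin_due: "Periodic skin examination is due on {due_date}."
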