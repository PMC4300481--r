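# Clinical cut points used by the automatic calculators. One versioned file so
# a guideline update never touches code. Convention everywhere: lower bound
# inclusive, upper bound exclusive (BMI 25.0 is overweight, FPG 100 is
# impaired). Units: kg/m2, mmHg, mg/dL, cm.
version: "atp3-jnc7-1.0"

bmi:
  underweight_below: 18.5
  overweight_from: 25
  obese_from: 30

blood_pressure:      # JNC-7 bands; label = worse of the two components
  high_normal: {systolic_from: 120, diastolic_from: 80}
  stage1:      {systolic_from: 140, diastolic_from: 90}
  stage2:      {systolic_from: 160, diastolic_from: 100}

fasting_glucose:
  impaired_from: 100
  diabetic_from: 126

lipids:              # ATP-III bands
  total_cholesterol: {borderline_from: 200, high_from: 240}
  ldl:               {borderline_from: 130, high_from: 160}
  triglycerides:     {borderline_from: 150, high_from: 200}
  low_hdl_below:     {male: 40, female: 50}

abdominal_obesity:   # waist circumference, strict '>' per ATP-III
  waist_over: {male: 102, female: 88}

metabolic_syndrome:  # ATP-III: positive when >= 3 criteria met
  min_criteria: 3
  triglycerides_from: 150
  low_hdl_below: {male: 40, female: 50}
  bp_from: {systolic: 130, diastolic: 85}
  fpg_from: 100

framingham_categories: {intermediate_from: 10, high_from: 20}  # percent
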