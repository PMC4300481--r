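# Clinical calculators: band lookups, boundary conventions (lower bound
# inclusive), and totality/partition properties.

test_that("BMI value and category follow the fixed cut points", {
  r <- compute_bmi(70, 175)
  expect_equal(r$value, 70 / 1.75^2, tolerance = 1e-12)  # 22.857...
  expect_identical(r$category, "normal")
  # unit identity: height 100 cm makes value == weight
  expect_equal(compute_bmi(57.3, 100)$value, 57.3)
  # boundaries are lower-inclusive (height 100 makes the value exact)
  expect_identical(compute_bmi(25, 100)$category, "overweight")
  expect_identical(compute_bmi(30, 100)$category, "obese")
  expect_identical(compute_bmi(18.5, 100)$category, "normal")
  expect_identical(compute_bmi(18.4, 100)$category, "underweight")
  expect_error(compute_bmi(0, 170), class = "smartscreen_domain_error")
  expect_error(compute_bmi(70, -3), class = "smartscreen_domain_error")
})

test_that("BMI scales linearly in weight", {
  w <- c(50, 65, 90)
  for (wi in w) {
    expect_equal(compute_bmi(2 * wi, 180)$value, 2 * compute_bmi(wi, 180)$value)
  }
})

test_that("blood pressure label is the worse of the two components", {
  expect_identical(categorize_bp(118, 78)$label, "normal")
  expect_identical(categorize_bp(118, 92)$label, "stage1")   # diastolic dominates
  expect_identical(categorize_bp(160, 80)$label, "stage2")
  expect_identical(categorize_bp(120, 80)$label, "high_normal")
  expect_identical(categorize_bp(139, 89)$label, "high_normal")
  expect_identical(categorize_bp(140, 90)$label, "stage1")
  expect_identical(categorize_bp(155, 101)$label, "stage2")
  expect_error(categorize_bp(80, 120), class = "smartscreen_domain_error")
})

test_that("abdominal obesity uses strict sex-specific waist thresholds", {
  expect_true(detect_abdominal_obesity(103, "male"))
  expect_false(detect_abdominal_obesity(102, "male"))
  expect_false(detect_abdominal_obesity(88, "female"))   # strict inequality
  expect_true(detect_abdominal_obesity(88.1, "female"))
  expect_false(detect_abdominal_obesity(60, "male"))
  expect_false(detect_abdominal_obesity(60, "female"))
})

test_that("fasting glucose bands partition at 100 and 126", {
  expect_identical(categorize_fpg(95)$category, "normal")
  expect_identical(categorize_fpg(100)$category, "impaired_fasting_glucose")
  expect_identical(categorize_fpg(125.9)$category, "impaired_fasting_glucose")
  expect_identical(categorize_fpg(126)$category, "diabetic_range")
  expect_error(categorize_fpg(0), class = "smartscreen_domain_error")
})

test_that("lipid panel components are banded per ATP-III", {
  all_ok <- categorize_lipids(list(total_cholesterol = 180, ldl = 100,
                                   triglycerides = 120, hdl = 55), "male")
  expect_identical(all_ok$total_cholesterol, "desirable")
  expect_identical(all_ok$ldl, "desirable")
  expect_identical(all_ok$triglycerides, "desirable")
  expect_false(all_ok$low_hdl)
  expect_false(all_ok$any_borderline_or_high)

  expect_identical(categorize_lipids(list(total_cholesterol = 200, ldl = 100,
                                          triglycerides = 100, hdl = 55),
                                     "male")$total_cholesterol, "borderline")
  m <- categorize_lipids(list(total_cholesterol = 180, ldl = 100,
                              triglycerides = 100, hdl = 39), "male")
  expect_true(m$low_hdl)
  # the same HDL is low for a woman only below 50
  f <- categorize_lipids(list(total_cholesterol = 180, ldl = 100,
                              triglycerides = 100, hdl = 49), "female")
  expect_true(f$low_hdl)
  expect_error(categorize_lipids(list(total_cholesterol = 150, hdl = 160,
                                      ldl = 10, triglycerides = 10), "male"),
               class = "smartscreen_domain_error")
})

test_that("metabolic syndrome counts ATP-III criteria and needs three", {
  sat <- detect_metabolic_syndrome(
    make_exam(systolic = 140, diastolic = 90, waist = 110),
    list(triglycerides = 200, hdl = 30), fpg = 110, sex = "male")
  expect_true(sat$positive)
  expect_length(sat$criteria_met, 5)

  two <- detect_metabolic_syndrome(
    make_exam(systolic = 110, diastolic = 70, waist = 110),
    list(triglycerides = 200, hdl = 60), fpg = 90, sex = "male")
  expect_false(two$positive)
  expect_length(two$criteria_met, 2)

  # criterion-by-criterion: waist 103 (m), TG 150 (>=150), HDL 39 (m), BP ok,
  # FPG 90 -> exactly the three named criteria
  three <- detect_metabolic_syndrome(
    make_exam(systolic = 118, diastolic = 70, waist = 103),
    list(triglycerides = 150, hdl = 39), fpg = 90, sex = "male")
  expect_true(three$positive)
  expect_setequal(three$criteria_met,
                  c("abdominal_obesity", "high_triglycerides", "low_hdl"))

  # treated blood pressure counts as the BP criterion
  treated <- detect_metabolic_syndrome(
    make_exam(systolic = 118, diastolic = 70, waist = 103),
    list(triglycerides = 150, hdl = 39), fpg = 90, sex = "male",
    treated_bp = TRUE)
  expect_length(treated$criteria_met, 4)

  # a missing component is judged not met and recorded
  partial <- detect_metabolic_syndrome(
    make_exam(waist = 110), NULL, fpg = NA, sex = "female")
  expect_setequal(partial$not_evaluable,
                  c("high_triglycerides", "low_hdl", "elevated_fpg"))
  expect_false(partial$positive)
})

test_that("adding a met criterion never turns metabolic syndrome negative", {
  # monotonicity: escalate one component at a time
  base_exam <- make_exam(systolic = 128, diastolic = 70, waist = 103)
  worse_exam <- make_exam(systolic = 135, diastolic = 70, waist = 103)
  panel <- list(triglycerides = 155, hdl = 40)
  worse_panel <- list(triglycerides = 155, hdl = 35)
  r00 <- detect_metabolic_syndrome(base_exam, panel, 95, "male")
  r10 <- detect_metabolic_syndrome(worse_exam, panel, 95, "male")
  r11 <- detect_metabolic_syndrome(worse_exam, worse_panel, 95, "male")
  r111 <- detect_metabolic_syndrome(worse_exam, worse_panel, 101, "male")
  counts <- c(length(r00$criteria_met), length(r10$criteria_met),
              length(r11$criteria_met), length(r111$criteria_met))
  expect_true(all(diff(counts) >= 0))
  expect_true(all(diff(as.integer(c(r00$positive, r10$positive,
                                    r11$positive, r111$positive))) >= 0))
})

test_that("unit conversion round-trips and uses analyte-specific factors", {
  for (a in c("glucose", "cholesterol", "triglycerides")) {
    expect_equal(mmol_to_mgdl(mgdl_to_mmol(123.4, a), a), 123.4)
  }
  expect_equal(mgdl_to_mmol(180.16, "glucose"), 10, tolerance = 1e-6)
  expect_equal(mgdl_to_mmol(38.67 * 5, "cholesterol"), 5)
})

test_that("every categorizer is total and its bands partition the domain", {
  for (bmi in seq(10, 45, by = 0.5)) {
    cat <- compute_bmi(bmi * 1.7^2, 170)$category
    expect_true(cat %in% c("underweight", "normal", "overweight", "obese"))
  }
  for (s in seq(90, 200, by = 2)) {
    for (d in c(55, 75, 85, 95, 105)) {
      if (s > d) {
        expect_true(categorize_bp(s, d)$label %in%
                      c("normal", "high_normal", "stage1", "stage2"))
      }
    }
  }
  for (g in seq(50, 300, by = 1)) {
    expect_true(categorize_fpg(g)$category %in%
                  c("normal", "impaired_fasting_glucose", "diabetic_range"))
  }
})
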