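# Recommendation engine: indication logic, due dates, plans, messages.

test_that("sex-inapplicable rules are never indicated and say why", {
  pap_rule <- rule_for(default_rs, "PAP_SMEAR")
  r <- is_indicated(make_person(sex = "male", age = 40), pap_rule, "2011-12-31")
  expect_false(r$indicated)
  expect_match(r$rationale[1], "sex mismatch")
})

test_that("the age window is inclusive at start_age and exclusive at stop_age", {
  fpg_rule <- rule_for(default_rs, "FPG")
  expect_true(is_indicated(make_person(age = 45), fpg_rule, "2011-12-31")$indicated)
  expect_false(is_indicated(make_person(age = 44), fpg_rule, "2011-12-31")$indicated)
  pap_rule <- rule_for(default_rs, "PAP_SMEAR")
  expect_true(is_indicated(make_person(sex = "female", age = 21), pap_rule,
                           "2011-12-31")$indicated)
  expect_true(is_indicated(make_person(sex = "female", age = 65), pap_rule,
                           "2011-12-31")$indicated)
  expect_false(is_indicated(make_person(sex = "female", age = 66), pap_rule,
                            "2011-12-31")$indicated)
})

test_that("a first-degree colorectal family history advances FOBT to 40", {
  fobt_rule <- rule_for(default_rs, "FOBT")
  plain <- make_person(age = 40)
  expect_false(is_indicated(plain, fobt_rule, "2011-12-31")$indicated)
  risky <- make_person(age = 40,
                       family_history = list(fh("colorectal_cancer", "father", 70)))
  r <- is_indicated(risky, fobt_rule, "2011-12-31")
  expect_true(r$indicated)
  expect_true(any(grepl("modifier", r$rationale)))
  # the endoscopy rule only advances for early-onset family history
  sig_rule <- rule_for(default_rs, "SIGMOIDOSCOPY_COLONOSCOPY")
  expect_false(is_indicated(risky, sig_rule, "2011-12-31")$indicated)
  early <- make_person(age = 40,
                       family_history = list(fh("colorectal_cancer", "father", 55)))
  expect_true(is_indicated(early, sig_rule, "2011-12-31")$indicated)
})

test_that("breast-cancer family history starts mammography 10y before onset, floor 30", {
  mam_rule <- rule_for(default_rs, "MAMMOGRAPHY")
  risky <- function(age, onset) make_person(
    sex = "female", age = age,
    family_history = list(fh("breast_cancer", "mother", onset)))
  expect_true(is_indicated(risky(35, 45), mam_rule, "2011-12-31")$indicated)
  expect_false(is_indicated(risky(34, 45), mam_rule, "2011-12-31")$indicated)
  # floor at 30 even for very early onsets
  expect_true(is_indicated(risky(30, 32), mam_rule, "2011-12-31")$indicated)
  expect_false(is_indicated(risky(29, 32), mam_rule, "2011-12-31")$indicated)
})

test_that("next_due_date handles never-tested, overdue and future cases", {
  r <- next_due_date(NULL, 365, "2012-06-15")
  expect_equal(r$due_date, as.Date("2012-06-15"))
  expect_true(r$overdue)
  r <- next_due_date(as.Date("2011-06-01"), 365, "2012-06-15")
  expect_equal(r$due_date, as.Date("2012-05-31"))
  expect_true(r$overdue)
  r <- next_due_date(as.Date("2012-06-01"), 365, "2012-06-15")
  expect_equal(r$due_date, as.Date("2013-06-01"))
  expect_false(r$overdue)
  expect_error(next_due_date(NULL, 0, "2012-06-15"),
               class = "smartscreen_domain_error")
})

test_that("a low-risk 30-year-old man gets no cancer screening indication", {
  plan <- evaluate_rules(make_person(age = 30), default_rs, "2011-12-31")
  ind <- vapply(plan$recommendations, function(r) r$indicated, TRUE)
  codes <- vapply(plan$recommendations, function(r) r$test_code, "")
  expect_false(any(ind[codes %in% c("FOBT", "SIGMOIDOSCOPY_COLONOSCOPY",
                                    "PSA", "SKIN_EXAM", "FPG",
                                    "LIPID_PROFILE")]))
  # recommendations are sorted by test code, one per applicable rule
  expect_identical(codes, sort(codes))
})

test_that("plans never contain a sex-inapplicable test", {
  f <- evaluate_rules(make_person(sex = "female", age = 50), default_rs,
                      "2011-12-31")
  m <- evaluate_rules(make_person(sex = "male", age = 50), default_rs,
                      "2011-12-31")
  f_codes <- vapply(f$recommendations, function(r) r$test_code, "")
  m_codes <- vapply(m$recommendations, function(r) r$test_code, "")
  expect_false("PSA" %in% f_codes)
  expect_false(any(c("PAP_SMEAR", "MAMMOGRAPHY") %in% m_codes))
})

test_that("identical inputs produce identical plans", {
  p <- make_person(sex = "female", age = 47, smoking = "current",
                   exams = list(make_exam(systolic = 136, diastolic = 86,
                                          weight = 80, waist = 95)),
                   results = list(test_result("FPG", "2010-03-01", 104)))
  expect_identical(evaluate_rules(p, default_rs, "2011-12-31"),
                   evaluate_rules(p, default_rs, "2011-12-31"))
})

test_that("detected conditions and referrals flow from the calculators", {
  p <- make_person(
    sex = "male", age = 50, treated_bp = TRUE,
    known_diseases = "hypertension",
    exams = list(make_exam(systolic = 136, diastolic = 86, waist = 105,
                           weight = 95)),
    results = list(
      test_result("FPG", "2011-05-01", 110),
      test_result("LIPID_PROFILE", "2011-05-01",
                  components = list(total_cholesterol = 230, hdl = 38,
                                    ldl = 150, triglycerides = 180))))
  plan <- evaluate_rules(p, default_rs, "2011-12-31")
  expect_true(plan$conditions_evaluable)
  expect_true("metabolic_syndrome" %in% plan$detected_conditions)
  expect_true("impaired_fasting_glucose" %in% plan$detected_conditions)
  expect_true("bp_high_normal" %in% plan$detected_conditions)
  expect_true("abdominal_obesity" %in% plan$detected_conditions)
  expect_true(any(grepl("^framingham_", plan$detected_conditions)))
  # configured specialty for metabolic syndrome lands in the referral list
  expect_true(default_rs$condition_referrals$metabolic_syndrome %in%
                plan$referrals)
  expect_identical(plan$referrals, sort(unique(plan$referrals)))
})

test_that("a record with no exam or results yields a plan with conditions not evaluable", {
  p <- make_person(age = 50, exams = list())
  plan <- evaluate_rules(p, default_rs, "2011-12-31")
  expect_false(plan$conditions_evaluable)
  expect_length(plan$detected_conditions, 0)
  expect_gt(length(plan$recommendations), 0)
})

test_that("message rendering: general always, one or more per indicated test", {
  none <- evaluate_rules(make_person(age = 30), default_rs, "2011-12-31")
  general_n <- sum(grepl("^general_", names(default_rs$message_catalog)))
  expect_length(none$messages, general_n)

  many <- evaluate_rules(make_person(sex = "female", age = 50), default_rs,
                         "2011-12-31")
  n_ind <- sum(vapply(many$recommendations, function(r) r$indicated, TRUE))
  expect_gte(n_ind, 3)
  expect_gte(length(many$messages), general_n + n_ind)
  # due dates are substituted into the rendered text
  expect_true(any(grepl("\\d{4}-\\d{2}-\\d{2}", many$messages)))
})

test_that("an unknown placeholder in a template is a config error", {
  doc <- minimal_ruleset_doc(list(simple_rule()))
  doc$message_catalog$due <- "{test_code} due {wrong_var}"
  rs <- load_ruleset_from(doc)
  expect_error(evaluate_rules(make_person(age = 50), rs, "2011-12-31"),
               "wrong_var", class = "smartscreen_config_error")
})

test_that("a matching risk modifier never removes an indication or delays the due date", {
  # property over ages: compare plain vs family-history person for FOBT
  fobt_rule <- rule_for(default_rs, "FOBT")
  for (age in c(35, 40, 45, 50, 60, 75)) {
    plain <- is_indicated(make_person(age = age), fobt_rule, "2011-12-31")
    risky <- is_indicated(
      make_person(age = age,
                  family_history = list(fh("colorectal_cancer", "father", 70))),
      fobt_rule, "2011-12-31")
    expect_true(risky$indicated >= plain$indicated)
    expect_lte(risky$effective_start_age, plain$effective_start_age)
    expect_lte(risky$effective_interval_days, plain$effective_interval_days)
  }
})
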