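# Audit metrics: proportions with truncation, coverage, irregular attendance,
# requested counts, tally conservation and the recount oracle.

make_tally <- function(code, ir, inr, nr, nnr) {
  structure(data.frame(test_code = code, indicated_requested = ir,
                       indicated_not_requested = inr,
                       notindicated_requested = nr,
                       notindicated_not_requested = nnr,
                       stringsAsFactors = FALSE),
            class = c("test_tally", "data.frame"))
}

test_that("proportions are truncated, not rounded, at two decimals", {
  # 24/44 = 54.5454... -> 54.54 ; 48/78 = 61.538... -> 61.53
  expect_equal(unname(underuse_proportion(make_tally("MAMMOGRAPHY", 20, 24, 2, 90))),
               54.54)
  expect_equal(unname(underuse_proportion(make_tally("PAP_SMEAR", 30, 48, 0, 58))),
               61.53)
  # 49/94 = 52.127... -> 52.12 ; 0/238 -> 0
  expect_equal(unname(overuse_proportion(make_tally("FPG", 108, 59, 49, 45))),
               52.12)
  expect_equal(unname(overuse_proportion(make_tally("FOBT", 1, 22, 0, 238))), 0)
  # rounding mode is available as an option
  expect_equal(unname(underuse_proportion(make_tally("X", 20, 24, 2, 90),
                                          rounding = "round")), 54.55)
  # zero numerators give 0.00
  expect_equal(unname(underuse_proportion(make_tally("X", 10, 0, 0, 5))), 0)
})

test_that("inappropriateness supports both denominator conventions", {
  fpg <- make_tally("FPG", 108, 59, 49, 45)   # 59+49 over 261 cases
  expect_equal(unname(inappropriateness(fpg, "cases")), 41.37)
  # over requested tests: 108/157 = 68.78...
  expect_equal(unname(inappropriateness(fpg, "requested")), 68.78)
  psa <- make_tally("PSA", 0, 13, 1, 111)     # 14/125
  expect_equal(unname(inappropriateness(psa, "cases")), 11.2)
  perfect <- make_tally("X", 40, 0, 0, 60)
  expect_equal(unname(inappropriateness(perfect, "cases")), 0)
  # zero denominator is not-applicable, not an error
  none <- make_tally("X", 0, 0, 0, 0)
  expect_true(is.na(inappropriateness(none, "cases")))
  expect_true(is.na(underuse_proportion(none)))
})

test_that("coverage truncates to a whole-percent headline", {
  expect_equal(coverage(261, 330)$headline, 79)
  expect_equal(coverage(281, 330)$headline, 85)
  expect_equal(coverage(261, 330)$percent, 79.09)
  expect_equal(coverage(0, 50)$headline, 0)
  expect_error(coverage(10, 0), class = "smartscreen_domain_error")
  expect_error(coverage(60, 50), class = "smartscreen_domain_error")
})

test_that("irregular attendance flags missed years and long gaps", {
  period <- c("2009-01-01", "2011-12-31")
  annual <- make_person(visits = list(visit_event("2009-06-01"),
                                      visit_event("2010-05-20"),
                                      visit_event("2011-05-01")))
  expect_equal(irregular_attendance(list(annual), period), 0)
  # a single 2-year gap forces 100%
  gappy <- make_person(visits = list(visit_event("2009-06-01"),
                                     visit_event("2011-08-01")))
  expect_equal(irregular_attendance(list(gappy), period), 100)
  expect_true(is.na(irregular_attendance(list(), period)))
  # constructed 40/100 cohort: 60 regular attenders, 40 with a missed year
  regular <- lapply(1:60, function(i) {
    p <- make_person(id = sprintf("R%03d", i))
    p$visits <- list(visit_event("2009-03-01"), visit_event("2010-02-20"),
                     visit_event("2011-02-10"))
    p
  })
  irregular <- lapply(1:40, function(i) {
    p <- make_person(id = sprintf("I%03d", i))
    p$visits <- list(visit_event("2009-03-01"), visit_event("2011-03-01"))
    p
  })
  expect_equal(irregular_attendance(c(regular, irregular), period), 40)
})

test_that("count_requested counts per-test requests within the period only", {
  period <- c("2009-01-01", "2011-12-31")
  expect_equal(count_requested(list(), period)$total, 0)
  p <- make_person(visits = list(
    visit_event("2010-01-01", c("FPG", "LIPID_PROFILE")),
    visit_event("2011-01-01", "FPG"),
    visit_event("2014-01-01", "PSA")))   # outside the period
  cc <- count_requested(list(p), period)
  expect_equal(unname(cc$per_test["FPG"]), 2)
  expect_equal(unname(cc$per_test["PSA"]), 0)
  expect_equal(cc$total, 3)
})

test_that("grand totals add under cohort concatenation", {
  period <- c("2009-01-01", "2011-12-31")
  a <- generate_cohort(cohort_spec(n = 20, seed = 1))
  b <- generate_cohort(cohort_spec(n = 15, seed = 2))
  expect_equal(count_requested(c(a, b), period)$total,
               count_requested(a, period)$total +
                 count_requested(b, period)$total)
})

test_that("tally cells conserve the sex-applicable cohort and match a recount oracle", {
  period <- c("2009-01-01", "2011-12-31")
  for (seed in 1:10) {
    cohort <- generate_cohort(cohort_spec(n = 30, seed = seed))
    tally <- classify_test_events(cohort, default_rs, period)
    n_f <- sum(vapply(cohort, function(p) p$sex == "female", TRUE))
    n_m <- length(cohort) - n_f
    sizes <- c(FPG = 30, LIPID_PROFILE = 30, FOBT = 30,
               SIGMOIDOSCOPY_COLONOSCOPY = 30, SKIN_EXAM = 30,
               PAP_SMEAR = n_f, MAMMOGRAPHY = n_f, PSA = n_m)
    cells <- tally$indicated_requested + tally$indicated_not_requested +
      tally$notindicated_requested + tally$notindicated_not_requested
    expect_equal(cells, unname(sizes[tally$test_code]))

    # independent brute-force recount of the inappropriateness numerator
    for (i in seq_len(nrow(tally))) {
      code <- tally$test_code[i]
      bad <- 0L
      for (p in cohort) {
        rules <- Filter(function(r) r$test_code == code &&
                          r$target_sex %in% c("any", p$sex), default_rs$rules)
        if (!length(rules)) next
        ind <- any(vapply(rules, function(r)
          is_indicated(p, r, period[2])$indicated, TRUE))
        req <- FALSE
        for (v in p$visits) {
          if (v$date >= as.Date(period[1]) && v$date <= as.Date(period[2]) &&
              code %in% v$tests_requested) req <- TRUE
        }
        if (ind != req) bad <- bad + 1L
      }
      expect_identical(tally$indicated_not_requested[i] +
                         tally$notindicated_requested[i], bad)
    }
  }
})

test_that("screening then auditing against the same ruleset is perfectly appropriate", {
  period <- c("2009-01-01", "2011-12-31")
  for (seed in c(3, 17)) {
    cohort <- generate_cohort(cohort_spec(n = 60, seed = seed))
    plans <- screen_cohort(cohort, default_rs, period[2])
    screened <- apply_screening_requests(cohort, plans, as.Date(period[2]))
    tally <- classify_test_events(screened, default_rs, period)
    expect_true(all(tally$indicated_not_requested == 0))
    expect_true(all(tally$notindicated_requested == 0))
    rep <- audit(screened, default_rs, period)
    expect_true(all(rep$inappropriateness_pct == 0, na.rm = TRUE))
  }
})

test_that("audit assembles a serialisable report and survives an empty cohort", {
  period <- c("2009-01-01", "2011-12-31")
  cohort <- generate_cohort(cohort_spec(n = 25, seed = 9))
  rep <- audit(cohort, default_rs, period, eligible_n = 50)
  expect_s3_class(rep, "quality_report")
  expect_equal(rep$coverage_headline, 50)
  expect_equal(rep$requested_total, sum(rep$requested))
  pcts <- c(rep$underuse_pct, rep$overuse_pct, rep$inappropriateness_pct)
  expect_true(all(pcts >= 0 & pcts <= 100, na.rm = TRUE))
  json <- report_to_json(rep)
  back <- jsonlite::fromJSON(json)
  expect_equal(back$requested_total, rep$requested_total)
  expect_output(print(rep), "total requested")

  empty <- audit(list(), default_rs, period)
  expect_true(is.na(empty$irregular_attendance_pct))
  expect_equal(empty$requested_total, 0)
  expect_true(all(is.na(empty$underuse_pct)))
})
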