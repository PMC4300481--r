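# Synthetic cohorts: (1) a seeded generator with controllable demographics,
# risk-factor prevalences and visit behaviour, emulating a mid-size workplace
# cohort; (2) an exact tally-matched constructor that builds a cohort whose
# audit reproduces a requested set of per-test 2x2 marginals cell-for-cell;
# (3) a deterministic bundled fixture reproducing the reference audit tallies
# shipped with the package. Everything is generated in code - no data files.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic cohort
#'
#' Defaults emulate a workplace cohort of roughly 330 staff: 52\% women, age
#' 36.4 +/- 8.68 years within 23-62. Prevalences are the package's chosen
#' realistic workplace values (the generator's defaults are study conditions,
#' not tuning knobs). Visit behaviour drives the audit: each person attends a
#' given year of the period with `attendance_prob`; at a visit, each truly
#' indicated test is omitted with `underuse_rate` and each non-indicated test
#' requested with `overuse_rate`.
#'
#' @param n Cohort size (> 0).
#' @param female_fraction Proportion of women.
#' @param age_mean,age_sd,age_min,age_max Age distribution in years
#'   (truncated normal).
#' @param prevalences Named list of risk-factor proportions: smoking,
#'   bmi_ge25, hypertension, diabetes, dyslipidemia, fh_diabetes, fh_breast,
#'   fh_colorectal, fh_premature_chd, fh_prostate.
#' @param attendance_prob Per-year visit probability over the period.
#' @param underuse_rate P(indicated test not requested at a visit).
#' @param overuse_rate P(non-indicated test requested at a visit).
#' @param period Two dates, the visit-log window.
#' @param reference_date Date at which ages are interpreted.
#' @param seed RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n = 330, female_fraction = 0.52,
                        age_mean = 36.4, age_sd = 8.68,
                        age_min = 23, age_max = 62,
                        prevalences = list(
                          smoking = 0.20, bmi_ge25 = 0.40,
                          hypertension = 0.12, diabetes = 0.05,
                          dyslipidemia = 0.15, fh_diabetes = 0.15,
                          fh_breast = 0.05, fh_colorectal = 0.05,
                          fh_premature_chd = 0.08, fh_prostate = 0.03),
                        attendance_prob = 0.7,
                        underuse_rate = 0.3, overuse_rate = 0.1,
                        period = c("2009-01-01", "2011-12-31"),
                        reference_date = "2011-12-31", seed = 1) {
  if (!isTRUE(n > 0)) stop_config("n must be > 0")
  props <- c(female_fraction = female_fraction, unlist(prevalences),
             attendance_prob = attendance_prob,
             underuse_rate = underuse_rate, overuse_rate = overuse_rate)
  bad <- names(props)[props < 0 | props > 1]
  if (length(bad)) stop_config("proportions outside [0,1]: ",
                               paste(bad, collapse = ", "))
  if (!(age_min <= age_mean && age_mean <= age_max)) {
    stop_config("need age_min <= age_mean <= age_max")
  }
  structure(list(n = as.integer(n), female_fraction = female_fraction,
                 age_mean = age_mean, age_sd = age_sd,
                 age_min = age_min, age_max = age_max,
                 prevalences = prevalences,
                 attendance_prob = attendance_prob,
                 underuse_rate = underuse_rate, overuse_rate = overuse_rate,
                 period = period, reference_date = reference_date,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

trunc_norm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  z <- stats::pnorm(b) - stats::pnorm(a)
  lam <- (stats::dnorm(a) - stats::dnorm(b)) / z
  v <- sigma^2 * (1 + (a * stats::dnorm(a) - b * stats::dnorm(b)) / z - lam^2)
  c(mean = mu + sigma * lam, sd = sqrt(v))
}

# Underlying normal parameters whose truncation to [lo, hi] has the target
# moments. Truncation pulls the realised mean toward the centre of the
# window, so sampling at the target parameters directly would bias the
# cohort's age distribution; this inverts that.
match_trunc_norm <- function(target_mean, target_sd, lo, hi) {
  obj <- function(p) {
    mo <- trunc_norm_moments(p[1], exp(p[2]), lo, hi)
    (mo[["mean"]] - target_mean)^2 + (mo[["sd"]] - target_sd)^2
  }
  p <- stats::optim(c(target_mean, log(target_sd)), obj)$par
  list(mean = p[1], sd = exp(p[2]))
}

# Integer ages whose empirical mean/SD match the spec: moment-match the
# continuous truncated normal (offsetting the -0.5 mean shift and +1/12
# variance of flooring), then floor.
sample_ages <- function(n, mean, sd, lo, hi) {
  if (sd <= 0 || lo >= hi) return(rep(as.integer(round(mean)), n))
  var_target <- max(sd^2 - 1 / 12, 1e-6)
  pars <- match_trunc_norm(mean + 0.5, sqrt(var_target), lo, hi + 1)
  pmin(floor(rtrunc_norm(n, pars$mean, pars$sd, lo, hi + 1)), hi)
}

birth_for_age <- function(age, reference_date) {
  ref <- as.POSIXlt(as_date(reference_date))
  anchor <- as.Date(sprintf("%04d-%02d-%02d", ref$year + 1900 - age,
                            ref$mon + 1, min(ref$mday, 28)))
  anchor - sample.int(364, 1)
}

#' Generate a synthetic cohort
#'
#' Seeded, reproducible sampler for `cohort_spec`: demographics, risk factors
#' (smoking, BMI via weight/height, hypertension with treatment, diabetes,
#' dyslipidemia, family histories with onset ages), one physical exam per
#' person, and a visit/request log produced by screening each person against
#' `ruleset` at each attended year and perturbing the request set with the
#' spec's underuse/overuse error rates. Every record passes
#' [validate_record()].
#'
#' @param spec A [cohort_spec()].
#' @param ruleset Ruleset driving the simulated (error-prone) requisitions;
#'   default is the shipped ruleset.
#' @return List of [person_record()].
#' @export
generate_cohort <- function(spec, ruleset = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(ruleset)) ruleset <- load_ruleset()
  with_seed(spec$seed, {
    n <- spec$n
    sexes <- ifelse(stats::runif(n) < spec$female_fraction, "female", "male")
    ages <- sample_ages(n, spec$age_mean, spec$age_sd,
                        spec$age_min, spec$age_max)
    pv <- spec$prevalences
    pr <- period_range(spec$period)
    years <- seq(as.integer(format(pr$start, "%Y")),
                 as.integer(format(pr$end, "%Y")))
    cohort <- lapply(seq_len(n), function(i) {
      overweight <- stats::runif(1) < pv$bmi_ge25
      height <- round(rtrunc_norm(1, if (sexes[i] == "male") 175 else 162, 7,
                                  145, 200), 1)
      bmi <- if (overweight) rtrunc_norm(1, 28, 2.5, 25, 40)
      else rtrunc_norm(1, 22, 1.8, 17, 24.9)
      hypertensive <- stats::runif(1) < pv$hypertension
      fh <- list()
      add_fh <- function(fh, p, condition, relation, onset_mean) {
        if (stats::runif(1) < p) {
          c(fh, list(list(relation = relation, condition = condition,
                          onset_age = round(rtrunc_norm(1, onset_mean, 8, 25, 85)))))
        } else fh
      }
      fh <- add_fh(fh, pv$fh_diabetes, "diabetes", "mother", 55)
      fh <- add_fh(fh, pv$fh_breast, "breast_cancer", "mother", 52)
      fh <- add_fh(fh, pv$fh_colorectal, "colorectal_cancer", "father", 62)
      fh <- add_fh(fh, pv$fh_premature_chd, "premature_chd", "father", 50)
      fh <- add_fh(fh, pv$fh_prostate, "prostate_cancer", "father", 66)
      diseases <- c(if (hypertensive) "hypertension",
                    if (stats::runif(1) < pv$diabetes) "diabetes",
                    if (stats::runif(1) < pv$dyslipidemia) "dyslipidemia")
      systolic <- round(rtrunc_norm(1, if (hypertensive) 148 else 114, 9, 95, 200))
      diastolic <- round(rtrunc_norm(1, if (hypertensive) 92 else 72, 6, 50,
                                     systolic - 15))
      person_record(
        person_id = sprintf("S%05d", i),
        name = sprintf("Person %d", i),
        birth_date = birth_for_age(ages[i], spec$reference_date),
        sex = sexes[i],
        marital_status = sample(c("single", "married"), 1),
        email = if (stats::runif(1) < 0.8) sprintf("s%05d@example.org", i)
        else NA_character_,
        phone = if (stats::runif(1) < 0.9) sprintf("+98%09d", i) else NA_character_,
        history = medical_history(
          known_diseases = diseases,
          family_history = fh,
          smoking_status = if (stats::runif(1) < pv$smoking) "current" else "never",
          treated_bp = hypertensive),
        exams = list(physical_exam(
          date = pr$start + 14, systolic = systolic, diastolic = diastolic,
          height = height, weight = round(bmi * (height / 100)^2, 1),
          waist = round(rtrunc_norm(1, if (sexes[i] == "male") 94 else 84,
                                    11, 60, 140))))
      )
    })
    # visit log: per attended year, request indicated tests perturbed by the
    # spec's request-error rates
    all_codes <- names(applicable_sexes(ruleset))
    for (i in seq_len(n)) {
      p <- cohort[[i]]
      applicable <- Filter(function(r) r$target_sex %in% c("any", p$sex),
                           ruleset$rules)
      visits <- list()
      for (y in years) {
        if (stats::runif(1) >= spec$attendance_prob) next
        vdate <- as.Date(sprintf("%d-06-15", y)) + sample.int(90, 1)
        vdate <- min(vdate, pr$end)
        indicated <- vapply(applicable, function(rule)
          is_indicated(p, rule, vdate)$indicated, TRUE)
        ind_codes <- vapply(applicable, function(r) r$test_code, "")[indicated]
        keep <- ind_codes[stats::runif(length(ind_codes)) >= spec$underuse_rate]
        extra_pool <- setdiff(
          vapply(applicable, function(r) r$test_code, ""), ind_codes)
        extra <- extra_pool[stats::runif(length(extra_pool)) < spec$overuse_rate]
        visits <- c(visits, list(visit_event(vdate, sort(c(keep, extra)))))
      }
      cohort[[i]]$visits <- visits
    }
    cohort
  })
}

# ---------------------------------------------------------------------------
# Exact tally-matched construction

#' Reference audit marginals bundled with the package
#'
#' The per-test 2x2 marginals of a manual-era screening audit over a 261-person
#' workplace cohort (136 women, 125 men): indicated totals, underused counts,
#' non-indicated totals and overused counts for each screening test. Used by
#' [study_fixture()]; the implied request counts per test are the column sums
#' `indicated_requested + notindicated_requested`.
#'
#' @return Data frame: test_code, indicated_total, indicated_not_requested,
#'   notindicated_total, notindicated_requested.
#' @export
reference_marginals <- function() {
  data.frame(
    test_code = c("FPG", "LIPID_PROFILE", "FOBT", "SIGMOIDOSCOPY_COLONOSCOPY",
                  "PAP_SMEAR", "MAMMOGRAPHY", "PSA", "SKIN_EXAM"),
    indicated_total = c(167, 145, 23, 5, 78, 44, 13, 0),
    indicated_not_requested = c(59, 49, 22, 5, 48, 24, 13, 0),
    notindicated_total = c(94, 116, 238, 256, 58, 92, 112, 261),
    notindicated_requested = c(49, 59, 0, 0, 0, 2, 1, 0),
    stringsAsFactors = FALSE)
}

marg_row <- function(marg, code) {
  i <- match(code, marg$test_code)
  list(itot = marg$indicated_total[i], inr = marg$indicated_not_requested[i],
       ntot = marg$notindicated_total[i], nr = marg$notindicated_requested[i])
}

# One synthetic person for the tally-matched planner. `knobs` toggle
# attributes that force indication of exactly one test each under the default
# ruleset structure.
synth_person <- function(id, sex, age, period,
                         colorectal_fh = FALSE, colorectal_onset = 70,
                         breast_fh = FALSE, prostate_fh = FALSE,
                         fpg_knob = FALSE, lipid_knob = FALSE,
                         skin_knob = FALSE) {
  pr <- period_range(period)
  fh <- list()
  if (colorectal_fh) fh <- c(fh, list(list(relation = "father",
    condition = "colorectal_cancer", onset_age = colorectal_onset)))
  if (breast_fh) fh <- c(fh, list(list(relation = "mother",
    condition = "breast_cancer", onset_age = 45)))
  if (prostate_fh) fh <- c(fh, list(list(relation = "father",
    condition = "prostate_cancer", onset_age = 65)))
  if (fpg_knob) fh <- c(fh, list(list(relation = "mother",
    condition = "diabetes", onset_age = 55)))
  if (lipid_knob) fh <- c(fh, list(list(relation = "father",
    condition = "premature_chd", onset_age = 50)))
  height <- 170
  weight <- if (fpg_knob) 78 else 63   # BMI 27.0 vs 21.8
  person_record(
    person_id = id,
    name = paste("Fixture", id),
    birth_date = birth_for_age_fixed(age, pr$end),
    sex = sex,
    email = sprintf("%s@example.org", tolower(id)),
    phone = sprintf("+98%09d", as.integer(gsub("\\D", "", id))),
    history = medical_history(
      family_history = fh,
      cancer_history = if (skin_knob) list(list(site = "skin", year = 2005))
      else list()),
    exams = list(physical_exam(date = pr$start + 30, systolic = 110,
                               diastolic = 70, height = height,
                               weight = weight, waist = 80))
  )
}

# Deterministic birth date giving exactly `age` completed years at `ref`.
birth_for_age_fixed <- function(age, ref) {
  ref <- as.POSIXlt(as_date(ref))
  as.Date(sprintf("%04d-06-15", ref$year + 1900 - age))
}

#' Construct a cohort whose audit reproduces given marginals exactly
#'
#' Builds person records (ages, family histories, BMI) that force each
#' person's indication status per test under the supplied ruleset, then
#' assigns visit requests to hit every 2x2 cell of `marginals` exactly. The
#' construction is specific to the structure of the shipped default ruleset
#' (neutral host ages plus per-test risk-factor "knobs"); it re-audits its own
#' output with [classify_test_events()] and fails with an error naming the
#' first mismatching cell rather than return an approximate cohort.
#' Infeasible marginals (e.g. more endoscopy-indicated than FOBT-indicated
#' persons, or more young indicated persons than hosts) are reported with the
#' unsatisfiable cell.
#'
#' @param marginals Data frame as [reference_marginals()]; tests absent from
#'   it are unconstrained (their tallies fall where the construction leaves
#'   them and are not checked).
#' @param ruleset Ruleset to audit against (default: shipped ruleset).
#' @param seed Seed for the (exactness-preserving) shuffling of host and
#'   request assignment.
#' @param period Audit period; indication is judged at its end.
#' @return List of [person_record()].
#' @export
generate_tally_matched_cohort <- function(marginals, ruleset = NULL, seed = 1,
                                          period = c("2009-01-01", "2011-12-31")) {
  if (is.null(ruleset)) ruleset <- load_ruleset()
  present <- intersect(test_codes(), marginals$test_code)
  m <- lapply(stats::setNames(nm = present), marg_row, marg = marginals)
  infeasible <- function(cell, why) {
    stop_config("infeasible marginals at ", cell, ": ", why)
  }
  # cohort sizes per sex from the sex-specific tests, else an even split
  size_of <- function(codes) {
    codes <- intersect(codes, present)
    tot <- vapply(codes, function(c) as.integer(m[[c]]$itot + m[[c]]$ntot), 1L)
    tot <- tot[!is.na(tot)]
    if (length(unique(tot)) > 1) {
      infeasible(paste(codes, collapse = "/"),
                 "inconsistent cohort sizes across tests")
    }
    if (length(tot)) tot[[1]] else NA_integer_
  }
  n_f <- size_of(c("PAP_SMEAR", "MAMMOGRAPHY"))
  n_m <- size_of("PSA")
  n_any <- size_of(c("FPG", "LIPID_PROFILE", "FOBT",
                     "SIGMOIDOSCOPY_COLONOSCOPY", "SKIN_EXAM"))
  if (is.na(n_f) && is.na(n_m)) {
    if (is.na(n_any)) return(list())  # no marginals at all: empty cohort
    n_m <- ceiling(n_any / 2)
    n_f <- n_any - n_m
  } else if (is.na(n_f)) {
    n_f <- if (is.na(n_any)) 0L else n_any - n_m
  } else if (is.na(n_m)) {
    n_m <- if (is.na(n_any)) 0L else n_any - n_f
  }
  if (!is.na(n_any) && n_f + n_m != n_any) {
    infeasible("cohort size", sprintf(
      "sex-specific sizes %d + %d do not sum to the any-sex size %d",
      n_f, n_m, n_any))
  }
  if (n_f < 0 || n_m < 0) infeasible("cohort size", "negative sex-specific size")
  rem <- vapply(m, function(x) as.integer(x$itot), 1L)
  rem0 <- function(code) if (code %in% names(rem)) rem[[code]] else 0L
  budget <- function(code) if (code %in% names(rem)) rem[[code]] else Inf

  specs <- list()
  push <- function(s) specs[[length(specs) + 1L]] <<- s
  take <- function(code, k, cell) {
    if (!code %in% names(rem)) return(invisible())  # unconstrained test
    if (rem[[code]] < k) infeasible(cell, sprintf(
      "needs %d more %s-indicated persons than the marginals allow", k, code))
    rem[[code]] <<- rem[[code]] - as.integer(k)
  }
  # --- male structural persons ---------------------------------------------
  sig_m <- min(rem0("SIGMOIDOSCOPY_COLONOSCOPY"), budget("PSA"),
               budget("FOBT"), n_m)
  for (i in seq_len(sig_m)) push(list(sex = "male", age = 50))
  if (sig_m) for (c in c("SIGMOIDOSCOPY_COLONOSCOPY", "PSA", "FOBT", "FPG",
                         "LIPID_PROFILE")) {
    take(c, sig_m, "SIGMOIDOSCOPY_COLONOSCOPY/indicated_total")
  }
  psa_x <- rem0("PSA")
  for (i in seq_len(psa_x)) push(list(sex = "male", age = 45, prostate_fh = TRUE))
  if (psa_x) for (c in c("PSA", "FPG", "LIPID_PROFILE")) {
    take(c, psa_x, "PSA/indicated_total")
  }
  fobt_m <- min(rem0("FOBT"), budget("LIPID_PROFILE"),
                n_m - sig_m - psa_x)
  for (i in seq_len(fobt_m)) push(list(sex = "male", age = 40,
                                       colorectal_fh = TRUE))
  if (fobt_m) for (c in c("FOBT", "LIPID_PROFILE")) {
    take(c, fobt_m, "FOBT/indicated_total")
  }
  n_m_free <- n_m - sig_m - psa_x - fobt_m
  if (n_m_free < 0) infeasible("male cohort size", "structural persons exceed it")
  for (i in seq_len(n_m_free)) push(list(sex = "male", age = 30))
  # --- female structural persons -------------------------------------------
  sig_f <- rem0("SIGMOIDOSCOPY_COLONOSCOPY")
  if (sig_f > 0) {
    # age-66 women: endoscopy window without Pap (stop 66), but mammography
    # and FPG/lipid/FOBT necessarily come along
    for (c in c("SIGMOIDOSCOPY_COLONOSCOPY", "FOBT", "FPG", "LIPID_PROFILE",
                "MAMMOGRAPHY")) {
      take(c, sig_f, "SIGMOIDOSCOPY_COLONOSCOPY/indicated_total")
    }
    for (i in seq_len(sig_f)) push(list(sex = "female", age = 66))
  }
  fobt_f <- rem0("FOBT")
  if (fobt_f > 0) {
    for (c in c("FOBT", "MAMMOGRAPHY", "PAP_SMEAR")) {
      take(c, fobt_f, "FOBT/indicated_total")
    }
    for (i in seq_len(fobt_f)) push(list(sex = "female", age = 40,
                                         colorectal_fh = TRUE))
  }
  mam_x <- rem0("MAMMOGRAPHY")
  if (mam_x > 0) {
    take("PAP_SMEAR", mam_x, "MAMMOGRAPHY/indicated_total")
    take("MAMMOGRAPHY", mam_x, "MAMMOGRAPHY/indicated_total")
    for (i in seq_len(mam_x)) push(list(sex = "female", age = 36,
                                        breast_fh = TRUE))
  }
  pap_x <- rem0("PAP_SMEAR")
  take("PAP_SMEAR", pap_x, "PAP_SMEAR/indicated_total")
  for (i in seq_len(pap_x)) push(list(sex = "female", age = 30))
  n_f_free <- n_f - sig_f - fobt_f - mam_x - pap_x
  if (n_f_free < 0) infeasible("female cohort size", "structural persons exceed it")
  # free women sit below the Pap window only when the Pap tally is
  # constrained; otherwise a host-capable age is used
  age_f_free <- if ("PAP_SMEAR" %in% names(rem)) 20 else 30
  for (i in seq_len(n_f_free)) push(list(sex = "female", age = age_f_free))

  cohort <- with_seed(seed, {
    # --- knob passes for the age-independent tests --------------------------
    assign_knob <- function(specs, code, field, min_age, cell) {
      need <- rem0(code)
      if (need == 0) return(specs)
      hosts <- which(vapply(specs, function(s) {
        s$age >= min_age && !isTRUE(s[[field]]) && !already_indicated(s, code)
      }, TRUE))
      if (length(hosts) < need) infeasible(cell, sprintf(
        "only %d hosts can carry the %s risk factor, %d needed",
        length(hosts), code, need))
      picked <- hosts[sample.int(length(hosts))][seq_len(need)]
      for (i in picked) specs[[i]][[field]] <- TRUE
      rem[[code]] <<- 0L
      specs
    }
    already_indicated <- function(s, code) {
      switch(code,
        FPG = s$age >= 45 || isTRUE(s$fpg_knob),
        LIPID_PROFILE = (s$sex == "male" && s$age >= 35) ||
          (s$sex == "female" && s$age >= 45) || isTRUE(s$lipid_knob),
        SKIN_EXAM = isTRUE(s$skin_knob),
        FALSE)
    }
    specs <- assign_knob(specs, "FPG", "fpg_knob", 25, "FPG/indicated_total")
    specs <- assign_knob(specs, "LIPID_PROFILE", "lipid_knob", 20,
                         "LIPID_PROFILE/indicated_total")
    specs <- assign_knob(specs, "SKIN_EXAM", "skin_knob", 18,
                         "SKIN_EXAM/indicated_total")
    left <- names(rem)[rem > 0]
    if (length(left)) infeasible(paste0(left[1], "/indicated_total"),
                                 "no construction reaches this count")
    cohort <- lapply(seq_along(specs), function(i) {
      do.call(synth_person, c(list(id = sprintf("P%03d", i), period = period),
                              specs[[i]]))
    })
    # --- request assignment per marginal cell -------------------------------
    pr <- period_range(period)
    requests <- vector("list", length(cohort))
    sexes_by_test <- applicable_sexes(ruleset)
    for (code in names(sexes_by_test)) {
      mm <- m[[code]]
      if (is.null(mm)) next  # unconstrained: no requests assigned
      ind <- vapply(cohort, function(p) {
        rules <- Filter(function(r) r$test_code == code &&
                          r$target_sex %in% c("any", p$sex), ruleset$rules)
        length(rules) > 0 &&
          any(vapply(rules, function(r) is_indicated(p, r, pr$end)$indicated,
                     TRUE))
      }, TRUE)
      applicable <- vapply(cohort, function(p) p$sex %in% sexes_by_test[[code]],
                           TRUE)
      shuffle <- function(x) x[sample.int(length(x))]
      ind_idx <- shuffle(which(ind))
      non_idx <- shuffle(which(applicable & !ind))
      n_ind_req <- mm$itot - mm$inr
      if (length(ind_idx) < mm$itot) infeasible(
        paste0(code, "/indicated_total"), "construction fell short")
      for (i in ind_idx[seq_len(n_ind_req)]) requests[[i]] <- c(requests[[i]], code)
      if (length(non_idx) < mm$nr) infeasible(
        paste0(code, "/notindicated_requested"), "not enough non-indicated persons")
      for (i in non_idx[seq_len(mm$nr)]) requests[[i]] <- c(requests[[i]], code)
    }
    for (i in seq_along(cohort)) {
      if (length(requests[[i]])) {
        cohort[[i]]$visits <- list(visit_event(pr$start + 530,
                                               sort(requests[[i]])))
      }
    }
    cohort
  })
  # --- exactness post-check -------------------------------------------------
  tally <- classify_test_events(cohort, ruleset, period)
  for (i in seq_len(nrow(tally))) {
    code <- tally$test_code[i]
    mm <- m[[code]]
    if (is.null(mm)) next  # unconstrained test: not checked
    got <- c(itot = tally$indicated_requested[i] + tally$indicated_not_requested[i],
             inr = tally$indicated_not_requested[i],
             ntot = tally$notindicated_requested[i] +
               tally$notindicated_not_requested[i],
             nr = tally$notindicated_requested[i])
    want <- c(itot = mm$itot, inr = mm$inr, ntot = mm$ntot, nr = mm$nr)
    if (any(got != want)) {
      bad <- names(got)[got != want][1]
      infeasible(paste0(code, "/", bad), sprintf(
        "constructed cohort audits to %d, marginals require %d",
        got[[bad]], want[[bad]]))
    }
  }
  cohort
}

#' Deterministic reference audit fixture
#'
#' A bundled synthetic 261-person cohort (136 women, 125 men) whose manual-era
#' visit log audits to the [reference_marginals()] cell-for-cell, with
#' per-test request counts summing to 366. The cohort, ruleset and period are
#' regenerated on demand (seeded); nothing is stored on disk.
#'
#' @param seed Seed forwarded to [generate_tally_matched_cohort()].
#' @return List with `cohort`, `ruleset`, `period` (2009-01-01 to 2011-12-31).
#' @export
study_fixture <- function(seed = 20120615) {
  ruleset <- load_ruleset()
  period <- c("2009-01-01", "2011-12-31")
  cohort <- generate_tally_matched_cohort(reference_marginals(), ruleset,
                                          seed = seed, period = period)
  list(cohort = cohort, ruleset = ruleset, period = period)
}

#' Software-era request-log fixture
#'
#' The same fixture cohort with a 2012 software-assisted visit log whose
#' per-test request counts are the reference software-era column
#' (156, 85, 12, 5, 40, 26, 10; total 334). Only the counts are constrained;
#' which persons carry the requests is an arbitrary deterministic choice.
#'
#' @param seed Seed forwarded to [study_fixture()].
#' @return List with `cohort`, `ruleset`, `period` (calendar year 2012).
#' @export
software_era_fixture <- function(seed = 20120615) {
  fx <- study_fixture(seed)
  counts <- c(FPG = 156, LIPID_PROFILE = 85, FOBT = 12,
              SIGMOIDOSCOPY_COLONOSCOPY = 5, PAP_SMEAR = 40, MAMMOGRAPHY = 26,
              PSA = 10)
  cohort <- fx$cohort
  vdate <- as.Date("2012-07-15")
  requests <- vector("list", length(cohort))
  sexes <- vapply(cohort, function(p) p$sex, "")
  for (code in names(counts)) {
    ok <- if (code %in% c("PAP_SMEAR", "MAMMOGRAPHY")) which(sexes == "female")
    else if (code == "PSA") which(sexes == "male")
    else seq_along(cohort)
    idx <- ok[seq_len(counts[[code]])]
    for (i in idx) requests[[i]] <- c(requests[[i]], code)
  }
  for (i in seq_along(cohort)) {
    cohort[[i]]$visits <- if (length(requests[[i]])) {
      list(visit_event(vdate, sort(requests[[i]])))
    } else list()
  }
  list(cohort = cohort, ruleset = fx$ruleset,
       period = c("2012-01-01", "2012-12-31"))
}

#' Record software-style screening requests as visits
#'
#' Gives every person one visit at `date` requesting exactly the tests their
#' screening plan indicates - the idealised requisition behaviour of
#' software-assisted screening. Auditing the result against the same ruleset
#' yields zero underuse and zero overuse for every test.
#'
#' @param cohort List of [person_record()].
#' @param plans Matching list of `screening_plan` (e.g. [screen_cohort()]).
#' @param date Visit date.
#' @return The cohort with the visit logs replaced.
#' @export
apply_screening_requests <- function(cohort, plans, date) {
  stopifnot(length(cohort) == length(plans))
  for (i in seq_along(cohort)) {
    indicated <- unlist(lapply(plans[[i]]$recommendations, function(r)
      if (r$indicated) r$test_code))
    cohort[[i]]$visits <- if (length(indicated)) {
      list(visit_event(date, sort(indicated)))
    } else list()
  }
  cohort
}
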