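# The intelligent-recommendation engine: evaluate a declarative ruleset
# against a person record to emit indicated tests with due dates, detected
# conditions, specialist referrals and rendered health messages.

#' Is a screening test indicated for this person?
#'
#' A rule indicates its test when the person's sex matches, any eligibility
#' predicate holds (OR; absent list means unconditionally eligible), and the
#' age in completed years at `as_of` lies in `[start_age, stop_age)`. Fired
#' risk-factor modifiers may lower the start age and/or shorten the interval
#' (the earliest start and the shortest interval win) and are reported in the
#' rationale.
#'
#' @param record A [person_record()].
#' @param rule One rule from a [load_ruleset()] ruleset.
#' @param as_of Evaluation date.
#' @return List: `indicated` (logical), `rationale` (character vector of fired
#'   predicates/conditions), `effective_start_age`, `effective_interval_days`.
#' @export
is_indicated <- function(record, rule, as_of) {
  as_of <- as_date(as_of)
  out <- function(ind, why) list(
    indicated = ind, rationale = why,
    effective_start_age = eff_start, effective_interval_days = eff_interval)
  eff_start <- rule$start_age
  eff_interval <- rule$interval_days
  if (rule$target_sex != "any" && rule$target_sex != record$sex) {
    return(out(FALSE, sprintf("sex mismatch: rule targets %s", rule$target_sex)))
  }
  rationale <- character(0)
  if (length(rule$eligibility_any)) {
    hits <- Filter(function(p) eval_predicate(p, record, as_of),
                   rule$eligibility_any)
    if (!length(hits)) {
      return(out(FALSE, "no eligibility criterion met"))
    }
    rationale <- c(rationale, paste0("eligible: ",
                                     describe_predicate(hits[[1]])))
  }
  for (mod in rule$modifiers) {
    fired <- all(vapply(mod$when, eval_predicate, TRUE,
                        record = record, as_of = as_of))
    if (fired) {
      ms <- modifier_start_age(mod, record)
      if (!is.na(ms)) eff_start <- min(eff_start, ms)
      if (!is.null(mod$interval_days)) {
        eff_interval <- min(eff_interval, mod$interval_days)
      }
      rationale <- c(rationale, paste0(
        "modifier: ", paste(vapply(mod$when, describe_predicate, ""),
                            collapse = " + ")))
    }
  }
  age <- age_years(record$birth_date, as_of)
  in_window <- age >= eff_start && (is.na(rule$stop_age) || age < rule$stop_age)
  rationale <- c(sprintf("age %d vs window [%g, %s)", age, eff_start,
                         ifelse(is.na(rule$stop_age), "Inf", rule$stop_age)),
                 rationale)
  out(in_window, rationale)
}

#' Next due date for a recurring screening test
#'
#' Never-tested persons are due immediately (and overdue); otherwise the test
#' falls due `interval` days after the last result, and is overdue when that
#' date has already passed at `as_of`.
#'
#' @param last_result_date Date of the most recent result, or `NULL`/`NA`.
#' @param interval Interval in days (> 0).
#' @param as_of Evaluation date.
#' @return List with `due_date` (Date) and `overdue` (logical).
#' @export
next_due_date <- function(last_result_date, interval, as_of) {
  if (!isTRUE(interval > 0)) stop_domain("interval must be > 0")
  as_of <- as_date(as_of)
  if (is.null(last_result_date) || all(is.na(last_result_date))) {
    return(list(due_date = as_of, overdue = TRUE))
  }
  due <- as_date(last_result_date) + interval
  list(due_date = due, overdue = due < as_of)
}

# Conditions detected from the latest exam, lipid panel and FPG result.
detect_conditions <- function(record, as_of) {
  exam <- latest_exam(record, as_of)
  lipid <- latest_result(record, "LIPID_PROFILE", as_of)
  panel <- if (!is.null(lipid)) lipid$components else NULL
  fpg_res <- latest_result(record, "FPG", as_of)
  fpg <- if (!is.null(fpg_res)) fpg_res$numeric_value else NA_real_
  treated <- record$history$treated_bp
  conditions <- character(0)
  if (is.null(exam) && is.null(panel) && is.na(fpg)) {
    return(list(conditions = conditions, evaluable = FALSE))
  }
  if (!is.null(exam)) {
    bp <- categorize_bp(exam$systolic, exam$diastolic)
    if (bp$label != "normal") conditions <- c(conditions, paste0("bp_", bp$label))
    if (detect_abdominal_obesity(exam$waist, record$sex)) {
      conditions <- c(conditions, "abdominal_obesity")
    }
  }
  if (!is.na(fpg)) {
    cat_fpg <- categorize_fpg(fpg)$category
    if (cat_fpg == "impaired_fasting_glucose") {
      conditions <- c(conditions, "impaired_fasting_glucose")
    } else if (cat_fpg == "diabetic_range") {
      conditions <- c(conditions, "diabetic_range_fpg")
    }
  }
  if (!is.null(panel)) {
    lc <- categorize_lipids(panel, record$sex)
    bands <- unlist(lc[c("total_cholesterol", "ldl", "triglycerides")])
    if (any(bands == "high", na.rm = TRUE)) {
      conditions <- c(conditions, "high_lipids")
    } else if (any(bands == "borderline", na.rm = TRUE) || isTRUE(lc$low_hdl)) {
      conditions <- c(conditions, "borderline_lipids")
    }
    ms <- detect_metabolic_syndrome(exam, panel, fpg, record$sex, treated)
    if (ms$positive) conditions <- c(conditions, "metabolic_syndrome")
  }
  if (!is.null(exam) && !is.null(panel) &&
      !is.null(panel$total_cholesterol) && !is.null(panel$hdl)) {
    age <- age_years(record$birth_date, as_of)
    if (age >= 20 && age <= 79) {
      fr <- framingham_risk(age, record$sex, panel$total_cholesterol,
                            panel$hdl, exam$systolic, treated,
                            identical(record$history$smoking_status, "current"))
      conditions <- c(conditions, paste0("framingham_", fr$category))
    }
  }
  list(conditions = conditions, evaluable = TRUE)
}

render_template <- function(id, template, vars) {
  for (k in names(vars)) {
    if (is.null(vars[[k]]) || is.na(vars[[k]])) next
    template <- gsub(paste0("{", k, "}"), vars[[k]], template, fixed = TRUE)
  }
  leftover <- regmatches(template, regexpr("\\{[a-zA-Z_]+\\}", template))
  if (length(leftover) && nzchar(leftover)) {
    stop_config(sprintf("message '%s': unknown placeholder %s", id, leftover))
  }
  template
}

#' Evaluate a ruleset against one person record
#'
#' Produces the screening plan: one recommendation per sex-applicable rule
#' (ordered by test code), each with indication, rationale, due date and
#' overdue flag, specialist referral and rendered messages; plus conditions
#' detected by the clinical calculators from the most recent exam, lipid panel
#' and fasting-glucose result, and a deduplicated referral list. A record with
#' no exam or results still yields a plan, with conditions marked not
#' evaluable.
#'
#' @param record A validated [person_record()].
#' @param ruleset A [load_ruleset()] ruleset.
#' @param as_of Evaluation date.
#' @return A `screening_plan`: `person_id`, `as_of`, `recommendations`,
#'   `detected_conditions`, `conditions_evaluable`, `referrals`, `channels`,
#'   `messages`.
#' @export
evaluate_rules <- function(record, ruleset, as_of) {
  as_of <- as_date(as_of)
  applicable <- Filter(function(r) r$target_sex %in% c("any", record$sex),
                       ruleset$rules)
  ord <- order(vapply(applicable, function(r) r$test_code, ""))
  applicable <- applicable[ord]
  vars_base <- list(name = if (nzchar(record$name)) record$name else record$person_id)
  recs <- lapply(applicable, function(rule) {
    ind <- is_indicated(record, rule, as_of)
    rec <- list(test_code = rule$test_code, indicated = ind$indicated,
                rationale = ind$rationale, due_date = as.Date(NA),
                overdue = FALSE, referral_specialty = NA_character_,
                messages = character(0))
    if (ind$indicated) {
      last <- latest_result(record, rule$test_code, as_of)
      due <- next_due_date(if (is.null(last)) NULL else last$date,
                           ind$effective_interval_days, as_of)
      rec$due_date <- due$due_date
      rec$overdue <- due$overdue
      rec$referral_specialty <- rule$referral_specialty
      vars <- c(vars_base, list(test_code = rule$test_code,
                                due_date = format(due$due_date),
                                specialty = rule$referral_specialty))
      rec$messages <- vapply(rule$messages, function(id) render_template(
        id, ruleset$message_catalog[[id]], vars), "")
    }
    rec
  })
  det <- detect_conditions(record, as_of)
  referrals <- c(
    unlist(lapply(recs, function(r) if (r$indicated) r$referral_specialty)),
    unlist(ruleset$condition_referrals[det$conditions])
  )
  referrals <- sort(unique(referrals[!is.na(referrals)]))
  plan <- structure(list(
    person_id = record$person_id,
    as_of = as_of,
    recommendations = recs,
    detected_conditions = det$conditions,
    conditions_evaluable = det$evaluable,
    referrals = referrals,
    channels = c(if (!is.na(record$email) && nzchar(record$email)) "email",
                 if (!is.na(record$phone) && nzchar(record$phone)) "sms")
  ), class = "screening_plan")
  plan$messages <- render_messages(plan, ruleset$message_catalog,
                                   name = vars_base$name)
  plan
}

#' Render the message set for a screening plan
#'
#' General messages (catalog ids prefixed `general_`) are always present;
#' every indicated recommendation contributes its disease-specific messages.
#'
#' @param plan A `screening_plan`.
#' @param catalog Message catalog (id -> template) from the ruleset.
#' @param name Display name substituted into `{name}` placeholders.
#' @return Character vector of rendered messages.
#' @export
render_messages <- function(plan, catalog, name = plan$person_id) {
  general_ids <- grep("^general_", names(catalog), value = TRUE)
  vars <- list(name = name, as_of = format(plan$as_of))
  general <- vapply(general_ids, function(id)
    render_template(id, catalog[[id]], vars), "")
  specific <- unlist(lapply(plan$recommendations, function(r)
    if (r$indicated) r$messages else character(0)))
  c(unname(general), unname(specific %||% character(0)))
}

#' @export
print.screening_plan <- function(x, ...) {
  cat(sprintf("Screening plan for %s as of %s\n", x$person_id, format(x$as_of)))
  for (r in x$recommendations) {
    if (r$indicated) {
      cat(sprintf("  [x] %-26s due %s%s\n", r$test_code, format(r$due_date),
                  if (r$overdue) " (overdue)" else ""))
    } else {
      cat(sprintf("  [ ] %-26s not indicated\n", r$test_code))
    }
  }
  if (length(x$detected_conditions)) {
    cat("  conditions:", paste(x$detected_conditions, collapse = ", "), "\n")
  } else if (!x$conditions_evaluable) {
    cat("  conditions: not evaluable (no exam or results)\n")
  }
  if (length(x$referrals)) {
    cat("  referrals:", paste(x$referrals, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Screen a whole cohort
#'
#' Convenience wrapper applying [evaluate_rules()] to every record.
#'
#' @param cohort List of [person_record()].
#' @param ruleset A ruleset. @param as_of Evaluation date.
#' @return List of `screening_plan`, one per person, in cohort order.
#' @export
screen_cohort <- function(cohort, ruleset, as_of) {
  lapply(cohort, evaluate_rules, ruleset = ruleset, as_of = as_of)
}
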