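# Declarative screening ruleset: loading, schema validation and the closed
# predicate vocabulary evaluated against person records. No code in config:
# predicates are named data, so a ruleset can be audited cell by cell.

PREDICATE_NAMES <- c("bmi_ge", "bp_ge", "smoker", "known_disease",
                     "family_history", "cancer_history")

#' Load and validate a screening ruleset
#'
#' Reads a YAML (or JSON) ruleset and checks it against the schema: known test
#' codes and sexes, positive intervals (including modifier intervals),
#' `start_age < stop_age`, at most one rule per (test_code, sex) with `any`
#' conflicting with both sexes, a closed predicate vocabulary, and every
#' message id resolvable in the message catalog.
#'
#' @param path Path to a ruleset file; `NULL` loads the package default
#'   (editable circa-2012 adult screening defaults).
#' @return A `ruleset` object: `version`, `rules` (each with canonicalised
#'   fields), `message_catalog`, `condition_referrals`.
#' @export
load_ruleset <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_ruleset.yaml",
                        package = "smartscreen")
  }
  if (!file.exists(path)) stop_config("no such ruleset file: ", path)
  raw <- tryCatch(
    if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = FALSE)
    else yaml::read_yaml(path),
    error = function(e) stop_config("ruleset parse failure: ", conditionMessage(e)))
  catalog <- raw$message_catalog %||% list()
  rules <- lapply(seq_along(raw$rules %||% list()), function(i) {
    canonicalise_rule(raw$rules[[i]], i, catalog)
  })
  # uniqueness per (test_code, sex); 'any' overlaps both sexes
  seen <- list(male = character(0), female = character(0))
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    sexes <- if (r$target_sex == "any") c("male", "female") else r$target_sex
    for (s in sexes) {
      if (r$test_code %in% seen[[s]]) {
        stop_config(sprintf(
          "rule %d: more than one rule applies to (%s, %s)", i, r$test_code, s))
      }
      seen[[s]] <- c(seen[[s]], r$test_code)
    }
  }
  structure(list(version = raw$version %||% "unversioned",
                 rules = rules,
                 message_catalog = catalog,
                 condition_referrals = raw$condition_referrals %||% list()),
            class = "ruleset")
}

canonicalise_rule <- function(r, i, catalog) {
  fail <- function(field, msg) {
    stop_config(sprintf("rule %d (%s), field '%s': %s",
                        i, r$test_code %||% "?", field, msg))
  }
  if (is.null(r$test_code) || !(r$test_code %in% test_codes())) {
    fail("test_code", "missing or unknown test code")
  }
  sex <- r$target_sex %||% "any"
  if (!sex %in% c("male", "female", "any")) fail("target_sex", "must be male/female/any")
  start_age <- r$start_age
  if (is.null(start_age) || !is.numeric(start_age) || start_age < 0) {
    fail("start_age", "must be a non-negative number")
  }
  stop_age <- r$stop_age
  if (!is.null(stop_age) && !(is.numeric(stop_age) && start_age < stop_age)) {
    fail("stop_age", "must exceed start_age when present")
  }
  interval <- r$interval_days
  if (is.null(interval) || !is.numeric(interval) || interval <= 0) {
    fail("interval_days", "must be > 0")
  }
  check_predicate <- function(p, where) {
    if (is.null(p$name) || !(p$name %in% PREDICATE_NAMES)) {
      fail(where, sprintf("unknown predicate '%s'", p$name %||% "<missing>"))
    }
    needed <- switch(p$name,
                     bmi_ge = "value", bp_ge = c("systolic", "diastolic"),
                     known_disease = "code", cancer_history = "site",
                     family_history = "condition", character(0))
    for (k in needed) {
      if (is.null(p[[k]])) fail(where, sprintf("predicate %s needs '%s'", p$name, k))
    }
    p
  }
  modifiers <- lapply(seq_along(r$modifiers %||% list()), function(j) {
    m <- r$modifiers[[j]]
    where <- sprintf("modifiers[%d]", j)
    if (is.null(m$when) || !length(m$when)) fail(where, "needs a 'when' predicate list")
    if (!is.null(m$interval_days) && !(is.numeric(m$interval_days) && m$interval_days > 0)) {
      fail(where, "modifier interval_days must be > 0")
    }
    if (is.null(m[["start_age"]]) && is.null(m[["interval_days"]]) &&
        is.null(m[["start_age_rule"]])) {
      fail(where, "modifier must override start_age, interval_days or start_age_rule")
    }
    list(when = lapply(m$when, check_predicate, where = where),
         start_age = m[["start_age"]],
         start_age_rule = m[["start_age_rule"]],
         interval_days = m[["interval_days"]])
  })
  eligibility <- lapply(seq_along(r$eligibility_any %||% list()), function(j) {
    check_predicate(r$eligibility_any[[j]], sprintf("eligibility_any[%d]", j))
  })
  messages <- unlist(r$messages %||% list())
  unresolved <- setdiff(messages, names(catalog))
  if (length(unresolved)) {
    fail("messages", sprintf("unresolvable message id '%s'", unresolved[1]))
  }
  list(test_code = r$test_code, target_sex = sex,
       start_age = as.numeric(start_age),
       stop_age = if (is.null(stop_age)) NA_real_ else as.numeric(stop_age),
       interval_days = as.numeric(interval),
       modifiers = modifiers,
       eligibility_any = eligibility,
       referral_specialty = r$referral_specialty %||% NA_character_,
       messages = as.character(messages))
}

#' @export
print.ruleset <- function(x, ...) {
  cat(sprintf("<ruleset %s: %d rules, %d message templates>\n",
              x$version, length(x$rules), length(x$message_catalog)))
  for (r in x$rules) {
    cat(sprintf("  %-26s %-6s age %g%s every %g d, %d modifier(s)\n",
                r$test_code, r$target_sex, r$start_age,
                if (is.na(r$stop_age)) "+" else paste0("-", r$stop_age - 1),
                r$interval_days, length(r$modifiers)))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Predicate evaluation against a person record at a date

latest_exam <- function(record, as_of) {
  dates <- vapply(record$exams, function(e) as.numeric(e$date), 0)
  keep <- which(dates <= as.numeric(as_date(as_of)))
  if (!length(keep)) return(NULL)
  record$exams[[keep[which.max(dates[keep])]]]
}

latest_result <- function(record, test_code, as_of) {
  hits <- Filter(function(r) r$test_code == test_code &&
                   r$date <= as_date(as_of), record$results)
  if (!length(hits)) return(NULL)
  hits[[which.max(vapply(hits, function(r) as.numeric(r$date), 0))]]
}

# Evaluate one named predicate; returns TRUE/FALSE (never NA).
eval_predicate <- function(pred, record, as_of) {
  h <- record$history
  switch(pred$name,
    smoker = identical(h$smoking_status, "current"),
    known_disease = pred$code %in% h$known_diseases,
    cancer_history = any(vapply(h$cancer_history,
                                function(c) identical(c$site, pred$site), TRUE)),
    family_history = {
      hits <- Filter(function(fh) {
        ok <- identical(fh$condition, pred$condition)
        if (ok && identical(pred$degree %||% "any", "first")) {
          ok <- fh$relation %in% FIRST_DEGREE_RELATIONS
        }
        if (ok && !is.null(pred$max_onset_age)) {
          ok <- !is.na(fh$onset_age) && fh$onset_age <= pred$max_onset_age
        }
        ok
      }, h$family_history)
      length(hits) > 0
    },
    bmi_ge = {
      e <- latest_exam(record, as_of)
      !is.null(e) && compute_bmi(e$weight, e$height)$value >= pred$value
    },
    bp_ge = {
      e <- latest_exam(record, as_of)
      !is.null(e) && (e$systolic >= pred$systolic || e$diastolic >= pred$diastolic)
    },
    stop_config("unknown predicate '", pred$name, "'")
  )
}

describe_predicate <- function(pred) {
  switch(pred$name,
    smoker = "current smoker",
    known_disease = paste0("known disease: ", pred$code),
    cancer_history = paste0("personal cancer history: ", pred$site),
    family_history = paste0(
      if (identical(pred$degree %||% "any", "first")) "first-degree " else "",
      "family history: ", pred$condition,
      if (!is.null(pred$max_onset_age)) paste0(" (onset <= ", pred$max_onset_age, ")")
      else ""),
    bmi_ge = paste0("BMI >= ", pred$value),
    bp_ge = paste0("BP >= ", pred$systolic, "/", pred$diastolic),
    pred$name)
}

# Earliest start-age a fired modifier grants; onset-based rules look up the
# youngest qualifying relative's onset age.
modifier_start_age <- function(mod, record) {
  if (!is.null(mod[["start_age"]])) return(as.numeric(mod[["start_age"]]))
  if (!is.null(mod[["start_age_rule"]])) {
    rule <- mod$start_age_rule
    fam <- mod$when[[which(vapply(mod$when, function(p)
      p$name == "family_history", TRUE))[1]]]
    onsets <- vapply(Filter(function(fh) identical(fh$condition, fam$condition) &&
                              !is.na(fh$onset_age),
                            record$history$family_history),
                     function(fh) fh$onset_age, 0)
    if (!length(onsets)) return(NA_real_)
    max(rule$floor %||% 0, min(onsets) - rule$onset_minus)
  } else {
    NA_real_
  }
}
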