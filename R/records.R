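# Data model for screenable individuals and cohorts, with CSV/JSON
# readers/writers and total (non-throwing) validation.
#
# File conventions:
#  * JSON: one nested document, an array of person objects.
#  * CSV: a normalised set of four files in one directory, keyed by person_id:
#    persons.csv, exams.csv, results.csv, visits.csv. List-valued cells are
#    pipe-delimited; structured items use ':' (family history, cancer history)
#    or '=' (lipid components) as the inner separator.
# Dates are ISO-8601 (YYYY-MM-DD) strings in files, Date objects in memory.

FIRST_DEGREE_RELATIONS <- c("mother", "father", "sibling", "child")
RELATION_VOCAB <- c(FIRST_DEGREE_RELATIONS,
                    "grandparent", "aunt_uncle", "cousin", "other")
SMOKING_LEVELS <- c("never", "former", "current")

#' Construct a medical history
#'
#' @param known_diseases Character vector of coded conditions (e.g.
#'   "hypertension", "diabetes").
#' @param cancer_history List of `list(site =, year =)` entries for the
#'   person's own cancer history.
#' @param family_history List of `list(relation =, condition =, onset_age =)`
#'   entries; `relation` comes from a fixed vocabulary in which first-degree
#'   relatives (mother, father, sibling, child) are distinguishable;
#'   `onset_age` may be `NA`.
#' @param smoking_status One of "never", "former", "current".
#' @param pack_years Optional non-negative pack-years (NA if unknown).
#' @param medications Character vector of medication codes.
#' @param treated_bp Logical; on antihypertensive treatment.
#' @return A `medical_history` list.
#' @export
medical_history <- function(known_diseases = character(0),
                            cancer_history = list(),
                            family_history = list(),
                            smoking_status = "never",
                            pack_years = NA_real_,
                            medications = character(0),
                            treated_bp = FALSE) {
  structure(list(
    known_diseases = as.character(known_diseases),
    cancer_history = cancer_history,
    family_history = family_history,
    smoking_status = smoking_status,
    pack_years = as.numeric(pack_years),
    medications = as.character(medications),
    treated_bp = isTRUE(treated_bp)
  ), class = "medical_history")
}

#' Construct a physical examination record
#'
#' @param date Exam date (Date or ISO string).
#' @param systolic,diastolic Blood pressure in mmHg (systolic > diastolic > 0).
#' @param height Height in cm. @param weight Weight in kg.
#' @param waist Waist circumference in cm.
#' @param other_findings Character vector of coded findings.
#' @return A `physical_exam` list.
#' @export
physical_exam <- function(date, systolic, diastolic, height, weight, waist,
                          other_findings = character(0)) {
  structure(list(
    date = as_date(date),
    systolic = as.numeric(systolic),
    diastolic = as.numeric(diastolic),
    height = as.numeric(height),
    weight = as.numeric(weight),
    waist = as.numeric(waist),
    other_findings = as.character(other_findings)
  ), class = "physical_exam")
}

#' Construct a screening test result
#'
#' At least one of `numeric_value`, `components`, `text_report` must be
#' present. Lipid panels carry their four analytes in `components`
#' (total_cholesterol, hdl, ldl, triglycerides, mg/dL).
#'
#' @param test_code One of [test_codes()].
#' @param date Result date.
#' @param numeric_value Optional numeric value. @param units Optional units.
#' @param components Optional named numeric list (lipid panel analytes).
#' @param text_report Optional free-text report.
#' @return A `test_result` list.
#' @export
test_result <- function(test_code, date, numeric_value = NA_real_,
                        units = NA_character_, components = NULL,
                        text_report = NA_character_) {
  structure(list(
    test_code = test_code,
    date = as_date(date),
    numeric_value = as.numeric(numeric_value),
    units = as.character(units),
    components = components,
    text_report = as.character(text_report)
  ), class = "test_result")
}

#' Construct a visit/test-request event
#'
#' One dated entry in the requisition log: which screening tests were
#' requested at that visit (possibly none).
#'
#' @param date Visit date.
#' @param tests_requested Character vector of test codes requested.
#' @return A `visit_event` list.
#' @export
visit_event <- function(date, tests_requested = character(0)) {
  structure(list(
    date = as_date(date),
    tests_requested = as.character(tests_requested)
  ), class = "visit_event")
}

#' Construct a person record
#'
#' One screenable individual: identity, demographics, medical history,
#' physical exams, screening test results and the visit/request log.
#' `person_id` is treated as an opaque client-unique string (a national
#' identification code in the original registry design).
#'
#' @param person_id Non-empty identifier, unique within a cohort.
#' @param birth_date Date of birth.
#' @param sex "male" or "female".
#' @param name Display name.
#' @param marital_status Free enum string (e.g. "single", "married").
#' @param email,phone Optional contact points; a missing contact disables the
#'   corresponding reminder channel but never blocks screening.
#' @param history A [medical_history()].
#' @param exams List of [physical_exam()].
#' @param results List of [test_result()].
#' @param visits List of [visit_event()].
#' @return A `person_record`.
#' @export
person_record <- function(person_id, birth_date, sex, name = "",
                          marital_status = "unknown",
                          email = NA_character_, phone = NA_character_,
                          history = medical_history(), exams = list(),
                          results = list(), visits = list()) {
  structure(list(
    person_id = as.character(person_id),
    name = as.character(name),
    birth_date = as_date(birth_date),
    sex = sex,
    marital_status = as.character(marital_status),
    email = as.character(email),
    phone = as.character(phone),
    history = history,
    exams = exams,
    results = results,
    visits = visits
  ), class = "person_record")
}

#' @export
print.person_record <- function(x, ...) {
  cat(sprintf("<person_record %s: %s, born %s, %d exams, %d results, %d visits>\n",
              x$person_id, x$sex, format(x$birth_date),
              length(x$exams), length(x$results), length(x$visits)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Validation (total: all problems surface as findings, nothing throws)

finding <- function(person_id, field, message) {
  data.frame(person_id = person_id, field = field, message = message,
             stringsAsFactors = FALSE)
}

no_findings <- function() {
  data.frame(person_id = character(0), field = character(0),
             message = character(0), stringsAsFactors = FALSE)
}

#' Validate a person record
#'
#' Checks every type invariant of the record and returns the problems found
#' as data, never raising: non-empty id, known sex and smoking level,
#' blood-pressure ordering and positive anthropometry per exam, presence of a
#' value in each test result, known test codes and family relations,
#' non-negative pack-years, birth date strictly before every dated entry, and
#' no duplicated visit dates.
#'
#' @param record A [person_record()].
#' @return A data frame of findings (person_id, field, message); zero rows
#'   if and only if the record is valid.
#' @export
validate_record <- function(record) {
  f <- no_findings()
  id <- record$person_id %||% NA_character_
  if (is.na(id) || !nzchar(id)) {
    f <- rbind(f, finding(id, "person_id", "person_id must be non-empty"))
    id <- "<missing>"
  }
  if (!record$sex %in% c("male", "female")) {
    f <- rbind(f, finding(id, "sex", sprintf("unknown sex '%s'", record$sex)))
  }
  if (is.na(record$birth_date)) {
    f <- rbind(f, finding(id, "birth_date", "birth_date missing or unparseable"))
  }
  h <- record$history
  if (!h$smoking_status %in% SMOKING_LEVELS) {
    f <- rbind(f, finding(id, "history.smoking_status",
                          sprintf("unknown smoking status '%s'", h$smoking_status)))
  }
  if (!is.na(h$pack_years) && h$pack_years < 0) {
    f <- rbind(f, finding(id, "history.pack_years", "pack_years must be >= 0"))
  }
  for (fh in h$family_history) {
    if (!(fh$relation %in% RELATION_VOCAB)) {
      f <- rbind(f, finding(id, "history.family_history",
                            sprintf("unknown relation '%s'", fh$relation)))
    }
  }
  chrono <- function(what, i, date) {
    if (!is.na(record$birth_date) && !is.na(date) && date <= record$birth_date) {
      finding(id, sprintf("%s[%d].date", what, i),
              sprintf("%s date %s does not follow birth_date %s",
                      what, format(date), format(record$birth_date)))
    } else no_findings()
  }
  for (i in seq_along(record$exams)) {
    e <- record$exams[[i]]
    if (!(e$systolic > e$diastolic && e$diastolic > 0)) {
      f <- rbind(f, finding(id, sprintf("exams[%d].blood_pressure", i),
                            sprintf("requires systolic > diastolic > 0, got %s/%s",
                                    e$systolic, e$diastolic)))
    }
    for (dim in c("height", "weight", "waist")) {
      if (!(isTRUE(e[[dim]] > 0))) {
        f <- rbind(f, finding(id, sprintf("exams[%d].%s", i, dim),
                              sprintf("%s must be > 0", dim)))
      }
    }
    f <- rbind(f, chrono("exams", i, e$date))
  }
  for (i in seq_along(record$results)) {
    r <- record$results[[i]]
    if (!r$test_code %in% test_codes()) {
      f <- rbind(f, finding(id, sprintf("results[%d].test_code", i),
                            sprintf("unknown test_code '%s'", r$test_code)))
    }
    has_value <- !is.na(r$numeric_value) || !is.null(r$components) ||
      (!is.na(r$text_report) && nzchar(r$text_report))
    if (!has_value) {
      f <- rbind(f, finding(id, sprintf("results[%d]", i),
                            "result needs numeric_value, components or text_report"))
    }
    f <- rbind(f, chrono("results", i, r$date))
  }
  vdates <- as.Date(vapply(record$visits, function(v) format(v$date), ""),
                    format = "%Y-%m-%d")
  if (anyDuplicated(vdates)) {
    f <- rbind(f, finding(id, "visits", "visit dates must be distinct"))
  }
  for (i in seq_along(record$visits)) {
    v <- record$visits[[i]]
    bad <- setdiff(v$tests_requested, test_codes())
    if (length(bad)) {
      f <- rbind(f, finding(id, sprintf("visits[%d].tests_requested", i),
                            sprintf("unknown test_code '%s'", bad[1])))
    }
    f <- rbind(f, chrono("visits", i, v$date))
  }
  f
}

#' Validate a whole cohort
#'
#' Runs [validate_record()] on every record and additionally checks that
#' `person_id` is unique across the cohort.
#'
#' @param cohort List of [person_record()].
#' @return Findings data frame (zero rows iff valid).
#' @export
validate_cohort <- function(cohort) {
  f <- do.call(rbind, c(list(no_findings()), lapply(cohort, validate_record)))
  ids <- vapply(cohort, function(p) p$person_id, "")
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) {
    f <- rbind(f, finding(d, "person_id", sprintf("duplicated person_id '%s'", d)))
  }
  f
}

# ---------------------------------------------------------------------------
# JSON I/O

person_to_plain <- function(p) {
  list(
    person_id = p$person_id, name = p$name,
    birth_date = format(p$birth_date), sex = p$sex,
    marital_status = p$marital_status,
    email = p$email, phone = p$phone,
    history = list(
      known_diseases = as.list(p$history$known_diseases),
      cancer_history = lapply(p$history$cancer_history, function(ch)
        list(site = ch$site, year = ch$year)),
      family_history = lapply(p$history$family_history, function(fh)
        list(relation = fh$relation, condition = fh$condition,
             onset_age = fh$onset_age)),
      smoking_status = p$history$smoking_status,
      pack_years = p$history$pack_years,
      medications = as.list(p$history$medications),
      treated_bp = p$history$treated_bp
    ),
    exams = lapply(p$exams, function(e) list(
      date = format(e$date), systolic = e$systolic, diastolic = e$diastolic,
      height = e$height, weight = e$weight, waist = e$waist,
      other_findings = as.list(e$other_findings))),
    results = lapply(p$results, function(r) list(
      test_code = r$test_code, date = format(r$date),
      numeric_value = r$numeric_value, units = r$units,
      components = r$components, text_report = r$text_report)),
    visits = lapply(p$visits, function(v) list(
      date = format(v$date), tests_requested = as.list(v$tests_requested)))
  )
}

null_na <- function(x, mode = "character") {
  if (is.null(x) || length(x) == 0 || (length(x) == 1 && is.na(x))) {
    return(switch(mode, character = NA_character_, numeric = NA_real_))
  }
  if (mode == "numeric") as.numeric(x) else as.character(x)
}

person_from_plain <- function(x) {
  h <- x$history %||% list()
  person_record(
    person_id = x$person_id,
    name = x$name %||% "",
    birth_date = x$birth_date,
    sex = x$sex,
    marital_status = x$marital_status %||% "unknown",
    email = null_na(x$email), phone = null_na(x$phone),
    history = medical_history(
      known_diseases = unlist(h$known_diseases) %||% character(0),
      cancer_history = lapply(h$cancer_history %||% list(), function(ch)
        list(site = ch$site, year = as.numeric(ch$year))),
      family_history = lapply(h$family_history %||% list(), function(fh)
        list(relation = fh$relation, condition = fh$condition,
             onset_age = null_na(fh$onset_age, "numeric"))),
      smoking_status = h$smoking_status %||% "never",
      pack_years = null_na(h$pack_years, "numeric"),
      medications = unlist(h$medications) %||% character(0),
      treated_bp = isTRUE(h$treated_bp)
    ),
    exams = lapply(x$exams %||% list(), function(e) physical_exam(
      date = e$date, systolic = e$systolic, diastolic = e$diastolic,
      height = e$height, weight = e$weight, waist = e$waist,
      other_findings = unlist(e$other_findings) %||% character(0))),
    results = lapply(x$results %||% list(), function(r) test_result(
      test_code = r$test_code, date = r$date,
      numeric_value = null_na(r$numeric_value, "numeric"),
      units = null_na(r$units),
      components = if (is.null(r$components) || !length(r$components)) NULL
                   else lapply(r$components, as.numeric),
      text_report = null_na(r$text_report))),
    visits = lapply(x$visits %||% list(), function(v) visit_event(
      date = v$date, tests_requested = unlist(v$tests_requested) %||% character(0)))
  )
}

# ---------------------------------------------------------------------------
# CSV I/O (normalised four-file set in one directory)

pack_family <- function(fh) {
  pack_list(vapply(fh, function(x) paste(x$relation, x$condition,
    ifelse(is.na(x$onset_age), "", x$onset_age), sep = ":"), ""))
}

unpack_family <- function(cell) {
  lapply(unpack_list(cell), function(s) {
    parts <- strsplit(s, ":", fixed = TRUE)[[1]]
    list(relation = parts[1], condition = parts[2],
         onset_age = if (length(parts) < 3 || !nzchar(parts[3])) NA_real_
                     else as.numeric(parts[3]))
  })
}

pack_cancer <- function(ch) {
  pack_list(vapply(ch, function(x) paste(x$site, x$year, sep = ":"), ""))
}

unpack_cancer <- function(cell) {
  lapply(unpack_list(cell), function(s) {
    parts <- strsplit(s, ":", fixed = TRUE)[[1]]
    list(site = parts[1], year = as.numeric(parts[2]))
  })
}

pack_components <- function(cmp) {
  if (is.null(cmp)) return("")
  pack_list(paste0(names(cmp), "=", unlist(cmp)))
}

unpack_components <- function(cell) {
  items <- unpack_list(cell)
  if (!length(items)) return(NULL)
  kv <- strsplit(items, "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(p) as.numeric(p[2])),
                  vapply(kv, `[`, "", 1))
}

cohort_to_csv_frames <- function(cohort) {
  persons <- do.call(rbind, lapply(cohort, function(p) data.frame(
    person_id = p$person_id, name = p$name, birth_date = format(p$birth_date),
    sex = p$sex, marital_status = p$marital_status,
    email = p$email, phone = p$phone,
    smoking_status = p$history$smoking_status,
    pack_years = p$history$pack_years,
    known_diseases = pack_list(p$history$known_diseases),
    cancer_history = pack_cancer(p$history$cancer_history),
    family_history = pack_family(p$history$family_history),
    medications = pack_list(p$history$medications),
    treated_bp = p$history$treated_bp,
    stringsAsFactors = FALSE)))
  rows <- function(get, build) do.call(rbind, c(
    list(NULL), lapply(cohort, function(p) {
      items <- get(p)
      if (!length(items)) return(NULL)
      do.call(rbind, lapply(items, function(it) build(p$person_id, it)))
    })))
  exams <- rows(function(p) p$exams, function(id, e) data.frame(
    person_id = id, date = format(e$date), systolic = e$systolic,
    diastolic = e$diastolic, height = e$height, weight = e$weight,
    waist = e$waist, other_findings = pack_list(e$other_findings),
    stringsAsFactors = FALSE))
  results <- rows(function(p) p$results, function(id, r) data.frame(
    person_id = id, test_code = r$test_code, date = format(r$date),
    numeric_value = r$numeric_value, units = r$units,
    components = pack_components(r$components), text_report = r$text_report,
    stringsAsFactors = FALSE))
  visits <- rows(function(p) p$visits, function(id, v) data.frame(
    person_id = id, date = format(v$date),
    tests_requested = pack_list(v$tests_requested), stringsAsFactors = FALSE))
  empty <- function(cols) as.data.frame(
    stats::setNames(rep(list(character(0)), length(cols)), cols))
  list(
    persons = persons %||% empty(c("person_id", "name", "birth_date", "sex",
      "marital_status", "email", "phone", "smoking_status", "pack_years",
      "known_diseases", "cancer_history", "family_history", "medications",
      "treated_bp")),
    exams = exams %||% empty(c("person_id", "date", "systolic", "diastolic",
      "height", "weight", "waist", "other_findings")),
    results = results %||% empty(c("person_id", "test_code", "date",
      "numeric_value", "units", "components", "text_report")),
    visits = visits %||% empty(c("person_id", "date", "tests_requested"))
  )
}

csv_frames_to_cohort <- function(fr) {
  str_or_na <- function(x) ifelse(is.na(x), NA_character_, as.character(x))
  lapply(seq_len(nrow(fr$persons)), function(i) {
    row <- fr$persons[i, ]
    id <- as.character(row$person_id)
    ex <- fr$exams[fr$exams$person_id == id, , drop = FALSE]
    re <- fr$results[fr$results$person_id == id, , drop = FALSE]
    vi <- fr$visits[fr$visits$person_id == id, , drop = FALSE]
    person_record(
      person_id = id, name = str_or_na(row$name) %||% "",
      birth_date = row$birth_date, sex = as.character(row$sex),
      marital_status = as.character(row$marital_status),
      email = str_or_na(row$email), phone = str_or_na(row$phone),
      history = medical_history(
        known_diseases = unpack_list(as.character(row$known_diseases)),
        cancer_history = unpack_cancer(as.character(row$cancer_history)),
        family_history = unpack_family(as.character(row$family_history)),
        smoking_status = as.character(row$smoking_status),
        pack_years = as.numeric(row$pack_years),
        medications = unpack_list(as.character(row$medications)),
        treated_bp = as.logical(row$treated_bp)),
      exams = lapply(seq_len(nrow(ex)), function(j) physical_exam(
        date = ex$date[j], systolic = ex$systolic[j], diastolic = ex$diastolic[j],
        height = ex$height[j], weight = ex$weight[j], waist = ex$waist[j],
        other_findings = unpack_list(as.character(ex$other_findings[j])))),
      results = lapply(seq_len(nrow(re)), function(j) test_result(
        test_code = as.character(re$test_code[j]), date = re$date[j],
        numeric_value = as.numeric(re$numeric_value[j]),
        units = str_or_na(re$units[j]),
        components = unpack_components(as.character(re$components[j])),
        text_report = str_or_na(re$text_report[j]))),
      visits = lapply(seq_len(nrow(vi)), function(j) visit_event(
        date = vi$date[j],
        tests_requested = unpack_list(as.character(vi$tests_requested[j]))))
    )
  })
}

# ---------------------------------------------------------------------------

#' Load a cohort from disk
#'
#' Reads a validated cohort of person records. For `format = "json"`, `path`
#' is one nested JSON document (array of persons). For `format = "csv"`,
#' `path` is a directory holding the normalised four-file set `persons.csv`,
#' `exams.csv`, `results.csv`, `visits.csv`, keyed by `person_id`.
#'
#' @param path File (json) or directory (csv).
#' @param format "csv" or "json".
#' @return List of [person_record()], validated; loading stops with a
#'   validation error (naming the person_id and field) if any invariant is
#'   breached, including duplicated person ids.
#' @export
load_cohort <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    if (!file.exists(path)) stop_io("no such file: ", path)
    raw <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                    error = function(e) stop_format(
                      "JSON parse failure in ", path, ": ", conditionMessage(e)))
    cohort <- lapply(raw, person_from_plain)
  } else {
    files <- file.path(path, c("persons.csv", "exams.csv", "results.csv",
                               "visits.csv"))
    missing <- files[!file.exists(files)]
    if (length(missing)) stop_io("missing CSV file(s): ",
                                 paste(missing, collapse = ", "))
    # read everything as character: ids and phone numbers must not be
    # type-converted; the record constructors coerce numeric fields
    read1 <- function(f) tryCatch(
      utils::read.csv(f, stringsAsFactors = FALSE, colClasses = "character"),
      error = function(e) stop_format("CSV parse failure in ", f, ": ",
                                      conditionMessage(e)))
    fr <- list(persons = read1(files[1]), exams = read1(files[2]),
               results = read1(files[3]), visits = read1(files[4]))
    cohort <- csv_frames_to_cohort(fr)
  }
  f <- validate_cohort(cohort)
  if (nrow(f) > 0) {
    stop_validation("cohort validation failed: ",
                    paste(sprintf("[%s] %s: %s", f$person_id, f$field, f$message),
                          collapse = "; "))
  }
  cohort
}

#' Save a cohort to disk
#'
#' Inverse of [load_cohort()]: `load_cohort(save_cohort(x, ...))` returns `x`
#' with field-level equality, for both formats.
#'
#' @param cohort List of [person_record()] (validated).
#' @param path Output file (json) or directory (csv; created if needed).
#' @param format "csv" or "json".
#' @return `path`, invisibly.
#' @export
save_cohort <- function(cohort, path, format = c("csv", "json")) {
  format <- match.arg(format)
  f <- validate_cohort(cohort)
  if (nrow(f) > 0) {
    stop_validation("refusing to save invalid cohort: ",
                    paste(sprintf("[%s] %s", f$person_id, f$field), collapse = "; "))
  }
  if (format == "json") {
    ok <- tryCatch({
      jsonlite::write_json(lapply(cohort, person_to_plain), path,
                           auto_unbox = TRUE, null = "null", na = "null",
                           digits = NA)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok))
  } else {
    if (!dir.exists(path)) {
      ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
      if (!ok) stop("cannot create directory ", path)
    }
    fr <- cohort_to_csv_frames(cohort)
    utils::write.csv(fr$persons, file.path(path, "persons.csv"), row.names = FALSE)
    utils::write.csv(fr$exams, file.path(path, "exams.csv"), row.names = FALSE)
    utils::write.csv(fr$results, file.path(path, "results.csv"), row.names = FALSE)
    utils::write.csv(fr$visits, file.path(path, "visits.csv"), row.names = FALSE)
  }
  invisible(path)
}
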