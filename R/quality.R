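# Screening-quality audit: per-test 2x2 tallies (indicated x requested),
# underuse / overuse / inappropriateness proportions, coverage, irregular
# attendance and requested-test counts. Percentages are truncated (not
# rounded) at 2 decimals by default, matching printed audit arithmetic;
# rounding is available as an option.

period_range <- function(period) {
  start <- as_date(period[[1]])
  end <- as_date(period[[2]])
  if (is.na(start) || is.na(end) || start > end) {
    stop_domain("period must be (start, end) with start <= end")
  }
  list(start = start, end = end)
}

# Which sexes a test applies to under a ruleset (union over its rules).
applicable_sexes <- function(ruleset) {
  out <- list()
  for (r in ruleset$rules) {
    sexes <- if (r$target_sex == "any") c("male", "female") else r$target_sex
    out[[r$test_code]] <- union(out[[r$test_code]] %||% character(0), sexes)
  }
  out
}

#' Classify screening-test events into per-test audit tallies
#'
#' For every test in the ruleset, each sex-applicable person contributes to
#' exactly one cell of a 2x2 tally: indication is judged by [is_indicated()]
#' at the end of the audit period; a test counts as requested when any visit
#' within the period lists it. Cell sums per test therefore equal the number
#' of sex-applicable persons.
#'
#' @param cohort List of [person_record()].
#' @param ruleset A [load_ruleset()] ruleset.
#' @param period Two dates `(start, end)` of the audit period.
#' @return A `test_tally` data frame: test_code, indicated_requested,
#'   indicated_not_requested (underused), notindicated_requested (overused),
#'   notindicated_not_requested.
#' @export
classify_test_events <- function(cohort, ruleset, period) {
  pr <- period_range(period)
  sexes <- applicable_sexes(ruleset)
  codes <- sort(names(sexes))
  cells <- matrix(0L, nrow = length(codes), ncol = 4,
                  dimnames = list(codes, c("ir", "inr", "nr", "nnr")))
  for (person in cohort) {
    requested <- unique(unlist(lapply(person$visits, function(v) {
      if (v$date >= pr$start && v$date <= pr$end) v$tests_requested
      else character(0)
    }))) %||% character(0)
    for (rule in ruleset$rules) {
      if (!(rule$target_sex %in% c("any", person$sex))) next
      code <- rule$test_code
      ind <- is_indicated(person, rule, pr$end)$indicated
      req <- code %in% requested
      cell <- if (ind && req) "ir" else if (ind) "inr"
      else if (req) "nr" else "nnr"
      cells[code, cell] <- cells[code, cell] + 1L
    }
  }
  structure(data.frame(
    test_code = codes,
    indicated_requested = cells[, "ir"],
    indicated_not_requested = cells[, "inr"],
    notindicated_requested = cells[, "nr"],
    notindicated_not_requested = cells[, "nnr"],
    row.names = NULL, stringsAsFactors = FALSE
  ), class = c("test_tally", "data.frame"))
}

tally_cols <- function(tally) {
  list(inr = tally$indicated_not_requested,
       itot = tally$indicated_requested + tally$indicated_not_requested,
       nr = tally$notindicated_requested,
       ntot = tally$notindicated_requested + tally$notindicated_not_requested)
}

#' Underuse proportion per test
#'
#' Indicated-but-not-requested tests as a percentage of all indicated cases,
#' truncated at 2 decimals by default; `NA` where no case was indicated.
#'
#' @param tally A `test_tally` from [classify_test_events()].
#' @param rounding "truncate" (default) or "round".
#' @return Named numeric vector (by test_code) of percentages.
#' @export
underuse_proportion <- function(tally, rounding = "truncate") {
  k <- tally_cols(tally)
  stats::setNames(mapply(percent_of, k$inr, k$itot,
                         MoreArgs = list(rounding = rounding)),
                  tally$test_code)
}

#' Overuse proportion per test
#'
#' Requested-but-not-indicated tests as a percentage of all non-indicated
#' cases; `NA` where every case was indicated.
#'
#' @inheritParams underuse_proportion
#' @return Named numeric vector of percentages.
#' @export
overuse_proportion <- function(tally, rounding = "truncate") {
  k <- tally_cols(tally)
  stats::setNames(mapply(percent_of, k$nr, k$ntot,
                         MoreArgs = list(rounding = rounding)),
                  tally$test_code)
}

#' Inappropriateness proportion per test
#'
#' Numerator: underused + overused tests. Denominator: either all cases
#' (indicated + non-indicated; the convention of published audit tables) or
#' all requested tests (an alternative convention); both are supported
#' because audit reports disagree on which to use.
#'
#' @inheritParams underuse_proportion
#' @param denominator "cases" (default) or "requested".
#' @return Named numeric vector of percentages (`NA` on a zero denominator).
#' @export
inappropriateness <- function(tally, denominator = c("cases", "requested"),
                              rounding = "truncate") {
  denominator <- match.arg(denominator)
  k <- tally_cols(tally)
  num <- k$inr + k$nr
  den <- if (denominator == "cases") k$itot + k$ntot
  else tally$indicated_requested + tally$notindicated_requested
  stats::setNames(mapply(percent_of, num, den,
                         MoreArgs = list(rounding = rounding)),
                  tally$test_code)
}

#' Screening coverage
#'
#' @param attended Number of persons screened.
#' @param eligible Number of eligible persons (> 0, >= attended).
#' @return List with `percent` (truncated at 2 decimals) and `headline`
#'   (truncated to a whole percent, the conventionally reported figure).
#' @export
coverage <- function(attended, eligible) {
  if (!isTRUE(eligible > 0)) stop_domain("eligible must be > 0")
  if (!isTRUE(attended <= eligible) || !isTRUE(attended >= 0)) {
    stop_domain("attended must be in [0, eligible]")
  }
  list(percent = percent_of(attended, eligible, 2),
       headline = percent_of(attended, eligible, 0))
}

#' Irregular attendance proportion
#'
#' A participant attends irregularly when some calendar year of the audit
#' period contains none of their visits, or any gap between consecutive
#' in-period visits exceeds `max_gap` days. The denominator is all persons in
#' the cohort.
#'
#' @param cohort List of [person_record()].
#' @param period Two dates `(start, end)`.
#' @param max_gap Maximum regular inter-visit gap in days (default 365).
#' @param rounding "truncate" or "round".
#' @return Percentage (truncated at 2 decimals), `NA` for an empty cohort.
#' @export
irregular_attendance <- function(cohort, period, max_gap = 365,
                                 rounding = "truncate") {
  pr <- period_range(period)
  if (!length(cohort)) return(NA_real_)
  years <- seq(as.integer(format(pr$start, "%Y")),
               as.integer(format(pr$end, "%Y")))
  irregular <- vapply(cohort, function(p) {
    dates <- sort(as.Date(vapply(p$visits, function(v) format(v$date), ""),
                          "%Y-%m-%d"))
    dates <- dates[dates >= pr$start & dates <= pr$end]
    if (!length(dates)) return(TRUE)
    visit_years <- as.integer(format(dates, "%Y"))
    if (any(!(years %in% visit_years))) return(TRUE)
    length(dates) > 1 && any(diff(as.numeric(dates)) > max_gap)
  }, TRUE)
  percent_of(sum(irregular), length(cohort), 2, rounding)
}

#' Requested-test counts over a period
#'
#' Counts, for every known test code, the visits in the period that requested
#' it (one count per visit mention), plus the grand total.
#'
#' @param cohort List of [person_record()].
#' @param period Two dates `(start, end)`.
#' @return List with `per_test` (named integer vector over [test_codes()])
#'   and `total`.
#' @export
count_requested <- function(cohort, period) {
  pr <- period_range(period)
  counts <- stats::setNames(integer(length(test_codes())), test_codes())
  for (p in cohort) {
    for (v in p$visits) {
      if (v$date >= pr$start && v$date <= pr$end) {
        for (tc in v$tests_requested) counts[tc] <- counts[tc] + 1L
      }
    }
  }
  list(per_test = counts, total = sum(counts))
}

#' Full screening-quality audit
#'
#' Assembles the audit layer in one report: per-test tallies, underuse,
#' overuse and inappropriateness proportions, requested counts with grand
#' total, irregular attendance, and (when `eligible_n` is supplied) coverage.
#'
#' @param cohort List of [person_record()].
#' @param ruleset A ruleset.
#' @param period Two dates `(start, end)`.
#' @param denominator Inappropriateness denominator, "cases" or "requested".
#' @param rounding "truncate" (default) or "round".
#' @param max_gap Irregular-attendance gap threshold in days.
#' @param eligible_n Optional size of the eligible population for coverage
#'   (attended = cohort size).
#' @return A `quality_report` list; print renders per-test audit tables, and
#'   [report_to_json()] serialises it.
#' @export
audit <- function(cohort, ruleset, period,
                  denominator = c("cases", "requested"),
                  rounding = c("truncate", "round"),
                  max_gap = 365, eligible_n = NULL) {
  denominator <- match.arg(denominator)
  rounding <- match.arg(rounding)
  tally <- classify_test_events(cohort, ruleset, period)
  counts <- count_requested(cohort, period)
  cov <- if (!is.null(eligible_n) && eligible_n > 0) {
    coverage(length(cohort), eligible_n)
  } else list(percent = NA_real_, headline = NA_real_)
  structure(list(
    period = vapply(period_range(period), format, ""),
    n_persons = length(cohort),
    denominator_convention = denominator,
    rounding = rounding,
    tally = tally,
    underuse_pct = underuse_proportion(tally, rounding),
    overuse_pct = overuse_proportion(tally, rounding),
    inappropriateness_pct = inappropriateness(tally, denominator, rounding),
    requested = counts$per_test,
    requested_total = counts$total,
    irregular_attendance_pct = irregular_attendance(cohort, period, max_gap,
                                                    rounding),
    coverage_pct = cov$percent,
    coverage_headline = cov$headline
  ), class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("Screening quality audit, %s to %s (%d persons)\n",
              x$period[["start"]], x$period[["end"]], x$n_persons))
  if (!is.na(x$coverage_headline)) {
    cat(sprintf("coverage: %g%%   ", x$coverage_headline))
  }
  cat(sprintf("irregular attendance: %s%%\n",
              format(x$irregular_attendance_pct)))
  t <- x$tally
  fmt <- function(v) ifelse(is.na(v), "n/a", sprintf("%.2f", v))
  cat(sprintf("%-26s %16s %16s %15s %9s\n", "test",
              "underuse", "overuse",
              paste0("inappropriate(", substr(x$denominator_convention, 1, 4), ")"),
              "requested"))
  for (i in seq_len(nrow(t))) {
    code <- t$test_code[i]
    itot <- t$indicated_requested[i] + t$indicated_not_requested[i]
    ntot <- t$notindicated_requested[i] + t$notindicated_not_requested[i]
    cat(sprintf("%-26s %7s (%s%%) %8s (%s%%) %8s%% %9d\n", code,
                sprintf("%d/%d", t$indicated_not_requested[i], itot),
                fmt(x$underuse_pct[[code]]),
                sprintf("%d/%d", t$notindicated_requested[i], ntot),
                fmt(x$overuse_pct[[code]]),
                fmt(x$inappropriateness_pct[[code]]),
                x$requested[[code]]))
  }
  cat(sprintf("total requested: %d\n", x$requested_total))
  invisible(x)
}

#' Serialise a quality report to JSON
#'
#' @param report A `quality_report` from [audit()].
#' @param path Optional output path; omitted returns the JSON string.
#' @return JSON string (invisibly, when `path` given).
#' @export
report_to_json <- function(report, path = NULL) {
  payload <- unclass(report)
  payload$underuse_pct <- as.list(payload$underuse_pct)
  payload$overuse_pct <- as.list(payload$overuse_pct)
  payload$inappropriateness_pct <- as.list(payload$inappropriateness_pct)
  payload$requested <- as.list(payload$requested)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, na = "null",
                           dataframe = "rows", digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
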