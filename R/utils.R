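# Internal helpers: date arithmetic, truncating percentages, small checks.
# All interval arithmetic is in whole days on Date objects; dates are ISO-8601
# strings in files.

#' @keywords internal
as_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x, format = "%Y-%m-%d")
}

# Completed years between two dates (floor of calendar age).
#' @keywords internal
age_years <- function(birth_date, as_of) {
  birth <- as.POSIXlt(as_date(birth_date))
  now <- as.POSIXlt(as_date(as_of))
  age <- now$year - birth$year
  # subtract one if the birthday has not yet occurred this year
  before_bday <- (now$mon < birth$mon) |
    (now$mon == birth$mon & now$mday < birth$mday)
  age - as.integer(before_bday)
}

# Percentage with configurable rounding mode. Default truncates (chops) at
# `digits` decimals, e.g. 108/261 -> 41.37, matching printed audit arithmetic.
#' @keywords internal
percent_of <- function(numerator, denominator, digits = 2,
                       rounding = c("truncate", "round")) {
  rounding <- match.arg(rounding)
  if (is.na(denominator) || denominator <= 0) return(NA_real_)
  pct <- 100 * numerator / denominator
  chop(pct, digits, rounding)
}

#' @keywords internal
chop <- function(x, digits = 2, rounding = c("truncate", "round")) {
  rounding <- match.arg(rounding)
  if (rounding == "round") return(round(x, digits))
  scale <- 10^digits
  # epsilon guards against 41.379999... style representation error
  floor(x * scale + 1e-9) / scale
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_domain <- function(...) {
  stop(structure(class = c("smartscreen_domain_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @keywords internal
stop_config <- function(...) {
  stop(structure(class = c("smartscreen_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @keywords internal
stop_validation <- function(...) {
  stop(structure(class = c("smartscreen_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @keywords internal
stop_io <- function(...) {
  stop(structure(class = c("smartscreen_io_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @keywords internal
stop_format <- function(...) {
  stop(structure(class = c("smartscreen_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Collapse a character vector into the pipe-delimited cell used by the CSV
# normalisation; empty vector -> "".
#' @keywords internal
pack_list <- function(x) paste(x, collapse = "|")

#' @keywords internal
unpack_list <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, "|", fixed = TRUE)[[1]]
}
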