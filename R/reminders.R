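# Reminder scheduling: the fixed six-shot notification schedule around each
# due date (two weeks, one week and three days before; three days, one week
# and two weeks after), enumeration of pending notifications over a window,
# and a minimal iCalendar (RFC 5545) export with all-day DATE events.

REMINDER_OFFSETS <- c(-14L, -7L, -3L, 3L, 7L, 14L)

#' Reminder schedule for one due date
#'
#' Exactly six events per channel: offsets -14, -7, -3 days (phase `pre`) and
#' +3, +7, +14 days (phase `post`); never an event on the due date itself.
#' "Week" and "two weeks" are wall-calendar days (7/14), with no business-day
#' adjustment.
#'
#' @param due_date Due date of the screening test.
#' @param person_id,test_code Identifiers carried on each event.
#' @param channels Channels to schedule ("email", "sms").
#' @return Data frame of reminder events (person_id, test_code, due_date,
#'   fire_date, phase, offset_days, channel), sorted by fire_date then channel.
#' @export
reminder_schedule <- function(due_date, person_id = NA_character_,
                              test_code = NA_character_,
                              channels = c("email", "sms")) {
  due <- as_date(due_date)
  if (is.na(due)) stop_domain("due_date must be a valid date")
  grid <- expand.grid(offset_days = REMINDER_OFFSETS, channel = channels,
                      stringsAsFactors = FALSE)
  ev <- data.frame(
    person_id = person_id, test_code = test_code, due_date = due,
    fire_date = due + grid$offset_days,
    phase = ifelse(grid$offset_days < 0, "pre", "post"),
    offset_days = as.integer(grid$offset_days),
    channel = grid$channel, stringsAsFactors = FALSE)
  ev <- ev[order(ev$fire_date, ev$channel), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

empty_events <- function() {
  data.frame(person_id = character(0), test_code = character(0),
             due_date = as.Date(character(0)), fire_date = as.Date(character(0)),
             phase = character(0), offset_days = integer(0),
             channel = character(0), stringsAsFactors = FALSE)
}

#' Pending notifications for a set of screening plans
#'
#' Enumerates every reminder event whose fire date falls inside
#' `[window_start, window_end]`, for indicated recommendations only, on the
#' channels for which the person has contact information (a missing e-mail
#' address or phone number silently disables that channel). Reminders stop
#' after the +14-day event; completing a test moves its due date at the next
#' plan evaluation, which is how post-due reminders cease.
#'
#' @param plans List of `screening_plan` (from [evaluate_rules()] /
#'   [screen_cohort()]).
#' @param window_start,window_end Inclusive date window
#'   (`window_start <= window_end`).
#' @return Data frame of reminder events as in [reminder_schedule()].
#' @export
pending_notifications <- function(plans, window_start, window_end) {
  ws <- as_date(window_start); we <- as_date(window_end)
  if (ws > we) stop_domain("window_start must not exceed window_end")
  chunks <- lapply(plans, function(plan) {
    if (!length(plan$channels)) return(NULL)
    do.call(rbind, lapply(plan$recommendations, function(r) {
      if (!r$indicated) return(NULL)
      reminder_schedule(r$due_date, plan$person_id, r$test_code, plan$channels)
    }))
  })
  ev <- do.call(rbind, c(list(empty_events()), chunks))
  ev <- ev[ev$fire_date >= ws & ev$fire_date <= we, , drop = FALSE]
  ev <- ev[order(ev$fire_date, ev$person_id, ev$test_code, ev$channel), ,
           drop = FALSE]
  rownames(ev) <- NULL
  ev
}

ics_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub(";", "\\;", x, fixed = TRUE)
  x <- gsub(",", "\\,", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

#' Export reminder events to an iCalendar file
#'
#' Writes one all-day VEVENT per reminder event. [parse_calendar()] reads the
#' file back, so `parse_calendar(export_calendar(ev))` preserves the event
#' count and dates.
#'
#' @param events Events data frame from [reminder_schedule()] or
#'   [pending_notifications()].
#' @param path Output `.ics` path.
#' @return `path`, invisibly.
#' @export
export_calendar <- function(events, path) {
  lines <- c("BEGIN:VCALENDAR", "VERSION:2.0",
             "PRODID:-//smartscreen//screening reminders//EN")
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    uid <- sprintf("%s-%s-%+d-%s@smartscreen", e$person_id, e$test_code,
                   e$offset_days, e$channel)
    summary <- sprintf("%s screening reminder (%s, %+dd) for %s via %s",
                       e$test_code, e$phase, e$offset_days, e$person_id,
                       e$channel)
    lines <- c(lines,
               "BEGIN:VEVENT",
               paste0("UID:", ics_escape(uid)),
               paste0("DTSTART;VALUE=DATE:", format(e$fire_date, "%Y%m%d")),
               paste0("SUMMARY:", ics_escape(summary)),
               paste0("CATEGORIES:", e$channel),
               paste0("DESCRIPTION:", ics_escape(sprintf(
                 "due %s\noffset %+d days\nchannel %s",
                 format(e$due_date), e$offset_days, e$channel))),
               "END:VEVENT")
  }
  lines <- c(lines, "END:VCALENDAR")
  ok <- tryCatch({ writeLines(lines, path); TRUE }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Re-parse an iCalendar file written by [export_calendar()]
#'
#' @param path `.ics` path.
#' @return Data frame with one row per VEVENT: `uid`, `fire_date`, `summary`.
#' @export
parse_calendar <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "BEGIN:VEVENT")
  ends <- which(lines == "END:VEVENT")
  if (length(starts) != length(ends)) stop_format("malformed calendar: ", path)
  rows <- lapply(seq_along(starts), function(i) {
    block <- lines[starts[i]:ends[i]]
    take <- function(prefix) {
      hit <- grep(paste0("^", prefix), block, value = TRUE)
      if (!length(hit)) NA_character_ else sub(paste0("^", prefix), "", hit[1])
    }
    data.frame(uid = take("UID:"),
               fire_date = as.Date(take("DTSTART;VALUE=DATE:"), "%Y%m%d"),
               summary = take("SUMMARY:"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(data.frame(uid = character(0),
                                          fire_date = as.Date(character(0)),
                                          summary = character(0))), rows))
  rownames(out) <- NULL
  out
}
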