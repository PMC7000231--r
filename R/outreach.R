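# Registry lifecycle tracking: an explicit outreach state machine plus
# disposition reporting.
#
# Lifecycle: identified -> provider_notified -> outreach_sent ->
# {scheduled | declined | consider_future | no_need | unreachable};
# scheduled -> {appointment_pending | completed_visit};
# completed_visit -> {tested_negative | tested_positive |
# completed_no_test}. The initial outreach message counts as contact
# attempt 1; up to three phone attempts follow, so a patient can only be
# marked unreachable after all 4 attempts.

# event -> c(from_status, to_status)
.TRANSITIONS <- list(
  notify_provider  = c("identified", "provider_notified"),
  send_outreach    = c("provider_notified", "outreach_sent"),
  phone_no_answer  = c("outreach_sent", "outreach_sent"),
  schedule         = c("outreach_sent", "scheduled"),
  decline          = c("outreach_sent", "declined"),
  consider_future  = c("outreach_sent", "consider_future"),
  no_need          = c("outreach_sent", "no_need"),
  mark_unreachable = c("outreach_sent", "unreachable"),
  mark_pending     = c("scheduled", "appointment_pending"),
  visit_completed  = c("scheduled", "completed_visit"),
  test_negative    = c("completed_visit", "tested_negative"),
  test_positive    = c("completed_visit", "tested_positive"),
  no_test          = c("completed_visit", "completed_no_test")
)

MAX_CONTACT_ATTEMPTS <- 4L  # 1 initial message + 3 phone attempts

#' Events legal from a given status
#'
#' @param status a registry status.
#' @param contact_attempts current attempt count (restricts
#'   `phone_no_answer` / `mark_unreachable`).
#' @return character vector of event names (empty for terminal states).
#' @export
legal_events <- function(status, contact_attempts = 0L) {
  ev <- names(.TRANSITIONS)[vapply(.TRANSITIONS, function(t) t[1] == status,
                                   TRUE)]
  if (status == "outreach_sent") {
    if (contact_attempts >= MAX_CONTACT_ATTEMPTS) {
      ev <- setdiff(ev, "phone_no_answer")
    } else {
      ev <- setdiff(ev, "mark_unreachable")
    }
  }
  ev
}

apply_event <- function(status, contact_attempts, event) {
  tr <- .TRANSITIONS[[event]]
  if (is.null(tr)) stop("unknown event '", event, "'")
  allowed <- legal_events(status, contact_attempts)
  if (!event %in% allowed) {
    stop(sprintf(
      "illegal transition: event '%s' from status '%s' (attempts %d); allowed: %s",
      event, status, contact_attempts,
      if (length(allowed)) paste(allowed, collapse = ", ") else "none (terminal)"),
      call. = FALSE)
  }
  if (event %in% c("send_outreach", "phone_no_answer")) {
    contact_attempts <- contact_attempts + 1L
  }
  list(status = tr[2], contact_attempts = contact_attempts)
}

#' Advance a registry entry through the outreach workflow
#'
#' Applies one event to one patient's entry, appending to the entry's
#' history. Illegal transitions are rejected with an error naming the
#' events allowed from the current status.
#'
#' @param registry an `fhh_registry`.
#' @param patient_id the entry to advance.
#' @param event an event name (see `legal_events()`): `notify_provider`,
#'   `send_outreach`, `phone_no_answer`, `schedule`, `decline`,
#'   `consider_future`, `no_need`, `mark_unreachable`, `mark_pending`,
#'   `visit_completed`, `test_negative`, `test_positive`, `no_test`.
#' @param timestamp character timestamp recorded in the history.
#' @return the updated registry.
#' @export
advance <- function(registry, patient_id, event,
                    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                       tz = "UTC")) {
  i <- match(patient_id, registry$patient_id)
  if (is.na(i)) stop("no registry entry for patient ", patient_id)
  from <- registry$status[i]
  upd <- apply_event(from, registry$contact_attempts[i], event)
  registry$status[i] <- upd$status
  registry$contact_attempts[i] <- upd$contact_attempts
  h <- registry$history[[i]]
  registry$history[[i]] <- rbind(h, data.frame(
    timestamp = as.character(timestamp), event = event,
    from_status = from, to_status = upd$status, stringsAsFactors = FALSE))
  registry
}

#' Replay a saved history onto a fresh entry
#'
#' Applies the recorded events in order starting from `identified` (with 0
#' contact attempts) and returns the resulting state. Replaying an entry's
#' history always reproduces its final status and attempt count, which is
#' the registry's integrity check after persistence.
#'
#' @param history a history data frame (`timestamp`, `event`,
#'   `from_status`, `to_status`).
#' @return `list(status, contact_attempts)`.
#' @export
replay_history <- function(history) {
  state <- list(status = "identified", contact_attempts = 0L)
  for (i in seq_len(nrow(history))) {
    state <- apply_event(state$status, state$contact_attempts,
                         history$event[i])
  }
  state
}

# Disposition bucket of a current status: where did outreach land?
# Downstream statuses collapse into "scheduled" (the patient did schedule).
.DISPOSITION_OF <- c(
  scheduled = "scheduled", appointment_pending = "scheduled",
  completed_visit = "scheduled", tested_negative = "scheduled",
  tested_positive = "scheduled", completed_no_test = "scheduled",
  declined = "declined", consider_future = "consider_future",
  unreachable = "unreachable", no_need = "no_need")

#' Disposition report over a registry
#'
#' Counts outreach outcomes over the entries whose outreach has concluded
#' (reached one of the five disposition buckets: scheduled — including all
#' downstream statuses —, declined, consider future, unreachable, no
#' need), with integer percentages rounded half away from zero over that
#' denominator. Nested rates use their own stated denominators: completed
#' visits among scheduled patients (appointment-pending entries stay in
#' the denominator's scheduled bucket but are not completed), and test
#' outcomes among completed visits. Zero-denominator rates are reported as
#' `NA` (undefined), never as 0.
#'
#' @param registry an `fhh_registry`.
#' @param annotations optional named logical vectors (e.g. self-reported
#'   prior counseling) indexed like the registry; each is tallied over the
#'   outreach denominator as an overlapping flag, outside the partition.
#' @return object of class `disposition_report`: a list with
#'   `outreach` (data frame status/count/pct over `n_outreach`),
#'   `n_outreach`, `completed` (`n`, `of_scheduled_pct`), `testing`
#'   (counts and pcts of `tested_negative`, `tested_positive`,
#'   `completed_no_test` over completed visits), and `annotations`.
#' @export
disposition_report <- function(registry, annotations = NULL) {
  disp <- unname(.DISPOSITION_OF[registry$status])
  in_denom <- !is.na(disp)
  n_outreach <- sum(in_denom)
  buckets <- c("scheduled", "declined", "consider_future", "unreachable",
               "no_need")
  counts <- vapply(buckets, function(b) sum(disp[in_denom] == b), 1L)
  pct <- if (n_outreach > 0L) {
    round_half_away(100 * counts / n_outreach)
  } else rep(NA_real_, length(buckets))

  completed_statuses <- c("completed_visit", "tested_negative",
                          "tested_positive", "completed_no_test")
  n_scheduled <- counts[["scheduled"]]
  n_completed <- sum(registry$status %in% completed_statuses)
  completed_pct <- if (n_scheduled > 0L) {
    round_half_away(100 * n_completed / n_scheduled)
  } else NA_real_

  test_counts <- c(tested_negative = sum(registry$status == "tested_negative"),
                   tested_positive = sum(registry$status == "tested_positive"),
                   completed_no_test = sum(registry$status == "completed_no_test"))
  test_pct <- if (n_completed > 0L) {
    round_half_away(100 * test_counts / n_completed)
  } else rep(NA_real_, 3L)

  ann <- NULL
  if (!is.null(annotations)) {
    ann <- lapply(annotations, function(flag) {
      n <- sum(flag[in_denom], na.rm = TRUE)
      list(count = n,
           pct = if (n_outreach > 0L) round_half_away(100 * n / n_outreach)
                 else NA_real_)
    })
  }

  structure(list(
    outreach = data.frame(status = buckets, count = unname(counts),
                          pct = unname(pct), stringsAsFactors = FALSE),
    n_outreach = n_outreach,
    completed = list(n = n_completed, of_scheduled = n_scheduled,
                     of_scheduled_pct = completed_pct),
    testing = list(counts = test_counts, pct = test_pct,
                   n_completed = n_completed),
    annotations = ann),
    class = "disposition_report")
}

#' @export
print.disposition_report <- function(x, ...) {
  cat(sprintf("Disposition report (n = %d contacted patients)\n", x$n_outreach))
  for (i in seq_len(nrow(x$outreach))) {
    cat(sprintf("  %-16s %4d (%s%%)\n", x$outreach$status[i],
                x$outreach$count[i], fmt_pct(x$outreach$pct[i])))
  }
  cat(sprintf("  completed visit: %d of %d scheduled (%s%%)\n",
              x$completed$n, x$completed$of_scheduled,
              fmt_pct(x$completed$of_scheduled_pct)))
  tc <- x$testing$counts; tp <- x$testing$pct
  cat(sprintf("  of completed: %d tested negative (%s%%), %d positive (%s%%), %d not tested (%s%%)\n",
              tc[["tested_negative"]], fmt_pct(tp[[1]]),
              tc[["tested_positive"]], fmt_pct(tp[[2]]),
              tc[["completed_no_test"]], fmt_pct(tp[[3]])))
  if (!is.null(x$annotations)) {
    for (nm in names(x$annotations)) {
      a <- x$annotations[[nm]]
      cat(sprintf("  [flag] %-14s %4d (%s%%)\n", nm, a$count, fmt_pct(a$pct)))
    }
  }
  invisible(x)
}

fmt_pct <- function(p) if (is.na(p)) "undefined" else format(p)
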