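# Fusing terminology and comment extraction into one normalized relative
# per FHH record — the fact base the rules engine consumes.

#' Construct a cancer event
#'
#' One cancer diagnosis in one relative, with its resolved onset interval.
#' `non_cancer` diagnoses never become events.
#'
#' @param category a cancer category (see [map_condition()]), not
#'   `"non_cancer"`.
#' @param onset an [onset_estimate()].
#' @param relative_ref the `record_id` of the relative carrying the event.
#' @return object of class `cancer_event`.
#' @export
cancer_event <- function(category, onset, relative_ref) {
  stopifnot(category %in% setdiff(.CANCER_CATEGORIES, "non_cancer"),
            inherits(onset, "onset_estimate"))
  structure(list(category = category, onset = onset,
                 relative_ref = relative_ref),
            class = "cancer_event")
}

#' Normalize one family-member record
#'
#' Fuses the relationship mapping, the lineage-side comment extraction, and
#' the onset resolution into a single normalized relative:
#'
#' * the relationship term is mapped to degree / lineage / sex /
#'   blood-relative status (an unmapped term keeps the relative with
#'   `degree = "unknown"`, which no criterion counts);
#' * a lineage side found in the comments fills in an unknown lineage, but
#'   never overrides a known one — a contradiction resets lineage to
#'   unknown and is logged;
#' * each diagnosis mapping to a cancer category becomes a
#'   [cancer_event()] with onset resolved by [resolve_onset()]; unmapped
#'   and non-cancer diagnoses are dropped (unmapped ones logged);
#' * events within the record are deduplicated by category, keeping the
#'   onset with the smallest lower bound, so one relative never
#'   double-counts toward a multi-relative criterion.
#'
#' Records that are already normalized pass through unchanged.
#'
#' @param raw a [family_member_record()] (or an already-normalized
#'   relative, returned as-is).
#' @param table optional [mapping_table()].
#' @param use_comments if `FALSE`, free-text comments are ignored for both
#'   onset and lineage (structured fields only).
#' @return object of class `normalized_relative`.
#' @export
normalize_relative <- function(raw, table = NULL, use_comments = TRUE) {
  if (inherits(raw, "normalized_relative")) return(raw)
  stopifnot(inherits(raw, "family_member_record"))
  logs <- character()

  concept <- map_relationship(raw$relationship_term, table)
  if (is.null(concept)) {
    logs <- c(logs, sprintf("unmapped relationship term '%s' (record %s)",
                            raw$relationship_term, raw$record_id))
    degree <- "unknown"; lineage <- "unknown"; sex <- "unknown"
    blood <- NA
  } else {
    degree <- concept$degree; lineage <- concept$lineage
    sex <- concept$sex; blood <- concept$blood_relative
  }

  if (use_comments && lineage %in% c("maternal", "paternal", "unknown")) {
    texts <- c(raw$record_comment,
               vapply(raw$diagnoses, function(d) d$comment %||% "", ""))
    comment_lineage <- extract_lineage(paste(texts, collapse = " "))
    if (comment_lineage != "unknown") {
      if (lineage == "unknown") {
        lineage <- comment_lineage
      } else if (lineage != comment_lineage) {
        logs <- c(logs, sprintf(
          "lineage conflict for record %s: term says %s, comment says %s; reset to unknown",
          raw$record_id, lineage, comment_lineage))
        lineage <- "unknown"
      }
    }
  }

  events <- list()
  for (d in raw$diagnoses) {
    category <- map_condition(d$condition_term, table)
    if (is.null(category)) {
      logs <- c(logs, sprintf("unmapped condition term '%s' (record %s)",
                              d$condition_term, raw$record_id))
      next
    }
    if (category == "non_cancer") next
    onset <- resolve_onset(d$onset_age_years,
                           if (use_comments) d$comment %||% "" else "")
    events[[length(events) + 1L]] <- cancer_event(category, onset,
                                                  raw$record_id)
  }
  events <- dedup_events(events)

  structure(list(record_id = raw$record_id,
                 patient_id = raw$patient_id,
                 degree = degree, lineage = lineage, sex = sex,
                 blood_relative = blood,
                 events = events,
                 date_captured = raw$date_captured,
                 logs = logs),
            class = "normalized_relative")
}

# Keep one event per category: the one whose onset lower bound is smallest
# (known onsets beat unknown; ties broken on the upper bound).
dedup_events <- function(events) {
  if (length(events) <= 1L) return(events)
  cats <- vapply(events, `[[`, "", "category")
  keep <- integer()
  for (cat in unique(cats)) {
    idx <- which(cats == cat)
    if (length(idx) == 1L) { keep <- c(keep, idx); next }
    lows <- vapply(events[idx], function(e) {
      if (e$onset$kind == "unknown") Inf else as.numeric(e$onset$low_years)
    }, 1)
    highs <- vapply(events[idx], function(e) {
      if (e$onset$kind == "unknown") Inf else as.numeric(e$onset$high_years)
    }, 1)
    keep <- c(keep, idx[order(lows, highs)][1])
  }
  events[sort(keep)]
}

#' @export
print.normalized_relative <- function(x, ...) {
  cat(sprintf("<relative %s: degree %s, lineage %s, sex %s, blood=%s, %d cancer event(s)>\n",
              x$record_id, x$degree, x$lineage, x$sex,
              as.character(x$blood_relative), length(x$events)))
  invisible(x)
}

#' Normalize all FHH records of a cohort
#'
#' @param cohort an `fhh_cohort`, see [read_cohort()].
#' @inheritParams normalize_relative
#' @return named list: for each patient_id, a list of
#'   [normalize_relative()] results (patients without FHH get an empty
#'   list).
#' @export
normalize_cohort <- function(cohort, table = NULL, use_comments = TRUE) {
  out <- stats::setNames(
    vector("list", nrow(cohort$demographics)),
    cohort$demographics$patient_id)
  for (i in seq_along(out)) out[[i]] <- list()
  for (rec in cohort$fhh) {
    nr <- normalize_relative(rec, table, use_comments)
    pid <- rec$patient_id
    if (pid %in% names(out)) {
      out[[pid]] <- c(out[[pid]], list(nr))
    }
  }
  out
}
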