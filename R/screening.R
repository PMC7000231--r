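# The Population Analyzer: target-population retrieval, rule evaluation,
# prior-counseling exclusion, and registry export over a whole cohort.

#' Build a screening summary from component counts
#'
#' The accounting identity is inclusion–exclusion over the two disease
#' tracks: `n_met_total = n_met_breast + n_met_colorectal - n_met_both`.
#' Patients with documented prior genetic counseling are excluded from
#' outreach *after* eligibility counting, so
#' `n_remaining_for_outreach = n_met_total - n_prior_counseling_excluded`.
#' Prevalence is reported to one decimal, rounded half away from zero.
#'
#' @param n_screened number of target-population patients evaluated.
#' @param n_met_breast,n_met_colorectal,n_met_both per-track counts (both
#'   = met both tracks).
#' @param n_prior_counseling_excluded patients meeting criteria with
#'   documented prior genetic counseling.
#' @return object of class `screening_summary`.
#' @export
#' @examples
#' # inclusion-exclusion over the tracks
#' screening_summary(143012, 4810, 562, 127, 60)
screening_summary <- function(n_screened, n_met_breast, n_met_colorectal,
                              n_met_both, n_prior_counseling_excluded = 0L) {
  stopifnot(n_met_both <= n_met_breast, n_met_both <= n_met_colorectal)
  n_met_total <- n_met_breast + n_met_colorectal - n_met_both
  stopifnot(n_prior_counseling_excluded <= n_met_total)
  if (n_screened == 0L) {
    if (n_met_total > 0L) stop("n_met_total > 0 with n_screened = 0")
    warning("empty screening population; prevalence reported as 0.0",
            call. = FALSE)
    prevalence <- 0.0
  } else {
    prevalence <- round_half_away(100 * n_met_total / n_screened, 1)
  }
  structure(list(n_screened = as.integer(n_screened),
                 n_met_total = as.integer(n_met_total),
                 n_met_breast = as.integer(n_met_breast),
                 n_met_colorectal = as.integer(n_met_colorectal),
                 n_met_both = as.integer(n_met_both),
                 n_prior_counseling_excluded =
                   as.integer(n_prior_counseling_excluded),
                 n_remaining_for_outreach =
                   as.integer(n_met_total - n_prior_counseling_excluded),
                 prevalence_pct = prevalence),
            class = "screening_summary")
}

#' @export
print.screening_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "Screening summary\n",
    "  screened:                 %d\n",
    "  met criteria:             %d (%.1f%%)\n",
    "    breast/ovarian track:   %d\n",
    "    colorectal track:       %d\n",
    "    both tracks:            %d\n",
    "  prior counseling (excl.): %d\n",
    "  remaining for outreach:   %d\n"),
    x$n_screened, x$n_met_total, x$prevalence_pct, x$n_met_breast,
    x$n_met_colorectal, x$n_met_both, x$n_prior_counseling_excluded,
    x$n_remaining_for_outreach))
  invisible(x)
}

#' Screen a cohort and build the registry
#'
#' Runs the full Population-Analyzer pass: filters the cohort to the
#' target population, normalizes each patient's FHH records, evaluates the
#' ruleset, and enters every patient with any met track into the registry.
#' Patients with documented prior genetic counseling are still counted as
#' meeting criteria but enter the registry with status
#' `prior_counseling_excluded` (the exclusion happens after eligibility
#' counting). Output is deterministic: the registry is ordered by
#' `patient_id` and re-running on the same inputs reproduces it exactly.
#'
#' @param cohort an `fhh_cohort`, see [read_cohort()].
#' @param table optional [mapping_table()] of site-local terms.
#' @param rules an `fhh_ruleset` (default [default_ruleset()]).
#' @param cfg a [target_population_config()].
#' @param mode onset interval mode, see [onset_satisfies()].
#' @param use_comments if `FALSE`, free-text comment extraction (onset and
#'   lineage) is disabled and only structured fields are used.
#' @return `list(registry = fhh_registry, summary = screening_summary,
#'   results = list of eligibility_result for flagged patients)`.
#' @export
screen_population <- function(cohort, table = NULL, rules = default_ruleset(),
                              cfg, mode = c("conservative", "optimistic"),
                              use_comments = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "fhh_cohort"),
            inherits(cfg, "target_population_config"))
  demo <- cohort$demographics
  enc_by_pid <- split(cohort$encounters, cohort$encounters$patient_id)
  facts <- normalize_cohort(cohort, table, use_comments)

  # resolve ancestry flags from religion codes via the terminology overlay
  ancestry <- lapply(demo$religion_code, function(code) {
    if (is.na(code)) character() else {
      f <- map_religion(code, table)
      if (is.null(f)) character() else f
    }
  })

  n_screened <- 0L
  results <- list()
  rows <- list()
  n_prior <- 0L
  for (i in seq_len(nrow(demo))) {
    pid <- demo$patient_id[i]
    p <- demo[i, , drop = FALSE]
    enc <- enc_by_pid[[pid]] %||% cohort$encounters[0, , drop = FALSE]
    if (!in_target_population(p, enc, cfg)) next
    n_screened <- n_screened + 1L
    p$ancestry_flags <- list(ancestry[[i]])
    res <- evaluate_patient(p, facts[[pid]] %||% list(), rules, mode,
                            evaluated_at = cfg$as_of_date)
    if (res$breast_met || res$colorectal_met) {
      results[[length(results) + 1L]] <- res
      prior <- isTRUE(p$prior_genetic_counseling)
      if (prior) n_prior <- n_prior + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid,
        breast_met = res$breast_met,
        colorectal_met = res$colorectal_met,
        fired_criteria = paste(vapply(res$fired_criteria, `[[`, "",
                                      "criterion_id"), collapse = ","),
        status = if (prior) "prior_counseling_excluded" else "identified",
        provider_id = p$provider_id %||% NA_character_,
        stringsAsFactors = FALSE)
    }
  }

  n_breast <- sum(vapply(results, `[[`, TRUE, "breast_met"))
  n_crc <- sum(vapply(results, `[[`, TRUE, "colorectal_met"))
  n_both <- sum(vapply(results, function(r) r$breast_met && r$colorectal_met,
                       TRUE))
  summary <- screening_summary(n_screened, n_breast, n_crc, n_both, n_prior)

  registry <- if (length(rows)) {
    flat <- do.call(rbind, rows)
    new_registry(patient_id = flat$patient_id,
                 breast_met = flat$breast_met,
                 colorectal_met = flat$colorectal_met,
                 fired_criteria = flat$fired_criteria,
                 status = flat$status,
                 provider_id = flat$provider_id)
  } else {
    new_registry()
  }
  list(registry = registry, summary = summary, results = results)
}

#' Notify providers ahead of patient outreach
#'
#' One week before a patient is contacted, the designated primary care
#' provider receives a notification. Produces one notification per
#' (provider, patient) pair for entries in status `identified`, with
#' `outreach_planned_date = notification_date + 7 days`, and advances
#' those entries to `provider_notified`. Entries without a designated
#' provider are skipped and logged.
#'
#' @param registry an `fhh_registry`.
#' @param as_of_date the notification date.
#' @return `list(notifications = data.frame(provider_id, patient_id,
#'   notification_date, outreach_planned_date), registry = updated
#'   registry)`.
#' @export
notify_providers <- function(registry, as_of_date) {
  as_of_date <- as.Date(as_of_date)
  idx <- which(registry$status == "identified")
  notif <- list()
  for (i in idx) {
    if (is.na(registry$provider_id[i])) {
      message("notify_providers: patient ", registry$patient_id[i],
              " has no designated provider; notification skipped")
      next
    }
    notif[[length(notif) + 1L]] <- data.frame(
      provider_id = registry$provider_id[i],
      patient_id = registry$patient_id[i],
      notification_date = as_of_date,
      outreach_planned_date = as_of_date + 7L,
      stringsAsFactors = FALSE)
    registry <- advance(registry, registry$patient_id[i], "notify_provider",
                        timestamp = format(as_of_date))
  }
  notifications <- if (length(notif)) do.call(rbind, notif) else
    data.frame(provider_id = character(), patient_id = character(),
               notification_date = as.Date(character()),
               outreach_planned_date = as.Date(character()),
               stringsAsFactors = FALSE)
  list(notifications = notifications, registry = registry)
}
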