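# The guideline rule engine: target-population filter and declarative
# family-history criteria for hereditary breast/ovarian and colorectal
# cancer risk.
#
# The engine is criteria-agnostic: every threshold lives in a ruleset
# config (YAML), so correcting or localizing a guideline is a config edit,
# not a code change.

#' Construct an eligibility criterion
#'
#' One declarative family-history rule. A relative counts toward the
#' criterion iff it is a blood relative, its degree is in
#' `allowed_degrees`, its sex matches `relative_sex` (when set), and it has
#' at least one cancer event whose category is in `categories`. The
#' criterion is met when at least `min_relatives` relatives count, at least
#' `min_onset_qualifying` of them have a qualifying event diagnosed at or
#' before `max_onset_age`, the same-lineage requirement (if any) holds on a
#' single side, and the proband carries `ancestry_required` (if set).
#'
#' @param criterion_id unique id string (e.g. `"B1"`).
#' @param disease_track `"breast_ovarian"` or `"colorectal"`.
#' @param categories character vector of cancer categories.
#' @param min_relatives integer >= 1.
#' @param allowed_degrees integer subset of `c(1, 2, 3)`.
#' @param max_onset_age optional threshold T ("diagnosed at or before T",
#'   inclusive); must be present iff `min_onset_qualifying >= 1`.
#' @param min_onset_qualifying how many counted relatives must individually
#'   satisfy `max_onset_age` (0 = age-free criterion).
#' @param same_lineage_required logical; when `TRUE` the counted relatives
#'   must sit on one lineage side (first-degree relatives count toward
#'   either side).
#' @param relative_sex optional `"female"` or `"male"`.
#' @param ancestry_required optional ancestry flag the proband must carry
#'   (e.g. `"ashkenazi_jewish"`).
#' @param enabled logical; disabled criteria are skipped by
#'   [evaluate_patient()].
#' @return object of class `fhh_criterion`.
#' @export
criterion <- function(criterion_id, disease_track = c("breast_ovarian", "colorectal"),
                      categories, min_relatives = 1L,
                      allowed_degrees = c(1L, 2L),
                      max_onset_age = NULL, min_onset_qualifying = 0L,
                      same_lineage_required = FALSE, relative_sex = NULL,
                      ancestry_required = NULL, enabled = TRUE) {
  disease_track <- match.arg(disease_track)
  stopifnot(nzchar(criterion_id),
            all(categories %in% setdiff(.CANCER_CATEGORIES, "non_cancer")),
            min_relatives >= 1L,
            all(allowed_degrees %in% 1:3), length(allowed_degrees) >= 1L,
            min_onset_qualifying >= 0L,
            min_onset_qualifying <= min_relatives)
  if (is.null(max_onset_age) != (min_onset_qualifying == 0L)) {
    stop("criterion ", criterion_id,
         ": max_onset_age must be present iff min_onset_qualifying >= 1")
  }
  if (!is.null(max_onset_age)) stopifnot(max_onset_age > 0L)
  if (!is.null(relative_sex)) relative_sex <- match.arg(relative_sex,
                                                        c("female", "male"))
  structure(list(criterion_id = criterion_id,
                 disease_track = disease_track,
                 categories = as.character(categories),
                 min_relatives = as.integer(min_relatives),
                 allowed_degrees = as.integer(sort(allowed_degrees)),
                 max_onset_age = if (is.null(max_onset_age)) NULL else
                   as.integer(max_onset_age),
                 min_onset_qualifying = as.integer(min_onset_qualifying),
                 same_lineage_required = isTRUE(same_lineage_required),
                 relative_sex = relative_sex,
                 ancestry_required = ancestry_required,
                 enabled = isTRUE(enabled)),
            class = "fhh_criterion")
}

#' Construct a ruleset
#'
#' @param version version string of the criteria collection.
#' @param criteria list of [criterion()]s; ids must be unique and both
#'   disease tracks must be represented.
#' @return object of class `fhh_ruleset`.
#' @export
ruleset <- function(version, criteria) {
  ids <- vapply(criteria, `[[`, "", "criterion_id")
  if (anyDuplicated(ids)) {
    stop("duplicate criterion ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  }
  tracks <- vapply(criteria, `[[`, "", "disease_track")
  if (!all(c("breast_ovarian", "colorectal") %in% tracks)) {
    stop("ruleset must contain at least one criterion per disease track")
  }
  structure(list(version = version, criteria = criteria),
            class = "fhh_ruleset")
}

#' @export
print.fhh_ruleset <- function(x, ...) {
  cat(sprintf("<fhh_ruleset %s: %d criteria (%d enabled)>\n", x$version,
              length(x$criteria),
              sum(vapply(x$criteria, `[[`, TRUE, "enabled"))))
  for (cr in x$criteria) {
    cat(sprintf("  %-4s [%s] >=%d relative(s) deg{%s} with {%s}%s%s%s%s\n",
                cr$criterion_id, cr$disease_track, cr$min_relatives,
                paste(cr$allowed_degrees, collapse = ","),
                paste(cr$categories, collapse = ","),
                if (!is.null(cr$max_onset_age))
                  sprintf(", >=%d dx at <=%d", cr$min_onset_qualifying,
                          cr$max_onset_age) else "",
                if (cr$same_lineage_required) ", same side" else "",
                if (!is.null(cr$relative_sex))
                  paste0(", ", cr$relative_sex, " relatives") else "",
                if (!cr$enabled) " [disabled]" else ""))
  }
  invisible(x)
}

#' Load a ruleset from a YAML (or JSON) config file
#'
#' The file carries a `version` string and a `criteria` array whose entries
#' use the [criterion()] fields verbatim; each entry is validated on load.
#'
#' @param path config file path.
#' @return an `fhh_ruleset`.
#' @export
load_ruleset <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  crit <- lapply(cfg$criteria, function(cc) {
    criterion(criterion_id = cc$criterion_id,
              disease_track = cc$disease_track,
              categories = unlist(cc$categories),
              min_relatives = cc$min_relatives %||% 1L,
              allowed_degrees = unlist(cc$allowed_degrees) %||% c(1L, 2L),
              max_onset_age = cc$max_onset_age,
              min_onset_qualifying = cc$min_onset_qualifying %||% 0L,
              same_lineage_required = cc$same_lineage_required %||% FALSE,
              relative_sex = cc$relative_sex,
              ancestry_required = cc$ancestry_required,
              enabled = cc$enabled %||% TRUE)
  })
  ruleset(cfg$version %||% "unversioned", crit)
}

#' The default NCCN-2018-derived ruleset
#'
#' Loads the ruleset shipped with the package
#' (`inst/extdata/ruleset-nccn-2018-derived.yaml`), a set of
#' family-history criteria derived from the 2018 NCCN guidelines for
#' genetic evaluation of hereditary breast/ovarian and colorectal cancer.
#' The Ashkenazi-ancestry criterion (`B6`) ships disabled: sites that map
#' religion codes to ancestry flags can enable it in a copy of the config.
#'
#' @return an `fhh_ruleset`.
#' @export
default_ruleset <- function() {
  cache_get("default_ruleset", function() {
    load_ruleset(system.file("extdata", "ruleset-nccn-2018-derived.yaml",
                             package = "fhhscreen", mustWork = TRUE))
  })
}

#' Target-population configuration
#'
#' The screening population: patients whose completed (floor) age at
#' `as_of_date` is within `[min_age_years, max_age_years]` and who had at
#' least one completed primary-care encounter within the lookback window
#' (both window ends inclusive).
#'
#' @param as_of_date screening reference date.
#' @param min_age_years,max_age_years inclusive age bounds (defaults 25
#'   and 60).
#' @param lookback_years encounter lookback (default 3).
#' @param primary_care_encounter_types encounter type codes that count as
#'   primary care.
#' @return object of class `target_population_config`.
#' @export
target_population_config <- function(as_of_date,
                                     min_age_years = 25L,
                                     max_age_years = 60L,
                                     lookback_years = 3L,
                                     primary_care_encounter_types = "primary_care") {
  as_of_date <- as.Date(as_of_date)
  stopifnot(min_age_years <= max_age_years, lookback_years > 0L,
            length(primary_care_encounter_types) >= 1L)
  structure(list(as_of_date = as_of_date,
                 min_age_years = as.integer(min_age_years),
                 max_age_years = as.integer(max_age_years),
                 lookback_years = as.integer(lookback_years),
                 primary_care_encounter_types = primary_care_encounter_types),
            class = "target_population_config")
}

#' Is a patient in the target population?
#'
#' @param demo one row of a cohort's `demographics` data frame.
#' @param encounters the patient's encounters (data frame).
#' @param cfg a [target_population_config()].
#' @return `TRUE`/`FALSE`; a missing birth date yields `FALSE` with a
#'   logged reason.
#' @export
in_target_population <- function(demo, encounters, cfg) {
  if (is.na(demo$birth_date)) {
    message("patient ", demo$patient_id, ": missing birth_date; excluded ",
            "from target population")
    return(FALSE)
  }
  age <- floor_age(demo$birth_date, cfg$as_of_date)
  if (age < cfg$min_age_years || age > cfg$max_age_years) return(FALSE)
  if (nrow(encounters) == 0L) return(FALSE)
  window_start <- add_years(cfg$as_of_date, -cfg$lookback_years)
  ok <- encounters$status == "completed" &
    encounters$encounter_type %in% cfg$primary_care_encounter_types &
    !is.na(encounters$date) &
    encounters$date >= window_start & encounters$date <= cfg$as_of_date
  any(ok, na.rm = TRUE)
}

#' Does an onset estimate satisfy an age threshold?
#'
#' Threshold semantics are "diagnosed at or before T" (inclusive). In
#' `conservative` mode the whole uncertainty interval must lie at or below
#' T (`high_years <= T`): a fuzzy onset only satisfies the criterion when
#' it cannot fail it, which favours positive predictive value. In
#' `optimistic` mode overlap suffices (`low_years <= T`). Unknown onsets
#' never satisfy an age threshold.
#'
#' @param onset an [onset_estimate()].
#' @param threshold_T positive integer age threshold.
#' @param mode `"conservative"` (default) or `"optimistic"`.
#' @return logical.
#' @export
onset_satisfies <- function(onset, threshold_T,
                            mode = c("conservative", "optimistic")) {
  mode <- match.arg(mode)
  stopifnot(threshold_T > 0)
  if (onset$kind == "unknown") return(FALSE)
  if (mode == "conservative") onset$high_years <= threshold_T
  else onset$low_years <= threshold_T
}

# Does a relative have >=1 event in the criterion's categories?
rel_counts_toward <- function(rel, crit) {
  if (!isTRUE(rel$blood_relative)) return(FALSE)
  if (!rel$degree %in% as.character(crit$allowed_degrees)) return(FALSE)
  if (!is.null(crit$relative_sex) && rel$sex != crit$relative_sex) return(FALSE)
  any(vapply(rel$events, function(e) e$category %in% crit$categories, TRUE))
}

# Does a relative have >=1 event in the categories that satisfies the
# criterion's onset threshold?
rel_onset_qualifies <- function(rel, crit, mode) {
  if (is.null(crit$max_onset_age)) return(TRUE)
  any(vapply(rel$events, function(e) {
    e$category %in% crit$categories &&
      onset_satisfies(e$onset, crit$max_onset_age, mode)
  }, TRUE))
}

# Can a relative be attributed to a given lineage side? First-degree
# relatives sit on the proband's own line and may count toward either
# side; unknown lineage combines toward a side only in optimistic mode.
rel_on_side <- function(rel, side, mode) {
  if (rel$lineage == "proband_line_not_applicable") return(TRUE)
  if (rel$lineage == side) return(TRUE)
  if (rel$lineage == "unknown") return(mode == "optimistic")
  FALSE
}

#' Evaluate one criterion against a patient's normalized relatives
#'
#' See [criterion()] for the counting semantics. The returned
#' `contributing` ids form the audit trace: removing all of them from the
#' fact base makes the criterion unmet.
#'
#' @param crit an [criterion()].
#' @param relatives list of [normalize_relative()] results.
#' @param patient optional one-row demographics (used for
#'   `ancestry_required`; its `ancestry_flags` entry is consulted).
#' @param mode onset interval mode, see [onset_satisfies()].
#' @return `list(met = logical, contributing = character vector of
#'   record_ids)`.
#' @export
evaluate_criterion <- function(crit, relatives, patient = NULL,
                               mode = c("conservative", "optimistic")) {
  mode <- match.arg(mode)
  if (!is.null(crit$ancestry_required)) {
    flags <- patient_ancestry_flags(patient)
    if (!crit$ancestry_required %in% flags) {
      return(list(met = FALSE, contributing = character()))
    }
  }
  counted <- Filter(function(r) rel_counts_toward(r, crit), relatives)
  if (length(counted) == 0L) return(list(met = FALSE, contributing = character()))
  qualifies <- vapply(counted, function(r) rel_onset_qualifies(r, crit, mode),
                      TRUE)
  ids <- vapply(counted, `[[`, "", "record_id")

  if (!crit$same_lineage_required) {
    met <- length(counted) >= crit$min_relatives &&
      sum(qualifies) >= crit$min_onset_qualifying
    return(list(met = met, contributing = if (met) ids else character()))
  }

  contributing <- character()
  met <- FALSE
  for (side in c("maternal", "paternal")) {
    on_side <- vapply(counted, function(r) rel_on_side(r, side, mode), TRUE)
    if (sum(on_side) >= crit$min_relatives &&
        sum(on_side & qualifies) >= crit$min_onset_qualifying) {
      met <- TRUE
      contributing <- union(contributing, ids[on_side])
    }
  }
  list(met = met, contributing = contributing)
}

patient_ancestry_flags <- function(patient) {
  if (is.null(patient)) return(character())
  flags <- patient$ancestry_flags
  if (is.null(flags)) return(character())
  if (is.list(flags)) flags <- unlist(flags)
  flags[!is.na(flags)]
}

#' Evaluate every criterion of a ruleset for one patient
#'
#' All enabled criteria are evaluated — no short-circuiting — so the audit
#' trace is complete. The proband's own cancer history is never consulted:
#' this is FHH-only screening of unaffected patients.
#'
#' @param patient one-row demographics data frame (may carry an
#'   `ancestry_flags` list column).
#' @param relatives list of [normalize_relative()] results.
#' @param rules an `fhh_ruleset` (default [default_ruleset()]).
#' @param mode onset interval mode, see [onset_satisfies()].
#' @param evaluated_at evaluation date recorded in the result.
#' @return object of class `eligibility_result`: `patient_id`,
#'   `breast_met`, `colorectal_met`, `fired_criteria` (list of
#'   `list(criterion_id, contributing)`), `evaluated_at`.
#' @export
evaluate_patient <- function(patient, relatives, rules = default_ruleset(),
                             mode = c("conservative", "optimistic"),
                             evaluated_at = Sys.Date()) {
  mode <- match.arg(mode)
  fired <- list()
  breast <- FALSE; crc <- FALSE
  for (crit in rules$criteria) {
    if (!crit$enabled) next
    res <- evaluate_criterion(crit, relatives, patient, mode)
    if (res$met) {
      fired[[length(fired) + 1L]] <- list(criterion_id = crit$criterion_id,
                                          contributing = res$contributing)
      if (crit$disease_track == "breast_ovarian") breast <- TRUE
      if (crit$disease_track == "colorectal") crc <- TRUE
    }
  }
  structure(list(patient_id = patient$patient_id,
                 breast_met = breast, colorectal_met = crc,
                 fired_criteria = fired,
                 evaluated_at = as.Date(evaluated_at)),
            class = "eligibility_result")
}

#' @export
print.eligibility_result <- function(x, ...) {
  cat(sprintf("<eligibility %s: breast=%s colorectal=%s; fired: %s>\n",
              x$patient_id, x$breast_met, x$colorectal_met,
              if (length(x$fired_criteria))
                paste(vapply(x$fired_criteria, `[[`, "", "criterion_id"),
                      collapse = ", ") else "none"))
  invisible(x)
}
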