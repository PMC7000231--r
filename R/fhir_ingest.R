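# Ingest of FHIR-R4-style JSON (Patient, Encounter, FamilyMemberHistory)
# into the internal cohort model.
#
# Only the fields the screening pipeline consumes are read; everything else
# in a resource is ignored. Both a single Bundle (entry array) and NDJSON
# (one resource per line) are accepted — EHR export adaptors vary, so
# tolerance beats strictness here.

EXT_PRIOR_COUNSELING <- "https://fhhscreen.example/fhir/ext/prior-genetic-counseling"
EXT_PREFERRED_CONTACT <- "https://fhhscreen.example/fhir/ext/preferred-contact"
EXT_RELIGION <- "http://hl7.org/fhir/StructureDefinition/patient-religion"

strip_ref <- function(ref) sub("^[A-Za-z]+/", "", ref %||% NA_character_)

# FHIR Encounter.status -> internal status vocabulary
ENC_STATUS_MAP <- c(finished = "completed", completed = "completed",
                    cancelled = "cancelled", noshow = "no_show",
                    "no_show" = "no_show", planned = "planned")

parse_patient <- function(res) {
  religion <- NA_character_
  prior <- FALSE
  contact <- "unknown"
  provider <- NA_character_
  for (ext in res$extension %||% list()) {
    url <- ext$url %||% ""
    if (url == EXT_RELIGION) {
      religion <- ext$valueCodeableConcept$coding[[1]]$code %||%
        ext$valueCodeableConcept$text %||% NA_character_
    } else if (url == EXT_PRIOR_COUNSELING) {
      prior <- isTRUE(ext$valueBoolean)
    } else if (url == EXT_PREFERRED_CONTACT) {
      contact <- ext$valueCode %||% "unknown"
    }
  }
  gp <- res$generalPractitioner
  if (!is.null(gp) && length(gp)) provider <- strip_ref(gp[[1]]$reference)
  sex <- res$gender %||% "unknown"
  if (!sex %in% c("female", "male", "other", "unknown")) sex <- "unknown"
  data.frame(
    patient_id = res$id %||% NA_character_,
    birth_date = parse_fhir_date(res$birthDate %||% NA_character_),
    sex = sex,
    religion_code = religion,
    prior_genetic_counseling = prior,
    preferred_contact = if (contact %in% c("portal", "mail")) contact else "unknown",
    provider_id = provider,
    stringsAsFactors = FALSE)
}

parse_encounter <- function(res) {
  status_raw <- res$status %||% NA_character_
  status <- unname(ENC_STATUS_MAP[status_raw])
  if (is.na(status)) status <- status_raw
  type <- NA_character_
  if (!is.null(res$type) && length(res$type)) {
    t1 <- res$type[[1]]
    if (!is.null(t1$coding) && length(t1$coding)) {
      type <- t1$coding[[1]]$code %||% t1$coding[[1]]$display %||% NA_character_
    }
    if (is.na(type)) type <- t1$text %||% NA_character_
  }
  loc <- NA_character_
  if (!is.null(res$location) && length(res$location)) {
    loc <- res$location[[1]]$location$display %||% NA_character_
  }
  data.frame(
    patient_id = strip_ref(res$subject$reference %||% NA_character_),
    encounter_type = type,
    date = parse_fhir_date(res$period$start %||% NA_character_),
    status = status,
    location = loc,
    stringsAsFactors = FALSE)
}

parse_fmh <- function(res) {
  rel <- res$relationship$text %||% NA_character_
  if (is.na(rel) && !is.null(res$relationship$coding) &&
      length(res$relationship$coding)) {
    rel <- res$relationship$coding[[1]]$display %||%
      res$relationship$coding[[1]]$code %||% NA_character_
  }
  diagnoses <- lapply(res$condition %||% list(), function(cnd) {
    term <- cnd$code$text %||% NA_character_
    if (is.na(term) && !is.null(cnd$code$coding) && length(cnd$code$coding)) {
      term <- cnd$code$coding[[1]]$display %||% cnd$code$coding[[1]]$code %||%
        NA_character_
    }
    age <- cnd$onsetAge$value %||% NA_real_
    note <- ""
    if (!is.null(cnd$note) && length(cnd$note)) {
      note <- cnd$note[[1]]$text %||% ""
    }
    # onsetString carries free text; route it to the comment pathway
    if (!is.null(cnd$onsetString)) {
      note <- if (nzchar(note)) paste(cnd$onsetString, note) else cnd$onsetString
    }
    list(condition_term = term,
         onset_age_years = if (is.na(age)) NULL else as.integer(age),
         comment = note)
  })
  record_comment <- ""
  if (!is.null(res$note) && length(res$note)) {
    record_comment <- res$note[[1]]$text %||% ""
  }
  family_member_record(
    record_id = res$id %||% NA_character_,
    patient_id = strip_ref(res$patient$reference %||% NA_character_),
    relationship_term = rel,
    diagnoses = diagnoses,
    date_captured = parse_fhir_date(res$date %||% NA_character_),
    record_comment = record_comment)
}

#' Construct a raw family-member-history record
#'
#' One relative's FHH entry as documented: the relationship term (local code
#' or text), the list of diagnoses (each with an optional structured onset
#' age and an optional short free-text comment), the capture date, and an
#' optional record-level comment.
#'
#' @param record_id,patient_id identifier strings.
#' @param relationship_term non-empty relationship string.
#' @param diagnoses list of `list(condition_term, onset_age_years, comment)`.
#' @param date_captured `Date`.
#' @param record_comment free text, possibly empty.
#' @return object of class `family_member_record`.
#' @export
family_member_record <- function(record_id, patient_id, relationship_term,
                                 diagnoses = list(),
                                 date_captured = as.Date(NA),
                                 record_comment = "") {
  if (is.na(relationship_term) || !nzchar(trimws(relationship_term))) {
    stop("relationship_term must be non-empty (record ", record_id, ")")
  }
  for (d in diagnoses) {
    if (!is.null(d$onset_age_years) && !is.na(d$onset_age_years)) {
      if (d$onset_age_years < 0 || d$onset_age_years > 120) {
        stop("onset_age_years out of [0, 120] in record ", record_id)
      }
    }
  }
  structure(list(record_id = record_id, patient_id = patient_id,
                 relationship_term = relationship_term,
                 diagnoses = diagnoses, date_captured = date_captured,
                 record_comment = record_comment %||% ""),
            class = "family_member_record")
}

#' Read a cohort from FHIR-style JSON files
#'
#' Accepts Bundle files (a JSON object with an `entry` array of
#' `resource`s) or NDJSON (one resource per line). Resource types other
#' than Patient, Encounter, and FamilyMemberHistory are skipped with a
#' warning; FamilyMemberHistory records whose patient reference does not
#' resolve to a Patient in the same cohort are logged as orphans and
#' excluded.
#'
#' @param paths character vector of file paths.
#' @param format `"bundle_json"` or `"ndjson"`; the default guesses from
#'   the file extension (`.ndjson` vs anything else).
#' @return an `fhh_cohort`: a list with `demographics` (data frame),
#'   `encounters` (data frame), `fhh` (list of
#'   [family_member_record()]s), and `log` (read/skip/orphan counts).
#' @export
read_cohort <- function(paths, format = c("auto", "bundle_json", "ndjson")) {
  format <- match.arg(format)
  resources <- list()
  for (p in paths) {
    if (!file.exists(p)) stop("file not found: ", p)
    fmt <- format
    if (fmt == "auto") {
      fmt <- if (grepl("\\.ndjson$", p)) "ndjson" else "bundle_json"
    }
    if (fmt == "ndjson") {
      lines <- readLines(p, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      for (i in seq_along(lines)) {
        res <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                        error = function(e) {
                          stop("parse error in ", p, " line ", i, ": ",
                               conditionMessage(e), call. = FALSE)
                        })
        resources[[length(resources) + 1L]] <- res
      }
    } else {
      bundle <- tryCatch(jsonlite::fromJSON(p, simplifyVector = FALSE),
                         error = function(e) {
                           stop("parse error in ", p, ": ",
                                conditionMessage(e), call. = FALSE)
                         })
      entries <- bundle$entry %||% list()
      for (e in entries) {
        if (!is.null(e$resource)) {
          resources[[length(resources) + 1L]] <- e$resource
        }
      }
    }
  }
  build_cohort(resources)
}

build_cohort <- function(resources) {
  demo <- list(); enc <- list(); fmh <- list()
  n_skipped <- 0L; skipped_types <- character()
  for (res in resources) {
    rt <- res$resourceType %||% ""
    if (rt == "Patient") {
      demo[[length(demo) + 1L]] <- parse_patient(res)
    } else if (rt == "Encounter") {
      enc[[length(enc) + 1L]] <- parse_encounter(res)
    } else if (rt == "FamilyMemberHistory") {
      fmh[[length(fmh) + 1L]] <- parse_fmh(res)
    } else {
      n_skipped <- n_skipped + 1L
      skipped_types <- c(skipped_types, rt)
    }
  }
  demographics <- if (length(demo)) do.call(rbind, demo) else
    data.frame(patient_id = character(), birth_date = as.Date(character()),
               sex = character(), religion_code = character(),
               prior_genetic_counseling = logical(),
               preferred_contact = character(), provider_id = character(),
               stringsAsFactors = FALSE)
  if (anyDuplicated(demographics$patient_id)) {
    stop("duplicate patient_id in cohort: ",
         paste(unique(demographics$patient_id[
           duplicated(demographics$patient_id)]), collapse = ", "))
  }
  encounters <- if (length(enc)) do.call(rbind, enc) else
    data.frame(patient_id = character(), encounter_type = character(),
               date = as.Date(character()), status = character(),
               location = character(), stringsAsFactors = FALSE)

  known <- demographics$patient_id
  is_orphan <- vapply(fmh, function(r) !(r$patient_id %in% known), TRUE)
  n_orphans <- sum(is_orphan)
  if (n_orphans > 0L) {
    message("read_cohort: ", n_orphans,
            " FamilyMemberHistory record(s) reference unknown patients; excluded")
  }
  if (n_skipped > 0L) {
    warning("read_cohort: skipped ", n_skipped,
            " resource(s) of unhandled type: ",
            paste(unique(skipped_types), collapse = ", "), call. = FALSE)
  }
  structure(list(
    demographics = demographics,
    encounters = encounters,
    fhh = fmh[!is_orphan],
    log = list(n_patients = nrow(demographics),
               n_encounters = nrow(encounters),
               n_fhh = sum(!is_orphan),
               n_skipped = n_skipped,
               n_orphans = as.integer(n_orphans))),
    class = "fhh_cohort")
}

#' @export
print.fhh_cohort <- function(x, ...) {
  cat(sprintf("<fhh_cohort: %d patients, %d encounters, %d FHH records (%d orphaned, %d resources skipped)>\n",
              x$log$n_patients, x$log$n_encounters, x$log$n_fhh,
              x$log$n_orphans, x$log$n_skipped))
  invisible(x)
}
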