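# Fixture builders used across the suite. Everything is constructed in
# code; no stored data files.

# a normalized relative built directly (bypasses terminology on purpose:
# rule-engine tests control the pedigree facts exactly)
make_rel <- function(record_id, degree, lineage = "unknown", sex = "unknown",
                     blood = TRUE, events = list()) {
  if (degree %in% c("1", "not_blood")) lineage <- "proband_line_not_applicable"
  structure(list(record_id = record_id, patient_id = "PX",
                 degree = degree, lineage = lineage, sex = sex,
                 blood_relative = blood, events = events,
                 date_captured = as.Date("2019-01-01"), logs = character()),
            class = "normalized_relative")
}

make_event <- function(category, low = NA, high = low, ref = "r") {
  onset <- if (is.na(low)) onset_estimate("unknown") else {
    kind <- if (low == high) "exact" else "range"
    onset_estimate(kind, low, high)
  }
  cancer_event(category, onset, ref)
}

make_demo <- function(patient_id = "P1", birth_date = "1979-01-15",
                      sex = "female", prior = FALSE,
                      provider = "PCP1", ancestry = character()) {
  d <- data.frame(patient_id = patient_id,
                  birth_date = as.Date(birth_date), sex = sex,
                  religion_code = NA_character_,
                  prior_genetic_counseling = prior,
                  preferred_contact = "portal", provider_id = provider,
                  stringsAsFactors = FALSE)
  d$ancestry_flags <- list(ancestry)
  d
}

make_enc <- function(patient_id = "P1", type = "primary_care",
                     date = "2018-06-01", status = "completed") {
  data.frame(patient_id = patient_id, encounter_type = type,
             date = as.Date(date), status = status,
             location = NA_character_, stringsAsFactors = FALSE)
}

no_enc <- function() make_enc()[0, , drop = FALSE]

# FHIR resource builders (plain lists, written with jsonlite)
fhir_patient <- function(id, birthDate = "1980-05-01", gender = "female",
                         extra = list()) {
  c(list(resourceType = "Patient", id = id, birthDate = birthDate,
         gender = gender), extra)
}

fhir_fmh <- function(id, patient, relationship, conditions = list(),
                     note = NULL, date = "2019-01-01") {
  res <- list(resourceType = "FamilyMemberHistory", id = id,
              patient = list(reference = paste0("Patient/", patient)),
              date = date, relationship = list(text = relationship))
  if (length(conditions)) res$condition <- conditions
  if (!is.null(note)) res$note <- list(list(text = note))
  res
}

fhir_condition <- function(text, onset_age = NULL, note = NULL,
                           onset_string = NULL) {
  cnd <- list(code = list(text = text))
  if (!is.null(onset_age)) cnd$onsetAge <- list(value = onset_age, unit = "a")
  if (!is.null(note)) cnd$note <- list(list(text = note))
  if (!is.null(onset_string)) cnd$onsetString <- onset_string
  cnd
}

write_bundle <- function(resources, path) {
  bundle <- list(resourceType = "Bundle", type = "collection",
                 entry = lapply(resources, function(r) list(resource = r)))
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  path
}

write_ndjson <- function(resources, path) {
  writeLines(vapply(resources, function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA))
  }, ""), path)
  path
}

# a small registry ready for outreach tests
make_registry <- function(n = 3, status = "identified") {
  new_registry(patient_id = sprintf("P%02d", seq_len(n)),
               breast_met = rep(TRUE, n),
               colorectal_met = rep(FALSE, n),
               fired_criteria = rep("B1", n),
               status = rep(status, n),
               provider_id = rep("PCP1", n))
}

# drive one entry through: identified -> ... -> target disposition
drive_to <- function(reg, pid, events) {
  for (ev in events) reg <- advance(reg, pid, ev, timestamp = "t")
  reg
}

# build a registry realizing given disposition counts by driving entries
# through the state machine
registry_with_dispositions <- function(n_sched_only, n_pending, n_completed,
                                       n_neg, n_pos, n_no_test, n_declined,
                                       n_consider, n_unreach, n_no_need) {
  n <- n_sched_only + n_pending + n_completed + n_neg + n_pos + n_no_test +
    n_declined + n_consider + n_unreach + n_no_need
  reg <- make_registry(n)
  base <- c("notify_provider", "send_outreach")
  i <- 0L
  take <- function(k, evs) {
    for (j in seq_len(k)) {
      i <<- i + 1L
      reg <<- drive_to(reg, sprintf("P%02d", i), evs)
    }
  }
  take(n_sched_only, c(base, "schedule"))
  take(n_pending, c(base, "schedule", "mark_pending"))
  take(n_completed, c(base, "schedule", "visit_completed"))
  take(n_neg, c(base, "schedule", "visit_completed", "test_negative"))
  take(n_pos, c(base, "schedule", "visit_completed", "test_positive"))
  take(n_no_test, c(base, "schedule", "visit_completed", "no_test"))
  take(n_declined, c(base, "decline"))
  take(n_consider, c(base, "consider_future"))
  take(n_unreach, c(base, rep("phone_no_answer", 3), "mark_unreachable"))
  take(n_no_need, c(base, "no_need"))
  reg
}
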