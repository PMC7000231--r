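# The screening registry: one row per qualifying patient, tracked through
# the outreach lifecycle, with CSV / JSON persistence that round-trips
# field-for-field.

REGISTRY_STATUSES <- c("identified", "prior_counseling_excluded",
                       "provider_notified", "outreach_sent", "scheduled",
                       "declined", "consider_future", "unreachable",
                       "no_need", "appointment_pending", "completed_visit",
                       "tested_negative", "tested_positive",
                       "completed_no_test")

empty_history <- function() {
  data.frame(timestamp = character(), event = character(),
             from_status = character(), to_status = character(),
             stringsAsFactors = FALSE)
}

#' Construct a registry
#'
#' A registry is a data frame (class `fhh_registry`) with one row per
#' patient who met at least one disease-track criterion: the track flags,
#' the fired criterion ids (audit trace), the current outreach status, the
#' contact-attempt counter (at most 1 initial message + 3 phone calls = 4),
#' the designated provider, and an append-only transition history.
#'
#' @param patient_id character vector.
#' @param breast_met,colorectal_met logical vectors.
#' @param fired_criteria character vector of comma-separated criterion ids.
#' @param status initial statuses (default `"identified"`).
#' @param contact_attempts integer vector.
#' @param provider_id character vector (may be `NA`).
#' @param history list of history data frames (one per entry).
#' @return an `fhh_registry` data frame ordered by `patient_id`.
#' @export
new_registry <- function(patient_id = character(),
                         breast_met = logical(),
                         colorectal_met = logical(),
                         fired_criteria = character(),
                         status = rep("identified", length(patient_id)),
                         contact_attempts = rep(0L, length(patient_id)),
                         provider_id = rep(NA_character_, length(patient_id)),
                         history = rep(list(empty_history()),
                                       length(patient_id))) {
  stopifnot(all(status %in% REGISTRY_STATUSES),
            all(contact_attempts >= 0L), all(contact_attempts <= 4L))
  reg <- data.frame(patient_id = as.character(patient_id),
                    breast_met = as.logical(breast_met),
                    colorectal_met = as.logical(colorectal_met),
                    fired_criteria = as.character(fired_criteria),
                    status = as.character(status),
                    contact_attempts = as.integer(contact_attempts),
                    provider_id = as.character(provider_id),
                    stringsAsFactors = FALSE)
  reg$history <- history
  reg <- reg[order(reg$patient_id), , drop = FALSE]
  rownames(reg) <- NULL
  class(reg) <- c("fhh_registry", "data.frame")
  reg
}

serialize_history <- function(h) {
  if (is.null(h) || nrow(h) == 0L) return("")
  paste(apply(h, 1L, paste, collapse = "|"), collapse = ";")
}

deserialize_history <- function(s) {
  if (is.na(s) || !nzchar(s)) return(empty_history())
  rows <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "|", fixed = TRUE)
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- names(empty_history())
  out
}

#' Write a registry to disk
#'
#' CSV output is RFC-4180 UTF-8 with a header row (an empty registry writes
#' a header-only file); JSON output is an array of objects. Rows are
#' written in stable `patient_id` order, and [read_registry()] reproduces
#' the registry field-for-field.
#'
#' @param registry an `fhh_registry`, see [new_registry()].
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path, format = c("csv", "json")) {
  format <- match.arg(format)
  reg <- registry[order(registry$patient_id), , drop = FALSE]
  flat <- as.data.frame(reg[setdiff(names(reg), "history")])
  flat$history <- vapply(reg$history, serialize_history, "")
  if (format == "csv") {
    utils::write.csv(flat, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(flat, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a registry written by [write_registry()]
#'
#' @param path file path.
#' @param format `"csv"`, `"json"`, or `"auto"` (by extension).
#' @return an `fhh_registry`.
#' @export
read_registry <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path)) "json" else "csv"
  }
  if (format == "csv") {
    flat <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(patient_id = "character",
                                           fired_criteria = "character",
                                           status = "character",
                                           provider_id = "character",
                                           history = "character"),
                            na.strings = character())
  } else {
    flat <- jsonlite::fromJSON(path)
    if (length(flat) == 0L || nrow(as.data.frame(flat)) == 0L) {
      return(new_registry())
    }
    flat <- as.data.frame(flat, stringsAsFactors = FALSE)
  }
  if (nrow(flat) == 0L) return(new_registry())
  prov <- as.character(flat$provider_id)
  prov[!nzchar(prov) | is.na(prov)] <- NA_character_
  new_registry(patient_id = flat$patient_id,
               breast_met = as.logical(flat$breast_met),
               colorectal_met = as.logical(flat$colorectal_met),
               fired_criteria = ifelse(is.na(flat$fired_criteria), "",
                                       flat$fired_criteria),
               status = flat$status,
               contact_attempts = as.integer(flat$contact_attempts),
               provider_id = prov,
               history = lapply(as.character(flat$history),
                                deserialize_history))
}

#' @export
print.fhh_registry <- function(x, ...) {
  cat(sprintf("<fhh_registry: %d entries>\n", nrow(x)))
  if (nrow(x)) {
    print(table(status = x$status))
  }
  invisible(x)
}
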