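# Age-of-onset and lineage extraction from short free-text FHH comments.
#
# Structured FHH entries are often supplemented with short comments carrying
# the age of diagnosis as a fuzzy range ("early 30s", "premenopausal") or the
# lineage side ("maternal side"). These rule-based extractors turn such
# phrases into computable intervals so guideline age thresholds can be
# evaluated against them.

#' Construct an age-of-onset estimate
#'
#' An onset estimate is an interval `[low_years, high_years]` in whole years
#' plus a kind tag. `exact` estimates have `low == high`; `unknown` estimates
#' carry no bounds (`NA`). Intervals are capped at 120 years.
#'
#' @param kind one of `"exact"`, `"range"`, `"qualitative"`, `"unknown"`.
#' @param low_years,high_years integer interval bounds (omitted for
#'   `"unknown"`).
#' @param source `"structured"` if the age came from a structured field,
#'   `"comment"` if extracted from free text.
#' @return an object of class `onset_estimate`.
#' @export
onset_estimate <- function(kind = c("unknown", "exact", "range", "qualitative"),
                           low_years = NA_integer_, high_years = NA_integer_,
                           source = c("comment", "structured")) {
  kind <- match.arg(kind)
  source <- match.arg(source)
  if (kind == "unknown") {
    low_years <- NA_integer_
    high_years <- NA_integer_
  } else {
    low_years <- as.integer(low_years)
    high_years <- as.integer(high_years)
    stopifnot(!is.na(low_years), !is.na(high_years),
              low_years >= 0L, high_years >= low_years, high_years <= 120L)
    if (kind == "exact") stopifnot(low_years == high_years)
  }
  structure(list(kind = kind, low_years = low_years,
                 high_years = high_years, source = source),
            class = "onset_estimate")
}

#' @export
print.onset_estimate <- function(x, ...) {
  if (x$kind == "unknown") {
    cat("<onset: unknown>\n")
  } else {
    cat(sprintf("<onset %s [%d, %d] from %s>\n",
                x$kind, x$low_years, x$high_years, x$source))
  }
  invisible(x)
}

#' Qualitative onset phrase table
#'
#' The phrase inventory for qualitative age-of-onset expressions, shipped as
#' a plain-text table (`inst/extdata/onset-qualitative.tsv`) so sites can
#' extend it. Each row is a case-insensitive regular expression and the
#' interval (in years) the phrase is taken to denote. The shipped
#' conventions align qualitative phrases with the criterion thresholds they
#' clinically signal: "premenopausal" denotes \[0, 50\], "early onset" and
#' "young" denote \[0, 45\].
#'
#' @param path optional path to an alternative table (same columns:
#'   `pattern`, `low`, `high`).
#' @return data frame with columns `pattern`, `low`, `high`.
#' @export
onset_qualitative_table <- function(path = NULL) {
  if (is.null(path)) {
    return(cache_get("onset_qual", function() {
      p <- system.file("extdata", "onset-qualitative.tsv",
                       package = "fhhscreen", mustWork = TRUE)
      utils::read.delim(p, stringsAsFactors = FALSE)
    }))
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# Regexes for explicit-age cues. A bare number is never taken as an age:
# a cue word ("at", "age", "dx", "diagnosed") must introduce it, keeping
# precision high on unconstrained comment text.
.re_exact <- c(
  "\\b(?:dx|dx'd|diagnosed|diag)(?:\\s+at)?(?:\\s+age)?\\s+([0-9]{1,3})\\b",
  "\\b(?:at|@)\\s+(?:age\\s+)?([0-9]{1,3})\\b",
  "\\bage[d]?\\s*:?\\s*([0-9]{1,3})\\b"
)

.re_decade <- "\\b(early|mid|late)?[- ]?([0-9]{1,2})0'?s\\b"

# first capture-group match of a perl regex, with its start offset
.match_one <- function(re, text) {
  m <- regexpr(re, text, perl = TRUE, ignore.case = TRUE)
  if (m == -1L) return(NULL)
  st <- attr(m, "capture.start")
  len <- attr(m, "capture.length")
  groups <- substring(text, st, st + len - 1L)
  list(start = as.integer(m), groups = groups)
}

#' Extract an age-of-onset estimate from a comment
#'
#' Scans left to right and returns the earliest-starting recognized pattern
#' (ties broken in favour of explicit ages, then decades, then qualitative
#' phrases). Recognized forms:
#'
#' * explicit ages introduced by a cue word: "at 42", "age 42", "dx 42",
#'   "diagnosed at age 42" -> `exact` \[42, 42\];
#' * decades: "40s" -> `range` \[40, 49\], with qualifiers
#'   "early 40s" -> \[40, 43\], "mid 40s" -> \[44, 46\],
#'   "late 40s" -> \[47, 49\];
#' * qualitative phrases from [onset_qualitative_table()], e.g.
#'   "premenopausal" -> \[0, 50\].
#'
#' Anything else (including ages above 120) yields `kind = "unknown"`;
#' extraction never throws.
#'
#' @param comment a character scalar (may be empty or `NA`).
#' @param qualitative phrase table, see [onset_qualitative_table()].
#' @return an [onset_estimate()] with `source = "comment"`.
#' @export
#' @examples
#' extract_onset("dx at age 42")
#' extract_onset("early 30s")
#' extract_onset("premenopausal")
extract_onset <- function(comment, qualitative = onset_qualitative_table()) {
  if (is.null(comment) || length(comment) == 0L || is.na(comment) ||
      !nzchar(trimws(comment))) {
    return(onset_estimate("unknown", source = "comment"))
  }
  comment <- as.character(comment)
  cand <- list()

  for (re in .re_exact) {
    m <- .match_one(re, comment)
    if (!is.null(m)) {
      age <- suppressWarnings(as.integer(m$groups[[1]]))
      if (!is.na(age) && age <= 120L) {
        cand[[length(cand) + 1L]] <- list(start = m$start, prio = 1L,
                                          kind = "exact", low = age, high = age)
      }
    }
  }

  m <- .match_one(.re_decade, comment)
  if (!is.null(m)) {
    qual <- tolower(m$groups[[1]])
    base <- suppressWarnings(as.integer(m$groups[[2]])) * 10L
    if (!is.na(base) && base <= 110L) {
      bounds <- switch(if (nzchar(qual)) qual else "none",
                       early = c(base, base + 3L),
                       mid   = c(base + 4L, base + 6L),
                       late  = c(base + 7L, base + 9L),
                       none  = c(base, base + 9L))
      cand[[length(cand) + 1L]] <- list(start = m$start, prio = 2L,
                                        kind = "range",
                                        low = bounds[1], high = bounds[2])
    }
  }

  for (i in seq_len(nrow(qualitative))) {
    m <- .match_one(paste0("(", qualitative$pattern[i], ")"), comment)
    if (!is.null(m)) {
      cand[[length(cand) + 1L]] <- list(start = m$start, prio = 3L,
                                        kind = "qualitative",
                                        low = qualitative$low[i],
                                        high = qualitative$high[i])
    }
  }

  if (length(cand) == 0L) return(onset_estimate("unknown", source = "comment"))
  ord <- order(vapply(cand, `[[`, 1L, "start"), vapply(cand, `[[`, 1L, "prio"))
  best <- cand[[ord[1]]]
  onset_estimate(best$kind, best$low, best$high, source = "comment")
}

#' Extract a lineage-side assignment from a comment
#'
#' Detects "maternal" / "mother's side" / "mom's side" and "paternal" /
#' "father's side" / "dad's side". When both sides are mentioned the result
#' is `"unknown"` (conflict).
#'
#' @param comment a character scalar (may be empty or `NA`).
#' @return `"maternal"`, `"paternal"`, or `"unknown"`.
#' @export
#' @examples
#' extract_lineage("maternal side")
#' extract_lineage("father's side")
extract_lineage <- function(comment) {
  if (is.null(comment) || length(comment) == 0L || is.na(comment)) {
    return("unknown")
  }
  mat <- grepl("\\bmaternal\\b|\\b(?:mother|mom)'?s?\\s+side\\b",
               comment, perl = TRUE, ignore.case = TRUE)
  pat <- grepl("\\bpaternal\\b|\\b(?:father|dad)'?s?\\s+side\\b",
               comment, perl = TRUE, ignore.case = TRUE)
  if (mat && pat) "unknown" else if (mat) "maternal" else if (pat) "paternal" else "unknown"
}

#' Resolve onset from structured and free-text sources
#'
#' A structured age, when present, always takes precedence (`exact`,
#' `source = "structured"`); otherwise the comment is parsed with
#' [extract_onset()].
#'
#' @param structured_age integer age in years, or `NULL`/`NA` when absent.
#' @param comment free-text comment, possibly empty.
#' @return an [onset_estimate()].
#' @export
resolve_onset <- function(structured_age, comment = "") {
  if (!is.null(structured_age) && length(structured_age) == 1L &&
      !is.na(structured_age)) {
    a <- as.integer(structured_age)
    return(onset_estimate("exact", a, a, source = "structured"))
  }
  extract_onset(comment)
}
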