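# Term mapping: local relationship / diagnosis / religion terms to
# normalized pedigree and cancer concepts.
#
# Health systems customize their FHH vocabularies, so the same concept may
# appear under many local strings. Mapping here is exact-match after case
# folding and whitespace collapse — no fuzzy matching — which favours
# positive predictive value over sensitivity: an unrecognized term is
# reported, never guessed at.

.DEGREES <- c("1", "2", "3", "not_blood", "unknown")
.LINEAGES <- c("maternal", "paternal", "proband_line_not_applicable", "unknown")
.SEXES <- c("female", "male", "unknown")
.CANCER_CATEGORIES <- c("breast", "ovarian", "colorectal", "endometrial",
                        "pancreatic", "other_lynch_associated", "other_cancer",
                        "non_cancer")

#' Construct a relationship concept
#'
#' The normalized meaning of one relationship term: degree of relationship
#' to the proband, lineage side, sex, and whether the relative shares blood
#' with the proband. First-degree relatives sit on the proband's own line,
#' so their lineage is `proband_line_not_applicable` and they may count
#' toward either side of a same-lineage criterion.
#'
#' @param degree `"1"`, `"2"`, `"3"`, `"not_blood"`, or `"unknown"`.
#' @param lineage `"maternal"`, `"paternal"`,
#'   `"proband_line_not_applicable"`, or `"unknown"`.
#' @param sex `"female"`, `"male"`, or `"unknown"`.
#' @param blood_relative logical.
#' @return object of class `relationship_concept`.
#' @export
relationship_concept <- function(degree, lineage = "unknown", sex = "unknown",
                                 blood_relative = TRUE) {
  degree <- match.arg(as.character(degree), .DEGREES)
  lineage <- match.arg(lineage, .LINEAGES)
  sex <- match.arg(sex, .SEXES)
  stopifnot(is.logical(blood_relative), length(blood_relative) == 1L)
  if ((degree == "not_blood") != !blood_relative) {
    stop("degree 'not_blood' and blood_relative = FALSE must coincide")
  }
  # first-degree relatives sit on the proband's own line by definition
  if (degree %in% c("1", "not_blood")) lineage <- "proband_line_not_applicable"
  structure(list(degree = degree, lineage = lineage, sex = sex,
                 blood_relative = blood_relative),
            class = "relationship_concept")
}

rc <- function(degree, sex = "unknown", lineage = "unknown",
               blood = TRUE) {
  if (degree == "1") lineage <- "proband_line_not_applicable"
  if (degree == "not_blood") lineage <- "proband_line_not_applicable"
  relationship_concept(degree, lineage, sex, blood)
}

default_relationship_map <- function() {
  cache_get("rel_map", function() {
    m <- list(
      # first degree: proband's own line, either side of a same-side rule
      "mother" = rc("1", "female"), "father" = rc("1", "male"),
      "sister" = rc("1", "female"), "brother" = rc("1", "male"),
      "sibling" = rc("1"), "daughter" = rc("1", "female"),
      "son" = rc("1", "male"), "child" = rc("1"),
      # second degree
      "grandmother" = rc("2", "female"), "grandfather" = rc("2", "male"),
      "grandparent" = rc("2"),
      "maternal grandmother" = rc("2", "female", "maternal"),
      "maternal grandfather" = rc("2", "male", "maternal"),
      "paternal grandmother" = rc("2", "female", "paternal"),
      "paternal grandfather" = rc("2", "male", "paternal"),
      "aunt" = rc("2", "female"), "uncle" = rc("2", "male"),
      "maternal aunt" = rc("2", "female", "maternal"),
      "maternal uncle" = rc("2", "male", "maternal"),
      "paternal aunt" = rc("2", "female", "paternal"),
      "paternal uncle" = rc("2", "male", "paternal"),
      "niece" = rc("2", "female"), "nephew" = rc("2", "male"),
      "half-sister" = rc("2", "female"), "half-brother" = rc("2", "male"),
      "half sister" = rc("2", "female"), "half brother" = rc("2", "male"),
      "half-sibling" = rc("2"), "half sibling" = rc("2"),
      # third degree
      "first cousin" = rc("3"), "cousin" = rc("3"),
      "great-grandmother" = rc("3", "female"),
      "great-grandfather" = rc("3", "male"),
      "great grandmother" = rc("3", "female"),
      "great grandfather" = rc("3", "male"),
      "great-grandparent" = rc("3"), "great grandparent" = rc("3"),
      # not blood
      "spouse" = rc("not_blood", blood = FALSE),
      "husband" = rc("not_blood", "male", blood = FALSE),
      "wife" = rc("not_blood", "female", blood = FALSE),
      "partner" = rc("not_blood", blood = FALSE),
      "step-mother" = rc("not_blood", "female", blood = FALSE),
      "stepmother" = rc("not_blood", "female", blood = FALSE),
      "step-father" = rc("not_blood", "male", blood = FALSE),
      "stepfather" = rc("not_blood", "male", blood = FALSE),
      "step-parent" = rc("not_blood", blood = FALSE),
      "step-sister" = rc("not_blood", "female", blood = FALSE),
      "step-brother" = rc("not_blood", "male", blood = FALSE),
      "mother-in-law" = rc("not_blood", "female", blood = FALSE),
      "father-in-law" = rc("not_blood", "male", blood = FALSE),
      "sister-in-law" = rc("not_blood", "female", blood = FALSE),
      "brother-in-law" = rc("not_blood", "male", blood = FALSE),
      "in-law" = rc("not_blood", blood = FALSE)
    )
    names(m) <- norm_term(names(m))
    m
  })
}

default_condition_map <- function() {
  cache_get("cond_map", function() {
    cat_of <- c(
      "breast cancer" = "breast", "breast ca" = "breast",
      "cancer of the breast" = "breast",
      "ovarian cancer" = "ovarian", "ovarian ca" = "ovarian",
      "cancer of the ovary" = "ovarian",
      "colon cancer" = "colorectal", "colorectal cancer" = "colorectal",
      "rectal cancer" = "colorectal", "bowel cancer" = "colorectal",
      "colon ca" = "colorectal",
      "uterine cancer" = "endometrial", "endometrial cancer" = "endometrial",
      "cancer of the uterus" = "endometrial",
      "pancreatic cancer" = "pancreatic", "pancreas cancer" = "pancreatic",
      "gastric cancer" = "other_lynch_associated",
      "stomach cancer" = "other_lynch_associated",
      "small bowel cancer" = "other_lynch_associated",
      "small intestine cancer" = "other_lynch_associated",
      "ureteral cancer" = "other_lynch_associated",
      "urothelial cancer" = "other_lynch_associated",
      "lung cancer" = "other_cancer", "prostate cancer" = "other_cancer",
      "melanoma" = "other_cancer", "skin cancer" = "other_cancer",
      "leukemia" = "other_cancer", "lymphoma" = "other_cancer",
      "thyroid cancer" = "other_cancer", "cervical cancer" = "other_cancer",
      "brain cancer" = "other_cancer",
      "diabetes" = "non_cancer", "type 2 diabetes" = "non_cancer",
      "hypertension" = "non_cancer", "high blood pressure" = "non_cancer",
      "heart disease" = "non_cancer", "coronary artery disease" = "non_cancer",
      "stroke" = "non_cancer", "asthma" = "non_cancer",
      "copd" = "non_cancer", "depression" = "non_cancer",
      "high cholesterol" = "non_cancer", "arthritis" = "non_cancer",
      "osteoporosis" = "non_cancer"
    )
    names(cat_of) <- norm_term(names(cat_of))
    as.list(cat_of)
  })
}

#' Construct a term-mapping table
#'
#' A mapping table carries site-local overlays for three domains:
#' relationship terms (to [relationship_concept()]s), condition terms (to
#' cancer categories), and religion codes (to ancestry flags). Lookups fall
#' back to the built-in default maps; a user entry for a term always wins
#' over the default. The religion overlay ships empty: sites opt in to
#' treating religion codes as an ancestry proxy.
#'
#' @param relationship named list of [relationship_concept()]s.
#' @param condition named list of cancer-category strings.
#' @param religion named list of ancestry-flag strings.
#' @return object of class `mapping_table`.
#' @export
mapping_table <- function(relationship = list(), condition = list(),
                          religion = list()) {
  chk <- function(x, what) {
    if (length(x) && (is.null(names(x)) || any(!nzchar(names(x))))) {
      stop("all ", what, " entries must be named by local term")
    }
    names(x) <- norm_term(names(x))
    x
  }
  condition <- chk(condition, "condition")
  bad <- !unlist(condition, use.names = FALSE) %in% .CANCER_CATEGORIES
  if (any(bad)) {
    stop("unknown cancer category: ",
         paste(unlist(condition)[bad], collapse = ", "))
  }
  structure(list(relationship = chk(relationship, "relationship"),
                 condition = condition,
                 religion = chk(religion, "religion")),
            class = "mapping_table")
}

#' @export
print.mapping_table <- function(x, ...) {
  cat(sprintf("<mapping_table: %d relationship, %d condition, %d religion entries (+ built-in defaults)>\n",
              length(x$relationship), length(x$condition), length(x$religion)))
  invisible(x)
}

parse_kv <- function(s, line) {
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  kv <- strsplit(trimws(parts), "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) {
    stop("malformed key=value field on line ", line, ": ", s)
  }
  stats::setNames(trimws(vapply(kv, `[[`, "", 2L)),
                  trimws(vapply(kv, `[[`, "", 1L)))
}

kv_get <- function(kv, key, default = NULL) {
  if (key %in% names(kv)) kv[[key]] else default
}

#' Load a term-mapping table from a TSV file
#'
#' The file has three tab-separated columns — `domain` (one of
#' `relationship`, `condition`, `religion`), `local_term`, and a
#' comma-separated `key=value` target — with an optional header row, e.g.
#'
#' ```
#' relationship<TAB>aunt<TAB>degree=2,sex=female,lineage=unknown,blood=true
#' condition<TAB>CA breast<TAB>category=breast
#' religion<TAB>ASHKENAZI<TAB>flag=ashkenazi_jewish
#' ```
#'
#' Duplicate local terms within a domain are a validation error (reported
#' with their line numbers): a term must map to exactly one concept.
#'
#' @param path path to the TSV file.
#' @return a [mapping_table()].
#' @export
load_mapping_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines_orig <- seq_along(lines)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  lines_orig <- lines_orig[keep]
  if (length(lines) && grepl("^domain\\t", lines[1])) {
    lines <- lines[-1]
    lines_orig <- lines_orig[-1]
  }
  rel <- list(); cond <- list(); rel_lines <- c(); cond_lines <- c()
  relig <- list(); relig_lines <- c()
  dup <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop("line ", lines_orig[i], " of ", path,
           ": expected 3 tab-separated columns")
    }
    domain <- trimws(f[1]); term <- norm_term(f[2])
    kv <- parse_kv(f[3], lines_orig[i])
    if (domain == "relationship") {
      if (term %in% names(rel)) {
        dup <- c(dup, sprintf("line %d: duplicate relationship term '%s' (first at line %d)",
                              lines_orig[i], term, rel_lines[[term]]))
        next
      }
      rel[[term]] <- relationship_concept(
        degree = kv_get(kv, "degree", "unknown"),
        lineage = kv_get(kv, "lineage", "unknown"),
        sex = kv_get(kv, "sex", "unknown"),
        blood_relative = tolower(kv_get(kv, "blood", "true")) %in%
          c("true", "t", "1", "yes"))
      rel_lines[[term]] <- lines_orig[i]
    } else if (domain == "condition") {
      if (term %in% names(cond)) {
        dup <- c(dup, sprintf("line %d: duplicate condition term '%s' (first at line %d)",
                              lines_orig[i], term, cond_lines[[term]]))
        next
      }
      if (!"category" %in% names(kv)) {
        stop("line ", lines_orig[i], ": condition row needs category=<...>")
      }
      cond[[term]] <- kv[["category"]]
      cond_lines[[term]] <- lines_orig[i]
    } else if (domain == "religion") {
      if (term %in% names(relig)) {
        dup <- c(dup, sprintf("line %d: duplicate religion code '%s' (first at line %d)",
                              lines_orig[i], term, relig_lines[[term]]))
        next
      }
      relig[[term]] <- kv_get(kv, "flag", unname(kv[1]))
      relig_lines[[term]] <- lines_orig[i]
    } else {
      stop("line ", lines_orig[i], ": unknown domain '", domain, "'")
    }
  }
  if (length(dup)) {
    stop("duplicate mappings in ", path, ":\n  ",
         paste(dup, collapse = "\n  "))
  }
  mapping_table(relationship = rel, condition = cond, religion = relig)
}

#' Map a relationship term to a concept
#'
#' Looks the normalized term up in the user table first, then in the
#' built-in default map of canonical English kin terms. An unrecognized
#' term returns `NULL` — unmapped is a reportable value, not an error.
#'
#' @param term relationship string as documented (e.g. `"aunt"`).
#' @param table optional [mapping_table()] of site-local overrides.
#' @return a [relationship_concept()], or `NULL` if unmapped.
#' @export
#' @examples
#' map_relationship("mother")
#' map_relationship("maternal grandmother")
map_relationship <- function(term, table = NULL) {
  key <- norm_term(term)
  if (!nzchar(key)) return(NULL)
  if (!is.null(table) && key %in% names(table$relationship)) {
    return(table$relationship[[key]])
  }
  default_relationship_map()[[key]]
}

#' Map a condition term to a cancer category
#'
#' @param term condition string as documented (e.g. `"colon cancer"`).
#' @param table optional [mapping_table()] of site-local overrides.
#' @return a category string (`"breast"`, `"ovarian"`, `"colorectal"`,
#'   `"endometrial"`, `"pancreatic"`, `"other_lynch_associated"`,
#'   `"other_cancer"`, `"non_cancer"`), or `NULL` if unmapped.
#' @export
map_condition <- function(term, table = NULL) {
  key <- norm_term(term)
  if (!nzchar(key)) return(NULL)
  if (!is.null(table) && key %in% names(table$condition)) {
    return(table$condition[[key]])
  }
  default_condition_map()[[key]]
}

#' Map a religion code to an ancestry flag
#'
#' The built-in religion map is empty by default; a site opting in supplies
#' rows such as `religion<TAB>ASHKENAZI<TAB>flag=ashkenazi_jewish` in its
#' mapping table.
#'
#' @param code religion code string.
#' @param table optional [mapping_table()].
#' @return an ancestry flag string, or `NULL` if unmapped.
#' @export
map_religion <- function(code, table = NULL) {
  key <- norm_term(code)
  if (!nzchar(key) || is.null(table)) return(NULL)
  table$religion[[key]]
}

#' Term coverage report over a cohort
#'
#' Tallies every relationship and condition term in a cohort's FHH records
#' and whether it maps under the given table (plus defaults). Every lookup
#' lands in exactly one of the mapped/unmapped buckets, so
#' `sum(n[mapped]) + sum(n[!mapped])` equals the number of lookups.
#'
#' @param cohort an `fhh_cohort`, see [read_cohort()].
#' @param table optional [mapping_table()].
#' @return data frame with columns `domain`, `term`, `n`, `mapped`.
#' @export
term_coverage <- function(cohort, table = NULL) {
  rel_terms <- vapply(cohort$fhh, function(r) norm_term(r$relationship_term), "")
  cond_terms <- unlist(lapply(cohort$fhh, function(r) {
    vapply(r$diagnoses, function(d) norm_term(d$condition_term), "")
  }))
  tab <- function(terms, domain, mapper) {
    if (length(terms) == 0L) {
      return(data.frame(domain = character(), term = character(),
                        n = integer(), mapped = logical()))
    }
    t <- table(terms)
    data.frame(domain = domain, term = names(t), n = as.integer(t),
               mapped = vapply(names(t),
                               function(x) !is.null(mapper(x, table)), TRUE),
               row.names = NULL)
  }
  out <- rbind(tab(rel_terms, "relationship", map_relationship),
               tab(cond_terms, "condition", map_condition))
  out[order(out$domain, -out$n, out$term), , drop = FALSE]
}
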