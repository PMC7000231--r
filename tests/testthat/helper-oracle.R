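# Independent brute-force oracle for criterion evaluation: exhaustive
# enumeration over relative subsets and lineage-side assignments. Written
# directly from the counting semantics, independent of the engine's
# per-side counting shortcut.

brute_evaluate <- function(crit, relatives, patient = NULL,
                           mode = "conservative") {
  if (!is.null(crit$ancestry_required)) {
    flags <- unlist(patient$ancestry_flags %||% list(character()))
    if (!crit$ancestry_required %in% flags) return(FALSE)
  }
  eligible <- function(r) {
    isTRUE(r$blood_relative) &&
      r$degree %in% as.character(crit$allowed_degrees) &&
      (is.null(crit$relative_sex) || r$sex == crit$relative_sex) &&
      any(vapply(r$events, function(e) e$category %in% crit$categories, TRUE))
  }
  onset_ok <- function(e) {
    if (!e$category %in% crit$categories) return(FALSE)
    if (e$onset$kind == "unknown") return(FALSE)
    if (mode == "conservative") e$onset$high_years <= crit$max_onset_age
    else e$onset$low_years <= crit$max_onset_age
  }
  qualifying <- function(r) {
    if (is.null(crit$max_onset_age)) return(TRUE)
    any(vapply(r$events, onset_ok, TRUE))
  }
  assignable <- function(r, side) {
    r$lineage == "proband_line_not_applicable" || r$lineage == side ||
      (r$lineage == "unknown" && mode == "optimistic")
  }
  n <- length(relatives)
  for (mask in seq_len(2^n) - 1L) {
    members <- relatives[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L]
    if (length(members) < crit$min_relatives) next
    if (!all(vapply(members, eligible, TRUE))) next
    if (sum(vapply(members, qualifying, TRUE)) < crit$min_onset_qualifying) next
    if (crit$same_lineage_required) {
      ok <- any(vapply(c("maternal", "paternal"), function(side) {
        all(vapply(members, assignable, TRUE, side = side))
      }, TRUE))
      if (!ok) next
    }
    return(TRUE)
  }
  FALSE
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- randomized case generators -------------------------------------------

.oracle_cats <- c("breast", "ovarian", "colorectal", "endometrial",
                  "other_lynch_associated", "other_cancer")

rand_onset <- function() {
  kind <- sample(c("unknown", "exact", "range"), 1L, prob = c(0.2, 0.45, 0.35))
  if (kind == "unknown") return(onset_estimate("unknown"))
  lo <- sample(20:70, 1L)
  hi <- if (kind == "exact") lo else lo + sample(0:15, 1L)
  onset_estimate(if (lo == hi) "exact" else "range", lo, hi)
}

rand_relative <- function(id) {
  degree <- sample(c("1", "2", "3", "not_blood", "unknown"), 1L,
                   prob = c(0.3, 0.3, 0.15, 0.15, 0.1))
  lineage <- if (degree %in% c("1", "not_blood")) {
    "proband_line_not_applicable"
  } else {
    sample(c("maternal", "paternal", "unknown"), 1L)
  }
  blood <- if (degree == "not_blood") FALSE else if (degree == "unknown") NA else TRUE
  n_events <- sample(0:2, 1L, prob = c(0.15, 0.6, 0.25))
  events <- lapply(seq_len(n_events), function(j) {
    cancer_event(sample(.oracle_cats, 1L), rand_onset(), id)
  })
  make_rel(id, degree, lineage, sample(c("female", "male", "unknown"), 1L),
           blood, events)
}

rand_criterion <- function() {
  min_rel <- sample(1:3, 1L)
  with_age <- stats::runif(1) < 0.6
  criterion(
    criterion_id = "RND",
    disease_track = sample(c("breast_ovarian", "colorectal"), 1L),
    categories = sample(.oracle_cats, sample(1:3, 1L)),
    min_relatives = min_rel,
    allowed_degrees = sort(sample(1:3, sample(1:3, 1L))),
    max_onset_age = if (with_age) sample(c(45L, 50L, 60L), 1L) else NULL,
    min_onset_qualifying = if (with_age) sample(seq_len(min_rel), 1L) else 0L,
    same_lineage_required = stats::runif(1) < 0.4,
    relative_sex = if (stats::runif(1) < 0.2)
      sample(c("female", "male"), 1L) else NULL)
}
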