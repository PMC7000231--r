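# Synthetic FHIR-style cohorts with planted ground truth.
#
# The generator emulates the documentation realities of structured FHH
# captured at visit intake: local (non-standard) terms, ages of onset that
# live only in short free-text comments ("early 40s"), lineage sides noted
# only in comments ("maternal side"), occasional cancer-affected non-blood
# relatives, and documented prior genetic counseling. Ground-truth labels
# are derived from the planting construction itself — never from the rule
# engine — so recovery tests are not circular.

#' Specify a synthetic cohort
#'
#' All fractions are of `n_patients`. Planted-eligible patients are always
#' members of the target population, so the eligible fractions cannot
#' exceed `fraction_in_target`. The same spec and seed always produce
#' byte-identical output.
#'
#' @param n_patients cohort size.
#' @param seed integer seed for the generator's private RNG stream.
#' @param age_range sampling range for patient ages (years).
#' @param fraction_in_target fraction of patients placed inside the
#'   target population (age 25-60 with a recent completed primary-care
#'   visit, under the default [target_population_config()]).
#' @param planted_eligible_fraction named fractions
#'   `c(breast_ovarian = , colorectal = )` of patients planted with an
#'   FHH pattern satisfying a randomly chosen enabled criterion of that
#'   track.
#' @param fraction_onset_comment_only probability that a structured onset
#'   age is rewritten into a free-text phrase whose convention interval
#'   still satisfies (or still misses) the planted criterion.
#' @param fraction_lineage_comment_only probability that a lineage-carrying
#'   relationship term ("maternal aunt") is stripped to its plain form with
#'   the side moved into the record comment.
#' @param fraction_local_terms probability that a term is replaced by a
#'   site-local alias (covered by [site_mapping_table()]).
#' @param fraction_nonblood_decoys probability that a planted-negative
#'   patient receives a cancer-affected non-blood relative.
#' @param fraction_prior_counseling probability of documented prior
#'   genetic counseling.
#' @param as_of_date screening reference date of the simulated cohort.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 200L, seed = 1L,
                        age_range = c(18L, 80L),
                        fraction_in_target = 0.8,
                        planted_eligible_fraction = c(breast_ovarian = 0.05,
                                                      colorectal = 0.02),
                        fraction_onset_comment_only = 0.3,
                        fraction_lineage_comment_only = 0.3,
                        fraction_local_terms = 0.2,
                        fraction_nonblood_decoys = 0.1,
                        fraction_prior_counseling = 0.01,
                        as_of_date = "2019-07-05") {
  fr <- c(fraction_in_target, planted_eligible_fraction,
          fraction_onset_comment_only, fraction_lineage_comment_only,
          fraction_local_terms, fraction_nonblood_decoys,
          fraction_prior_counseling)
  if (any(fr < 0 | fr > 1)) stop("all fractions must be in [0, 1]")
  if (!all(c("breast_ovarian", "colorectal") %in%
           names(planted_eligible_fraction))) {
    stop("planted_eligible_fraction needs entries 'breast_ovarian' and 'colorectal'")
  }
  if (sum(planted_eligible_fraction) > fraction_in_target) {
    stop("spec cannot be satisfied: planted eligible fraction (",
         sum(planted_eligible_fraction),
         ") exceeds fraction_in_target (", fraction_in_target, ")")
  }
  stopifnot(n_patients >= 1L, length(age_range) == 2L,
            age_range[1] <= age_range[2])
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 age_range = as.integer(age_range),
                 fraction_in_target = fraction_in_target,
                 planted_eligible_fraction = planted_eligible_fraction,
                 fraction_onset_comment_only = fraction_onset_comment_only,
                 fraction_lineage_comment_only = fraction_lineage_comment_only,
                 fraction_local_terms = fraction_local_terms,
                 fraction_nonblood_decoys = fraction_nonblood_decoys,
                 fraction_prior_counseling = fraction_prior_counseling,
                 as_of_date = as.Date(as_of_date)),
            class = "cohort_spec")
}

# run code under a private RNG stream, restoring the caller's stream after
with_private_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister")
  force(code)
}

# ---- site-local alias dictionaries -----------------------------------------

.LOCAL_REL_ALIAS <- c(
  "mother" = "mom", "father" = "dad", "sister" = "sis", "brother" = "bro",
  "grandmother" = "gma", "grandfather" = "gpa",
  "maternal aunt" = "mat aunt", "paternal aunt" = "pat aunt",
  "maternal uncle" = "mat uncle", "paternal uncle" = "pat uncle",
  "maternal grandmother" = "mat gma", "paternal grandmother" = "pat gma",
  "maternal grandfather" = "mat gpa", "paternal grandfather" = "pat gpa",
  "aunt" = "aunt of pt", "uncle" = "uncle of pt", "spouse" = "sp")

.LOCAL_COND_ALIAS <- c(
  "breast cancer" = "CA breast", "ovarian cancer" = "CA ovary",
  "colon cancer" = "CA colon", "endometrial cancer" = "CA uterus",
  "stomach cancer" = "CA stomach", "lung cancer" = "CA lung",
  "prostate cancer" = "CA prostate", "melanoma" = "CA skin - melanoma",
  "diabetes" = "DM type II", "hypertension" = "HTN",
  "heart disease" = "CAD", "high cholesterol" = "hyperlipidemia")

#' Site mapping table for the generator's local terms
#'
#' The synthetic cohort renders a configurable fraction of terms as
#' site-local aliases ("mom", "CA breast"). This table maps every alias
#' back to the concept of its canonical term, emulating a deployed
#' term-mapping configuration; [generate_cohort()] bundles it with its
#' output so the cohort is screenable.
#'
#' @return a [mapping_table()].
#' @export
site_mapping_table <- function() {
  rel <- lapply(names(.LOCAL_REL_ALIAS), function(canon) {
    map_relationship(canon)
  })
  names(rel) <- unname(.LOCAL_REL_ALIAS)
  cond <- lapply(names(.LOCAL_COND_ALIAS), function(canon) {
    map_condition(canon)
  })
  names(cond) <- unname(.LOCAL_COND_ALIAS)
  mapping_table(relationship = rel, condition = cond)
}

#' Write a mapping table as TSV
#'
#' Inverse of [load_mapping_table()] for tables built in code.
#'
#' @param table a [mapping_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mapping_table <- function(table, path) {
  lines <- "domain\tlocal_term\tmapping"
  for (term in names(table$relationship)) {
    cc <- table$relationship[[term]]
    lines <- c(lines, sprintf(
      "relationship\t%s\tdegree=%s,lineage=%s,sex=%s,blood=%s",
      term, cc$degree, cc$lineage, cc$sex, tolower(cc$blood_relative)))
  }
  for (term in names(table$condition)) {
    lines <- c(lines, sprintf("condition\t%s\tcategory=%s", term,
                              table$condition[[term]]))
  }
  for (term in names(table$religion)) {
    lines <- c(lines, sprintf("religion\t%s\tflag=%s", term,
                              table$religion[[term]]))
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- planting --------------------------------------------------------------

# A relative plan is list(term, side ("maternal"/"paternal"/NA: side encoded
# in the term), diagnoses = list(list(term, age, max_high))); max_high is the
# largest admissible upper bound when the onset is rendered as a comment
# phrase (NA = unconstrained).

rel_plan <- function(term, diagnoses, side = NA_character_) {
  list(term = term, side = side, diagnoses = diagnoses)
}

dx_plan <- function(term, age = NA_integer_, max_high = NA_integer_) {
  list(term = term, age = age, max_high = max_high)
}

sided <- function(side, base) paste(side, base)

# Construct the relative plans satisfying one criterion of the default
# ruleset, by the construction itself (the engine is never consulted).
plant_criterion <- function(cid) {
  pick <- function(x) x[[sample.int(length(x), 1L)]]
  side <- pick(c("maternal", "paternal"))
  switch(cid,
    B1 = list(rel_plan(pick(c("mother", "sister", "aunt", "grandmother",
                              sided(side, "aunt"))),
                       list(dx_plan("breast cancer", sample(28:45, 1L), 45L)))),
    B2 = list(rel_plan(pick(c("mother", "sister", "aunt",
                              sided(side, "aunt"))),
                       list(dx_plan("ovarian cancer",
                                    if (stats::runif(1) < 0.5) NA_integer_
                                    else sample(35:70, 1L))))),
    B3 = list(rel_plan(pick(c("father", "brother", "uncle")),
                       list(dx_plan("breast cancer",
                                    if (stats::runif(1) < 0.3) NA_integer_
                                    else sample(45:75, 1L))))),
    B4 = list(rel_plan(sided(side, "aunt"),
                       list(dx_plan("breast cancer", sample(35:50, 1L), 50L))),
              rel_plan(pick(c("mother", sided(side, "grandmother"))),
                       list(dx_plan("breast cancer", sample(40:70, 1L))))),
    B5 = list(rel_plan(sided(side, "aunt"),
                       list(dx_plan("breast cancer", sample(35:75, 1L)))),
              rel_plan(sided(side, "grandmother"),
                       list(dx_plan("breast cancer", sample(40:80, 1L)))),
              rel_plan("mother",
                       list(dx_plan("breast cancer", sample(35:75, 1L))))),
    C1 = list(rel_plan(pick(c("mother", "father", "sister", "brother")),
                       list(dx_plan("colon cancer", sample(30:50, 1L), 50L)))),
    C2 = list(rel_plan(pick(c("mother", "sister")),
                       list(dx_plan("endometrial cancer", sample(32:50, 1L),
                                    50L)))),
    C3 = list(rel_plan(sided(side, "aunt"),
                       list(dx_plan(pick(c("colon cancer",
                                           "endometrial cancer")),
                                    sample(30:50, 1L), 50L))),
              rel_plan(pick(c("mother", sided(side, "uncle"))),
                       list(dx_plan(pick(c("colon cancer", "stomach cancer")),
                                    sample(40:70, 1L))))),
    C4 = list(rel_plan(sided(side, "aunt"),
                       list(dx_plan("colon cancer", sample(40:75, 1L)))),
              rel_plan(sided(side, "uncle"),
                       list(dx_plan("stomach cancer", sample(45:75, 1L)))),
              rel_plan("father",
                       list(dx_plan("colon cancer", sample(40:75, 1L))))),
    stop("no planting construction for criterion ", cid))
}

# criteria of a track that the planting constructions cover
plantable_criteria <- function(rules, track) {
  ids <- vapply(rules$criteria, `[[`, "", "criterion_id")
  enabled <- vapply(rules$criteria, `[[`, TRUE, "enabled")
  tr <- vapply(rules$criteria, `[[`, "", "disease_track")
  ids[enabled & tr == track &
        ids %in% c("B1", "B2", "B3", "B4", "B5", "C1", "C2", "C3", "C4")]
}

.BENIGN_CONDS <- c("diabetes", "hypertension", "heart disease",
                   "high cholesterol", "asthma", "arthritis",
                   "lung cancer", "prostate cancer", "melanoma")

# benign relatives + optional near-miss / non-blood decoys; misses every
# default criterion by construction (see vignette for the argument)
plan_negative_fhh <- function(spec) {
  plans <- list()
  n_benign <- sample(0:3, 1L)
  for (k in seq_len(n_benign)) {
    term <- sample(c("mother", "father", "sister", "brother", "aunt",
                     "uncle", "grandmother", "grandfather", "cousin"), 1L)
    plans[[length(plans) + 1L]] <- rel_plan(
      term, list(dx_plan(sample(.BENIGN_CONDS, 1L),
                         if (stats::runif(1) < 0.5) NA_integer_
                         else sample(40:80, 1L))))
  }
  # near-miss: one female blood relative with a criterion-category cancer
  # diagnosed strictly above every age threshold plus the widest comment
  # interval (>= 56 > 50 + decade-qualifier width), and counts of 1 relative
  # so the multi-relative age-free criteria cannot fire either
  if (stats::runif(1) < 0.3) {
    cat_term <- sample(c("breast cancer", "colon cancer"), 1L)
    term <- sample(c("mother", "sister", "aunt", "grandmother"), 1L)
    plans[[length(plans) + 1L]] <- rel_plan(
      term, list(dx_plan(cat_term, sample(56:80, 1L))))
  }
  if (stats::runif(1) < spec$fraction_nonblood_decoys) {
    plans[[length(plans) + 1L]] <- rel_plan(
      sample(c("spouse", "husband", "wife"), 1L),
      list(dx_plan(sample(c("colon cancer", "breast cancer"), 1L),
                   sample(40:50, 1L))))
  }
  plans
}

# ---- comment rendering -----------------------------------------------------

# Render an age as a free-text onset phrase whose convention interval
# contains the age and whose upper bound stays at or below max_high (when
# constrained). The exact-age phrase is always admissible.
render_onset_phrase <- function(age, max_high = NA_integer_) {
  cands <- sprintf(sample(c("dx at age %d", "at %d", "age %d",
                            "diagnosed at %d"), 1L), age)
  base <- (age %/% 10L) * 10L
  decades <- list(c(sprintf("%ds", base), base, base + 9L),
                  c(sprintf("early %ds", base), base, base + 3L),
                  c(sprintf("mid %ds", base), base + 4L, base + 6L),
                  c(sprintf("late %ds", base), base + 7L, base + 9L))
  for (d in decades) {
    lo <- as.integer(d[2]); hi <- as.integer(d[3])
    if (lo <= age && age <= hi && (is.na(max_high) || hi <= max_high)) {
      cands <- c(cands, d[1])
    }
  }
  sample(cands, 1L)
}

# ---- FHIR rendering --------------------------------------------------------

to_fhir_patient <- function(pid, birth_date, sex, prior, contact, provider) {
  ext <- list(list(url = EXT_PRIOR_COUNSELING, valueBoolean = prior),
              list(url = EXT_PREFERRED_CONTACT, valueCode = contact))
  list(resourceType = "Patient", id = pid,
       birthDate = format(birth_date), gender = sex,
       extension = ext,
       generalPractitioner = list(list(
         reference = paste0("Practitioner/", provider))))
}

to_fhir_encounter <- function(eid, pid, type, date, status) {
  fhir_status <- c(completed = "finished", cancelled = "cancelled",
                   planned = "planned", no_show = "noshow")[[status]]
  list(resourceType = "Encounter", id = eid, status = fhir_status,
       type = list(list(coding = list(list(
         system = "https://fhhscreen.example/encounter-type", code = type)))),
       subject = list(reference = paste0("Patient/", pid)),
       period = list(start = format(date)))
}

to_fhir_fmh <- function(rid, pid, relationship, diagnoses, date_captured,
                        record_comment) {
  res <- list(resourceType = "FamilyMemberHistory", id = rid,
              patient = list(reference = paste0("Patient/", pid)),
              date = format(date_captured),
              relationship = list(text = relationship))
  if (length(diagnoses)) {
    res$condition <- lapply(diagnoses, function(d) {
      cnd <- list(code = list(text = d$term))
      if (!is.na(d$age)) {
        cnd$onsetAge <- list(value = as.integer(d$age), unit = "a",
                             system = "http://unitsofmeasure.org")
      }
      if (nzchar(d$comment %||% "")) {
        cnd$note <- list(list(text = d$comment))
      }
      cnd
    })
  }
  if (nzchar(record_comment %||% "")) {
    res$note <- list(list(text = record_comment))
  }
  res
}

# sample a birth date giving exactly `age` completed years at `as_of`
sample_birth_date <- function(age, as_of) {
  bd <- add_years(as_of, -age) - sample(0:364, 1L)
  while (floor_age(bd, as_of) > age) bd <- bd + 1L
  while (floor_age(bd, as_of) < age) bd <- bd - 1L
  bd
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Planted-eligible patients receive an FHH pattern that satisfies one
#' randomly chosen enabled criterion of their track (rendered with decoy
#' relatives and, per the noise knobs, local terms, comment-only onsets,
#' and comment-only lineage). Planted-negative patients receive FHH that
#' misses every criterion by construction: benign or non-criterion cancer
#' categories, onsets strictly above all thresholds plus the comment
#' interval width, insufficient relative counts, and non-blood decoys.
#'
#' @param spec a [cohort_spec()].
#' @param rules ruleset the planting draws its criteria from (default
#'   [default_ruleset()]); planting covers the shipped criteria B1-B5 and
#'   C1-C4.
#' @return list with `cohort` (an `fhh_cohort`, as [read_cohort()] would
#'   return), `resources` (FHIR resources as R lists), `labels` (ground
#'   truth data frame: `patient_id`, `in_target`, `eligible_breast`,
#'   `eligible_colorectal`, `qualifying_criterion_ids`), `table` (the
#'   [site_mapping_table()]), and `spec`.
#' @export
generate_cohort <- function(spec, rules = default_ruleset()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_private_seed(spec$seed, {
    n <- spec$n_patients
    as_of <- spec$as_of_date
    n_b <- round(spec$planted_eligible_fraction[["breast_ovarian"]] * n)
    n_c <- round(spec$planted_eligible_fraction[["colorectal"]] * n)
    n_t <- max(round(spec$fraction_in_target * n), n_b + n_c)
    if (n_t > n) stop("spec cannot be satisfied: in-target count exceeds n")

    ord <- sample.int(n)
    in_target <- logical(n); in_target[ord[seq_len(n_t)]] <- TRUE
    track <- rep(NA_character_, n)
    if (n_b > 0L) track[ord[seq_len(n_b)]] <- "breast_ovarian"
    if (n_c > 0L) track[ord[n_b + seq_len(n_c)]] <- "colorectal"

    b_ids <- plantable_criteria(rules, "breast_ovarian")
    c_ids <- plantable_criteria(rules, "colorectal")
    if (n_b > 0L && length(b_ids) == 0L ||
        n_c > 0L && length(c_ids) == 0L) {
      stop("no plantable enabled criteria for a requested track")
    }

    resources <- list()
    labels <- vector("list", n)
    rid_counter <- 0L
    for (i in seq_len(n)) {
      pid <- sprintf("P%05d", i)
      if (in_target[i]) {
        age <- sample(25:60, 1L)
      } else if (stats::runif(1) < 0.5 &&
                 (spec$age_range[1] < 25L || spec$age_range[2] > 60L)) {
        pool <- c(seq(spec$age_range[1], min(24L, spec$age_range[2])),
                  seq(max(61L, spec$age_range[1]), spec$age_range[2]))
        pool <- pool[pool >= spec$age_range[1] & pool <= spec$age_range[2]]
        age <- pool[sample.int(length(pool), 1L)]
      } else {
        age <- sample(25:60, 1L)  # in age range but with no qualifying visit
      }
      birth <- sample_birth_date(age, as_of)
      sex <- sample(c("female", "male"), 1L)
      prior <- stats::runif(1) < spec$fraction_prior_counseling
      contact <- sample(c("portal", "mail"), 1L, prob = c(0.7, 0.3))
      provider <- sprintf("PCP%d", sample.int(5L, 1L))
      resources[[length(resources) + 1L]] <-
        to_fhir_patient(pid, birth, sex, prior, contact, provider)

      # encounters
      age_in_band <- age >= 25L && age <= 60L
      if (in_target[i]) {
        enc_date <- as_of - sample(0:1090, 1L)
        resources[[length(resources) + 1L]] <- to_fhir_encounter(
          sprintf("E%05d-1", i), pid, "primary_care", enc_date, "completed")
      } else if (age_in_band) {
        # exclusion by visit history: stale, cancelled, or non-primary-care
        reason <- sample(c("stale", "cancelled", "specialty", "none"), 1L)
        if (reason == "stale") {
          resources[[length(resources) + 1L]] <- to_fhir_encounter(
            sprintf("E%05d-1", i), pid, "primary_care",
            add_years(as_of, -3L) - sample(30:700, 1L), "completed")
        } else if (reason == "cancelled") {
          resources[[length(resources) + 1L]] <- to_fhir_encounter(
            sprintf("E%05d-1", i), pid, "primary_care",
            as_of - sample(0:1000, 1L), "cancelled")
        } else if (reason == "specialty") {
          resources[[length(resources) + 1L]] <- to_fhir_encounter(
            sprintf("E%05d-1", i), pid, "dermatology",
            as_of - sample(0:1000, 1L), "completed")
        }
      } else if (stats::runif(1) < 0.7) {
        resources[[length(resources) + 1L]] <- to_fhir_encounter(
          sprintf("E%05d-1", i), pid, "primary_care",
          as_of - sample(0:1090, 1L), "completed")
      }

      # FHH
      qualifying <- ""
      if (!is.na(track[i])) {
        cid <- if (track[i] == "breast_ovarian") {
          b_ids[sample.int(length(b_ids), 1L)]
        } else {
          c_ids[sample.int(length(c_ids), 1L)]
        }
        qualifying <- cid
        plans <- c(plant_criterion(cid),
                   if (stats::runif(1) < 0.5) plan_negative_fhh(spec))
      } else if (in_target[i] || stats::runif(1) < 0.5) {
        plans <- plan_negative_fhh(spec)
      } else {
        plans <- list()
      }

      for (pl in plans) {
        rid_counter <- rid_counter + 1L
        rendered <- render_relative_plan(pl, spec)
        resources[[length(resources) + 1L]] <- to_fhir_fmh(
          sprintf("FMH%06d", rid_counter), pid, rendered$term,
          rendered$diagnoses, as_of - sample(0:1090, 1L),
          rendered$record_comment)
      }

      labels[[i]] <- data.frame(
        patient_id = pid, in_target = in_target[i],
        eligible_breast = identical(track[i], "breast_ovarian"),
        eligible_colorectal = identical(track[i], "colorectal"),
        qualifying_criterion_ids = qualifying,
        stringsAsFactors = FALSE)
    }
    labels <- do.call(rbind, labels)
    cohort <- build_cohort(resources)
    list(cohort = cohort, resources = resources, labels = labels,
         table = site_mapping_table(), spec = spec)
  })
}

# Apply the noise knobs to one relative plan; returns term, record_comment,
# and diagnoses rendered as list(term, age, comment). Every random draw is
# made unconditionally, so two runs of the same seed that differ only in a
# noise fraction see identical RNG streams: the cohorts then differ only in
# the rewrites that fraction controls, which is what makes the noise knobs
# monotone by construction.
render_relative_plan <- function(pl, spec) {
  term <- pl$term
  record_comment <- ""
  # lineage into the comment: strip a side-qualified term to its plain form
  side_match <- regmatches(term, regexpr("^(maternal|paternal) ", term))
  u_lineage <- stats::runif(1)
  if (length(side_match) == 1L && nzchar(side_match) &&
      u_lineage < spec$fraction_lineage_comment_only) {
    side <- trimws(side_match)
    term <- sub("^(maternal|paternal) ", "", term)
    record_comment <- paste0(side, " side")
  }
  diagnoses <- lapply(pl$diagnoses, function(d) {
    dterm <- d$term
    age <- d$age
    comment <- ""
    u_onset <- stats::runif(1)
    if (!is.na(age)) {
      phrase <- render_onset_phrase(age, d$max_high)
      if (u_onset < spec$fraction_onset_comment_only) {
        comment <- phrase
        age <- NA_integer_
      }
    }
    u_local <- stats::runif(1)
    if (u_local < spec$fraction_local_terms &&
        dterm %in% names(.LOCAL_COND_ALIAS)) {
      dterm <- unname(.LOCAL_COND_ALIAS[[dterm]])
    }
    list(term = dterm, age = age, comment = comment)
  })
  u_term <- stats::runif(1)
  if (u_term < spec$fraction_local_terms &&
      term %in% names(.LOCAL_REL_ALIAS)) {
    term <- unname(.LOCAL_REL_ALIAS[[term]])
  }
  list(term = term, record_comment = record_comment, diagnoses = diagnoses)
}

#' Write a generated cohort to a directory
#'
#' Writes `cohort.ndjson` (one FHIR resource per line), `labels.csv`,
#' `mappings.tsv` (the site term-mapping table covering the generator's
#' local aliases), and `spec.resolved.yaml`.
#'
#' @param gen result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lines <- vapply(gen$resources, function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA))
  }, "")
  writeLines(lines, file.path(dir, "cohort.ndjson"))
  utils::write.csv(gen$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE)
  write_mapping_table(gen$table, file.path(dir, "mappings.tsv"))
  sp <- gen$spec
  sp$as_of_date <- format(sp$as_of_date)
  sp$planted_eligible_fraction <- as.list(sp$planted_eligible_fraction)
  yaml::write_yaml(unclass(sp), file.path(dir, "spec.resolved.yaml"))
  invisible(dir)
}

#' Read a cohort spec from YAML
#'
#' @param path YAML file with the [cohort_spec()] fields.
#' @return a `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  y <- yaml::read_yaml(path)
  pe <- unlist(y$planted_eligible_fraction)
  defaults <- formals(cohort_spec)
  cohort_spec(
    n_patients = y$n_patients %||% eval(defaults$n_patients),
    seed = y$seed %||% eval(defaults$seed),
    age_range = unlist(y$age_range) %||% eval(defaults$age_range),
    fraction_in_target = y$fraction_in_target %||%
      eval(defaults$fraction_in_target),
    planted_eligible_fraction = if (is.null(pe))
      eval(defaults$planted_eligible_fraction) else pe,
    fraction_onset_comment_only = y$fraction_onset_comment_only %||%
      eval(defaults$fraction_onset_comment_only),
    fraction_lineage_comment_only = y$fraction_lineage_comment_only %||%
      eval(defaults$fraction_lineage_comment_only),
    fraction_local_terms = y$fraction_local_terms %||%
      eval(defaults$fraction_local_terms),
    fraction_nonblood_decoys = y$fraction_nonblood_decoys %||%
      eval(defaults$fraction_nonblood_decoys),
    fraction_prior_counseling = y$fraction_prior_counseling %||%
      eval(defaults$fraction_prior_counseling),
    as_of_date = y$as_of_date %||% eval(defaults$as_of_date))
}
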