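# Synthetic cohort generation: determinism, spec validation, and
# planted-label soundness.

test_that("the same spec and seed produce byte-identical output", {
  spec <- cohort_spec(n_patients = 60, seed = 7)
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(generate_cohort(spec), d1)
  write_cohort(generate_cohort(spec), d2)
  for (f in c("cohort.ndjson", "labels.csv", "mappings.tsv",
              "spec.resolved.yaml")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # a different seed changes the cohort
  d3 <- tempfile()
  write_cohort(generate_cohort(cohort_spec(n_patients = 60, seed = 8)), d3)
  expect_false(identical(readLines(file.path(d1, "cohort.ndjson")),
                         readLines(file.path(d3, "cohort.ndjson"))))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99); a <- runif(3)
  set.seed(99); invisible(generate_cohort(cohort_spec(n_patients = 10)))
  b <- runif(3)
  expect_identical(a, b)
})

test_that("unsatisfiable specs are rejected at construction", {
  expect_error(cohort_spec(fraction_in_target = 0.05,
                           planted_eligible_fraction = c(breast_ovarian = 0.2,
                                                         colorectal = 0.0)),
               "cannot be satisfied")
  expect_error(cohort_spec(fraction_local_terms = 1.5), "fractions")
  expect_error(cohort_spec(planted_eligible_fraction = c(breast = 0.1)),
               "breast_ovarian")
})

test_that("labels are sound: conservative screening of noise-free output reproduces them exactly", {
  spec <- cohort_spec(n_patients = 300, seed = 13,
                      fraction_onset_comment_only = 0,
                      fraction_lineage_comment_only = 0,
                      fraction_local_terms = 0,
                      fraction_prior_counseling = 0)
  gen <- generate_cohort(spec)
  cfg <- target_population_config(as_of_date = spec$as_of_date)
  out <- screen_population(gen$cohort, cfg = cfg, mode = "conservative")
  lab <- gen$labels
  reg <- as.data.frame(out$registry)
  m <- merge(lab, reg[c("patient_id", "breast_met", "colorectal_met")],
             by = "patient_id", all.x = TRUE)
  m$breast_met[is.na(m$breast_met)] <- FALSE
  m$colorectal_met[is.na(m$colorectal_met)] <- FALSE
  discordant <- sum((m$eligible_breast != m$breast_met |
                       m$eligible_colorectal != m$colorectal_met) & m$in_target)
  expect_equal(discordant, 0)
  # n_screened equals the planted in-target count
  expect_equal(out$summary$n_screened, sum(lab$in_target))
})

test_that("planted_eligible_fraction 0 yields zero flagged patients", {
  spec <- cohort_spec(n_patients = 150, seed = 17,
                      planted_eligible_fraction = c(breast_ovarian = 0,
                                                    colorectal = 0))
  gen <- generate_cohort(spec)
  cfg <- target_population_config(as_of_date = spec$as_of_date)
  out <- screen_population(gen$cohort, gen$table, cfg = cfg)
  expect_equal(nrow(out$registry), 0)
})

test_that("cancer in non-blood relatives never fires criteria (decoy specificity)", {
  spec <- cohort_spec(n_patients = 150, seed = 19,
                      planted_eligible_fraction = c(breast_ovarian = 0,
                                                    colorectal = 0),
                      fraction_nonblood_decoys = 1.0)
  gen <- generate_cohort(spec)
  # confirm decoys exist: some relative maps to a non-blood concept with a
  # cancer event
  nb_cancer <- vapply(gen$cohort$fhh, function(r) {
    cc <- map_relationship(r$relationship_term, gen$table)
    !is.null(cc) && !cc$blood_relative && length(r$diagnoses) > 0
  }, TRUE)
  expect_gte(sum(nb_cancer), 30)
  cfg <- target_population_config(as_of_date = spec$as_of_date)
  out <- screen_population(gen$cohort, gen$table, cfg = cfg)
  expect_equal(nrow(out$registry), 0)
})

test_that("raising comment-only onset noise with comments disabled only lowers flagged counts", {
  cfg <- target_population_config(as_of_date = "2019-07-05")
  flagged <- vapply(c(0, 0.5, 1), function(frac) {
    spec <- cohort_spec(n_patients = 200, seed = 29,
                        fraction_onset_comment_only = frac,
                        fraction_lineage_comment_only = 0,
                        fraction_local_terms = 0,
                        fraction_prior_counseling = 0)
    gen <- generate_cohort(spec)
    out <- screen_population(gen$cohort, gen$table, cfg = cfg,
                             use_comments = FALSE)
    # never a false positive
    planted <- gen$labels$patient_id[gen$labels$eligible_breast |
                                       gen$labels$eligible_colorectal]
    expect_true(all(out$registry$patient_id %in% planted))
    nrow(out$registry)
  }, 1)
  expect_true(all(diff(flagged) <= 0))
})

test_that("generated resources pass through the file reader unchanged", {
  spec <- cohort_spec(n_patients = 40, seed = 3)
  gen <- generate_cohort(spec)
  dir <- tempfile()
  write_cohort(gen, dir)
  cohort <- read_cohort(file.path(dir, "cohort.ndjson"))
  expect_identical(cohort$demographics, gen$cohort$demographics)
  expect_identical(cohort$fhh, gen$cohort$fhh)
  tab <- load_mapping_table(file.path(dir, "mappings.tsv"))
  expect_equal(map_relationship("mom", tab)$degree, "1")
  expect_equal(map_condition("CA breast", tab), "breast")
  spec2 <- read_cohort_spec(file.path(dir, "spec.resolved.yaml"))
  expect_equal(spec2$n_patients, spec$n_patients)
  expect_equal(spec2$seed, spec$seed)
})
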