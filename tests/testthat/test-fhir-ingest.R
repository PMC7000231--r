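# FHIR-style ingest and registry persistence.

test_that("a Bundle with one patient and two relatives reads as counted", {
  path <- tempfile(fileext = ".json")
  write_bundle(list(
    fhir_patient("P1", "1980-05-01"),
    fhir_fmh("F1", "P1", "aunt", list(fhir_condition("breast cancer", 42))),
    fhir_fmh("F2", "P1", "mother")), path)
  cohort <- read_cohort(path)
  expect_equal(nrow(cohort$demographics), 1)
  expect_length(cohort$fhh, 2)
  # a relative with no condition entries is retained with empty diagnoses
  expect_length(cohort$fhh[[2]]$diagnoses, 0)
  expect_equal(cohort$log$n_orphans, 0L)
})

test_that("an empty NDJSON file yields an empty cohort with no warnings", {
  path <- tempfile(fileext = ".ndjson")
  writeLines(character(), path)
  expect_no_warning(cohort <- read_cohort(path))
  expect_equal(nrow(cohort$demographics), 0)
  expect_length(cohort$fhh, 0)
})

test_that("a relative referencing an absent patient is logged as an orphan", {
  path <- tempfile(fileext = ".json")
  write_bundle(list(
    fhir_fmh("F1", "GHOST", "aunt", list(fhir_condition("breast cancer")))),
    path)
  expect_message(cohort <- read_cohort(path), "1 FamilyMemberHistory")
  expect_equal(nrow(cohort$demographics), 0)
  expect_length(cohort$fhh, 0)
  expect_equal(cohort$log$n_orphans, 1L)
})

test_that("unknown resource types are skipped with a warning; malformed JSON names the file", {
  path <- tempfile(fileext = ".json")
  write_bundle(list(fhir_patient("P1"),
                    list(resourceType = "Observation", id = "O1")), path)
  expect_warning(cohort <- read_cohort(path), "Observation")
  expect_equal(cohort$log$n_skipped, 1L)

  bad <- tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(read_cohort(bad), basename(bad))
})

test_that("NDJSON and Bundle renderings of the same resources read identically", {
  res <- list(
    fhir_patient("P1", "1975-11-30", "male"),
    fhir_fmh("F1", "P1", "brother",
             list(fhir_condition("colon cancer", 48, note = "late 40s"))))
  p1 <- write_bundle(res, tempfile(fileext = ".json"))
  p2 <- write_ndjson(res, tempfile(fileext = ".ndjson"))
  c1 <- read_cohort(p1)
  c2 <- read_cohort(p2)
  expect_identical(c1$demographics, c2$demographics)
  expect_identical(c1$fhh, c2$fhh)
  # determinism: re-reading gives an identical cohort
  expect_identical(c1, read_cohort(p1))
})

test_that("structured fields and comments land in the right record slots", {
  path <- tempfile(fileext = ".json")
  write_bundle(list(
    fhir_patient("P1", extra = list(
      extension = list(
        list(url = fhhscreen:::EXT_PRIOR_COUNSELING, valueBoolean = TRUE),
        list(url = fhhscreen:::EXT_PREFERRED_CONTACT, valueCode = "mail")),
      generalPractitioner = list(list(reference = "Practitioner/PCP9")))),
    fhir_fmh("F1", "P1", "aunt",
             list(fhir_condition("breast cancer", note = "early 30s"),
                  fhir_condition("diabetes", onset_string = "in her 50s")),
             note = "maternal side")), path)
  cohort <- read_cohort(path)
  d <- cohort$demographics
  expect_true(d$prior_genetic_counseling)
  expect_equal(d$preferred_contact, "mail")
  expect_equal(d$provider_id, "PCP9")
  rec <- cohort$fhh[[1]]
  expect_equal(rec$record_comment, "maternal side")
  expect_equal(rec$diagnoses[[1]]$comment, "early 30s")
  # onsetString routes into the comment pathway
  expect_match(rec$diagnoses[[2]]$comment, "in her 50s")
})

test_that("partial birth dates resolve to deterministic midpoints", {
  expect_equal(fhhscreen:::parse_fhir_date("1980"), as.Date("1980-07-01"))
  expect_equal(fhhscreen:::parse_fhir_date("1980-03"), as.Date("1980-03-15"))
  expect_equal(fhhscreen:::parse_fhir_date("1980-03-09"), as.Date("1980-03-09"))
  expect_true(is.na(fhhscreen:::parse_fhir_date("last year")))
})

test_that("registry write/read round-trips field-for-field in CSV and JSON", {
  reg <- make_registry(3)
  reg <- drive_to(reg, "P02", c("notify_provider", "send_outreach", "schedule"))
  reg$colorectal_met[1] <- TRUE  # an entry with both flags true
  reg$provider_id[3] <- NA
  for (fmt in c("csv", "json")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_registry(reg, path, fmt)
    back <- read_registry(path)
    expect_equal(back, reg, ignore_attr = FALSE)
  }
})

test_that("an empty registry writes a header-only CSV and reads back empty", {
  path <- tempfile(fileext = ".csv")
  write_registry(new_registry(), path, "csv")
  lines <- readLines(path)
  expect_length(lines, 1)
  expect_match(lines, "patient_id")
  expect_equal(nrow(read_registry(path)), 0)
})

test_that("registry rows are ordered by patient_id regardless of input order", {
  reg <- new_registry(patient_id = c("P9", "P1", "P5"),
                      breast_met = c(TRUE, TRUE, FALSE),
                      colorectal_met = c(FALSE, FALSE, TRUE),
                      fired_criteria = c("B1", "B2", "C1"))
  expect_equal(reg$patient_id, c("P1", "P5", "P9"))
  path <- tempfile(fileext = ".csv")
  write_registry(reg, path)
  expect_equal(read_registry(path)$patient_id, c("P1", "P5", "P9"))
})
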