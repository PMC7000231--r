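# Rule engine: target population, onset thresholds, criterion evaluation.

cfg_2019 <- target_population_config(as_of_date = "2019-07-05")

test_that("target population filters on floor age 25-60 and a recent completed primary-care visit", {
  # age 40, completed visit 2 years ago
  expect_true(in_target_population(
    make_demo(birth_date = "1979-01-15"), make_enc(date = "2017-07-10"),
    cfg_2019))
  # age 61: excluded
  expect_false(in_target_population(
    make_demo(birth_date = "1958-06-01"), make_enc(date = "2018-07-10"),
    cfg_2019))
  # age 24: excluded; 25 on the boundary: included
  expect_false(in_target_population(
    make_demo(birth_date = "1994-08-01"), make_enc(date = "2018-07-10"),
    cfg_2019))
  expect_true(in_target_population(
    make_demo(birth_date = "1994-07-05"), make_enc(date = "2018-07-10"),
    cfg_2019))
  # visit exactly on the lookback boundary date counts (inclusive window)
  expect_true(in_target_population(
    make_demo(birth_date = "1979-01-15"), make_enc(date = "2016-07-05"),
    cfg_2019))
  expect_false(in_target_population(
    make_demo(birth_date = "1979-01-15"), make_enc(date = "2016-07-04"),
    cfg_2019))
  # cancelled or non-primary-care visits never qualify
  expect_false(in_target_population(
    make_demo(), make_enc(date = "2018-07-10", status = "cancelled"),
    cfg_2019))
  expect_false(in_target_population(
    make_demo(), make_enc(date = "2018-07-10", type = "dermatology"),
    cfg_2019))
  # no encounters at all
  expect_false(in_target_population(make_demo(), no_enc(), cfg_2019))
})

test_that("a missing birth date excludes the patient with a logged reason", {
  d <- make_demo(); d$birth_date <- as.Date(NA)
  expect_message(res <- in_target_population(d, make_enc(), cfg_2019),
                 "birth_date")
  expect_false(res)
})

test_that("onset thresholds treat the uncertainty interval per mode", {
  t45 <- function(o, m) onset_satisfies(o, 45, m)
  expect_true(t45(onset_estimate("range", 30, 33), "conservative"))
  expect_false(t45(onset_estimate("range", 40, 49), "conservative"))
  expect_true(t45(onset_estimate("range", 40, 49), "optimistic"))
  expect_false(t45(onset_estimate("unknown"), "conservative"))
  expect_false(t45(onset_estimate("unknown"), "optimistic"))
  # inclusive threshold: exactly T satisfies
  expect_true(t45(onset_estimate("exact", 45, 45), "conservative"))
  expect_false(t45(onset_estimate("exact", 46, 46), "conservative"))
})

test_that("a single early-onset breast relative fires; a spouse with the same history does not", {
  b1 <- criterion("B1", "breast_ovarian", "breast", 1, 1:2,
                  max_onset_age = 45, min_onset_qualifying = 1)
  aunt <- make_rel("r1", "2", events = list(make_event("breast", 42)))
  res <- evaluate_criterion(b1, list(aunt))
  expect_true(res$met)
  expect_equal(res$contributing, "r1")

  spouse <- make_rel("r1", "not_blood", blood = FALSE,
                     events = list(make_event("breast", 42)))
  expect_false(evaluate_criterion(b1, list(spouse))$met)
})

test_that("same-lineage criteria require one side; first-degree counts toward either", {
  b4 <- criterion("B4", "breast_ovarian", "breast", 2, 1:3,
                  max_onset_age = 50, min_onset_qualifying = 1,
                  same_lineage_required = TRUE)
  mat_aunt <- make_rel("r1", "2", "maternal",
                       events = list(make_event("breast", 48)))
  pat_gma <- make_rel("r2", "2", "paternal",
                      events = list(make_event("breast", 45)))
  # different sides: not met
  expect_false(evaluate_criterion(b4, list(mat_aunt, pat_gma))$met)
  # two maternal-side relatives: met
  mat_gma <- make_rel("r3", "2", "maternal",
                      events = list(make_event("breast", 60)))
  res <- evaluate_criterion(b4, list(mat_aunt, mat_gma))
  expect_true(res$met)
  expect_setequal(res$contributing, c("r1", "r3"))
  # a mother (first-degree) combines with either side
  mother <- make_rel("r4", "1", events = list(make_event("breast", 60)))
  expect_true(evaluate_criterion(b4, list(mat_aunt, mother))$met)
  expect_true(evaluate_criterion(b4, list(pat_gma, mother))$met)
  # unknown lineage never combines toward a side in conservative mode...
  unk <- make_rel("r5", "2", "unknown",
                  events = list(make_event("breast", 41)))
  expect_false(evaluate_criterion(b4, list(mat_aunt, unk),
                                  mode = "conservative")$met)
  # ...but may in optimistic mode
  expect_true(evaluate_criterion(b4, list(mat_aunt, unk),
                                 mode = "optimistic")$met)
})

test_that("ancestry-gated criteria need the proband flag", {
  b6 <- criterion("B6", "breast_ovarian", "breast", 1, 1:2,
                  ancestry_required = "ashkenazi_jewish")
  aunt <- make_rel("r1", "2", events = list(make_event("breast", 60)))
  expect_false(evaluate_criterion(b6, list(aunt), make_demo())$met)
  expect_true(evaluate_criterion(
    b6, list(aunt), make_demo(ancestry = "ashkenazi_jewish"))$met)
})

test_that("evaluate_patient aggregates tracks and keeps a complete audit trace", {
  # ovarian aunt at any (unknown) age -> breast/ovarian track
  aunt <- make_rel("r1", "2", events = list(make_event("ovarian", NA)))
  res <- evaluate_patient(make_demo(), list(aunt))
  expect_true(res$breast_met)
  expect_false(res$colorectal_met)
  expect_equal(vapply(res$fired_criteria, `[[`, "", "criterion_id"), "B2")

  # father's colorectal cancer at 45 -> colorectal track
  father <- make_rel("r2", "1", sex = "male",
                     events = list(make_event("colorectal", 45)))
  res <- evaluate_patient(make_demo(), list(father))
  expect_true(res$colorectal_met)
  expect_false(res$breast_met)

  # no FHH: both flags false, empty trace
  res <- evaluate_patient(make_demo(), list())
  expect_false(res$breast_met || res$colorectal_met)
  expect_length(res$fired_criteria, 0)
})

test_that("criterion and ruleset invariants are enforced at construction", {
  expect_error(criterion("X", "colorectal", "colorectal", 1, 1:2,
                         max_onset_age = 50, min_onset_qualifying = 0),
               "iff")
  expect_error(criterion("X", "colorectal", "colorectal", 1, 1:2,
                         min_onset_qualifying = 2))
  expect_error(ruleset("v", list(
    criterion("A", "colorectal", "colorectal", 1, 1:2),
    criterion("A", "colorectal", "colorectal", 1, 1:2))),
    "duplicate")
  expect_error(ruleset("v", list(
    criterion("A", "colorectal", "colorectal", 1, 1:2))),
    "disease track")
})

test_that("the shipped ruleset loads, validates, and matches its config file", {
  rs <- default_ruleset()
  ids <- vapply(rs$criteria, `[[`, "", "criterion_id")
  expect_setequal(ids, c("B1", "B2", "B3", "B4", "B5", "B6",
                         "C1", "C2", "C3", "C4"))
  b6 <- rs$criteria[[which(ids == "B6")]]
  expect_false(b6$enabled)
  expect_equal(b6$ancestry_required, "ashkenazi_jewish")
  c1 <- rs$criteria[[which(ids == "C1")]]
  expect_equal(c1$allowed_degrees, 1L)
  expect_equal(c1$max_onset_age, 50L)
})

test_that("engine agrees with the exhaustive subset/lineage oracle on random cases", {
  set.seed(101)
  for (i in 1:400) {
    crit <- rand_criterion()
    rels <- lapply(seq_len(sample(0:6, 1)), function(j) {
      rand_relative(paste0("r", j))
    })
    mode <- sample(c("conservative", "optimistic"), 1)
    got <- evaluate_criterion(crit, rels, mode = mode)$met
    want <- brute_evaluate(crit, rels, mode = mode)
    expect_equal(got, want,
                 info = sprintf("case %d (mode %s)", i, mode))
  }
})

test_that("adding relatives or events never un-meets a criterion (monotonicity)", {
  set.seed(202)
  for (i in 1:120) {
    crit <- rand_criterion()
    rels <- lapply(seq_len(sample(1:4, 1)), function(j) {
      rand_relative(paste0("r", j))
    })
    mode <- sample(c("conservative", "optimistic"), 1)
    base <- evaluate_criterion(crit, rels, mode = mode)$met
    if (!base) next
    # add a relative
    more <- c(rels, list(rand_relative("extra")))
    expect_true(evaluate_criterion(crit, more, mode = mode)$met)
    # add an event to an existing relative
    rels2 <- rels
    rels2[[1]]$events <- c(rels2[[1]]$events,
                           list(make_event("breast", 30, ref = "r1")))
    expect_true(evaluate_criterion(crit, rels2, mode = mode)$met)
  }
})

test_that("conservative-met implies optimistic-met (mode dominance)", {
  set.seed(303)
  for (i in 1:150) {
    crit <- rand_criterion()
    rels <- lapply(seq_len(sample(0:5, 1)), function(j) {
      rand_relative(paste0("r", j))
    })
    if (evaluate_criterion(crit, rels, mode = "conservative")$met) {
      expect_true(evaluate_criterion(crit, rels, mode = "optimistic")$met)
    }
  }
})

test_that("removing all contributing relatives un-meets the criterion (trace soundness)", {
  set.seed(404)
  tested <- 0L
  for (i in 1:200) {
    crit <- rand_criterion()
    rels <- lapply(seq_len(sample(1:6, 1)), function(j) {
      rand_relative(paste0("r", j))
    })
    res <- evaluate_criterion(crit, rels)
    if (!res$met) next
    tested <- tested + 1L
    kept <- Filter(function(r) !r$record_id %in% res$contributing, rels)
    expect_false(evaluate_criterion(crit, kept)$met)
  }
  expect_gte(tested, 10L)
})
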