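# Outreach state machine and disposition reporting.

test_that("the happy path advances through the documented lifecycle", {
  reg <- make_registry(1)
  reg <- drive_to(reg, "P01", c("notify_provider", "send_outreach",
                                "schedule", "visit_completed",
                                "test_positive"))
  expect_equal(reg$status, "tested_positive")
  expect_equal(reg$contact_attempts, 1L)  # the initial outreach message
  expect_equal(nrow(reg$history[[1]]), 5)
})

test_that("three unanswered phone attempts are required before unreachable", {
  reg <- make_registry(1)
  reg <- drive_to(reg, "P01", c("notify_provider", "send_outreach"))
  # cannot mark unreachable after only the initial message
  expect_error(advance(reg, "P01", "mark_unreachable"), "illegal")
  reg <- drive_to(reg, "P01", rep("phone_no_answer", 3))
  expect_equal(reg$contact_attempts, 4L)
  # a fourth phone attempt is not allowed
  expect_error(advance(reg, "P01", "phone_no_answer"), "illegal")
  reg <- advance(reg, "P01", "mark_unreachable", timestamp = "t")
  expect_equal(reg$status, "unreachable")
})

test_that("illegal transitions are rejected with the allowed events named", {
  reg <- make_registry(1)
  err <- tryCatch(advance(reg, "P01", "schedule"), error = identity)
  expect_match(conditionMessage(err), "illegal transition")
  expect_match(conditionMessage(err), "notify_provider")
  # terminal states allow nothing
  reg <- drive_to(reg, "P01", c("notify_provider", "send_outreach",
                                "schedule", "visit_completed",
                                "test_negative"))
  for (ev in c("schedule", "visit_completed", "test_positive",
               "send_outreach")) {
    expect_error(advance(reg, "P01", ev), "illegal|terminal")
  }
  expect_error(advance(reg, "P01", "made_up_event"), "unknown event")
})

test_that("every non-terminal status accepts exactly its tabled events", {
  expect_setequal(legal_events("identified"), "notify_provider")
  expect_setequal(legal_events("provider_notified"), "send_outreach")
  expect_setequal(legal_events("outreach_sent", 1L),
                  c("phone_no_answer", "schedule", "decline",
                    "consider_future", "no_need"))
  expect_setequal(legal_events("outreach_sent", 4L),
                  c("schedule", "decline", "consider_future", "no_need",
                    "mark_unreachable"))
  expect_setequal(legal_events("scheduled"),
                  c("mark_pending", "visit_completed"))
  expect_setequal(legal_events("completed_visit"),
                  c("test_negative", "test_positive", "no_test"))
  for (terminal in c("declined", "consider_future", "unreachable", "no_need",
                     "appointment_pending", "tested_negative",
                     "tested_positive", "completed_no_test",
                     "prior_counseling_excluded")) {
    expect_length(legal_events(terminal), 0)
  }
})

test_that("replaying a saved history reproduces the final state", {
  set.seed(77)
  paths <- list(
    c("notify_provider", "send_outreach", "schedule", "visit_completed",
      "test_negative"),
    c("notify_provider", "send_outreach", "phone_no_answer",
      "phone_no_answer", "schedule", "mark_pending"),
    c("notify_provider", "send_outreach", rep("phone_no_answer", 3),
      "mark_unreachable"),
    c("notify_provider", "send_outreach", "decline"))
  for (evs in paths) {
    reg <- make_registry(1)
    reg <- drive_to(reg, "P01", evs)
    st <- replay_history(reg$history[[1]])
    expect_equal(st$status, reg$status)
    expect_equal(st$contact_attempts, reg$contact_attempts)
  }
  # and through a persistence round trip
  reg <- make_registry(1)
  reg <- drive_to(reg, "P01", paths[[2]])
  path <- tempfile(fileext = ".csv")
  write_registry(reg, path)
  back <- read_registry(path)
  st <- replay_history(back$history[[1]])
  expect_equal(st$status, back$status)
})

test_that("disposition percentages reproduce a pilot-style accounting", {
  # 71 contacted: 25 scheduled (11 still scheduled, 1 pending, 13 completed:
  # 8 negative / 2 positive / 3 untested), 10 declined, 7 considering,
  # 27 unreachable, 2 no need
  reg <- registry_with_dispositions(11, 1, 0, 8, 2, 3, 10, 7, 27, 2)
  rep_ <- disposition_report(reg)
  expect_equal(rep_$n_outreach, 71)
  got <- setNames(rep_$outreach$pct, rep_$outreach$status)
  expect_equal(got[["scheduled"]], 35)
  expect_equal(got[["declined"]], 14)
  expect_equal(got[["consider_future"]], 10)
  expect_equal(got[["unreachable"]], 38)
  expect_equal(got[["no_need"]], 3)
  # nested: 13 completed of 25 scheduled
  expect_equal(rep_$completed$n, 13)
  expect_equal(rep_$completed$of_scheduled, 25)
  expect_equal(rep_$completed$of_scheduled_pct, 52)
  # testing outcomes over the 13 completed visits
  expect_equal(unname(rep_$testing$pct),
               c(62, 15, 23))  # negative, positive, no test
})

test_that("overlapping annotation flags are tallied outside the partition", {
  reg <- registry_with_dispositions(11, 1, 0, 8, 2, 3, 10, 7, 27, 2)
  self_reported <- rep(FALSE, nrow(reg)); self_reported[1:3] <- TRUE
  rep_ <- disposition_report(reg, annotations = list(
    self_reported_prior_counseling = self_reported))
  ann <- rep_$annotations$self_reported_prior_counseling
  expect_equal(ann$count, 3)
  expect_equal(ann$pct, 4)
})

test_that("an empty registry reports zero counts and undefined rates", {
  rep_ <- disposition_report(new_registry())
  expect_equal(rep_$n_outreach, 0)
  expect_true(all(rep_$outreach$count == 0))
  expect_true(all(is.na(rep_$outreach$pct)))
  expect_true(is.na(rep_$completed$of_scheduled_pct))
  expect_true(all(is.na(rep_$testing$pct)))
})

test_that("half-away-from-zero rounding reproduces all printed percent pairs", {
  pairs <- list(  # count, denominator, printed percent
    c(25, 71, 35), c(10, 71, 14), c(7, 71, 10), c(27, 71, 38), c(2, 71, 3),
    c(13, 25, 52), c(2, 13, 15), c(10, 13, 77), c(8, 13, 62), c(3, 13, 23),
    c(3, 71, 4))
  for (p in pairs) {
    expect_equal(round_half_away(100 * p[1] / p[2]), p[3],
                 info = sprintf("%d/%d", p[1], p[2]))
  }
  # one-decimal prevalence rounding
  expect_equal(round_half_away(100 * 5245 / 143012, 1), 3.7)
  expect_equal(round_half_away(100 * 60 / 5245, 1), 1.1)
  expect_equal(round_half_away(100 * 16850 / 311957, 1), 5.4)
  # and the half-way behaviour itself
  expect_equal(round_half_away(2.5), 3)
  expect_equal(round_half_away(3.65, 1), 3.7)
  expect_equal(round_half_away(-2.5), -3)
})
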