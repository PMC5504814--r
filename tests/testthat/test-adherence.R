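plan_row <- function(plan_id = "p1", option_id = "drug_a", times = 1L,
                     days = "daily", start = "2020-01-06", end = NA,
                     kind = "medication") {
  tibble::tibble(plan_id = plan_id, option_id = option_id, dose_label = NA_character_,
                 times_per_day = as.integer(times), days = days, kind = kind,
                 start = as.Date(start), end = as.Date(end))
}

test_that("schedule expansion walks the calendar with the documented slot times", {
  s1 <- expand_schedule(plan_row(times = 1), "2020-01-06", "2020-01-12")
  expect_equal(nrow(s1), 7)
  expect_true(all(format(s1$planned_time, "%H:%M", tz = "UTC") == "08:00"))

  s2 <- expand_schedule(plan_row(times = 2), "2020-01-06", "2020-01-07")
  expect_equal(nrow(s2), 4)
  expect_setequal(unique(format(s2$planned_time, "%H:%M", tz = "UTC")),
                  c("08:00", "20:00"))

  s3 <- expand_schedule(plan_row(times = 3), "2020-01-06", "2020-01-06")
  expect_equal(format(s3$planned_time, "%H:%M", tz = "UTC"),
               c("08:00", "14:00", "20:00")) # evenly spaced between anchors

  wk <- expand_schedule(plan_row(days = "weekdays"), "2020-01-06", "2020-01-12")
  expect_equal(nrow(wk), 5) # 2020-01-06 is a Monday
  mwf <- expand_schedule(plan_row(days = "mon,wed,fri"), "2020-01-06", "2020-01-12")
  expect_equal(nrow(mwf), 3)

  expect_equal(nrow(expand_schedule(plan_row(end = "2020-01-10"),
                                    "2021-01-01", "2021-02-01")), 0)
})

test_that("schedule expansion matches a day-by-day oracle and concatenates over ranges", {
  set.seed(31)
  for (i in 1:60) {
    start <- as.Date("2020-01-01") + sample(0:30, 1)
    end <- if (runif(1) < 0.3) as.Date(NA) else start + sample(5:40, 1)
    days <- sample(c("daily", "weekdays", "mon,thu", "tue,sat,sun"), 1)
    times <- sample(1:3, 1)
    p <- plan_row(times = times, days = days, start = start, end = end)
    from <- as.Date("2020-01-01") + sample(0:20, 1)
    to <- from + sample(0:50, 1)
    got <- nrow(expand_schedule(p, from, to))
    expect_equal(got, oracle_slot_count(start, end, from, to, days, times))
    # adjacent disjoint ranges concatenate to the full expansion
    mid <- from + sample(0:as.numeric(to - from), 1)
    a <- expand_schedule(p, from, mid)
    b <- if (mid < to) expand_schedule(p, mid + 1, to) else a[0, ]
    full <- expand_schedule(p, from, to)
    expect_equal(nrow(a) + nrow(b), nrow(full))
    expect_equal(dplyr::bind_rows(a, b)$planned_time, full$planned_time)
  }
})

intakes_for <- function(slots, take_idx) {
  tibble::tibble(
    planned_datetime = slots$planned_time[take_idx],
    option_id = slots$option_id[take_idx],
    taken = TRUE,
    taken_datetime = slots$planned_time[take_idx] + 300
  )
}

test_that("adherence rates count matched slots per option and pooled", {
  slots <- expand_schedule(plan_row(), "2020-01-06", "2020-01-09") # 4 slots
  all_taken <- adherence_rate(slots, intakes_for(slots, 1:4), "2020-01-06", "2020-01-09")
  expect_equal(all_taken$rate[all_taken$option_id == "(overall)"], 100)
  three <- adherence_rate(slots, intakes_for(slots, 1:3), "2020-01-06", "2020-01-09")
  expect_equal(three$rate[three$option_id == "(overall)"], 75)
  expect_equal(three$planned[three$option_id == "drug_a"], 4)
  expect_equal(three$taken[three$option_id == "drug_a"], 3)
  # an event on a day with no free slot is logged, not counted
  extra <- dplyr::bind_rows(intakes_for(slots, 1:4), intakes_for(slots, 4))
  a2 <- adherence_rate(slots, extra, "2020-01-06", "2020-01-09")
  expect_equal(a2$rate[a2$option_id == "(overall)"], 100)
  expect_equal(attr(a2, "unmatched_taken"), 1L)
})

test_that("adherence matching agrees with an exhaustive by-key oracle and ignores event order", {
  set.seed(32)
  for (i in 1:40) {
    plans <- dplyr::bind_rows(
      plan_row("p1", "drug_a", times = sample(1:2, 1)),
      plan_row("p2", "drug_b", times = sample(1:2, 1))
    )
    from <- as.Date("2020-01-06"); to <- from + 6
    slots <- expand_schedule(plans, from, to)
    take <- sample(nrow(slots), sample(0:nrow(slots), 1))
    intakes <- intakes_for(slots, take)
    res <- adherence_rate(slots, intakes, from, to)
    # oracle: count per (option, day) the min of planned slots and taken events
    matched <- 0
    for (opt in unique(slots$option_id)) {
      for (d in unique(as.character(slots$date))) {
        n_slots <- sum(slots$option_id == opt & as.character(slots$date) == d)
        n_events <- sum(intakes$option_id == opt &
                        as.character(as.Date(intakes$taken_datetime)) == d)
        matched <- matched + min(n_slots, n_events)
      }
    }
    expect_equal(res$taken[res$option_id == "(overall)"], matched)
    # permutation of events leaves every rate unchanged
    res2 <- adherence_rate(slots, intakes[sample(nrow(intakes)), ], from, to)
    expect_equal(res2$rate, res$rate)
    expect_true(all(res$rate >= 0 & res$rate <= 100, na.rm = TRUE))
  }
})

test_that("monitoring fidelity counts submitted-on-schedule days", {
  mp <- tibble::tibble(outcome_id = "mood", days = "daily",
                       start = as.Date("2020-01-06"), end = as.Date(NA))
  obs <- tibble::tibble(timestamp = as.Date("2020-01-06") + c(0, 1, 3),
                        outcome_id = "mood", value = 5)
  mf <- monitoring_fidelity(mp, obs, "2020-01-06", "2020-01-09")
  expect_equal(mf$scheduled[mf$outcome_id == "mood"], 4)
  expect_equal(mf$submitted[mf$outcome_id == "mood"], 3)
  expect_equal(mf$rate[mf$outcome_id == "(overall)"], 75)
  none <- monitoring_fidelity(mp, obs[0, ], "2020-01-06", "2020-01-09")
  expect_equal(none$rate[none$outcome_id == "(overall)"], 0)
  full <- monitoring_fidelity(mp, obs, "2020-01-06", "2020-01-07")
  expect_equal(full$rate[full$outcome_id == "(overall)"], 100)
})

record_with_adherence <- function(rate, n_days = 14, end = as.Date("2020-01-19"),
                                  fidelity_days = n_days) {
  start <- end - n_days + 1
  plans <- plan_row(start = start)
  slots <- expand_schedule(plans, start, end)
  k <- round(rate / 100 * nrow(slots))
  obs <- tibble::tibble(timestamp = start + seq_len(fidelity_days) - 1,
                        option_id = "drug_a", outcome_id = "mood",
                        value = 50, source = "patient", retrospective = 0L)
  patient_record("pt", plans = plans,
                 observations = obs[seq_len(fidelity_days), ],
                 intake_events = intakes_for(slots, seq_len(k)),
                 monitoring_plan = tibble::tibble(outcome_id = "mood", days = "daily",
                                                  start = start, end = as.Date(NA)))
}

test_that("alert rules fire strictly below the threshold and are monotone in it", {
  rec <- record_with_adherence(50) # 7 of 14 daily slots taken: exactly 50%
  rules <- tibble::tibble(rule_id = "r1", metric = "adherence_rate",
                          threshold_percent = 80, window_days = 14,
                          recipients = list("carer_1"))
  fired <- evaluate_alert_rules(rules, rec, "2020-01-19")
  expect_equal(nrow(fired), 1)
  expect_equal(fired$value, 50)
  expect_equal(fired$recipients[[1]], "carer_1")

  at_threshold <- dplyr::mutate(rules, threshold_percent = 50)
  expect_equal(nrow(evaluate_alert_rules(at_threshold, rec, "2020-01-19")), 0)

  # raising the threshold never unfires an alert
  set.seed(33)
  for (th in c(50, 60, 76, 90, 100)) {
    f_lo <- nrow(evaluate_alert_rules(dplyr::mutate(rules, threshold_percent = th),
                                      rec, "2020-01-19"))
    f_hi <- nrow(evaluate_alert_rules(dplyr::mutate(rules, threshold_percent = min(th + 10, 100)),
                                      rec, "2020-01-19"))
    expect_gte(f_hi, f_lo)
  }
  expect_error(evaluate_alert_rules(dplyr::mutate(rules, threshold_percent = 0),
                                    rec, "2020-01-19"),
               class = "healthopt_bounds_error")
})

test_that("alert evaluation matches independent recomputation over random records", {
  set.seed(34)
  for (i in 1:20) {
    rate <- sample(seq(0, 100, 5), 1)
    rec <- record_with_adherence(rate)
    th <- sample(seq(10, 100, 10), 1)
    rules <- tibble::tibble(rule_id = "r", metric = "adherence_rate",
                            threshold_percent = th, window_days = 14,
                            recipients = list("c"))
    fired <- evaluate_alert_rules(rules, rec, "2020-01-19")
    actual <- adherence_rate(rec, from = "2020-01-06", to = "2020-01-19")
    v <- actual$rate[actual$option_id == "(overall)"]
    expect_equal(nrow(fired) == 1, v < th)
  }
})

test_that("improvement snippets follow the severity rule table over the trailing fortnight", {
  good <- improvement_snippets(record_with_adherence(100), "2020-01-19")
  expect_equal(nrow(good), 1)
  expect_equal(good$severity, "on_track")

  half <- improvement_snippets(record_with_adherence(50), "2020-01-19")
  med <- half[half$metric == "medication_adherence", ]
  expect_equal(nrow(med), 1)
  expect_true(med$severity %in% c("warning", "urgent"))
  expect_equal(half$metric[1], "medication_adherence") # the only lagging metric

  # a missed monitoring streak outranks a mild medication dip
  both <- improvement_snippets(record_with_adherence(85, fidelity_days = 3), "2020-01-19")
  expect_equal(both$metric[1], "monitoring_fidelity")
  expect_equal(both$severity[1], "urgent")
  sev <- both$severity
  expect_true(all(diff(match(sev, c("urgent", "warning", "nudge"))) >= 0))

  # deterministic: recomputation yields the identical table
  expect_identical(half, improvement_snippets(record_with_adherence(50), "2020-01-19"))
})
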