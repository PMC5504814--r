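mood10 <- outcome_def("mood", instrument_min = 0, instrument_max = 10)
mood100 <- outcome_def("mood", instrument_min = 0, instrument_max = 100)

plans2 <- tibble::tibble(
  plan_id = c("p1", "p2"), option_id = "drug_a", dose_label = c("low", "high"),
  times_per_day = 1L, days = "daily", kind = "medication",
  start = as.Date(c("2020-01-01", "2020-02-01")),
  end = as.Date(c("2020-02-01", NA))
)

obs_on <- function(dates, values, outcome_id = "mood") {
  tibble::tibble(timestamp = as.Date(dates), outcome_id = outcome_id, value = values)
}

test_that("phase segmentation uses half-open intervals and partitions the observations", {
  obs <- obs_on(c("2019-12-25", "2020-01-15", "2020-02-01", "2020-03-01"), 1:4)
  seg <- segment_phases(plans2, obs)
  expect_equal(seg$plan_id, c(NA, "p1", "p2", "p2")) # switch day -> NEW plan
  expect_equal(nrow(seg), nrow(obs))                 # conservation

  one_open <- plans2[2, ]
  seg2 <- segment_phases(one_open, obs_on(c("2020-02-01", "2021-05-05"), c(1, 2)))
  expect_true(all(seg2$plan_id == "p2"))

  bad <- plans2
  bad$end[1] <- as.Date("2020-02-10")
  expect_error(segment_phases(bad, obs), class = "healthopt_period_error")
  expect_error(segment_phases(bad, obs), "p1.*p2")
})

test_that("random switch dates yield an exhaustive one-bucket-per-observation partition", {
  set.seed(21)
  for (i in 1:40) {
    k <- sample(1:4, 1)
    starts <- as.Date("2020-01-01") + sort(sample(0:200, k))
    ends <- c(starts[-1], as.Date(NA))
    plans <- tibble::tibble(plan_id = sprintf("p%d", 1:k), option_id = "a",
                            dose_label = NA, times_per_day = 1L, days = "daily",
                            kind = "medication", start = starts, end = ends)
    d <- as.Date("2019-12-15") + sample(0:250, 30, replace = TRUE)
    seg <- segment_phases(plans, obs_on(d, runif(30, 0, 10)))
    for (j in seq_along(d)) {
      expected <- NA_character_
      for (p in 1:k) {
        if (d[j] >= starts[p] && (is.na(ends[p]) || d[j] < ends[p])) expected <- sprintf("p%d", p)
      }
      expect_identical(seg$plan_id[j], expected)
    }
  }
})

test_that("phase summaries give exact statistics on constructed series", {
  obs <- obs_on(as.Date("2020-01-10") + 0:4, c(1, 2, 3, 4, 5))
  seg <- segment_phases(plans2, obs)
  s <- phase_summary(seg, mood10)
  expect_equal(s$n, 5)
  expect_equal(s$mean, 30)         # instrument 0-10 -> ratings 10..50
  expect_equal(s$trend_slope, 10)  # 10 rating points per day
  const <- phase_summary(segment_phases(plans2, obs_on(as.Date("2020-01-10") + 0:3, rep(4, 4))), mood10)
  expect_equal(const$sd, 0)
  expect_equal(const$trend_slope, 0)
  empty <- phase_summary(obs_on(character(0), numeric(0)), mood10)
  expect_equal(empty$n, 0)
  expect_true(is.na(empty$mean))
  single <- phase_summary(segment_phases(plans2, obs_on("2020-01-10", 5)), mood10)
  expect_true(is.na(single$trend_slope)) # slope needs n >= 2
})

test_that("trend slopes match the normal-equations oracle on random series", {
  set.seed(22)
  for (i in 1:50) {
    n <- sample(3:25, 1)
    d <- as.Date("2020-01-01") + sort(sample(0:60, n))
    v <- runif(n, 0, 10)
    s <- phase_summary(dplyr::mutate(obs_on(d, v), plan_id = "p"), mood10)
    expect_equal(s$trend_slope, oracle_slope(as.numeric(d), v * 10), tolerance = 1e-9)
    expect_equal(s$mean, mean(v * 10), tolerance = 1e-12)
    expect_equal(s$sd, stats::sd(v * 10), tolerance = 1e-12)
  }
})

test_that("NAP enumerates all pairs with half-credit ties and respects polarity", {
  r <- nonoverlap(obs_on(rep("2020-01-01", 3), c(3, 4, 5)),
                  obs_on(rep("2020-02-01", 2), c(4, 6)), mood10)
  expect_equal(r$pair_count, 6)
  expect_equal(r$improving_pairs, 4)
  expect_equal(r$ties, 1)
  expect_equal(r$nap, 0.75)

  all_better <- nonoverlap(obs_on(rep("2020-01-01", 3), c(1, 2, 3)),
                           obs_on(rep("2020-02-01", 3), c(4, 5, 6)), mood10)
  expect_equal(all_better$nap, 1)
  all_tied <- nonoverlap(obs_on(rep("2020-01-01", 2), c(5, 5)),
                         obs_on(rep("2020-02-01", 2), c(5, 5)), mood10)
  expect_equal(all_tied$nap, 0.5)
  # on a lower-is-better instrument, decreasing values are improvement
  lower <- outcome_def("pain", polarity = "lower_is_better",
                       instrument_min = 0, instrument_max = 10)
  dec <- nonoverlap(obs_on(rep("2020-01-01", 2), c(8, 9)),
                    obs_on(rep("2020-02-01", 2), c(1, 2)), lower)
  expect_equal(dec$nap, 1)
  expect_error(nonoverlap(obs_on(character(0), numeric(0)),
                          obs_on("2020-01-01", 5), mood10),
               class = "healthopt_empty_input")
})

test_that("NAP matches brute force and satisfies the symmetry identity", {
  set.seed(23)
  for (i in 1:80) {
    nb <- sample(2:15, 1); np <- sample(2:15, 1)
    b <- obs_on(rep("2020-01-01", nb), sample(0:10, nb, replace = TRUE))
    p <- obs_on(rep("2020-02-01", np), sample(0:10, np, replace = TRUE))
    ab <- nonoverlap(b, p, mood10)
    ba <- nonoverlap(p, b, mood10)
    expect_equal(ab$nap, oracle_nap(b$value * 10, p$value * 10), tolerance = 1e-12)
    expect_equal(ab$nap + ba$nap, 1, tolerance = 1e-12) # ties credited 0.5 each way
  }
})

test_that("on simulated data with a 2-sigma true improvement NAP is large", {
  set.seed(24)
  naps <- replicate(200, {
    b <- obs_on(rep("2020-01-01", 8), pmin(pmax(rnorm(8, 40, 10), 0), 100))
    p <- obs_on(rep("2020-02-01", 8), pmin(pmax(rnorm(8, 60, 10), 0), 100))
    nonoverlap(b, p, mood100)$nap
  })
  expect_gt(mean(naps), 0.85)
})

test_that("dosage effect groups phases by dose and conserves observation counts", {
  obs <- obs_on(as.Date("2020-01-10") + c(0:9, 40:49),
                c(rnorm(10, 4, 0.1), rnorm(10, 6, 0.1)))
  d <- dosage_effect(plans2, obs, mood10, "drug_a")
  expect_setequal(d$dose_label, c("low", "high"))
  expect_equal(sum(d$n), 20)
  single <- dosage_effect(plans2[1, ], obs[1:10, ], mood10, "drug_a")
  ps <- phase_summary(segment_phases(plans2[1, ], obs[1:10, ]), mood10)
  expect_equal(single$mean, ps$mean)
  expect_error(dosage_effect(plans2, obs, mood10, "ghost"),
               class = "healthopt_unknown_option")
})

test_that("a simulated dose-response is recovered to within a few rating points", {
  set.seed(25)
  obs <- obs_on(as.Date("2020-01-02") + c(0:29, 31:60),
                c(pmin(pmax(rnorm(30, 40, 5), 0), 100),
                  pmin(pmax(rnorm(30, 60, 5), 0), 100)))
  plans_mg <- tibble::tibble(
    plan_id = c("p1", "p2"), option_id = "drug_a",
    dose_label = c("300 mg", "600 mg"), times_per_day = 1L, days = "daily",
    kind = "medication",
    start = as.Date(c("2020-01-01", "2020-02-01")), end = as.Date(c("2020-02-01", NA))
  )
  d <- dosage_effect(plans_mg, obs, mood100, "drug_a")
  expect_equal(d$dose_label, c("300 mg", "600 mg")) # numeric prefix ordering
  expect_lt(abs(d$mean[1] - 40), 3)
  expect_lt(abs(d$mean[2] - 60), 3)
})

test_that("event windows form a union and membership matches a per-day oracle", {
  events <- tibble::tibble(timestamp = as.Date(c("2020-01-05", "2020-01-08")),
                           label = c("e1", "e2"), category = "stress")
  obs <- obs_on(as.Date("2020-01-01") + 0:19, rep(5, 20))
  ee <- event_effect(events, obs, mood10, window_days = 5)
  # per-day oracle: days 5-9 and 8-12 of January, union = 5..12 -> 8 days
  expect_equal(ee$n_post, 8)
  expect_equal(ee$n_background, 12)
  expect_equal(ee$difference, 0) # constant series

  none <- event_effect(events[0, ], obs, mood10, 5)
  expect_equal(none$n_post, 0)
  expect_equal(none$n_background, 20)
  expect_true(is.na(none$difference))
  expect_error(event_effect(events, obs, mood10, 0), class = "healthopt_bounds_error")

  set.seed(26)
  for (i in 1:30) {
    ev <- tibble::tibble(timestamp = as.Date("2020-01-01") + sample(0:30, 3),
                         label = "e", category = "c")
    d <- as.Date("2020-01-01") + sample(0:40, 25, replace = TRUE)
    w <- sample(1:10, 1)
    res <- event_effect(ev, obs_on(d, runif(25, 0, 10)), mood10, w)
    in_w <- vapply(d, function(day) {
      any(day >= ev$timestamp & day < ev$timestamp + w)
    }, logical(1))
    expect_equal(res$n_post, sum(in_w))
    expect_equal(res$n_background, sum(!in_w))
  }
})

test_that("timeline export emits one reconciled row per calendar day", {
  rec <- patient_record(
    "pt", plans = plans2,
    observations = tibble::tibble(timestamp = as.Date("2020-01-10") + 0:4,
                                  option_id = "drug_a", outcome_id = "mood",
                                  value = 1:5, source = "patient", retrospective = 0L),
    life_events = tibble::tibble(timestamp = as.Date("2020-01-12"),
                                 label = "argument", category = "stress")
  )
  tl <- timeline_export(rec, mood10, "2020-01-09", "2020-01-15")
  expect_equal(nrow(tl), 7)
  expect_equal(tl$date, as.Date("2020-01-09") + 0:6)
  expect_true(is.na(tl$rating[1])) # day without data carries an explicit null
  expect_equal(tl$rating[2:6], c(10, 20, 30, 40, 50))
  expect_equal(tl$events[4], "argument")
  expect_true(all(tl$plan_id == "p1"))
  # no intake events recorded: planned slots exist, so adherence is 0 that day
  expect_true(all(tl$adherence_pct == 0))

  empty <- timeline_export(patient_record("px"), mood10, "2020-01-01", "2020-01-03")
  expect_equal(nrow(empty), 3)
  expect_true(all(is.na(empty$rating)))
  expect_error(timeline_export(rec, mood10, "2020-02-01", "2020-01-01"),
               class = "healthopt_range_error")
})

test_that("decision-quality summaries are grouped means per provider and aspect", {
  dq <- tibble::tibble(
    provider_id = c("gp", "gp", "gp", "psychiatrist"),
    date = as.Date("2020-01-01") + 0:3,
    aspect = c("listening", "listening", "explanation", "listening"),
    score = c(3, 5, 2, 4), scale_min = 1, scale_max = 5
  )
  s <- decision_quality_summary(dq)
  expect_equal(s$mean_score[s$provider_id == "gp" & s$aspect == "listening"], 4)
  expect_equal(s$n[s$provider_id == "gp" & s$aspect == "listening"], 2)
  expect_equal(nrow(s), 3)
  expect_equal(nrow(decision_quality_summary(dq[0, ])), 0)
  set.seed(27)
  r <- tibble::tibble(provider_id = sample(c("a", "b"), 50, TRUE),
                      date = as.Date("2020-01-01"),
                      aspect = sample(c("x", "y"), 50, TRUE),
                      score = runif(50, 1, 5), scale_min = 1, scale_max = 5)
  s2 <- decision_quality_summary(r)
  agg <- stats::aggregate(score ~ provider_id + aspect, data = r, FUN = mean)
  for (i in seq_len(nrow(agg))) {
    expect_equal(s2$mean_score[s2$provider_id == agg$provider_id[i] &
                               s2$aspect == agg$aspect[i]],
                 agg$score[i], tolerance = 1e-12)
  }
})
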