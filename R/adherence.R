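slot_hours <- function(times_per_day) {
  if (times_per_day == 1) return(8)
  8 + (seq_len(times_per_day) - 1) * 12 / (times_per_day - 1)
}

weekday_token <- function(dates) {
  c("mon", "tue", "wed", "thu", "fri", "sat", "sun")[
    (as.integer(as.Date(dates)) + 3) %% 7 + 1]
}

day_qualifies <- function(dates, days_spec) {
  wd <- weekday_token(dates)
  if (days_spec == "daily") return(rep(TRUE, length(dates)))
  if (days_spec == "weekdays") return(wd %in% c("mon", "tue", "wed", "thu", "fri"))
  wd %in% trimws(strsplit(days_spec, ",")[[1]])
}

#' Expand a treatment plan into planned intake slots
#'
#' Walks every calendar day in the intersection of each plan row's period
#' and the requested range, keeps the days qualifying under the row's
#' `days` spec (`"daily"`, `"weekdays"`, or an explicit weekday set such as
#' `"mon,wed,fri"`), and emits one slot per scheduled time. Slot times are
#' a fixed convention: 08:00 for once daily, 08:00/20:00 for twice daily,
#' evenly spaced between those anchors otherwise — so expansion is fully
#' deterministic and expansions over adjacent disjoint ranges concatenate
#' to the full-range expansion.
#'
#' @param plans Plan tibble as in [patient_record()].
#' @param from,to Inclusive date range. A range disjoint from all periods
#'   yields an empty slot list, not an error.
#' @return A tibble with columns `plan_id`, `option_id`, `kind`,
#'   `dose_label`, `date`, `planned_time` (UTC POSIXct).
#' @export
expand_schedule <- function(plans, from, to) {
  plans <- as_tibble(plans)
  from <- as.Date(from); to <- as.Date(to)
  rows <- vector("list", nrow(plans))
  for (i in seq_len(nrow(plans))) {
    p <- plans[i, ]
    lo <- max(p$start, from)
    hi <- min(if (is.na(p$end)) to else p$end - 1, to)
    if (lo > hi) next
    dates <- seq(lo, hi, by = "day")
    dates <- dates[day_qualifies(dates, p$days)]
    if (length(dates) == 0) next
    hours <- slot_hours(p$times_per_day)
    rows[[i]] <- tidyr::expand_grid(date = dates, hour = hours) %>%
      transmute(
        plan_id = p$plan_id, option_id = p$option_id,
        kind = if ("kind" %in% names(p)) p$kind else "medication",
        dose_label = p$dose_label, date = .data$date,
        planned_time = as.POSIXct(.data$date, tz = "UTC") + .data$hour * 3600
      )
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(plan_id = character(), option_id = character(), kind = character(),
                  dose_label = character(), date = as.Date(character()),
                  planned_time = as.POSIXct(character(), tz = "UTC"))
  }
  arrange(out, .data$planned_time, .data$option_id)
}

# Match taken intake events to planned slots: key is (option_id, same day);
# each event claims the nearest-in-time unmatched slot.
match_intakes <- function(slots, intakes) {
  slots$matched <- FALSE
  slots$.slot <- seq_len(nrow(slots))
  unmatched_taken <- 0L
  intakes <- as_tibble(intakes)
  taken <- intakes[which(intakes$taken), , drop = FALSE]
  if (nrow(taken) > 0) {
    t_at <- taken$taken_datetime
    if (is.null(t_at)) t_at <- taken$planned_datetime
    t_at[is.na(t_at)] <- taken$planned_datetime[is.na(t_at)]
    ord <- order(t_at)
    for (j in ord) {
      cand <- which(!slots$matched &
                      slots$option_id == taken$option_id[j] &
                      slots$date == as.Date(t_at[j]))
      if (length(cand) == 0) {
        unmatched_taken <- unmatched_taken + 1L
        next
      }
      best <- cand[which.min(abs(as.numeric(slots$planned_time[cand]) - as.numeric(t_at[j])))]
      slots$matched[best] <- TRUE
    }
  }
  attr(slots, "unmatched_taken") <- unmatched_taken
  slots
}

#' Treatment adherence over a window
#'
#' Matches taken intake events to planned slots by (option, day), each
#' event claiming the nearest same-day slot not yet matched; taken events
#' with no available slot are logged, never counted. Reports planned and
#' taken counts and the adherence rate `100 * taken / planned` per option
#' plus a pooled `"(overall)"` row. Rates are invariant to event ordering
#' and bounded in \[0, 100\]; a rate is absent (`NA`) when nothing was
#' planned.
#'
#' @param slots Planned slots from [expand_schedule()], or a
#'   [patient_record()] (slots are then expanded from its plans).
#' @param intakes Intake-event tibble as in [patient_record()]; ignored
#'   when `slots` is a record.
#' @param from,to Inclusive date window.
#' @return A tibble of class `adherence_summary`: `option_id`, `planned`,
#'   `taken`, `rate`; the attribute `unmatched_taken` counts logged
#'   unmatchable events.
#' @export
adherence_rate <- function(slots, intakes = NULL, from, to) {
  if (inherits(slots, "patient_record")) {
    intakes <- slots$intake_events
    slots <- expand_schedule(slots$plans, from, to)
  }
  slots <- slots[slots$date >= as.Date(from) & slots$date <= as.Date(to), , drop = FALSE]
  matched <- match_intakes(slots, intakes)
  per <- matched %>%
    group_by(.data$option_id) %>%
    summarise(planned = dplyr::n(), taken = sum(.data$matched), .groups = "drop")
  overall <- tibble(option_id = "(overall)",
                    planned = nrow(matched), taken = sum(matched$matched))
  out <- bind_rows(per, overall) %>%
    mutate(rate = ifelse(.data$planned > 0, 100 * .data$taken / .data$planned, NA_real_))
  attr(out, "unmatched_taken") <- attr(matched, "unmatched_taken")
  attr(out, "window") <- c(from = as.Date(from), to = as.Date(to))
  class(out) <- c("adherence_summary", class(out))
  out
}

#' Monitoring fidelity over a window
#'
#' The self-report analogue of [adherence_rate()]: for every outcome in
#' the data-collection plan, counts the scheduled reporting days in the
#' window and the days on which at least one observation of that outcome
#' was actually submitted; fidelity is `100 * submitted / scheduled`.
#'
#' @param monitoring_plan Monitoring-plan tibble as in [patient_record()],
#'   or a `patient_record`.
#' @param observations Observation tibble; ignored when a record is given.
#' @param from,to Inclusive date window.
#' @return A tibble: `outcome_id`, `scheduled`, `submitted`, `rate`, with
#'   a pooled `"(overall)"` row.
#' @export
monitoring_fidelity <- function(monitoring_plan, observations = NULL, from, to) {
  if (inherits(monitoring_plan, "patient_record")) {
    observations <- monitoring_plan$observations
    monitoring_plan <- monitoring_plan$monitoring_plan
  }
  monitoring_plan <- as_tibble(monitoring_plan)
  from <- as.Date(from); to <- as.Date(to)
  rows <- vector("list", nrow(monitoring_plan))
  for (i in seq_len(nrow(monitoring_plan))) {
    p <- monitoring_plan[i, ]
    lo <- max(p$start, from)
    hi <- min(if (is.na(p$end)) to else p$end - 1, to)
    if (lo > hi) next
    dates <- seq(lo, hi, by = "day")
    dates <- dates[day_qualifies(dates, p$days)]
    if (length(dates) == 0) next
    rows[[i]] <- tibble(outcome_id = p$outcome_id, date = dates)
  }
  sched <- bind_rows(rows)
  if (nrow(sched) == 0) {
    sched <- tibble(outcome_id = character(), date = as.Date(character()))
  }
  obs_days <- as_tibble(observations) %>%
    mutate(date = as.Date(.data$timestamp)) %>%
    distinct(.data$outcome_id, .data$date) %>%
    mutate(submitted = TRUE)
  sched <- left_join(sched, obs_days, by = c("outcome_id", "date")) %>%
    mutate(submitted = !is.na(.data$submitted))
  per <- sched %>%
    group_by(.data$outcome_id) %>%
    summarise(scheduled = dplyr::n(), submitted = sum(.data$submitted), .groups = "drop")
  overall <- tibble(outcome_id = "(overall)",
                    scheduled = nrow(sched), submitted = sum(sched$submitted))
  bind_rows(per, overall) %>%
    mutate(rate = ifelse(.data$scheduled > 0,
                         100 * .data$submitted / .data$scheduled, NA_real_))
}

#' Evaluate warning rules over a patient record
#'
#' A rule fires when its metric, computed over the trailing `window_days`
#' ending at `as_of`, is strictly below the threshold ("dropped below":
#' boundary equality does not fire). Raising a threshold can only add
#' fired alerts, never remove one.
#'
#' @param rules Tibble with columns `rule_id`, `metric`
#'   (`"adherence_rate"` or `"monitoring_fidelity"`), `threshold_percent`
#'   (in (0, 100\]), `window_days` (>= 1) and a `recipients` list-column of
#'   collaborator tokens.
#' @param record A [patient_record()].
#' @param as_of Date on which the rules are evaluated.
#' @return A tibble of fired alerts: `rule_id`, `metric`, `value`,
#'   `threshold_percent`, `recipients`.
#' @export
evaluate_alert_rules <- function(rules, record, as_of) {
  rules <- as_tibble(rules)
  as_of <- as.Date(as_of)
  if (any(rules$threshold_percent <= 0 | rules$threshold_percent > 100) ||
      any(rules$window_days < 1)) {
    stop_hopt("alert rule thresholds must lie in (0, 100] and windows be >= 1 day",
              "healthopt_bounds_error")
  }
  fired <- vector("list", nrow(rules))
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    from <- as_of - r$window_days + 1
    value <- trailing_metric(record, r$metric, from, as_of)
    if (!is.na(value) && value < r$threshold_percent) {
      fired[[i]] <- tibble(rule_id = r$rule_id, metric = r$metric, value = value,
                           threshold_percent = r$threshold_percent,
                           recipients = r$recipients)
    }
  }
  out <- bind_rows(fired)
  if (nrow(out) == 0) {
    out <- tibble(rule_id = character(), metric = character(), value = numeric(),
                  threshold_percent = numeric(), recipients = list())
  }
  out
}

trailing_metric <- function(record, metric, from, to, kind = NULL) {
  if (metric == "monitoring_fidelity") {
    mf <- monitoring_fidelity(record, from = from, to = to)
    return(mf$rate[mf$outcome_id == "(overall)"])
  }
  plans <- record$plans
  if (!is.null(kind) && nrow(plans) > 0) plans <- plans[plans$kind == kind, , drop = FALSE]
  slots <- expand_schedule(plans, from, to)
  ar <- adherence_rate(slots, record$intake_events, from, to)
  ar$rate[ar$option_id == "(overall)"]
}

#' Default improvement-snippet rule table
#'
#' Read from the packaged `snippet_rules.csv`: one row per (metric,
#' severity band) with the threshold below which the band applies and a
#' message template (`{value}` is replaced by the measured percentage).
#' The table is plain CSV precisely so deployments can edit it.
#'
#' @param path Path to an alternative rule-table CSV.
#' @return A tibble: `metric`, `below`, `severity`, `message`.
#' @export
default_snippet_rules <- function(path = system.file("extdata", "snippet_rules.csv",
                                                     package = "healthopt")) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Day-to-day improvement snippets from the last two weeks
#'
#' Computes the trailing 14-day medication adherence, lifestyle-measure
#' adherence and monitoring fidelity, looks each up in the snippet rule
#' table, and returns at most one snippet per metric — the most severe
#' band whose threshold the value falls below — ordered by severity
#' (urgent, then warning, then nudge) and metric name. When every metric
#' is on track (or absent), a single "on track" snippet is returned.
#'
#' @param record A [patient_record()].
#' @param as_of Date ending the 14-day window.
#' @param rules Snippet rule table; defaults to [default_snippet_rules()].
#' @return A tibble: `metric`, `value`, `severity`, `message`.
#' @export
improvement_snippets <- function(record, as_of, rules = default_snippet_rules()) {
  as_of <- as.Date(as_of)
  from <- as_of - 13
  metrics <- c(
    medication_adherence = trailing_metric(record, "adherence_rate", from, as_of,
                                           kind = "medication"),
    lifestyle_adherence = trailing_metric(record, "adherence_rate", from, as_of,
                                          kind = "lifestyle"),
    monitoring_fidelity = trailing_metric(record, "monitoring_fidelity", from, as_of)
  )
  sev_rank <- c(urgent = 1, warning = 2, nudge = 3)
  out <- list()
  for (m in names(metrics)) {
    v <- metrics[[m]]
    if (is.na(v)) next
    hits <- rules[rules$metric == m & v < rules$below, , drop = FALSE]
    if (nrow(hits) == 0) next
    hit <- hits[which.min(sev_rank[hits$severity]), ]
    out[[m]] <- tibble(metric = m, value = v, severity = hit$severity,
                       message = gsub("{value}", sprintf("%.0f%%", v),
                                      hit$message, fixed = TRUE))
  }
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(metric = "all", value = NA_real_, severity = "on_track",
                  message = "You are on track: adherence and monitoring look good over the last two weeks."))
  }
  out[order(sev_rank[out$severity], out$metric), , drop = FALSE]
}
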