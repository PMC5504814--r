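#' Assign observations to treatment-plan phases
#'
#' Each observation is assigned to the unique plan period whose half-open
#' interval `[start, end)` contains its date; an observation dated exactly
#' on a switch date therefore belongs to the NEW plan. Observations outside
#' all periods get `plan_id = NA` (the "unassigned" bucket). The
#' assignment is a partition: every observation lands in exactly one
#' bucket, so counts are conserved.
#'
#' @param plans Plan tibble as in [patient_record()]; periods must be
#'   non-overlapping (an overlap is an error naming the offending pair).
#' @param observations Observation tibble with a `timestamp` Date column.
#' @return The observations tibble with a `plan_id` column added
#'   (`NA_character_` for unassigned).
#' @export
segment_phases <- function(plans, observations) {
  observations <- as_tibble(observations)
  per <- check_periods(as_tibble(plans))
  d <- as.Date(observations$timestamp)
  plan_id <- rep(NA_character_, length(d))
  for (i in seq_len(nrow(per))) {
    hit <- d >= per$start[i] & (is.na(per$end[i]) | d < per$end[i])
    plan_id[hit] <- per$plan_id[i]
  }
  observations$plan_id <- plan_id
  observations
}

#' Per-phase statistical summary for one outcome
#'
#' Observations (already carrying a `plan_id`, see [segment_phases()]) are
#' rescaled to the 0-100 rating scale and summarised per phase: count,
#' mean, standard deviation and the ordinary-least-squares trend slope of
#' rating on day index (rating points per day; reported only when the
#' phase holds at least two observations). No autocorrelation correction
#' is applied to the trend.
#'
#' @param observations Tibble with `timestamp`, `value` and `plan_id`
#'   columns, all for the stated outcome.
#' @param outcome The [outcome_def()] row the values were measured on.
#' @return A tibble with one row per phase: `plan_id`, `n`, `mean`, `sd`,
#'   `trend_slope`, `first_date`, `last_date`. An empty input yields one
#'   row with `n = 0` and absent statistics.
#' @export
phase_summary <- function(observations, outcome) {
  observations <- as_tibble(observations)
  if (nrow(observations) == 0) {
    return(tibble(plan_id = NA_character_, n = 0L, mean = NA_real_, sd = NA_real_,
                  trend_slope = NA_real_, first_date = as.Date(NA), last_date = as.Date(NA)))
  }
  if (!"plan_id" %in% names(observations)) observations$plan_id <- NA_character_
  observations %>%
    mutate(rating = rescale_to_rating(.data$value, outcome),
           date = as.Date(.data$timestamp)) %>%
    group_by(.data$plan_id) %>%
    summarise(
      n = dplyr::n(),
      mean = mean(.data$rating),
      sd = if (dplyr::n() >= 2) stats::sd(.data$rating) else NA_real_,
      trend_slope = ols_slope(as.numeric(.data$date), .data$rating),
      first_date = min(.data$date),
      last_date = max(.data$date),
      .groups = "drop"
    )
}

ols_slope <- function(x, y) {
  if (length(x) < 2 || length(unique(x)) < 2) return(NA_real_)
  stats::cov(x, y) / stats::var(x)
}

#' Non-overlap of all pairs (NAP) between two phases
#'
#' The assumption-light single-case effect measure: every baseline
#' observation is compared with every phase observation on the rating
#' scale (so polarity is already accounted for and higher always means
#' improvement); `nap = (improving_pairs + 0.5 * ties) / pair_count`.
#' A value of 1 means complete non-overlap in the improving direction;
#' 0.5 means chance-level overlap. For tie-free data
#' `nap(A, B) + nap(B, A) = 1`.
#'
#' @param baseline,phase Observation tibbles with `value` columns, both
#'   non-empty and for the same outcome.
#' @param outcome The [outcome_def()] row.
#' @return A one-row tibble of class `hopt_nap`: `nap`, `pair_count`,
#'   `improving_pairs`, `ties`.
#' @examples
#' o <- outcome_def("mood", instrument_min = 0, instrument_max = 10)
#' nonoverlap(tibble::tibble(value = c(3, 4, 5)),
#'            tibble::tibble(value = c(4, 6)), o)
#' @export
nonoverlap <- function(baseline, phase, outcome) {
  baseline <- as_tibble(baseline)
  phase <- as_tibble(phase)
  if (nrow(baseline) == 0 || nrow(phase) == 0) {
    stop_hopt("both phases must be non-empty", "healthopt_empty_input")
  }
  b <- rescale_to_rating(baseline$value, outcome)
  p <- rescale_to_rating(phase$value, outcome)
  cmp <- outer(b, p, function(x, y) sign(y - x))
  out <- tibble(
    nap = (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / length(cmp),
    pair_count = length(cmp),
    improving_pairs = sum(cmp > 0),
    ties = sum(cmp == 0)
  )
  class(out) <- c("hopt_nap", class(out))
  out
}

#' Dose-response summaries for one treatment option
#'
#' Groups the plan periods in which `option_id` was in use by dose label,
#' pools each group's assigned observations, and returns one
#' [phase_summary()]-style row per dose, ordered by dose (numeric prefix
#' of the dose label when parseable, else lexicographic).
#'
#' @inheritParams segment_phases
#' @param outcome The [outcome_def()] row.
#' @param option_id The option whose dosages are compared.
#' @return A tibble with one row per dose label: `dose_label`, `n`, `mean`,
#'   `sd`, `trend_slope`, `first_date`, `last_date`.
#' @export
dosage_effect <- function(plans, observations, outcome, option_id) {
  plans <- as_tibble(plans)
  mine <- plans[plans$option_id == option_id, , drop = FALSE]
  if (nrow(mine) == 0) {
    stop_hopt(sprintf("option '%s' appears in no treatment plan", option_id),
              "healthopt_unknown_option")
  }
  seg <- segment_phases(plans, observations)
  seg <- seg[!is.na(seg$plan_id) & seg$plan_id %in% mine$plan_id, , drop = FALSE]
  dose_of <- stats::setNames(mine$dose_label, mine$plan_id)
  seg$dose_label <- unname(dose_of[seg$plan_id])
  out <- seg %>%
    mutate(plan_id = .data$dose_label) %>%
    phase_summary(outcome) %>%
    rename(dose_label = "plan_id")
  num <- suppressWarnings(as.numeric(sub("^([0-9.]+).*", "\\1", out$dose_label)))
  out[order(if (all(!is.na(num))) num else out$dose_label), , drop = FALSE]
}

#' Effect of life events on an outcome
#'
#' Splits the observations into a post-event set — observations falling
#' within `window_days` days after any life event, counted once even under
#' overlapping windows — and the background complement, and reports the
#' difference in mean rating (post minus background).
#'
#' @param events Life-event tibble with a `timestamp` Date column.
#' @param observations Observation tibble for one outcome.
#' @param outcome The [outcome_def()] row.
#' @param window_days Length of the post-event window in days (>= 1); an
#'   observation on the event day itself is in the window.
#' @return A one-row tibble: `n_post`, `mean_post`, `n_background`,
#'   `mean_background`, `difference`. Empty sets yield `NA` means.
#' @export
event_effect <- function(events, observations, outcome, window_days = 7) {
  if (window_days < 1) {
    stop_hopt("window_days must be >= 1", "healthopt_bounds_error")
  }
  observations <- as_tibble(observations)
  events <- as_tibble(events)
  d <- as.Date(observations$timestamp)
  in_window <- rep(FALSE, length(d))
  for (e in as.list(as.Date(events$timestamp))) {
    in_window <- in_window | (d >= e & d < e + window_days)
  }
  rating <- if (nrow(observations) > 0) rescale_to_rating(observations$value, outcome) else numeric(0)
  mean_or_na <- function(x) if (length(x) > 0) mean(x) else NA_real_
  post <- rating[in_window]
  bg <- rating[!in_window]
  tibble(
    n_post = length(post), mean_post = mean_or_na(post),
    n_background = length(bg), mean_background = mean_or_na(bg),
    difference = mean_or_na(post) - mean_or_na(bg)
  )
}

#' Export a daily timeline for one outcome
#'
#' One row per calendar day in the range: the day's mean rating for the
#' outcome (NA when nothing was recorded), the active treatment plan, any
#' life events (semicolon-joined labels), and the day's medication
#' adherence percentage (NA on days with no planned intakes). The export
#' is deterministic and reconciles with [segment_phases()] and
#' [adherence_rate()].
#'
#' @param record A [patient_record()].
#' @param outcome The [outcome_def()] row to chart.
#' @param from,to Inclusive date range; `from` must not exceed `to`.
#' @return A tibble of class `hopt_timeline` with columns `date`, `rating`,
#'   `plan_id`, `events`, `adherence_pct`.
#' @export
timeline_export <- function(record, outcome, from, to) {
  from <- as.Date(from); to <- as.Date(to)
  if (from > to) {
    stop_hopt("reversed date range: 'from' is after 'to'", "healthopt_range_error")
  }
  days <- tibble(date = seq(from, to, by = "day"))

  obs <- record$observations
  obs <- obs[obs$outcome_id == outcome$id, , drop = FALSE]
  daily_rating <- if (nrow(obs) > 0) {
    obs %>%
      mutate(date = as.Date(.data$timestamp),
             rating = rescale_to_rating(.data$value, outcome)) %>%
      group_by(.data$date) %>%
      summarise(rating = mean(.data$rating), .groups = "drop")
  } else {
    tibble(date = as.Date(character()), rating = numeric())
  }

  plan_of_day <- if (nrow(record$plans) > 0) {
    segment_phases(record$plans, tibble(timestamp = days$date)) %>%
      transmute(date = as.Date(.data$timestamp), plan_id = .data$plan_id)
  } else {
    tibble(date = days$date, plan_id = NA_character_)
  }

  events_of_day <- if (nrow(record$life_events) > 0) {
    record$life_events %>%
      mutate(date = as.Date(.data$timestamp)) %>%
      group_by(.data$date) %>%
      summarise(events = paste(sort(.data$label), collapse = "; "), .groups = "drop")
  } else {
    tibble(date = as.Date(character()), events = character())
  }

  adh_of_day <- if (nrow(record$plans) > 0) {
    slots <- expand_schedule(record$plans, from, to)
    if (nrow(slots) > 0) {
      matched <- match_intakes(slots, record$intake_events)
      matched %>%
        mutate(date = as.Date(.data$planned_time)) %>%
        group_by(.data$date) %>%
        summarise(adherence_pct = 100 * mean(.data$matched), .groups = "drop")
    } else {
      tibble(date = as.Date(character()), adherence_pct = numeric())
    }
  } else {
    tibble(date = as.Date(character()), adherence_pct = numeric())
  }

  out <- days %>%
    left_join(daily_rating, by = "date") %>%
    left_join(plan_of_day, by = "date") %>%
    left_join(events_of_day, by = "date") %>%
    left_join(adh_of_day, by = "date") %>%
    arrange(.data$date)
  class(out) <- c("hopt_timeline", class(out))
  out
}

#' Decision-quality tracking summary
#'
#' Mean decision-quality score per healthcare provider and aspect, with
#' observation counts; providers with no records are simply absent.
#'
#' @param records Decision-quality tibble as in [patient_record()].
#' @return A tibble with columns `provider_id`, `aspect`, `mean_score`, `n`.
#' @export
decision_quality_summary <- function(records) {
  records <- as_tibble(records)
  if (nrow(records) == 0) {
    return(tibble(provider_id = character(), aspect = character(),
                  mean_score = numeric(), n = integer()))
  }
  records %>%
    group_by(.data$provider_id, .data$aspect) %>%
    summarise(mean_score = mean(.data$score), n = dplyr::n(), .groups = "drop") %>%
    arrange(.data$provider_id, .data$aspect)
}
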