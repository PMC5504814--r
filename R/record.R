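empty_observations <- function() {
  tibble(timestamp = as.Date(character()), option_id = character(),
         outcome_id = character(), value = numeric(),
         source = character(), retrospective = integer())
}

empty_plans <- function() {
  tibble(plan_id = character(), option_id = character(), dose_label = character(),
         times_per_day = integer(), days = character(), kind = character(),
         start = as.Date(character()), end = as.Date(character()))
}

empty_intakes <- function() {
  tibble(planned_datetime = as.POSIXct(character(), tz = "UTC"),
         option_id = character(), taken = logical(),
         taken_datetime = as.POSIXct(character(), tz = "UTC"))
}

empty_events <- function() {
  tibble(timestamp = as.Date(character()), label = character(), category = character())
}

empty_decision_quality <- function() {
  tibble(provider_id = character(), date = as.Date(character()),
         aspect = character(), score = numeric(),
         scale_min = numeric(), scale_max = numeric())
}

empty_monitoring_plan <- function() {
  tibble(outcome_id = character(), days = character(),
         start = as.Date(character()), end = as.Date(character()))
}

#' Assemble a longitudinal patient record
#'
#' The self-monitoring store for one patient: outcome observations,
#' treatment-plan periods, medication intake events, life events,
#' decision-quality records, and the data-collection (monitoring) plan.
#' All components are plain tibbles with ISO-8601 dates, so they round-trip
#' through CSV/JSON losslessly.
#'
#' Treatment-plan periods are half-open `[start, end)` intervals, one row
#' per (plan, intervention); `end = NA` means the plan is still in force.
#' A patient's plan periods must not overlap in time.
#'
#' @param patient_id Lowercase token.
#' @param attributes Named list of profile attribute values.
#' @param observations Tibble: `timestamp` (Date), `option_id`,
#'   `outcome_id`, `value` (instrument scale), `source`, `retrospective`.
#' @param plans Tibble: `plan_id`, `option_id`, `dose_label`,
#'   `times_per_day`, `days` (`"daily"`, `"weekdays"`, or a comma-separated
#'   weekday set like `"mon,wed,fri"`), `kind` (`"medication"`/
#'   `"lifestyle"`), `start`, `end`.
#' @param intake_events Tibble: `planned_datetime`, `option_id`, `taken`,
#'   `taken_datetime` (NA when not taken).
#' @param life_events Tibble: `timestamp`, `label`, `category`.
#' @param decision_quality Tibble: `provider_id`, `date`, `aspect`,
#'   `score`, `scale_min`, `scale_max`.
#' @param monitoring_plan Tibble: `outcome_id`, `days`, `start`, `end` —
#'   the schedule of self-reports the patient agreed to.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id,
                           attributes = list(),
                           observations = empty_observations(),
                           plans = empty_plans(),
                           intake_events = empty_intakes(),
                           life_events = empty_events(),
                           decision_quality = empty_decision_quality(),
                           monitoring_plan = empty_monitoring_plan()) {
  plans <- as_tibble(plans)
  if (nrow(plans) > 0) {
    if (!"kind" %in% names(plans)) plans$kind <- "medication"
    if (!"dose_label" %in% names(plans)) plans$dose_label <- NA_character_
    if (!"times_per_day" %in% names(plans)) plans$times_per_day <- 1L
    if (!"days" %in% names(plans)) plans$days <- "daily"
    check_periods(plans)
  }
  dq <- as_tibble(decision_quality)
  if (nrow(dq) > 0 && all(c("score", "scale_min", "scale_max") %in% names(dq))) {
    bad <- dq$score < dq$scale_min | dq$score > dq$scale_max
    if (any(bad)) {
      stop_hopt("decision-quality score outside its declared scale", "healthopt_bounds_error")
    }
  }
  structure(
    list(
      patient_id = patient_id,
      attributes = attributes,
      observations = as_tibble(observations),
      plans = plans,
      intake_events = as_tibble(intake_events),
      life_events = as_tibble(life_events),
      decision_quality = dq,
      monitoring_plan = as_tibble(monitoring_plan)
    ),
    class = "patient_record"
  )
}

plan_periods <- function(plans) {
  plans %>%
    distinct(.data$plan_id, .data$start, .data$end) %>%
    arrange(.data$start)
}

check_periods <- function(plans) {
  per <- plan_periods(plans)
  if (anyDuplicated(per$plan_id)) {
    stop_hopt("a plan_id maps to more than one period", "healthopt_period_error")
  }
  if (nrow(per) >= 2) {
    for (i in seq_len(nrow(per) - 1)) {
      end_i <- per$end[i]
      if (is.na(end_i) || end_i > per$start[i + 1]) {
        stop_hopt(sprintf("overlapping treatment-plan periods: '%s' and '%s'",
                          per$plan_id[i], per$plan_id[i + 1]),
                  "healthopt_period_error")
      }
    }
  }
  invisible(per)
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf(paste0("<patient_record '%s'> %d observations, %d plan rows, ",
                     "%d intakes, %d life events\n"),
              x$patient_id, nrow(x$observations), nrow(x$plans),
              nrow(x$intake_events), nrow(x$life_events)))
  invisible(x)
}
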