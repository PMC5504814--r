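json_write <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, null = "null",
                       na = "null", pretty = TRUE)
}

#' Read and write condition templates, models and patient records
#'
#' All documents are UTF-8 JSON with ISO-8601 dates and ids restricted to
#' lowercase tokens; writing then reading reproduces an equal document.
#' Structural problems are reported as schema errors naming the offending
#' field, never as crashes.
#'
#' @param template,model,record The object to write.
#' @param path File path.
#' @return Readers return the parsed object; writers return `path`
#'   invisibly.
#' @name healthopt_io
NULL

template_to_list <- function(template) {
  list(
    condition_id = template$condition_id,
    attributes = lapply(seq_len(nrow(template$attributes)), function(i)
      as.list(template$attributes[i, ])),
    options = lapply(seq_len(nrow(template$options)), function(i) {
      o <- template$options[i, ]
      list(id = o$id, label = o$label, kind = o$kind,
           dosage_levels = as.list(o$dosage_levels[[1]]),
           contraindications = lapply(o$contraindications[[1]], rule_to_list))
    }),
    outcomes = lapply(seq_len(nrow(template$outcomes)), function(i) {
      o <- template$outcomes[i, ]
      list(id = o$id, label = o$label, polarity = o$polarity,
           instrument_min = o$instrument_min, instrument_max = o$instrument_max,
           relevance_rule = rule_to_list(o$relevance_rule[[1]]))
    }),
    ratings = lapply(seq_len(nrow(template$ratings)), function(i)
      as.list(template$ratings[i, ]))
  )
}

#' @rdname healthopt_io
#' @export
write_template <- function(template, path) {
  json_write(template_to_list(template), path)
  invisible(path)
}

#' @rdname healthopt_io
#' @export
read_template <- function(path) {
  x <- jsonlite::read_json(path)
  need <- c("condition_id", "options", "outcomes", "ratings")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    stop_hopt(sprintf("template JSON missing field(s) at $: %s",
                      paste(missing, collapse = ", ")), "healthopt_schema_error")
  }
  options <- bind_rows(lapply(x$options, function(o) {
    treatment_option(
      id = o$id, label = o$label %||% o$id, kind = o$kind %||% "medication",
      dosage_levels = if (length(o$dosage_levels)) unlist(o$dosage_levels) else NULL,
      contraindications = lapply(o$contraindications %||% list(), rule_from_list)
    )
  }))
  outcomes <- bind_rows(lapply(x$outcomes, function(o) {
    outcome_def(
      id = o$id, label = o$label %||% o$id,
      polarity = o$polarity %||% "higher_is_better",
      instrument_min = o$instrument_min %||% 0,
      instrument_max = o$instrument_max %||% 100,
      relevance_rule = rule_from_list(o$relevance_rule)
    )
  }))
  ratings <- bind_rows(lapply(x$ratings, function(r) {
    tibble(option_id = r$option_id, outcome_id = r$outcome_id,
           score = as.numeric(r$score), confidence = as.numeric(r$confidence),
           source = r$source %||% "research")
  }))
  attributes <- bind_rows(lapply(x$attributes %||% list(), function(a) {
    tibble(name = a$name, type = a$type %||% "text")
  }))
  if (nrow(attributes) == 0) {
    attributes <- tibble(name = character(), type = character())
  }
  condition_template(x$condition_id, options, outcomes, ratings, attributes)
}

#' @rdname healthopt_io
#' @export
write_model <- function(model, path) {
  json_write(list(
    condition_id = model$condition_id,
    patient_id = model$patient_id,
    options = lapply(seq_len(nrow(model$options)), function(i) {
      o <- model$options[i, ]
      list(id = o$id, label = o$label, kind = o$kind,
           dosage_levels = as.list(o$dosage_levels[[1]]),
           contraindications = lapply(o$contraindications[[1]], rule_to_list))
    }),
    outcomes = lapply(seq_len(nrow(model$outcomes)), function(i) {
      o <- model$outcomes[i, ]
      list(id = o$id, label = o$label, polarity = o$polarity,
           instrument_min = o$instrument_min, instrument_max = o$instrument_max,
           relevance_rule = rule_to_list(o$relevance_rule[[1]]))
    }),
    ratings = lapply(seq_len(nrow(model$ratings)), function(i)
      as.list(model$ratings[i, ])),
    removals = lapply(seq_len(nrow(model$removals)), function(i)
      as.list(model$removals[i, ]))
  ), path)
  invisible(path)
}

#' @rdname healthopt_io
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path)
  options <- bind_rows(lapply(x$options, function(o) {
    treatment_option(
      id = o$id, label = o$label %||% o$id, kind = o$kind %||% "medication",
      dosage_levels = if (length(o$dosage_levels)) unlist(o$dosage_levels) else NULL,
      contraindications = lapply(o$contraindications %||% list(), rule_from_list)
    )
  }))
  outcomes <- bind_rows(lapply(x$outcomes, function(o) {
    outcome_def(id = o$id, label = o$label %||% o$id,
                polarity = o$polarity %||% "higher_is_better",
                instrument_min = o$instrument_min %||% 0,
                instrument_max = o$instrument_max %||% 100,
                relevance_rule = rule_from_list(o$relevance_rule))
  }))
  ratings <- bind_rows(lapply(x$ratings, function(r) {
    tibble(option_id = r$option_id, outcome_id = r$outcome_id,
           score = as.numeric(r$score), confidence = as.numeric(r$confidence),
           source = r$source %||% "research",
           provenance = r$provenance %||% "research default")
  }))
  removals <- bind_rows(lapply(x$removals %||% list(), as_tibble))
  if (nrow(removals) == 0) {
    removals <- tibble(kind = character(), id = character(), rule = character())
  }
  structure(
    list(condition_id = x$condition_id, patient_id = x$patient_id,
         options = options, outcomes = outcomes, ratings = ratings,
         removals = removals),
    class = "personalized_model"
  )
}

#' Read or write a longitudinal evidence bundle
#'
#' CSV with columns `timestamp` (ISO-8601 date), `option_id`, `outcome_id`,
#' `value` (instrument scale), `source`, `retrospective` (0/1) — the
#' dialect produced by the simulator and consumed by [update_model()].
#'
#' @param path CSV path.
#' @param evidence Evidence tibble to write.
#' @return `read_evidence()` a tibble; `write_evidence()` `path`,
#'   invisibly.
#' @export
read_evidence <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           timestamp = readr::col_date(),
                           option_id = readr::col_character(),
                           outcome_id = readr::col_character(),
                           value = readr::col_double(),
                           source = readr::col_character(),
                           retrospective = readr::col_integer()
                         ))
  assert_cols(out, c("timestamp", "option_id", "outcome_id", "value", "source"),
              "evidence CSV")
  out
}

#' @rdname read_evidence
#' @export
write_evidence <- function(evidence, path) {
  readr::write_csv(evidence, path, progress = FALSE)
  invisible(path)
}

#' @rdname healthopt_io
#' @export
write_record <- function(record, path) {
  to_chr_dates <- function(df) {
    mutate(df, across(where(function(x) inherits(x, "Date")), as.character),
           across(where(function(x) inherits(x, "POSIXct")),
                  function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")))
  }
  json_write(list(
    patient_id = record$patient_id,
    attributes = record$attributes,
    observations = to_chr_dates(record$observations),
    plans = to_chr_dates(record$plans),
    intake_events = to_chr_dates(record$intake_events),
    life_events = to_chr_dates(record$life_events),
    decision_quality = to_chr_dates(record$decision_quality),
    monitoring_plan = to_chr_dates(record$monitoring_plan)
  ), path)
  invisible(path)
}

#' @rdname healthopt_io
#' @export
read_record <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tb <- function(df, empty) {
    if (is.null(df) || (is.data.frame(df) && nrow(df) == 0) || length(df) == 0) {
      return(empty)
    }
    as_tibble(df)
  }
  obs <- tb(x$observations, empty_observations())
  if (nrow(obs) > 0) obs$timestamp <- as.Date(obs$timestamp)
  plans <- tb(x$plans, empty_plans())
  if (nrow(plans) > 0) {
    plans$start <- as.Date(plans$start)
    plans$end <- as.Date(plans$end)
    plans$times_per_day <- as.integer(plans$times_per_day)
  }
  ie <- tb(x$intake_events, empty_intakes())
  if (nrow(ie) > 0) {
    ie$planned_datetime <- as.POSIXct(ie$planned_datetime, tz = "UTC",
                                      format = "%Y-%m-%dT%H:%M:%SZ")
    ie$taken_datetime <- as.POSIXct(ie$taken_datetime, tz = "UTC",
                                    format = "%Y-%m-%dT%H:%M:%SZ")
  }
  le <- tb(x$life_events, empty_events())
  if (nrow(le) > 0) le$timestamp <- as.Date(le$timestamp)
  dq <- tb(x$decision_quality, empty_decision_quality())
  if (nrow(dq) > 0) dq$date <- as.Date(dq$date)
  mp <- tb(x$monitoring_plan, empty_monitoring_plan())
  if (nrow(mp) > 0) {
    mp$start <- as.Date(mp$start)
    mp$end <- as.Date(mp$end)
  }
  patient_record(x$patient_id, attributes = as.list(x$attributes),
                 observations = obs, plans = plans, intake_events = ie,
                 life_events = le, decision_quality = dq, monitoring_plan = mp)
}

#' Standards checklist and feature registry
#'
#' The package ships two small fixtures describing the system's core
#' components: a checklist comparing each core feature against the AGREE
#' (clinical practice guidelines) and IPDAS (patient decision aids)
#' quality standards, and a registry mapping the supported
#' health-optimization strategies to their features.
#'
#' @param path Fixture path; defaults to the packaged files.
#' @return Tibbles: the checklist has columns `feature`, `in_system`,
#'   `agree`, `ipdas`, `footnote`; the registry `strategy_id`,
#'   `strategy_label`, `feature`.
#' @export
read_standards_checklist <- function(path = system.file("extdata", "standards_checklist.json",
                                                        package = "healthopt")) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- as_tibble(x)
  assert_cols(out, c("feature", "in_system", "agree", "ipdas"), "standards checklist")
  if (anyDuplicated(out$feature)) {
    stop_hopt("feature labels must be unique", "healthopt_schema_error")
  }
  out
}

#' @rdname read_standards_checklist
#' @export
read_feature_registry <- function(path = system.file("extdata", "feature_registry.json",
                                                     package = "healthopt")) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- as_tibble(x)
  assert_cols(out, c("strategy_id", "strategy_label", "feature"), "feature registry")
  if (any(out$strategy_id < 1 | out$strategy_id > 6)) {
    stop_hopt("strategy ids must lie in 1..6", "healthopt_schema_error")
  }
  out
}

#' Summarise the standards checklist
#'
#' Counts, among the features present in the system, how many are required
#' by at least one of the AGREE/IPDAS standards and how many by neither.
#'
#' @param checklist A checklist tibble from [read_standards_checklist()].
#' @return A one-row tibble: `n_features`, `n_required_by_either`,
#'   `n_required_by_neither`.
#' @export
standards_summary <- function(checklist) {
  checklist <- as_tibble(checklist)
  if (nrow(checklist) == 0) {
    stop_hopt("empty checklist", "healthopt_empty_input")
  }
  rows <- checklist[checklist$in_system, , drop = FALSE]
  either <- rows$agree | rows$ipdas
  tibble(
    n_features = nrow(rows),
    n_required_by_either = sum(either),
    n_required_by_neither = nrow(rows) - sum(either)
  )
}

#' Summarise the feature registry
#'
#' @param registry A registry tibble from [read_feature_registry()].
#' @return A one-row tibble: `n_strategies` (distinct strategies),
#'   `n_features` (total feature rows).
#' @export
registry_summary <- function(registry) {
  registry <- as_tibble(registry)
  if (nrow(registry) == 0) {
    stop_hopt("empty registry", "healthopt_empty_input")
  }
  tibble(
    n_strategies = dplyr::n_distinct(registry$strategy_id),
    n_features = nrow(registry)
  )
}
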