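#' Define an outcome for a condition template
#'
#' An outcome is a patient-important criterion (for example mood stability or
#' weight gain) measured on a bounded instrument scale. Performance ratings
#' live on a common 0-100 scale where 100 is always best; the `polarity`
#' records whether larger instrument values are better or worse, so that
#' instrument values can be mapped onto the rating scale (see
#' [rescale_to_rating()]).
#'
#' @param id Lowercase token (`[a-z0-9_]+`) unique within the template.
#' @param label Human-readable label.
#' @param polarity `"higher_is_better"` or `"lower_is_better"`.
#' @param instrument_min,instrument_max Bounds of the measurement instrument;
#'   `instrument_min < instrument_max`.
#' @param relevance_rule Optional [rule()] deciding whether this outcome is
#'   relevant for a given patient; absent means always relevant.
#' @return A one-row tibble suitable for `condition_template(outcomes = ...)`.
#' @export
outcome_def <- function(id, label = id, polarity = c("higher_is_better", "lower_is_better"),
                        instrument_min = 0, instrument_max = 100, relevance_rule = NULL) {
  polarity <- match.arg(polarity)
  tibble(
    id = id, label = label, polarity = polarity,
    instrument_min = as.numeric(instrument_min),
    instrument_max = as.numeric(instrument_max),
    relevance_rule = list(relevance_rule)
  )
}

#' Define a treatment option for a condition template
#'
#' @param id Lowercase token unique within the template.
#' @param label Human-readable label.
#' @param kind `"medication"`, `"lifestyle"` or `"other"`.
#' @param dosage_levels Optional character vector of dose labels, ordered
#'   from lowest to highest.
#' @param contraindications List of [rule()] objects; the option is removed
#'   for a patient when any rule evaluates true.
#' @return A one-row tibble suitable for `condition_template(options = ...)`.
#' @export
treatment_option <- function(id, label = id, kind = c("medication", "lifestyle", "other"),
                             dosage_levels = NULL, contraindications = list()) {
  kind <- match.arg(kind)
  tibble(
    id = id, label = label, kind = kind,
    dosage_levels = list(dosage_levels),
    contraindications = list(contraindications)
  )
}

#' Assemble a condition template
#'
#' A condition template is the authored decision model for one long-term
#' condition: the treatment options, the patient-important outcomes, the
#' performance ratings linking them, and the dictionary of patient
#' attributes that personalization rules may reference. A template is
#' *complete* when a research-source rating exists for every
#' (option, outcome) pair.
#'
#' @param condition_id Lowercase token identifying the condition.
#' @param options Tibble of options, usually built by row-binding
#'   [treatment_option()] calls.
#' @param outcomes Tibble of outcomes from [outcome_def()].
#' @param ratings Tibble with columns `option_id`, `outcome_id`, `score`
#'   (0-100, 100 best), `confidence` (0-1, 1 = highest evidence quality) and
#'   `source` (`"research"`, `"clinician"` or `"patient"`).
#' @param attributes Tibble with columns `name` and `type` declaring the
#'   patient attributes rules may reference; types are `"number"`, `"text"`
#'   or `"flag"`.
#' @return An object of class `condition_template`.
#' @seealso [validate_template()], [personalize()]
#' @export
condition_template <- function(condition_id, options, outcomes, ratings,
                               attributes = tibble(name = character(), type = character())) {
  options <- as_tibble(options)
  outcomes <- as_tibble(outcomes)
  ratings <- as_tibble(ratings)
  assert_cols(options, c("id", "label", "kind"), "options")
  assert_cols(outcomes, c("id", "label", "polarity", "instrument_min", "instrument_max"), "outcomes")
  assert_cols(ratings, c("option_id", "outcome_id", "score", "confidence", "source"), "ratings")
  if (!"dosage_levels" %in% names(options)) options$dosage_levels <- list(NULL)
  if (!"contraindications" %in% names(options)) options$contraindications <- list(list())
  if (!"relevance_rule" %in% names(outcomes)) outcomes$relevance_rule <- list(NULL)
  structure(
    list(
      condition_id = condition_id,
      options = options,
      outcomes = outcomes,
      ratings = ratings,
      attributes = as_tibble(attributes)
    ),
    class = "condition_template"
  )
}

#' Create a patient profile
#'
#' @param patient_id Lowercase token.
#' @param attributes Named list of attribute values; names must match the
#'   template's attribute dictionary for rules to evaluate.
#' @return An object of class `patient_profile`.
#' @export
patient_profile <- function(patient_id, attributes = list()) {
  structure(list(patient_id = patient_id, attributes = attributes),
            class = "patient_profile")
}

#' Validate a condition template
#'
#' Checks structural integrity (unique ids, token syntax, rating bounds,
#' instrument bounds, rule attributes declared in the dictionary) and
#' completeness: a research-source rating must exist for every
#' (option, outcome) pair, so the required rating count is
#' `n_options * n_outcomes`.
#'
#' @param template A [condition_template()].
#' @return A list of class `validation_report` with elements `complete`
#'   (logical), `required_rating_count`, `missing_pairs` (tibble of
#'   option/outcome ids lacking a research rating) and `errors`
#'   (character vector; empty when the template is well-formed).
#' @examples
#' tpl <- condition_template(
#'   "demo",
#'   treatment_option("opt_a"),
#'   outcome_def("mood"),
#'   tibble::tibble(option_id = "opt_a", outcome_id = "mood",
#'                  score = 70, confidence = 0.8, source = "research")
#' )
#' validate_template(tpl)$complete
#' @export
validate_template <- function(template) {
  errors <- character(0)
  opts <- template$options
  outs <- template$outcomes
  rat <- template$ratings

  add_err <- function(cond, msg) if (any(cond, na.rm = TRUE)) c(errors, msg) else errors

  errors <- add_err(duplicated(opts$id), "duplicate option id")
  errors <- add_err(duplicated(outs$id), "duplicate outcome id")
  errors <- add_err(!is_token(opts$id), "option id is not a lowercase token")
  errors <- add_err(!is_token(outs$id), "outcome id is not a lowercase token")
  errors <- add_err(outs$instrument_min >= outs$instrument_max,
                    "instrument_min must be < instrument_max")
  errors <- add_err(rat$score < 0 | rat$score > 100, "rating score outside [0, 100]")
  errors <- add_err(rat$confidence < 0 | rat$confidence > 1,
                    "rating confidence outside [0, 1]")
  errors <- add_err(!rat$source %in% c("research", "clinician", "patient"),
                    "unknown rating source")
  errors <- add_err(!rat$option_id %in% opts$id, "rating references unknown option")
  errors <- add_err(!rat$outcome_id %in% outs$id, "rating references unknown outcome")
  errors <- add_err(
    duplicated(rat[, c("option_id", "outcome_id", "source")]),
    "more than one rating per (option, outcome, source)"
  )

  declared <- template$attributes$name
  referenced <- unique(c(
    unlist(lapply(opts$contraindications, function(rs) unlist(lapply(rs, rule_attributes)))),
    unlist(lapply(outs$relevance_rule, rule_attributes))
  ))
  undeclared <- setdiff(referenced, declared)
  if (length(undeclared) > 0) {
    errors <- c(errors, sprintf("rule references undeclared attribute(s): %s",
                                paste(undeclared, collapse = ", ")))
  }

  required <- tidyr::expand_grid(option_id = opts$id, outcome_id = outs$id)
  research <- rat[rat$source == "research", c("option_id", "outcome_id")]
  missing_pairs <- anti_join(required, research, by = c("option_id", "outcome_id"))

  structure(
    list(
      complete = nrow(missing_pairs) == 0,
      required_rating_count = nrow(opts) * nrow(outs),
      missing_pairs = missing_pairs,
      errors = errors
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat("  complete:", x$complete, "\n")
  cat("  required ratings:", x$required_rating_count, "\n")
  cat("  missing pairs:", nrow(x$missing_pairs), "\n")
  cat("  errors:", length(x$errors), "\n")
  invisible(x)
}

#' Personalize a condition template to one patient
#'
#' Removes treatment options whose contraindication rules fire for the
#' patient's profile and outcomes whose relevance rule evaluates false, then
#' initializes the effective ratings from the research-source defaults.
#' Every removal is logged with the triggering rule. Personalizing an
#' already-personalized model with the same profile is a no-op.
#'
#' @param template A complete [condition_template()] (or a
#'   `personalized_model` to re-personalize).
#' @param profile A [patient_profile()] or named list of attribute values.
#' @return An object of class `personalized_model`: retained `options` and
#'   `outcomes` tibbles, an effective `ratings` tibble (one row per retained
#'   option x outcome, with `score`, `confidence`, `source` and `provenance`)
#'   and a `removals` log tibble.
#' @export
personalize <- function(template, profile) {
  if (inherits(profile, "patient_profile")) {
    patient_id <- profile$patient_id
  } else {
    patient_id <- "patient"
    profile <- patient_profile(patient_id, as.list(profile))
  }

  if (inherits(template, "personalized_model")) {
    opts <- template$options
    outs <- template$outcomes
    ratings <- template$ratings
    condition_id <- template$condition_id
  } else {
    rep <- validate_template(template)
    if (!rep$complete) {
      stop_hopt("template is incomplete: a research rating is required for every (option, outcome) pair",
                "healthopt_incomplete_template")
    }
    if (length(rep$errors) > 0) {
      stop_hopt(paste0("template has errors: ", paste(rep$errors, collapse = "; ")),
                "healthopt_schema_error")
    }
    opts <- template$options
    outs <- template$outcomes
    ratings <- template$ratings %>%
      filter(.data$source == "research") %>%
      mutate(provenance = "research default")
    condition_id <- template$condition_id
  }

  opt_removed <- map_lgl(opts$contraindications, function(rules) {
    any(vapply(rules, evaluate_rule, logical(1), profile = profile))
  })
  removals <- tibble(
    kind = character(0), id = character(0), rule = character(0)
  )
  if (any(opt_removed)) {
    fired <- map_chr(opts$contraindications[opt_removed], function(rules) {
      hits <- vapply(rules, evaluate_rule, logical(1), profile = profile)
      paste(vapply(rules[hits], rule_text, character(1)), collapse = " | ")
    })
    removals <- bind_rows(removals,
                          tibble(kind = "option", id = opts$id[opt_removed], rule = fired))
  }
  out_removed <- map_lgl(outs$relevance_rule, function(r) {
    !is.null(r) && !evaluate_rule(r, profile)
  })
  if (any(out_removed)) {
    removals <- bind_rows(removals, tibble(
      kind = "outcome", id = outs$id[out_removed],
      rule = map_chr(outs$relevance_rule[out_removed], rule_text)
    ))
  }

  opts_kept <- opts[!opt_removed, , drop = FALSE]
  outs_kept <- outs[!out_removed, , drop = FALSE]
  if (nrow(opts_kept) == 0) {
    stop_hopt("no admissible options: every option is contraindicated for this patient",
              "healthopt_no_options")
  }
  if (nrow(outs_kept) == 0) {
    stop_hopt("no relevant outcomes for this patient", "healthopt_no_outcomes")
  }

  ratings_kept <- ratings %>%
    filter(.data$option_id %in% opts_kept$id, .data$outcome_id %in% outs_kept$id)

  prior_removals <- if (inherits(template, "personalized_model")) template$removals else NULL

  structure(
    list(
      condition_id = condition_id,
      patient_id = patient_id,
      options = opts_kept,
      outcomes = outs_kept,
      ratings = ratings_kept,
      removals = bind_rows(prior_removals, removals)
    ),
    class = "personalized_model"
  )
}

#' @export
print.condition_template <- function(x, ...) {
  cat(sprintf("<condition_template '%s'> %d options x %d outcomes, %d ratings\n",
              x$condition_id, nrow(x$options), nrow(x$outcomes), nrow(x$ratings)))
  invisible(x)
}

#' @export
print.personalized_model <- function(x, ...) {
  cat(sprintf("<personalized_model '%s' for '%s'> %d options x %d outcomes, %d removals\n",
              x$condition_id, x$patient_id, nrow(x$options), nrow(x$outcomes),
              nrow(x$removals)))
  invisible(x)
}
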