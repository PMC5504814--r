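#' Map instrument values onto the 0-100 rating scale (and back)
#'
#' All evidence integration and ranking happen on a common 0-100 rating
#' scale where 100 is the best attainable level of an outcome. Instrument
#' values are mapped linearly: for a higher-is-better outcome
#' `(value - min) / (max - min) * 100`; for a lower-is-better outcome the
#' map is mirrored so that 100 is still best. `rating_to_instrument()` is
#' the exact algebraic inverse.
#'
#' @param value Numeric vector on the outcome's instrument scale (must lie
#'   within the instrument bounds).
#' @param outcome A one-row outcome tibble (see [outcome_def()]) or a list
#'   with `polarity`, `instrument_min`, `instrument_max`.
#' @return Numeric vector of ratings in \[0, 100\] (or instrument values for
#'   the inverse).
#' @examples
#' o <- outcome_def("tremor", polarity = "lower_is_better",
#'                  instrument_min = 0, instrument_max = 10)
#' rescale_to_rating(c(0, 5, 10), o) # 100, 50, 0
#' @export
rescale_to_rating <- function(value, outcome) {
  lo <- outcome$instrument_min
  hi <- outcome$instrument_max
  if (any(value < lo | value > hi, na.rm = TRUE)) {
    stop_hopt(sprintf("value outside instrument bounds [%s, %s]", lo, hi),
              "healthopt_bounds_error")
  }
  r <- (value - lo) / (hi - lo) * 100
  if (identical(outcome$polarity, "lower_is_better")) r <- 100 - r
  r
}

#' @rdname rescale_to_rating
#' @param rating Numeric vector of ratings in \[0, 100\].
#' @export
rating_to_instrument <- function(rating, outcome) {
  if (any(rating < 0 | rating > 100, na.rm = TRUE)) {
    stop_hopt("rating outside [0, 100]", "healthopt_bounds_error")
  }
  r <- rating
  if (identical(outcome$polarity, "lower_is_better")) r <- 100 - r
  outcome$instrument_min + r / 100 * (outcome$instrument_max - outcome$instrument_min)
}

#' Summarise one source's observations into a rating estimate
#'
#' Rescales a series of instrument-scale observations for one
#' option-exposure onto the rating scale and reduces it to a mean and a
#' standard error (`sd / sqrt(n)`). The standard error is floored at
#' `se_floor` so that a single self-report, or a zero-variance streak,
#' cannot overwhelm research evidence during pooling.
#'
#' @param observations Tibble with a `value` column on the instrument scale
#'   (optionally `option_id`/`outcome_id`, carried through).
#' @param outcome The [outcome_def()] row the values were measured on.
#' @param source Label for the estimate's source; default `"patient"`.
#' @param se_floor Minimum standard error, in rating points. Default 2.5.
#' @return A one-row tibble: `source`, `mean_rating`, `standard_error`, `n`
#'   (plus `option_id`/`outcome_id` when present in the input).
#' @export
summarize_patient_evidence <- function(observations, outcome, source = "patient",
                                       se_floor = 2.5) {
  observations <- as_tibble(observations)
  if (nrow(observations) == 0) {
    stop_hopt("no observations to summarise", "healthopt_empty_input")
  }
  ratings <- rescale_to_rating(observations$value, outcome)
  n <- length(ratings)
  se <- if (n >= 2) stats::sd(ratings) / sqrt(n) else 0
  out <- tibble(
    source = source,
    mean_rating = mean(ratings),
    standard_error = max(se, se_floor),
    n = n
  )
  for (col in c("option_id", "outcome_id")) {
    if (col %in% names(observations)) {
      ids <- unique(observations[[col]])
      if (length(ids) > 1) {
        stop_hopt(sprintf("observations span multiple %ss", col), "healthopt_schema_error")
      }
      out[[col]] <- ids
    }
  }
  out
}

#' Standard error implied by an authored research confidence
#'
#' Research-default ratings carry an authored evidence-quality confidence
#' `c` in \[0, 1\] rather than a standard error. For pooling, the
#' confidence is mapped linearly onto the rating-scale SE range:
#' `se = se_max * (1 - c) + se_min * c`, so full confidence gives the
#' tightest admissible SE and zero confidence the widest.
#'
#' @param confidence Numeric vector in \[0, 1\].
#' @param se_min,se_max SE at confidence 1 and 0; defaults 2.5 and 25
#'   rating points.
#' @return Numeric vector of standard errors.
#' @export
research_se <- function(confidence, se_min = 2.5, se_max = 25) {
  se_max * (1 - confidence) + se_min * confidence
}

se_to_confidence <- function(se, se_max = 25) clamp(1 - se / se_max, 0, 1)

#' Pool source estimates into one integrated rating
#'
#' Fixed-effect inverse-variance pooling of the research, clinician and
#' patient estimates for one (option, outcome) pair: each source is
#' weighted by `1 / se^2`, the pooled mean is the weighted mean, and
#' `pooled_se = (sum 1/se_i^2)^(-1/2)`, which is never larger than the
#' smallest input SE. The pooled SE is mapped back to a confidence via
#' `clamp(1 - pooled_se / se_max, 0, 1)`, the complement of the SE scale
#' used by [research_se()], so tighter pooled evidence always reads as
#' higher confidence.
#'
#' @param estimates Tibble with columns `source`, `mean_rating`,
#'   `standard_error` (all for the same option and outcome; `option_id` and
#'   `outcome_id` columns, if present, must be constant).
#' @param se_max SE mapped to confidence 0; default 25.
#' @return A one-row tibble of class `integrated_rating`: `pooled_mean`,
#'   `pooled_se`, `confidence`, and a `sources` list-column holding the
#'   contributing estimates with their normalized pooling weights.
#' @export
pool_estimates <- function(estimates, se_max = 25) {
  estimates <- as_tibble(estimates)
  assert_cols(estimates, c("source", "mean_rating", "standard_error"), "estimates")
  if (nrow(estimates) == 0) {
    stop_hopt("no estimates to pool", "healthopt_empty_input")
  }
  for (col in c("option_id", "outcome_id")) {
    if (col %in% names(estimates) && length(unique(estimates[[col]])) > 1) {
      stop_hopt(sprintf("estimates mix multiple %ss; pool one (option, outcome) at a time", col),
                "healthopt_schema_error")
    }
  }
  if (any(estimates$standard_error <= 0)) {
    stop_hopt("standard errors must be positive", "healthopt_bounds_error")
  }
  prec <- 1 / estimates$standard_error^2
  w <- prec / sum(prec)
  pooled_mean <- sum(w * estimates$mean_rating)
  pooled_se <- 1 / sqrt(sum(prec))
  out <- tibble(
    pooled_mean = pooled_mean,
    pooled_se = pooled_se,
    confidence = se_to_confidence(pooled_se, se_max),
    sources = list(mutate(estimates, weight = w))
  )
  for (col in c("option_id", "outcome_id")) {
    if (col %in% names(estimates)) out[[col]] <- estimates[[col]][1]
  }
  class(out) <- c("integrated_rating", class(out))
  out
}

#' Fold patient and clinician evidence into a personalized model
#'
#' For every (option, outcome) pair with evidence, the effective rating is
#' replaced by the inverse-variance pool of the research default (SE
#' derived from its authored confidence via [research_se()]) and one
#' estimate per evidence source; all other effective ratings are untouched.
#' Evidence for options or outcomes not retained in the model is ignored
#' with a logged note: filtering is [personalize()]'s job, and updating
#' never alters the retained sets. Retrospective observations (entered
#' about a past treatment) pool identically but are flagged in provenance.
#'
#' @param model A [personalize()]d decision model.
#' @param evidence Tibble with columns `timestamp`, `option_id`,
#'   `outcome_id`, `value` (instrument scale), `source` (`"patient"` or
#'   `"clinician"`) and `retrospective` (0/1); see [read_evidence()].
#' @param se_floor,se_min,se_max Pooling parameters, in rating points; see
#'   [summarize_patient_evidence()] and [research_se()].
#' @return A new `personalized_model`; the input is not modified. Ignored
#'   evidence rows are recorded in the `ignored_evidence` attribute.
#' @export
update_model <- function(model, evidence, se_floor = 2.5, se_min = 2.5, se_max = 25) {
  if (!inherits(model, "personalized_model")) {
    stop_hopt("model must be a personalized_model (see personalize())",
              "healthopt_schema_error")
  }
  evidence <- as_tibble(evidence)
  if (nrow(evidence) == 0) {
    attr(model, "ignored_evidence") <- evidence
    return(model)
  }
  assert_cols(evidence, c("option_id", "outcome_id", "value", "source"), "evidence")
  if (!"retrospective" %in% names(evidence)) evidence$retrospective <- 0L

  in_model <- evidence$option_id %in% model$options$id &
    evidence$outcome_id %in% model$outcomes$id
  ignored <- evidence[!in_model, , drop = FALSE]
  evidence <- evidence[in_model, , drop = FALSE]

  new_ratings <- model$ratings
  groups <- evidence %>% distinct(.data$option_id, .data$outcome_id)
  for (i in seq_len(nrow(groups))) {
    oid <- groups$option_id[i]
    kid <- groups$outcome_id[i]
    outc <- model$outcomes[model$outcomes$id == kid, , drop = FALSE]
    idx <- which(new_ratings$option_id == oid & new_ratings$outcome_id == kid)
    default <- new_ratings[idx, , drop = FALSE]
    research_est <- tibble(
      source = "research",
      mean_rating = default$score,
      standard_error = research_se(default$confidence, se_min, se_max)
    )
    ev <- evidence[evidence$option_id == oid & evidence$outcome_id == kid, , drop = FALSE]
    src_est <- ev %>%
      group_by(.data$source) %>%
      group_map(~ summarize_patient_evidence(.x, outc, source = .y$source,
                                             se_floor = se_floor)) %>%
      bind_rows()
    pooled <- pool_estimates(
      bind_rows(research_est, src_est[, c("source", "mean_rating", "standard_error")]),
      se_max = se_max
    )
    retro <- any(ev$retrospective == 1)
    new_ratings$score[idx] <- pooled$pooled_mean
    new_ratings$confidence[idx] <- pooled$confidence
    new_ratings$source[idx] <- "integrated"
    new_ratings$provenance[idx] <- paste0(
      "pooled: ", paste(sprintf("%s(w=%.3f)", pooled$sources[[1]]$source,
                                pooled$sources[[1]]$weight), collapse = ", "),
      if (retro) " [includes retrospective observations]" else ""
    )
  }
  model$ratings <- new_ratings
  attr(model, "ignored_evidence") <- ignored
  model
}
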