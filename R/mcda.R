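#' Normalize raw outcome importances into preference weights
#'
#' Patients express the relative importance of each outcome on a 0-100
#' scale; the MCDA engine uses the normalized weights
#' `w_k = raw_k / sum(raw)`, which sum to one. Raw values are preserved for
#' display. Scaling all raw importances by a positive constant leaves the
#' normalized weights (and hence every downstream ranking) unchanged.
#'
#' @param raw A named numeric vector of importances in \[0, 100\], or a
#'   data frame with columns `outcome_id` and `importance`.
#' @return A tibble of class `preference_weights` with columns `outcome_id`,
#'   `raw` and `weight`.
#' @examples
#' normalize_weights(c(mania = 20, depression = 30, weight_gain = 50))
#' @export
normalize_weights <- function(raw) {
  if (is.data.frame(raw)) {
    assert_cols(raw, c("outcome_id", "importance"), "weights")
    ids <- raw$outcome_id
    vals <- raw$importance
  } else {
    if (is.null(names(raw)) || any(names(raw) == "")) {
      stop_hopt("raw importances must be named by outcome_id", "healthopt_weights_error")
    }
    ids <- names(raw)
    vals <- unname(as.numeric(raw))
  }
  if (any(vals < 0 | vals > 100)) {
    stop_hopt("raw importances must lie in [0, 100]", "healthopt_weights_error")
  }
  if (all(vals == 0)) {
    stop_hopt("no preferences expressed: all raw importances are zero",
              "healthopt_weights_error")
  }
  if (anyDuplicated(ids)) {
    stop_hopt("duplicate outcome_id in weights", "healthopt_weights_error")
  }
  out <- tibble(outcome_id = ids, raw = vals, weight = vals / sum(vals))
  class(out) <- c("preference_weights", class(out))
  out
}

check_weights_cover <- function(model, weights) {
  if (!inherits(weights, "preference_weights")) weights <- normalize_weights(weights)
  if (!setequal(weights$outcome_id, model$outcomes$id)) {
    stop_hopt(sprintf(
      "weights must cover exactly the model's retained outcomes (%s); got (%s)",
      paste(sort(model$outcomes$id), collapse = ", "),
      paste(sort(weights$outcome_id), collapse = ", ")
    ), "healthopt_weights_error")
  }
  weights
}

effective_matrix <- function(model, weights, what = c("score", "confidence")) {
  what <- match.arg(what)
  wtab <- weights[, c("outcome_id", "weight")]
  joined <- inner_join(model$ratings, wtab, by = "outcome_id")
  missing <- anti_join(
    tidyr::expand_grid(option_id = model$options$id, outcome_id = model$outcomes$id),
    model$ratings, by = c("option_id", "outcome_id")
  )
  if (nrow(missing) > 0) {
    stop_hopt(sprintf("missing effective rating for (%s, %s)",
                      missing$option_id[1], missing$outcome_id[1]),
              "healthopt_missing_rating")
  }
  joined %>%
    group_by(.data$option_id) %>%
    summarise(value = sum(.data$weight * .data[[what]]), .groups = "drop")
}

#' Expected value of one option under preference weights
#'
#' The weighted additive value model: `EV(o) = sum_k w_k * s_ok`, where
#' `s_ok` is the effective 0-100 rating of option `o` on outcome `k` and
#' `w_k` the normalized preference weight. The expected value always lies
#' within the convex hull of the option's ratings.
#'
#' @param model A [personalize()]d decision model.
#' @param option_id A retained option id.
#' @param weights Preference weights over exactly the retained outcomes
#'   (see [normalize_weights()]).
#' @return A single number in \[0, 100\].
#' @export
expected_value <- function(model, option_id, weights) {
  weights <- check_weights_cover(model, weights)
  if (!option_id %in% model$options$id) {
    stop_hopt(sprintf("unknown or removed option '%s'", option_id), "healthopt_unknown_option")
  }
  ev <- effective_matrix(model, weights, "score")
  ev$value[ev$option_id == option_id]
}

#' Confidence index of one option under preference weights
#'
#' The preference-weighted mean of the evidence quality behind an option's
#' effective ratings: `CI(o) = sum_k w_k * c_ok` with confidences
#' `c_ok` in \[0, 1\]. It is displayed alongside the expected value rather
#' than folded into it, so the ranking semantics stay transparent; see the
#' `confidence_adjusted` flag of [rank_options()] for the alternative.
#'
#' @inheritParams expected_value
#' @return A single number in \[0, 1\].
#' @export
confidence_index <- function(model, option_id, weights) {
  weights <- check_weights_cover(model, weights)
  if (!option_id %in% model$options$id) {
    stop_hopt(sprintf("unknown or removed option '%s'", option_id), "healthopt_unknown_option")
  }
  ci <- effective_matrix(model, weights, "confidence")
  ci$value[ci$option_id == option_id]
}

#' Rank treatment options by preference-weighted expected value
#'
#' Sorts retained options by expected value (descending). Ties are broken by
#' higher confidence index, then lexicographic option id, so output is fully
#' deterministic. With `confidence_adjusted = TRUE`, options are instead
#' sorted by `EV * CI`, discounting options backed by weak evidence; the
#' unadjusted columns are still reported.
#'
#' @inheritParams expected_value
#' @param confidence_adjusted If `TRUE`, rank by the confidence-adjusted
#'   value `EV * CI` instead of the raw expected value. Default `FALSE`.
#' @return A tibble of class `hopt_ranking` with columns `option_id`,
#'   `expected_value`, `confidence_index`, (`adjusted_value` when
#'   `confidence_adjusted`), and `rank` (1 = best).
#' @examples
#' # see the package vignette for an end-to-end example
#' @export
rank_options <- function(model, weights, confidence_adjusted = FALSE) {
  weights <- check_weights_cover(model, weights)
  if (nrow(model$options) == 0) {
    stop_hopt("no admissible options to rank", "healthopt_no_options")
  }
  ev <- effective_matrix(model, weights, "score") %>% rename(expected_value = "value")
  ci <- effective_matrix(model, weights, "confidence") %>% rename(confidence_index = "value")
  out <- inner_join(ev, ci, by = "option_id")
  if (confidence_adjusted) {
    out$adjusted_value <- out$expected_value * out$confidence_index
    key <- out$adjusted_value
  } else {
    key <- out$expected_value
  }
  ord <- order(-key, -out$confidence_index, out$option_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  attr(out, "weights") <- weights
  attr(out, "confidence_adjusted") <- confidence_adjusted
  class(out) <- c("hopt_ranking", class(out))
  out
}

#' Explore how changed preferences would alter the ranking
#'
#' Re-ranks the model under a second weight vector and reports, per option,
#' the old and new rank and the change in expected value. The model itself
#' is never mutated, so what-if exploration is free of side effects.
#'
#' @inheritParams expected_value
#' @param base_weights,new_weights Two weight vectors over the model's
#'   retained outcomes.
#' @param confidence_adjusted Passed through to [rank_options()].
#' @return A tibble of class `hopt_whatif` with columns `option_id`,
#'   `old_rank`, `new_rank`, `rank_change` (positive = moved up) and
#'   `ev_change`.
#' @export
what_if <- function(model, base_weights, new_weights, confidence_adjusted = FALSE) {
  r0 <- rank_options(model, base_weights, confidence_adjusted)
  r1 <- rank_options(model, new_weights, confidence_adjusted)
  out <- inner_join(
    as_tibble(r0)[, c("option_id", "rank", "expected_value")],
    as_tibble(r1)[, c("option_id", "rank", "expected_value")],
    by = "option_id", suffix = c("_old", "_new")
  ) %>%
    transmute(
      option_id = .data$option_id,
      old_rank = .data$rank_old,
      new_rank = .data$rank_new,
      rank_change = .data$rank_old - .data$rank_new,
      ev_change = .data$expected_value_new - .data$expected_value_old
    ) %>%
    arrange(.data$new_rank)
  class(out) <- c("hopt_whatif", class(out))
  out
}

#' Head-to-head comparison of two treatment options
#'
#' Per-outcome differences in effective ratings and confidences between two
#' retained options, plus the expected-value and confidence-index
#' differences when weights are supplied. The comparison is antisymmetric:
#' `head_to_head(m, a, b)` is the componentwise negation of
#' `head_to_head(m, b, a)`.
#'
#' @inheritParams expected_value
#' @param option_a,option_b Retained option ids.
#' @param weights Optional preference weights; when supplied the EV and CI
#'   differences are attached as attributes `ev_diff` and `ci_diff`.
#' @return A tibble of class `hopt_h2h` with one row per retained outcome:
#'   `outcome_id`, `score_a`, `score_b`, `score_diff` (a minus b),
#'   `confidence_a`, `confidence_b`, `confidence_diff`.
#' @export
head_to_head <- function(model, option_a, option_b, weights = NULL) {
  for (o in c(option_a, option_b)) {
    if (!o %in% model$options$id) {
      stop_hopt(sprintf("unknown or removed option '%s'", o), "healthopt_unknown_option")
    }
  }
  get_side <- function(o) {
    model$ratings %>%
      filter(.data$option_id == o) %>%
      select("outcome_id", "score", "confidence")
  }
  out <- inner_join(get_side(option_a), get_side(option_b),
                    by = "outcome_id", suffix = c("_a", "_b")) %>%
    transmute(
      outcome_id = .data$outcome_id,
      score_a = .data$score_a, score_b = .data$score_b,
      score_diff = .data$score_a - .data$score_b,
      confidence_a = .data$confidence_a, confidence_b = .data$confidence_b,
      confidence_diff = .data$confidence_a - .data$confidence_b
    )
  attr(out, "option_a") <- option_a
  attr(out, "option_b") <- option_b
  if (!is.null(weights)) {
    weights <- check_weights_cover(model, weights)
    attr(out, "ev_diff") <- expected_value(model, option_a, weights) -
      expected_value(model, option_b, weights)
    attr(out, "ci_diff") <- confidence_index(model, option_a, weights) -
      confidence_index(model, option_b, weights)
  }
  class(out) <- c("hopt_h2h", class(out))
  out
}
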