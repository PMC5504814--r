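#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @method tidy hopt_ranking
#' @export
tidy.hopt_ranking <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @method glance hopt_ranking
#' @export
glance.hopt_ranking <- function(x, ...) {
  tibble(
    n_options = nrow(x),
    top_option = x$option_id[x$rank == 1],
    top_expected_value = x$expected_value[x$rank == 1],
    top_confidence_index = x$confidence_index[x$rank == 1],
    ev_spread = max(x$expected_value) - min(x$expected_value),
    confidence_adjusted = isTRUE(attr(x, "confidence_adjusted"))
  )
}

#' @method tidy hopt_h2h
#' @export
tidy.hopt_h2h <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @method glance hopt_h2h
#' @export
glance.hopt_h2h <- function(x, ...) {
  tibble(
    option_a = attr(x, "option_a"),
    option_b = attr(x, "option_b"),
    n_outcomes = nrow(x),
    ev_diff = attr(x, "ev_diff") %||% NA_real_,
    ci_diff = attr(x, "ci_diff") %||% NA_real_
  )
}

#' @method glance hopt_nap
#' @export
glance.hopt_nap <- function(x, ...) as_tibble(x)

#' @method glance recovery_result
#' @export
glance.recovery_result <- function(x, ...) {
  tibble(
    n_replicates = nrow(x),
    recovery_rate_integrated = mean(x$integrated_correct),
    recovery_rate_default = mean(x$default_correct),
    mean_rmse_integrated = mean(x$rmse_integrated),
    mean_rmse_default = mean(x$rmse_default)
  )
}
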