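#' @importFrom rlang %||% abort
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_chr map_lgl map_dbl map2
NULL

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_token <- function(x) is.character(x) & grepl("^[a-z0-9_]+$", x)

stop_hopt <- function(msg, class) {
  rlang::abort(msg, class = c(class, "healthopt_error"))
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_hopt(
      sprintf("%s is missing column(s): %s", what, paste(missing, collapse = ", ")),
      "healthopt_schema_error"
    )
  }
  invisible(df)
}

as_date_strict <- function(x, what = "date") {
  out <- tryCatch(as.Date(x), error = function(e) NA)
  if (any(is.na(out) & !is.na(x))) {
    stop_hopt(sprintf("could not parse %s as ISO-8601 date", what), "healthopt_schema_error")
  }
  out
}
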