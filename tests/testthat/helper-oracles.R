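# Independent brute-force oracles, written as plain loops over the raw
# numbers so they share no code path with the package implementation.

oracle_ev <- function(scores, weights) {
  total <- 0
  for (k in seq_along(weights)) total <- total + weights[k] * scores[k]
  total
}

oracle_rank <- function(ev, ci, ids) {
  # selection sort on (ev desc, ci desc, id asc)
  n <- length(ids)
  remaining <- seq_len(n)
  out <- integer(0)
  while (length(remaining) > 0) {
    best <- remaining[1]
    for (j in remaining) {
      if (ev[j] > ev[best] ||
          (ev[j] == ev[best] && ci[j] > ci[best]) ||
          (ev[j] == ev[best] && ci[j] == ci[best] && ids[j] < ids[best])) {
        best <- j
      }
    }
    out <- c(out, best)
    remaining <- setdiff(remaining, best)
  }
  ids[out]
}

oracle_nap <- function(baseline, phase) {
  improving <- 0; ties <- 0; pairs <- 0
  for (b in baseline) {
    for (p in phase) {
      pairs <- pairs + 1
      if (p > b) improving <- improving + 1
      if (p == b) ties <- ties + 1
    }
  }
  (improving + 0.5 * ties) / pairs
}

oracle_pool <- function(means, ses) {
  num <- 0; den <- 0
  for (i in seq_along(means)) {
    num <- num + means[i] / ses[i]^2
    den <- den + 1 / ses[i]^2
  }
  list(mean = num / den, se = sqrt(1 / den))
}

oracle_slope <- function(x, y) {
  # normal equations for simple regression
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x * x); sxy <- sum(x * y)
  (n * sxy - sx * sy) / (n * sxx - sx^2)
}

oracle_rule <- function(rule, attrs) {
  # direct truth-table walk over the clause/atom structure
  if (is.null(rule) || length(rule$clauses) == 0) return(TRUE)
  for (cl in rule$clauses) {
    clause_true <- FALSE
    for (a in cl$atoms) {
      v <- attrs[[a$attribute]]
      hit <- switch(a$op,
        "=" = identical(v == a$value, TRUE),
        "!=" = identical(v != a$value, TRUE),
        "<" = v < a$value, "<=" = v <= a$value,
        ">" = v > a$value, ">=" = v >= a$value,
        "in" = v %in% a$value)
      if (isTRUE(hit)) { clause_true <- TRUE; break }
    }
    if (!clause_true) return(FALSE)
  }
  TRUE
}

# day-by-day calendar walk for schedule expansion counts
oracle_slot_count <- function(start, end, from, to, days_spec, times_per_day) {
  count <- 0
  d <- max(as.Date(start), as.Date(from))
  stop_at <- min(if (is.na(end)) as.Date(to) else as.Date(end) - 1, as.Date(to))
  while (d <= stop_at) {
    wd <- format(d, "%a")
    ok <- switch(days_spec,
      daily = TRUE,
      weekdays = wd %in% c("Mon", "Tue", "Wed", "Thu", "Fri"),
      tolower(substr(wd, 1, 3)) %in% trimws(strsplit(days_spec, ",")[[1]]))
    if (ok) count <- count + times_per_day
    d <- d + 1
  }
  count
}

# -- fixture builders ---------------------------------------------------------

make_model <- function(n_opt, n_out, scores = NULL, confidences = NULL) {
  option_ids <- sprintf("o%02d", seq_len(n_opt))
  outcome_ids <- sprintf("k%d", seq_len(n_out))
  if (is.null(scores)) scores <- matrix(runif(n_opt * n_out, 0, 100), n_opt)
  if (is.null(confidences)) confidences <- matrix(runif(n_opt * n_out), n_opt)
  ratings <- tidyr::expand_grid(option_id = option_ids, outcome_id = outcome_ids)
  ratings$score <- as.vector(t(scores))
  ratings$confidence <- as.vector(t(confidences))
  ratings$source <- "research"
  tpl <- condition_template(
    "test_condition",
    dplyr::bind_rows(lapply(option_ids, treatment_option)),
    dplyr::bind_rows(lapply(outcome_ids, outcome_def)),
    ratings
  )
  personalize(tpl, patient_profile("pt"))
}

random_weights <- function(outcome_ids) {
  raw <- runif(length(outcome_ids), 1, 100)
  normalize_weights(stats::setNames(raw, outcome_ids))
}

simplex_grid <- function(n, step = 0.05) {
  # all weight vectors on the n-simplex with coordinates on a `step` grid
  # (stars and bars: bar positions p in 1..ticks+n-1 give gap sizes)
  ticks <- round(1 / step)
  combos <- utils::combn(ticks + n - 1, n - 1)
  apply(combos, 2, function(p) {
    x <- diff(c(0, p, ticks + n)) - 1
    x * step
  })
}
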