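#' Configure the synthetic-patient simulator
#'
#' The simulator generates condition templates and full patient records
#' with known ground truth, so every pipeline stage — personalization,
#' evidence integration, ranking, adherence — can be exercised end to end
#' and checked against the truth it was generated from.
#'
#' The generative model: each day the patient is (intended to be) on the
#' active plan's option; a Bernoulli draw with probability
#' `adherence_prob` decides whether the dose is actually taken. The
#' latent rating for outcome `k` is
#' `y_t = a_t * mu(option, k) + (1 - a_t) * mu_untreated_k + eta_t + event effects`,
#' where `eta_t` is AR(1) noise with autocorrelation `rho` and innovation
#' SD `sigma` (mood and similar outcomes persist day to day; non-adherent
#' days revert to the untreated mean immediately, i.e. no pharmacokinetic
#' carryover). Life events arrive as a Poisson process with rate
#' `event_rate` per day and add a shift that decays linearly to zero over
#' `event_decay_days`. Observations are the latent ratings clamped to
#' \[0, 100\] and mapped back to each outcome's instrument scale.
#'
#' Research-default ratings are displaced from the truth by `research_bias`
#' plus `N(0, research_bias_sd)` noise, emulating population estimates
#' that are imperfect for the individual.
#'
#' @param n_options,n_outcomes Size of the decision model.
#' @param true_effects Optional `n_options x n_outcomes` matrix of true
#'   mean ratings. By default option means are spaced so the truly best
#'   option beats the runner-up by `effect_gap` rating points on every
#'   outcome.
#' @param effect_gap Gap in mean rating between the best option and the
#'   runner-up (default 10).
#' @param untreated_mean Mean rating on non-adherent days (default 40).
#' @param sigma AR(1) innovation SD in rating points (default 8).
#' @param rho AR(1) autocorrelation in \[0, 1) (default 0.3).
#' @param adherence_prob Probability a planned intake is taken (default 0.9).
#' @param days_per_phase Length of each treatment phase in days (default 30).
#' @param phase_sequence Character vector of option ids tried in order;
#'   default is every option once, in id order.
#' @param research_bias Systematic displacement of research defaults from
#'   truth (scalar or matrix; default 0).
#' @param research_bias_sd SD of the random per-cell displacement
#'   (default 8).
#' @param research_confidence Authored confidence of research defaults
#'   (default 0.7).
#' @param event_rate Life events per day (default 0).
#' @param event_shift Rating shift on an event day (default -15).
#' @param event_decay_days Days over which an event's effect decays
#'   linearly to zero (default 7).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_options = 5, n_outcomes = 3, true_effects = NULL,
                       effect_gap = 10, untreated_mean = 40,
                       sigma = 8, rho = 0.3, adherence_prob = 0.9,
                       days_per_phase = 30, phase_sequence = NULL,
                       research_bias = 0, research_bias_sd = 8,
                       research_confidence = 0.7,
                       event_rate = 0, event_shift = -15, event_decay_days = 7) {
  if (sigma < 0 || rho < 0 || rho >= 1) {
    stop_hopt("require sigma >= 0 and 0 <= rho < 1", "healthopt_config_error")
  }
  if (adherence_prob < 0 || adherence_prob > 1) {
    stop_hopt("adherence_prob must lie in [0, 1]", "healthopt_config_error")
  }
  if (days_per_phase < 1) {
    stop_hopt("days_per_phase must be >= 1", "healthopt_config_error")
  }
  option_ids <- sprintf("opt_%02d", seq_len(n_options))
  outcome_ids <- sprintf("out_%d", seq_len(n_outcomes))
  if (is.null(true_effects)) {
    # best option 70, runner-up 70 - gap, the rest sliding down toward 45
    mu <- c(70, 70 - effect_gap,
            if (n_options > 2) seq(70 - effect_gap - 4, 45, length.out = n_options - 2))
    mu <- mu[seq_len(n_options)]
    true_effects <- matrix(rep(mu, n_outcomes), nrow = n_options,
                           dimnames = list(option_ids, outcome_ids))
  } else {
    true_effects <- as.matrix(true_effects)
    stopifnot(nrow(true_effects) == n_options, ncol(true_effects) == n_outcomes)
    dimnames(true_effects) <- list(option_ids, outcome_ids)
  }
  if (is.null(phase_sequence)) phase_sequence <- option_ids
  structure(
    list(
      n_options = n_options, n_outcomes = n_outcomes,
      option_ids = option_ids, outcome_ids = outcome_ids,
      true_effects = true_effects, untreated_mean = untreated_mean,
      sigma = sigma, rho = rho, adherence_prob = adherence_prob,
      days_per_phase = days_per_phase, phase_sequence = phase_sequence,
      research_bias = research_bias, research_bias_sd = research_bias_sd,
      research_confidence = research_confidence,
      event_rate = event_rate, event_shift = event_shift,
      event_decay_days = event_decay_days
    ),
    class = "sim_config"
  )
}

sim_outcomes <- function(config) {
  # outcome 2 (when present) is lower-is-better on a 0-10 instrument so the
  # polarity/rescaling path is exercised inside the simulation loop
  bind_rows(lapply(seq_len(config$n_outcomes), function(k) {
    if (k == 2) {
      outcome_def(config$outcome_ids[k], polarity = "lower_is_better",
                  instrument_min = 0, instrument_max = 10)
    } else {
      outcome_def(config$outcome_ids[k], instrument_min = 0, instrument_max = 100)
    }
  }))
}

#' Simulate a condition template with known ground truth
#'
#' Research-source ratings are the true effect matrix displaced by the
#' configured bias and noise, clamped to \[0, 100\]; every (option,
#' outcome) pair gets a rating, so the template is always complete. The
#' true effect matrix is attached as the `truth` attribute.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical (config, seed) gives an identical
#'   template.
#' @return A complete [condition_template()] with attribute `truth`.
#' @export
simulate_template <- function(config, seed) {
  force(config)
  set.seed(seed)
  truth <- config$true_effects
  bias <- config$research_bias
  noise <- matrix(stats::rnorm(length(truth), 0, config$research_bias_sd),
                  nrow = nrow(truth))
  research <- clamp(truth + bias + noise, 0, 100)
  ratings <- tidyr::expand_grid(option_id = config$option_ids,
                                outcome_id = config$outcome_ids) %>%
    mutate(score = research[cbind(.data$option_id, .data$outcome_id)],
           confidence = config$research_confidence,
           source = "research")
  tpl <- condition_template(
    "simulated_condition",
    options = bind_rows(lapply(config$option_ids, treatment_option)),
    outcomes = sim_outcomes(config),
    ratings = ratings
  )
  attr(tpl, "truth") <- truth
  tpl
}

decayed_event_effect <- function(day_index, event_days, shift, decay_days) {
  if (length(event_days) == 0) return(0)
  age <- day_index - event_days
  sum(ifelse(age >= 0 & age < decay_days, shift * (1 - age / decay_days), 0))
}

#' Simulate a patient record under a template
#'
#' Generates one phase per entry of the configured phase sequence, each
#' `days_per_phase` days long, with daily observations of every outcome,
#' once-daily intake events realized from the adherence probability, and
#' Poisson life events. The realized truth (effect matrix, latent states
#' and adherence draws) is attached as the `truth` attribute.
#'
#' @param config A [sim_config()].
#' @param template A template from [simulate_template()] (used for
#'   instrument definitions; its ratings are not consulted).
#' @param seed Integer seed.
#' @param start_date First day of the first phase.
#' @return A [patient_record()] with attribute `truth`.
#' @export
simulate_patient <- function(config, template, seed, start_date = as.Date("2020-01-06")) {
  force(config); force(template) # evaluate before seeding: both may touch the RNG
  set.seed(seed)
  if (!all(config$phase_sequence %in% template$options$id)) {
    stop_hopt("phase sequence references options absent from the template",
              "healthopt_config_error")
  }
  n_phases <- length(config$phase_sequence)
  total_days <- n_phases * config$days_per_phase
  dates <- start_date + seq_len(total_days) - 1
  active <- rep(config$phase_sequence, each = config$days_per_phase)

  plans <- tibble(
    plan_id = sprintf("p%02d", seq_len(n_phases)),
    option_id = config$phase_sequence,
    dose_label = NA_character_, times_per_day = 1L, days = "daily",
    kind = "medication",
    start = start_date + (seq_len(n_phases) - 1) * config$days_per_phase,
    end = start_date + seq_len(n_phases) * config$days_per_phase
  )

  a <- stats::rbinom(total_days, 1, config$adherence_prob)

  n_events <- stats::rpois(1, config$event_rate * total_days)
  event_days <- sort(sample.int(total_days, min(n_events, total_days)))
  life_events <- tibble(
    timestamp = dates[event_days],
    label = sprintf("life event %d", seq_along(event_days)),
    category = "stress"
  )

  outs <- template$outcomes
  obs <- vector("list", config$n_outcomes)
  latent <- matrix(NA_real_, nrow = total_days, ncol = config$n_outcomes)
  for (k in seq_len(config$n_outcomes)) {
    eta <- numeric(total_days)
    eps <- stats::rnorm(total_days, 0, config$sigma)
    for (t in seq_len(total_days)) {
      eta[t] <- if (t == 1) eps[t] else config$rho * eta[t - 1] + eps[t]
    }
    mu_on <- unname(config$true_effects[active, k])
    ev_fx <- vapply(seq_len(total_days), decayed_event_effect, numeric(1),
                    event_days = event_days, shift = config$event_shift,
                    decay_days = config$event_decay_days)
    y <- a * mu_on + (1 - a) * config$untreated_mean + eta + ev_fx
    latent[, k] <- y
    outc <- outs[k, ]
    obs[[k]] <- tibble(
      timestamp = dates,
      option_id = active,
      outcome_id = outc$id,
      value = rating_to_instrument(clamp(y, 0, 100), outc),
      source = "patient",
      retrospective = 0L
    )
  }

  intakes <- tibble(
    planned_datetime = as.POSIXct(dates, tz = "UTC") + 8 * 3600,
    option_id = active,
    taken = a == 1,
    taken_datetime = as.POSIXct(ifelse(a == 1, as.POSIXct(dates, tz = "UTC") + 8 * 3600, NA),
                                tz = "UTC", origin = "1970-01-01")
  )

  record <- patient_record(
    patient_id = "sim_patient",
    observations = bind_rows(obs) %>% arrange(.data$timestamp, .data$outcome_id),
    plans = plans,
    intake_events = intakes,
    life_events = life_events,
    monitoring_plan = tibble(outcome_id = config$outcome_ids, days = "daily",
                             start = start_date, end = as.Date(NA))
  )
  attr(record, "truth") <- list(
    effects = config$true_effects, latent = latent, adherence = a,
    active_option = active
  )
  record
}

#' End-to-end parameter-recovery experiment
#'
#' For each replicate: simulate a template (biased research defaults) and
#' a patient record, rank on the research defaults alone, then fold the
#' patient's observations into the model with [update_model()] and rank
#' again, recording whether each ranking's top option is the truly best
#' option under the given weights, plus the root-mean-square error of the
#' effective ratings against truth before and after integration.
#'
#' @param config A [sim_config()].
#' @param n_replicates Number of independent replicates.
#' @param seed Base seed; replicate `r` uses `seed + r` for the template
#'   and `seed + 100000 + r` for the patient.
#' @param weights Preference weights over the simulated outcomes; default
#'   equal importances.
#' @param days_per_phase Optional override of `config$days_per_phase`.
#' @return A tibble of class `recovery_result`, one row per replicate:
#'   `replicate`, `true_best`, `default_top`, `integrated_top`,
#'   `default_correct`, `integrated_correct`, `rmse_default`,
#'   `rmse_integrated`. Summarise with [glance()].
#' @export
recovery_experiment <- function(config, n_replicates = 50, seed = 1,
                                weights = NULL, days_per_phase = NULL) {
  if (!is.null(days_per_phase)) {
    config$days_per_phase <- days_per_phase
  }
  if (is.null(weights)) {
    weights <- normalize_weights(
      stats::setNames(rep(50, config$n_outcomes), config$outcome_ids))
  }
  w <- weights$weight[match(config$outcome_ids, weights$outcome_id)]
  true_ev <- as.vector(config$true_effects %*% w)
  true_best <- config$option_ids[which.max(true_ev)]
  if (sum(true_ev == max(true_ev)) > 1) {
    stop_hopt("no unique truly-best option under these weights", "healthopt_config_error")
  }

  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    tpl <- simulate_template(config, seed + r)
    model <- personalize(tpl, patient_profile("sim_patient"))
    rank_default <- rank_options(model, weights)
    record <- simulate_patient(config, tpl, seed + 100000 + r)
    model_upd <- update_model(model, record$observations)
    rank_upd <- rank_options(model_upd, weights)
    rmse <- function(m) {
      eff <- m$ratings
      truth <- config$true_effects[cbind(eff$option_id, eff$outcome_id)]
      sqrt(mean((eff$score - truth)^2))
    }
    rows[[r]] <- tibble(
      replicate = r,
      true_best = true_best,
      default_top = rank_default$option_id[1],
      integrated_top = rank_upd$option_id[1],
      default_correct = rank_default$option_id[1] == true_best,
      integrated_correct = rank_upd$option_id[1] == true_best,
      rmse_default = rmse(model),
      rmse_integrated = rmse(model_upd)
    )
  }
  out <- bind_rows(rows)
  class(out) <- c("recovery_result", class(out))
  out
}
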