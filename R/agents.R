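#' Agent policy parameters
#'
#' A synthetic participant is a statistical learner with an escape policy.
#' Its `tracker` names the learned quantity that drives behaviour: a
#' *hazard* tracker acts on the conditional shock probability given
#' survival so far, a *probability* tracker acts on the marginal
#' per-second shock probability. The two trackers make different
#' predictions precisely where the paradigm dissociates them: inside a
#' P(Threat)-matched window, probability trackers see identical signals
#' in both conditions while hazard trackers see a strictly higher signal
#' in the early-threat condition.
#'
#' The escape policy is a per-second logistic choice rule: at second `t`
#' the agent escapes with probability
#' `plogis(escape_intercept + escape_slope * signal(t))`. Ratings are an
#' affine readout of the same signal, `clip(rating_gain * signal + noise,
#' 0, 10)`, with Gaussian noise.
#'
#' @param id Integer participant id.
#' @param tracker `"hazard"` or `"probability"`.
#' @param escape_intercept Log-odds of escaping in a second with zero
#'   signal (baseline escapiness).
#' @param escape_slope Log-odds increase per unit of tracked signal;
#'   0 switches the policy off, leaving only the baseline.
#' @param rating_gain Rating units per unit signal on the 0-10 scale.
#' @param rating_noise_sd SD of Gaussian rating noise (>= 0).
#' @param smoothing Pseudo-count added to every trial second when the
#'   agent turns its experienced shock times into an estimated schedule
#'   (>= 0; 0 reproduces the raw empirical histogram).
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(id = 1L,
                         tracker = c("hazard", "probability"),
                         escape_intercept = -5.5,
                         escape_slope = 25,
                         rating_gain = 10,
                         rating_noise_sd = 1,
                         smoothing = 0.5) {
  tracker <- match.arg(tracker)
  if (rating_noise_sd < 0 || smoothing < 0) {
    th_error("threathazard_bad_agent",
             "rating_noise_sd and smoothing must be non-negative")
  }
  structure(
    list(id = as.integer(id), tracker = tracker,
         escape_intercept = escape_intercept, escape_slope = escape_slope,
         rating_gain = rating_gain, rating_noise_sd = rating_noise_sd,
         smoothing = smoothing),
    class = "agent_params"
  )
}

#' Population distribution of agent parameters
#'
#' Hyperparameters from which [simulate_cohort()] draws each
#' participant's policy: Gaussian intercepts and slopes (slopes truncated
#' at 0 so no agent is repelled by its own threat signal) and Gaussian
#' rating gains (truncated at 0). Defaults describe a cohort of hazard
#' trackers with moderate between-participant variability.
#'
#' @param tracker Tracker shared by the cohort.
#' @param intercept_mean,intercept_sd Escape-intercept distribution
#'   (log-odds).
#' @param slope_mean,slope_sd Escape-slope distribution (log-odds per
#'   unit signal).
#' @param gain_mean,gain_sd Rating-gain distribution (rating units per
#'   unit signal).
#' @param rating_noise_sd Rating noise SD, common to the cohort.
#' @param smoothing Schedule-estimation pseudo-count, common to the
#'   cohort.
#' @return A list of class `agent_population`.
#' @export
agent_population <- function(tracker = c("hazard", "probability"),
                             intercept_mean = -5.5, intercept_sd = 0.75,
                             slope_mean = 25, slope_sd = 3,
                             gain_mean = 10, gain_sd = 2,
                             rating_noise_sd = 1,
                             smoothing = 0.5) {
  tracker <- match.arg(tracker)
  if (intercept_sd < 0 || slope_sd < 0 || gain_sd < 0 ||
      rating_noise_sd < 0 || smoothing < 0) {
    th_error("threathazard_bad_agent",
             "population scale parameters must be non-negative")
  }
  structure(
    list(tracker = tracker,
         intercept_mean = intercept_mean, intercept_sd = intercept_sd,
         slope_mean = slope_mean, slope_sd = slope_sd,
         gain_mean = gain_mean, gain_sd = gain_sd,
         rating_noise_sd = rating_noise_sd, smoothing = smoothing),
    class = "agent_population"
  )
}

draw_agent <- function(id, pop) {
  agent_params(
    id = id, tracker = pop$tracker,
    escape_intercept = stats::rnorm(1, pop$intercept_mean, pop$intercept_sd),
    escape_slope = max(0, stats::rnorm(1, pop$slope_mean, pop$slope_sd)),
    rating_gain = max(0, stats::rnorm(1, pop$gain_mean, pop$gain_sd)),
    rating_noise_sd = pop$rating_noise_sd,
    smoothing = pop$smoothing
  )
}

empty_records <- function(n = 0) {
  data.frame(
    participant_id = integer(n), condition = character(n),
    phase = character(n), trial_index = integer(n),
    outcome = character(n), event_time_s = integer(n),
    earnings_cents = integer(n), shocks_so_far = integer(n),
    rating = numeric(n), rating_time_s = integer(n),
    stringsAsFactors = FALSE
  )
}

#' Simulate the unavoidable-shock learning phase for one condition
#'
#' Draws `n_trials` i.i.d. shock times from the condition's true
#' schedule; every trial ends in shock and earns nothing. The agent's
#' state after learning is its estimated schedule: the empirical
#' shock-time histogram over the trial grid plus `smoothing` pseudo-counts
#' per second, normalised to a proper pmf.
#'
#' @param agent An [agent_params()] object.
#' @param schedule The condition's true `threat_schedule`.
#' @param n_trials Number of unavoidable shocks to deliver (default 50).
#' @param condition Condition label stored in the records.
#' @param seed Optional integer seed; when `NULL` the current RNG stream
#'   is used.
#' @return A list with `state` (class `agent_state`: `estimate`, a
#'   `threat_schedule`, and `shocks_received`) and `records`, one row per
#'   learning trial.
#' @export
simulate_learning <- function(agent, schedule, n_trials = 50,
                              condition = "early", seed = NULL) {
  if (n_trials < 1) {
    th_error("threathazard_bad_agent", "n_trials must be at least 1")
  }
  if (!is.null(seed)) set.seed(seed)
  validate_schedule(schedule)
  grid <- schedule$timepoints
  shock_times <- sample(grid, n_trials, replace = TRUE, prob = schedule$pmf)
  counts <- tabulate(match(shock_times, grid), nbins = length(grid))
  est <- counts + agent$smoothing
  state <- structure(
    list(estimate = threat_schedule(grid, est / sum(est),
                                    sprintf("estimate-p%d-%s", agent$id, condition)),
         shocks_received = n_trials),
    class = "agent_state"
  )
  rec <- empty_records(n_trials)
  rec$participant_id <- agent$id
  rec$condition <- condition
  rec$phase <- "learning"
  rec$trial_index <- seq_len(n_trials)
  rec$outcome <- "shock"
  rec$event_time_s <- as.integer(shock_times)
  rec$earnings_cents <- 0L
  rec$shocks_so_far <- seq_len(n_trials) - 1L
  rec$rating <- NA_real_
  rec$rating_time_s <- NA_integer_
  list(state = state, records = rec)
}

#' Tracked threat signal at a trial second
#'
#' The agent's decision signal at second `t`, computed from its *learned*
#' schedule estimate (never the true schedule): the estimate's hazard
#' rate at `t` for hazard trackers, or the estimate's pmf at `t` for
#' probability trackers. Beyond the estimate's last support point the
#' hazard is undefined and `NA` is returned (unreachable for smoothed
#' estimates, whose support covers the whole trial).
#'
#' @param state An `agent_state` from [simulate_learning()].
#' @param tracker `"hazard"` or `"probability"`.
#' @param t Vector of trial seconds (must lie on the estimate's grid).
#' @return Numeric signal values, one per element of `t`.
#' @export
escape_signal <- function(state, tracker = c("hazard", "probability"), t) {
  tracker <- match.arg(tracker)
  est <- state$estimate
  if (any(!(t %in% est$timepoints))) {
    th_error("threathazard_bad_time", "t lies beyond the trial grid")
  }
  if (tracker == "probability") {
    est$pmf[match(t, est$timepoints)]
  } else {
    hazard_on_grid(est, est$timepoints)[match(t, est$timepoints)]
  }
}

# per-second escape probabilities for one agent x condition
escape_prob_vector <- function(agent, state) {
  sig <- escape_signal(state, agent$tracker, state$estimate$timepoints)
  stats::plogis(agent$escape_intercept + agent$escape_slope * sig)
}

# first second at which a Bernoulli(p[t]) sequence fires, NA if never;
# vectorised over n independent trials
r_first_success <- function(p, n) {
  u <- matrix(stats::runif(n * length(p)), nrow = n)
  hit <- u < rep(p, each = n)
  first <- apply(hit, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
  as.integer(first) - 1L
}

#' Simulate one testing-phase trial
#'
#' In the testing phase the agent earns 1 cent for every second it
#' persists, and may end the trial ("escape") to avoid the shock. Each
#' second `t` unfolds as: the agent first decides, escaping with
#' probability `plogis(escape_intercept + escape_slope * signal(t))`
#' where the signal comes from its learned estimate; if it stays, the
#' shock lands with the *true* schedule's hazard at `t`; surviving the
#' second banks 1 cent. Earnings therefore equal the event time in cents
#' under the default 1 cent/s rate. A proper true schedule guarantees the
#' trial ends by its last support point.
#'
#' @param agent An [agent_params()].
#' @param state The agent's learned `agent_state` for this condition.
#' @param true_schedule The condition's true `threat_schedule`.
#' @param reward_rate_cents_per_s Earnings per survived second.
#' @param condition,trial_index,shocks_so_far Bookkeeping stored in the
#'   record.
#' @param seed Optional integer seed.
#' @return A one-row trial-record `data.frame`.
#' @export
simulate_testing_trial <- function(agent, state, true_schedule,
                                   reward_rate_cents_per_s = 1,
                                   condition = "early", trial_index = 1L,
                                   shocks_so_far = 0L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_schedule(true_schedule)
  p_escape <- escape_prob_vector(agent, state)
  h_true <- hazard_on_grid(true_schedule, true_schedule$timepoints)
  grid <- true_schedule$timepoints
  outcome <- "shock"
  event_t <- grid[length(grid)]
  for (i in seq_along(grid)) {
    if (stats::runif(1) < p_escape[i]) {           # decision precedes shock
      outcome <- "escape"; event_t <- grid[i]; break
    }
    if (!is.na(h_true[i]) && stats::runif(1) < h_true[i]) {
      outcome <- "shock"; event_t <- grid[i]; break
    }
  }
  rec <- empty_records(1)
  rec$participant_id <- agent$id
  rec$condition <- condition
  rec$phase <- "testing"
  rec$trial_index <- as.integer(trial_index)
  rec$outcome <- outcome
  rec$event_time_s <- as.integer(event_t)
  rec$earnings_cents <- as.integer(round(reward_rate_cents_per_s * event_t))
  rec$shocks_so_far <- as.integer(shocks_so_far)
  rec$rating <- NA_real_
  rec$rating_time_s <- NA_integer_
  rec
}

#' Generate a fear/anxiety rating from a signal
#'
#' Ratings live on a 0-10 scale and are an affine, noisy readout of the
#' tracked threat signal: `clip(rating_gain * signal + noise, 0, 10)`
#' with Gaussian noise of SD `rating_noise_sd`.
#'
#' @param agent An [agent_params()].
#' @param signal Numeric signal value(s).
#' @param seed Optional integer seed.
#' @return Rating value(s) in `[0, 10]`.
#' @export
generate_rating <- function(agent, signal, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  raw <- agent$rating_gain * signal +
    stats::rnorm(length(signal), 0, agent$rating_noise_sd)
  pmin(pmax(raw, 0), 10)
}
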