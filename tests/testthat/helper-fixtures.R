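# Shared fixtures: all synthetic, built in code at test time.

uniform4 <- function() threat_schedule(0:3, rep(0.25, 4), "uniform-4")
certain4 <- function() threat_schedule(0:3, c(0, 0, 0, 1), "certain-4")

# a small cohort for structural tests (fast; not the study-scale default)
tiny_cohort <- function(seed = 42, tracker = "hazard", n = 8) {
  simulate_cohort(
    n_participants = n, pair = design_matched_pair(),
    population = agent_population(tracker = tracker),
    n_learning = 15, n_testing = 8,
    rating_every_learning = 5, rating_every_testing = 2,
    n_final_subset = n, n_choice_subset = n, seed = seed
  )
}

# exchangeable, tracker-blind null cohort: identical schedules, beta = 0,
# gain = 0, homogeneous participants (matches the independence assumptions
# of the tests being calibrated)
null_population <- function() {
  agent_population(intercept_mean = stats::qlogis(0.08), intercept_sd = 0,
                   slope_mean = 0, slope_sd = 0,
                   gain_mean = 0, gain_sd = 0,
                   rating_noise_sd = 2)
}

null_pair <- function() design_matched_pair(window_mass = 1)

null_cohort <- function(seed) {
  simulate_cohort(n_participants = 20, pair = null_pair(),
                  population = null_population(),
                  n_learning = 20, n_testing = 10,
                  n_final_subset = 20, n_choice_subset = 20, seed = seed)
}

# construct an agent_state directly from a known estimate
state_from <- function(schedule, shocks = 0L) {
  structure(list(estimate = schedule, shocks_received = shocks),
            class = "agent_state")
}

# hand-rolled testing records: one row per trial
make_testing_records <- function(pid, condition, time, outcome,
                                 rating = NA_real_, rating_time = NA_integer_,
                                 phase = "testing", shocks_so_far = 0L) {
  n <- max(length(pid), length(condition), length(time), length(outcome),
           length(rating), length(rating_time))
  data.frame(
    participant_id = rep_len(pid, n), condition = rep_len(condition, n),
    phase = rep_len(phase, n), trial_index = seq_len(n),
    outcome = rep_len(outcome, n), event_time_s = rep_len(as.integer(time), n),
    earnings_cents = rep_len(as.integer(time), n),
    shocks_so_far = rep_len(as.integer(shocks_so_far), n),
    rating = rep_len(rating, n), rating_time_s = rep_len(rating_time, n),
    stringsAsFactors = FALSE
  )
}
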