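#' Simulate a full learning-testing cohort
#'
#' Generates the complete synthetic dataset of the paradigm: each
#' participant learns both conditions' statistics from unavoidable shocks
#' (50 per condition by default, in a pseudo-randomised interleaved
#' order), then completes a testing phase in which persisting earns 1
#' cent per second and escaping forfeits further earnings but avoids the
#' shock. Fear/anxiety ratings are collected periodically during learning
#' and testing, each prompted at a recorded trial second. Subsets of
#' participants additionally experience one final, inescapable 30-s trial
#' per condition (rated), and answer a forced-choice question about which
#' condition felt more anxiogenic — answered with the condition whose
#' experienced ratings were higher on average (ties broken at random).
#'
#' The whole dataset is a deterministic function of `seed`.
#'
#' @param n_participants Cohort size (default 42).
#' @param pair A [design_matched_pair()] condition pair.
#' @param population An [agent_population()] describing the cohort.
#' @param n_learning Unavoidable learning shocks per condition.
#' @param n_testing Testing trials per condition (default 25).
#' @param rating_every_learning Rate a learning trial every this many
#'   trials per condition (0 disables).
#' @param rating_every_testing Same for testing trials.
#' @param n_final_subset Participants receiving the final inescapable
#'   trial per condition.
#' @param n_choice_subset Participants answering the forced choice.
#' @param reward_rate_cents_per_s Testing-phase earnings per second.
#' @param seed Integer seed; the single source of randomness.
#' @return An object of class `threat_cohort`: list with `records` (one
#'   `data.frame` of all trial records), `choices` (`participant_id`,
#'   `choice`), `agents` (drawn parameters, one row per participant) and
#'   the `pair` used.
#' @export
simulate_cohort <- function(n_participants = 42,
                            pair = design_matched_pair(),
                            population = agent_population(),
                            n_learning = 50,
                            n_testing = 25,
                            rating_every_learning = 10,
                            rating_every_testing = 5,
                            n_final_subset = 21,
                            n_choice_subset = 21,
                            reward_rate_cents_per_s = 1,
                            seed = NULL) {
  if (n_participants < 1 || n_learning < 1 || n_testing < 1) {
    th_error("threathazard_bad_agent", "cohort sizes must be positive")
  }
  if (!is.null(seed)) set.seed(seed)
  verify_pair(pair)  # validates both schedules and the shared grid
  conds <- c("early", "late")
  schedules <- list(early = pair$early, late = pair$late)
  grid <- pair$early$timepoints

  final_ids <- sort(sample(n_participants, min(n_final_subset, n_participants)))
  choice_ids <- sort(sample(n_participants, min(n_choice_subset, n_participants)))

  all_records <- vector("list", n_participants)
  agents_tab <- vector("list", n_participants)
  choices <- empty_choices()

  for (pid in seq_len(n_participants)) {
    agent <- draw_agent(pid, population)
    agents_tab[[pid]] <- data.frame(
      participant_id = pid, tracker = agent$tracker,
      escape_intercept = agent$escape_intercept,
      escape_slope = agent$escape_slope,
      rating_gain = agent$rating_gain,
      rating_noise_sd = agent$rating_noise_sd,
      smoothing = agent$smoothing, stringsAsFactors = FALSE
    )

    # ---- learning phase: interleaved unavoidable shocks ----
    learn <- list()
    states <- list()
    for (cond in conds) {
      learn[[cond]] <- simulate_learning(agent, schedules[[cond]],
                                         n_trials = n_learning,
                                         condition = cond)
    }
    order_lab <- sample(rep(conds, each = n_learning))
    lrec <- interleave_records(learn, order_lab)
    for (cond in conds) states[[cond]] <- learn[[cond]]$state

    # ratings on every k-th learning trial of each condition
    if (rating_every_learning > 0) {
      lrec <- add_ratings(lrec, agent, states, rating_every_learning)
    }

    # ---- testing phase ----
    trec <- list()
    for (cond in conds) {
      p_escape <- escape_prob_vector(agent, states[[cond]])
      sched <- schedules[[cond]]
      shock_t <- sample(grid, n_testing, replace = TRUE, prob = sched$pmf)
      escape_t <- r_first_success(p_escape, n_testing)
      esc <- !is.na(escape_t) & escape_t <= shock_t  # decision precedes shock
      ev <- ifelse(esc, escape_t, shock_t)
      rec <- empty_records(n_testing)
      rec$participant_id <- pid
      rec$condition <- cond
      rec$phase <- "testing"
      rec$trial_index <- seq_len(n_testing)
      rec$outcome <- ifelse(esc, "escape", "shock")
      rec$event_time_s <- as.integer(ev)
      rec$earnings_cents <- as.integer(round(reward_rate_cents_per_s * ev))
      rec$rating <- NA_real_
      rec$rating_time_s <- NA_integer_
      trec[[cond]] <- rec
    }
    order_lab <- sample(rep(conds, each = n_testing))
    trec <- interleave_records(lapply(trec, function(r) list(records = r)),
                               order_lab)
    if (rating_every_testing > 0) {
      trec <- add_ratings(trec, agent, states, rating_every_testing)
    }

    # ---- final inescapable trial per condition (subset) ----
    frec <- empty_records(0)
    if (pid %in% final_ids) {
      forder <- sample(conds)
      frec <- do.call(rbind, lapply(forder, function(cond) {
        st <- sample(grid, 1, prob = schedules[[cond]]$pmf)
        r <- empty_records(1)
        r$participant_id <- pid
        r$condition <- cond
        r$phase <- "final"
        r$trial_index <- 1L
        r$outcome <- "shock"
        r$event_time_s <- as.integer(st)
        r$earnings_cents <- 0L
        rt <- sample.int(st + 1L, 1L) - 1L
        sig <- escape_signal(states[[cond]], agent$tracker, rt)
        r$rating <- generate_rating(agent, sig)
        r$rating_time_s <- as.integer(rt)
        r
      }))
    }

    prec <- rbind(lrec, trec, frec)
    prec <- add_shock_counts(prec)
    all_records[[pid]] <- prec

    # ---- forced choice: condition with higher mean experienced rating ----
    if (pid %in% choice_ids) {
      rated <- prec[!is.na(prec$rating), ]
      m_e <- mean(rated$rating[rated$condition == "early"])
      m_l <- mean(rated$rating[rated$condition == "late"])
      choice <- if (is.na(m_e) || is.na(m_l) || m_e == m_l) {
        sample(conds, 1)
      } else if (m_e > m_l) "early" else "late"
      choices <- rbind(choices,
                       data.frame(participant_id = pid, choice = choice,
                                  stringsAsFactors = FALSE))
    }
  }

  structure(
    list(records = do.call(rbind, all_records),
         choices = choices,
         agents = do.call(rbind, agents_tab),
         pair = pair),
    class = "threat_cohort"
  )
}

empty_choices <- function() {
  data.frame(participant_id = integer(0), choice = character(0),
             stringsAsFactors = FALSE)
}

# merge per-condition record blocks into one pseudo-randomised sequence
interleave_records <- function(by_cond, order_lab) {
  recs <- lapply(names(by_cond), function(cond) {
    r <- by_cond[[cond]]$records
    r$trial_index <- which(order_lab == cond)
    r
  })
  out <- do.call(rbind, recs)
  out[order(out$trial_index), , drop = FALSE]
}

# rate every k-th trial of each condition within a phase block
add_ratings <- function(rec, agent, states, every_k) {
  for (cond in unique(rec$condition)) {
    idx <- which(rec$condition == cond)
    pick <- idx[seq_along(idx) %% every_k == 0]
    for (i in pick) {
      rt <- sample.int(rec$event_time_s[i] + 1L, 1L) - 1L
      sig <- escape_signal(states[[cond]], agent$tracker, rt)
      rec$rating[i] <- generate_rating(agent, sig)
      rec$rating_time_s[i] <- as.integer(rt)
    }
  }
  rec
}

# cumulative shocks received before each trial, in chronological order
add_shock_counts <- function(rec) {
  phase_rank <- match(rec$phase, c("learning", "testing", "final"))
  ord <- order(phase_rank, rec$trial_index)
  shocks <- cumsum(rec$outcome[ord] == "shock")
  rec$shocks_so_far[ord] <- c(0L, shocks[-length(shocks)])
  rec
}

#' @export
print.threat_cohort <- function(x, ...) {
  cat(sprintf(
    "<threat_cohort> %d participants, %d trial records (%d rated), %d forced choices\n",
    length(unique(x$records$participant_id)), nrow(x$records),
    sum(!is.na(x$records$rating)), nrow(x$choices)))
  invisible(x)
}

#' Read and write trial-record tables
#'
#' Trial records round-trip through a plain CSV with one row per trial
#' (`participant_id, condition, phase, trial_index, outcome,
#' event_time_s, earnings_cents, shocks_so_far, rating, rating_time_s`);
#' forced choices through a two-column CSV.
#'
#' @param records,choices Data frames as produced by [simulate_cohort()].
#' @param path File path.
#' @name records_io
NULL

#' @rdname records_io
#' @export
write_trials_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname records_io
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$rating <- as.numeric(df$rating)
  df$rating_time_s <- as.integer(df$rating_time_s)
  df
}

#' @rdname records_io
#' @export
write_choices_csv <- function(choices, path) {
  utils::write.csv(choices, path, row.names = FALSE)
  invisible(path)
}

#' @rdname records_io
#' @export
read_choices_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
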