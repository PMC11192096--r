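# t tests tolerant of zero-variance input: a constant zero difference is
# reported as t = 0, p = 1 rather than an error
safe_t_one <- function(d, mu = 0) {
  if (stats::sd(d) == 0) {
    t <- if (mean(d) == mu) 0 else sign(mean(d) - mu) * Inf
    return(list(statistic = t, parameter = length(d) - 1,
                p.value = if (is.finite(t)) 1 else 0))
  }
  stats::t.test(d, mu = mu)
}

safe_t_two <- function(x, y) {
  if (stats::sd(c(x - mean(x), y - mean(y))) == 0) {
    t <- if (mean(x) == mean(y)) 0 else sign(mean(x) - mean(y)) * Inf
    return(list(statistic = t, parameter = length(x) + length(y) - 2,
                p.value = if (is.finite(t)) 1 else 0))
  }
  stats::t.test(x, y, var.equal = TRUE)
}

#' Kaplan-Meier curve of escape behaviour
#'
#' Product-limit estimate of "survival in the trial" for testing-phase
#' records of one condition, where the event of interest is the decision
#' to escape and a delivered shock censors the escape time at its second.
#' With no censoring the estimate equals the empirical survival function
#' of the escape times.
#'
#' @param records Trial-record `data.frame` (only `phase == "testing"`
#'   rows are used).
#' @param condition Condition to estimate (`"early"` or `"late"`); `NULL`
#'   pools all testing records.
#' @return An object of class `survival_curve`: `data.frame` with
#'   `time`, `n_risk`, `n_event` (escapes), `n_censor` (shocks) and
#'   `survival`, one row per distinct observed time.
#' @export
kaplan_meier <- function(records, condition = NULL) {
  rec <- records[records$phase == "testing", ]
  if (!is.null(condition)) rec <- rec[rec$condition == condition, ]
  if (nrow(rec) == 0) {
    th_error("threathazard_no_records", "no testing-phase records")
  }
  tt <- rec$event_time_s
  ev <- rec$outcome == "escape"
  times <- sort(unique(tt))
  n_risk <- vapply(times, function(s) sum(tt >= s), integer(1))
  n_event <- vapply(times, function(s) sum(tt == s & ev), integer(1))
  n_censor <- vapply(times, function(s) sum(tt == s & !ev), integer(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(
    data.frame(time = times, n_risk = n_risk, n_event = n_event,
               n_censor = n_censor, survival = surv),
    class = c("survival_curve", "data.frame")
  )
}

#' Log-rank test of escape times between conditions
#'
#' Standard observed-vs-expected log-rank statistic (1 df) comparing
#' escape-time distributions of two record sets, with shocks treated as
#' independent right-censoring. The statistic is symmetric in the group
#' labels and exactly zero when a group is compared with itself.
#'
#' @param records_early,records_late Testing-phase record sets for the
#'   two groups (non-testing rows are dropped).
#' @return List with `chi2`, `df` (always 1), `p`, and the summed
#'   observed and expected escape counts for the first group (`o1`, `e1`).
#' @export
log_rank <- function(records_early, records_late) {
  g1 <- records_early[records_early$phase == "testing", ]
  g2 <- records_late[records_late$phase == "testing", ]
  if (nrow(g1) == 0 || nrow(g2) == 0 ||
      !any(g1$outcome == "escape") || !any(g2$outcome == "escape")) {
    th_error("threathazard_no_records",
             "log-rank needs escape events in both groups")
  }
  t1 <- g1$event_time_s; e1 <- g1$outcome == "escape"
  t2 <- g2$event_time_s; e2 <- g2$outcome == "escape"
  times <- sort(unique(c(t1[e1], t2[e2])))
  o1 <- exp1 <- v <- 0
  for (s in times) {
    n1 <- sum(t1 >= s); n2 <- sum(t2 >= s); n <- n1 + n2
    d1 <- sum(t1 == s & e1); d <- d1 + sum(t2 == s & e2)
    o1 <- o1 + d1
    exp1 <- exp1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (v > 0) (o1 - exp1)^2 / v else 0
  list(chi2 = chi2, df = 1,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       o1 = o1, e1 = exp1)
}

#' Epoch-wise avoidance comparison
#'
#' For each epoch and participant, the fraction of that participant's
#' testing trials *entering* the epoch (no escape or shock before its
#' first second) that end in escape within it, computed per condition;
#' conditions are then compared per epoch with an independent-samples
#' Student t-test across participants. The default epochs tile the
#' probability-matched window, where any escape-rate difference isolates
#' the hazard-rate manipulation.
#'
#' @param records Trial-record `data.frame`.
#' @param epochs List of inclusive `[start, end]` second pairs.
#' @return A `data.frame` of class `epoch_stats`, one row per epoch:
#'   bounds, per-condition mean escape proportions, participant counts,
#'   `t`, `df`, `p`.
#' @export
epoch_avoidance <- function(records,
                            epochs = list(c(6, 10), c(11, 15),
                                          c(16, 20), c(21, 25))) {
  rec <- records[records$phase == "testing", ]
  if (nrow(rec) == 0) {
    th_error("threathazard_no_records", "no testing-phase records")
  }
  rows <- lapply(epochs, function(ep) {
    a <- ep[1]; b <- ep[2]
    prop <- function(cond) {
      rc <- rec[rec$condition == cond & rec$event_time_s >= a, ]
      if (nrow(rc) == 0) {
        th_error("threathazard_no_records",
                 sprintf("no %s trials enter epoch [%d, %d]", cond, a, b))
      }
      esc <- rc$outcome == "escape" & rc$event_time_s <= b
      tapply(esc, rc$participant_id, mean)
    }
    pe <- prop("early"); pl <- prop("late")
    tt <- safe_t_two(pe, pl)
    data.frame(epoch_start = a, epoch_end = b,
               mean_early = mean(pe), mean_late = mean(pl),
               n_early = length(pe), n_late = length(pl),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  structure(do.call(rbind, rows), class = c("epoch_stats", "data.frame"))
}

#' Testing-phase earnings comparison
#'
#' Mean testing earnings per participant and condition, their group
#' means, the percentage shortfall of the early condition relative to the
#' late condition (`100 * (late - early) / late`), and a paired-samples
#' t-test across participants.
#'
#' @param records Trial-record `data.frame`.
#' @return List with `mean_early`, `mean_late` (cents), `pct_difference`,
#'   `t`, `df`, `p`, and the per-participant means (`by_participant`).
#' @export
earnings_comparison <- function(records) {
  rec <- records[records$phase == "testing", ]
  by_pc <- tapply(rec$earnings_cents,
                  list(rec$participant_id, rec$condition), mean)
  if (anyNA(by_pc) || !all(c("early", "late") %in% colnames(by_pc))) {
    th_error("threathazard_no_records",
             "every participant needs testing trials in both conditions")
  }
  m_e <- mean(by_pc[, "early"]); m_l <- mean(by_pc[, "late"])
  tt <- safe_t_one(by_pc[, "early"] - by_pc[, "late"])
  list(mean_early = m_e, mean_late = m_l,
       pct_difference = 100 * (m_l - m_e) / m_l,
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       by_participant = by_pc)
}

#' Rating-signal association (two-stage summary-statistics model)
#'
#' Tests whether in-trial fear/anxiety ratings track a threat statistic
#' of the *true* condition schedules. Stage 1 fits, per participant, an
#' ordinary least-squares regression of rating on the chosen regressor
#' evaluated at each rating's recorded second — the true schedule's
#' hazard rate or its marginal probability — optionally adjusted for the
#' cumulative number of shocks received before the trial. Stage 2 tests
#' the per-participant slopes against zero with a one-sample t-test.
#' Participants with fewer than `min_obs` usable rated observations are
#' dropped with a warning.
#'
#' @param records Trial-record `data.frame` containing rated rows.
#' @param pair The true `condition_pair` (source of the regressor).
#' @param regressor `"hazard"` or `"probability"`.
#' @param adjust_shocks Include `shocks_so_far` as a per-participant
#'   covariate (default `TRUE`).
#' @param min_obs Minimum rated observations per participant.
#' @return An object of class `association_result`: `slopes` (named by
#'   participant), `t`, `df`, `p`, `mean_slope`, `regressor`,
#'   `n_subjects`, `n_dropped`.
#' @export
rating_association <- function(records, pair,
                               regressor = c("hazard", "probability"),
                               adjust_shocks = TRUE, min_obs = 3) {
  regressor <- match.arg(regressor)
  rated <- records[!is.na(records$rating) & !is.na(records$rating_time_s), ]
  if (nrow(rated) == 0) {
    th_error("threathazard_no_records", "no rated observations")
  }
  grid <- pair$early$timepoints
  xval <- function(cond, t) {
    sched <- if (cond == "early") pair$early else pair$late
    if (regressor == "probability") {
      sched$pmf[match(t, grid)]
    } else {
      hazard_on_grid(sched, grid)[match(t, grid)]
    }
  }
  rated$x <- mapply(xval, rated$condition, rated$rating_time_s)
  rated <- rated[is.finite(rated$x), ]

  slopes <- c()
  dropped <- 0L
  for (pid in sort(unique(rated$participant_id))) {
    d <- rated[rated$participant_id == pid, ]
    if (nrow(d) < min_obs || stats::var(d$x) == 0) {
      dropped <- dropped + 1L
      next
    }
    fit <- if (adjust_shocks && stats::var(d$shocks_so_far) > 0) {
      stats::lm(rating ~ x + shocks_so_far, data = d)
    } else {
      stats::lm(rating ~ x, data = d)
    }
    b <- unname(stats::coef(fit)["x"])
    if (is.finite(b)) {
      slopes <- c(slopes, stats::setNames(b, pid))
    } else {
      dropped <- dropped + 1L
    }
  }
  if (dropped > 0) {
    warning(sprintf("rating_association: dropped %d participant(s) with < %d usable rated observations",
                    dropped, min_obs))
  }
  if (length(slopes) < 2) {
    th_error("threathazard_no_records",
             "need at least 2 participants with estimable slopes")
  }
  tt <- safe_t_one(slopes)
  structure(
    list(slopes = slopes, mean_slope = mean(slopes),
         t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
         regressor = regressor, n_subjects = length(slopes),
         n_dropped = dropped),
    class = "association_result"
  )
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(
    "<association_result> rating ~ %s: mean slope %.3f, t(%d) = %.2f, p = %.3g (n = %d, dropped %d)\n",
    x$regressor, x$mean_slope, x$df, x$t, x$p, x$n_subjects, x$n_dropped))
  invisible(x)
}

#' Exact two-sided binomial forced-choice test
#'
#' Tests whether the proportion of participants naming the early-threat
#' condition as more anxiogenic departs from chance (0.5), using the
#' exact binomial distribution with the doubled-smaller-tail convention
#' `p = min(1, 2 * min(P(X <= k), P(X >= k)))`.
#'
#' @param choices `data.frame` with one `choice` (`"early"`/`"late"`) per
#'   participant, or a character vector of choices.
#' @return List with `k` (early choices), `n`, and `p`.
#' @export
forced_choice_test <- function(choices) {
  ch <- if (is.data.frame(choices)) choices$choice else choices
  n <- length(ch)
  if (n == 0) th_error("threathazard_no_records", "no forced choices")
  k <- sum(ch == "early")
  lower <- stats::pbinom(k, n, 0.5)
  upper <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  list(k = k, n = n, p = min(1, 2 * min(lower, upper)))
}

#' Wilcoxon rank-sum with midranks and small-sample exact permutation p
#'
#' Mann-Whitney U for two samples using midranks for ties. When the
#' combined sample size is at most `exact_max` the two-sided p-value is
#' computed by complete enumeration of group assignments (distance of
#' the rank sum from its permutation mean); otherwise a tie-corrected
#' normal approximation is used.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest combined n for exact enumeration (default 12).
#' @return List with `U` (for the `x` group), `p`, and `method`.
#' @export
rank_sum_test <- function(x, y, exact_max = 12) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 == 0 || n2 == 0) {
    th_error("threathazard_no_records", "both samples must be non-empty")
  }
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  u <- w - n1 * (n1 + 1) / 2
  mu_w <- n1 * (n + 1) / 2
  if (n <= exact_max) {
    combos <- utils::combn(n, n1)
    ws <- colSums(matrix(r[combos], nrow = n1))
    p <- mean(abs(ws - mu_w) >= abs(w - mu_w) - 1e-12)
    method <- "exact"
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    p <- if (sigma2 <= 0) 1 else
      2 * stats::pnorm(-abs(w - mu_w) / sqrt(sigma2))
    method <- "normal"
  }
  list(U = u, p = min(1, p), method = method)
}

#' Final-trial fear/anxiety comparison
#'
#' Compares early- vs late-condition fear/anxiety ratings from the final
#' inescapable trials with a Wilcoxon rank-sum test (midranks; exact
#' permutation p for combined n <= 12), then repeats the comparison on
#' ratings residualised for the cumulative number of shocks received
#' (pooled OLS of rating on shock count), so a difference cannot be
#' carried by shock exposure alone.
#'
#' @param records Trial-record `data.frame` with `phase == "final"` rows.
#' @return List with `U`, `p`, the residualised `U_resid`, `p_resid`,
#'   `mean_diff_resid` (early minus late mean residual) and sample sizes.
#' @export
final_trial_comparison <- function(records) {
  fin <- records[records$phase == "final" & !is.na(records$rating), ]
  if (!all(c("early", "late") %in% fin$condition)) {
    th_error("threathazard_no_records",
             "final-trial ratings required for both conditions")
  }
  xe <- fin$rating[fin$condition == "early"]
  xl <- fin$rating[fin$condition == "late"]
  raw <- rank_sum_test(xe, xl)
  res <- stats::resid(stats::lm(rating ~ shocks_so_far, data = fin))
  re <- res[fin$condition == "early"]
  rl <- res[fin$condition == "late"]
  adj <- rank_sum_test(re, rl)
  list(U = raw$U, p = raw$p,
       U_resid = adj$U, p_resid = adj$p,
       mean_diff_resid = mean(re) - mean(rl),
       n_early = length(xe), n_late = length(xl))
}

#' Run the full avoidance and fear/anxiety analysis battery
#'
#' Applies every analysis to a cohort's records: per-condition
#' Kaplan-Meier escape curves, the log-rank test, epoch-wise avoidance in
#' the probability-matched window, the earnings comparison, the
#' rating-hazard association (with a probability-regressor counterpart),
#' the forced-choice binomial test, and the final-trial rank-sum
#' comparison.
#'
#' @param cohort A `threat_cohort` from [simulate_cohort()], or a list
#'   with `records`, `choices` and `pair`.
#' @return An object of class `avoidance_report`: a named list with
#'   elements `km`, `log_rank`, `epochs`, `earnings`, `rating_hazard`,
#'   `forced_choice`, `final_trial` (plus `rating_probability`).
#' @export
analyze_cohort <- function(cohort) {
  rec <- cohort$records
  early <- rec[rec$condition == "early", ]
  late <- rec[rec$condition == "late", ]
  rep <- list(
    km = list(early = kaplan_meier(rec, "early"),
              late = kaplan_meier(rec, "late")),
    log_rank = log_rank(early, late),
    epochs = epoch_avoidance(rec),
    earnings = earnings_comparison(rec),
    rating_hazard = rating_association(rec, cohort$pair, "hazard"),
    rating_probability = rating_association(rec, cohort$pair, "probability"),
    forced_choice = forced_choice_test(cohort$choices),
    final_trial = final_trial_comparison(rec)
  )
  structure(rep, class = "avoidance_report")
}

#' @export
print.avoidance_report <- function(x, ...) {
  cat("<avoidance_report>\n")
  cat(sprintf("  log-rank: chi2 = %.2f, p = %.3g\n", x$log_rank$chi2, x$log_rank$p))
  ep <- x$epochs
  for (i in seq_len(nrow(ep))) {
    cat(sprintf("  epoch %2d-%2ds: escape %.3f vs %.3f, t = %.2f, p = %.3g\n",
                ep$epoch_start[i], ep$epoch_end[i], ep$mean_early[i],
                ep$mean_late[i], ep$t[i], ep$p[i]))
  }
  cat(sprintf("  earnings: early %.1f vs late %.1f cents (%.1f%% less), t = %.2f, p = %.3g\n",
              x$earnings$mean_early, x$earnings$mean_late,
              x$earnings$pct_difference, x$earnings$t, x$earnings$p))
  cat(sprintf("  rating ~ hazard: mean slope %.2f, t = %.2f, p = %.3g\n",
              x$rating_hazard$mean_slope, x$rating_hazard$t, x$rating_hazard$p))
  cat(sprintf("  forced choice: %d/%d early, p = %.3g\n",
              x$forced_choice$k, x$forced_choice$n, x$forced_choice$p))
  cat(sprintf("  final trial: U = %.1f, p = %.3g (residualised p = %.3g)\n",
              x$final_trial$U, x$final_trial$p, x$final_trial$p_resid))
  invisible(x)
}
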