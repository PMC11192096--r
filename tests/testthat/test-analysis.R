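test_that("Kaplan-Meier matches hand computation and the empirical survival", {
  rec <- make_testing_records(1, "early", c(1, 2), "escape")
  km <- kaplan_meier(rec)
  expect_equal(km$survival, c(.5, 0))

  # all shocked: survival stays at 1, censoring recorded
  rec2 <- make_testing_records(1, "early", c(3, 5, 9), "shock")
  km2 <- kaplan_meier(rec2)
  expect_true(all(km2$survival == 1))
  expect_equal(sum(km2$n_censor), 3)

  # without censoring the product-limit equals the empirical survival
  set.seed(21)
  times <- sample(0:29, 40, replace = TRUE)
  rec3 <- make_testing_records(1, "early", times, "escape")
  km3 <- kaplan_meier(rec3)
  emp <- vapply(km3$time, function(s) mean(times > s), numeric(1))
  expect_equal(km3$survival, emp, tolerance = 1e-12)

  expect_error(kaplan_meier(make_testing_records(1, "early", 1, "escape",
                                                 phase = "learning")),
               class = "threathazard_no_records")
})

test_that("Kaplan-Meier agrees with the survival package under censoring", {
  skip_if_not_installed("survival")
  set.seed(22)
  times <- sample(0:29, 60, replace = TRUE)
  status <- sample(c(0, 1), 60, replace = TRUE)
  rec <- make_testing_records(1, "early", times,
                              ifelse(status == 1, "escape", "shock"))
  km <- kaplan_meier(rec)
  sf <- survival::survfit(survival::Surv(times, status) ~ 1)
  ours <- km$survival[match(sf$time, km$time)]
  expect_equal(ours, sf$surv, tolerance = 1e-12)
})

test_that("log-rank is zero on identical groups and symmetric in labels", {
  set.seed(23)
  rec <- make_testing_records(1, "early", sample(0:29, 30, TRUE),
                              sample(c("escape", "shock"), 30, TRUE))
  lr <- log_rank(rec, rec)
  expect_equal(lr$chi2, 0)
  expect_equal(lr$p, 1)

  rec2 <- make_testing_records(1, "late", sample(0:29, 30, TRUE),
                               sample(c("escape", "shock"), 30, TRUE))
  expect_equal(log_rank(rec, rec2)$chi2, log_rank(rec2, rec)$chi2,
               tolerance = 1e-12)
})

test_that("log-rank detects complete separation of escape times", {
  e <- make_testing_records(1, "early", rep(1, 20), "escape")
  l <- make_testing_records(1, "late", rep(29, 20), "escape")
  lr <- log_rank(e, l)
  # independent oracle: direct O-E bookkeeping on the two event times
  # t=1: n1=20, n2=20, d=20 (all from group 1); t=29: only group 2 at risk
  e1 <- 20 * 20 / 40
  v1 <- 20 * (20 / 40) * (20 / 40) * (40 - 20) / (40 - 1)
  expect_equal(lr$chi2, (20 - e1)^2 / v1, tolerance = 1e-12)
  expect_lt(lr$p, .005)
  expect_error(log_rank(e, make_testing_records(1, "late", rep(5, 4), "shock")),
               class = "threathazard_no_records")
})

test_that("log-rank agrees with survival::survdiff on censored data", {
  skip_if_not_installed("survival")
  set.seed(24)
  t1 <- sample(0:29, 50, TRUE); s1 <- sample(c(0, 1), 50, TRUE, prob = c(.3, .7))
  t2 <- sample(3:29, 50, TRUE); s2 <- sample(c(0, 1), 50, TRUE, prob = c(.5, .5))
  r1 <- make_testing_records(1, "early", t1, ifelse(s1 == 1, "escape", "shock"))
  r2 <- make_testing_records(1, "late", t2, ifelse(s2 == 1, "escape", "shock"))
  sd <- survival::survdiff(
    survival::Surv(c(t1, t2), c(s1, s2)) ~ rep(1:2, each = 50))
  expect_equal(log_rank(r1, r2)$chi2, sd$chisq, tolerance = 1e-9)
})

test_that("epoch avoidance computes escape-given-entry per participant", {
  # 3 participants, all escape at t=7 in early; late escapes at t=27
  e <- make_testing_records(rep(1:3, each = 4), "early", 7, "escape")
  l <- make_testing_records(rep(1:3, each = 4), "late", 27, "escape")
  ep <- epoch_avoidance(rbind(e, l), epochs = list(c(6, 10)))
  expect_equal(ep$mean_early, 1)
  expect_equal(ep$mean_late, 0)  # late trials enter but escape later

  # identical behaviour in both conditions: t = 0, p = 1
  l2 <- e; l2$condition <- "late"
  ep2 <- epoch_avoidance(rbind(e, l2), epochs = list(c(6, 10)))
  expect_equal(ep2$t, 0)
  expect_equal(ep2$p, 1)

  # trials ending before the epoch never enter it
  early_only <- make_testing_records(1:4, "early", 2, "shock")
  expect_error(epoch_avoidance(rbind(early_only,
                                     make_testing_records(1:4, "late", 20, "escape")),
                               epochs = list(c(6, 10))),
               class = "threathazard_no_records")
})

test_that("earnings comparison handles identical and extreme cohorts", {
  e <- make_testing_records(rep(1:4, each = 3), "early", 10, "escape")
  l <- make_testing_records(rep(1:4, each = 3), "late", 10, "escape")
  res <- earnings_comparison(rbind(e, l))
  expect_equal(res$pct_difference, 0)
  expect_equal(res$t, 0)

  e0 <- make_testing_records(rep(1:4, each = 3), "early", 0, "shock")
  l10 <- make_testing_records(rep(1:4, each = 3), "late", 10, "escape")
  res2 <- earnings_comparison(rbind(e0, l10))
  expect_equal(res2$pct_difference, 100)

  # a participant missing one condition is an error
  bad <- rbind(e, l[l$participant_id != 2, ])
  expect_error(earnings_comparison(bad), class = "threathazard_no_records")
})

test_that("forced-choice binomial matches the exact tail-sum oracle", {
  res <- forced_choice_test(c(rep("early", 19), rep("late", 2)))
  oracle <- 2 * (choose(21, 19) + choose(21, 20) + choose(21, 21)) / 2^21
  expect_equal(res$p, oracle, tolerance = 1e-15)
  expect_lt(res$p, .001)
  expect_equal(res$k, 19)

  expect_equal(forced_choice_test(rep(c("early", "late"), 10))$p, 1)
  expect_equal(forced_choice_test(rep("early", 21))$p, 2 * 2^-21,
               tolerance = 1e-15)
  expect_error(forced_choice_test(character(0)),
               class = "threathazard_no_records")
})

test_that("rank-sum test matches exact enumeration and wilcox.test", {
  # identical samples: no evidence either way
  expect_equal(rank_sum_test(1:4, 1:4)$p, 1)

  # complete separation, n = 5 each: only the two extreme assignments
  rs <- rank_sum_test(6:10, 1:5)
  expect_equal(rs$U, 25)
  expect_equal(rs$p, 2 / choose(10, 5), tolerance = 1e-12)

  # tie-free small samples agree with wilcox.test's exact p
  set.seed(25)
  for (i in 1:10) {
    x <- stats::rnorm(5); y <- stats::rnorm(6)
    ours <- rank_sum_test(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }

  # independent enumeration oracle with ties (midranks)
  x <- c(1, 2, 2, 5); y <- c(2, 3, 4)
  ours <- rank_sum_test(x, y)
  r <- rank(c(x, y))
  combos <- utils::combn(7, 4)
  ws <- apply(combos, 2, function(ix) sum(r[ix]))
  mu <- 4 * 8 / 2
  oracle <- mean(abs(ws - mu) >= abs(sum(r[1:4]) - mu) - 1e-12)
  expect_equal(ours$p, oracle, tolerance = 1e-12)
})

test_that("rating association recovers a noiseless linear signal exactly", {
  pair <- design_matched_pair()
  h <- hazard_rate(pair$early)
  gain <- 7
  recs <- do.call(rbind, lapply(1:6, function(pid) {
    tp <- c(0, 3, 7, 11, 15, 19, 23)
    make_testing_records(pid, "early", 25, "escape",
                         rating = gain * h$hazard[match(tp, h$timepoints)],
                         rating_time = tp)
  }))
  res <- rating_association(recs, pair, "hazard", adjust_shocks = FALSE)
  expect_equal(unname(res$slopes), rep(gain, 6), tolerance = 1e-9)
  expect_lt(res$p, 1e-10)

  # participants with too few rated observations are dropped with a warning
  thin <- recs[!(recs$participant_id == 6 & recs$trial_index > 2), ]
  expect_warning(res2 <- rating_association(thin, pair, "hazard",
                                            adjust_shocks = FALSE),
                 "dropped 1")
  expect_equal(res2$n_subjects, 5)
})

test_that("hazard-driven ratings are better explained by hazard than probability", {
  co <- simulate_cohort(n_participants = 16, pair = design_matched_pair(),
                        population = agent_population(),
                        n_learning = 30, n_testing = 15,
                        rating_every_testing = 2, seed = 26)
  rh <- suppressWarnings(rating_association(co$records, co$pair, "hazard"))
  rp <- suppressWarnings(rating_association(co$records, co$pair, "probability"))
  expect_gt(abs(rh$t), abs(rp$t))
  expect_gt(rh$mean_slope, 0)
})

test_that("final-trial comparison is null for identical ratings and exact for separation", {
  mk <- function(r_e, r_l) {
    n <- length(r_e)
    rbind(
      make_testing_records(1:n, "early", 29, "shock", rating = r_e,
                           rating_time = 10L, phase = "final",
                           shocks_so_far = seq_len(n) + 50L),
      make_testing_records(1:n, "late", 29, "shock", rating = r_l,
                           rating_time = 10L, phase = "final",
                           shocks_so_far = seq_len(n) + 30L)
    )
  }
  same <- mk(c(1, 4, 6, 8, 2), c(1, 4, 6, 8, 2))
  expect_equal(final_trial_comparison(same)$p, 1)

  sep <- mk(c(6, 7, 8, 9, 10), c(1, 2, 3, 4, 5))
  res <- final_trial_comparison(sep)
  expect_equal(res$U, 25)
  expect_equal(res$p, 2 / choose(10, 5), tolerance = 1e-12)
  expect_error(final_trial_comparison(same[same$condition == "early", ]),
               class = "threathazard_no_records")
})

test_that("the full battery runs and reports every block", {
  co <- tiny_cohort(seed = 27)
  rep <- suppressWarnings(analyze_cohort(co))
  expect_named(rep, c("km", "log_rank", "epochs", "earnings", "rating_hazard",
                      "rating_probability", "forced_choice", "final_trial"))
  expect_s3_class(rep$km$early, "survival_curve")
  expect_equal(nrow(rep$epochs), 4)
  expect_output(print(rep), "log-rank")
})
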