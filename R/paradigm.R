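#' Certain countdown schedule
#'
#' The classic certain-threat countdown: the shock arrives at the final
#' second with probability 1. Its hazard is 0 everywhere except the last
#' timepoint, and its cumulative hazard is exactly 1 (e.g. for four
#' steps, 0 + 0 + 0 + 1 = 1).
#'
#' @param length_s Trial length in whole seconds (>= 1).
#' @return A `threat_schedule` with a point mass at `length_s - 1`.
#' @export
make_certain_countdown <- function(length_s) {
  if (length(length_s) != 1 || length_s < 1) {
    th_error("threathazard_bad_length", "length_s must be a positive integer")
  }
  length_s <- as.integer(length_s)
  threat_schedule(seq_len(length_s) - 1L,
                  c(rep(0, length_s - 1L), 1),
                  sprintf("certain-%d", length_s))
}

#' Uniform uncertain countdown schedule
#'
#' An uncertain countdown with an equal chance of shock at every second.
#' Its hazard rises over the trial (for four steps: .25, 1/3, .5, 1) and
#' its cumulative hazard exceeds 1 whenever `length_s >= 2`.
#'
#' @inheritParams make_certain_countdown
#' @return A `threat_schedule` with pmf `1/length_s` everywhere.
#' @export
make_uniform_uncertain <- function(length_s) {
  if (length(length_s) != 1 || length_s < 1) {
    th_error("threathazard_bad_length", "length_s must be a positive integer")
  }
  length_s <- as.integer(length_s)
  threat_schedule(seq_len(length_s) - 1L,
                  rep(1 / length_s, length_s),
                  sprintf("uniform-%d", length_s))
}

#' Predictable/unpredictable block schedules (NPU-style)
#'
#' Fear/anxiety paradigms that contrast predictable- and
#' unpredictable-shock blocks confound the contrast with hazard dynamics:
#' the predictable cue is a certain countdown (cumulative hazard 1), while
#' shock timing in the unpredictable block is uniform over the block, so
#' its cumulative hazard exceeds 1 for any block of two or more seconds.
#'
#' @param cue_len_s Predictable-cue length in seconds (shock at cue end).
#' @param block_len_s Unpredictable-block length in seconds (must be at
#'   least `cue_len_s`).
#' @return A list with `predictable` and `unpredictable` schedules.
#' @export
make_npu_schedules <- function(cue_len_s, block_len_s) {
  if (length(cue_len_s) != 1 || length(block_len_s) != 1 ||
      cue_len_s < 1 || block_len_s < cue_len_s) {
    th_error("threathazard_bad_length",
             "need 1 <= cue_len_s <= block_len_s")
  }
  list(predictable = make_certain_countdown(cue_len_s),
       unpredictable = make_uniform_uncertain(block_len_s))
}

#' Construct a probability-matched, hazard-dissociated condition pair
#'
#' Builds the paradigm's central design object: two 30-second threat
#' schedules ("early" and "late") whose marginal shock probability
#' P(Threat) is identical at every second of a matched window, while the
#' hazard rate in that window is strictly higher in the early condition.
#' The dissociation is purely algebraic: both conditions carry the same
#' pmf inside the window, but the early condition has already spent its
#' off-window mass before the window, so less probability survives into
#' it and the conditional shock probability (the hazard) is inflated at
#' every matched second.
#'
#' The off-window mass `1 - window_mass` is spread uniformly over the
#' seconds before the window (early condition) or after it (late
#' condition). Inside the window both conditions share an
#' exponentially-tilted pmf `p(t) proportional to exp(-window_decay * (t -
#' start))`; `window_decay = 0` gives a uniform window. The defaults
#' (`window_mass = 0.62`, `window_decay = 0.053`) put the expected shock
#' time near 9.5 s in the early condition and 19 s in the late condition.
#'
#' @param trial_length_s Trial length in seconds (default 30).
#' @param matched_window Inclusive `[start, end]` of the matched window in
#'   trial seconds (default `c(6, 25)`, the middle 20 s of a 30-s trial).
#' @param window_mass Total probability placed inside the matched window
#'   (shared by both conditions). `window_mass = 1` yields two identical
#'   schedules, which is the degenerate no-dissociation design.
#' @param window_decay Exponential tilt of the shared window pmf per
#'   second; 0 means uniform.
#' @return An object of class `condition_pair`: list with `early`,
#'   `late`, `matched_window`, `trial_length_s`.
#' @seealso [verify_pair()]
#' @export
design_matched_pair <- function(trial_length_s = 30,
                                matched_window = c(6, 25),
                                window_mass = 0.62,
                                window_decay = 0.053) {
  L <- as.integer(trial_length_s)
  ws <- as.integer(matched_window[1])
  we <- as.integer(matched_window[2])
  if (ws < 0 || we >= L || ws > we) {
    th_error("threathazard_bad_window", "matched window must lie inside the trial")
  }
  if (window_mass < 0 || window_mass > 1) {
    th_error("threathazard_bad_mass", "window_mass must lie in [0, 1]")
  }
  off <- 1 - window_mass
  if (off > 0 && (ws < 1 || we > L - 2)) {
    th_error("threathazard_bad_mass",
             "off-window mass needs non-empty regions before and after the window")
  }
  wts <- exp(-window_decay * (0:(we - ws)))
  win <- window_mass * wts / sum(wts)

  early <- numeric(L)
  late <- numeric(L)
  if (off > 0) {
    early[seq_len(ws)] <- off / ws                 # seconds 0 .. ws-1
    late[(we + 2):L] <- off / (L - 1 - we)         # seconds we+1 .. L-1
  }
  idx <- (ws + 1):(we + 1)
  early[idx] <- win
  late[idx] <- win

  structure(
    list(early = threat_schedule(0:(L - 1), early, "early-threat"),
         late = threat_schedule(0:(L - 1), late, "late-threat"),
         matched_window = c(ws, we),
         trial_length_s = L),
    class = "condition_pair"
  )
}

#' @export
print.condition_pair <- function(x, ...) {
  cat(sprintf(
    "<condition_pair> %d-s trials, matched window [%d, %d]\n  E[shock time] early %.2f s, late %.2f s\n",
    x$trial_length_s, x$matched_window[1], x$matched_window[2],
    expected_shock_time(x$early), expected_shock_time(x$late)))
  invisible(x)
}

# hazard aligned to a full per-second grid; NA beyond the support truncation
hazard_on_grid <- function(schedule, grid) {
  prof <- hazard_rate(schedule)
  out <- rep(NA_real_, length(grid))
  m <- match(prof$timepoints, grid)
  out[m[!is.na(m)]] <- prof$hazard[!is.na(m)]
  out
}

#' Verify a condition pair's design contract
#'
#' Checks each design invariant of a [design_matched_pair()]-style pair
#' independently: (i) identical pmf at every matched-window second
#' (`matched_ok`), (ii) strictly higher early hazard at every
#' matched-window second (`dominance_ok`), and (iii) higher early
#' cumulative hazard over the full trial (`cumulative_ok`). Hazard that is
#' undefined at a window second (schedule support exhausted) counts
#' against dominance.
#'
#' @param pair A `condition_pair`.
#' @param tol Absolute tolerance for the pmf-matching check.
#' @return An object of class `design_report`: `matched_ok`,
#'   `dominance_ok`, `cumulative_ok`, `expected_times` (early, late, in
#'   seconds), and `hazard_gap`, the per-second early-minus-late hazard
#'   over the matched window.
#' @export
verify_pair <- function(pair, tol = 1e-9) {
  early <- validate_schedule(pair$early)
  late <- validate_schedule(pair$late)
  if (!identical(early$timepoints, late$timepoints)) {
    th_error("threathazard_bad_window", "conditions must share one trial grid")
  }
  ws <- pair$matched_window[1]
  we <- pair$matched_window[2]
  in_win <- early$timepoints >= ws & early$timepoints <= we
  if (!any(in_win)) {
    th_error("threathazard_bad_window", "matched window contains no timepoints")
  }
  matched_ok <- all(abs(early$pmf[in_win] - late$pmf[in_win]) <= tol)
  h_e <- hazard_on_grid(early, early$timepoints)[in_win]
  h_l <- hazard_on_grid(late, late$timepoints)[in_win]
  gap <- h_e - h_l
  dominance_ok <- !anyNA(gap) && all(gap > 0)
  cumulative_ok <- cumulative_hazard(early) > cumulative_hazard(late)
  structure(
    list(matched_ok = matched_ok,
         dominance_ok = dominance_ok,
         cumulative_ok = cumulative_ok,
         expected_times = c(early = expected_shock_time(early),
                            late = expected_shock_time(late)),
         hazard_gap = stats::setNames(gap, early$timepoints[in_win])),
    class = "design_report"
  )
}

#' @export
print.design_report <- function(x, ...) {
  cat("<design_report>\n")
  cat(sprintf("  matched pmf in window : %s\n", x$matched_ok))
  cat(sprintf("  early hazard dominance: %s\n", x$dominance_ok))
  cat(sprintf("  early cum. hazard >   : %s\n", x$cumulative_ok))
  cat(sprintf("  E[shock time] early %.2f s, late %.2f s\n",
              x$expected_times["early"], x$expected_times["late"]))
  cat(sprintf("  window hazard gap: min %.4f, max %.4f\n",
              min(x$hazard_gap), max(x$hazard_gap)))
  invisible(x)
}
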