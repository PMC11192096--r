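#' Discrete threat schedules
#'
#' A threat schedule is the generative object of a threat-anticipation
#' trial: a probability mass function over the discrete timepoints (whole
#' seconds, 0-based) at which the aversive event ("shock") can occur.
#' Because every learning-phase trial ends in shock, a schedule is a
#' proper pmf: non-negative mass summing to one.
#'
#' @param timepoints Integer vector of trial seconds (0-based, strictly
#'   increasing). Timepoint `t` means "during second `t`".
#' @param pmf Numeric vector of shock probabilities, one per timepoint;
#'   non-negative, summing to 1 within `1e-9`.
#' @param label Free-text label for the schedule.
#' @return An object of class `threat_schedule` with fields `timepoints`,
#'   `pmf` and `label`.
#' @examples
#' threat_schedule(0:3, rep(0.25, 4), "uniform-4")
#' @seealso [hazard_rate()], [cumulative_hazard()], [validate_schedule()]
#' @export
threat_schedule <- function(timepoints, pmf, label = "") {
  x <- structure(
    list(timepoints = as.integer(timepoints), pmf = as.numeric(pmf),
         label = as.character(label)[1]),
    class = "threat_schedule"
  )
  validate_schedule(x)
}

th_error <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "threathazard_validation"),
                      call = call))
}

#' Validate a threat schedule
#'
#' Checks the schedule invariants and returns the schedule unchanged when
#' they hold. Each violation raises a distinct, named condition so callers
#' can discriminate failure modes:
#' \describe{
#'   \item{`threathazard_negative_mass`}{some pmf value is negative}
#'   \item{`threathazard_mass_sum`}{pmf does not sum to 1 within `tol`}
#'   \item{`threathazard_unsorted_timepoints`}{timepoints not strictly
#'     increasing, or lengths differ}
#' }
#' All three also inherit from `threathazard_validation`.
#'
#' @param schedule A `threat_schedule` (or a bare list with the same fields).
#' @param tol Absolute tolerance for the pmf normalisation check.
#' @return `schedule`, invisibly unchanged, if valid.
#' @export
validate_schedule <- function(schedule, tol = 1e-9) {
  tp <- schedule$timepoints
  p <- schedule$pmf
  if (length(tp) != length(p) || length(p) == 0L || any(diff(tp) <= 0)) {
    th_error("threathazard_unsorted_timepoints",
             "timepoints must be strictly increasing and match pmf length")
  }
  if (any(p < 0)) {
    th_error("threathazard_negative_mass",
             "pmf values must be non-negative")
  }
  if (abs(sum(p) - 1) > tol) {
    th_error("threathazard_mass_sum",
             sprintf("pmf must sum to 1 (got %.12g)", sum(p)))
  }
  schedule
}

#' @export
print.threat_schedule <- function(x, ...) {
  cat(sprintf("<threat_schedule> %s: %d timepoints on [%d, %d]\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$timepoints), min(x$timepoints), max(x$timepoints)))
  invisible(x)
}

#' Hazard profile of a threat schedule
#'
#' Derives the survival function, the discrete hazard rate and the
#' cumulative hazard from a schedule's pmf. The hazard at timepoint `t` is
#' the conditional probability of shock at `t` given no shock before `t`:
#' `h(t) = p(t) / (1 - sum of p before t)`. The survival entry at `t` is
#' the probability of reaching `t` without a shock, so `p(t) =
#' survival(t) * h(t)` exactly. The profile is truncated at the last
#' support point of the pmf: beyond it survival is zero and the hazard is
#' undefined, so no values are emitted there. For any proper pmf the
#' hazard at the last support point is 1.
#'
#' @param schedule A valid `threat_schedule`.
#' @return An object of class `hazard_profile`: a list with `timepoints`,
#'   `survival`, `hazard` and `cumulative_hazard`, all truncated at the
#'   schedule's last support point.
#' @examples
#' hazard_rate(threat_schedule(0:3, rep(.25, 4)))$hazard # .25 1/3 .5 1
#' @export
hazard_rate <- function(schedule) {
  validate_schedule(schedule)
  p <- schedule$pmf
  last <- max(which(p > 0))
  keep <- seq_len(last)
  surv <- 1 - c(0, cumsum(p))[keep]       # P(no shock before t)
  haz <- pmin(p[keep] / surv, 1)          # clamp roundoff at the support end
  structure(
    list(timepoints = schedule$timepoints[keep],
         survival = surv,
         hazard = haz,
         cumulative_hazard = cumsum(haz)),
    class = "hazard_profile"
  )
}

#' @export
print.hazard_profile <- function(x, ...) {
  df <- data.frame(t = x$timepoints, survival = x$survival,
                   hazard = x$hazard, cum_hazard = x$cumulative_hazard)
  cat("<hazard_profile>\n")
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Cumulative hazard of a schedule
#'
#' Sum of the discrete hazard rate over the schedule's support. Equals 1
#' for a point mass (a temporally certain shock) and exceeds 1 for any
#' schedule with mass at two or more timepoints, which is what makes the
#' cumulative hazard, unlike total probability, sensitive to temporal
#' uncertainty.
#'
#' @inheritParams hazard_rate
#' @return A single number, the full-precision sum of hazards. Display
#'   conventions that round each addend first (e.g. .25 + .33 + .5 + 1 =
#'   2.08) are available via [round_hazard()].
#' @export
cumulative_hazard <- function(schedule) {
  prof <- hazard_rate(schedule)
  sum(prof$hazard)
}

#' Expected shock time of a schedule
#'
#' The pmf-weighted mean of the schedule's timepoints, in seconds.
#'
#' @inheritParams hazard_rate
#' @return Expected shock time in seconds.
#' @export
expected_shock_time <- function(schedule) {
  validate_schedule(schedule)
  sum(schedule$timepoints * schedule$pmf)
}

#' Round hazard values for display
#'
#' Worked examples in the literature print hazards at two decimals
#' (1/3 prints as .33) and sum the rounded addends (.25 + .33 + .5 + 1 =
#' 2.08, while the full-precision cumulative hazard is 2.0833...). This
#' helper applies that display rounding.
#'
#' @param x Numeric vector of hazard values (or a `hazard_profile`, in
#'   which case its `hazard` field is used).
#' @param digits Decimal places to keep (default 2).
#' @return Rounded numeric vector.
#' @export
round_hazard <- function(x, digits = 2) {
  if (inherits(x, "hazard_profile")) x <- x$hazard
  round(x, digits)
}

# ---- schedule I/O -----------------------------------------------------

#' Read and write threat schedules
#'
#' Schedules round-trip through two plain-text formats: a JSON object
#' `{label, timepoints, pmf}` and a two-column CSV (`timepoint,
#' probability`, label optional in a `# label:` header comment). Both are
#' loss-free to at least 12 significant digits.
#'
#' @param schedule A `threat_schedule`.
#' @param path File path.
#' @return The readers return a validated `threat_schedule`; the writers
#'   return `path` invisibly.
#' @name schedule_io
NULL

#' @rdname schedule_io
#' @export
write_schedule_json <- function(schedule, path) {
  validate_schedule(schedule)
  jsonlite::write_json(
    list(label = schedule$label,
         timepoints = schedule$timepoints,
         pmf = schedule$pmf),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname schedule_io
#' @export
read_schedule_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  threat_schedule(x$timepoints, x$pmf, if (is.null(x$label)) "" else x$label)
}

#' @rdname schedule_io
#' @export
write_schedule_csv <- function(schedule, path) {
  validate_schedule(schedule)
  con <- file(path, "w")
  on.exit(close(con))
  if (nzchar(schedule$label)) {
    writeLines(sprintf("# label: %s", schedule$label), con)
  }
  writeLines("timepoint,probability", con)
  writeLines(sprintf("%d,%.15g", schedule$timepoints, schedule$pmf), con)
  invisible(path)
}

#' @rdname schedule_io
#' @export
read_schedule_csv <- function(path) {
  lines <- readLines(path)
  label <- ""
  hdr <- grep("^# label:", lines, value = TRUE)
  if (length(hdr)) label <- trimws(sub("^# label:", "", hdr[1]))
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  threat_schedule(df$timepoint, df$probability, label)
}
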