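#' Time-dependent feedback schedule
#'
#' A feedback schedule is a piecewise-linear multiplier applied to the P-to-A
#' antagonism coefficient `kAP` (and, for the co-oscillation variant, to `kPA`
#' as well). It encodes the cell-cycle entrainment of mutual-antagonism
#' feedback: low after cell birth, rising as CDK-1 activity increases toward
#' mitosis. Outside the breakpoint range the multiplier is held constant at
#' the nearest breakpoint value.
#'
#' @param times numeric vector of strictly increasing breakpoint times.
#' @param multipliers nonnegative multipliers at each breakpoint.
#' @param apply_to_kPA logical; if `TRUE` the multiplier also scales `kPA`
#'   (simultaneous oscillation of both feedback arms).
#' @return An object of class `feedback_schedule`.
#' @examples
#' sch <- feedback_schedule(c(0, 60, 70), c(0.01, 0.01, 1))
#' schedule_multiplier(sch, c(0, 65, 100))
#' @export
feedback_schedule <- function(times, multipliers, apply_to_kPA = FALSE) {
  stopifnot(length(times) == length(multipliers), length(times) >= 1)
  if (is.unsorted(times, strictly = TRUE))
    stop("schedule breakpoint times must be strictly increasing")
  if (any(multipliers < 0)) stop("schedule multipliers must be >= 0")
  structure(list(times = as.numeric(times),
                 multipliers = as.numeric(multipliers),
                 apply_to_kPA = isTRUE(apply_to_kPA)),
            class = "feedback_schedule")
}

#' Constant feedback schedule
#'
#' A single-breakpoint schedule; reproduces the fixed-feedback model exactly.
#'
#' @param multiplier the constant multiplier (default 1, the bare model).
#' @param apply_to_kPA see [feedback_schedule()].
#' @return A `feedback_schedule`.
#' @export
constant_schedule <- function(multiplier = 1, apply_to_kPA = FALSE) {
  feedback_schedule(0, multiplier, apply_to_kPA)
}

#' Default oscillating (cell-cycle) feedback schedule
#'
#' Low feedback from cell birth, mimicking low CDK-1 activity early in the
#' cell cycle, followed by a linear rise to full feedback at mitotic entry.
#'
#' @param low multiplier during the low-feedback phase.
#' @param t_rise_start,t_rise_end start and end of the linear low-to-high rise.
#' @param apply_to_kPA see [feedback_schedule()].
#' @return A `feedback_schedule`.
#' @export
oscillating_schedule <- function(low = 0.01, t_rise_start = 60,
                                 t_rise_end = 70, apply_to_kPA = FALSE) {
  feedback_schedule(c(0, t_rise_start, t_rise_end), c(low, low, 1),
                    apply_to_kPA)
}

#' Evaluate a feedback schedule
#'
#' @param schedule a `feedback_schedule`.
#' @param t time(s) at which to evaluate.
#' @return Multiplier value(s), piecewise-linear between breakpoints and
#'   constant outside them.
#' @export
schedule_multiplier <- function(schedule, t) {
  stopifnot(inherits(schedule, "feedback_schedule"))
  if (length(schedule$times) == 1L)
    return(rep(schedule$multipliers, length(t)))
  stats::approx(schedule$times, schedule$multipliers, xout = t,
                rule = 2)$y
}

#' Orientation cue acting on aPARs
#'
#' The cue is a continuous, first-order redistribution of membrane aPAR from
#' the posterior to the anterior compartment: while active it adds
#' `rate * Ap` to `dAa/dt` and removes the same flux from `dAp/dt`, so total
#' aPAR is conserved exactly.
#'
#' @param rate first-order redistribution rate (1/time), >= 0.
#' @param t_on,t_off active window; `t_on < t_off`.
#' @return An object of class `polarity_cue`.
#' @export
polarity_cue <- function(rate, t_on, t_off) {
  stopifnot(rate >= 0, t_on < t_off)
  structure(list(rate = rate, t_on = t_on, t_off = t_off),
            class = "polarity_cue")
}

#' Cue rate at a given time
#'
#' @param cue a `polarity_cue` or `NULL` (no cue).
#' @param t time(s).
#' @return `rate` where `t` lies in `[t_on, t_off]`, otherwise 0.
#' @export
cue_rate <- function(cue, t) {
  if (is.null(cue)) return(rep(0, length(t)))
  stopifnot(inherits(cue, "polarity_cue"))
  ifelse(t >= cue$t_on & t <= cue$t_off, cue$rate, 0)
}

## times at which the rhs is non-smooth; integration is segmented here
.event_times <- function(schedule, cue, t0, t1) {
  ts <- numeric(0)
  if (!is.null(schedule)) ts <- c(ts, schedule$times)
  if (!is.null(cue)) ts <- c(ts, cue$t_on, cue$t_off)
  sort(unique(ts[ts > t0 & ts < t1]))
}
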