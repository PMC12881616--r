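#' Control-parameter schedules
#'
#' Tipping runs ramp a control parameter (growth rate, stress, rainfall)
#' through a bifurcation. Three shapes are supported: a constant, a linear
#' ramp between two values over `[t_start, t_end]` (constant outside), and a
#' logistic sigmoid `from + (to - from) / (1 + exp(-steepness (t - midpoint)))`.
#'
#' @param value Constant value.
#' @return A schedule object evaluable with [eval_schedule()].
#' @export
#' @rdname schedules
schedule_constant <- function(value) {
  structure(list(type = "constant", from = value), class = "fq_schedule")
}

#' @param from,to Start and end values.
#' @param t_start,t_end Ramp interval (time units of the simulation).
#' @export
#' @rdname schedules
schedule_linear <- function(from, to, t_start, t_end) {
  if (t_end <= t_start) stop("`t_end` must exceed `t_start`")
  structure(list(type = "linear", from = from, to = to,
                 t_start = t_start, t_end = t_end), class = "fq_schedule")
}

#' @param midpoint,steepness Sigmoid midpoint time and rate (1/time units).
#' @export
#' @rdname schedules
schedule_sigmoid <- function(from, to, midpoint, steepness) {
  if (steepness <= 0) stop("`steepness` must be positive")
  structure(list(type = "sigmoid", from = from, to = to,
                 midpoint = midpoint, steepness = steepness),
            class = "fq_schedule")
}

#' Evaluate a schedule at a vector of times
#'
#' @param sched A schedule from [schedule_constant()], [schedule_linear()] or
#'   [schedule_sigmoid()] (a bare number is promoted to a constant schedule).
#' @param t Numeric vector of times.
#' @return Numeric vector of parameter values.
#' @export
eval_schedule <- function(sched, t) {
  if (is.numeric(sched) && length(sched) == 1L) sched <- schedule_constant(sched)
  stopifnot(inherits(sched, "fq_schedule"))
  switch(sched$type,
    constant = rep(sched$from, length(t)),
    linear = {
      frac <- (t - sched$t_start) / (sched$t_end - sched$t_start)
      frac <- pmin(pmax(frac, 0), 1)
      sched$from + frac * (sched$to - sched$from)
    },
    sigmoid = sched$from + (sched$to - sched$from) /
      (1 + exp(-sched$steepness * (t - sched$midpoint))),
    stop("unknown schedule type"))
}

# Time at which a schedule starts moving away from its initial value; used to
# delimit the pre-ramp segment for ground-truth transition marking.
schedule_ramp_start <- function(sched) {
  if (is.numeric(sched)) return(Inf)
  switch(sched$type,
    constant = Inf,
    linear = sched$t_start,
    # the sigmoid never sits exactly at `from`; treat everything more than
    # 4 e-folds before the midpoint as pre-ramp
    sigmoid = sched$midpoint - 4 / sched$steepness)
}
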