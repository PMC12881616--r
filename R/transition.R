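#' Ground-truth transition marker
#'
#' Marks the time a series leaves its pre-ramp equilibrium branch: a
#' trailing window mean must depart from the pre-ramp mean by more than
#' `k_sd` pre-ramp standard deviations. The pre-ramp statistics are
#' computed on the window means of the segment before `pre_end`,
#' discarding the first `burn_frac` of it to let the simulator settle.
#'
#' The rolling width defaults to one seasonal period (365 steps for daily
#' saves) so that the window means, and the pre-ramp SD computed from
#' them, are insensitive to the seasonal cycle itself. Because critical
#' slowing down inflates the fluctuation variance on the approach to a
#' bifurcation, transient excursions past a fixed SD multiple become
#' common shortly before the actual escape; with `sustained = TRUE` (the
#' default used by the simulators) the marker therefore returns the
#' earliest departure that persists through the end of the run; the
#' escape onto a new branch is irreversible, excursions are not. With
#' `sustained = FALSE` a departure persisting `persist` consecutive steps
#' qualifies.
#'
#' @param series A `uniform_series`.
#' @param pre_end Time where the control ramp starts (end of the pre-ramp
#'   segment).
#' @param k_sd Departure threshold in pre-ramp SD units (SD of the rolling
#'   window means over the pre-ramp segment).
#' @param roll_width Width (steps) of the trailing mean window.
#' @param burn_frac Fraction of the pre-ramp segment discarded as burn-in.
#' @param sustained If `TRUE`, the departure must last until the end of
#'   the series; otherwise `persist` consecutive steps suffice.
#' @param persist Number of consecutive departed steps required when
#'   `sustained = FALSE`.
#' @return Time of the transition, or `NA_real_` if no qualifying
#'   departure.
#' @export
detect_transition <- function(series, pre_end, k_sd = 5, roll_width = 365L,
                              burn_frac = 0.25, sustained = TRUE,
                              persist = 30L) {
  stopifnot(inherits(series, "uniform_series"))
  rm <- as.numeric(zoo::rollmeanr(zoo::zoo(series$value), roll_width,
                                  fill = NA))
  pre_idx <- which(series$time < pre_end & !is.na(rm))
  if (length(pre_idx) < 2L * roll_width)
    return(NA_real_)
  pre_idx <- pre_idx[seq.int(ceiling(burn_frac * length(pre_idx)) + 1L,
                             length(pre_idx))]
  pre_mean <- mean(rm[pre_idx])
  pre_sd <- stats::sd(rm[pre_idx])
  if (!is.finite(pre_sd) || pre_sd == 0) return(NA_real_)
  dep <- abs(rm - pre_mean) > k_sd * pre_sd
  dep[is.na(dep)] <- FALSE
  dep[series$time < pre_end] <- FALSE
  r <- rle(dep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  if (sustained) {
    n_runs <- length(r$values)
    if (!r$values[n_runs]) return(NA_real_)
    return(series$time[starts[n_runs]])
  }
  hit <- which(r$values & r$lengths >= persist)
  if (length(hit) == 0L) return(NA_real_)
  series$time[starts[hit[1]]]
}
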