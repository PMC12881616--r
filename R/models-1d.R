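#' Seasonally forced 1D tipping models
#'
#' Euler-Maruyama integrators for two stochastic bifurcation models with
#' additive seasonal forcing, and a piecewise-noise stationary process used
#' to emulate multi-instrument records. Time is measured in years for the
#' bifurcation models (annual angular frequency `omega = 2 * pi`) and in days
#' for the stationary process. All simulators are bit-reproducible given
#' identical parameters and seed.
#'
#' @name models_1d
NULL

new_model_run <- function(params, output, seed, transition_time) {
  structure(list(params = params, output = output, seed = seed,
                 transition_time = transition_time), class = "model_run")
}

#' @export
print.model_run <- function(x, ...) {
  cat(sprintf("<model_run> %s, seed %d, transition at %s\n",
              class(x$params)[1], x$seed,
              if (is.na(x$transition_time)) "none" else
                format(x$transition_time, digits = 6)))
  print(x$output)
  invisible(x)
}

#' Parameters of the seasonally forced pitchfork model
#'
#' The model is `dx/dt = p(t) x - x^3 - lambda x + A cos(omega t) + sigma xi`.
#' The default schedule holds `p = -6` for 20 years (a strongly damped
#' pre-ramp state whose memory, about 2 months, is short against the annual
#' period), then ramps linearly to `+2` over the remaining 60 years: the
#' deterministic bifurcation at `p = 0` is crossed at year 65 and the
#' noise-seeded escape onto a pitchfork branch follows several years later,
#' in the final third of the run. The seasonal response amplitude
#' (`A / sqrt(p^2 + omega^2)`, about 0.23 pre-ramp) dominates the
#' stationary noise SD (`sigma / sqrt(2 |p|)`, about 0.003) so the periodic
#' orbit, and hence the seasonal Floquet multiplier, is sharply defined,
#' while the escape itself remains noise-triggered.
#'
#' @param p_schedule Schedule for the control parameter `p` (see
#'   [schedule_linear()]).
#' @param lambda_damp Extra linear damping (default 0).
#' @param A Seasonal forcing amplitude.
#' @param omega Angular frequency (radians per year; annual period).
#' @param sigma Additive white-noise amplitude.
#' @param x0 Initial state.
#' @param dt Integration step (years). The default, 1/365, is one step per
#'   day so that daily saves carry exactly 365 samples per seasonal period.
#' @param duration Total simulated time (years).
#' @param save_stride Substeps per saved sample (the last substep of each
#'   block is saved).
#' @param seed RNG seed.
#' @return A `pitchfork_params` object.
#' @export
pitchfork_params <- function(p_schedule = schedule_linear(-6, 2, 20, 80),
                             lambda_damp = 0, A = 2, omega = 2 * pi,
                             sigma = 0.01, x0 = 0, dt = 1 / 365,
                             duration = 80, save_stride = 1L, seed = 1L) {
  stopifnot(dt > 0, duration > 0, save_stride >= 1)
  structure(list(p_schedule = p_schedule, lambda_damp = lambda_damp, A = A,
                 omega = omega, sigma = sigma, x0 = x0, dt = dt,
                 duration = duration, save_stride = as.integer(save_stride),
                 seed = as.integer(seed)),
            class = c("pitchfork_params", "fq_params"))
}

#' Parameters of the seasonally forced logistic model
#'
#' `dx/dt = r(t) x (1 - x/K) + A cos(omega t) + sigma xi`, clipped to
#' `x >= 0` at every substep. The default ramps the growth rate from 1
#' through the transcritical loss of the vegetated state (`r = 0`) to -0.5,
#' so the carrying-capacity branch destabilizes in the final third of the
#' run. Once `r < 0` the logistic drift is repulsive above `K` and has no
#' finite attractor there; trajectories escaping upward (a pathology of the
#' model, not of the integrator) are clipped at `x_cap`. The ground-truth
#' transition marker treats any sustained departure from the
#' carrying-capacity branch as the transition.
#'
#' @inheritParams pitchfork_params
#' @param r_schedule Schedule for the growth rate `r`.
#' @param K Carrying capacity.
#' @param x_cap Upper clip bound for the state (in units of `K`).
#' @return A `logistic_params` object.
#' @export
logistic_params <- function(r_schedule = schedule_linear(1, -0.5, 20, 80),
                            K = 1, A = 0.05, omega = 2 * pi, sigma = 0.02,
                            x0 = 1, dt = 1 / 365, duration = 80,
                            save_stride = 1L, x_cap = 3 * K, seed = 1L) {
  stopifnot(K > 0, dt > 0, duration > 0, save_stride >= 1, x_cap > K)
  structure(list(r_schedule = r_schedule, K = K, A = A, omega = omega,
                 sigma = sigma, x0 = x0, dt = dt, duration = duration,
                 save_stride = as.integer(save_stride), x_cap = x_cap,
                 seed = as.integer(seed)),
            class = c("logistic_params", "fq_params"))
}

# Shared Euler-Maruyama driver for the two scalar models. `drift(x, i)` gets
# the current state and substep index (schedules are pre-evaluated).
integrate_scalar_em <- function(drift, params, clip_nonneg = FALSE,
                                clip_max = Inf) {
  n_sub <- round(params$duration / params$dt)
  set.seed(params$seed)
  noise <- stats::rnorm(n_sub)
  x <- params$x0
  stride <- params$save_stride
  n_save <- n_sub %/% stride
  out <- numeric(n_save)
  sdt <- sqrt(params$dt)
  for (i in seq_len(n_sub)) {
    x <- x + drift(x, i) * params$dt + params$sigma * sdt * noise[i]
    if (clip_nonneg && x < 0) x <- 0
    if (x > clip_max) x <- clip_max
    if (!is.finite(x))
      stop(sprintf("state became non-finite at substep %d (t = %g)",
                   i, i * params$dt))
    if (i %% stride == 0L) out[i %/% stride] <- x
  }
  uniform_series(params$dt * stride * seq_len(n_save), out)
}

#' Simulate the seasonally forced pitchfork model
#'
#' @param params A [pitchfork_params()] object.
#' @return A `model_run` holding the saved `uniform_series`, the seed, and
#'   the ground-truth `transition_time` (see [detect_transition()]).
#' @export
simulate_pitchfork <- function(params) {
  stopifnot(inherits(params, "pitchfork_params"))
  n_sub <- round(params$duration / params$dt)
  t_sub <- params$dt * (seq_len(n_sub) - 1L)
  p <- eval_schedule(params$p_schedule, t_sub)
  forcing <- params$A * cos(params$omega * t_sub)
  lam <- params$lambda_damp
  drift <- function(x, i) p[i] * x - x^3 - lam * x + forcing[i]
  out <- integrate_scalar_em(drift, params)
  tt <- detect_transition(out, schedule_ramp_start(params$p_schedule))
  new_model_run(params, out, params$seed, tt)
}

#' Simulate the seasonally forced logistic model
#'
#' @param params A [logistic_params()] object.
#' @return A `model_run`; saved values are clipped to be non-negative.
#' @export
simulate_logistic <- function(params) {
  stopifnot(inherits(params, "logistic_params"))
  n_sub <- round(params$duration / params$dt)
  t_sub <- params$dt * (seq_len(n_sub) - 1L)
  r <- eval_schedule(params$r_schedule, t_sub)
  forcing <- params$A * cos(params$omega * t_sub)
  K <- params$K
  drift <- function(x, i) r[i] * x * (1 - x / K) + forcing[i]
  out <- integrate_scalar_em(drift, params, clip_nonneg = TRUE,
                             clip_max = params$x_cap %||% Inf)
  tt <- detect_transition(out, schedule_ramp_start(params$r_schedule))
  new_model_run(params, out, params$seed, tt)
}

#' Parameters of the piecewise-noise stationary process
#'
#' A stationary AR(1) recursion plus a sinusoidal seasonal cycle, observed
#' through consecutive time slices with different additional additive white
#' noise (emulating instrument changes), then averaged into bins (daily by
#' default). Time is in days.
#'
#' @param base_process AR(1) coefficient per substep (memory).
#' @param base_sd Innovation SD of the AR(1) recursion per substep.
#' @param season_amplitude,season_period Seasonal sine amplitude and period
#'   (days).
#' @param segments Data frame with columns `start`, `end`, `extra_noise_sd`;
#'   must tile `[0, duration]` without overlap.
#' @param bin_width Output bin width (days).
#' @param substeps_per_day Substeps per day of the latent process.
#' @param duration Total length (days).
#' @param seed RNG seed.
#' @return A `piecewise_noise_params` object.
#' @export
piecewise_noise_params <- function(base_process = 0.95, base_sd = 0.1,
                                   season_amplitude = 3, season_period = 365,
                                   segments = NULL, bin_width = 1,
                                   substeps_per_day = 4L, duration = 3650,
                                   seed = 1L) {
  if (is.null(segments))
    segments <- data.frame(start = c(0, duration / 3, 2 * duration / 3),
                           end = c(duration / 3, 2 * duration / 3, duration),
                           extra_noise_sd = c(0, 0.4, 0.2))
  segments <- segments[order(segments$start), , drop = FALSE]
  if (nrow(segments) == 0L) stop("`segments` must not be empty")
  if (any(segments$extra_noise_sd < 0)) stop("noise SDs must be >= 0")
  if (abs(segments$start[1]) > 1e-9 ||
      abs(segments$end[nrow(segments)] - duration) > 1e-9 ||
      (nrow(segments) > 1L &&
       any(abs(segments$start[-1] - segments$end[-nrow(segments)]) > 1e-9)))
    stop("`segments` must tile [0, duration] without gaps or overlap")
  structure(list(base_process = base_process, base_sd = base_sd,
                 season_amplitude = season_amplitude,
                 season_period = season_period, segments = segments,
                 bin_width = bin_width,
                 substeps_per_day = as.integer(substeps_per_day),
                 duration = duration, seed = as.integer(seed)),
            class = c("piecewise_noise_params", "fq_params"))
}

#' Simulate the piecewise-noise stationary process
#'
#' @param params A [piecewise_noise_params()] object.
#' @return A `model_run`; the output series is the binned average of the
#'   observed substep process. `transition_time` is `NA` (the latent process
#'   is stationary by construction).
#' @export
simulate_piecewise_noise <- function(params) {
  stopifnot(inherits(params, "piecewise_noise_params"))
  sub_dt <- 1 / params$substeps_per_day
  n_sub <- round(params$duration / sub_dt)
  t_sub <- sub_dt * seq_len(n_sub)
  set.seed(params$seed)
  # AR(1) recursion started at its stationary distribution
  phi <- params$base_process
  innov <- stats::rnorm(n_sub, sd = params$base_sd)
  z <- numeric(n_sub)
  z0 <- if (abs(phi) < 1) stats::rnorm(1, sd = params$base_sd / sqrt(1 - phi^2))
        else 0
  prev <- z0
  for (i in seq_len(n_sub)) {
    prev <- phi * prev + innov[i]
    z[i] <- prev
  }
  season <- params$season_amplitude * sin(2 * pi * t_sub / params$season_period)
  extra_sd <- numeric(n_sub)
  for (k in seq_len(nrow(params$segments)))
    extra_sd[t_sub > params$segments$start[k] &
             t_sub <= params$segments$end[k] + 1e-9] <-
      params$segments$extra_noise_sd[k]
  obs <- z + season + stats::rnorm(n_sub) * extra_sd
  per_bin <- round(params$bin_width / sub_dt)
  n_bin <- n_sub %/% per_bin
  binned <- colMeans(matrix(obs[seq_len(n_bin * per_bin)], nrow = per_bin))
  out <- uniform_series(params$bin_width * seq_len(n_bin), binned)
  new_model_run(params, out, params$seed, NA_real_)
}
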