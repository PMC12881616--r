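#' Spatio-temporal vegetation simulators
#'
#' Stochastic reaction-diffusion models on a regular grid, integrated with
#' Euler-Maruyama at a fine substep and saved at the last substep of each
#' day. Both models ramp a control parameter (environmental stress or
#' rainfall) through a transition while a seasonal component forces the
#' system at an annual period.
#'
#' @name models_spatial
NULL

# Precompute 5-point Laplacian neighbor indices for an ny x nx grid in
# row-major cell order. boundary = "periodic" wraps; "noflux" reflects
# (boundary neighbor = the cell itself, giving a zero-gradient edge).
laplacian_indices <- function(ny, nx, boundary = c("periodic", "noflux")) {
  boundary <- match.arg(boundary)
  iy <- rep(seq_len(ny), each = nx)
  ix <- rep(seq_len(nx), times = ny)
  wrap <- function(i, n) ((i - 1) %% n) + 1
  clampv <- function(i, n) pmin(pmax(i, 1), n)
  shift <- if (boundary == "periodic") wrap else clampv
  idx <- function(y, x) (y - 1) * nx + x
  list(up    = idx(shift(iy - 1, ny), ix),
       down  = idx(shift(iy + 1, ny), ix),
       left  = idx(iy, shift(ix - 1, nx)),
       right = idx(iy, shift(ix + 1, nx)))
}

apply_laplacian <- function(v, li) {
  v[li$up] + v[li$down] + v[li$left] + v[li$right] - 4 * v
}

#' Parameters of the seasonal reaction-diffusion vegetation model
#'
#' Vegetation cover `V(x, y, t)` obeys
#' `dV/dt = r_v V (1 - V (h_E^p + E^p) / h_E^p) + D lap(V) + sigma eta`,
#' with stress `E = E0(t) h_v / (h_v + V)` and
#' `E0(t) = E0_base(t) + A_E0 sin(2 pi t / T_year)`. The growth rate carries
#' a spatially heterogeneous seasonal component
#' `r_v = r_v0 + A_rv(x, y) sin(2 pi t / T_year + phi(x, y))` whose per-cell
#' amplitudes and phases (drawn from the run's seed unless supplied)
#' prevent the grid from phase-locking. Time is in days; the default year
#' is 360 days so daily saves are commensurate with a 30-day monthly
#' analysis stride.
#'
#' @param grid Integer vector `c(n_y, n_x)`.
#' @param r_v0 Base growth rate (1/day).
#' @param A_rv_field Per-cell seasonal growth-rate amplitude (vector of
#'   length `n_y * n_x`, row-major), or `NULL` to draw from the seed.
#' @param phase_field Per-cell seasonal phase (radians), or `NULL` to draw.
#' @param E0_schedule Schedule of the base stress `E0_base(t)`.
#' @param A_E0 Seasonal stress amplitude.
#' @param h_E,h_v,p_exp Shape parameters of the stress response.
#' @param D Diffusion coefficient (cell^2/day).
#' @param sigma Noise amplitude.
#' @param T_year Seasonal period (days).
#' @param dt Integration step (days).
#' @param duration Saved run length (days).
#' @param spinup Spin-up length (days) integrated before saving, with the
#'   stress held at its base value (seasonal component off).
#' @param boundary Laplacian boundary handling, `"periodic"` or `"noflux"`.
#' @param seed RNG seed.
#' @return A `vegetation_rd_params` object.
#' @export
vegetation_rd_params <- function(grid = c(32L, 32L), r_v0 = 0.2,
                                 A_rv_field = NULL, phase_field = NULL,
                                 E0_schedule = schedule_linear(2.2, 3.6, 1440, 7200),
                                 A_E0 = 0.3, h_E = 1, h_v = 0.2, p_exp = 4,
                                 D = 0.1, sigma = 0.02, T_year = 360,
                                 dt = 0.1, duration = 7200, spinup = 360,
                                 boundary = "periodic", seed = 1L) {
  stopifnot(length(grid) == 2L, all(grid >= 2L), h_E > 0, h_v > 0,
            dt > 0, duration > 0, spinup >= 0)
  structure(list(grid = as.integer(grid), r_v0 = r_v0,
                 A_rv_field = A_rv_field, phase_field = phase_field,
                 E0_schedule = E0_schedule, A_E0 = A_E0, h_E = h_E,
                 h_v = h_v, p_exp = p_exp, D = D, sigma = sigma,
                 T_year = T_year, dt = dt, duration = duration,
                 spinup = spinup, boundary = boundary,
                 seed = as.integer(seed)),
            class = c("vegetation_rd_params", "fq_params"))
}

#' Simulate the seasonal reaction-diffusion vegetation model
#'
#' @param params A [vegetation_rd_params()] object.
#' @return A `model_run` whose output is an `st_field` with one snapshot per
#'   day after spin-up (the last substep of each day). `transition_time` is
#'   derived from the domain-mean series.
#' @export
simulate_vegetation_rd <- function(params) {
  stopifnot(inherits(params, "vegetation_rd_params"))
  ny <- params$grid[1]; nx <- params$grid[2]; d <- ny * nx
  li <- laplacian_indices(ny, nx, params$boundary)
  set.seed(params$seed)
  # heterogeneous seasonal growth (row-major draws, before dynamic noise)
  A_rv <- params$A_rv_field
  if (is.null(A_rv)) A_rv <- 0.1 * params$r_v0 * (0.5 + stats::runif(d))
  phi <- params$phase_field
  if (is.null(phi)) phi <- stats::rnorm(d, sd = 0.3)
  if (length(A_rv) != d || length(phi) != d)
    stop("A_rv_field and phase_field must have length ny * nx")

  sub_per_day <- round(1 / params$dt)
  hEp <- params$h_E^params$p_exp
  sdt <- sqrt(params$dt)
  omega <- 2 * pi / params$T_year

  # vegetated equilibrium under the base stress (with cover feedback),
  # found by fixed-point iteration, as homogeneous initial state
  E0_init <- eval_schedule(params$E0_schedule, 0)
  V0 <- 0.9
  for (k in 1:200) {
    E <- E0_init * params$h_v / (params$h_v + V0)
    V0 <- hEp / (hEp + E^params$p_exp)
  }
  V <- rep(V0, d)

  step_once <- function(V, t, seasonal) {
    E0 <- eval_schedule(params$E0_schedule, t)
    if (seasonal) E0 <- E0 + params$A_E0 * sin(omega * t)
    E <- E0 * params$h_v / (params$h_v + V)
    rv <- params$r_v0 + if (seasonal) A_rv * sin(omega * t + phi) else 0
    growth <- rv * V * (1 - V * (hEp + E^params$p_exp) / hEp)
    V <- V + (growth + params$D * apply_laplacian(V, li)) * params$dt +
      params$sigma * sdt * stats::rnorm(d)
    pmax(V, 0)
  }

  n_spin <- round(params$spinup / params$dt)
  for (i in seq_len(n_spin)) {
    V <- step_once(V, 0, seasonal = FALSE)
    if (any(!is.finite(V)))
      stop(sprintf("state became non-finite at spin-up substep %d", i))
  }

  n_days <- floor(params$duration)
  out <- matrix(NA_real_, d, n_days)
  for (day in seq_len(n_days)) {
    for (s in seq_len(sub_per_day)) {
      t <- (day - 1) + (s - 1) * params$dt
      V <- step_once(V, t, seasonal = TRUE)
    }
    if (any(!is.finite(V)))
      stop(sprintf("state became non-finite on day %d", day))
    out[, day] <- V
  }
  field <- st_field(out, as.numeric(seq_len(n_days)), ny, nx)
  tt <- detect_transition(field_mean_series(field),
                          schedule_ramp_start(params$E0_schedule),
                          roll_width = round(params$T_year))
  new_model_run(params, field, params$seed, tt)
}

#' Parameters of the seasonal Klausmeier pattern-formation model
#'
#' The classic two-equation setup for biomass `N` and water `W`:
#' `dN/dt = W N^2 - m N + D_n lap(N) + sigma eta_N` and
#' `dW/dt = a(t) - W - W N^2 + e lap(W)`, with rainfall
#' `a(t) = a_base(t) + A_season sin(2 pi t / T_season)` declining along a
#' logistic curve. Noise enters the biomass equation only; biomass is
#' clipped to `N >= 0`.
#'
#' @inheritParams vegetation_rd_params
#' @param m_mort Vegetation mortality `m`.
#' @param a_schedule Schedule for base rainfall `a_base(t)`.
#' @param A_season Rainfall seasonal amplitude.
#' @param T_season Seasonal period (365 days).
#' @param D_n Biomass diffusion coefficient.
#' @param e_diff Water diffusion coefficient.
#' @return A `klausmeier_params` object.
#' @export
klausmeier_params <- function(grid = c(16L, 16L), m_mort = 0.45,
                              a_schedule = schedule_sigmoid(2.5, 0.2,
                                                            midpoint = 1825,
                                                            steepness = 0.004),
                              A_season = 0.3, T_season = 365, D_n = 0.5,
                              e_diff = 2, sigma = 0.05, dt = 0.01,
                              duration = 3650, spinup = 50,
                              boundary = "periodic", seed = 1L) {
  stopifnot(length(grid) == 2L, all(grid >= 2L), m_mort > 0, dt > 0,
            duration > 0, spinup >= 0)
  structure(list(grid = as.integer(grid), m_mort = m_mort,
                 a_schedule = a_schedule, A_season = A_season,
                 T_season = T_season, D_n = D_n, e_diff = e_diff,
                 sigma = sigma, dt = dt, duration = duration,
                 spinup = spinup, boundary = boundary,
                 seed = as.integer(seed)),
            class = c("klausmeier_params", "fq_params"))
}

#' Simulate the seasonal Klausmeier model
#'
#' @param params A [klausmeier_params()] object.
#' @return A `model_run` whose output is an `st_field` of biomass `N` with
#'   one snapshot per day after spin-up; the water field's final state is
#'   attached as `attr(output, "W_final")`.
#' @export
simulate_klausmeier <- function(params) {
  stopifnot(inherits(params, "klausmeier_params"))
  ny <- params$grid[1]; nx <- params$grid[2]; d <- ny * nx
  li <- laplacian_indices(ny, nx, params$boundary)
  set.seed(params$seed)
  m <- params$m_mort
  a0 <- eval_schedule(params$a_schedule, 0)
  # high-biomass initialization: upper vegetated branch for rainfall a0
  # (N solves N^2 - (a/m) N + 1 = 0), or a nominal low cover if absent
  disc <- (a0 / m)^2 - 4
  N0 <- if (disc > 0) (a0 / m + sqrt(disc)) / 2 else 0.1
  N <- rep(N0, d)
  W <- rep(if (N0 > 0) m / max(N0, 1e-12) else a0, d)
  sdt <- sqrt(params$dt)
  omega <- 2 * pi / params$T_season
  sub_per_day <- round(1 / params$dt)

  step_once <- function(N, W, t, seasonal) {
    a <- eval_schedule(params$a_schedule, t)
    if (seasonal) a <- a + params$A_season * sin(omega * t)
    uptake <- W * N^2
    Nn <- N + (uptake - m * N + params$D_n * apply_laplacian(N, li)) * params$dt +
      params$sigma * sdt * stats::rnorm(d)
    Wn <- W + (a - W - uptake + params$e_diff * apply_laplacian(W, li)) * params$dt
    list(N = pmax(Nn, 0), W = Wn)
  }

  n_spin <- round(params$spinup / params$dt)
  for (i in seq_len(n_spin)) {
    st <- step_once(N, W, 0, seasonal = FALSE)
    N <- st$N; W <- st$W
    if (any(!is.finite(N)) || any(!is.finite(W)))
      stop(sprintf("state became non-finite at spin-up substep %d", i))
  }

  n_days <- floor(params$duration)
  out <- matrix(NA_real_, d, n_days)
  for (day in seq_len(n_days)) {
    for (s in seq_len(sub_per_day)) {
      t <- (day - 1) + (s - 1) * params$dt
      st <- step_once(N, W, t, seasonal = TRUE)
      N <- st$N; W <- st$W
    }
    if (any(!is.finite(N)) || any(!is.finite(W)))
      stop(sprintf("state became non-finite on day %d", day))
    out[, day] <- N
  }
  field <- st_field(out, as.numeric(seq_len(n_days)), ny, nx)
  attr(field, "W_final") <- W
  tt <- detect_transition(field_mean_series(field),
                          schedule_ramp_start(params$a_schedule))
  new_model_run(params, field, params$seed, tt)
}
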