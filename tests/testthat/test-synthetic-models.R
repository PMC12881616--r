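# Simulator contracts: fixed points, independent-integrator oracles,
# clipping, seed determinism, noise scaling, and spatial symmetry.

test_that("pitchfork fixed point, oracle trajectory, and determinism", {
  # sigma = 0, A = 0, p < 0: x = 0 is a fixed point of dx/dt = -x^3 + p x
  quiet <- simulate_pitchfork(pitchfork_params(
    p_schedule = schedule_constant(-1), A = 0, sigma = 0, x0 = 0,
    duration = 2, seed = 1))
  expect_true(all(quiet$output$value == 0))

  # noiseless seasonal run equals an independently written Euler iteration
  prm <- pitchfork_params(p_schedule = schedule_linear(-1, 0.5, 1, 4),
                          A = 0.5, sigma = 0, x0 = 0.1, duration = 4,
                          seed = 99)
  run <- simulate_pitchfork(prm)
  p_fun <- function(t) eval_schedule(prm$p_schedule, t)
  oracle <- oracle_pitchfork_euler(p_fun, A = 0.5, omega = 2 * pi,
                                   x0 = 0.1, dt = prm$dt,
                                   n_steps = length(run$output$value))
  expect_equal(run$output$value, oracle, tolerance = 1e-12)

  # identical params + seed reproduce bit-for-bit
  a <- simulate_pitchfork(pitchfork_params(seed = 5, duration = 3))
  b <- simulate_pitchfork(pitchfork_params(seed = 5, duration = 3))
  expect_identical(a$output$value, b$output$value)
  expect_false(identical(
    a$output$value,
    simulate_pitchfork(pitchfork_params(seed = 6, duration = 3))$output$value))
})

test_that("pitchfork saved length and blow-up diagnostics", {
  prm <- pitchfork_params(duration = 2, save_stride = 5L, seed = 1)
  run <- simulate_pitchfork(prm)
  expect_length(run$output$value, floor(prm$duration / (prm$dt * 5)))
  expect_error(
    simulate_pitchfork(pitchfork_params(
      p_schedule = schedule_constant(1e8), sigma = 0, x0 = 1,
      duration = 0.1, seed = 1)),
    "non-finite at substep")
})

test_that("Euler-Maruyama noise scaling leaves stationary variance invariant", {
  # small-fluctuation pitchfork at fixed p: Var = sigma^2 / (2|p|),
  # independent of dt when the sqrt(dt) scaling is correct
  vars <- sapply(c(1 / 365, 1 / 730), function(dt) {
    run <- simulate_pitchfork(pitchfork_params(
      p_schedule = schedule_constant(-1), A = 0, sigma = 0.1, x0 = 0,
      dt = dt, duration = 60, save_stride = 1L, seed = 21))
    stats::var(run$output$value[-(1:365)])
  })
  expect_equal(vars[1], vars[2], tolerance = 0.15)
  expect_equal(vars[1], 0.1^2 / 2, tolerance = 0.15)
})

test_that("logistic honors absorbing state, carrying capacity, and clipping", {
  zero <- simulate_logistic(logistic_params(x0 = 0, sigma = 0, A = 0,
                                            duration = 2, seed = 1))
  expect_true(all(zero$output$value == 0))

  cap <- simulate_logistic(logistic_params(
    r_schedule = schedule_constant(1), K = 1, A = 0, sigma = 0,
    x0 = 0.01, duration = 30, seed = 1))
  vals <- cap$output$value
  expect_lt(abs(vals[length(vals)] - 1), 1e-6)
  expect_true(all(diff(vals) >= -1e-12))

  noisy <- simulate_logistic(logistic_params(sigma = 1, duration = 3,
                                             seed = 3))
  expect_gte(min(noisy$output$value), 0)
})

test_that("piecewise-noise process matches its closed-form variance ratio", {
  # base coefficient 0 and no season: binned white noise, AC1 ~ 0
  white <- simulate_piecewise_noise(piecewise_noise_params(
    base_process = 0, base_sd = 1, season_amplitude = 0,
    segments = data.frame(start = 0, end = 2000, extra_noise_sd = 0),
    duration = 2000, seed = 2))
  v <- white$output$value
  ac1 <- stats::cor(v[-1], v[-length(v)])
  expect_lt(abs(ac1), 3 / sqrt(length(v)))

  # two segments with extra SDs (0, s): variance ratio (sigma^2+s^2)/sigma^2
  s_extra <- 1.5
  run <- simulate_piecewise_noise(piecewise_noise_params(
    base_process = 0, base_sd = 1, season_amplitude = 0,
    segments = data.frame(start = c(0, 4000), end = c(4000, 8000),
                          extra_noise_sd = c(0, s_extra)),
    duration = 8000, seed = 7))
  v <- run$output$value
  seg1 <- v[run$output$time <= 4000]
  seg2 <- v[run$output$time > 4000]
  ratio <- stats::var(seg2) / stats::var(seg1)
  expect_equal(ratio, 1 + s_extra^2, tolerance = 0.15)

  # homogeneous case: variance ratio near 1
  hom <- simulate_piecewise_noise(piecewise_noise_params(
    base_process = 0, base_sd = 1, season_amplitude = 0,
    segments = data.frame(start = c(0, 3000), end = c(3000, 6000),
                          extra_noise_sd = c(0.5, 0.5)),
    duration = 6000, seed = 8))
  v <- hom$output$value
  r <- stats::var(v[hom$output$time <= 3000]) /
    stats::var(v[hom$output$time > 3000])
  expect_equal(r, 1, tolerance = 0.15)

  expect_error(piecewise_noise_params(
    segments = data.frame(start = numeric(0), end = numeric(0),
                          extra_noise_sd = numeric(0))))
})

test_that("vegetation model preserves symmetry and matches the root oracle", {
  base <- vegetation_rd_params(grid = c(8L, 8L), sigma = 0,
                               A_rv_field = rep(0, 64),
                               phase_field = rep(0, 64),
                               E0_schedule = schedule_constant(2.5),
                               A_E0 = 0, duration = 60, spinup = 30,
                               seed = 1)
  run <- simulate_vegetation_rd(base)
  spatial_var <- apply(run$output$values, 2, stats::var)
  expect_true(all(spatial_var == 0))

  # trajectory converges to the uniform root of the coupled equilibrium
  # equations, found by an independent 1D root-finder
  eq <- function(V) {
    E <- 2.5 * base$h_v / (base$h_v + V)
    V - base$h_E^base$p_exp / (base$h_E^base$p_exp + E^base$p_exp)
  }
  V_star <- stats::uniroot(eq, c(0.5, 1.2), tol = 1e-12)$root
  expect_equal(unname(run$output$values[1, 60]), V_star, tolerance = 1e-4)

  # seed determinism with noise on
  p2 <- vegetation_rd_params(grid = c(6L, 6L), duration = 20, spinup = 5,
                             seed = 4)
  r1 <- simulate_vegetation_rd(p2)
  r2 <- simulate_vegetation_rd(p2)
  expect_identical(r1$output$values, r2$output$values)
})

test_that("Klausmeier equilibria match the algebraic oracle", {
  # constant rainfall a > 2m: uniform state on the upper branch solves
  # W N^2 = m N and a = W + W N^2
  a <- 2; m <- 0.45
  run <- simulate_klausmeier(klausmeier_params(
    grid = c(8L, 8L), a_schedule = schedule_constant(a), A_season = 0,
    sigma = 0, duration = 60, spinup = 0, seed = 1))
  N_star <- (a / m + sqrt((a / m)^2 - 4)) / 2
  final_N <- run$output$values[, 60]
  expect_equal(unname(final_N[1]), N_star, tolerance = 1e-6)
  expect_true(all(apply(run$output$values, 2, stats::var) == 0))
  W_final <- attr(run$output, "W_final")
  expect_equal(unname(W_final[1] * N_star^2), m * N_star, tolerance = 1e-4)
  expect_equal(unname(W_final[1] + W_final[1] * N_star^2), a,
               tolerance = 1e-4)

  # a < 2m: the equilibrium quadratic has negative discriminant and the
  # vegetated state decays away
  dec <- simulate_klausmeier(klausmeier_params(
    grid = c(8L, 8L), a_schedule = schedule_constant(0.8), A_season = 0,
    sigma = 0, duration = 80, spinup = 0, seed = 1))
  expect_lt(mean(dec$output$values[, 80]) / mean(dec$output$values[, 1]),
            1e-3)

  # biomass clipping holds under noise
  noisy <- simulate_klausmeier(klausmeier_params(
    grid = c(6L, 6L), sigma = 0.5, duration = 10, spinup = 0, seed = 2))
  expect_gte(min(noisy$output$values), 0)
})

test_that("schedules evaluate their stated shapes", {
  lin <- schedule_linear(-1, 1, 10, 20)
  expect_equal(eval_schedule(lin, c(0, 10, 15, 20, 30)), c(-1, -1, 0, 1, 1))
  sig <- schedule_sigmoid(0, 1, midpoint = 5, steepness = 2)
  expect_equal(eval_schedule(sig, 5), 0.5)
  expect_lt(eval_schedule(sig, 0), 0.01)
  expect_equal(eval_schedule(0.7, 1:3), rep(0.7, 3))
})

test_that("transition marker finds a sustained departure and ignores noise", {
  set.seed(1)
  n <- 3000
  x <- rnorm(n, sd = 0.05)
  x[2001:n] <- x[2001:n] + 2   # permanent shift
  s <- uniform_series(1:n, x)
  tt <- detect_transition(s, pre_end = 1500, roll_width = 100L)
  expect_true(!is.na(tt) && tt >= 1950 && tt <= 2150)
  # stationary series: no transition
  s2 <- uniform_series(1:n, rnorm(n, sd = 0.05))
  expect_true(is.na(detect_transition(s2, pre_end = 1500,
                                      roll_width = 100L)))
})
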