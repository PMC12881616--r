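# Sliding-window Floquet estimation, track matching and labeling,
# crossing detection, and spatial-mode extraction.

test_that("an exactly periodic waveform pins the dominant multiplier at 1", {
  t <- 1:4000
  # non-sinusoidal periodic waveform (period 100)
  x <- 1.3 * sin(2 * pi * t / 100) + 0.6 * cos(6 * pi * t / 100) + 0.4
  s <- uniform_series(t, x)
  cfg <- embedding_config(m = 3, tau = 25, T_steps = 100, window_len = 300)
  et <- rolling_floquet(s, cfg, rank = "auto")
  doms <- sapply(et$fits, spectral_radius)
  expect_true(all(abs(doms - 1) < 1e-6))
  # the dominant eigenvalue is 1 + 0i, not merely of unit magnitude
  lead <- sapply(et$fits, function(f) f$eigenvalues[1])
  expect_true(all(Mod(lead - 1) < 1e-6))
})

test_that("period-lag multipliers match the AR(1) closed form", {
  set.seed(30)
  phi <- 0.98; Tt <- 50
  doms <- replicate(25, {
    x <- as.numeric(arima.sim(list(ar = phi), 1500))
    s <- uniform_series(seq_along(x), x)
    p <- build_delay_pair(s, 1, embedding_config(m = 1, T_steps = Tt,
                                                 window_len = 1450))
    spectral_radius(fit_dmd(p, rank = 1))
  })
  se <- stats::sd(doms) / sqrt(length(doms))
  expect_lt(abs(mean(doms) - phi^Tt), 3 * se + 0.01)
})

test_that("rolling windows skip gappy stretches instead of failing", {
  set.seed(31)
  x <- rnorm(900)
  x[300:420] <- NA   # a hole larger than any window tolerates
  s <- uniform_series(1:900, x)
  cfg <- embedding_config(m = 2, tau = 5, T_steps = 50, window_len = 100,
                          stride = 50)
  et <- rolling_floquet(s, cfg, rank = 2)
  expect_gt(nrow(et$skipped), 0)
  expect_gt(length(et$fits), 2)
  expect_error(rolling_floquet(uniform_series(1:40, rnorm(40)), cfg),
               "shorter")
})

test_that("track matching chains identical and drifting spectra correctly", {
  # identical spectra: every track spans both windows with zero jump
  sp <- list(c(1 + 0i, 0.5 + 0.2i, 0.1 + 0i),
             c(1 + 0i, 0.5 + 0.2i, 0.1 + 0i))
  et <- match_tracks(fake_eigen_track(sp))
  expect_length(et$tracks, 3L)
  expect_true(all(sapply(et$tracks, nrow) == 2L))

  # an eigenvalue present only in window 2 opens a new track there
  sp2 <- list(c(1 + 0i), c(1 + 0i, 0.4 + 0i))
  et2 <- match_tracks(fake_eigen_track(sp2))
  lens <- sapply(et2$tracks, nrow)
  births <- sapply(et2$tracks, function(tr) tr$window[1])
  expect_setequal(lens, c(2L, 1L))
  expect_true(any(births == 2L))

  # slow drift with permuted storage order: chains equal the ground truth
  set.seed(32)
  true_paths <- list(0.9 + 0i, 0.5 + 0.3i, 0.2 - 0.1i)
  n_w <- 12
  spectra <- list(); truth <- matrix(NA_complex_, n_w, 3)
  for (w in seq_len(n_w)) {
    vals <- sapply(seq_along(true_paths), function(k)
      true_paths[[k]] + (w - 1) * 0.008 * k + 0.002i * w)
    truth[w, ] <- vals
    spectra[[w]] <- sample(vals)   # storage order permuted
  }
  etd <- match_tracks(fake_eigen_track(spectra), max_jump = 0.1)
  full <- Filter(function(tr) nrow(tr) == n_w, etd$tracks)
  expect_length(full, 3L)
  for (tr in full) {
    got <- sapply(seq_len(n_w), function(r)
      spectra[[tr$window[r]]][tr$eig[r]])
    k <- which.min(Mod(truth[1, ] - got[1]))
    expect_true(all(Mod(got - truth[, k]) < 1e-9))
  }
  # greedy and exhaustive-assignment matching agree on these small spectra
  eto <- match_tracks(fake_eigen_track(spectra), max_jump = 0.1,
                      method = "optimal")
  expect_equal(sort(sapply(eto$tracks, nrow)), sort(sapply(etd$tracks, nrow)))
})

test_that("classification labels seasonal, candidate, and noise tracks", {
  n_w <- 10
  seas <- rep(1 + 0i, n_w)
  rising <- complex(real = seq(0.6, 0.95, length.out = n_w))
  spectra <- lapply(seq_len(n_w), function(w) c(seas[w], rising[w]))
  et <- classify_tracks(match_tracks(fake_eigen_track(spectra)))
  expect_setequal(et$labels, c("seasonal", "csd_candidate"))
  # filtered max excludes the seasonal eigenvalue
  expect_equal(et$filtered_max, Re(rising), tolerance = 1e-12)

  # all-low spectra are noise
  low <- lapply(1:6, function(w) c(0.25 + 0i, 0.1 + 0.05i))
  et2 <- classify_tracks(match_tracks(fake_eigen_track(low)))
  expect_true(all(et2$labels == "noise"))
  expect_true(all(et2$filtered_max < 0.3))

  # a track at 1.0 covering only 40% of windows is not seasonal
  spectra3 <- lapply(1:10, function(w)
    if (w <= 4) c(1 + 0i, 0.3 + 0i) else c(0.3 + 0i))
  et3 <- classify_tracks(match_tracks(fake_eigen_track(spectra3)),
                         min_coverage = 0.8)
  expect_false("seasonal" %in% et3$labels)
})

test_that("crossing detection requires persistence", {
  mk <- function(fm) {
    et <- fake_eigen_track(lapply(fm, function(v) complex(real = v)))
    et$filtered_max <- fm
    et
  }
  expect_equal(detect_crossing(mk(c(0.8, 0.9, 1.01, 1.02, 1.05)),
                               persistence = 2), 3)
  expect_true(is.na(detect_crossing(mk(c(0.8, 1.2, 0.7, 0.8)),
                                    persistence = 2)))
  expect_true(is.na(detect_crossing(mk(c(0.8, 0.9, 0.95)))))
})

test_that("spatial modes are recovered from planted low-rank fields", {
  set.seed(33)
  ny <- nx <- 12; d <- ny * nx; nt <- 100
  v1 <- rep(0, d); v1[1:(d / 2)] <- runif(d / 2, 0.5, 1)
  v2 <- rep(0, d); v2[(d / 2 + 1):d] <- runif(d / 2, 0.5, 1)
  # rank-1 field v(x) 0.9^t: extracted mode proportional to |v|
  X1 <- outer(v1, 0.9^(1:nt))
  f1 <- st_field(X1, 1:nt, ny, nx)
  fit1 <- fit_dmd(build_delay_pair(
    f1, 1, embedding_config(m = 1, T_steps = 1, window_len = 60)), rank = 1)
  m1 <- extract_spatial_mode(fit1, d, 1)
  expect_gt(cosine_sim(m1$values, abs(v1)), 0.999)

  # two orthogonal planted modes with distinct decay rates plus noise
  X2 <- outer(v1, 0.9^(1:nt)) + outer(v2, 5 * 0.6^(1:nt))
  X2 <- X2 + 0.3 * sd(X2) * matrix(rnorm(d * nt), d, nt)
  f2 <- st_field(X2, 1:nt, ny, nx)
  fit2 <- fit_dmd(build_delay_pair(
    f2, 1, embedding_config(m = 1, T_steps = 1, window_len = 60)), rank = 2)
  mA <- extract_spatial_mode(fit2, d, 1)
  mB <- extract_spatial_mode(fit2, d, 2)
  # descending order: eigenvalue ~0.9 first (pattern v1), ~0.6 second
  expect_gt(cosine_sim(mA$values, abs(v1)), 0.99)
  expect_gt(cosine_sim(mB$values, abs(v2)), 0.99)
  expect_lt(cosine_sim(mA$values, abs(v2)), 0.1)
  expect_lt(cosine_sim(mB$values, abs(v1)), 0.1)
  expect_error(extract_spatial_mode(fit2, d, 5), "range")

  # delay-embedded fit: only the first spatial block is analyzed
  fit3 <- fit_dmd(build_delay_pair(
    f1, 1, embedding_config(m = 2, tau = 2, T_steps = 1, window_len = 60)),
    rank = 1)
  m3 <- extract_spatial_mode(fit3, d, 1)
  expect_length(m3$values, d)
  expect_gt(cosine_sim(m3$values, abs(v1)), 0.999)
})

test_that("mode change maps localize planted shifts and vanish when static", {
  ny <- nx <- 6; d <- ny * nx; n_w <- 10
  region_a <- 1:(d / 2); region_b <- (d / 2 + 1):d
  mk_mode <- function(wA, wB) {
    v <- numeric(d); v[region_a] <- wA; v[region_b] <- wB
    v / sqrt(sum(v^2))
  }
  static <- lapply(1:n_w, function(w)
    matrix(complex(real = mk_mode(1, 0.2)), ncol = 1))
  spectra <- lapply(1:n_w, function(w) c(0.8 + 0i))
  et <- fake_eigen_track(spectra, modes = static)
  et$is_field <- TRUE; et$d <- d; et$grid <- c(ny, nx)
  et$mask <- rep(TRUE, d)
  et$tracks <- list(data.frame(window = 1:n_w, eig = rep(1L, n_w)))
  et$labels <- "csd_candidate"
  m_static <- mode_change_map(et, 1:3, 8:10)
  expect_lt(max(abs(m_static)), 0.02)

  shifting <- lapply(1:n_w, function(w) {
    frac <- (w - 1) / (n_w - 1)
    matrix(complex(real = mk_mode(1 - 0.8 * frac, 0.2 + 0.8 * frac)),
           ncol = 1)
  })
  et$fits <- fake_eigen_track(spectra, modes = shifting)$fits
  m_shift <- mode_change_map(et, 1:3, 8:10)
  # row-major cell order: the first half of cells are the top grid rows
  # (region A, losing weight), the second half the bottom rows (region B)
  expect_true(all(m_shift[1:(ny / 2), ] < 0))
  expect_true(all(m_shift[(ny / 2 + 1):ny, ] > 0))
})
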