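# Independent oracles used across the suite. These are deliberately written
# from scratch (loops, brute force, closed forms) so they share no code with
# the implementation paths they check.

# brute-force histogram mutual information (nats) at one lag
brute_ami <- function(x, lag, n_bins = 16L) {
  rng <- range(x)
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  cut2 <- function(v) pmin(pmax(findInterval(v, br, rightmost.closed = TRUE),
                                1L), n_bins)
  a <- cut2(x[seq_len(length(x) - lag)])
  b <- cut2(x[seq_len(length(x) - lag) + lag])
  joint <- matrix(0, n_bins, n_bins)
  for (k in seq_along(a)) joint[a[k], b[k]] <- joint[a[k], b[k]] + 1
  p <- joint / sum(joint)
  total <- 0
  for (i in seq_len(n_bins)) for (j in seq_len(n_bins)) {
    if (p[i, j] > 0)
      total <- total + p[i, j] * log(p[i, j] / (sum(p[i, ]) * sum(p[, j])))
  }
  total
}

# brute-force double-sum Moran's I with rook weights
brute_moran <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  z <- m - mean(m)
  num <- 0; s0 <- 0
  for (i1 in 1:ny) for (j1 in 1:nx) for (i2 in 1:ny) for (j2 in 1:nx) {
    w <- as.integer(abs(i1 - i2) + abs(j1 - j2) == 1)
    num <- num + w * z[i1, j1] * z[i2, j2]
    s0 <- s0 + w
  }
  (ny * nx / s0) * num / sum(z^2)
}

# independently written Euler iteration of the seasonal pitchfork drift
oracle_pitchfork_euler <- function(p_fun, A, omega, x0, dt, n_steps) {
  x <- numeric(n_steps)
  cur <- x0
  for (i in seq_len(n_steps)) {
    t <- (i - 1) * dt
    cur <- cur + (p_fun(t) * cur - cur^3 + A * cos(omega * t)) * dt
    x[i] <- cur
  }
  x
}

# noiseless trajectory matrix of a linear map, one column per snapshot
linear_trajectory <- function(A0, x0, n_steps) {
  d <- nrow(A0)
  out <- matrix(NA_real_, d, n_steps)
  out[, 1] <- x0
  for (k in 2:n_steps) out[, k] <- A0 %*% out[, k - 1]
  out
}

# random stable matrix with spectral radius `rho`
random_stable_matrix <- function(d, rho = 0.8) {
  A0 <- matrix(stats::rnorm(d * d), d, d)
  A0 / max(Mod(eigen(A0, only.values = TRUE)$values)) * rho
}

# delay pair assembled directly from a raw matrix (bypasses the builders)
raw_pair <- function(X, Y, center = FALSE) {
  structure(list(X = X, Y = Y, t_start = 1L,
                 config = list(center = center), d = nrow(X)),
            class = "delay_pair")
}

# hand-built eigen_track from a list of per-window complex spectra
fake_eigen_track <- function(spectra, times = seq_along(spectra),
                             modes = NULL) {
  fits <- lapply(seq_along(spectra), function(i) {
    structure(list(eigenvalues = spectra[[i]],
                   modes = if (is.null(modes)) NULL else modes[[i]],
                   rank_used = length(spectra[[i]]), t_start = i),
              class = "dmd_fit")
  })
  structure(list(window_times = times, t_starts = seq_along(spectra),
                 fits = fits, config = NULL,
                 skipped = data.frame(t_start = integer(0),
                                      reason = character(0)),
                 is_field = FALSE, d = 1L, grid = NULL, mask = NULL,
                 tracks = NULL, labels = NULL, filtered_max = NULL,
                 crossing_time = NA_real_),
            class = "eigen_track")
}

cosine_sim <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

# first strict local minimum of a vector (independent of select_tau)
oracle_first_local_min <- function(v) {
  for (k in 2:(length(v) - 1L))
    if (v[k] < v[k - 1L] && v[k] < v[k + 1L]) return(k)
  NA_integer_
}
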