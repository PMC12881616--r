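#' Delay-embedding parameter selection and window matrices
#'
#' Utilities to choose the delay `tau` (first minimum of the average mutual
#' information), the embedding dimension `m` (false-nearest-neighbor
#' fraction), and to assemble the period-lagged, delay-embedded snapshot
#' matrices `X` and `Y` analyzed by the DMD operator fit.
#'
#' @name embedding
NULL

#' Embedding and window configuration
#'
#' @param m Embedding dimension (number of delay levels).
#' @param tau Delay between levels, in steps.
#' @param T_steps Period lag `T`, in steps: each column of `Y` is the state
#'   exactly `T_steps` after the matching column of `X`.
#' @param window_len Number of columns `n` per analysis window.
#' @param stride Step between window starts; defaults to 1/8 of
#'   `window_len`.
#' @param center If `TRUE`, the row means of the combined columns of `X`
#'   and `Y` are subtracted from both matrices.
#' @return An `embedding_config` object.
#' @export
embedding_config <- function(m, tau = 1L, T_steps, window_len,
                             stride = max(1L, window_len %/% 8L),
                             center = FALSE) {
  m <- as.integer(m); tau <- as.integer(tau)
  T_steps <- as.integer(T_steps); window_len <- as.integer(window_len)
  stride <- as.integer(stride)
  if (m < 1L) stop("`m` must be >= 1")
  if (m > 1L && tau < 1L) stop("`tau` must be >= 1 when m > 1")
  if (T_steps < 1L) stop("`T_steps` must be >= 1")
  if (window_len < m) stop("`window_len` must be >= m (rank feasibility)")
  if (stride < 1L) stop("`stride` must be >= 1")
  structure(list(m = m, tau = tau, T_steps = T_steps,
                 window_len = window_len, stride = stride,
                 center = isTRUE(center)),
            class = "embedding_config")
}

# span of raw samples consumed by one window (X plus the period-lagged Y)
config_span <- function(config) {
  config$T_steps + (config$m - 1L) * config$tau + config$window_len
}

#' Average mutual information across lags
#'
#' Histogram estimator of the mutual information (in nats) between the
#' series and its lagged copy, using `n_bins` equal-width bins over the
#' finite range. Lag 0 returns the entropy of the binned marginal.
#'
#' @param series A `uniform_series` (or bare numeric vector).
#' @param max_lag Largest lag (steps) to evaluate.
#' @param n_bins Number of histogram bins.
#' @return Numeric vector of AMI values for lags `0:max_lag` (named by lag).
#' @export
average_mutual_information <- function(series, max_lag, n_bins = 16L) {
  x <- if (inherits(series, "uniform_series")) series$value else as.numeric(series)
  if (max_lag >= length(x) / 2)
    stop("`max_lag` must be below half the series length")
  fin <- is.finite(x)
  if (sum(fin) < 10L * n_bins)
    stop("series too short: need at least 10 * n_bins finite values")
  rng <- range(x[fin])
  if (diff(rng) == 0) stop("degenerate input: series is constant")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  bin[!fin] <- NA_integer_
  n <- length(x)
  ami <- vapply(0:max_lag, function(lag) {
    i <- seq_len(n - lag)
    b1 <- bin[i]; b2 <- bin[i + lag]
    ok <- !is.na(b1) & !is.na(b2)
    joint <- table(factor(b1[ok], levels = seq_len(n_bins)),
                   factor(b2[ok], levels = seq_len(n_bins)))
    p <- joint / sum(joint)
    px <- rowSums(p); py <- colSums(p)
    nz <- p > 0
    sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
  }, numeric(1))
  names(ami) <- 0:max_lag
  ami
}

#' Select the delay from an AMI curve
#'
#' Returns the lag of the first strict local minimum of the AMI curve over
#' positive lags. If no local minimum exists, falls back to the first lag
#' where the AMI drops below `AMI(1)/e`; failing that, returns 1.
#'
#' @param ami_curve Numeric vector of AMI values. If named `0, 1, 2, ...`
#'   (as returned by [average_mutual_information()]) the lag-0 entry is
#'   dropped; otherwise the vector is taken to start at lag 1.
#' @return Selected delay (integer steps).
#' @export
select_tau <- function(ami_curve) {
  if (length(ami_curve) == 0L) stop("empty AMI curve")
  if (!is.null(names(ami_curve)) && names(ami_curve)[1] == "0")
    ami_curve <- ami_curve[-1]
  v <- as.numeric(ami_curve)
  L <- length(v)
  if (L >= 3L)
    for (k in 2:(L - 1L))
      if (v[k] < v[k - 1L] && v[k] < v[k + 1L]) return(k)
  below <- which(v < v[1] / exp(1))
  if (length(below) > 0L) return(below[1])
  1L
}

#' False-nearest-neighbor fraction per embedding dimension
#'
#' For each `m` in `1:m_max`, embeds the series with delay `tau`, finds each
#' point's nearest neighbor, and flags the neighbor as false when the
#' distance grows by more than a factor `r_tol` upon extending the embedding
#' to `m + 1`. Low fractions indicate that `m` dimensions suffice to unfold
#' the attractor.
#'
#' @param series A `uniform_series` (or numeric vector) without missing
#'   values in the embedded range.
#' @param tau Delay (steps).
#' @param m_max Largest embedding dimension tested.
#' @param r_tol Distance-growth ratio above which a neighbor is false.
#' @return Numeric vector of false-neighbor fractions for `m = 1:m_max`.
#' @export
false_nearest_fraction <- function(series, tau, m_max, r_tol = 10) {
  x <- if (inherits(series, "uniform_series")) series$value else as.numeric(series)
  tau <- as.integer(tau); m_max <- as.integer(m_max)
  if (length(x) < (m_max - 1L) * tau + 2L)
    stop("series too short to embed at m_max")
  fractions <- numeric(m_max)
  for (m in seq_len(m_max)) {
    # points usable at dimension m + 1 (need the extension coordinate)
    n_pts <- length(x) - m * tau
    if (n_pts < 2L) stop("series too short to embed at m_max")
    emb <- sapply(0:(m - 1L), function(k) x[(1:n_pts) + k * tau])
    if (m == 1L) emb <- matrix(emb, ncol = 1L)
    dmat <- as.matrix(stats::dist(emb))
    diag(dmat) <- Inf
    # exact recurrences (e.g. noiseless periodic signals) revisit the same
    # embedded state to rounding error; such pairs carry no geometric
    # information and are excluded as neighbor candidates
    tol <- 1e-8 * stats::sd(x)
    dmat[dmat < tol] <- Inf
    nn <- apply(dmat, 1L, which.min)
    r_m <- dmat[cbind(seq_len(n_pts), nn)]
    usable <- is.finite(r_m)
    if (!any(usable)) stop("degenerate input: all neighbor pairs recur")
    ext <- abs(x[(1:n_pts) + m * tau] - x[nn + m * tau])
    fractions[m] <- mean((ext / r_m > r_tol)[usable])
  }
  fractions
}

#' Build the period-lagged delay-pair matrices for one window
#'
#' Assembles `X` (and its period-lagged partner `Y`) for the window whose
#' first column sits at step index `t_start`. For scalar series, row `k`
#' (0-based) of `X` holds `x[t + k tau]`; for a field with `d` valid cells,
#' delay levels are stacked level-major: rows `[k d + 1, (k + 1) d]` hold
#' the `k`-th delay of all `d` cells, so rows `1:d` are the un-lagged
#' snapshot. `Y` is the same construction shifted by `T_steps`.
#'
#' @param data A `uniform_series` or `st_field`.
#' @param t_start 1-based step index of the first column of `X`.
#' @param config An [embedding_config()].
#' @param na_action `"error"` aborts on missing entries; `"drop"` removes
#'   (paired) columns containing any missing value from both matrices.
#' @return A `delay_pair` with matrices `X`, `Y`, the window time
#'   `t_start`, and the configuration.
#' @export
build_delay_pair <- function(data, t_start, config,
                             na_action = c("error", "drop")) {
  na_action <- match.arg(na_action)
  stopifnot(inherits(config, "embedding_config"))
  t_start <- as.integer(t_start)
  if (inherits(data, "uniform_series")) {
    vals <- matrix(data$value, nrow = 1L)
  } else if (inherits(data, "st_field")) {
    vals <- data$values[data$mask, , drop = FALSE]
  } else stop("`data` must be a uniform_series or st_field")
  d <- nrow(vals)
  n_t <- ncol(vals)
  span <- config_span(config)
  if (t_start < 1L || t_start + span - 1L > n_t)
    stop("window does not fit inside the data")
  cols <- t_start + 0:(config$window_len - 1L)
  lags <- (0:(config$m - 1L)) * config$tau
  stack <- function(offset) {
    do.call(rbind, lapply(lags, function(k)
      vals[, cols + k + offset, drop = FALSE]))
  }
  X <- stack(0L)
  Y <- stack(config$T_steps)
  bad <- colSums(!is.finite(X)) + colSums(!is.finite(Y)) > 0
  if (any(bad)) {
    if (na_action == "error")
      stop("missing values inside the delay-pair window")
    X <- X[, !bad, drop = FALSE]
    Y <- Y[, !bad, drop = FALSE]
    if (ncol(X) < config$m) stop("too few complete columns after dropping")
  }
  if (config$center) {
    rm <- rowMeans(cbind(X, Y))
    X <- X - rm
    Y <- Y - rm
  }
  structure(list(X = X, Y = Y, t_start = t_start, config = config, d = d),
            class = "delay_pair")
}
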