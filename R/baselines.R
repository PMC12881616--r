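#' Baseline critical-slowing-down indicators
#'
#' Reference indicators the Floquet analysis is compared against: rolling
#' lag-1 autocorrelation, variance, and a regression-based restoring rate
#' for scalar series; spatial variance, spatial skewness, Moran's I, and a
#' rolling temporal-autocorrelation map for fields. Rolling windows are
#' trailing (right-aligned) and reported at their end time, the usual
#' convention in early-warning analysis.
#'
#' @name baselines
NULL

#' Rolling early-warning indicator of a scalar series
#'
#' @param series A `uniform_series`.
#' @param window_len Window length (steps); windows with fewer than 10
#'   finite points give a missing value.
#' @param which One of `"ac1"` (lag-1 Pearson autocorrelation),
#'   `"variance"` (sample variance, denominator `n - 1`), or
#'   `"restoring_rate"` (OLS slope of one-step increments on the state,
#'   approximately the recovery rate times the sampling step; negative for
#'   stable systems).
#' @param stride Step between evaluated windows.
#' @return An `indicator_series` with `window_times` (window end times) and
#'   `values`.
#' @export
rolling_indicator <- function(series, window_len,
                              which = c("ac1", "variance", "restoring_rate"),
                              stride = 1L) {
  which <- match.arg(which)
  stopifnot(inherits(series, "uniform_series"))
  window_len <- as.integer(window_len)
  if (window_len < 10L) stop("`window_len` must be at least 10")
  x <- series$value
  n <- length(x)
  if (n < window_len) stop("series shorter than one window")
  ends <- seq(window_len, n, by = stride)
  f <- switch(which,
    ac1 = function(w) {
      w <- w[is.finite(w)]
      if (length(w) < 10L || stats::sd(w) == 0) return(NA_real_)
      stats::cor(w[-1], w[-length(w)])
    },
    variance = function(w) {
      w <- w[is.finite(w)]
      if (length(w) < 10L) return(NA_real_)
      stats::var(w)
    },
    restoring_rate = function(w) {
      w <- w[is.finite(w)]
      if (length(w) < 10L || stats::sd(w) == 0) return(NA_real_)
      dx <- diff(w)
      xs <- w[-length(w)]
      sum((xs - mean(xs)) * (dx - mean(dx))) / sum((xs - mean(xs))^2)
    })
  vals <- vapply(ends, function(e) f(x[(e - window_len + 1L):e]), numeric(1))
  structure(list(window_times = series$time[ends], values = vals,
                 indicator_name = which, window_len = window_len),
            class = "indicator_series")
}

#' @export
print.indicator_series <- function(x, ...) {
  cat(sprintf("<indicator_series> %s, %d windows of %d steps\n",
              x$indicator_name, length(x$values), x$window_len))
  invisible(x)
}

#' Remove seasonality (and trend) from a series
#'
#' Two deseasoning routes used in the early-warning literature:
#' `"stl"` delegates to seasonal-trend decomposition via loess
#' ([stats::stl()] with a periodic seasonal window) and returns the
#' remainder; `"climatology_rolling"` subtracts the long-term mean of each
#' seasonal phase (e.g. each calendar month), then a centered rolling mean
#' of width `trend_window`.
#'
#' @param series A `uniform_series` covering at least two full periods.
#' @param method `"stl"` or `"climatology_rolling"`.
#' @param period Season length in steps.
#' @param trend_window Rolling-mean width (steps) for
#'   `"climatology_rolling"`; defaults to five periods.
#' @return The residual as a `uniform_series`.
#' @export
deseason <- function(series, method = c("stl", "climatology_rolling"),
                     period, trend_window = 5L * period) {
  method <- match.arg(method)
  stopifnot(inherits(series, "uniform_series"))
  period <- as.integer(period)
  x <- series$value
  if (period > length(x) / 2)
    stop("`period` must not exceed half the series length")
  if (method == "stl") {
    filled <- x
    if (anyNA(filled))
      filled <- as.numeric(zoo::na.approx(zoo::zoo(filled), na.rm = FALSE))
    fit <- stats::stl(stats::ts(filled, frequency = period),
                      s.window = "periodic")
    resid <- as.numeric(fit$time.series[, "remainder"])
    resid[is.na(x)] <- NA_real_
  } else {
    phase <- ((seq_along(x) - 1L) %% period) + 1L
    clim <- tapply(x, phase, mean, na.rm = TRUE)
    resid <- x - clim[phase]
    resid <- resid - rollmean_centered(resid, as.integer(trend_window))
  }
  uniform_series(series$time, resid)
}

# centered rolling mean with shrinking (partial) edge windows, O(n)
rollmean_centered <- function(x, w) {
  n <- length(x)
  if (anyNA(x)) {
    return(as.numeric(zoo::rollapply(zoo::zoo(x), w, mean, na.rm = TRUE,
                                     partial = TRUE, align = "center")))
  }
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# lag-1 autocorrelation of every row of a matrix (NA-propagating)
row_ac1 <- function(B) {
  n <- ncol(B)
  x <- B[, -n, drop = FALSE]
  y <- B[, -1L, drop = FALSE]
  mx <- rowMeans(x); my <- rowMeans(y)
  sxy <- rowSums((x - mx) * (y - my))
  sxx <- rowSums((x - mx)^2)
  syy <- rowSums((y - my)^2)
  out <- sxy / sqrt(sxx * syy)
  out[sxx == 0 | syy == 0] <- NA_real_
  out
}

#' Moran's I spatial autocorrelation of one snapshot
#'
#' Standard Moran's I, `(N / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2`, with
#' symmetric, row-unnormalized rook (4-neighbor) adjacency weights and
#' non-periodic boundaries. `NA` cells are excluded (adjacency is built
#' among valid cells only).
#'
#' @param snapshot Numeric matrix (`ny` by `nx`).
#' @return Moran's I value.
#' @export
morans_i <- function(snapshot) {
  snapshot <- as.matrix(snapshot)
  valid <- is.finite(snapshot)
  if (sum(valid) < 2L) stop("need at least two valid cells")
  z <- snapshot - mean(snapshot[valid])
  if (sum(z[valid]^2) == 0) stop("degenerate input: zero spatial variance")
  ny <- nrow(snapshot); nx <- ncol(snapshot)
  num <- 0; s0 <- 0
  # horizontal and vertical neighbor pairs, each counted in both directions
  h1 <- valid[, -nx] & valid[, -1]
  v1 <- valid[-ny, ] & valid[-1, ]
  num <- 2 * (sum((z[, -nx] * z[, -1])[h1]) + sum((z[-ny, ] * z[-1, ])[v1]))
  s0 <- 2 * (sum(h1) + sum(v1))
  if (s0 == 0) stop("no adjacent valid cell pairs")
  (sum(valid) / s0) * num / sum(z[valid]^2)
}

#' Spatial early-warning indicator suite of a field
#'
#' Per snapshot: spatial variance, bias-corrected spatial skewness, and
#' Moran's I over valid cells (undefined values recorded as missing).
#' Per cell: trailing rolling lag-1 autocorrelation over `ac_window`
#' snapshots, summarized by the domain mean. When a deseason method is
#' given, all indicators operate on the per-cell residuals.
#'
#' @param field An `st_field`.
#' @param ac_window Temporal autocorrelation window (snapshots).
#' @param deseason_method `NULL`, `"stl"` or `"climatology_rolling"`,
#'   applied cell-wise before the indicators.
#' @param period,trend_window Passed to [deseason()] when used.
#' @param ac_stride Step (snapshots) between evaluations of the
#'   autocorrelation map; intermediate snapshots get `NA`.
#' @return A `spatial_ews` object with `snapshot_times`, `spatial_variance`,
#'   `spatial_skewness`, `morans_i`, and `temporal_ac1` (domain mean;
#'   `NA` before the first full window).
#' @export
spatial_ews <- function(field, ac_window, deseason_method = NULL,
                        period = NULL, trend_window = NULL,
                        ac_stride = 1L) {
  stopifnot(inherits(field, "st_field"))
  ac_window <- as.integer(ac_window)
  vals <- field$values[field$mask, , drop = FALSE]
  n_t <- ncol(vals)
  if (n_t < ac_window) stop("field has fewer snapshots than `ac_window`")
  if (!is.null(deseason_method)) {
    if (is.null(period)) stop("`period` is required for deseasoning")
    tw <- if (is.null(trend_window)) 5L * period else trend_window
    for (i in seq_len(nrow(vals))) {
      s <- uniform_series(field$time, vals[i, ])
      vals[i, ] <- deseason(s, deseason_method, period, tw)$value
    }
  }
  sv <- apply(vals, 2L, stats::var, na.rm = TRUE)
  sk <- apply(vals, 2L, function(col) {
    col <- col[is.finite(col)]
    if (length(col) < 3L || stats::sd(col) == 0) return(NA_real_)
    e1071::skewness(col, type = 2L)
  })
  ny <- field$ny; nx <- field$nx
  mi <- vapply(seq_len(n_t), function(j) {
    full <- rep(NA_real_, ny * nx)
    full[field$mask] <- vals[, j]
    snap <- matrix(full, ny, nx, byrow = TRUE)
    tryCatch(morans_i(snap), error = function(e) NA_real_)
  }, numeric(1))
  # per-cell trailing AC1, then domain mean
  ac <- rep(NA_real_, n_t)
  for (e in seq(ac_window, n_t, by = as.integer(ac_stride))) {
    idx <- (e - ac_window + 1L):e
    ac[e] <- mean(row_ac1(vals[, idx, drop = FALSE]), na.rm = TRUE)
  }
  structure(list(snapshot_times = field$time, spatial_variance = sv,
                 spatial_skewness = sk, morans_i = mi, temporal_ac1 = ac,
                 ac_window = ac_window,
                 deseason_method = deseason_method %||% "none"),
            class = "spatial_ews")
}

#' @export
print.spatial_ews <- function(x, ...) {
  cat(sprintf("<spatial_ews> %d snapshots, AC window %d, deseason: %s\n",
              length(x$snapshot_times), x$ac_window, x$deseason_method))
  invisible(x)
}
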