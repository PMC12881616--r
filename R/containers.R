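#' Uniformly sampled scalar series
#'
#' The atom of 1D analysis: a scalar state variable sampled on a uniform time
#' grid, with `NA` marking missing observations. Uniform spacing is required
#' because period lags and delay embeddings are expressed in integer steps.
#'
#' @param time Numeric vector of sample times, strictly increasing and
#'   uniformly spaced (relative tolerance 1e-6 on the step).
#' @param value Numeric vector of the same length; `NA` = missing.
#' @return An object of class `uniform_series` with fields `time`, `value`
#'   and attribute-like field `dt` (the sampling step).
#' @export
uniform_series <- function(time, value) {
  time <- as.numeric(time)
  value <- as.numeric(value)
  if (length(time) != length(value))
    stop("`time` and `value` must have the same length")
  if (length(time) < 2L)
    stop("a uniform series needs at least two samples")
  steps <- diff(time)
  dt <- stats::median(steps)
  if (dt <= 0 || any(abs(steps - dt) > 1e-6 * max(abs(dt), 1)))
    stop("`time` must be strictly increasing and uniformly spaced")
  structure(list(time = time, value = value, dt = dt),
            class = "uniform_series")
}

#' @export
print.uniform_series <- function(x, ...) {
  n_na <- sum(is.na(x$value))
  cat(sprintf("<uniform_series> %d samples, dt = %g, t in [%g, %g], %d missing\n",
              length(x$value), x$dt, x$time[1], x$time[length(x$time)], n_na))
  invisible(x)
}

#' @export
length.uniform_series <- function(x) length(x$value)

#' Spatio-temporal field
#'
#' Flattened spatial snapshots of one state variable on a regular `n_y` by
#' `n_x` grid. Cells are stored row-major (cell index `(iy - 1) * n_x + ix`),
#' one row per cell and one column per snapshot. A logical validity mask
#' flags cells that carry data; invalid cells are `NA` throughout.
#'
#' @param values Numeric matrix, `n_y * n_x` rows by `n_time` columns.
#' @param time Numeric vector of snapshot times (uniformly spaced).
#' @param ny,nx Grid dimensions.
#' @param mask Logical vector of length `n_y * n_x`; `TRUE` = valid cell.
#'   Defaults to all valid.
#' @return An object of class `st_field`.
#' @export
st_field <- function(values, time, ny, nx, mask = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ny * nx)
    stop("`values` must have ny * nx rows (row-major cell order)")
  if (ncol(values) != length(time))
    stop("`values` must have one column per element of `time`")
  if (ny < 2L || nx < 2L) stop("grid dimensions must be at least 2")
  if (is.null(mask)) mask <- rep(TRUE, ny * nx)
  if (length(mask) != ny * nx) stop("`mask` must have length ny * nx")
  steps <- diff(time)
  dt <- stats::median(steps)
  if (dt <= 0 || any(abs(steps - dt) > 1e-6 * max(abs(dt), 1)))
    stop("`time` must be strictly increasing and uniformly spaced")
  structure(list(values = values, time = time, ny = ny, nx = nx,
                 mask = as.logical(mask), dt = dt),
            class = "st_field")
}

#' @export
print.st_field <- function(x, ...) {
  cat(sprintf("<st_field> %d x %d grid (%d valid cells), %d snapshots, dt = %g\n",
              x$ny, x$nx, sum(x$mask), ncol(x$values), x$dt))
  invisible(x)
}

#' Thin a field or series in time
#'
#' Keeps every `every`-th sample (the last of each block, so daily saves
#' thinned by 30 yield end-of-month snapshots). Used to move from the
#' simulator's native sampling to a coarser analysis grid.
#'
#' @param x A `uniform_series` or `st_field`.
#' @param every Positive integer stride.
#' @return Object of the same class.
#' @export
thin_time <- function(x, every) {
  every <- as.integer(every)
  if (every < 1L) stop("`every` must be >= 1")
  if (inherits(x, "uniform_series")) {
    idx <- seq(every, length(x$value), by = every)
    uniform_series(x$time[idx], x$value[idx])
  } else if (inherits(x, "st_field")) {
    idx <- seq(every, ncol(x$values), by = every)
    st_field(x$values[, idx, drop = FALSE], x$time[idx], x$ny, x$nx, x$mask)
  } else stop("`x` must be a uniform_series or st_field")
}

#' Domain-mean series of a field
#'
#' @param field An `st_field`.
#' @return A `uniform_series` of the mean over valid cells per snapshot.
#' @export
field_mean_series <- function(field) {
  stopifnot(inherits(field, "st_field"))
  uniform_series(field$time,
                 colMeans(field$values[field$mask, , drop = FALSE], na.rm = TRUE))
}
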