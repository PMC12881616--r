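#' Plain-text I/O and resampling utilities
#'
#' Readers and writers for the package's on-disk formats (all plain text),
#' the consensus resampling procedure for irregularly sampled measurement
#' records, and the gap-filling policy applied before windowed analysis.
#'
#' Formats: scalar series are CSV with columns `time,value`; fields are
#' long-format CSV with columns `time,y,x,value` (`NA` for masked cells);
#' eigenvalue tracks are CSV with one row per (window, eigenvalue);
#' configurations are YAML; run summaries are JSON. Floats are written with
#' 17 significant digits so that write-then-read is exact.
#'
#' @name io
NULL

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' @param series A `uniform_series`.
#' @param path Output file path.
#' @export
#' @rdname io
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "uniform_series"))
  df <- data.frame(time = fmt_num(series$time), value = fmt_num(series$value))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
#' @rdname io
read_series_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("time", "value"))
    if (!col %in% names(df))
      stop(sprintf("malformed series CSV: missing column \"%s\"", col))
  uniform_series(as.numeric(df$time), as.numeric(df$value))
}

#' @param field An `st_field`.
#' @export
#' @rdname io
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "st_field"))
  d <- field$ny * field$nx
  iy <- rep(rep(seq_len(field$ny), each = field$nx), times = ncol(field$values))
  ix <- rep(rep(seq_len(field$nx), times = field$ny), times = ncol(field$values))
  tt <- rep(field$time, each = d)
  vals <- as.vector(field$values)
  vals[rep(!field$mask, times = ncol(field$values))] <- NA_real_
  df <- data.frame(time = fmt_num(tt), y = iy, x = ix, value = fmt_num(vals))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
#' @rdname io
read_field_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("time", "y", "x", "value"))
    if (!col %in% names(df))
      stop(sprintf("malformed field CSV: missing column \"%s\"", col))
  df$time <- as.numeric(df$time)
  times <- sort(unique(df$time))
  ny <- max(df$y); nx <- max(df$x)
  d <- ny * nx
  ord <- order(df$time, df$y, df$x)
  df <- df[ord, ]
  vals <- matrix(as.numeric(df$value), nrow = d)
  mask <- rowSums(is.na(vals)) < ncol(vals)
  st_field(vals, times, ny, nx, mask)
}

#' @param et An `eigen_track`.
#' @export
#' @rdname io
write_eigentrack_csv <- function(et, path) {
  stopifnot(inherits(et, "eigen_track"))
  rows <- list()
  track_of <- function(w, j) {
    if (is.null(et$tracks)) return(NA_integer_)
    for (i in seq_along(et$tracks)) {
      tr <- et$tracks[[i]]
      if (any(tr$window == w & tr$eig == j)) return(i)
    }
    NA_integer_
  }
  for (w in seq_along(et$fits)) {
    e <- et$fits[[w]]$eigenvalues
    for (j in seq_along(e)) {
      ti <- track_of(w, j)
      rows[[length(rows) + 1L]] <- data.frame(
        window_time = et$window_times[w], real = Re(e[j]), imag = Im(e[j]),
        magnitude = Mod(e[j]), track_id = ti,
        label = if (is.na(ti) || is.null(et$labels)) NA_character_
                else et$labels[ti])
    }
  }
  df <- do.call(rbind, rows)
  df$window_time <- fmt_num(df$window_time)
  df$real <- fmt_num(df$real); df$imag <- fmt_num(df$imag)
  df$magnitude <- fmt_num(df$magnitude)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
#' @rdname io
write_track_summary_json <- function(et, path) {
  stopifnot(inherits(et, "eigen_track"))
  terminal <- list()
  if (!is.null(et$labels)) {
    for (lab in unique(et$labels)) {
      idx <- which(et$labels == lab)
      mags <- vapply(idx, function(i) {
        tr <- et$tracks[[i]]
        r <- nrow(tr)
        Mod(window_eigs(et, tr$window[r])[tr$eig[r]])
      }, numeric(1))
      terminal[[lab]] <- max(mags)
    }
  }
  out <- list(n_windows = length(et$fits),
              n_skipped = nrow(et$skipped),
              crossing_time = if (is.na(et$crossing_time)) NULL
                              else et$crossing_time,
              terminal_magnitudes = terminal)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @param config A named list.
#' @export
#' @rdname io
write_config_yaml <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @export
#' @rdname io
read_config_yaml <- function(path) {
  yaml::read_yaml(path)
}

#' Consensus resampling of irregular measurement records
#'
#' Each record is an average over an interval `[t_begin, t_end]` and is
#' assigned to the midpoint of that interval. Midpoints are binned onto an
#' equally spaced grid of width `bin_width`; `k` is the minimum record count
#' over non-empty bins; each of `n_iter` iterations draws `k` records per
#' bin without replacement and averages them; the output value of a bin is
#' the mean over iterations (the plain bin mean when every bin holds exactly
#' `k` records). Empty bins are missing. Records are sorted before sampling
#' so the result is invariant to input order.
#'
#' @param samples Data frame with columns `t_begin`, `t_end`, `value`
#'   (times in days).
#' @param bin_width Bin width in days.
#' @param n_iter Number of random iterations.
#' @param seed RNG seed.
#' @return A `uniform_series` on bin centers.
#' @export
consensus_resample <- function(samples, bin_width, n_iter = 100L, seed = 1L) {
  if (is.null(samples) || nrow(samples) == 0L) stop("no samples")
  for (col in c("t_begin", "t_end", "value"))
    if (!col %in% names(samples))
      stop(sprintf("samples must have column \"%s\"", col))
  if (any(samples$t_end < samples$t_begin))
    stop("t_end must be >= t_begin")
  if (any(!is.finite(samples$value))) stop("values must be finite")
  if (n_iter < 1L) stop("`n_iter` must be >= 1")
  mid <- (samples$t_begin + samples$t_end) / 2
  ord <- order(mid, samples$value, samples$t_begin)
  mid <- mid[ord]; val <- samples$value[ord]
  edges <- seq(min(mid), max(mid) + bin_width, by = bin_width)
  bin <- findInterval(mid, edges, rightmost.closed = FALSE)
  n_bins <- length(edges) - 1L
  counts <- tabulate(bin, nbins = n_bins)
  occupied <- which(counts > 0L)
  k <- min(counts[occupied])
  set.seed(seed)
  acc <- matrix(NA_real_, n_iter, n_bins)
  for (it in seq_len(n_iter)) {
    for (b in occupied) {
      members <- which(bin == b)
      pick <- if (length(members) == k) members
              else members[sample.int(length(members), k)]
      acc[it, b] <- mean(val[pick])
    }
  }
  centers <- edges[-length(edges)] + bin_width / 2
  uniform_series(centers, colMeans(acc))
}

#' Fill short gaps by linear interpolation
#'
#' Runs of missing values no longer than `max_gap` are linearly
#' interpolated (per cell for fields); longer runs, and leading or trailing
#' missing stretches, are left missing and exclude overlapping windows in
#' the downstream analysis.
#'
#' @param x A `uniform_series` or `st_field`.
#' @param max_gap Longest run of missing steps that is filled.
#' @return Object of the same class.
#' @export
fill_gaps <- function(x, max_gap = 2L) {
  fill_vec <- function(v) {
    if (!anyNA(v)) return(v)
    filled <- as.numeric(zoo::na.approx(zoo::zoo(v), na.rm = FALSE,
                                        maxgap = max_gap))
    filled
  }
  if (inherits(x, "uniform_series")) {
    uniform_series(x$time, fill_vec(x$value))
  } else if (inherits(x, "st_field")) {
    vals <- x$values
    for (i in which(x$mask)) vals[i, ] <- fill_vec(vals[i, ])
    st_field(vals, x$time, x$ny, x$nx, x$mask)
  } else stop("`x` must be a uniform_series or st_field")
}
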