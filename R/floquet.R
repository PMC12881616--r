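#' Sliding-window Floquet multiplier estimation
#'
#' Slides period-lagged analysis windows over a series or field, fits a DMD
#' propagator per window, and collects the eigenvalue spectra into an
#' `eigen_track` for matching, labeling (seasonal / CSD candidate / noise),
#' crossing detection, and spatial-mode extraction.
#'
#' @param data A `uniform_series` or `st_field`.
#' @param config An [embedding_config()]; `config$T_steps` must equal the
#'   known period of the system in steps for the eigenvalues to be read as
#'   Floquet multipliers.
#' @param rank Passed to [fit_dmd()].
#' @param min_valid_frac Windows retaining fewer than this fraction of
#'   complete columns (after dropping columns with missing values) are
#'   recorded as gaps, not fitted.
#' @param ... Further arguments passed to [fit_dmd()].
#' @return An `eigen_track` with one `dmd_fit` per admissible window,
#'   window center times, and a record of skipped windows.
#' @export
rolling_floquet <- function(data, config, rank = "auto",
                            min_valid_frac = 0.8, ...) {
  stopifnot(inherits(config, "embedding_config"))
  is_field <- inherits(data, "st_field")
  n_t <- if (is_field) ncol(data$values) else length(data$value)
  span <- config_span(config)
  if (n_t < span)
    stop("data shorter than one window span (T + (m-1)*tau + n)")
  starts <- seq(1L, n_t - span + 1L, by = config$stride)
  fits <- list(); window_times <- numeric(0); fit_starts <- integer(0)
  skipped <- data.frame(t_start = integer(0), reason = character(0))
  time <- if (is_field) data$time else data$time
  for (ts in starts) {
    pair <- tryCatch(build_delay_pair(data, ts, config, na_action = "drop"),
                     error = function(e) e)
    if (inherits(pair, "error") ||
        ncol(pair$X) < min_valid_frac * config$window_len) {
      skipped <- rbind(skipped, data.frame(
        t_start = ts,
        reason = if (inherits(pair, "error")) conditionMessage(pair)
                 else "too many missing columns"))
      next
    }
    fit <- tryCatch(fit_dmd(pair, rank = rank, ...), error = function(e) e)
    if (inherits(fit, "error")) {
      skipped <- rbind(skipped,
                       data.frame(t_start = ts, reason = conditionMessage(fit)))
      next
    }
    fits[[length(fits) + 1L]] <- fit
    fit_starts <- c(fit_starts, ts)
    window_times <- c(window_times, (time[ts] + time[ts + span - 1L]) / 2)
  }
  if (length(fits) == 0L) stop("no valid windows")
  structure(list(window_times = window_times, t_starts = fit_starts,
                 fits = fits, config = config, skipped = skipped,
                 is_field = is_field,
                 d = if (is_field) sum(data$mask) else 1L,
                 grid = if (is_field) c(data$ny, data$nx) else NULL,
                 mask = if (is_field) data$mask else NULL,
                 tracks = NULL, labels = NULL, filtered_max = NULL,
                 crossing_time = NA_real_),
            class = "eigen_track")
}

#' @export
print.eigen_track <- function(x, ...) {
  cat(sprintf("<eigen_track> %d windows (%d skipped), %s data\n",
              length(x$fits), nrow(x$skipped),
              if (x$is_field) sprintf("%dx%d field", x$grid[1], x$grid[2])
              else "scalar"))
  if (!is.null(x$tracks))
    cat(sprintf("  %d tracks; labels: %s\n", length(x$tracks),
                paste(unique(x$labels), collapse = ", ")))
  if (!is.na(x$crossing_time))
    cat(sprintf("  threshold crossing at t = %g\n", x$crossing_time))
  invisible(x)
}

# eigenvalues of window i as a complex vector
window_eigs <- function(et, i) et$fits[[i]]$eigenvalues

#' Match eigenvalues across windows into tracks
#'
#' Chains eigenvalues of consecutive windows by nearest-neighbor distance in
#' the complex plane. Matches farther than `max_jump` are refused, ending
#' one track and starting another; unmatched eigenvalues open new tracks.
#' A track left unmatched may bridge up to `max_skip` windows and resume if
#' an eigenvalue within `max_jump` of its last value reappears (a single
#' glitched window then does not sever an otherwise continuous track).
#' `method = "optimal"` replaces the greedy pairing with the assignment
#' minimizing the total distance (exhaustive; intended for small spectra).
#'
#' @param et An `eigen_track` from [rolling_floquet()].
#' @param max_jump Largest complex-plane distance joined into one track.
#' @param max_skip Number of consecutive windows a track may be absent from
#'   without being closed.
#' @param method `"greedy"` (default) or `"optimal"`.
#' @return The `eigen_track` with `tracks` filled: a list of data frames
#'   with columns `window` and `eig` (eigenvalue index within the window).
#' @export
match_tracks <- function(et, max_jump = 0.2, max_skip = 1L,
                         method = c("greedy", "optimal")) {
  method <- match.arg(method)
  stopifnot(inherits(et, "eigen_track"))
  n_w <- length(et$fits)
  if (n_w < 2L) stop("need at least two windows to match tracks")
  tracks <- list()
  # open tracks carry their id, last matched value and last matched window
  open_id <- integer(0); open_val <- complex(0); open_win <- integer(0)
  e1 <- window_eigs(et, 1L)
  for (j in seq_along(e1)) {
    tracks[[j]] <- data.frame(window = 1L, eig = j)
    open_id <- c(open_id, j); open_val <- c(open_val, e1[j])
    open_win <- c(open_win, 1L)
  }
  for (i in 2L:n_w) {
    e_cur <- window_eigs(et, i)
    alive <- open_win >= i - 1L - max_skip
    open_id <- open_id[alive]; open_val <- open_val[alive]
    open_win <- open_win[alive]
    pairs <- match_spectra(open_val, e_cur, max_jump, method)
    matched_eig <- rep(FALSE, length(e_cur))
    matched_open <- rep(FALSE, length(open_id))
    for (row in seq_len(nrow(pairs))) {
      a <- pairs$from[row]; b <- pairs$to[row]
      id <- open_id[a]
      tracks[[id]] <- rbind(tracks[[id]], data.frame(window = i, eig = b))
      open_val[a] <- e_cur[b]; open_win[a] <- i
      matched_eig[b] <- TRUE; matched_open[a] <- TRUE
    }
    for (b in which(!matched_eig)) {
      id <- length(tracks) + 1L
      tracks[[id]] <- data.frame(window = i, eig = b)
      open_id <- c(open_id, id); open_val <- c(open_val, e_cur[b])
      open_win <- c(open_win, i)
    }
  }
  et$tracks <- tracks
  et
}

# pairing of two spectra: data.frame(from, to) with distances <= max_jump
match_spectra <- function(e1, e2, max_jump, method = "greedy") {
  dmat <- outer(e1, e2, function(a, b) Mod(a - b))
  dmat <- matrix(dmat, length(e1), length(e2))
  if (method == "optimal" && length(e1) <= 7L && length(e2) <= 7L) {
    # exhaustive assignment over the smaller side
    k <- min(length(e1), length(e2))
    perms <- all_perms(seq_along(if (length(e1) <= length(e2)) e2 else e1), k)
    best <- NULL; best_cost <- Inf
    for (p in perms) {
      if (length(e1) <= length(e2)) {
        cost <- sum(pmin(dmat[cbind(seq_len(k), p)], max_jump * 2))
        pairs <- data.frame(from = seq_len(k), to = p)
      } else {
        cost <- sum(pmin(dmat[cbind(p, seq_len(k))], max_jump * 2))
        pairs <- data.frame(from = p, to = seq_len(k))
      }
      if (cost < best_cost) { best_cost <- cost; best <- pairs }
    }
    keep <- dmat[cbind(best$from, best$to)] <= max_jump
    return(best[keep, , drop = FALSE])
  }
  pairs <- data.frame(from = integer(0), to = integer(0))
  used1 <- logical(length(e1)); used2 <- logical(length(e2))
  repeat {
    dmat[used1, ] <- Inf; dmat[, used2] <- Inf
    if (all(!is.finite(dmat)) || min(dmat) > max_jump) break
    idx <- arrayInd(which.min(dmat), dim(dmat))
    pairs <- rbind(pairs, data.frame(from = idx[1], to = idx[2]))
    used1[idx[1]] <- TRUE; used2[idx[2]] <- TRUE
    if (all(used1) || all(used2)) break
  }
  pairs
}

all_perms <- function(v, k) {
  if (k == 0L) return(list(integer(0)))
  out <- list()
  for (i in seq_along(v)) {
    rest <- all_perms(v[-i], k - 1L)
    for (r in rest) out[[length(out) + 1L]] <- c(v[i], r)
  }
  out
}

#' Label eigenvalue tracks and compute the filtered maximum
#'
#' A track is *seasonal* when it covers at least `min_coverage` of all
#' windows and its magnitude stays inside `[1 - seasonal_band,
#' 1 + seasonal_band]` in every window it covers: the signature of a stable
#' periodic cycle under a period lag. Tracks whose mean magnitude falls
#' below `noise_floor` are *noise*. Among the remainder, the track with the
#' largest terminal magnitude is the *csd_candidate*. The per-window
#' `filtered_max` is the largest magnitude over all eigenvalues not claimed
#' by a seasonal track (0 when a window has none).
#'
#' @param et An `eigen_track` with tracks matched.
#' @param seasonal_band Half-width `delta` of the seasonal magnitude band.
#' @param min_coverage Minimum fraction of windows a seasonal track must
#'   cover.
#' @param noise_floor Mean-magnitude floor below which a track is noise.
#' @return The `eigen_track` with `labels` (one per track) and
#'   `filtered_max` (one per window) filled.
#' @export
classify_tracks <- function(et, seasonal_band = 0.1, min_coverage = 0.9,
                            noise_floor = 0.5) {
  stopifnot(inherits(et, "eigen_track"))
  if (is.null(et$tracks)) stop("tracks not matched; call match_tracks() first")
  n_w <- length(et$fits)
  track_mags <- lapply(et$tracks, function(tr)
    vapply(seq_len(nrow(tr)), function(r)
      Mod(window_eigs(et, tr$window[r])[tr$eig[r]]), numeric(1)))
  labels <- character(length(et$tracks))
  for (i in seq_along(et$tracks)) {
    mags <- track_mags[[i]]
    coverage <- nrow(et$tracks[[i]]) / n_w
    if (coverage >= min_coverage &&
        all(abs(mags - 1) <= seasonal_band)) {
      labels[i] <- "seasonal"
    } else if (mean(mags) < noise_floor) {
      labels[i] <- "noise"
    } else {
      labels[i] <- "candidate"
    }
  }
  cand <- which(labels == "candidate")
  if (length(cand) > 0L) {
    terminal <- vapply(cand, function(i) {
      mags <- track_mags[[i]]
      mags[length(mags)]
    }, numeric(1))
    labels[cand] <- "other"
    labels[cand[which.max(terminal)]] <- "csd_candidate"
  }
  # per-window filtered maximum over non-seasonal eigenvalues
  seasonal_cells <- do.call(rbind, c(
    list(data.frame(window = integer(0), eig = integer(0))),
    et$tracks[labels == "seasonal"]))
  fm <- vapply(seq_len(n_w), function(i) {
    mags <- Mod(window_eigs(et, i))
    drop <- seasonal_cells$eig[seasonal_cells$window == i]
    if (length(drop) > 0L) mags <- mags[-drop]
    if (length(mags) == 0L) 0 else max(mags)
  }, numeric(1))
  et$labels <- labels
  et$filtered_max <- fm
  et
}

#' Detect a persistent stability-threshold crossing
#'
#' Scans the per-window filtered maximum magnitude for the earliest run of
#' `persistence` consecutive windows at or above `threshold`.
#'
#' @param et An `eigen_track` with `filtered_max` available (see
#'   [classify_tracks()]).
#' @param threshold Stability threshold (1 = Floquet stability boundary).
#' @param persistence Number of consecutive windows required.
#' @return The window time of the first window of the earliest qualifying
#'   run, or `NA_real_` when there is none.
#' @export
detect_crossing <- function(et, threshold = 1, persistence = 3L) {
  stopifnot(inherits(et, "eigen_track"))
  if (is.null(et$filtered_max))
    stop("filtered_max not available; call classify_tracks() first")
  above <- et$filtered_max >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= persistence)
  if (length(hit) == 0L) return(NA_real_)
  first <- ends[hit[1]] - r$lengths[hit[1]] + 1L
  et$window_times[first]
}

#' Extract the spatial mode of an eigenvalue
#'
#' Projects a delay-embedded DMD mode back onto its first spatial component:
#' only rows `1:d` of the mode column (the un-lagged snapshot block of the
#' level-major stacking) are kept. Element-wise magnitudes are normalized to
#' unit norm and mapped back onto the grid.
#'
#' @param fit A `dmd_fit` produced from spatial data.
#' @param d Number of valid spatial cells.
#' @param which Eigenvalue index (by the fit's descending-magnitude order).
#' @param grid Optional `c(ny, nx)`; with `mask`, magnitudes are placed into
#'   an `ny` by `nx` matrix (`NA` outside the mask).
#' @param mask Optional logical validity mask of length `ny * nx`.
#' @return A `spatial_mode` with `values` (vector, or matrix when `grid` is
#'   given), `eigenvalue`, and `window_time`.
#' @export
extract_spatial_mode <- function(fit, d, which = 1L, grid = NULL,
                                 mask = NULL) {
  stopifnot(inherits(fit, "dmd_fit"))
  which <- as.integer(which)
  if (which < 1L || which > length(fit$eigenvalues))
    stop("eigenvalue index out of range")
  if (nrow(fit$modes) %% d != 0L)
    stop("mode length is not a multiple of d; wrong stacking?")
  v <- Mod(fit$modes[seq_len(d), which])
  nv <- sqrt(sum(v^2))
  if (nv > 0) v <- v / nv
  values <- v
  if (!is.null(grid)) {
    full <- rep(NA_real_, grid[1] * grid[2])
    if (is.null(mask)) mask <- rep(TRUE, grid[1] * grid[2])
    full[mask] <- v
    values <- matrix(full, grid[1], grid[2], byrow = TRUE)
  }
  structure(list(values = values, eigenvalue = fit$eigenvalues[which],
                 window_time = fit$t_start, normalization = "unit-norm magnitude"),
            class = "spatial_mode")
}

#' Change in the candidate mode map between two window sets
#'
#' For the `csd_candidate` track, extracts the (unit-normalized) spatial
#' mode magnitude map in each listed window and returns the per-cell median
#' over `late_windows` minus the median over `early_windows`.
#'
#' @param et A classified `eigen_track` built from spatial data.
#' @param early_windows,late_windows Integer vectors of window indices; the
#'   sets may overlap.
#' @return Matrix (`ny` by `nx`) of mode-magnitude change.
#' @export
mode_change_map <- function(et, early_windows, late_windows) {
  stopifnot(inherits(et, "eigen_track"))
  if (!et$is_field) stop("mode maps require spatial data")
  if (is.null(et$labels)) stop("call classify_tracks() first")
  ci <- which(et$labels == "csd_candidate")
  if (length(ci) == 0L) stop("no csd_candidate track")
  tr <- et$tracks[[ci[1]]]
  mode_mag <- function(w) {
    row <- which(tr$window == w)
    if (length(row) == 0L)
      stop(sprintf("csd_candidate track does not cover window %d", w))
    m <- extract_spatial_mode(et$fits[[w]], et$d, tr$eig[row[1]])
    m$values
  }
  med_map <- function(ws) {
    apply(vapply(ws, mode_mag, numeric(et$d)), 1L, stats::median)
  }
  delta <- med_map(late_windows) - med_map(early_windows)
  full <- rep(NA_real_, et$grid[1] * et$grid[2])
  full[et$mask] <- delta
  matrix(full, et$grid[1], et$grid[2], byrow = TRUE)
}
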