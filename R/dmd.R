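#' Dynamic mode decomposition of a delay pair
#'
#' Estimates the linear propagator `A = Y X^+` (Moore-Penrose pseudo-inverse
#' via the SVD of `X`) with optional rank truncation, and returns the
#' eigenvalues and exact DMD modes of the reduced operator
#' `A~ = U_r' Y V_r S_r^-1`. When `X` and `Y` are period-lagged snapshot
#' matrices, the eigenvalues approximate the Floquet multipliers of the
#' underlying periodic system.
#'
#' Automatic rank selection keeps the smallest rank capturing at least
#' `energy` of the squared singular-value mass of `X` (capped at
#' `max_rank`); singular values below `svd_tol` times the largest are
#' treated as zero. Eigenvalues are sorted by descending magnitude, ties
#' broken by descending real part. Modes are lifted to the full space as
#' `Y V_r S_r^-1 w` and normalized to unit norm.
#'
#' @param pair A [build_delay_pair()] result.
#' @param rank `"auto"` or a positive integer (clipped, with a warning, to
#'   the number of usable singular values).
#' @param energy Squared singular-value energy fraction for automatic rank.
#' @param max_rank Upper cap on the automatic rank.
#' @param svd_tol Relative tolerance below which singular values are zero.
#' @return A `dmd_fit` with `eigenvalues` (complex), `modes` (complex
#'   matrix, one unit-norm column per eigenvalue), `singular_values`,
#'   `rank_used`, `centered`, and `t_start`.
#' @export
fit_dmd <- function(pair, rank = "auto", energy = 0.995, max_rank = Inf,
                    svd_tol = 1e-10) {
  stopifnot(inherits(pair, "delay_pair"))
  X <- pair$X; Y <- pair$Y
  if (all(X == 0)) stop("degenerate input: X is identically zero")
  sv <- svd(X)
  usable <- which(sv$d > svd_tol * sv$d[1])
  n_usable <- length(usable)
  if (n_usable == 0L) stop("degenerate input: X has no usable singular values")
  if (identical(rank, "auto")) {
    frac <- cumsum(sv$d[usable]^2) / sum(sv$d[usable]^2)
    r <- which(frac >= energy)[1]
    r <- min(r, max_rank, n_usable)
  } else {
    r <- as.integer(rank)
    if (r < 1L) stop("`rank` must be >= 1")
    if (r > n_usable) {
      warning(sprintf("rank %d exceeds usable rank %d; clipped", r, n_usable))
      r <- n_usable
    }
  }
  U <- sv$u[, seq_len(r), drop = FALSE]
  V <- sv$v[, seq_len(r), drop = FALSE]
  s_inv <- 1 / sv$d[seq_len(r)]
  YVs <- Y %*% sweep(V, 2L, s_inv, `*`)
  Atil <- crossprod(U, YVs)
  eg <- eigen(Atil)
  modes <- YVs %*% eg$vectors
  norms <- sqrt(colSums(Mod(modes)^2))
  norms[norms == 0] <- 1
  modes <- sweep(modes, 2L, norms, `/`)
  ord <- order(-Mod(eg$values), -Re(eg$values))
  structure(list(eigenvalues = eg$values[ord],
                 modes = modes[, ord, drop = FALSE],
                 singular_values = sv$d, rank_used = r,
                 centered = pair$config$center %||% FALSE,
                 t_start = pair$t_start),
            class = "dmd_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dmd_fit <- function(x, ...) {
  cat(sprintf("<dmd_fit> rank %d, |rho| = %s\n", x$rank_used,
              paste(sprintf("%.4f", Mod(x$eigenvalues)), collapse = ", ")))
  invisible(x)
}

#' Spectral radius of a DMD fit
#'
#' The largest eigenvalue magnitude; values at or above 1 indicate an
#' unstable (or marginally stable) propagator.
#'
#' @param fit A `dmd_fit`.
#' @return Maximum `|rho_i|`.
#' @export
spectral_radius <- function(fit) {
  stopifnot(inherits(fit, "dmd_fit"))
  if (length(fit$eigenvalues) == 0L) stop("empty fit: no eigenvalues")
  max(Mod(fit$eigenvalues))
}

# Keep the `k` dominant eigenvalues without splitting a conjugate pair:
# if eigenvalue k and k+1 are conjugates, k is extended by one.
keep_dominant <- function(eigenvalues, k) {
  n <- length(eigenvalues)
  k <- min(k, n)
  if (k < n &&
      abs(Im(eigenvalues[k])) > 1e-12 &&
      Mod(eigenvalues[k] - Conj(eigenvalues[k + 1L])) <
        1e-8 * max(Mod(eigenvalues[k]), 1))
    k <- k + 1L
  seq_len(k)
}
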