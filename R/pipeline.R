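#' Full Floquet stability analysis of a series or field
#'
#' Convenience wrapper chaining [rolling_floquet()], [match_tracks()],
#' [classify_tracks()] and [detect_crossing()], returning a classified
#' `eigen_track` with `crossing_time` filled.
#'
#' @inheritParams rolling_floquet
#' @param max_jump Passed to [match_tracks()].
#' @param seasonal_band,min_coverage,noise_floor Passed to
#'   [classify_tracks()].
#' @param threshold,persistence Passed to [detect_crossing()].
#' @return A classified `eigen_track`.
#' @export
floquet_analysis <- function(data, config, rank = "auto",
                             min_valid_frac = 0.8, max_jump = 0.2,
                             seasonal_band = 0.1, min_coverage = 0.9,
                             noise_floor = 0.5, threshold = 1,
                             persistence = 3L, ...) {
  et <- rolling_floquet(data, config, rank = rank,
                        min_valid_frac = min_valid_frac, ...)
  if (length(et$fits) >= 2L) {
    et <- match_tracks(et, max_jump = max_jump)
    et <- classify_tracks(et, seasonal_band = seasonal_band,
                          min_coverage = min_coverage,
                          noise_floor = noise_floor)
  } else {
    et$filtered_max <- vapply(et$fits, spectral_radius, numeric(1))
  }
  et$crossing_time <- detect_crossing(et, threshold = threshold,
                                      persistence = persistence)
  et
}
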