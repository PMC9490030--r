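#' Quartile and spread conventions used throughout the package
#'
#' All quartile-based statistics (amplitude quartiles in protocol I,
#' similarity quartiles in protocol II, quartile deviations of latencies)
#' use linear interpolation between order statistics (the type-7 convention
#' of [stats::quantile()]), applied uniformly so that fixtures pinned to one
#' operation remain valid for all of them.
#'
#' @param x numeric vector, non-empty.
#' @return `lower_quartile(x)`: the 25th percentile of `x`; `quartile_dev(x)`:
#'   half the interquartile range (Q3 - Q1)/2.
#' @examples
#' lower_quartile(c(2, 4, 6, 8))  # 3.5
#' quartile_dev(c(1, 2, 3, 4))    # 0.75
#' @export
lower_quartile <- function(x) {
  if (length(x) == 0L) stop("lower_quartile: empty input")
  unname(stats::quantile(x, probs = 0.25, type = 7, names = FALSE))
}

#' @rdname lower_quartile
#' @export
quartile_dev <- function(x) {
  if (length(x) == 0L) stop("quartile_dev: empty input")
  q <- stats::quantile(x, probs = c(0.25, 0.75), type = 7, names = FALSE)
  (q[2] - q[1]) / 2
}

# ms <-> sample conversions (0-based sample indices internally; interfaces
# report ms with sub-sample fractions where interpolated)
ms_to_samples <- function(ms, fs) ms * fs / 1000
samples_to_ms <- function(s, fs) s * 1000 / fs

#' Sub-sample peak localization by spline interpolation
#'
#' Refines the time of a waveform extremum to sub-sample resolution by cubic
#' spline interpolation with 20-fold oversampling, as used for evoked-spike
#' latency estimates and trough-to-peak durations.
#'
#' @param w numeric waveform (samples).
#' @param oversample oversampling factor for the interpolant grid.
#' @param what `"min"` for a trough, `"max"` for a peak.
#' @return list with `t` (fractional sample index, 0-based within `w`) and
#'   `value` (interpolated extremum).
#' @export
spline_peak <- function(w, oversample = 20, what = c("min", "max")) {
  what <- match.arg(what)
  n <- length(w)
  if (n < 4L) stop("spline_peak: waveform too short for spline interpolation")
  sf <- stats::splinefun(seq_len(n) - 1, w, method = "natural")
  grid <- seq(0, n - 1, by = 1 / oversample)
  vals <- sf(grid)
  i <- if (what == "min") which.min(vals) else which.max(vals)
  list(t = grid[i], value = vals[i])
}
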