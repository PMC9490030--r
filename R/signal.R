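#' Multichannel recording segment
#'
#' Container for a block of multichannel extracellular samples with its
#' sampling rate and tetrode grouping. Channels are grouped into tetrodes of
#' exactly four channels; a spike's four-channel amplitude pattern on a
#' tetrode fingerprints the source neuron.
#'
#' @param samples numeric matrix, time x channel.
#' @param fs sampling rate in samples/s.
#' @param tetrodes list of integer vectors, each naming exactly 4 channel
#'   indices; a channel may appear in at most one tetrode.
#' @param t0 session time of the first sample (samples, 0-based).
#' @return an object of class `recording_segment`.
#' @export
recording_segment <- function(samples, fs = 20000, tetrodes, t0 = 0) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("recording_segment: samples must be numeric")
  if (fs <= 0) stop("recording_segment: fs must be positive")
  tetrodes <- lapply(tetrodes, as.integer)
  if (any(vapply(tetrodes, length, 1L) != 4L))
    stop("recording_segment: every tetrode must have exactly 4 channels")
  all_ch <- unlist(tetrodes)
  if (anyDuplicated(all_ch))
    stop("recording_segment: a channel may appear in at most one tetrode")
  if (length(all_ch) && max(all_ch) > ncol(samples))
    stop("recording_segment: tetrode channel index exceeds channel count")
  structure(list(samples = samples, fs = fs, tetrodes = tetrodes, t0 = t0),
            class = "recording_segment")
}

#' @export
print.recording_segment <- function(x, ...) {
  cat(sprintf("<recording_segment> %d samples x %d channels @ %g Hz (%d tetrodes, %.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              length(x$tetrodes), nrow(x$samples) / x$fs))
  invisible(x)
}

#' Convert an averaging timescale to a one-sided exponential filter gain
#'
#' The running-average (high-pass) and running-variance recursions are
#' parameterized by gains in (0, 1]; a gain is the reciprocal of the
#' averaging timescale expressed in samples. The defaults of the online
#' detector are 0.25 ms for the signal average (gain 0.2 at 20 kHz) and
#' 1 s for the variance estimate (gain 5e-5 at 20 kHz).
#'
#' @param tau averaging timescale in seconds (`tau >= 1/fs`).
#' @param fs sampling rate in samples/s.
#' @return gain in (0, 1].
#' @examples
#' gain_from_timescale(0.25e-3, 20000)  # 0.2
#' gain_from_timescale(1, 20000)        # 5e-05
#' @export
gain_from_timescale <- function(tau, fs) {
  if (!is.numeric(tau) || !is.numeric(fs) || tau <= 0 || fs <= 0)
    stop("gain_from_timescale: tau and fs must be positive")
  min(1, 1 / (tau * fs))
}

#' Causal one-sided exponential high-pass filter
#'
#' Single-pass recursion used by the real-time detector: the filtered value
#' is the sample minus a running local average, `z(t) = x(t) - y(t)`, with
#' the average updated as `y(t+1) = y(t) + G_y z(t)`. DC and slow components
#' (local field potential) are rejected; on a constant input the output
#' decays geometrically as `(1 - G_y)^n`.
#'
#' @param x numeric vector (one channel's sample stream).
#' @param gain_y averaging gain in (0, 1]; see [gain_from_timescale()].
#' @param y_init initial running average; defaults to the first sample so
#'   that the filter starts converged for locally stationary input.
#' @return numeric vector `z`, same length as `x`, with the final running
#'   average in attribute `"y"`.
#' @export
online_highpass <- function(x, gain_y = 0.2, y_init = x[1]) {
  if (gain_y <= 0 || gain_y > 1) stop("online_highpass: gain_y must be in (0,1]")
  n <- length(x)
  if (n == 0L) return(x)
  # y(t+1) = (1-G) y(t) + G x(t)  -> first-order recursive filter
  w <- stats::filter(gain_y * x, 1 - gain_y, method = "recursive",
                     init = y_init)
  y <- c(y_init, as.numeric(w)[-n])
  z <- x - y
  attr(z, "y") <- as.numeric(w)[n]
  z
}

gaussian_kernel <- function(sigma_samples, truncate = 4) {
  h <- max(1L, ceiling(truncate * sigma_samples))
  k <- stats::dnorm(seq(-h, h), sd = sigma_samples)
  k / sum(k)
}

#' Zero-phase Gaussian-subtraction high-pass filter
#'
#' The precise symmetric high-pass used semi-offline and offline: subtract
#' the Gaussian-smoothed signal (default sigma = 0.25 ms) from the raw
#' signal. The kernel is truncated at +/- 4 sigma and renormalized to unit
#' sum so constant input maps exactly to zero; boundaries are handled by
#' reflection. The filter is linear and zero-phase.
#'
#' @param x numeric vector, or a matrix filtered along its columns
#'   (time runs down the rows).
#' @param sigma_ms Gaussian smoothing width in ms.
#' @param fs sampling rate in samples/s.
#' @return filtered object of the same shape as `x`.
#' @export
gaussian_subtract_filter <- function(x, sigma_ms = 0.25, fs = 20000) {
  if (sigma_ms <= 0) stop("gaussian_subtract_filter: sigma_ms must be positive")
  k <- gaussian_kernel(ms_to_samples(sigma_ms, fs))
  h <- (length(k) - 1L) / 2L
  filt1 <- function(v) {
    n <- length(v)
    if (n <= h) stop("gaussian_subtract_filter: input shorter than kernel support")
    vp <- c(v[(h + 1):2], v, v[(n - 1):(n - h)])
    sm <- stats::filter(vp, k, sides = 2)
    v - as.numeric(sm)[(h + 1):(h + n)]
  }
  if (is.matrix(x)) {
    n <- nrow(x)
    if (n <= h) stop("gaussian_subtract_filter: input shorter than kernel support")
    xp <- rbind(x[(h + 1):2, , drop = FALSE], x,
                x[(n - 1):(n - h), , drop = FALSE])
    sm <- stats::filter(xp, k, sides = 2)
    x - as.matrix(sm)[(h + 1):(h + n), , drop = FALSE]
  } else {
    filt1(x)
  }
}

#' Detect spikes on a filtered tetrode stream
#'
#' Emulates the real-time detector. Extracellular spikes are negative
#' deflections, so each channel is rectified to its non-positive part,
#' `zhat_c(t) = min(z_c(t), 0)`, and the squared four-channel amplitude
#' `a(t) = sum_c zhat_c(t)^2` is compared against a running noise-variance
#' estimate `v(t)` updated as `v(t+1) = v(t) + G_v (a(t) - v(t))`. A sample
#' is "spike on" when `a(t) > theta_sp^2 v(t)`; within each maximal run of
#' spike-on samples exactly one spike is emitted at the sample maximizing
#' `a(t)` (ties broken to the earlier sample).
#'
#' The variance recursion is seeded from the mean of `a(t)` over a warm-up
#' segment (default 1 s) and detections within the warm-up are discarded.
#'
#' @param z numeric matrix, time x 4 channels, already high-pass filtered.
#' @param gain_v variance-averaging gain; default corresponds to a 1 s scale
#'   at 20 kHz.
#' @param theta_sp detection threshold in SD units (default 4).
#' @param fs sampling rate in samples/s.
#' @param warmup_s warm-up duration in seconds used to seed `v` and blanked
#'   for detection. Set to 0 to disable (then `v_init` must be given).
#' @param v_init optional explicit initial variance, bypassing the warm-up
#'   seed.
#' @return data frame of detected spikes: `t` (0-based sample index of the
#'   peak), `z1..z4` (rectified four-channel amplitudes at the peak, all
#'   `<= 0`), `a` (their squared amplitude).
#' @export
detect_spikes <- function(z, gain_v = 5e-5, theta_sp = 4, fs = 20000,
                          warmup_s = 1, v_init = NULL) {
  z <- as.matrix(z)
  if (ncol(z) != 4L) stop("detect_spikes: z must have exactly 4 channels")
  n <- nrow(z)
  zhat <- pmin(z, 0)
  a <- rowSums(zhat^2)
  warm_n <- round(warmup_s * fs)
  if (is.null(v_init)) {
    if (warm_n < 1L)
      stop("detect_spikes: v_init required when warmup_s = 0")
    v_init <- mean(a[seq_len(min(warm_n, n))])
  }
  # v(t): value *before* incorporating a(t)
  w <- stats::filter(gain_v * a, 1 - gain_v, method = "recursive", init = v_init)
  v <- c(v_init, as.numeric(w)[-n])
  on <- a > theta_sp^2 * v
  if (warm_n > 0L) on[seq_len(min(warm_n, n))] <- FALSE
  if (!any(on)) {
    return(data.frame(t = integer(0), z1 = numeric(0), z2 = numeric(0),
                      z3 = numeric(0), z4 = numeric(0), a = numeric(0)))
  }
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  si <- starts[r$values]
  ei <- ends[r$values]
  peaks <- mapply(function(s, e) s + which.max(a[s:e]) - 1L, si, ei)
  data.frame(t = peaks - 1L,
             z1 = zhat[peaks, 1], z2 = zhat[peaks, 2],
             z3 = zhat[peaks, 3], z4 = zhat[peaks, 4],
             a = a[peaks])
}

#' Z-normalize evoked traces by a pooled tetrode noise level
#'
#' The noise level of a tetrode is estimated once, pooled over its four
#' channels and over the pre-stimulation segments of all trials of all
#' stimulation sites, as the root-mean-square of the filtered samples
#' (the filtered signal is zero-mean). All traces of the tetrode are then
#' divided by it.
#'
#' @param trials numeric 3-D array, time x 4 channels x trials, of filtered
#'   traces aligned to stimulation onset.
#' @param prestim_idx integer vector of time indices (rows) belonging to the
#'   pre-stimulation segment used for the noise estimate.
#' @return list with `z` (the Z-scored array) and `noise` (the scalar noise
#'   SD in the input units).
#' @export
normalize_evoked <- function(trials, prestim_idx) {
  if (!is.array(trials) || length(dim(trials)) != 3L)
    stop("normalize_evoked: trials must be a time x channel x trial array")
  if (length(prestim_idx) == 0L)
    stop("normalize_evoked: need at least one pre-stimulation sample")
  pre <- trials[prestim_idx, , , drop = FALSE]
  noise <- sqrt(mean(pre^2))
  if (!is.finite(noise) || noise == 0)
    stop("normalize_evoked: noise level is zero, cannot normalize")
  list(z = trials / noise, noise = noise)
}
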