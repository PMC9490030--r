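#' Trough-to-peak duration of a spike waveform
#'
#' Duration from the (spline-interpolated) negative trough to the
#' subsequent positive peak of an unfiltered single-channel waveform, the
#' standard discriminator between wide (regular-spiking, projection-like)
#' and narrow (fast-spiking-like) units.
#'
#' @param waveform numeric single-channel trace containing a negative
#'   trough followed by a positive peak.
#' @param fs sampling rate (samples/s).
#' @param oversample spline oversampling factor.
#' @return duration in ms.
#' @export
trough_to_peak <- function(waveform, fs = 20000, oversample = 20) {
  n <- length(waveform)
  tr <- spline_peak(waveform, oversample, "min")
  post0 <- ceiling(tr$t) + 1L
  if (post0 >= n - 2L)
    stop("trough_to_peak: no post-trough maximum within the window")
  post <- waveform[post0:n]
  if (which.max(post) %in% c(1L, length(post)) && all(diff(post) < 0))
    stop("trough_to_peak: no post-trough maximum within the window")
  pk <- spline_peak(post, oversample, "max")
  samples_to_ms((post0 - 1 + pk$t) - tr$t, fs)
}

#' Ongoing spontaneous firing rate
#'
#' Spike count divided by observation time, restricted to the range from
#' the first to the last stimulation of the session and excluding a 30 ms
#' period following every stimulation (where evoked activity would
#' contaminate the estimate).
#'
#' @param spike_times spike times (ms).
#' @param stim_times stimulation onsets (ms); must be non-empty.
#' @param excl_ms exclusion window after each stimulation (ms).
#' @return rate in Hz.
#' @export
ongoing_rate <- function(spike_times, stim_times, excl_ms = 30) {
  if (!length(stim_times)) stop("ongoing_rate: no stimulations")
  t0 <- min(stim_times); t1 <- max(stim_times)
  st <- sort(stim_times)
  # exclusion zones (t_stim, t_stim + excl], clipped to t1, merged if they
  # overlap
  lo <- st; hi <- pmin(st + excl_ms, t1)
  keep_dur <- (t1 - t0) - merged_zone_length(lo, hi)
  if (keep_dur <= 0) stop("ongoing_rate: zero retained duration")
  s <- spike_times[spike_times >= t0 & spike_times <= t1]
  in_zone <- vapply(s, function(x) any(x > lo & x <= hi), TRUE)
  sum(!in_zone) / (keep_dur / 1000)
}

merged_zone_length <- function(lo, hi) {
  o <- order(lo); lo <- lo[o]; hi <- hi[o]
  tot <- 0; cur_lo <- lo[1]; cur_hi <- hi[1]
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= cur_hi) cur_hi <- max(cur_hi, hi[i])
    else { tot <- tot + cur_hi - cur_lo; cur_lo <- lo[i]; cur_hi <- hi[i] }
  }
  tot + cur_hi - cur_lo
}

# concatenate the 4 channels of a waveform matrix over a peak-relative
# window: rows are time, peak at row `peak_row`
concat_window <- function(wf, peak_row, pre_samp, post_samp) {
  idx <- (peak_row - pre_samp):(peak_row + post_samp)
  if (min(idx) < 1L || max(idx) > nrow(wf))
    stop("concat_window: window exceeds waveform extent")
  as.numeric(wf[idx, ])
}

#' Waveform stability across no-trigger trials
#'
#' The median, across trials, of the Pearson correlation between each
#' trial's evoked waveform and the median waveform, with the four channels
#' concatenated over a window around the peak (default -0.25 ms to
#' +0.5 ms).
#'
#' @param trial_wfs 3-D array, time x 4 channels x trials, peak-aligned.
#' @param peak_row row index of the aligned peak.
#' @param pre_ms,post_ms window before/after the peak (ms).
#' @param fs sampling rate (samples/s).
#' @return median correlation in \[-1, 1\].
#' @export
waveform_stability <- function(trial_wfs, peak_row, pre_ms = 0.25,
                               post_ms = 0.5, fs = 20000) {
  n_tr <- dim(trial_wfs)[3]
  if (n_tr < 3L) stop("waveform_stability: need at least 3 trials")
  pre <- round(ms_to_samples(pre_ms, fs)); post <- round(ms_to_samples(post_ms, fs))
  med <- apply(trial_wfs, c(1, 2), stats::median)
  mv <- concat_window(med, peak_row, pre, post)
  if (stats::sd(mv) == 0)
    stop("waveform_stability: constant median waveform")
  r <- vapply(seq_len(n_tr), function(j) {
    tv <- concat_window(trial_wfs[, , j], peak_row, pre, post)
    if (stats::sd(tv) == 0) stop("waveform_stability: constant trial waveform")
    stats::cor(tv, mv)
  }, 0)
  stats::median(r)
}

#' Bias of the four-channel peak pattern
#'
#' Coefficient of variation (population SD over mean) of the median peak
#' amplitude magnitudes on the four tetrode channels. 0 for a perfectly
#' even pattern; larger for spikes localized on one channel.
#'
#' @param median_peaks numeric length-4 vector of peak magnitudes.
#' @return CV `>= 0`.
#' @export
peak_pattern_bias <- function(median_peaks) {
  x <- abs(median_peaks)
  if (length(x) != 4L) stop("peak_pattern_bias: need 4 peak amplitudes")
  m <- mean(x)
  if (m == 0) stop("peak_pattern_bias: zero mean amplitude")
  sqrt(mean((x - m)^2)) / m
}

#' Similarity between two median waveforms
#'
#' Two complementary measures used to compare evoked and trigger spikes:
#' the direction cosine of the two four-channel peak-amplitude vectors
#' (`pattern_cos`), and the Pearson correlation of the concatenated
#' waveforms over a peak-relative window (`waveform_r`; the default
#' -0.25 ms to +0.5 ms window gives 16 points per channel at 20 kHz).
#'
#' @param w1,w2 waveform matrices, time x 4 channels, peak-aligned.
#' @param peak_row row index of the aligned peak (common to both).
#' @param pre_ms,post_ms window before/after the peak (ms).
#' @param fs sampling rate (samples/s).
#' @return list with `pattern_cos` and `waveform_r`.
#' @export
waveform_similarity <- function(w1, w2, peak_row, pre_ms = 0.25,
                                post_ms = 0.5, fs = 20000) {
  p1 <- w1[peak_row, ]; p2 <- w2[peak_row, ]
  n1 <- sqrt(sum(p1^2)); n2 <- sqrt(sum(p2^2))
  if (n1 == 0 || n2 == 0) stop("waveform_similarity: zero peak pattern")
  pre <- round(ms_to_samples(pre_ms, fs)); post <- round(ms_to_samples(post_ms, fs))
  v1 <- concat_window(w1, peak_row, pre, post)
  v2 <- concat_window(w2, peak_row, pre, post)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("waveform_similarity: constant waveform")
  list(pattern_cos = sum(p1 * p2) / (n1 * n2),
       waveform_r = stats::cor(v1, v2))
}

#' Discriminability sweep over waveform-window widths
#'
#' For every combination of pre-peak and post-peak extent (0 to
#' `max_samp` samples each, i.e. 0-0.5 ms at 20 kHz), computes the
#' waveform correlation for every success and every other pair over that
#' window and the AUC `P(success > other)` between the two classes.
#'
#' @param success_pairs,other_pairs lists of `list(w1, w2, peak_row)` as
#'   accepted by [waveform_similarity()].
#' @param fs sampling rate (samples/s).
#' @param max_samp maximum pre/post extent in samples (default 10).
#' @return `(max_samp+1) x (max_samp+1)` AUC matrix with `pre` in rows and
#'   `post` in columns (dimnames in samples) and attribute `"argmax"`
#'   (`c(pre, post)` in samples).
#' @export
width_sweep_auc <- function(success_pairs, other_pairs, fs = 20000,
                            max_samp = 10) {
  if (!length(success_pairs) || !length(other_pairs))
    stop("width_sweep_auc: both classes must be non-empty")
  corr_at <- function(p, pre, post) {
    if (pre + post == 0) return(NA_real_)  # single point: r undefined
    v1 <- concat_window(p$w1, p$peak_row, pre, post)
    v2 <- concat_window(p$w2, p$peak_row, pre, post)
    if (stats::sd(v1) == 0 || stats::sd(v2) == 0) return(0)
    stats::cor(v1, v2)
  }
  grid <- matrix(NA_real_, max_samp + 1L, max_samp + 1L,
                 dimnames = list(pre = 0:max_samp, post = 0:max_samp))
  for (pre in 0:max_samp) {
    for (post in 0:max_samp) {
      if (pre + post == 0) next
      sv <- vapply(success_pairs, corr_at, 0, pre = pre, post = post)
      ov <- vapply(other_pairs, corr_at, 0, pre = pre, post = post)
      grid[pre + 1L, post + 1L] <- roc_auc(sv, ov)
    }
  }
  am <- which(grid == max(grid, na.rm = TRUE), arr.ind = TRUE)[1, ]
  attr(grid, "argmax") <- c(pre = unname(am[1]) - 1L,
                            post = unname(am[2]) - 1L)
  grid
}
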