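#' Amplitude quartile of a peak distribution
#'
#' The "first quartile from the largest": the value exceeded by 75% of the
#' entries. For non-negative amplitude magnitudes this is the 25th
#' percentile under the package-wide linear-interpolation convention; a
#' large amplitude quartile indicates that a window captures a spike in at
#' least three quarters of the trials.
#'
#' @param values numeric vector of non-negative amplitudes.
#' @return scalar quartile.
#' @examples
#' amplitude_quartile(c(8, 6, 4, 2))  # 3.5
#' @export
amplitude_quartile <- function(values) {
  if (length(values) == 0L) stop("amplitude_quartile: empty input")
  lower_quartile(values)
}

#' Similarity kernel between two evoked spikes (protocol II)
#'
#' `S_kl = exp[ cos^2(theta_kl) - 1 - sin^2(pi/18)/alpha^2 * (t_k - t_l)^2 ]`
#' where `theta_kl` is the angle between the two rectified four-channel
#' amplitude patterns. Identical spikes give the maximum `S_kk = 1`; a
#' timing deviation of `alpha` lowers S by the same amount as a pattern
#' angle of pi/18. Since rectified patterns lie in one orthant their angle
#' is below pi/2 and S decreases monotonically with angle and |timing
#' difference|.
#'
#' @param z_k,z_l rectified (non-positive) four-channel peak vectors.
#' @param t_k,t_l spike times (ms from stimulation onset).
#' @param alpha acceptable-jitter timescale (ms); 1 ms in offline analyses.
#' @return similarity in (0, 1].
#' @export
spike_similarity <- function(z_k, t_k, z_l, t_l, alpha = 1) {
  if (alpha <= 0) stop("spike_similarity: alpha must be positive")
  nk <- sqrt(sum(z_k^2)); nl <- sqrt(sum(z_l^2))
  if (nk == 0 || nl == 0) stop("spike_similarity: zero amplitude vector")
  cth <- min(1, sum(z_k * z_l) / (nk * nl))  # guard rounding above 1
  exp(cth^2 - 1 - sin(pi / 18)^2 / alpha^2 * (t_k - t_l)^2)
}

# rowwise max of a matrix without matrixStats
row_max <- function(m) do.call(pmax, lapply(seq_len(ncol(m)), function(j) m[, j]))

#' Detect supra-threshold spikes in normalized evoked trials
#'
#' Thresholding of Z-scored traces: samples where the most negative channel
#' is below `-detect_sd` form "spike on" runs; each run yields one spike at
#' the sample with the deepest trough, with the rectified four-channel
#' vector at that sample. Only the post-stimulus range `(0, T_range]` is
#' searched (optogenetic stimulation has no electrical artifact, so spikes
#' during the light pulse are eligible).
#'
#' @param trials_z Z-scored trial array (time x 4 x trials) with attribute
#'   `"t_axis_ms"`.
#' @param detect_sd detection threshold in SD units (default 5).
#' @return data frame: `trial`, `t_ms`, `z1..z4`, `a`.
#' @export
detect_trial_spikes <- function(trials_z, detect_sd = 5) {
  t_axis <- attr(trials_z, "t_axis_ms")
  post <- which(t_axis > 0)
  out <- list()
  for (j in seq_len(dim(trials_z)[3])) {
    m <- trials_z[post, , j, drop = TRUE]
    mn <- row_max(-m)          # depth of deepest channel, positive
    on <- mn > detect_sd
    if (!any(on)) next
    r <- rle(on)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    si <- starts[r$values]; ei <- ends[r$values]
    pk <- mapply(function(s, e) s + which.max(mn[s:e]) - 1L, si, ei)
    zh <- pmin(m[pk, , drop = FALSE], 0)
    out[[length(out) + 1L]] <-
      data.frame(trial = j, t_ms = t_axis[post[pk]],
                 z1 = zh[, 1], z2 = zh[, 2], z3 = zh[, 3], z4 = zh[, 4],
                 a = rowSums(zh^2))
  }
  if (!length(out))
    return(data.frame(trial = integer(0), t_ms = numeric(0), z1 = numeric(0),
                      z2 = numeric(0), z3 = numeric(0), z4 = numeric(0),
                      a = numeric(0)))
  do.call(rbind, out)
}

# per-trial most negative peak (value and time) within a window, one channel
window_peaks <- function(trials_z, channel, start_ms, end_ms) {
  t_axis <- attr(trials_z, "t_axis_ms")
  idx <- which(t_axis >= start_ms & t_axis < end_ms)
  if (!length(idx)) stop("window_peaks: empty window")
  m <- trials_z[idx, channel, , drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, nrow = length(idx))
  pk <- apply(m, 2, which.min)
  data.frame(trial = seq_len(ncol(m)),
             t_ms = t_axis[idx[pk]],
             amp = -m[cbind(pk, seq_len(ncol(m)))])
}

#' Protocol I: sliding-window search for antidromic spikes
#'
#' A fixed-width temporal window is slid (1-sample steps) over post-stimulus
#' time on each of the four channels. For each window position the most
#' negative peak per trial is collected and the window is scored by the
#' amplitude quartile of the peak magnitudes; positions scoring below
#' `theta_win` are excluded. The best window is refined iteratively: the
#' 75% largest peaks are retained, the quartile deviation (QD) of their
#' timings estimated, and the window reset to median +/- `W_jitter` * QD
#' until the bounds move by less than one sample (windows that fail to
#' converge within `max_iter` iterations are rejected). After adoption, all
#' window positions on any channel overlapping the adopted time range are
#' removed and the search repeats.
#'
#' @param trials_z Z-scored trial array with `"t_axis_ms"` attribute.
#' @param width_ms initial window width (ms); 1 ms offline, 2 ms online.
#' @param W_jitter window-refit multiplier (4 offline, 5 online).
#' @param theta_win candidate amplitude-quartile threshold (Z units).
#' @param fs sampling rate (samples/s).
#' @param max_iter refinement iteration cap.
#' @param max_targets stop after adopting this many windows.
#' @param min_halfwidth_ms lower bound on the refined half-width, so a
#'   near-zero jitter estimate cannot collapse the window below the
#'   sampling resolution.
#' @return list of adopted windows, each a list with `channel`, `start_ms`,
#'   `end_ms`, `quartile`, `reps` (data frame `trial`, `t_ms`, `amp` of the
#'   retained 75%), `converged`.
#' @export
window_search <- function(trials_z, width_ms = 1, W_jitter = 4,
                          theta_win = 5, fs = 20000, max_iter = 20,
                          max_targets = Inf, min_halfwidth_ms = 0.1) {
  t_axis <- attr(trials_z, "t_axis_ms")
  dt <- 1000 / fs
  post <- which(t_axis > 0)
  w <- max(2L, round(ms_to_samples(width_ms, fs)))
  n_tr <- dim(trials_z)[3]
  n_starts <- length(post) - w + 1L
  if (n_starts < 1L) return(list())
  # sliding per-trial minima and their quartiles, all channels at once
  cand <- list()
  for (ch in 1:4) {
    m <- trials_z[post, ch, , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = length(post))
    s <- m[seq_len(n_starts), , drop = FALSE]
    for (k in 2:w) s <- pmin(s, m[k:(n_starts + k - 1L), , drop = FALSE])
    q <- apply(-s, 1, lower_quartile)
    keep <- which(q >= theta_win)
    if (length(keep))
      cand[[ch]] <- data.frame(channel = ch, start = keep, q = q[keep])
  }
  cand <- if (length(cand)) do.call(rbind, cand) else return(list())
  refine <- function(channel, start_ms, end_ms) {
    for (it in seq_len(max_iter)) {
      pks <- window_peaks(trials_z, channel, start_ms, end_ms)
      m75 <- ceiling(0.75 * nrow(pks))
      reps <- pks[order(-pks$amp)[seq_len(m75)], ]
      med <- stats::median(reps$t_ms)
      hw <- max(W_jitter * quartile_dev(reps$t_ms), min_halfwidth_ms)
      new_start <- med - hw; new_end <- med + hw
      if (abs(new_start - start_ms) < dt && abs(new_end - end_ms) < dt) {
        return(list(channel = channel, start_ms = new_start,
                    end_ms = new_end, reps = reps, converged = TRUE))
      }
      start_ms <- new_start; end_ms <- new_end
    }
    list(converged = FALSE)
  }
  adopted <- list()
  while (nrow(cand) && length(adopted) < max_targets) {
    o <- order(-cand$q, cand$start, cand$channel)
    best <- cand[o[1], ]
    win <- refine(best$channel, t_axis[post[best$start]],
                  t_axis[post[best$start]] + w * dt)
    if (win$converged) {
      win$quartile <- best$q
      adopted[[length(adopted) + 1L]] <- win
      # drop window positions (all channels) overlapping the adopted range
      st_ms <- t_axis[post[cand$start]]
      cand <- cand[st_ms + w * dt <= win$start_ms | st_ms >= win$end_ms, ]
    } else {
      cand <- cand[!(cand$channel == best$channel & cand$start == best$start), ]
    }
  }
  adopted
}

#' Protocol II: center-spike search by similarity aggregation
#'
#' Spikes are detected in every trial ([detect_trial_spikes()]). Each
#' detected spike is a candidate aggregation center: for every trial the
#' spike most similar to the candidate (by [spike_similarity()]; the
#' candidate represents its own trial with S = 1) is found, and the
#' candidate is scored by the first quartile of these similarities (75%
#' from the most similar). Candidates scoring below `theta_aggr` are
#' excluded (`theta_aggr = NULL`, the offline mode, keeps all candidates to
#' gather control samples). The best candidate is adopted, the 75% most
#' similar per-trial spikes become its representatives and leave the
#' candidate pool, and the search iterates.
#'
#' @param trials_z Z-scored trial array with `"t_axis_ms"` attribute.
#' @param alpha similarity timing scale (ms).
#' @param theta_aggr candidate similarity-quartile threshold, or `NULL`.
#' @param detect_sd detection threshold (SD units).
#' @param max_targets stop after adopting this many centers.
#' @return list of adopted centers, each a list with `center` (row of the
#'   spike table), `quartile`, `reps` (representative spikes, one per
#'   contributing trial, with `sim` column).
#' @export
center_spike_search <- function(trials_z, alpha = 1, theta_aggr = NULL,
                                detect_sd = 5, max_targets = Inf) {
  sp <- detect_trial_spikes(trials_z, detect_sd)
  n <- nrow(sp)
  if (n == 0L) return(list())
  Z <- as.matrix(sp[, c("z1", "z2", "z3", "z4")])
  nrm <- sqrt(rowSums(Z^2))
  cth <- (Z %*% t(Z)) / outer(nrm, nrm)
  dt2 <- outer(sp$t_ms, sp$t_ms, "-")^2
  S <- exp(pmin(cth, 1)^2 - 1 - sin(pi / 18)^2 / alpha^2 * dt2)
  trials <- sort(unique(sp$trial))
  cols_by_trial <- split(seq_len(n), sp$trial)
  # best similarity of each candidate within each trial
  M <- vapply(cols_by_trial, function(cols)
    row_max(S[, cols, drop = FALSE]), numeric(n))
  q_all <- apply(M, 1, lower_quartile)
  active <- rep(TRUE, n)
  if (!is.null(theta_aggr)) active <- active & q_all >= theta_aggr
  adopted <- list()
  while (any(active) && length(adopted) < max_targets) {
    idx <- which(active)
    o <- idx[order(-q_all[idx], sp$t_ms[idx], sp$trial[idx])]
    k <- o[1]
    # representative = most similar spike per trial, best 75% retained
    rep_idx <- vapply(cols_by_trial, function(cols)
      cols[which.max(S[k, cols])], integer(1))
    sims <- S[k, rep_idx]
    m75 <- ceiling(0.75 * length(rep_idx))
    keep <- order(-sims)[seq_len(m75)]
    reps <- sp[rep_idx[keep], ]
    reps$sim <- sims[keep]
    adopted[[length(adopted) + 1L]] <- list(center = sp[k, ],
                                            quartile = q_all[k],
                                            reps = reps)
    active[rep_idx[keep]] <- FALSE
    active[k] <- FALSE
  }
  adopted
}

#' Build a collision target from representative antidromic spikes
#'
#' Aggregates the representatives of an adopted window (protocol I) or
#' center spike (protocol II) into the object that parameterizes both the
#' online trigger and the offline judgment: the median four-channel peak
#' pattern `u`, the median waveform aligned at the peak, the earliest and
#' latest representative timings `t_min`/`t_max` (ms post-stimulus), and
#' the conservative latency bounds `L_min = t_min - t_off` and
#' `L_max = t_max - t_stim` (with trial-relative time, `t_stim = 0` and
#' `t_off` = stimulation duration).
#'
#' @param reps data frame with `trial` and `t_ms` (representative spikes).
#' @param trials_z Z-scored trial array the representatives refer to.
#' @param duration_ms stimulation duration `D_i` (ms), i.e. trial-relative
#'   `t_off`.
#' @param protocol `"I"` or `"II"`.
#' @param tetrode_id,site identifiers carried along.
#' @param extra list merged into the target (e.g. window or center info).
#' @param wf_half_ms half-width of the stored median waveform (ms).
#' @return object of class `collision_target`.
#' @export
build_target <- function(reps, trials_z, duration_ms = 1,
                         protocol = c("I", "II"), tetrode_id = NA,
                         site = NA, extra = list(), wf_half_ms = 1.5) {
  protocol <- match.arg(protocol)
  if (is.null(reps) || nrow(reps) == 0L)
    stop("build_target: empty representative set")
  t_axis <- attr(trials_z, "t_axis_ms")
  fs <- 1000 / (t_axis[2] - t_axis[1])
  hw <- round(ms_to_samples(wf_half_ms, fs))
  n_t <- dim(trials_z)[1]
  pk_idx <- vapply(reps$t_ms, function(t) which.min(abs(t_axis - t)), 1L)
  u_mat <- t(vapply(seq_len(nrow(reps)), function(i)
    pmin(trials_z[pk_idx[i], , reps$trial[i]], 0), numeric(4)))
  u <- apply(u_mat, 2, stats::median)
  wfs <- array(NA_real_, c(2L * hw + 1L, 4L, nrow(reps)))
  for (i in seq_len(nrow(reps))) {
    lo <- pk_idx[i] - hw; hi <- pk_idx[i] + hw
    src <- max(1L, lo):min(n_t, hi)
    wfs[src - lo + 1L, , i] <- trials_z[src, , reps$trial[i]]
  }
  med_wf <- apply(wfs, c(1, 2), stats::median, na.rm = TRUE)
  attr(med_wf, "t_rel_ms") <- samples_to_ms(seq(-hw, hw), fs)
  t_min <- min(reps$t_ms); t_max <- max(reps$t_ms)
  if (!is.na(tetrode_id)) tetrode_id <- as.integer(tetrode_id)
  if (!is.na(site)) site <- as.integer(site)
  structure(c(list(tetrode_id = tetrode_id, site = site, protocol = protocol,
                   u = u, median_waveform = med_wf,
                   t_min = t_min, t_max = t_max,
                   L_min = t_min - duration_ms, L_max = t_max,
                   duration_ms = duration_ms, reps = reps),
              extra),
            class = "collision_target")
}

#' @export
print.collision_target <- function(x, ...) {
  cat(sprintf(
    "<collision_target> protocol %s tetrode %s site %s: t in [%.2f, %.2f] ms, |u| = %.1f (%d reps)\n",
    x$protocol, x$tetrode_id, x$site, x$t_min, x$t_max,
    sqrt(sum(x$u^2)), nrow(x$reps)))
  invisible(x)
}

#' Infer collision targets for one tetrode and stimulation site
#'
#' Runs protocol I ([window_search()]) or protocol II
#' ([center_spike_search()]) on the normalized evoked trials and builds a
#' [build_target()] for every adopted window / center.
#'
#' @param trials_z Z-scored trial array with `"t_axis_ms"` attribute.
#' @param protocol `"I"` or `"II"`.
#' @param tetrode_id,site identifiers stamped on the targets.
#' @param duration_ms stimulation duration (ms).
#' @param fs sampling rate (samples/s).
#' @param width_ms,W_jitter,theta_win protocol-I parameters.
#' @param alpha,theta_aggr,detect_sd protocol-II parameters.
#' @param max_targets cap on adopted targets per tetrode-site pair.
#' @return list of `collision_target`s.
#' @export
infer_targets <- function(trials_z, protocol = c("I", "II"),
                          tetrode_id = NA, site = NA, duration_ms = 1,
                          fs = 20000, width_ms = 1, W_jitter = 4,
                          theta_win = 5, alpha = 1, theta_aggr = NULL,
                          detect_sd = 5, max_targets = 12) {
  protocol <- match.arg(protocol)
  if (protocol == "I") {
    wins <- window_search(trials_z, width_ms, W_jitter, theta_win, fs,
                          max_targets = max_targets)
    lapply(wins, function(w)
      build_target(w$reps, trials_z, duration_ms, "I", tetrode_id, site,
                   extra = list(channel = w$channel,
                                window = c(w$start_ms, w$end_ms),
                                quartile = w$quartile)))
  } else {
    ctr <- center_spike_search(trials_z, alpha, theta_aggr, detect_sd,
                               max_targets = max_targets)
    lapply(ctr, function(cs)
      build_target(cs$reps, trials_z, duration_ms, "II", tetrode_id, site,
                   extra = list(center = cs$center, alpha = alpha,
                                detect_sd = detect_sd,
                                quartile = cs$quartile)))
  }
}
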