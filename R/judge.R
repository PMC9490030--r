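#' Extract trigger and no-trigger trials for a neuron-target pair
#'
#' Implements the conservative trial classification of the collision test,
#' with trial-relative times (stimulation onset at 0, offset at the pulse
#' duration `t_off`):
#' \enumerate{
#'   \item Refractory exclusion: trials with any spike of the neuron inside
#'     `(t_min - R_max, t_min)` are dropped, because a spike there could
#'     eliminate even a synaptic evoked spike through the somatic
#'     refractory period.
#'   \item Trigger trials: at least one spike in `[t_off - L_min, 0]`; a
#'     spontaneous spike in this range must collide with the antidromic
#'     spike.
#'   \item If fewer than `min_triggers` (15) trigger trials remain, the
#'     pair is excluded.
#'   \item No-trigger trials: no spike in `[-L_max - R_max, 0]`, so a
#'     collision is impossible; only the `cap` (10) temporally nearest
#'     no-trigger trials per trigger trial are taken, duplicates merged, so
#'     the no-trigger set is at most `cap` times the trigger set.
#' }
#'
#' @param spike_times sorted spike times of the neuron (ms, session time).
#' @param stims data frame of the target site's stimulations: `t_stim`,
#'   `t_off` (ms, session time); row order defines trial indices.
#' @param target a `collision_target` (fields `t_min`, `L_min`, `L_max`).
#' @param R_max supremum of refractory periods assumed for the recorded
#'   area (ms).
#' @param min_triggers minimum trigger-trial count (pair excluded below it).
#' @param cap no-trigger trials retained per trigger trial.
#' @return list with `excluded` (logical), `reason`, `trigger` and
#'   `no_trigger` (integer row indices into `stims`), and
#'   `n_refractory_dropped`.
#' @export
extract_trials <- function(spike_times, stims, target, R_max = 4,
                           min_triggers = 15, cap = 10) {
  eps <- 1e-9
  n_in <- function(lo, hi)  # spikes in [lo, hi] per trial (vectorized)
    findInterval(hi + eps, spike_times) - findInterval(lo - eps, spike_times)
  ts <- stims$t_stim
  toff <- stims$t_off
  # (1) refractory-confound exclusion, open interval (t_min - R_max, t_min)
  refr <- n_in(ts + target$t_min - R_max + 2 * eps,
               ts + target$t_min - 2 * eps) > 0
  # (2) trigger range [t_off - L_min, t_stim]
  trig <- !refr & n_in(toff - target$L_min, ts) > 0
  if (sum(trig) < min_triggers) {
    return(list(excluded = TRUE, reason = "too_few_trigger_trials",
                trigger = which(trig), no_trigger = integer(0),
                n_refractory_dropped = sum(refr)))
  }
  # (4) no-trigger range [t_stim - L_max - R_max, t_stim]
  no_trig <- !refr & !trig & n_in(ts - target$L_max - R_max, ts) == 0
  trig_i <- which(trig)
  nt_i <- which(no_trig)
  if (length(nt_i)) {
    k <- min(cap, length(nt_i))
    picked <- lapply(trig_i, function(i)
      nt_i[order(abs(ts[nt_i] - ts[i]))[seq_len(k)]])
    nt_i <- sort(unique(unlist(picked)))
  }
  list(excluded = FALSE, reason = "ok", trigger = trig_i, no_trigger = nt_i,
       n_refractory_dropped = sum(refr))
}

# Per-(target, trial) metrics shared by elimination_values() and
# latency_and_jitter(): the elimination variable and the spline-refined
# latency of the designated evoked spike (NA where no spike is present).
target_trial_metrics <- function(trials_z, target, detect_sd = 5,
                                 refine_half_ms = 0.4) {
  t_axis <- attr(trials_z, "t_axis_ms")
  fs <- 1000 / (t_axis[2] - t_axis[1])
  hw <- round(ms_to_samples(refine_half_ms, fs))
  n_trial <- dim(trials_z)[3]
  refine <- function(trial, i_pk, ch) {
    lo <- max(1L, i_pk - hw); hi <- min(length(t_axis), i_pk + hw)
    pk <- spline_peak(trials_z[lo:hi, ch, trial], what = "min")
    t_axis[lo] + samples_to_ms(pk$t, fs)
  }
  value <- numeric(n_trial)
  latency <- rep(NA_real_, n_trial)
  if (target$protocol == "I") {
    idx <- which(t_axis >= target$window[1] & t_axis < target$window[2])
    m <- trials_z[idx, target$channel, , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = length(idx))
    pk_row <- apply(m, 2, which.min)
    value <- pmax(0, -m[cbind(pk_row, seq_len(n_trial))])
    for (j in which(value >= detect_sd))
      latency[j] <- refine(j, idx[pk_row[j]], target$channel)
  } else {
    sd_th <- if (!is.null(target$detect_sd)) target$detect_sd else detect_sd
    sp <- detect_trial_spikes(trials_z, sd_th)
    if (nrow(sp)) {
      Z <- as.matrix(sp[, c("z1", "z2", "z3", "z4")])
      zc <- as.numeric(target$center[c("z1", "z2", "z3", "z4")])
      cth <- (Z %*% zc) / (sqrt(rowSums(Z^2)) * sqrt(sum(zc^2)))
      sims <- exp(pmin(cth, 1)^2 - 1 - sin(pi / 18)^2 / target$alpha^2 *
                    (sp$t_ms - target$center$t_ms)^2)
      for (jj in unique(sp$trial)) {
        rows <- which(sp$trial == jj)
        best <- rows[which.max(sims[rows])]
        value[jj] <- sims[best]
        ch <- which.min(Z[best, ])
        i_pk <- which.min(abs(t_axis - sp$t_ms[best]))
        latency[jj] <- refine(jj, i_pk, ch)
      }
    }
  }
  data.frame(trial = seq_len(n_trial), value = value, latency = latency)
}

#' Per-trial elimination variable for a target
#'
#' The scalar summarizing whether the expected evoked spike is present in a
#' trial: in protocol I, the magnitude of the most negative peak within the
#' inferred window on the window's channel; in protocol II, the maximum
#' [spike_similarity()] between the inferred center spike and any detected
#' spike in the trial. Trials with no deflection/detected spike score 0.
#' Elimination (collision) lowers the variable, so in the subsequent ROC
#' analysis no-trigger trials score higher than trigger trials.
#'
#' @param trials_z Z-scored trial array (time x 4 x trials) with
#'   `"t_axis_ms"` attribute.
#' @param target a `collision_target` of either protocol.
#' @return numeric vector, one value per trial in the array.
#' @export
elimination_values <- function(trials_z, target) {
  target_trial_metrics(trials_z, target)$value
}

#' Area under the ROC curve by the Mann-Whitney identity
#'
#' `AUC = P(no-trigger value > trigger value) + 0.5 P(tie)`, computed from
#' midranks. With the elimination variable of [elimination_values()],
#' elimination of evoked spikes in trigger trials drives AUC above 0.5.
#'
#' @param no_trigger_values,trigger_values numeric vectors, both non-empty.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(no_trigger_values, trigger_values) {
  n <- length(no_trigger_values); m <- length(trigger_values)
  if (n == 0L || m == 0L) stop("roc_auc: both sets must be non-empty")
  r <- rank(c(no_trigger_values, trigger_values))
  (sum(r[seq_len(n)]) - n * (n + 1) / 2) / (n * m)
}

#' Robust standard deviation via the median absolute deviation
#'
#' `sigma = median(|x - median(x)|) / 0.6745`, the Gaussian-consistent MAD
#' estimate used to set the AUC success criterion from the batch of all
#' tested pairs.
#'
#' @param x numeric vector with at least 2 values.
#' @return sigma `>= 0`.
#' @export
robust_sigma <- function(x) {
  if (length(x) < 2L) stop("robust_sigma: need at least 2 values")
  stats::median(abs(x - stats::median(x))) / 0.6745
}

#' Evoked-spike latency and jitter in no-trigger trials
#'
#' For each selected trial the evoked spike designated by the target (the
#' deepest deflection in the inferred window for protocol I; the detected
#' spike most similar to the center for protocol II) is localized to
#' sub-sample precision by cubic-spline interpolation of its waveform on
#' the deepest channel. Latency is the interpolated trough time (ms from
#' stimulation onset); the jitter is the quartile deviation of the
#' latencies. Antidromic spikes have jitters well below 0.25 ms; synaptic
#' responses are more variable.
#'
#' @param trials_z Z-scored trial array with `"t_axis_ms"` attribute.
#' @param target a `collision_target`.
#' @param trial_idx trials to use (typically the no-trigger set).
#' @param min_n minimum number of trials with an evoked spike.
#' @param detect_sd presence threshold (SD units).
#' @return list with `latency_median`, `jitter_qd` (ms) and `latencies`.
#' @export
latency_and_jitter <- function(trials_z, target, trial_idx, min_n = 4,
                               detect_sd = 5) {
  sub <- trials_z[, , trial_idx, drop = FALSE]
  attr(sub, "t_axis_ms") <- attr(trials_z, "t_axis_ms")
  mt <- target_trial_metrics(sub, target, detect_sd)
  lat <- mt$latency[!is.na(mt$latency)]
  if (length(lat) < min_n)
    stop("latency_and_jitter: too few trials with an evoked spike")
  list(latency_median = stats::median(lat), jitter_qd = quartile_dev(lat),
       latencies = lat)
}

#' Success criterion for one tested pair
#'
#' A pair is successful when its AUC exceeds the batch median by more than
#' `sigma_mult` robust sigmas of the batch AUC distribution
#' ([robust_sigma()]) and its latency jitter is below `jitter_max`
#' (0.25 ms). The AUC distribution of unrelated pairs is centered near 0.5,
#' so the criterion measures deviation from the bulk.
#'
#' @param auc the pair's AUC.
#' @param jitter_qd the pair's latency quartile deviation (ms), `NA` if
#'   unmeasurable (counts as failure).
#' @param batch_aucs AUCs of all tested pairs in the analysis batch.
#' @param sigma_mult multiplier on the robust sigma (default 5).
#' @param jitter_max jitter criterion (ms).
#' @return logical.
#' @export
judge_pair <- function(auc, jitter_qd, batch_aucs, sigma_mult = 5,
                       jitter_max = 0.25) {
  !is.na(jitter_qd) && jitter_qd < jitter_max &&
    (auc - stats::median(batch_aucs)) > sigma_mult * robust_sigma(batch_aucs)
}

#' Judge all neuron-target pairs of a session
#'
#' Runs the full offline judgment: for every pair of a neuron (spike
#' cluster) and a same-tetrode collision target, extracts trigger and
#' no-trigger trials ([extract_trials()]), computes the elimination-variable
#' ROC AUC ([roc_auc()]) and the evoked latency and jitter in the
#' no-trigger trials, then applies the batch-level success criterion
#' ([judge_pair()]). Among multiple successful pairs of one neuron only the
#' highest-AUC pair is adopted.
#'
#' @param neuron_spikes named list: per neuron, sorted spike times (ms).
#' @param neuron_tetrode named integer vector: tetrode of each neuron.
#' @param trials_by_tetrode list over tetrodes of Z-scored trial arrays
#'   whose trials correspond row-for-row to `stims`.
#' @param stims data frame of all stimulations (`site`, `t_stim`, `t_off`),
#'   rows aligned with the trial arrays.
#' @param targets list of `collision_target`s.
#' @param R_max,min_triggers,cap,sigma_mult,jitter_max judgment parameters.
#' @param min_latency_n minimum no-trigger trials with an evoked spike for
#'   the jitter estimate.
#' @return data frame, one row per tested pair: ids, trial counts, `auc`,
#'   `jitter_qd`, `latency_med`, `sigma` (batch), `success`, `adopted`.
#' @export
judge_pairs <- function(neuron_spikes, neuron_tetrode, trials_by_tetrode,
                        stims, targets, R_max = 4, min_triggers = 15,
                        cap = 10, sigma_mult = 5, jitter_max = 0.25,
                        min_latency_n = 4) {
  rows <- list()
  for (tg_i in seq_along(targets)) {
    tg <- targets[[tg_i]]
    site_rows <- which(stims$site == tg$site)
    if (!length(site_rows)) next
    trials_z <- trials_by_tetrode[[tg$tetrode_id]]
    sub <- trials_z[, , site_rows, drop = FALSE]
    attr(sub, "t_axis_ms") <- attr(trials_z, "t_axis_ms")
    mt <- target_trial_metrics(sub, tg)
    st <- stims[site_rows, ]
    for (nid in names(neuron_spikes)) {
      if (neuron_tetrode[[nid]] != tg$tetrode_id) next
      ex <- extract_trials(neuron_spikes[[nid]], st, tg, R_max,
                           min_triggers, cap)
      if (ex$excluded || length(ex$no_trigger) == 0L) next
      auc <- roc_auc(mt$value[ex$no_trigger], mt$value[ex$trigger])
      lat <- mt$latency[ex$no_trigger]
      lat <- lat[!is.na(lat)]
      jit <- if (length(lat) >= min_latency_n) quartile_dev(lat) else NA_real_
      lmed <- if (length(lat) >= min_latency_n) stats::median(lat) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        neuron = nid, target = tg_i, protocol = tg$protocol,
        tetrode = tg$tetrode_id, site = tg$site,
        n_trigger = length(ex$trigger), n_no_trigger = length(ex$no_trigger),
        auc = auc, jitter_qd = jit, latency_med = lmed)
    }
  }
  if (!length(rows)) {
    return(data.frame(neuron = character(0), target = integer(0),
                      protocol = character(0), tetrode = integer(0),
                      site = integer(0), n_trigger = integer(0),
                      n_no_trigger = integer(0), auc = numeric(0),
                      jitter_qd = numeric(0), latency_med = numeric(0),
                      sigma = numeric(0), success = logical(0),
                      adopted = logical(0)))
  }
  res <- do.call(rbind, rows)
  sg <- robust_sigma(res$auc)
  res$sigma <- sg
  res$success <- !is.na(res$jitter_qd) & res$jitter_qd < jitter_max &
    (res$auc - stats::median(res$auc)) > sigma_mult * sg
  res$adopted <- FALSE
  for (nid in unique(res$neuron[res$success])) {
    i <- which(res$neuron == nid & res$success)
    res$adopted[i[which.max(res$auc[i])]] <- TRUE
  }
  rownames(res) <- NULL
  res
}
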