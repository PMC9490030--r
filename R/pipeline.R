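#' Render, filter and normalize evoked trials for all tetrodes
#'
#' The evoked-response collection step applied to a simulated session:
#' per-stimulation raw snippets are rendered for each tetrode
#' ([render_trials()]), high-pass filtered with the precise symmetric
#' Gaussian-subtraction filter, and Z-normalized by the tetrode noise level
#' pooled over the pre-stimulation segments of all trials and sites
#' ([normalize_evoked()]). When `noise` is supplied (e.g. from the
#' collection phase) it is reused instead of re-estimated, as the online
#' system does for trials collected later in the session.
#'
#' @param truth a `sim_ground_truth`.
#' @param stims stimulation table (`t_stim`, `t_off`, ms); default the
#'   collection-phase schedule.
#' @param sigma_ms filter width (ms).
#' @param noise optional per-tetrode noise levels to reuse.
#' @return list with `trials` (per-tetrode Z-scored arrays), `noise`
#'   (per-tetrode SDs), `t_axis_ms`.
#' @export
collect_evoked <- function(truth, stims = truth$schedule, sigma_ms = 0.25,
                           noise = NULL) {
  cfg <- truth$config
  n_tet <- length(cfg$tetrodes)
  trials <- vector("list", n_tet)
  noise_out <- numeric(n_tet)
  for (tt in seq_len(n_tet)) {
    raw <- render_trials(truth, tt, stims)
    t_axis <- attr(raw, "t_axis_ms")
    d <- dim(raw)
    flt <- gaussian_subtract_filter(matrix(raw, d[1]), sigma_ms, cfg$fs)
    flt <- array(flt, d)
    if (is.null(noise)) {
      nz <- normalize_evoked(flt, which(t_axis < 0))
      z <- nz$z
      noise_out[tt] <- nz$noise
    } else {
      z <- flt / noise[tt]
      noise_out[tt] <- noise[tt]
    }
    attr(z, "t_axis_ms") <- t_axis
    trials[[tt]] <- z
  }
  list(trials = trials, noise = noise_out, t_axis_ms = t_axis)
}

# concatenate two trial arrays along the trial dimension
bind_trials <- function(a, b) {
  t_axis <- attr(a, "t_axis_ms")
  out <- array(c(a, b), c(dim(a)[1:2], dim(a)[3] + dim(b)[3]))
  attr(out, "t_axis_ms") <- t_axis
  out
}

#' Run a full simulated collision-test study
#'
#' End-to-end pipeline on synthetic ground truth:
#' \enumerate{
#'   \item generate the session ([make_ground_truth()]): spontaneous
#'     trains, collection-phase schedule, evoked events with collision /
#'     refractory outcomes;
#'   \item collect and normalize the collection-phase evoked trials
#'     ([collect_evoked()]);
#'   \item infer collision targets per tetrode and site under the requested
#'     protocols ([infer_targets()]);
#'   \item emulate the closed-loop collision-test phase: the controller
#'     ([run_collision_session()]) monitors the simulated spike stream and
#'     fires spike-triggered stimulations for the protocol-I targets, and
#'     the evoked outcome of every triggered stimulation is simulated under
#'     the same collision physics;
#'   \item judge every neuron-target pair offline on all trials of both
#'     phases ([judge_pairs()]), separately per protocol.
#' }
#'
#' @param sim_cfg a [sim_config()]; default [default_study_config()].
#' @param seed integer seed for the whole study.
#' @param protocols character subset of `c("I", "II")`.
#' @param run_cfg analysis parameters from [load_config()].
#' @param collision_s duration of the closed-loop phase (s); it starts
#'   after the last collection-phase stimulation.
#' @return list with `truth`, `targets` (per protocol), `ctrl` (controller
#'   log and counts), `stims` (all stimulations), `trials`
#'   (per-tetrode arrays), `judgment` (per protocol), `noise`.
#' @export
run_study <- function(sim_cfg = default_study_config(), seed = 1,
                      protocols = c("I", "II"), run_cfg = load_config(),
                      collision_s = 600) {
  truth <- make_ground_truth(sim_cfg, seed)
  with_seed(seed + 1L, {
    coll <- collect_evoked(truth, sigma_ms = run_cfg$sigma_ms)
    dur <- rep_len(sim_cfg$durations_ms, length(sim_cfg$sites))
    targets <- list()
    for (pr in protocols) {
      tg <- list()
      for (tt in seq_along(sim_cfg$tetrodes)) {
        for (s in sim_cfg$sites) {
          rows <- which(truth$schedule$site == s)
          sub <- coll$trials[[tt]][, , rows, drop = FALSE]
          attr(sub, "t_axis_ms") <- coll$t_axis_ms
          tg <- c(tg, infer_targets(
            sub, pr, tetrode_id = tt, site = s,
            duration_ms = dur[match(s, sim_cfg$sites)], fs = sim_cfg$fs,
            width_ms = run_cfg$width_ms, W_jitter = run_cfg$W_jitter,
            theta_win = run_cfg$theta_win, alpha = run_cfg$alpha,
            theta_aggr = run_cfg$theta_aggr, detect_sd = run_cfg$detect_sd,
            max_targets = run_cfg$max_targets))
        }
      }
      targets[[pr]] <- tg
    }
    ctrl_targets <- targets[[protocols[1]]]
    t_phaseB0 <- max(truth$schedule$t_off) + 1000
    t_phaseB1 <- min(t_phaseB0 + collision_s * 1000,
                     sim_cfg$session_s * 1000 - sim_cfg$T_range_ms - 10)
    scfg <- session_config(theta_trig = run_cfg$theta_trig,
                           N_test = run_cfg$N_test,
                           I_same = run_cfg$I_same, I_diff = run_cfg$I_diff,
                           latency_range_ms = run_cfg$latency_range_ms,
                           T_range_ms = run_cfg$T_range_ms,
                           N_anti = run_cfg$N_anti,
                           durations_ms = sim_cfg$durations_ms)
    stream <- spike_stream(truth, c(t_phaseB0, t_phaseB1))
    ctrl <- run_collision_session(stream, ctrl_targets, scfg,
                                  prior_stims = truth$schedule)
    stims <- truth$schedule[, c("stim_id", "site", "t_stim", "duration_ms",
                                "t_off")]
    if (nrow(ctrl$log)) {
      extra <- data.frame(stim_id = max(stims$stim_id) + seq_len(nrow(ctrl$log)),
                          site = ctrl$log$site, t_stim = ctrl$log$t_stim,
                          duration_ms = ctrl$log$t_off - ctrl$log$t_stim,
                          t_off = ctrl$log$t_off)
      ev_extra <- evoked_events_for(truth$neurons, truth$spont, extra,
                                    sim_cfg)
      truth$events <- rbind(truth$events, ev_extra)
      truth$events <- truth$events[order(truth$events$t), ]
      collB <- collect_evoked(truth, extra, sigma_ms = run_cfg$sigma_ms,
                              noise = coll$noise)
      all_trials <- mapply(bind_trials, coll$trials, collB$trials,
                           SIMPLIFY = FALSE)
      stims <- rbind(stims, extra)
    } else {
      all_trials <- coll$trials
    }
    nrn_ids <- vapply(truth$neurons, function(nr) nr$id, 1L)
    neuron_spikes <- lapply(nrn_ids, function(id) neuron_spike_times(truth, id))
    names(neuron_spikes) <- as.character(nrn_ids)
    neuron_tetrode <- stats::setNames(
      vapply(truth$neurons, function(nr) nr$tetrode_id, 1L),
      as.character(nrn_ids))
    judgment <- lapply(targets, function(tg)
      judge_pairs(neuron_spikes, neuron_tetrode, all_trials, stims, tg,
                  R_max = run_cfg$R_max, min_triggers = run_cfg$min_triggers,
                  cap = run_cfg$cap, sigma_mult = run_cfg$sigma_mult,
                  jitter_max = run_cfg$jitter_max))
    list(truth = truth, targets = targets, ctrl = ctrl, stims = stims,
         trials = all_trials, judgment = judgment, noise = coll$noise)
  })
}

#' Score a judgment against the simulated ground truth
#'
#' For every projection neuron, checks whether some successful pair links
#' it to a target at its projection site whose time range brackets the true
#' latency; reports the recovery fraction, the false-positive count among
#' synaptic responders (with their jitter QD), and the adopted-pair latency
#' errors relative to the true `d + C`.
#'
#' @param judgment output of [judge_pairs()].
#' @param truth the `sim_ground_truth` that was judged.
#' @param targets the target list the judgment refers to.
#' @param latency_tol_ms tolerance when matching a target's time range to
#'   the true latency.
#' @return list with `n_projection`, `n_recovered`, `recovery`,
#'   `false_synaptic` (successful synaptic responders), `latency_err_ms`
#'   (per recovered projection neuron), `per_neuron` table.
#' @export
evaluate_recovery <- function(judgment, truth, targets,
                              latency_tol_ms = 0.5) {
  nrns <- truth$neurons
  proj <- Filter(function(nr) length(nr$projections) > 0, nrns)
  syn <- Filter(function(nr) length(nr$synaptic_inputs) > 0 &&
                  length(nr$projections) == 0, nrns)
  rows <- list()
  for (nr in proj) {
    p <- nr$projections[[1]]
    lat_true <- p$d + p$C
    i <- which(judgment$neuron == as.character(nr$id) & judgment$success)
    hit <- FALSE; lat_err <- NA_real_
    for (k in i) {
      tg <- targets[[judgment$target[k]]]
      if (tg$site == p$site &&
          tg$t_min - latency_tol_ms <= lat_true &&
          tg$t_max + latency_tol_ms >= lat_true) {
        hit <- TRUE
        if (judgment$adopted[k] || is.na(lat_err))
          lat_err <- judgment$latency_med[k] - lat_true
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      neuron = nr$id, site = p$site, lat_true = lat_true,
      recovered = hit, latency_err = lat_err)
  }
  per_neuron <- do.call(rbind, rows)
  syn_ids <- vapply(syn, function(nr) as.character(nr$id), "")
  fp <- judgment[judgment$neuron %in% syn_ids & judgment$success, ]
  list(n_projection = nrow(per_neuron),
       n_recovered = sum(per_neuron$recovered),
       recovery = mean(per_neuron$recovered),
       false_synaptic = fp,
       latency_err_ms = per_neuron$latency_err[per_neuron$recovered],
       per_neuron = per_neuron)
}
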