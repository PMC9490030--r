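# Shared fixture builders. Everything is generated in code; no data files.

# Trial array (time x 4 x trials) built directly from per-trial spike lists.
# events: list over trials; each element a data.frame with t_ms (relative to
# stimulation onset), amp (4-vector rows as list-columns not needed: use
# columns a1..a4, negative trough depths)
make_trial_array <- function(events, n_trials, T_range_ms = 30, fs = 20000,
                             noise_sd = 0, ttp_ms = 0.7) {
  t_axis <- seq(-T_range_ms, T_range_ms, by = 1000 / fs)
  n_t <- length(t_axis)
  tpl <- spike_template(ttp_ms)
  sup <- attr(tpl, "support")
  arr <- if (noise_sd > 0)
    array(stats::rnorm(n_t * 4 * n_trials, 0, noise_sd), c(n_t, 4, n_trials))
  else array(0, c(n_t, 4, n_trials))
  for (j in seq_len(n_trials)) {
    ev <- events[[j]]
    if (is.null(ev) || !nrow(ev)) next
    for (k in seq_len(nrow(ev))) {
      idx <- which(t_axis >= ev$t_ms[k] + sup[1] & t_axis <= ev$t_ms[k] + sup[2])
      if (!length(idx)) next
      w <- tpl(t_axis[idx] - ev$t_ms[k])
      amp <- abs(as.numeric(ev[k, c("a1", "a2", "a3", "a4")]))
      arr[idx, , j] <- arr[idx, , j] + outer(w, amp)
    }
  }
  attr(arr, "t_axis_ms") <- t_axis
  arr
}

ev_row <- function(t_ms, amp) {
  data.frame(t_ms = t_ms, a1 = amp[1], a2 = amp[2], a3 = amp[3], a4 = amp[4])
}

# A clean antidromic cluster: one spike per trial at lat +/- N(0, jitter_sd)
cluster_events <- function(n_trials, lat_ms, amp, jitter_sd = 0.05) {
  lapply(seq_len(n_trials), function(j)
    ev_row(lat_ms + stats::rnorm(1, 0, jitter_sd), amp))
}

# Hand-assembled noise-free collision session: one projection neuron; the
# first n_coll stimulations are "collection" trials with no spontaneous
# spikes, then n_test "test" trials alternate trigger (spontaneous spike in
# the trigger range -> collision) and no-trigger (no spikes).
make_collision_fixture <- function(n_coll = 100, n_test = 500, lat = 10,
                                   d = 0.5, R_prime = 1, jitter_sd = 0.02,
                                   seed = 5) {
  set.seed(seed)
  nr <- sim_neuron(1, 1, c(-20, -9, -5, -2), rate = 0,
                   projections = list(list(site = 1, d = d, C = lat - d,
                                           jitter_sd = jitter_sd,
                                           R_prime = R_prime)))
  n_all <- n_coll + n_test
  t_stim <- 2000 + (seq_len(n_all) - 1) * 1500
  schedule <- data.frame(stim_id = seq_len(n_all), site = 1, t_stim = t_stim,
                         duration_ms = 1, t_off = t_stim + 1)
  is_test <- seq_len(n_all) > n_coll
  is_trig <- is_test & (seq_len(n_all) %% 2L == 0L)
  spont <- t_stim[is_trig] - 3          # inside the trigger range
  proj <- nr$projections[[1]]
  jit <- stats::rnorm(n_all, 0, jitter_sd)
  out <- lapply(seq_len(n_all), function(i)
    evoked_spike_outcome(proj, t_stim[i], spont, "antidromic", R = nr$R,
                         jitter = jit[i]))
  events <- rbind(
    data.frame(neuron = 1L, t = spont, kind = "spontaneous",
               eliminated = FALSE, cause = "none", stim_id = NA_integer_,
               site = NA_integer_, scale = 1),
    data.frame(neuron = 1L, t = vapply(out, `[[`, 0, "t"),
               kind = "antidromic",
               eliminated = !vapply(out, `[[`, TRUE, "present"),
               cause = vapply(out, `[[`, "", "cause"),
               stim_id = schedule$stim_id, site = 1L,
               scale = nr$evoked_scale))
  cfg <- sim_config(list(nr), list(1:4), sites = 1, N_anti = n_all,
                    noise_sd = 0, lfp_sd = 0,
                    schedule_s = max(t_stim) / 1000 + 10,
                    session_s = max(t_stim) / 1000 + 20)
  truth <- structure(list(neurons = list(nr), events = events,
                          schedule = schedule, spont = list("1" = spont),
                          config = cfg, seed = seed),
                     class = "sim_ground_truth")
  list(truth = truth, is_trig = is_trig, is_test = is_test, spont = spont,
       lat = lat)
}

# filtered (not normalized; noise-free) trial array for a fixture
filtered_trials <- function(truth, stims = truth$schedule) {
  raw <- render_trials(truth, 1, stims, noise_sd = 0, lfp_sd = 0)
  d <- dim(raw)
  flt <- gaussian_subtract_filter(matrix(raw, d[1]), 0.25, truth$config$fs)
  flt <- array(flt, d)
  attr(flt, "t_axis_ms") <- attr(raw, "t_axis_ms")
  flt
}
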