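#' Biphasic spike waveform template
#'
#' Extracellular spikes are modelled as a negative trough followed by a
#' positive after-peak, parameterized by the trough width (FWHM) and the
#' trough-to-peak duration. Wide templates (default 0.7 ms trough-to-peak)
#' stand for regular-spiking/projection-like cells, narrow ones (0.3 ms)
#' for fast-spiking-like cells. The template is returned as a vectorized
#' function of time in ms (trough at 0, depth -1), so events can be rendered
#' at arbitrary sub-sample offsets; the attribute `"support"` gives the time
#' range outside which the template is negligible.
#'
#' @param ttp_ms trough-to-peak duration in ms.
#' @param trough_w_ms trough full width at half maximum in ms.
#' @param pos_frac amplitude of the positive after-peak relative to the
#'   trough depth.
#' @return function `f(t_ms)` with attribute `support = c(t_lo, t_hi)`.
#' @export
spike_template <- function(ttp_ms = 0.7, trough_w_ms = 0.25, pos_frac = 0.4) {
  stopifnot(ttp_ms > 0, trough_w_ms > 0, pos_frac >= 0)
  s1 <- trough_w_ms / 2.3548  # FWHM -> SD
  s2 <- 1.5 * s1
  f <- function(t_ms) {
    -exp(-t_ms^2 / (2 * s1^2)) +
      pos_frac * exp(-(t_ms - ttp_ms)^2 / (2 * s2^2))
  }
  attr(f, "support") <- c(-4 * s1, ttp_ms + 4 * s2)
  attr(f, "ttp_ms") <- ttp_ms
  f
}

#' Simulated neuron
#'
#' A neuron lives on one tetrode with a fixed four-channel peak-amplitude
#' pattern (non-positive, in units of the raw noise SD) and a spontaneous
#' Poisson rate with somatic refractory period `R`. It may project axons to
#' stimulation sites (each projection has an evoking delay `d`, conduction
#' time `C`, antidromic latency jitter SD, and axonal refractory period
#' `R_prime`) and/or receive synaptic input from sites (latency, jitter
#' quartile deviation, response probability). Evoked spikes are rendered
#' `evoked_scale` times larger than spontaneous ones.
#'
#' @param id integer neuron id.
#' @param tetrode_id integer tetrode index.
#' @param amp_pattern numeric length-4, all `<= 0`: per-channel trough depths
#'   in raw-noise-SD units.
#' @param ttp_ms trough-to-peak duration of the waveform template (ms).
#' @param rate spontaneous rate (Hz), `>= 0`.
#' @param R somatic refractory period (ms), `> 0`.
#' @param projections list of lists with fields `site`, `d`, `C`,
#'   `jitter_sd`, `R_prime` (all times in ms).
#' @param synaptic_inputs list of lists with fields `site`, `latency`,
#'   `jitter_QD`, `probability`.
#' @param evoked_scale ratio of evoked to spontaneous spike amplitude
#'   (`>= 1`).
#' @param trough_w_ms trough width (FWHM, ms) of the template.
#' @return object of class `sim_neuron`.
#' @export
sim_neuron <- function(id, tetrode_id, amp_pattern, ttp_ms = 0.7, rate = 8,
                       R = 2.8, projections = list(),
                       synaptic_inputs = list(), evoked_scale = 1.2,
                       trough_w_ms = 0.25) {
  if (length(amp_pattern) != 4L || any(amp_pattern > 0))
    stop("sim_neuron: amp_pattern must be 4 non-positive values")
  if (rate < 0) stop("sim_neuron: rate must be >= 0")
  if (R <= 0) stop("sim_neuron: R must be > 0")
  if (evoked_scale < 1) stop("sim_neuron: evoked_scale must be >= 1")
  for (p in projections) {
    if (is.null(p$site) || p$d <= 0 || p$C <= 0)
      stop("sim_neuron: projection needs site and positive d, C")
  }
  structure(list(id = as.integer(id), tetrode_id = as.integer(tetrode_id),
                 amp_pattern = as.numeric(amp_pattern),
                 ttp_ms = ttp_ms, trough_w_ms = trough_w_ms, rate = rate,
                 R = R, projections = projections,
                 synaptic_inputs = synaptic_inputs,
                 evoked_scale = evoked_scale),
            class = "sim_neuron")
}

#' Schedule site-rotating stimulations
#'
#' Stimulation sites are selected serially (rotation) with randomized
#' timing such that the gap between consecutive stimulations of the same
#' site is at least `I_same` and the gap between any two stimulations is at
#' least `I_diff` (defaults 1.0 s and 0.5 s, chosen to avoid epileptic
#' responses). Exactly `N_anti` stimulations are scheduled per site.
#'
#' @param sites vector of site ids.
#' @param I_same minimum same-site interval (s).
#' @param I_diff minimum any-pair interval (s).
#' @param N_anti number of stimulations per site.
#' @param session_length_s available session length (s); scheduling past it
#'   is an error.
#' @param durations_ms stimulation (light pulse) duration per site, ms;
#'   recycled to `length(sites)`.
#' @param t_start_s time of the first stimulation (s).
#' @param gap_jitter_s upper bound of the uniform random slack added to each
#'   minimum-interval wait.
#' @return data frame: `stim_id`, `site`, `t_stim` (ms), `duration_ms`,
#'   `t_off` (ms).
#' @export
schedule_stimulations <- function(sites, I_same = 1.0, I_diff = 0.5,
                                  N_anti = 100, session_length_s,
                                  durations_ms = 1.0, t_start_s = 2,
                                  gap_jitter_s = 0.2) {
  ns <- length(sites)
  durations_ms <- rep_len(durations_ms, ns)
  n_ev <- N_anti * ns
  site_seq <- rep_len(seq_len(ns), n_ev)
  t <- numeric(n_ev)
  last_any <- t_start_s * 1000 - I_diff * 1000
  last_site <- rep(-Inf, ns)
  jit <- stats::runif(n_ev, 0, gap_jitter_s * 1000)
  for (k in seq_len(n_ev)) {
    s <- site_seq[k]
    tk <- max(last_any + I_diff * 1000, last_site[s] + I_same * 1000) + jit[k]
    t[k] <- tk
    last_any <- tk
    last_site[s] <- tk
  }
  if (t[n_ev] > session_length_s * 1000)
    stop(sprintf(
      "schedule_stimulations: %d events need %.1f s but session is %.1f s",
      n_ev, t[n_ev] / 1000, session_length_s))
  data.frame(stim_id = seq_len(n_ev), site = sites[site_seq], t_stim = t,
             duration_ms = durations_ms[site_seq],
             t_off = t + durations_ms[site_seq])
}

#' Outcome of an evoked spike under collision and refractory physics
#'
#' Decides whether a stimulation-evoked spike survives, given the neuron's
#' spontaneous spike times. The somatic arrival time is
#' `t_A = t_stim + d + C + jitter`. Two elimination rules apply:
#' \itemize{
#'   \item Collision (antidromic spikes only): a spontaneous spike travelling
#'     down the axon annihilates the antidromic spike if it occupies the
#'     axon when the evoked spike is initiated, i.e. if some
#'     `t_spon <= t_A` satisfies `t_spon + C + R_prime >= t_stim + d`.
#'   \item Refractory (both antidromic and synaptic spikes): the soma cannot
#'     fire if a spontaneous spike occurred in `[t_A - R, t_A)`.
#' }
#' When both rules fire, collision takes precedence in the reported cause.
#' For synaptic spikes `d + C` is read as the synaptic response latency and
#' only the refractory rule applies.
#'
#' @param proj list with `d`, `C`, `R_prime` (ms); for synaptic outcomes
#'   `d + C` is the latency and `R_prime` is ignored.
#' @param t_stim stimulation onset (ms).
#' @param spont_times sorted numeric vector of the neuron's spontaneous
#'   spike times (ms).
#' @param kind `"antidromic"` or `"synaptic"`.
#' @param R somatic refractory period (ms).
#' @param jitter latency jitter added to `t_A` (ms); the collision
#'   inequality uses the unjittered axonal parameters.
#' @return list with `present` (logical), `cause` (`"none"`, `"collision"`
#'   or `"refractory"`), and `t` (the arrival time `t_A`).
#' @export
evoked_spike_outcome <- function(proj, t_stim, spont_times,
                                 kind = c("antidromic", "synaptic"),
                                 R = 2.8, jitter = 0) {
  kind <- match.arg(kind)
  t_A <- t_stim + proj$d + proj$C + jitter
  cause <- "none"
  if (kind == "antidromic" &&
      any(spont_times <= t_A &
          spont_times + proj$C + proj$R_prime >= t_stim + proj$d)) {
    cause <- "collision"
  } else if (any(spont_times >= t_A - R & spont_times < t_A)) {
    cause <- "refractory"
  }
  list(present = cause == "none", cause = cause, t = t_A)
}

# Spontaneous Poisson train with refractory thinning: inter-spike intervals
# are R plus an exponential chosen so the nominal rate is preserved.
gen_spont_train <- function(rate, R, t_end_ms, t_start_ms = 0) {
  if (rate <= 0) return(numeric(0))
  mean_isi <- 1000 / rate
  if (mean_isi <= R)
    stop("gen_spont_train: rate incompatible with refractory period")
  n_guess <- ceiling((t_end_ms - t_start_ms) / mean_isi * 1.5) + 20L
  t <- t_start_ms + cumsum(R + stats::rexp(n_guess, 1 / (mean_isi - R)))
  while (t[length(t)] < t_end_ms) {
    t <- c(t, t[length(t)] +
             cumsum(R + stats::rexp(n_guess, 1 / (mean_isi - R))))
  }
  t[t <= t_end_ms]
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(code)
}

#' Generate a labelled ground-truth session
#'
#' Builds the complete latent state of a simulated session: spontaneous
#' Poisson trains (with refractory thinning) for every neuron, a
#' site-rotating stimulation schedule for the evoked-response collection
#' phase, and every evoked (antidromic or synaptic) spike labelled with its
#' survival or elimination cause under [evoked_spike_outcome()]. The result
#' is reproducible for a fixed seed.
#'
#' @param config a simulation config as returned by [sim_config()].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return object of class `sim_ground_truth`: list with `neurons`,
#'   `events` (data frame: `neuron`, `t` ms, `kind`, `eliminated`, `cause`,
#'   `stim_id`, `site`, `scale`), `schedule`, `config`, `seed`.
#' @export
make_ground_truth <- function(config, seed = NULL) {
  validate_sim_config(config)
  with_seed(seed, {
    schedule <- schedule_stimulations(
      config$sites, config$I_same, config$I_diff, config$N_anti,
      session_length_s = config$schedule_s,
      durations_ms = config$durations_ms)
    spont <- lapply(config$neurons, function(nr)
      gen_spont_train(nr$rate, nr$R, config$session_s * 1000))
    names(spont) <- vapply(config$neurons, function(nr) as.character(nr$id), "")
    ev <- evoked_events_for(config$neurons, spont, schedule, config)
    spont_df <- do.call(rbind, lapply(seq_along(config$neurons), function(i) {
      ts <- spont[[i]]
      if (!length(ts)) return(NULL)
      data.frame(neuron = config$neurons[[i]]$id, t = ts,
                 kind = "spontaneous", eliminated = FALSE, cause = "none",
                 stim_id = NA_integer_, site = NA_integer_, scale = 1)
    }))
    events <- rbind(spont_df, ev)
    events <- events[order(events$t), ]
    rownames(events) <- NULL
    structure(list(neurons = config$neurons, events = events,
                   schedule = schedule, spont = spont, config = config,
                   seed = seed),
              class = "sim_ground_truth")
  })
}

# Label evoked events (with elimination causes) for a stimulation schedule.
# Used for the initial schedule and again for triggered stimulations added
# by the closed-loop phase.
evoked_events_for <- function(neurons, spont, schedule, config) {
  rows <- list()
  add <- function(df) rows[[length(rows) + 1L]] <<- df
  for (i in seq_along(neurons)) {
    nr <- neurons[[i]]
    ts <- spont[[i]]
    for (p in nr$projections) {
      st <- schedule[schedule$site == p$site, ]
      if (!nrow(st)) next
      jit <- stats::rnorm(nrow(st), 0, p$jitter_sd)
      out <- lapply(seq_len(nrow(st)), function(j)
        evoked_spike_outcome(p, st$t_stim[j], ts, "antidromic",
                             R = nr$R, jitter = jit[j]))
      add(data.frame(neuron = nr$id,
                     t = vapply(out, `[[`, 0, "t"),
                     kind = "antidromic",
                     eliminated = !vapply(out, `[[`, TRUE, "present"),
                     cause = vapply(out, `[[`, "", "cause"),
                     stim_id = st$stim_id, site = st$site,
                     scale = nr$evoked_scale))
    }
    for (sy in nr$synaptic_inputs) {
      st <- schedule[schedule$site == sy$site, ]
      if (!nrow(st)) next
      resp <- stats::runif(nrow(st)) < sy$probability
      st <- st[resp, ]
      if (!nrow(st)) next
      jit <- stats::rnorm(nrow(st), 0, sy$jitter_QD / 0.6745)
      fake_proj <- list(d = sy$latency / 2, C = sy$latency / 2, R_prime = 0)
      out <- lapply(seq_len(nrow(st)), function(j)
        evoked_spike_outcome(fake_proj, st$t_stim[j], ts, "synaptic",
                             R = nr$R, jitter = jit[j]))
      add(data.frame(neuron = nr$id,
                     t = vapply(out, `[[`, 0, "t"),
                     kind = "synaptic",
                     eliminated = !vapply(out, `[[`, TRUE, "present"),
                     cause = vapply(out, `[[`, "", "cause"),
                     stim_id = st$stim_id, site = st$site,
                     scale = nr$evoked_scale))
    }
  }
  if (!length(rows)) {
    return(data.frame(neuron = integer(0), t = numeric(0),
                      kind = character(0), eliminated = logical(0),
                      cause = character(0), stim_id = integer(0),
                      site = integer(0), scale = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Spike times of one simulated neuron (its "cluster")
#'
#' Spontaneous spikes plus surviving evoked spikes, sorted; this is what a
#' (perfect) spike sorter would assign to the unit, and is the cluster
#' input to the judgment stage.
#'
#' @param truth a `sim_ground_truth`.
#' @param neuron_id neuron id.
#' @return sorted numeric vector of spike times (ms).
#' @export
neuron_spike_times <- function(truth, neuron_id) {
  e <- truth$events
  sort(e$t[e$neuron == neuron_id & !e$eliminated])
}

# template lookup per neuron id
neuron_templates <- function(neurons) {
  tpl <- lapply(neurons, function(nr)
    spike_template(nr$ttp_ms, nr$trough_w_ms))
  names(tpl) <- vapply(neurons, function(nr) as.character(nr$id), "")
  tpl
}

# low-frequency background (stands in for local field potential)
lfp_component <- function(t_ms, sd, n_ch) {
  if (sd <= 0) return(matrix(0, length(t_ms), n_ch))
  f <- stats::runif(n_ch, 2, 8)      # Hz
  ph <- stats::runif(n_ch, 0, 2 * pi)
  amp <- sd * sqrt(2)
  vapply(seq_len(n_ch),
         function(c) amp * sin(2 * pi * f[c] * t_ms / 1000 + ph[c]),
         numeric(length(t_ms)))
}

#' Render a continuous raw recording from ground truth
#'
#' Additive model: white Gaussian noise, a slow sinusoidal background, and
#' each non-eliminated event's template scaled by the neuron's amplitude
#' pattern (times `evoked_scale` for evoked kinds, already folded into the
#' event's `scale`). Eliminated events render nothing. Events are placed at
#' their exact (sub-sample) times by evaluating the analytic template.
#'
#' @param truth a `sim_ground_truth`.
#' @param noise_sd white noise SD in raw units (default from config).
#' @param t_range_ms optional `c(t0, t1)` in ms; default the whole session.
#' @param lfp_sd slow-background SD (default from config).
#' @return a [recording_segment()].
#' @export
render_recording <- function(truth, noise_sd = truth$config$noise_sd,
                             t_range_ms = NULL,
                             lfp_sd = truth$config$lfp_sd) {
  cfg <- truth$config
  fs <- cfg$fs
  if (is.null(t_range_ms)) t_range_ms <- c(0, cfg$session_s * 1000)
  n <- round(ms_to_samples(t_range_ms[2] - t_range_ms[1], fs))
  n_ch <- 4L * length(cfg$tetrodes)
  x <- if (noise_sd > 0)
    matrix(stats::rnorm(n * n_ch, 0, noise_sd), n, n_ch)
  else matrix(0, n, n_ch)
  grid_ms <- t_range_ms[1] + samples_to_ms(seq_len(n) - 1, fs)
  x <- x + lfp_component(grid_ms, lfp_sd, n_ch)
  tpl <- neuron_templates(truth$neurons)
  nrn_by_id <- stats::setNames(truth$neurons,
                               vapply(truth$neurons, function(z)
                                 as.character(z$id), ""))
  ev <- truth$events[!truth$events$eliminated, ]
  ev <- ev[ev$t > t_range_ms[1] - 5 & ev$t < t_range_ms[2] + 5, ]
  for (k in seq_len(nrow(ev))) {
    id <- as.character(ev$neuron[k])
    nr <- nrn_by_id[[id]]
    f <- tpl[[id]]
    sup <- attr(f, "support")
    i0 <- max(1L, floor(ms_to_samples(ev$t[k] + sup[1] - t_range_ms[1], fs)))
    i1 <- min(n, ceiling(ms_to_samples(ev$t[k] + sup[2] - t_range_ms[1], fs)) + 1L)
    if (i1 < i0) next
    w <- f(grid_ms[i0:i1] - ev$t[k]) * ev$scale[k]
    chs <- cfg$tetrodes[[nr$tetrode_id]]
    # template trough is -1; amp_pattern holds the (negative) trough depths
    x[i0:i1, chs] <- x[i0:i1, chs] + outer(w, abs(nr$amp_pattern))
  }
  recording_segment(x, fs, cfg$tetrodes, t0 = round(ms_to_samples(t_range_ms[1], fs)))
}

#' Render peristimulus trial snippets for one tetrode
#'
#' For each stimulation in `stims`, renders the raw trace of the tetrode's
#' four channels over `[-T_range, +T_range]` around stimulation onset, with
#' the same additive model as [render_recording()]. Rendering per-trial
#' snippets avoids materializing hour-long sessions when only the evoked
#' responses are needed.
#'
#' @param truth a `sim_ground_truth`.
#' @param tetrode_id tetrode index.
#' @param stims data frame with at least `t_stim` (ms); default the full
#'   schedule.
#' @param T_range_ms half-window in ms.
#' @param noise_sd,lfp_sd see [render_recording()].
#' @return 3-D array, time x 4 channels x trials, with attribute
#'   `"t_axis_ms"` (trial-relative time of each row).
#' @export
render_trials <- function(truth, tetrode_id, stims = truth$schedule,
                          T_range_ms = truth$config$T_range_ms,
                          noise_sd = truth$config$noise_sd,
                          lfp_sd = truth$config$lfp_sd) {
  cfg <- truth$config
  fs <- cfg$fs
  t_axis <- seq(-T_range_ms, T_range_ms, by = 1000 / fs)
  n_t <- length(t_axis)
  n_trial <- nrow(stims)
  ids <- vapply(truth$neurons, function(nr) nr$tetrode_id, 1L) == tetrode_id
  nrns <- truth$neurons[ids]
  tpl <- neuron_templates(nrns)
  nrn_ids <- vapply(nrns, function(nr) nr$id, 1L)
  ev <- truth$events[!truth$events$eliminated &
                       truth$events$neuron %in% nrn_ids, ]
  ev <- ev[order(ev$t), ]
  amp_by_id <- lapply(nrns, function(nr) nr$amp_pattern)
  names(amp_by_id) <- as.character(nrn_ids)
  out <- if (noise_sd > 0)
    array(stats::rnorm(n_t * 4 * n_trial, 0, noise_sd), c(n_t, 4, n_trial))
  else array(0, c(n_t, 4, n_trial))
  pad <- 2  # ms, template support margin
  lo <- findInterval(stims$t_stim - T_range_ms - pad, ev$t) + 1L
  hi <- findInterval(stims$t_stim + T_range_ms + pad, ev$t)
  for (j in seq_len(n_trial)) {
    if (lfp_sd > 0)
      out[, , j] <- out[, , j] + lfp_component(t_axis, lfp_sd, 4L)
    if (hi[j] < lo[j]) next
    for (k in lo[j]:hi[j]) {
      id <- as.character(ev$neuron[k])
      f <- tpl[[id]]
      sup <- attr(f, "support")
      trel <- ev$t[k] - stims$t_stim[j]
      i0 <- max(1L, floor(ms_to_samples(trel + sup[1] + T_range_ms, fs)))
      i1 <- min(n_t, ceiling(ms_to_samples(trel + sup[2] + T_range_ms, fs)) + 1L)
      if (i1 < i0) next
      w <- f(t_axis[i0:i1] - trel) * ev$scale[k]
      out[i0:i1, , j] <- out[i0:i1, , j] + outer(w, abs(amp_by_id[[id]]))
    }
  }
  attr(out, "t_axis_ms") <- t_axis
  out
}
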