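#' Simulation configuration
#'
#' Bundles the experiment geometry (tetrodes, stimulation sites), the
#' stimulation parameters of the evoked-collection phase, the neuron
#' population and the noise model. Use [default_study_config()] for the
#' standard synthetic session used in the package's validation.
#'
#' @param neurons list of [sim_neuron()] objects.
#' @param tetrodes list of length-4 integer channel groups.
#' @param sites vector of stimulation site ids.
#' @param fs sampling rate (samples/s).
#' @param N_anti stimulations per site in the evoked-collection phase.
#' @param I_same,I_diff minimum same-site / any-pair stimulation intervals (s).
#' @param durations_ms light-pulse duration per site (ms).
#' @param T_range_ms peristimulus half-window (ms).
#' @param noise_sd white-noise SD (raw units; amplitude patterns are
#'   expressed in this unit).
#' @param lfp_sd SD of the slow sinusoidal background (raw units).
#' @param schedule_s session length available for the evoked-collection
#'   schedule (s).
#' @param session_s total simulated session length (s), covering the
#'   closed-loop collision phase after the collection phase.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(neurons, tetrodes, sites = 1:3, fs = 20000,
                       N_anti = 100, I_same = 1.0, I_diff = 0.5,
                       durations_ms = 1.0, T_range_ms = 30,
                       noise_sd = 1.0, lfp_sd = 3.0,
                       schedule_s = 300, session_s = 900) {
  cfg <- structure(list(neurons = neurons, tetrodes = tetrodes, sites = sites,
                        fs = fs, N_anti = N_anti, I_same = I_same,
                        I_diff = I_diff, durations_ms = durations_ms,
                        T_range_ms = T_range_ms, noise_sd = noise_sd,
                        lfp_sd = lfp_sd, schedule_s = schedule_s,
                        session_s = session_s),
                   class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  for (f in c("fs", "N_anti", "I_same", "I_diff", "T_range_ms",
              "schedule_s", "session_s")) {
    if (is.null(cfg[[f]]) || cfg[[f]] <= 0)
      stop(sprintf("sim_config: field '%s' must be positive", f))
  }
  if (cfg$noise_sd < 0) stop("sim_config: field 'noise_sd' must be >= 0")
  if (!length(cfg$tetrodes)) stop("sim_config: field 'tetrodes' is empty")
  if (any(vapply(cfg$tetrodes, length, 1L) != 4L))
    stop("sim_config: field 'tetrodes' must contain groups of 4 channels")
  for (nr in cfg$neurons) {
    if (!inherits(nr, "sim_neuron"))
      stop("sim_config: field 'neurons' must contain sim_neuron objects")
    if (nr$tetrode_id > length(cfg$tetrodes))
      stop("sim_config: field 'neurons' references unknown tetrode")
  }
  invisible(cfg)
}

# Random four-channel trough pattern: one dominant channel, the rest scaled
# down, all non-positive. Patterns are in raw-noise-SD units; the symmetric
# high-pass filter attenuates these narrow troughs to roughly 0.42 of the
# raw depth, so the default range keeps filtered spikes 6-13 SD above the
# filtered noise, the regime of well-isolated units.
random_amp_pattern <- function(dominant, depth = stats::runif(1, 14, 25)) {
  rel <- stats::runif(4, 0.1, 0.7)
  rel[dominant] <- 1
  -depth * rel
}

#' Default synthetic study session
#'
#' The standard validation conditions: 2 tetrodes and 3 stimulation sites,
#' 100 stimulations per site in the collection phase. Per tetrode the
#' population holds 10 projection neurons (antidromic latencies spread over
#' 5-15 ms, jitter SD 0.05 ms, sites assigned in rotation), 10 synaptic
#' responders (latencies 6-14 ms, jitter QD 1-2 ms, response probability
#' 0.7) and 5 fast-spiking-like non-responders (narrow 0.3 ms waveforms,
#' 20 Hz). Projection and responder rates default to 5 Hz; the somatic
#' refractory period is 2.8 ms (juxtacellular estimate for the recorded
#' area) and the axonal refractory period 1 ms.
#'
#' @param seed seed for drawing the population's amplitude patterns and
#'   latencies.
#' @param n_proj,n_syn,n_fs neurons per tetrode in each class.
#' @param rate spontaneous rate (Hz) of projection/responder neurons.
#' @param ... overrides passed on to [sim_config()].
#' @return a `sim_config`.
#' @export
default_study_config <- function(seed = 1, n_proj = 10, n_syn = 10,
                                 n_fs = 5, rate = 5, ...) {
  with_seed(seed, {
    sites <- 1:3
    tetrodes <- list(1:4, 5:8)
    neurons <- list()
    id <- 0L
    for (tt in 1:2) {
      lat <- seq(5, 15, length.out = n_proj) +
        stats::runif(n_proj, -0.3, 0.3)
      for (i in seq_len(n_proj)) {
        id <- id + 1L
        neurons[[id]] <- sim_neuron(
          id, tt, random_amp_pattern(((id - 1L) %% 4L) + 1L),
          ttp_ms = 0.7, rate = rate, R = 2.8,
          projections = list(list(site = sites[((i - 1L) %% 3L) + 1L],
                                  d = 0.5, C = lat[i] - 0.5,
                                  jitter_sd = 0.05, R_prime = 1.0)),
          evoked_scale = 1.2)
      }
      for (i in seq_len(n_syn)) {
        id <- id + 1L
        neurons[[id]] <- sim_neuron(
          id, tt, random_amp_pattern(((id - 1L) %% 4L) + 1L),
          ttp_ms = 0.7, rate = rate, R = 2.8,
          synaptic_inputs = list(list(site = sites[((i - 1L) %% 3L) + 1L],
                                      latency = stats::runif(1, 6, 14),
                                      jitter_QD = stats::runif(1, 1, 2),
                                      probability = 0.7)),
          evoked_scale = 1.2)
      }
      for (i in seq_len(n_fs)) {
        id <- id + 1L
        neurons[[id]] <- sim_neuron(
          id, tt, random_amp_pattern(((id - 1L) %% 4L) + 1L),
          ttp_ms = 0.3, trough_w_ms = 0.15, rate = 20, R = 1.5)
      }
    }
    sim_config(neurons = neurons, tetrodes = tetrodes, sites = sites, ...)
  })
}
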