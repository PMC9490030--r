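#' Closed-loop session configuration
#'
#' Parameters of the online collision-test controller. Defaults follow the
#' standard operating values: trigger criterion `theta_trig = 0.99` on the
#' direction cosine, `N_test = 200` collision tests per target, minimum
#' inter-stimulation intervals `I_same = 1.0` s (same site) and
#' `I_diff = 0.5` s (different sites), and a closed-loop actuation latency
#' bounded by 3.2 ms (two 1.6 ms communication packets). The emulated
#' latency of each trigger is drawn uniformly from `latency_range_ms`;
#' set both ends equal for a deterministic latency.
#'
#' @param theta_trig trigger threshold on the direction cosine, in (0, 1).
#' @param N_test collision-test budget per target.
#' @param I_same,I_diff minimum stimulation intervals (s).
#' @param latency_range_ms range of the emulated spike-to-TTL latency (ms);
#'   upper end is the 3.2 ms hardware guarantee.
#' @param T_range_ms peristimulus half-window (ms).
#' @param N_anti stimulations per site in the collection phase.
#' @param durations_ms stimulation duration per site (ms).
#' @return list of class `session_config`.
#' @export
session_config <- function(theta_trig = 0.99, N_test = 200, I_same = 1.0,
                           I_diff = 0.5, latency_range_ms = c(1.6, 3.2),
                           T_range_ms = 30, N_anti = 100,
                           durations_ms = 1.0) {
  if (theta_trig <= 0 || theta_trig >= 1)
    stop("session_config: theta_trig must be in (0,1)")
  for (v in list(N_test, I_same, I_diff, T_range_ms, N_anti))
    if (any(v <= 0)) stop("session_config: parameters must be positive")
  if (any(latency_range_ms < 0) || latency_range_ms[2] > 3.2)
    stop("session_config: latency range must lie within [0, 3.2] ms")
  structure(list(theta_trig = theta_trig, N_test = N_test, I_same = I_same,
                 I_diff = I_diff, latency_range_ms = latency_range_ms,
                 T_range_ms = T_range_ms, N_anti = N_anti,
                 durations_ms = durations_ms),
            class = "session_config")
}

#' Squared direction cosine between a detected spike and a target pattern
#'
#' The online trigger similarity: `D = (zhat . u)^2 / (|u|^2 a_k)`, the
#' squared cosine of the angle between the spike's rectified four-channel
#' peak vector and the target's median peak pattern. Invariant to positive
#' rescaling of either vector; 1 for parallel patterns, 0 for orthogonal.
#'
#' @param z_hat rectified four-channel peak vector of the spike.
#' @param a_k squared amplitude of the spike (`sum(z_hat^2)`).
#' @param u target peak-pattern vector.
#' @return D in \[0, 1\].
#' @export
trigger_similarity <- function(z_hat, a_k, u) {
  nu2 <- sum(u^2)
  if (a_k <= 0 || nu2 == 0)
    stop("trigger_similarity: zero amplitude vector")
  sum(z_hat * u)^2 / (nu2 * a_k)
}

#' Emulate a closed-loop collision-test session
#'
#' Replays a time-ordered detected-spike stream against a set of collision
#' targets. For every spike, the same-tetrode targets whose site satisfies
#' both minimum-interval constraints (relative to the would-be stimulation
#' onset) are evaluated by [trigger_similarity()]; if the best similarity
#' exceeds `theta_trig^2` the corresponding site is stimulated, with an
#' emulated spike-to-TTL latency drawn from the configured range. Each
#' stimulation decrements the fired target's test budget; targets retire at
#' `N_test` and the session ends when all targets are retired or the stream
#' is exhausted. When one spike matches several eligible targets, only the
#' highest-D target fires.
#'
#' @param spikes data frame of detected spikes: `t_ms`, `tetrode`,
#'   `z1..z4`, `a`; time-ordered.
#' @param targets list of [build_target()] objects (fields `tetrode_id`,
#'   `site`, `u` used).
#' @param cfg a [session_config()].
#' @param prior_stims optional data frame with `site`, `t_stim` (ms) of
#'   stimulations already delivered (e.g. the collection phase), so the
#'   interval constraints hold across phase boundaries.
#' @return list with `log` (data frame: `site`, `t_stim`, `t_off`,
#'   `trigger_t`, `target`, `D`, `latency_ms`) and `counts` (per-target
#'   stimulation counts).
#' @export
run_collision_session <- function(spikes, targets, cfg = session_config(),
                                  prior_stims = NULL) {
  n_tg <- length(targets)
  if (n_tg == 0L || nrow(spikes) == 0L)
    return(list(log = empty_stim_log(), counts = integer(n_tg)))
  th2 <- cfg$theta_trig^2
  Z <- as.matrix(spikes[, c("z1", "z2", "z3", "z4")])
  tg_tet <- vapply(targets, function(x) as.integer(x$tetrode_id), 1L)
  tg_site <- vapply(targets, function(x) as.integer(x$site), 1L)
  U <- vapply(targets, function(x) x$u / sqrt(sum(x$u^2)), numeric(4))
  D <- (Z %*% U)^2 / spikes$a                       # spikes x targets
  D[spikes$tetrode != rep(tg_tet, each = nrow(D))] <- -1
  sites <- sort(unique(tg_site))
  last_site <- stats::setNames(rep(-Inf, length(sites)), sites)
  last_any <- -Inf
  if (!is.null(prior_stims) && nrow(prior_stims)) {
    last_any <- max(prior_stims$t_stim)
    for (s in as.character(sites)) {
      ts <- prior_stims$t_stim[prior_stims$site == as.integer(s)]
      if (length(ts)) last_site[s] <- max(ts)
    }
  }
  counts <- integer(n_tg)
  retired <- rep(FALSE, n_tg)
  cand <- which(row_max(D) > th2)
  lat <- stats::runif(length(cand), cfg$latency_range_ms[1],
                      cfg$latency_range_ms[2])
  dur <- rep_len(cfg$durations_ms, max(sites))
  log_rows <- list()
  for (i in seq_along(cand)) {
    if (all(retired)) break
    k <- cand[i]
    onset <- spikes$t_ms[k] + lat[i]
    if (onset - last_any < cfg$I_diff * 1000) next
    ok <- !retired & D[k, ] > th2 &
      onset - last_site[as.character(tg_site)] >= cfg$I_same * 1000
    if (!any(ok)) next
    j <- which(ok)[which.max(D[k, ok])]
    s <- tg_site[j]
    counts[j] <- counts[j] + 1L
    if (counts[j] >= cfg$N_test) retired[j] <- TRUE
    last_any <- onset
    last_site[as.character(s)] <- onset
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(site = s, t_stim = onset, t_off = onset + dur[s],
                 trigger_t = spikes$t_ms[k], target = j, D = D[k, j],
                 latency_ms = lat[i])
  }
  log <- if (length(log_rows)) do.call(rbind, log_rows) else empty_stim_log()
  list(log = log, counts = counts)
}

empty_stim_log <- function() {
  data.frame(site = integer(0), t_stim = numeric(0), t_off = numeric(0),
             trigger_t = numeric(0), target = integer(0), D = numeric(0),
             latency_ms = numeric(0))
}

#' Build a detected-spike stream from simulated ground truth
#'
#' Converts the non-eliminated ground-truth events in a time range into the
#' detected-spike representation consumed by [run_collision_session()]:
#' each spike's four-channel peak vector is the neuron's amplitude pattern
#' (times the event scale) perturbed by per-channel Gaussian noise and
#' rectified, emulating measurement noise on the online peak estimates.
#'
#' @param truth a `sim_ground_truth`.
#' @param t_range_ms `c(t0, t1)` window of the stream (ms).
#' @param pattern_noise_sd per-channel noise SD on peak amplitudes
#'   (noise-SD units).
#' @param kinds event kinds included in the stream.
#' @return data frame: `t_ms`, `tetrode`, `neuron`, `z1..z4`, `a`.
#' @export
spike_stream <- function(truth, t_range_ms,
                         pattern_noise_sd = 1,
                         kinds = c("spontaneous", "antidromic", "synaptic")) {
  ev <- truth$events
  ev <- ev[!ev$eliminated & ev$kind %in% kinds &
             ev$t >= t_range_ms[1] & ev$t <= t_range_ms[2], ]
  ev <- ev[order(ev$t), ]
  nrn <- stats::setNames(truth$neurons,
                         vapply(truth$neurons, function(z)
                           as.character(z$id), ""))
  pat <- t(vapply(as.character(ev$neuron),
                  function(id) nrn[[id]]$amp_pattern, numeric(4)))
  tet <- vapply(as.character(ev$neuron),
                function(id) nrn[[id]]$tetrode_id, 1L)
  zh <- pmin(pat * ev$scale +
               matrix(stats::rnorm(4L * nrow(ev), 0, pattern_noise_sd),
                      ncol = 4L), 0)
  data.frame(t_ms = ev$t, tetrode = tet, neuron = ev$neuron,
             z1 = zh[, 1], z2 = zh[, 2], z3 = zh[, 3], z4 = zh[, 4],
             a = rowSums(zh^2))
}
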