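test_that("stimulation scheduling honors counts and interval constraints", {
  set.seed(1)
  sch <- schedule_stimulations(1, N_anti = 1, session_length_s = 10)
  expect_equal(nrow(sch), 1)
  # counting oracle over 20 seeds: exactly N_anti per site, every same-site
  # gap >= I_same, every gap >= I_diff
  for (s in 1:20) {
    set.seed(s)
    sch <- schedule_stimulations(1:3, I_same = 1.0, I_diff = 0.5,
                                 N_anti = 100, session_length_s = 300)
    expect_equal(nrow(sch), 300)
    expect_true(all(table(sch$site) == 100))
    expect_true(all(diff(sch$t_stim) >= 500))
    for (site in 1:3)
      expect_true(all(diff(sch$t_stim[sch$site == site]) >= 1000))
    expect_true(all(sch$t_off > sch$t_stim))
  }
  expect_error(schedule_stimulations(1:3, N_anti = 100,
                                     session_length_s = 10), "session")
})

test_that("collision and refractory rules reproduce the printed inequalities", {
  proj <- list(d = 1, C = 9, R_prime = 1)
  # no spontaneous spikes: present
  expect_true(evoked_spike_outcome(proj, 0, numeric(0), "antidromic")$present)
  # t_spon = -5: -5 + 9 + 1 = 5 >= 1, antidromic collides ...
  o <- evoked_spike_outcome(proj, 0, -5, "antidromic", R = 2)
  expect_false(o$present); expect_equal(o$cause, "collision")
  # ... but a synaptic spike of equal latency survives (no axon to collide in)
  o2 <- evoked_spike_outcome(list(d = 5, C = 5, R_prime = 0), 0, -5,
                             "synaptic", R = 2)
  expect_true(o2$present)
  # t_spon = -9.5: -9.5 + 9 + 1 = 0.5 < 1, the spike "misses" the axon
  o3 <- evoked_spike_outcome(proj, 0, -9.5, "antidromic", R = 2)
  expect_true(o3$present); expect_equal(o3$cause, "none")
  # refractory hits both kinds: spike just before arrival t_A = 10
  o4 <- evoked_spike_outcome(list(d = 1, C = 9, R_prime = 0), 0, 9.5,
                             "antidromic", R = 2)
  expect_false(o4$present)
  o5 <- evoked_spike_outcome(list(d = 5, C = 5, R_prime = 0), 0, 9.5,
                             "synaptic", R = 2)
  expect_false(o5$present); expect_equal(o5$cause, "refractory")
  # collision takes precedence when both rules fire
  o6 <- evoked_spike_outcome(proj, 0, 9.5, "antidromic", R = 2)
  expect_equal(o6$cause, "collision")
})

small_cfg <- function(rate = 5, jitter_sd = 0.05, syn = FALSE, seed = 9) {
  withr::with_seed(seed, {
    nr <- if (syn)
      sim_neuron(1, 1, c(-18, -8, -4, -2), rate = rate,
                 synaptic_inputs = list(list(site = 1, latency = 10,
                                             jitter_QD = 1, probability = 1)))
    else
      sim_neuron(1, 1, c(-18, -8, -4, -2), rate = rate,
                 projections = list(list(site = 1, d = 0.5, C = 9.5,
                                         jitter_sd = jitter_sd,
                                         R_prime = 1)))
    sim_config(list(nr), list(1:4), sites = 1, N_anti = 100,
               schedule_s = 130, session_s = 140)
  })
}

test_that("ground truth is reproducible and empty for empty populations", {
  cfg0 <- sim_config(list(), list(1:4), sites = 1, N_anti = 5,
                     schedule_s = 20, session_s = 25)
  tr0 <- make_ground_truth(cfg0, seed = 1)
  expect_equal(nrow(tr0$events), 0)
  cfg <- small_cfg()
  tr1 <- make_ground_truth(cfg, seed = 42)
  tr2 <- make_ground_truth(cfg, seed = 42)
  expect_identical(tr1$events, tr2$events)
  expect_identical(tr1$schedule, tr2$schedule)
  # eliminated events always carry a cause; antidromic events have a stim
  ev <- tr1$events
  expect_true(all(ev$cause[ev$eliminated] %in% c("collision", "refractory")))
  expect_true(all(!is.na(ev$stim_id[ev$kind == "antidromic"])))
})

test_that("empirical latency spread separates antidromic from synaptic", {
  # Monte-Carlo oracle on the generator alone
  tr_a <- make_ground_truth(small_cfg(jitter_sd = 0.05), seed = 3)
  ev <- tr_a$events
  lat <- ev$t[ev$kind == "antidromic"] -
    tr_a$schedule$t_stim[ev$stim_id[ev$kind == "antidromic"]]
  expect_lt(quartile_dev(lat), 0.25)
  tr_s <- make_ground_truth(small_cfg(syn = TRUE), seed = 3)
  evs <- tr_s$events
  lats <- evs$t[evs$kind == "synaptic"] -
    tr_s$schedule$t_stim[evs$stim_id[evs$kind == "synaptic"]]
  expect_gt(quartile_dev(lats), 0.25)
  expect_equal(quartile_dev(lats), 1, tolerance = 0.35)  # configured QD 1 ms
})

test_that("noise-free rendering is additive and conserves events", {
  cfg <- small_cfg(rate = 2)
  tr <- make_ground_truth(cfg, seed = 4)
  # restrict to a 20 s window for a compact continuous render
  rec <- render_recording(tr, noise_sd = 0, t_range_ms = c(5000, 25000),
                          lfp_sd = 0)
  ev <- tr$events[!tr$events$eliminated &
                    tr$events$t > 5002 & tr$events$t < 24998, ]
  # threshold crossings on the dominant channel equal the number of
  # non-eliminated events (counting oracle; spikes are sparse at 2 Hz)
  on <- rec$samples[, 1] < -5
  runs <- rle(on)
  expect_equal(sum(runs$values), nrow(ev))
  # zero neurons, zero noise -> all-zero traces
  cfg0 <- sim_config(list(), list(1:4), sites = 1, N_anti = 3,
                     schedule_s = 15, session_s = 16)
  tr0 <- make_ground_truth(cfg0, seed = 1)
  rec0 <- render_recording(tr0, noise_sd = 0, t_range_ms = c(0, 1000),
                           lfp_sd = 0)
  expect_true(all(rec0$samples == 0))
})

test_that("evoked spikes render larger than spontaneous by evoked_scale", {
  cfg <- small_cfg(rate = 2)
  tr <- make_ground_truth(cfg, seed = 8)
  raw <- render_trials(tr, 1, noise_sd = 0, lfp_sd = 0)
  t_axis <- attr(raw, "t_axis_ms")
  ev <- tr$events
  ant <- ev[ev$kind == "antidromic" & !ev$eliminated, ]
  peaks_ev <- vapply(seq_len(nrow(ant)), function(i) {
    j <- ant$stim_id[i]
    rel <- ant$t[i] - tr$schedule$t_stim[j]
    idx <- which(abs(t_axis - rel) < 0.5)
    -min(raw[idx, 1, j])
  }, 0)
  # spontaneous spikes falling inside trial windows
  sp <- ev[ev$kind == "spontaneous", ]
  peaks_sp <- c()
  for (j in seq_len(nrow(tr$schedule))) {
    rel <- sp$t - tr$schedule$t_stim[j]
    for (r in rel[rel > -29 & rel < -1]) {
      idx <- which(abs(t_axis - r) < 0.5)
      peaks_sp <- c(peaks_sp, -min(raw[idx, 1, j]))
    }
  }
  expect_equal(median(peaks_ev) / median(peaks_sp),
               tr$neurons[[1]]$evoked_scale, tolerance = 0.05)
})

test_that("with zero noise, detection recalls exactly the surviving events", {
  cfg <- small_cfg(rate = 2)
  tr <- make_ground_truth(cfg, seed = 12)
  rec <- render_recording(tr, noise_sd = 0, t_range_ms = c(0, 30000),
                          lfp_sd = 0)
  z <- gaussian_subtract_filter(rec$samples, 0.25, rec$fs)
  # unit variance floor: what the 1 s warm-up would estimate on unit noise
  sp <- detect_spikes(z[, 1:4], v_init = 1, warmup_s = 0, fs = rec$fs)
  ev <- tr$events[!tr$events$eliminated & tr$events$t < 29998, ]
  got <- sp$t * 1000 / rec$fs
  # recall 1: every surviving event yields a detection at its trough;
  # precision 1: every detection lies within the rendered extent of some
  # event (the filtered biphasic shape can split into more than one
  # supra-threshold run, but never outside an event)
  expect_true(all(vapply(ev$t, function(t) any(abs(got - t) < 0.25), TRUE)))
  sup <- attr(spike_template(0.7), "support")
  expect_true(all(vapply(got, function(g)
    any(ev$t + sup[1] - 0.3 <= g & g <= ev$t + sup[2] + 0.3), TRUE)))
})

test_that("simulated neurons validate their parameters", {
  expect_error(sim_neuron(1, 1, c(1, -1, -1, -1)), "non-positive")
  expect_error(sim_neuron(1, 1, rep(-1, 4), rate = -2), "rate")
  expect_error(sim_neuron(1, 1, rep(-1, 4), R = 0), "R must")
  expect_error(sim_neuron(1, 1, rep(-1, 4), evoked_scale = 0.5),
               "evoked_scale")
  expect_error(sim_neuron(1, 1, rep(-1, 4),
                          projections = list(list(site = 1, d = -1, C = 5))),
               "positive d, C")
  expect_error(sim_config(list(sim_neuron(1, 9, rep(-1, 4))), list(1:4)),
               "unknown tetrode")
})
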