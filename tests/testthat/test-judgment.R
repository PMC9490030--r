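mk_target <- function(t_min = 9.8, t_max = 10.2, D = 1, protocol = "I",
                      channel = 1, window = c(9.5, 10.5)) {
  structure(list(tetrode_id = 1L, site = 1L, protocol = protocol,
                 u = c(-8, -3, -1, -0.5), t_min = t_min, t_max = t_max,
                 L_min = t_min - D, L_max = t_max, duration_ms = D,
                 channel = channel, window = window, alpha = 1),
            class = "collision_target")
}

mk_stims <- function(n, gap_ms = 2000, D = 1, t0 = 5000) {
  t <- t0 + (seq_len(n) - 1) * gap_ms
  data.frame(stim_id = seq_len(n), site = 1L, t_stim = t, duration_ms = D,
             t_off = t + D)
}

test_that("trigger and no-trigger ranges follow the printed formulas", {
  tg <- mk_target()      # t_min 9.8, t_max 10.2, D_i = 1
  st <- mk_stims(4)
  # trigger range [t_off - L_min, t_stim] = [-7.8, 0] relative to onset
  # no-trigger range [t_stim - L_max - R_max, t_stim] = [-14.2, 0]
  spikes <- sort(c(
    st$t_stim[1] - 5,      # inside trigger range       -> trigger trial
    st$t_stim[2] - 7.9,    # outside trigger, inside no-trigger range
    st$t_stim[3] - 14.0))  # deep but still inside no-trigger range
  ex <- extract_trials(spikes, st, tg, R_max = 4, min_triggers = 1)
  expect_false(ex$excluded)
  expect_equal(ex$trigger, 1L)
  expect_equal(ex$no_trigger, 4L)  # trials 2 and 3 have in-range spikes
  # boundary checks: exactly at the edges counts as inside
  sp2 <- c(st$t_stim[1] - 7.8, st$t_stim[2] - 14.2)
  ex2 <- extract_trials(sort(sp2), st, tg, R_max = 4, min_triggers = 1)
  expect_equal(ex2$trigger, 1L)
  expect_false(2L %in% ex2$no_trigger)
})

test_that("refractory-confounded trials are dropped before classification", {
  tg <- mk_target()
  st <- mk_stims(3)
  # spike at t_min - 3 ms (3 < R_max = 4): the trial is dropped entirely,
  # even though the spike is after stimulation onset
  spikes <- sort(c(st$t_stim[1] + tg$t_min - 3, st$t_stim[2] - 5))
  ex <- extract_trials(spikes, st, tg, R_max = 4, min_triggers = 1)
  expect_equal(ex$n_refractory_dropped, 1L)
  expect_false(1L %in% c(ex$trigger, ex$no_trigger))
  expect_equal(ex$trigger, 2L)
})

test_that("pairs with fewer than 15 trigger trials are excluded", {
  tg <- mk_target()
  st <- mk_stims(50)
  spikes <- st$t_stim[1:14] - 3           # 14 trigger trials
  ex <- extract_trials(sort(spikes), st, tg)
  expect_true(ex$excluded)
  expect_equal(ex$reason, "too_few_trigger_trials")
  spikes15 <- st$t_stim[1:15] - 3
  expect_false(extract_trials(sort(spikes15), st, tg)$excluded)
})

test_that("the no-trigger set is capped at ten times the trigger set", {
  tg <- mk_target()
  st <- mk_stims(400)
  # 20 well-separated trigger trials, every other trial spike-free
  trig_idx <- seq(10, 390, by = 20)[1:20]
  spikes <- sort(st$t_stim[trig_idx] - 3)
  ex <- extract_trials(spikes, st, tg)
  expect_equal(length(ex$trigger), 20)
  expect_equal(length(ex$no_trigger), 200)       # exactly 10x
  expect_lte(length(ex$no_trigger), 10 * length(ex$trigger))
  # scarcity: few eligible no-trigger trials -> all of them, still <= 10x
  st2 <- mk_stims(25)
  sp2 <- sort(st2$t_stim[1:20] - 3)
  ex2 <- extract_trials(sp2, st2, tg)
  expect_lte(length(ex2$no_trigger), 10 * length(ex2$trigger))
  expect_equal(length(ex2$no_trigger), 5)
})

test_that("ROC AUC equals brute-force pair counting and is antisymmetric", {
  expect_equal(roc_auc(c(2, 2, 2), c(2, 2)), 0.5)
  expect_equal(roc_auc(c(5, 6, 7), c(1, 2)), 1.0)
  expect_equal(roc_auc(c(3, 5), 4), 0.5)
  set.seed(41)
  for (i in 1:100) {
    nt <- sample(1:50, 1); tr <- sample(1:50, 1)
    a <- sample(1:8, nt, replace = TRUE)  # heavy ties
    b <- sample(1:8, tr, replace = TRUE)
    brute <- (sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))) /
      (nt * tr)
    expect_identical(roc_auc(a, b), brute)
    expect_equal(roc_auc(a, b), 1 - roc_auc(b, a))
  }
  expect_error(roc_auc(numeric(0), 1), "non-empty")
})

test_that("robust sigma implements the scaled MAD", {
  expect_equal(robust_sigma(c(1, 1, 1, 1)), 0)
  expect_equal(robust_sigma(c(0.4, 0.5, 0.6)), 0.1 / 0.6745)
  set.seed(42)
  x <- rnorm(1e4)
  expect_equal(robust_sigma(x), 1, tolerance = 0.05)  # 0.6745 consistency
  expect_equal(robust_sigma(x), mad(x, constant = 1 / 0.6745))
  expect_error(robust_sigma(1), "at least 2")
})

test_that("elimination variables separate present from eliminated spikes", {
  set.seed(43)
  amp <- c(-8, -3, -1, -0.5)
  ev <- c(lapply(1:10, function(j) ev_row(10 + rnorm(1, 0, 0.05), amp)),
          vector("list", 10))             # 10 present, 10 eliminated (flat)
  trials <- make_trial_array(ev, 20, noise_sd = 0)
  tgI <- mk_target()
  vI <- elimination_values(trials, tgI)
  expect_true(all(vI[1:10] > 5))
  expect_equal(vI[11:20], rep(0, 10))     # flat trials score 0
  # protocol II: similarity to the center; a trial containing the exact
  # center spike scores ~1, flat trials 0
  ctr <- data.frame(trial = 1L, t_ms = 10, z1 = amp[1], z2 = amp[2],
                    z3 = amp[3], z4 = amp[4])
  tgII <- mk_target(protocol = "II")
  tgII$center <- ctr
  vII <- elimination_values(trials, tgII)
  expect_true(all(vII[1:10] > 0.9))
  expect_equal(vII[11:20], rep(0, 10))
  expect_equal(roc_auc(vI[1:10], vI[11:20]), 1.0)
  expect_equal(roc_auc(vII[1:10], vII[11:20]), 1.0)
  # two spikes, one similar one not: the larger similarity wins
  tr2 <- make_trial_array(list(rbind(ev_row(10.02, amp),
                                     ev_row(17, c(-1, -9, -4, -2)))),
                          1, noise_sd = 0)
  v2 <- elimination_values(tr2, tgII)
  s_near <- spike_similarity(amp, 10.02, amp, 10, alpha = 1)
  expect_equal(v2, s_near, tolerance = 0.05)
})

test_that("latency estimates are sub-sample accurate and jitter uses QD", {
  set.seed(44)
  amp <- c(-8, -3, -1, -0.5)
  # spikes at exact half-sample offsets (0.025 ms)
  lats <- 10 + c(0.025, 0.075, -0.025, 0.125, 0, 0.05)
  ev <- lapply(lats, function(t) ev_row(t, amp))
  trials <- make_trial_array(ev, length(lats), noise_sd = 0)
  lj <- latency_and_jitter(trials, mk_target(), seq_along(lats))
  expect_equal(sort(lj$latencies), sort(lats), tolerance = 0.01)
  expect_equal(lj$latency_median, median(lats), tolerance = 0.01)
  # QD matches the sort-and-interpolate oracle
  l4 <- c(9.9, 10.0, 10.1, 10.2)
  expect_equal(quartile_dev(l4),
               (quantile(l4, 0.75, names = FALSE) -
                  quantile(l4, 0.25, names = FALSE)) / 2)
  # identical latencies -> QD 0
  ev0 <- lapply(1:5, function(i) ev_row(10, amp))
  tr0 <- make_trial_array(ev0, 5, noise_sd = 0)
  expect_equal(latency_and_jitter(tr0, mk_target(), 1:5)$jitter_qd, 0,
               tolerance = 1e-9)
  expect_error(latency_and_jitter(trials, mk_target(), 1:2), "too few")
})

test_that("the success rule combines the 5-sigma AUC and jitter criteria", {
  batch <- c(rep(0.5, 30) + seq(-0.029, 0.029, length.out = 30), 0.97)
  sg <- robust_sigma(batch)
  expect_true(judge_pair(0.97, 0.04, batch))
  expect_false(judge_pair(0.97, 0.30, batch))          # jitter too large
  expect_false(judge_pair(median(batch) + 4.9 * sg, 0.04, batch))
  expect_true(judge_pair(median(batch) + 5.1 * sg, 0.04, batch))
  expect_false(judge_pair(0.97, NA, batch))
})

test_that("judging all pairs adopts one best pair per neuron", {
  set.seed(45)
  fx <- make_collision_fixture(n_coll = 60, n_test = 200, lat = 10)
  trials <- filtered_trials(fx$truth)
  coll_idx <- which(!fx$is_test)
  sub <- trials[, , coll_idx, drop = FALSE]
  attr(sub, "t_axis_ms") <- attr(trials, "t_axis_ms")
  tgs <- c(infer_targets(sub, "I", tetrode_id = 1, site = 1, max_targets = 1),
           infer_targets(sub, "II", tetrode_id = 1, site = 1, max_targets = 1))
  spikes <- list("1" = neuron_spike_times(fx$truth, 1),
                 "2" = sort(runif(300, 0, max(fx$truth$schedule$t_off))))
  res <- judge_pairs(spikes, c("1" = 1L, "2" = 1L), list(trials),
                     fx$truth$schedule, tgs, sigma_mult = 2)
  expect_true(all(res$auc[res$neuron == "1"] > 0.99))
  # both protocol targets succeed for neuron 1, but only one is adopted
  expect_equal(sum(res$adopted[res$neuron == "1"]),
               min(1, sum(res$success[res$neuron == "1"])))
  expect_lte(sum(res$adopted), length(unique(res$neuron[res$success])))
})
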