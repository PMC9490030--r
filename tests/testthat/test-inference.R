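test_that("amplitude quartile follows the linear-interpolation convention", {
  expect_equal(amplitude_quartile(c(5, 5, 5, 5)), 5)
  expect_equal(amplitude_quartile(3.2), 3.2)
  # sort + interpolate oracle, pinned to the type-7 convention
  expect_equal(amplitude_quartile(c(8, 6, 4, 2)), 3.5)
  set.seed(4)
  for (i in 1:20) {
    x <- runif(sample(2:40, 1), 0, 10)
    s <- sort(x)
    h <- (length(s) - 1) * 0.25
    oracle <- s[floor(h) + 1] + (h - floor(h)) *
      (s[min(floor(h) + 2, length(s))] - s[floor(h) + 1])
    expect_equal(amplitude_quartile(x), oracle)
  }
  expect_error(amplitude_quartile(numeric(0)), "empty")
})

test_that("similarity kernel matches its closed form and symmetries", {
  z <- c(-3, -1, -0.5, 0)
  expect_equal(spike_similarity(z, 5, z, 5, alpha = 1), 1)
  # timing deviation of alpha equals a pattern angle of pi/18
  s_dt <- spike_similarity(z, 5, z, 6, alpha = 1)
  th <- pi / 18
  rot <- c(-cos(th) * 1, -sin(th) * 1, 0, 0)
  s_ang <- spike_similarity(c(-1, 0, 0, 0), 5, rot, 5, alpha = 1)
  expect_equal(s_dt, exp(-sin(pi / 18)^2), tolerance = 1e-12)
  expect_equal(s_ang, s_dt, tolerance = 1e-12)
  # symmetry, bound, monotonic decrease in |dt| and in angle
  set.seed(11)
  for (i in 1:50) {
    a <- -runif(4); b <- -runif(4)
    t1 <- runif(1, 0, 30); t2 <- runif(1, 0, 30)
    s <- spike_similarity(a, t1, b, t2, alpha = 1)
    expect_equal(s, spike_similarity(b, t2, a, t1, alpha = 1))
    expect_lte(s, 1)
    expect_gt(s, 0)
  }
  dts <- seq(0, 3, by = 0.5)
  vals <- vapply(dts, function(dt) spike_similarity(z, 0, z, dt, 1), 0)
  expect_true(all(diff(vals) < 0))
  angs <- seq(0, pi / 2 - 0.1, length.out = 8)
  vala <- vapply(angs, function(a)
    spike_similarity(c(-1, 0, 0, 0), 0, c(-cos(a), -sin(a), 0, 0), 0, 1), 0)
  expect_true(all(diff(vala) < 0))
  expect_error(spike_similarity(c(0, 0, 0, 0), 0, z, 0, 1), "zero")
  expect_error(spike_similarity(z, 0, z, 0, alpha = 0), "alpha")
})

test_that("window search recovers a single clean latency cluster", {
  set.seed(21)
  amp <- c(-2, -9, -1, -0.5)  # dominant channel 2
  trials <- make_trial_array(cluster_events(100, 10, amp, 0.05), 100,
                             noise_sd = 1)
  wins <- window_search(trials)
  expect_length(wins, 1)
  expect_equal(wins[[1]]$channel, 2)
  expect_true(wins[[1]]$start_ms < 10 && wins[[1]]$end_ms > 10)
  expect_true(wins[[1]]$converged)
  expect_equal(nrow(wins[[1]]$reps), 75)   # ceil(0.75 x 100)
  expect_true(all(abs(wins[[1]]$reps$t_ms - 10) < 0.5))
})

test_that("window search separates two latency clusters on two channels", {
  set.seed(22)
  ev <- lapply(seq_len(100), function(j) rbind(
    ev_row(8 + rnorm(1, 0, 0.05), c(-9, -2, -1, -0.5)),
    ev_row(14 + rnorm(1, 0, 0.05), c(-1, -0.5, -8, -2))))
  trials <- make_trial_array(ev, 100, noise_sd = 1)
  wins <- window_search(trials)
  expect_length(wins, 2)
  chans <- vapply(wins, `[[`, 0, "channel")
  mids <- vapply(wins, function(w) (w$start_ms + w$end_ms) / 2, 0)
  expect_setequal(chans, c(1, 3))
  expect_equal(sort(mids), c(8, 14), tolerance = 0.05)
  # adopted windows never overlap in time
  o <- order(mids)
  expect_lt(wins[[o[1]]]$end_ms, wins[[o[2]]]$start_ms)
  # pure sub-threshold noise yields no window
  noise <- make_trial_array(vector("list", 50), 50, noise_sd = 1)
  expect_length(window_search(noise), 0)
})

test_that("center-spike search aggregates a tight cluster and outranks a diffuse one", {
  set.seed(23)
  trials <- make_trial_array(cluster_events(100, 10, c(-9, -3, -1, -0.5), 0.05),
                             100, noise_sd = 1)
  ctr <- center_spike_search(trials, alpha = 1, max_targets = 1)
  expect_length(ctr, 1)
  expect_equal(ctr[[1]]$center$t_ms, 10, tolerance = 0.3)
  expect_gte(length(unique(ctr[[1]]$reps$trial)), 75)
  # antidromic cluster + diffuse synaptic spikes: the tight cluster is
  # adopted first because its similarity quartile is higher (brute-force
  # check over all detected spikes)
  ev <- lapply(seq_len(80), function(j) rbind(
    ev_row(10 + rnorm(1, 0, 0.05), c(-9, -3, -1, -0.5)),
    ev_row(18 + rnorm(1, 0, 1.5), c(-1, -8, -3, -0.5))))
  tr2 <- make_trial_array(ev, 80, noise_sd = 1)
  sp <- detect_trial_spikes(tr2, 5)
  brute_q <- vapply(seq_len(nrow(sp)), function(k) {
    best <- tapply(seq_len(nrow(sp)), sp$trial, function(rows)
      max(vapply(rows, function(l)
        spike_similarity(as.numeric(sp[k, c("z1", "z2", "z3", "z4")]),
                         sp$t_ms[k],
                         as.numeric(sp[l, c("z1", "z2", "z3", "z4")]),
                         sp$t_ms[l], 1), 0)))
    lower_quartile(best)
  }, 0)
  ctr2 <- center_spike_search(tr2, alpha = 1, max_targets = 1)
  k_best <- which.max(brute_q)
  expect_equal(ctr2[[1]]$center$t_ms, sp$t_ms[k_best])
  expect_equal(ctr2[[1]]$quartile, brute_q[k_best])
  expect_lt(abs(ctr2[[1]]$center$t_ms - 10), 0.5)
  # empty when nothing crosses threshold
  expect_length(center_spike_search(
    make_trial_array(vector("list", 30), 30, noise_sd = 1)), 0)
})

test_that("targets carry the printed latency-bound algebra", {
  set.seed(24)
  ev <- lapply(c(9.8, 10.0, 10.2), function(t)
    ev_row(t, c(-8, -3, -1, -0.5)))
  trials <- make_trial_array(ev, 3, noise_sd = 0)
  reps <- data.frame(trial = 1:3, t_ms = c(9.8, 10.0, 10.2))
  tg <- build_target(reps, trials, duration_ms = 1, protocol = "I",
                     extra = list(channel = 1, window = c(9.5, 10.5)))
  expect_equal(tg$t_min, 9.8)
  expect_equal(tg$t_max, 10.2)
  expect_equal(tg$L_min, 8.8)   # t_min - t_off
  expect_equal(tg$L_max, 10.2)  # t_max - t_stim
  # identical representatives: t_min = t_max, L_max - L_min = D_i
  reps1 <- data.frame(trial = 1:3, t_ms = rep(10, 3))
  tg1 <- build_target(reps1, trials, duration_ms = 1, protocol = "I",
                      extra = list(channel = 1, window = c(9.5, 10.5)))
  expect_equal(tg1$t_min, tg1$t_max)
  expect_equal(tg1$L_max - tg1$L_min, 1)
  # median peak pattern matches the rendered (filtered-free) amplitudes
  expect_equal(which.min(tg$u), 1)
  expect_error(build_target(reps[0, ], trials), "empty")
})

test_that("protocols I and II agree on a clean simulated projection", {
  set.seed(25)
  trials <- make_trial_array(cluster_events(100, 10, c(-9, -4, -2, -1), 0.05),
                             100, noise_sd = 1)
  tgI <- infer_targets(trials, "I", max_targets = 1)
  tgII <- infer_targets(trials, "II", max_targets = 1)
  expect_length(tgI, 1); expect_length(tgII, 1)
  expect_true(tgI[[1]]$t_min <= 10 && tgI[[1]]$t_max >= 10)
  expect_true(tgII[[1]]$t_min <= 10 && tgII[[1]]$t_max >= 10)
  expect_lt(abs(median(tgI[[1]]$reps$t_ms) - median(tgII[[1]]$reps$t_ms)),
            0.1)
})

test_that("a purely synaptic (diffuse) response yields high-jitter targets", {
  set.seed(26)
  ev <- lapply(seq_len(100), function(j)
    ev_row(12 + rnorm(1, 0, 1.5), c(-8, -3, -1, -0.5)))
  trials <- make_trial_array(ev, 100, noise_sd = 1)
  for (tg in infer_targets(trials, "II", max_targets = 3))
    expect_gt(quartile_dev(tg$reps$t_ms), 0.25)
})
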