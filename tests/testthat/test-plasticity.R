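test_that("correlation sensors accumulate exact pair sums", {
  s <- correlation_sensors(rows = 2, cols = 2, eta_plus = 1,
                           tau_plus = 10e-6, tau_minus = 8e-6)
  # one pre at 0, one post at tau_plus
  s1 <- update_correlation(s, 1, 1, pre_times = 0, post_times = 10e-6)
  expect_equal(s1$c_causal[1, 1], exp(-1))
  expect_equal(s1$c_acausal[1, 1], 0)

  # no post spikes: both banks stay zero
  s2 <- update_correlation(s, 1, 1, pre_times = c(0, 1e-6), post_times = numeric(0))
  expect_equal(s2$c_causal[1, 1], 0)
  expect_equal(s2$c_acausal[1, 1], 0)

  # monotone decay of the increment with lag
  inc <- vapply(c(1e-6, 10e-6), function(d)
    update_correlation(s, 1, 1, 0, d)$c_causal[1, 1], numeric(1))
  expect_gt(inc[1], inc[2])

  # arbitrary spike lists vs the closed-form nearest-preceding pair sum
  set.seed(11)
  pre <- sort(runif(15, 0, 100e-6))
  post <- sort(runif(12, 0, 100e-6))
  s3 <- update_correlation(s, 2, 2, pre, post)
  causal_ref <- sum(vapply(post, function(tp) {
    prev <- pre[pre <= tp]
    if (length(prev)) exp(-(tp - max(prev)) / 10e-6) else 0
  }, numeric(1)))
  expect_equal(s3$c_causal[2, 2], causal_ref, tolerance = 1e-9)
})

test_that("CADC quantization saturates, resets and bounds the error", {
  expect_identical(cadc_quantize(2, 0, 1), 255L)
  expect_identical(cadc_quantize(-1, 0, 1), 0L)
  set.seed(12)
  v <- runif(1000)
  codes <- cadc_quantize(v, 0, 1)
  expect_true(all(abs(cadc_dequantize(codes, 0, 1) - v) <= 0.5 / 255 + 1e-12))

  s <- correlation_sensors(rows = 1, cols = 4)
  s$c_causal[1, ] <- c(0.2, 0.4, 0.6, 0.8)
  rd <- cadc_read_row(s, 1, "causal", v_min = 0, v_max = 1, reset = TRUE)
  expect_equal(rd$codes, as.integer(round(c(0.2, 0.4, 0.6, 0.8) * 255)))
  rd2 <- cadc_read_row(rd$sensors, 1, "causal", v_min = 0, v_max = 1)
  expect_true(all(rd2$codes == 0L))
})

test_that("the rule scheduler applies, clips and logs weight writes", {
  w0 <- matrix(63L, 4, 4)
  ident <- plasticity_rule(10e-6, function(view) view$weights)
  r1 <- run_plasticity_schedule(w0, ident, duration = 100e-6)
  expect_equal(r1$weights, w0)
  expect_equal(nrow(r1$log), 0)

  dec <- plasticity_rule(10e-6, function(view) view$weights - 1)
  r2 <- run_plasticity_schedule(w0, dec, duration = 100e-6)
  expect_true(all(r2$weights == 53))

  # clipping at the 6-bit floor is counted and logged
  big <- plasticity_rule(10e-6, function(view) view$weights - 10)
  r3 <- run_plasticity_schedule(matrix(5L, 2, 2), big, duration = 20e-6)
  expect_true(all(r3$weights == 0))
  expect_gt(r3$clipped, 0)

  # the audit log replays to the final state
  set.seed(13)
  noisy <- plasticity_rule(10e-6, function(view)
    view$weights + sample(-2:2, length(view$weights), TRUE))
  r4 <- run_plasticity_schedule(matrix(30L, 4, 4), noisy, duration = 200e-6)
  expect_equal(replay_weight_log(matrix(30L, 4, 4), r4$log), r4$weights)
})

test_that("an STDP rule driven by causal pairs potentiates monotonically", {
  sensors <- correlation_sensors(rows = 1, cols = 1, tau_plus = 10e-6,
                                 reset_on_read = FALSE)
  period <- 20e-6
  pre <- data.frame(time = seq(5e-6, 195e-6, by = period), row = 1)
  post <- data.frame(time = pre$time + 2e-6, col = 1)
  stdp <- plasticity_rule(period, function(view) {
    view$weights + round(0.05 * (view$corr_causal - view$corr_acausal))
  })
  r <- run_plasticity_schedule(matrix(10L, 1, 1), stdp, duration = 200e-6,
                               sensors = sensors, pre_spikes = pre,
                               post_spikes = post, cadc_range = c(0, 20))
  traj <- c(10L, r$log$new)
  expect_true(all(diff(traj) >= 0))
  expect_gt(r$weights[1, 1], 10)
})

test_that("homeostatic deltas follow the proportional-control formula", {
  expect_identical(homeostatic_update(20e3, 20e3), 0L)
  expect_identical(homeostatic_update(0, 20e3, lambda_h = 1L), 1L)
  expect_identical(homeostatic_update(0, 20e3, lambda_h = 5L, delta_max = 2L),
                   2L)
  expect_identical(homeostatic_update(c(10e3, 40e3), 20e3, lambda_h = 2L),
                   c(1L, -2L))
})

test_that("a single neuron under homeostasis reaches the target rate", {
  net <- reservoir_network(N = 1, K_ext = 8, n_sources = 32, seed = 5)
  r <- run_reservoir(net, n_updates = 200, seed = 6)
  stationary <- mean(r$rates[151:200, ])
  expect_lt(abs(stationary - net$nu_target) / net$nu_target, 0.1)
})

test_that("autocorrelation-time estimation matches known processes", {
  # white noise: memoryless, tau below two bins
  set.seed(14)
  est_w <- estimate_autocorrelation_time(rnorm(5e4), bin = 1)
  expect_lt(est_w$tau_ac, 2)

  # AR(1): tau = -bin / log(phi) within 10% at 1e5 samples
  for (sd in 1:3) {
    set.seed(sd)
    x <- as.numeric(stats::filter(rnorm(1e5), 0.9, method = "recursive"))
    est <- estimate_autocorrelation_time(x, bin = 1)
    expect_true(est$reliable)
    expect_lt(abs(est$tau_ac - (-1 / log(0.9))) / (-1 / log(0.9)), 0.1)
  }

  # shuffling destroys correlation
  set.seed(15)
  y <- as.numeric(stats::filter(rnorm(2e4), 0.8, method = "recursive"))
  t_orig <- estimate_autocorrelation_time(y, 1)$tau_ac
  t_shuf <- estimate_autocorrelation_time(sample(y), 1)$tau_ac
  expect_lte(t_shuf, t_orig)
})

test_that("reservoir readout solves last-bit recall but not shuffled labels", {
  ex <- reservoir_experiment(K_ext = 16, n = 1)
  r <- run_reservoir_task(ex, seed = 2, n_bits = 300)
  expect_gt(r$accuracy, 0.8)

  # same reservoir features, label-shuffled targets: binomial chance band
  net <- reservoir_network(N = 32, K_ext = 16, seed = 2)
  run <- run_reservoir(net, n_updates = 60, period = 60e-6,
                       record_spikes = TRUE, seed = 3)
  feats <- t(vapply(seq_len(60), function(k) {
    sel <- run$spikes$time > (k - 1) * 60e-6 & run$spikes$time <= k * 60e-6
    tabulate(run$spikes$id[sel], nbins = 32)
  }, numeric(32)))
  set.seed(17)
  y <- rbinom(60, 1, 0.5)
  acc <- analognet:::ridge_readout_accuracy(feats[1:40, ], sample(y[1:40]),
                                            feats[41:60, ], y[41:60], 1)
  expect_lt(acc, 0.5 + 2 * sqrt(0.25 / 20))  # within ~2 sigma of chance
})
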