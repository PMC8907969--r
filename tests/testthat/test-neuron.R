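test_that("biological-to-hardware conversion rescales time constants only", {
  p <- adex_params(C_m = 200e-12, g_l = 10e-9, tau_w = 30e-3, t_r = 2e-3,
                   domain = "biological")
  hw <- convert_biological_params(p, 1000)
  expect_equal(hw$C_m / hw$g_l, 1e-3 * (p$C_m / p$g_l))  # tau_m 10 ms -> 10 us
  expect_equal(hw$tau_w, p$tau_w / 1000)
  expect_equal(hw$t_r, p$t_r / 1000)
  expect_equal(hw$E_l, p$E_l)
  expect_equal(hw$V_th, p$V_th)
  expect_identical(attr(hw, "domain"), "hardware")

  # identity and round-trip
  id <- convert_biological_params(p, 1)
  expect_equal(unclass(id), unclass(p))
  back <- convert_biological_params(hw, 1 / 1000)
  expect_equal(back$C_m, p$C_m, tolerance = 1e-12)
  expect_equal(back$tau_w, p$tau_w, tolerance = 1e-12)

  expect_error(convert_biological_params(p, 0), "positive")
  expect_error(convert_biological_params(p, -2), "positive")
})

test_that("parameter invariants are enforced", {
  expect_error(adex_params(C_m = 0), "C_m")
  expect_error(adex_params(Delta_T = -1e-3, enable_exp = TRUE), "Delta_T")
  expect_error(adex_params(V_th = -60e-3, V_T = -50e-3, enable_exp = TRUE),
               "V_th")
  # V_th default sits 5 Delta_T above V_T
  p <- adex_params(V_T = -50e-3, Delta_T = 2e-3)
  expect_equal(p$V_th, -40e-3)
})

test_that("step_neuron fixed point, refractory clamp and overflow guard", {
  p <- lif_hw_params()
  s0 <- neuron_state(V = p$E_l)
  s1 <- step_neuron(s0, p, I_in = 0, dt = 1e-7)
  expect_equal(s1$V, p$E_l)
  expect_equal(s1$w, 0)

  s_ref <- neuron_state(V = -0.02, refractory_until = 1e-5)
  s2 <- step_neuron(s_ref, p, I_in = 1e-9, dt = 1e-7, t = 0)
  expect_equal(s2$V, p$V_r)

  expect_error(step_neuron(neuron_state(V = NaN), p, 0, 1e-7), "non-finite")
})

test_that("LIF charging and adaptation decay match the closed forms", {
  p <- lif_hw_params(t_r = 1e-6)
  tau_m <- p$C_m / p$g_l
  I <- 1e-10
  T <- 100e-6
  res <- run_neuron(p, stim_protocol(I, t_on = 0, t_off = T, T = T),
                    dt = tau_m / 100)
  V_pred <- p$E_l + (I / p$g_l) * (1 - exp(-T * p$g_l / p$C_m))
  expect_equal(res$V[length(res$V)], V_pred, tolerance = 1e-4)

  pw <- adex_params(enable_exp = FALSE, enable_adapt = TRUE, a = 0,
                    tau_w = 30e-6)
  res2 <- run_neuron(pw, stim_protocol(0, 0, 1e-6, 100e-6), dt = 1e-7,
                     w0 = 1e-10)
  expect_equal(res2$w[length(res2$w)], 1e-10 * exp(-100e-6 / 30e-6),
               tolerance = 1e-4)
})

test_that("no stimulus means no spikes and a flat membrane", {
  p <- regular_bursting_hw()$params
  res <- run_neuron(p, stim_protocol(0))
  expect_length(as.numeric(res$spikes), 0)
  # with the exponential term enabled there is a tiny subthreshold offset;
  # the LIF configuration rests exactly at E_l
  expect_true(all(abs(res$V - p$E_l) < 1e-3))
  lif <- lif_hw_params()
  res2 <- run_neuron(lif, stim_protocol(0))
  expect_true(all(abs(res2$V - lif$E_l) < 1e-12))
})

test_that("firing-pattern classifier follows its ISI rules", {
  prot <- stim_protocol(1e-10)   # window [50, 400] us
  expect_identical(classify_firing_pattern(numeric(0), prot), "silent")
  expect_identical(classify_firing_pattern(c(60e-6), prot), "transient")
  # synthetic bimodal ISI sequence (2,2,20) us repeating until t_off
  isis <- rep(c(2e-6, 2e-6, 20e-6), 14)
  spikes <- 55e-6 + cumsum(c(0, isis))
  spikes <- spikes[spikes < 400e-6]
  expect_identical(classify_firing_pattern(spikes, prot), "regular_bursting")
  # regular unimodal train continuing until t_off
  tonic <- seq(60e-6, 395e-6, by = 12e-6)
  expect_identical(classify_firing_pattern(tonic, prot), "tonic")
  # same train starting after 30% of the window is not tonic
  expect_error(classify_firing_pattern(c(-1e-6), prot), "outside")
})

test_that("the regime grid reproduces the four named patterns", {
  res <- run_experiment(list(experiment = "firing-patterns"))
  labels <- vapply(res$patterns, `[[`, character(1), "label")
  expect_identical(unname(labels[["transient_spiking"]]), "transient")
  expect_identical(unname(labels[["regular_bursting"]]), "regular_bursting")
  expect_identical(unname(labels[["initial_burst"]]), "initial_burst")
  expect_identical(unname(labels[["delayed_bursting"]]),
                   "delayed_regular_bursting")
  expect_identical(unname(labels[["tonic_spiking"]]), "tonic")
})

test_that("refractoriness separates spikes by at least t_r - dt", {
  rb <- regular_bursting_hw()
  dt <- 1e-7
  res <- run_neuron(rb$params, stim_protocol(rb$I_0), dt = dt)
  expect_gt(length(res$spikes), 3)
  expect_true(all(diff(res$spikes) >= rb$params$t_r - dt))
})

test_that("integrator mode conserves charge", {
  p <- adex_params(enable_exp = FALSE, enable_adapt = FALSE,
                   enable_leak = FALSE, enable_threshold = FALSE)
  I <- 3e-10
  res <- run_neuron(p, stim_protocol(I, 100e-6, 300e-6, 400e-6), dt = 1e-7)
  dV <- res$V[length(res$V)] - res$V[1]
  expect_equal(dV, I * 200e-6 / p$C_m, tolerance = 1e-6)
})

test_that("regular bursting settles on a stable limit cycle", {
  rb <- regular_bursting_hw()
  res <- run_neuron(rb$params, stim_protocol(rb$I_0, t_off = 950e-6,
                                             T = 1e-3))
  s <- as.numeric(res$spikes)
  d <- diff(s)
  burst_starts <- s[c(TRUE, d > 20e-6)]
  periods <- diff(burst_starts)
  periods <- periods[-seq_len(min(2, length(periods) - 2))]
  expect_gt(length(periods), 2)
  expect_lt((max(periods) - min(periods)) / mean(periods), 0.02)
})

test_that("interpolated spike times converge at first order in dt", {
  ts <- adex_pattern_sets()$tonic_spiking
  hw <- convert_biological_params(ts$params)
  s <- vapply(c(4e-7, 2e-7, 1e-7),
              function(dt) run_neuron(hw, stim_protocol(ts$I_0),
                                      dt = dt)$spikes[1], numeric(1))
  err1 <- abs(s[1] - s[2])
  err2 <- abs(s[2] - s[3])
  expect_lt(err2, err1)           # halving dt shrinks the shift
  expect_lt(err1, 10 * 4e-7)      # O(dt) magnitude
})
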