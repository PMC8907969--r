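test_that("the default core configuration matches the hardware topology", {
  cfg <- analog_core_config()
  expect_identical(cfg$quadrants, 4L)
  expect_identical(cfg$rows, 256L)
  expect_identical(cfg$cols, 128L)
  expect_identical(cfg$neurons, 512L)
  expect_identical(cfg$synapses, 2L^17L)
  arr <- synapse_array()
  expect_length(arr$quadrants, 4)
  expect_equal(dim(arr$quadrants[[1]]$weights), c(256, 128))
  expect_equal(4 * 256 * 128, 2^17)
})

test_that("events reach exactly the address-matched synapses", {
  arr <- synapse_array(rows = 2, cols = 3, quadrants = 1,
                       weights = matrix(40L, 2, 3),
                       addresses = matrix(c(5L, 0L, 7L, 0L, 5L, 0L), 2, 3))
  st <- synaptic_state(3)
  st <- deliver_event(arr, st, event_packet(0, row = 1, label = 5))
  expect_equal(st$I_exc > 0, c(TRUE, FALSE, TRUE))   # columns 1 and 3

  # exhaustive address matching on a random array over all 64 labels
  arr2 <- small_array(rows = 4, cols = 16, seed = 3)
  for (lab in 0:63) {
    st2 <- deliver_event(arr2, synaptic_state(16),
                         event_packet(0, row = 2, label = lab))
    hit <- arr2$quadrants[[1]]$addresses[2, ] == lab
    w <- arr2$quadrants[[1]]$weights[2, ]
    expect_equal(st2$I_exc != 0, hit & w > 0)
  }
})

test_that("zero weight, payload scaling and row sign behave exactly", {
  arr <- synapse_array(rows = 1, cols = 2, quadrants = 1,
                       weights = matrix(c(0L, 63L), 1, 2),
                       addresses = matrix(0L, 1, 2))
  st <- deliver_event(arr, synaptic_state(2),
                      event_packet(0, 1, 0, payload = 31), gamma = 1e-11)
  expect_identical(st$I_exc[1], 0)
  expect_equal(st$I_exc[2], 1e-11 * 63)
  st2 <- deliver_event(arr, synaptic_state(2),
                       event_packet(0, 1, 0, payload = 15), gamma = 1e-11)
  expect_equal(st2$I_exc[2], 1e-11 * 63 * 15 / 31)

  arr$quadrants[[1]]$row_sign <- -1L
  st3 <- deliver_event(arr, synaptic_state(2), event_packet(0, 1, 0))
  expect_equal(st3$I_exc, c(0, 0))
  expect_gt(st3$I_inh[2], 0)
})

test_that("disabled rows drop events with a counted loss", {
  arr <- synapse_array(rows = 2, cols = 2, quadrants = 1,
                       weights = matrix(10L, 2, 2),
                       row_enabled = c(FALSE, TRUE))
  st <- deliver_event(arr, synaptic_state(2), event_packet(0, 1, 0))
  expect_equal(st$I_exc, c(0, 0))
  expect_identical(st$dropped, 1L)
})

test_that("event-driven synaptic currents equal the closed-form kernel sum", {
  # two identical events tau apart: I = gamma w (1 + e^-1) just after
  arr <- synapse_array(rows = 1, cols = 1, quadrants = 1,
                       weights = matrix(63L, 1, 1),
                       addresses = matrix(0L, 1, 1))
  tau <- 5e-6
  st <- synaptic_state(1, tau_exc = tau)
  st <- deliver_event(arr, st, event_packet(0, 1, 0), gamma = 1e-11)
  st <- decay_currents(st, tau)
  st <- deliver_event(arr, st, event_packet(tau, 1, 0), gamma = 1e-11)
  expect_equal(st$I_exc[1], 1e-11 * 63 * (1 + exp(-1)), tolerance = 1e-12)

  # arbitrary event list vs the analytic sum
  set.seed(4)
  ev_t <- sort(runif(20, 0, 50e-6))
  st2 <- synaptic_state(1, tau_exc = tau)
  t_prev <- 0
  for (te in ev_t) {
    st2 <- decay_currents(st2, te - t_prev)
    st2 <- deliver_event(arr, st2, event_packet(te, 1, 0), gamma = 1e-11)
    t_prev <- te
  }
  t_end <- 60e-6
  st2 <- decay_currents(st2, t_end - t_prev)
  I_ref <- sum(1e-11 * 63 * exp(-(t_end - ev_t) / tau))
  expect_equal(st2$I_exc[1], I_ref, tolerance = 1e-9)
})

test_that("decay is exact, linear and a no-op at dt = 0", {
  st <- synaptic_state(3, tau_exc = 5e-6, tau_inh = 10e-6)
  st$I_exc <- c(1, 2, 3); st$I_inh <- c(4, 5, 6)
  d1 <- decay_currents(st, 5e-6)
  expect_equal(d1$I_exc, c(1, 2, 3) * exp(-1))
  expect_equal(d1$I_inh, c(4, 5, 6) * exp(-0.5))
  expect_equal(decay_currents(st, 0)$I_exc, st$I_exc)
  sa <- st; sa$I_exc <- c(1, 0, 0)
  sb <- st; sb$I_exc <- c(0, 2, 3)
  expect_equal(decay_currents(st, 3e-6)$I_exc,
               decay_currents(sa, 3e-6)$I_exc + decay_currents(sb, 3e-6)$I_exc)
})

test_that("MAC mode reproduces the exact product and its symmetries", {
  set.seed(7)
  W <- diag(sample(-63:63, 16))
  x <- runif(16)
  out <- mac_forward(W, x, quantize = FALSE)
  expect_gt(cor(out, diag(W) * x), 0.999)
  expect_equal(out, diag(W) * x, tolerance = 1e-12)

  # zero input, baseline-subtracted output is zero
  expect_equal(as.numeric(mac_forward(W, rep(0, 16))), rep(0, 16))

  # signed-row-pair negation identity
  W2 <- matrix(sample(-63:63, 64, TRUE), 8, 8)
  xq <- runif(8)
  expect_equal(as.numeric(mac_forward(-W2, xq)),
               -as.numeric(mac_forward(W2, xq)))

  # linearity pre-quantization
  expect_equal(mac_forward(W2, xq / 2, quantize = FALSE) * 2,
               mac_forward(W2, xq, quantize = FALSE), tolerance = 1e-6)

  expect_error(mac_forward(W2, xq + 1), "\\[0, 1\\]")
  expect_error(mac_forward(W2 * 2, xq), "-63")
})

test_that("8-bit readout quantization error is bounded by half an LSB", {
  set.seed(8)
  W <- matrix(sample(-63:63, 64 * 64, TRUE), 64, 64)
  x <- runif(64)
  xq <- round(x * 31) / 31
  ideal <- as.numeric(W %*% xq)
  out <- mac_forward(W, x, quantize = TRUE)
  lsb <- attr(out, "lsb")
  expect_true(all(abs(as.numeric(out) - ideal) <= lsb / 2 + 1e-12))
})

test_that("tiling reproduces mac_forward and the exact product", {
  set.seed(9)
  W <- matrix(sample(-63:63, 40 * 30, TRUE), 40, 30)
  x <- runif(30)
  expect_equal(mac_tiled(W, x, quantize = FALSE),
               as.numeric(mac_forward(W, x, quantize = FALSE)))

  Wb <- matrix(sample(-63:63, 200 * 600, TRUE), 200, 600)
  xb <- runif(600)
  out <- mac_tiled(Wb, xb, quantize = FALSE)
  ref <- as.numeric(Wb %*% xb)
  expect_equal(out, ref, tolerance = 1e-6)
})
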