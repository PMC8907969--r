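test_that("EPSPs attenuate and broaden along a passive chain", {
  graph <- passive_chain(n = 4, inject_at = 1)
  res <- simulate_compartments(graph, T = 120e-6)
  psp <- lapply(1:4, function(j)
    measure_psp(res$time, res$V[, j], baseline_until = 15e-6))
  amp <- vapply(psp, `[[`, numeric(1), "amplitude")
  fwhm <- vapply(psp, `[[`, numeric(1), "fwhm")
  expect_true(all(diff(amp) < 0))
  expect_true(all(diff(fwhm) > 0))
})

test_that("interior injection yields a smaller local EPSP than end injection", {
  res_end <- simulate_compartments(passive_chain(inject_at = 1), T = 120e-6)
  res_mid <- simulate_compartments(passive_chain(inject_at = 2), T = 120e-6)
  a_end <- measure_psp(res_end$time, res_end$V[, 1], 15e-6)$amplitude
  a_mid <- measure_psp(res_mid$time, res_mid$V[, 2], 15e-6)$amplitude
  expect_lt(a_mid, a_end)
})

test_that("a decoupled chain leaves non-injected compartments at rest", {
  graph <- passive_chain(g_ic = 0, inject_at = 1)
  res <- simulate_compartments(graph, T = 100e-6)
  E_l <- graph$compartments[[2]]$E_l
  for (j in 2:4) expect_true(all(abs(res$V[, j] - E_l) < 1e-12))
  expect_gt(max(res$V[, 1]) - E_l, 1e-3)
})

test_that("disconnected graphs are rejected", {
  p <- adex_params(enable_exp = FALSE, enable_adapt = FALSE)
  edges <- data.frame(i = 1, j = 2, g_ic = 1e-8)
  expect_error(compartment_graph(rep(list(p), 3), rep("passive", 3), edges),
               "disconnected")
})

test_that("measure_psp matches the closed-form double-exponential kernel", {
  tau1 <- 20e-6; tau2 <- 5e-6
  tt <- seq(0, 200e-6, by = 1e-8)
  V <- exp(-tt / tau1) - exp(-tt / tau2)
  t_pk <- log(tau1 / tau2) * tau1 * tau2 / (tau1 - tau2)
  A_pk <- exp(-t_pk / tau1) - exp(-t_pk / tau2)
  m <- measure_psp(tt, V, baseline_until = 0)
  expect_equal(m$amplitude, A_pk, tolerance = 0.01)
  expect_equal(m$peak_time, t_pk, tolerance = 0.01)
  # closed-form FWHM by dense root finding on the same kernel
  half <- A_pk / 2
  above <- which(V >= half)
  fwhm_ref <- tt[above[length(above)]] - tt[above[1]]
  expect_equal(m$fwhm, fwhm_ref, tolerance = 0.01)

  flat <- measure_psp(tt, rep(1, length(tt)), baseline_until = 100e-6)
  expect_equal(flat$amplitude, 0)
  expect_true(is.na(flat$fwhm))
})

test_that("passive chains are linear: amplitude scales and inputs superpose", {
  g1 <- passive_chain(weight = 2e-9)
  g2 <- passive_chain(weight = 4e-9)
  r1 <- simulate_compartments(g1, T = 120e-6)
  r2 <- simulate_compartments(g2, T = 120e-6)
  a1 <- measure_psp(r1$time, r1$V[, 3], 15e-6)$amplitude
  a2 <- measure_psp(r2$time, r2$V[, 3], 15e-6)$amplitude
  expect_equal(a2 / a1, 2, tolerance = 0.01)

  # superposition of two injection sites
  ga <- passive_chain(inject_at = 1)
  gb <- passive_chain(inject_at = 3)
  gab <- passive_chain(inject_at = 1)
  gab$injections <- rbind(gab$injections,
                          data.frame(comp = 3, time = 20e-6, weight = 2e-9))
  ra <- simulate_compartments(ga, T = 120e-6)
  rb <- simulate_compartments(gb, T = 120e-6)
  rab <- simulate_compartments(gab, T = 120e-6)
  E_l <- ga$compartments[[1]]$E_l
  sum_dev <- (ra$V - E_l) + (rb$V - E_l)
  dev_ab <- rab$V - E_l
  expect_lt(max(abs(dev_ab - sum_dev)) / max(abs(dev_ab)), 1e-6)
})

test_that("axial conductance moves charge downstream monotonically", {
  gs <- c(0.5, 1, 2, 4, 8) * 1e-8
  amps <- t(vapply(gs, function(g) {
    graph <- passive_chain(n = 2, g_ic = g, inject_at = 1)
    res <- simulate_compartments(graph, T = 120e-6)
    c(measure_psp(res$time, res$V[, 1], 15e-6)$amplitude,
      measure_psp(res$time, res$V[, 2], 15e-6)$amplitude)
  }, numeric(2)))
  expect_true(all(diff(amps[, 1]) < 0))  # injected site loses amplitude
  expect_true(all(diff(amps[, 2]) > 0))  # downstream gains
})

test_that("plateau coincidence detection is order and location sensitive", {
  graph <- branched_plateau_model()
  d <- 4e-6
  expect_true(coincidence_protocol(graph, c(1, 2), d)$fired)
  expect_false(coincidence_protocol(graph, c(4, 6), d)$fired)
  distal_first <- coincidence_protocol(graph, c(3, 1), d)$fired
  proximal_first <- coincidence_protocol(graph, c(1, 3), d)$fired
  expect_true(distal_first)
  expect_false(proximal_first)
})

test_that("plateau spikes clamp the zone at V_plateau for t_plateau", {
  graph <- branched_plateau_model()
  res <- coincidence_protocol(graph, c(1, 2), 2e-6)
  zone <- res$zone
  tr <- res$trace
  t_sp <- res$spikes$time[res$spikes$comp == zone][1]
  p <- graph$compartments[[zone]]
  sel <- tr$time > t_sp + 1e-7 & tr$time < t_sp + p$t_plateau - 1e-7
  expect_true(all(abs(tr$V[sel, zone] - p$V_plateau) < 1e-9))
})
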