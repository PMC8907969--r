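test_that("forward event times match the closed-form LIF spike time", {
  sys <- lif_system(1, I_ext = 1.6)
  fwd <- forward_hybrid(sys, 60e-6, dt = 1.5e-7)
  ts <- vapply(fwd$events, `[[`, numeric(1), "time")
  t_star <- -sys$tau_m * log(1 - (sys$v_th - sys$v_leak) / (sys$R * 1.6))
  expect_equal(ts, t_star * seq_along(ts), tolerance = 1e-9)
})

test_that("subthreshold drive yields an empty event list", {
  sys <- lif_system(2, I_ext = c(0.5, 0.9))
  fwd <- forward_hybrid(sys, 80e-6)
  expect_length(fwd$events, 0)
})

test_that("synaptic transitions jump I by exactly the weight column", {
  W <- matrix(0, 2, 2); W[2, 1] <- 1.7
  sys <- lif_system(2, I_ext = c(1.6, 0), W = W)
  fwd <- forward_hybrid(sys, 40e-6)
  spikes1 <- Filter(function(e) e$type == "spike" && e$neuron == 1,
                    fwd$events)
  expect_gt(length(spikes1), 0)
  for (ev in spikes1) {
    expect_equal(ev$x_plus$I - ev$x_minus$I, W[, 1])
    expect_equal(ev$x_plus$V[1], sys$v_reset)
  }
})

test_that("event-time derivatives follow the implicit function theorem", {
  # closed form: t* = -tau_m log(1 - (V_T - V_L)/(R I)); differentiate in I
  I0 <- 1.6
  sys <- lif_system(1, I_ext = I0)
  fwd <- forward_hybrid(sys, 12e-6)
  ev <- fwd$events[[1]]
  etd <- event_time_derivative(ev, sys)
  expect_false(etd$grazing)
  # dt*/dV- = -1 / f_V at the crossing
  expect_equal(etd$dt_dV, -1 / ev$f_minus$V[1])
  # full dt*/dI via the chain matches the analytic derivative
  h <- 1e-7
  t_of_I <- function(I) -sys$tau_m * log(1 - sys$v_th / (sys$R * I))
  dt_dI_ref <- (t_of_I(I0 + h) - t_of_I(I0 - h)) / (2 * h)
  # adjoint route: loss = t*, gradient w.r.t. I_ext
  loss <- loss_spec(event_time_grad = rep(0, length(fwd$events)))
  loss$event_time_grad[1] <- 1
  adj <- adjoint_gradient(sys, loss, 12e-6, dt = 1e-7)
  expect_equal(unname(adj$grad["I_ext1"]), dt_dI_ref, tolerance = 1e-5)
})

test_that("parameters with no influence before the event have zero derivative", {
  W <- matrix(0, 2, 2); W[2, 1] <- 2.5
  sys <- lif_system(2, I_ext = c(1.6, 0.2), W = W)
  loss <- loss_spec(terminal = function(V, I) V[1],
                    terminal_grad = function(V, I) list(V = c(1, 0),
                                                        I = c(0, 0)))
  adj <- adjoint_gradient(sys, loss, 25e-6)
  # neuron 2 never feeds neuron 1: its drive and afferent weight are inert
  expect_equal(unname(adj$grad["I_ext2"]), 0)
  expect_equal(unname(adj$grad["W2"]), 0)   # W[2,1] drives neuron 2 only
})

test_that("an excitatory weight increase advances the postsynaptic spike", {
  W <- matrix(0, 2, 2); W[2, 1] <- 2.6
  sys <- lif_system(2, I_ext = c(1.6, 0.8), W = W)
  spike2_time <- function(s) {
    fwd <- forward_hybrid(s, 40e-6)
    sp <- Filter(function(e) e$type == "spike" && e$neuron == 2, fwd$events)
    sp[[1]]$time
  }
  s_hi <- sys; s_hi$W[2, 1] <- 2.7
  expect_lt(spike2_time(s_hi), spike2_time(sys))
})

test_that("smooth-case adjoint matches the analytic linear-system gradient", {
  # no events: dL/dI_ext for L = V(T)^2 has the closed form of the driven
  # two-exponential solution
  sys <- lif_system(1, I_ext = 0.5)
  T <- 50e-6
  loss <- loss_spec(terminal = function(V, I) V[1]^2,
                    terminal_grad = function(V, I) list(V = 2 * V, I = 0 * I))
  adj <- adjoint_gradient(sys, loss, T, dt = T / 800)
  VT <- sys$R * 0.5 * (1 - exp(-T / sys$tau_m))
  dVT <- sys$R * (1 - exp(-T / sys$tau_m))
  expect_equal(unname(adj$grad["I_ext1"]), 2 * VT * dVT, tolerance = 1e-8)
})

test_that("weights without presynaptic spikes receive exactly zero gradient", {
  # weak convergence onto neuron 3 keeps it silent over the horizon
  W <- matrix(0, 3, 3); W[2, 1] <- 2.6; W[3, 2] <- 0.3
  sys <- lif_system(3, I_ext = c(1.55, 0.4, 0.1), W = W)
  loss <- loss_spec(terminal = function(V, I) V[3],
                    terminal_grad = function(V, I) list(V = c(0, 0, 1),
                                                        I = c(0, 0, 0)))
  fwd <- forward_hybrid(sys, 60e-6)
  spiking <- unique(vapply(Filter(function(e) e$type == "spike", fwd$events),
                           `[[`, numeric(1), "neuron"))
  bk <- backward_adjoint(sys, fwd, loss)
  silent <- setdiff(1:3, spiking)
  expect_gt(length(silent), 0)
  for (j in silent) expect_equal(bk$W[, j], rep(0, 3))
})

test_that("adjoint gradients agree with finite differences on the fixture family", {
  tab <- gradcheck_suite(seed = 42, tol = 1e-3)
  expect_true(all(tab$pass))
  expect_gte(max(tab$n_events), 10)   # family spans 0..10+ events
  expect_equal(min(tab$n_events), 0)
})

test_that("finite differences are second-order accurate (Richardson)", {
  # cubic terminal loss: non-vanishing third derivative in the drive
  sys <- lif_system(1, I_ext = 0.5)
  loss <- loss_spec(terminal = function(V, I) V[1]^3,
                    terminal_grad = function(V, I)
                      list(V = 3 * V^2, I = 0 * I))
  g <- function(eps) finite_difference_gradient(sys, loss, 50e-6,
                                                eps = eps)$grad[["I_ext1"]]
  exact <- adjoint_gradient(sys, loss, 50e-6,
                            dt = 50e-6 / 800)$grad[["I_ext1"]]
  e1 <- abs(g(0.2) - exact)
  e2 <- abs(g(0.1) - exact)
  expect_gt(e1 / e2, 3)   # central differences: error ratio -> 4
  expect_lt(e1 / e2, 5)
})

test_that("adjoint propagation respects the block-diagonal Jacobian", {
  # two uncoupled neurons: perturbing the terminal adjoint of one must not
  # leak into the other's gradient components
  sys <- lif_system(2, I_ext = c(0.5, 0.7))
  loss1 <- loss_spec(terminal = function(V, I) V[1],
                     terminal_grad = function(V, I) list(V = c(1, 0),
                                                         I = c(0, 0)))
  adj <- adjoint_gradient(sys, loss1, 40e-6)
  expect_equal(unname(adj$grad["I_ext2"]), 0)
  expect_true(abs(adj$grad[["I_ext1"]]) > 0)
})

test_that("composed subsystems chain through spike times", {
  # A: one neuron driven to spike; B: one neuron receiving A's spikes as
  # fixed-time inputs.  dL/dI_ext(A) of the composition equals
  # sum_k dL/dt_k (from B's adjoint) * dt_k/dI_ext (from A's adjoint).
  T <- 60e-6
  WA <- matrix(0, 2, 2); WA[2, 1] <- 1.9
  sysAB <- lif_system(2, I_ext = c(1.6, 0.3), W = WA)
  lossAB <- loss_spec(terminal = function(V, I) V[2]^2,
                      terminal_grad = function(V, I)
                        list(V = c(0, 2 * V[2]), I = c(0, 0)))
  full <- adjoint_gradient(sysAB, lossAB, T)

  # subsystem A alone
  sysA <- lif_system(1, I_ext = 1.6)
  fwdA <- forward_hybrid(sysA, T)
  tA <- vapply(fwdA$events, `[[`, numeric(1), "time")

  # subsystem B driven by A's spike times through W_in
  sysB <- lif_system(1, I_ext = 0.3, W_in = matrix(1.9, 1, 1),
                     input_times = tA, input_src = rep(1L, length(tA)))
  lossB <- loss_spec(terminal = function(V, I) V[1]^2,
                     terminal_grad = function(V, I) list(V = 2 * V, I = 0 * I))
  fwdB <- forward_hybrid(sysB, T)
  bkB <- backward_adjoint(sysB, fwdB, lossB)

  # A's adjoint with loss = sum_k (dL/dt_k) t_k
  lossA <- loss_spec(event_time_grad = bkB$input_time_grad)
  adjA <- adjoint_gradient(sysA, lossA, T)
  expect_equal(unname(adjA$grad["I_ext1"]), unname(full$grad["I_ext1"]),
               tolerance = 1e-6 * max(abs(full$grad["I_ext1"]), 1))
})

test_that("sparse observations recover a perturbed leak parameter", {
  # generate observations from a model with shifted v_leak, then descend
  # the observation loss from the nominal start
  T <- 60e-6
  true_leak <- 0.12
  sys_true <- lif_system(1, v_leak = true_leak, I_ext = 0.5)
  fwd_true <- forward_hybrid(sys_true, T, x0 = list(V = 0, I = 0))
  P <- matrix(c(1, 0), 1, 2)    # observe V only
  t_obs <- seq(5e-6, 55e-6, length.out = 10)
  obs <- lapply(t_obs, function(tt) {
    k <- which.min(abs(fwd_true$time - tt))
    list(t = tt, P = P, xhat = fwd_true$V[k, 1])
  })
  loss <- loss_spec(observations = obs)

  sys <- lif_system(1, v_leak = 0, I_ext = 0.5)
  leak <- sys$v_leak
  lr <- 0.05
  for (it in 1:60) {
    sys$v_leak <- leak
    adj <- adjoint_gradient(sys, loss, T,
                            x0 = list(V = 0, I = 0))
    leak <- leak - lr * adj$grad[["v_leak"]]
  }
  expect_lt(abs(leak - true_leak) / true_leak, 0.05)
})
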