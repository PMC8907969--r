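#' Leaky integrate-and-fire hybrid dynamical system
#'
#' The reference hybrid system: `N` neurons with state `x = (V, I)` obeying
#' \deqn{\tau_m \dot V = (V_L - V) + R (I + I_{ext}), \qquad
#'       \tau_s \dot I = -I,}
#' jump conditions `V_i - V_T = 0`, and transitions
#' `I+ = I- + W e_i`, `V_i+ = V_reset` when neuron `i` fires.  The flow is
#' linear, so trajectories are propagated by the closed-form solution (no
#' integration error) and event times are located exactly by root finding
#' inside a grid step; the per-neuron Jacobian is the sparse 2x2 block
#' `[[-1/tau_m, R/tau_m], [0, -1/tau_s]]`.
#'
#' Parameters split into flow parameters (`tau_m`, `tau_s`, `v_leak`, `R`,
#' `I_ext`), transition parameters (`W`, `v_reset`, and the input weights
#' `W_in`) and the jump-condition parameter `v_th`.  Optional external input
#' spikes at fixed times add columns of `W_in` to `I`.
#'
#' @param n number of neurons.
#' @param tau_m,tau_s membrane and synaptic time constants (s), distinct.
#' @param v_leak leak potential (V).
#' @param R membrane resistance (Ohm).
#' @param v_th,v_reset threshold and reset potentials (V).
#' @param W recurrent weight matrix (n x n, amperes per spike); column `j`
#'   is presynaptic neuron `j`.
#' @param I_ext constant external current per neuron (A).
#' @param W_in input weight matrix (n x n_in) for external spike sources.
#' @param input_times,input_src external spike times (s) and source indices.
#' @return An object of class `lif_system`.
#' @export
lif_system <- function(n, tau_m = 10e-6, tau_s = 5e-6, v_leak = 0,
                       R = 1, v_th = 1, v_reset = 0,
                       W = matrix(0, n, n), I_ext = rep(0, n),
                       W_in = NULL, input_times = numeric(0),
                       input_src = integer(0)) {
  stopifnot(tau_m > 0, tau_s > 0, abs(tau_m - tau_s) > 1e-12 * tau_m,
            nrow(W) == n, ncol(W) == n, length(I_ext) == n,
            length(input_times) == length(input_src))
  if (!is.null(W_in)) stopifnot(nrow(W_in) == n)
  o <- order(input_times)
  structure(list(n = n, tau_m = tau_m, tau_s = tau_s, v_leak = v_leak,
                 R = R, v_th = v_th, v_reset = v_reset, W = W,
                 I_ext = I_ext, W_in = W_in,
                 input_times = input_times[o],
                 input_src = as.integer(input_src[o])),
            class = "lif_system")
}

#' @export
print.lif_system <- function(x, ...) {
  cat(sprintf(
    "lif_system: %d neurons, tau_m = %.3g s, tau_s = %.3g s, %d input events\n",
    x$n, x$tau_m, x$tau_s, length(x$input_times)))
  invisible(x)
}

# internal: closed-form flow over an interval d from state (V, I)
lif_flow <- function(sys, V, I, d) {
  Em <- exp(-d / sys$tau_m)
  Es <- exp(-d / sys$tau_s)
  Vc <- sys$v_leak + sys$R * sys$I_ext
  cc <- sys$R * sys$tau_s / (sys$tau_s - sys$tau_m)
  list(V = Vc + cc * I * Es + (V - Vc - cc * I) * Em, I = I * Es)
}

# internal: membrane voltage of one neuron along the flow (for root finding)
lif_flow_Vi <- function(sys, Vi, Ii, Iext_i, d) {
  Em <- exp(-d / sys$tau_m)
  Es <- exp(-d / sys$tau_s)
  Vc <- sys$v_leak + sys$R * Iext_i
  cc <- sys$R * sys$tau_s / (sys$tau_s - sys$tau_m)
  Vc + cc * Ii * Es + (Vi - Vc - cc * Ii) * Em
}

# internal: vector field f(x) = (dV/dt, dI/dt)
lif_f <- function(sys, V, I) {
  list(V = (sys$v_leak - V + sys$R * (I + sys$I_ext)) / sys$tau_m,
       I = -I / sys$tau_s)
}

#' Integrate a hybrid LIF system and log its events
#'
#' Piecewise-exact integration: the linear flow between events is propagated
#' in closed form on a fixed grid of step `dt` (the dense trajectory), and
#' every threshold crossing is located by root finding on the closed-form
#' membrane trajectory inside the step (simultaneous crossings are processed
#' in ascending neuron index).  Each transition is applied atomically and an
#' event record (time, neuron, pre/post states, pre/post flow values) is
#' stored for the backward pass.  External input spikes are applied at their
#' exact times.
#'
#' @param sys a [lif_system()].
#' @param T total duration (s).
#' @param dt grid step (s) for the dense trajectory.
#' @param x0 optional initial state `list(V =, I =)`; defaults to the leak
#'   potential and zero current.
#' @param max_events guard against runaway spiking.
#' @return A list with `time`, `V`, `I` (dense trajectory, matrices with one
#'   column per neuron) and `events` (list of event records; `type` is
#'   `"spike"` or `"input"`).
#' @export
forward_hybrid <- function(sys, T, dt = 1e-7, x0 = NULL, max_events = 1e6) {
  n <- sys$n
  if (is.null(x0)) x0 <- list(V = rep(sys$v_leak, n), I = rep(0, n))
  nsteps <- ceiling(T / dt - 1e-9)
  times <- seq(0, by = dt, length.out = nsteps + 1)
  times[nsteps + 1] <- min(times[nsteps + 1], T)
  Vm <- matrix(0, nsteps + 1, n); Im <- matrix(0, nsteps + 1, n)
  Vm[1, ] <- x0$V; Im[1, ] <- x0$I
  V <- x0$V; I <- x0$I
  events <- list()
  in_idx <- 1L
  n_in <- length(sys$input_times)

  apply_spike <- function(i, tstar) {
    fm <- lif_f(sys, V, I)
    xm <- list(V = V, I = I)
    I <<- I + sys$W[, i]
    V[i] <<- sys$v_reset
    fp <- lif_f(sys, V, I)
    events[[length(events) + 1]] <<- list(
      type = "spike", neuron = i, time = tstar,
      x_minus = xm, x_plus = list(V = V, I = I), f_minus = fm, f_plus = fp)
  }
  apply_input <- function(src, tev) {
    fm <- lif_f(sys, V, I)
    xm <- list(V = V, I = I)
    I <<- I + sys$W_in[, src]
    fp <- lif_f(sys, V, I)
    events[[length(events) + 1]] <<- list(
      type = "input", src = src, time = tev,
      x_minus = xm, x_plus = list(V = V, I = I), f_minus = fm, f_plus = fp)
  }

  # advance from time a to time b handling spikes and inputs inside
  advance <- function(a, b) {
    t_cur <- a
    repeat {
      if (length(events) > max_events)
        stop("maximum event count exceeded (runaway spiking)")
      t_next_in <- if (in_idx <= n_in) sys$input_times[in_idx] else Inf
      seg_end <- min(b, t_next_in)
      # earliest threshold crossing inside (t_cur, seg_end]
      d <- seg_end - t_cur
      if (d > 1e-18) {
        cand_t <- rep(Inf, n)
        for (i in seq_len(n)) {
          if (V[i] >= sys$v_th) { cand_t[i] <- t_cur; next }
          Vend <- lif_flow_Vi(sys, V[i], I[i], sys$I_ext[i], d)
          if (Vend >= sys$v_th) {
            root <- stats::uniroot(
              function(u) lif_flow_Vi(sys, V[i], I[i], sys$I_ext[i], u) -
                sys$v_th,
              lower = 0, upper = d, tol = 1e-16 * max(1, d))
            cand_t[i] <- t_cur + root$root
          }
        }
        if (any(is.finite(cand_t))) {
          i_star <- which.min(cand_t)      # ties: ascending neuron index
          t_star <- cand_t[i_star]
          fl <- lif_flow(sys, V, I, t_star - t_cur)
          V <<- fl$V; I <<- fl$I
          V[i_star] <<- sys$v_th           # exact crossing state
          apply_spike(i_star, t_star)
          t_cur <- t_star
          next
        }
        fl <- lif_flow(sys, V, I, d)
        V <<- fl$V; I <<- fl$I
        t_cur <- seg_end
      }
      if (t_next_in <= b && abs(t_cur - t_next_in) < 1e-18) {
        apply_input(sys$input_src[in_idx], t_next_in)
        in_idx <<- in_idx + 1L
        next
      }
      if (t_cur >= b - 1e-18) break
    }
  }

  for (s in seq_len(nsteps)) {
    advance(times[s], times[s + 1])
    Vm[s + 1, ] <- V; Im[s + 1, ] <- I
  }
  list(time = times, V = Vm, I = Im, events = events,
       x_final = list(V = V, I = I))
}

#' Event-time derivatives from the implicit function theorem
#'
#' For a threshold-crossing event `j(x, p, t) = V_i - V_T = 0` the crossing
#' time is an implicit function of the pre-event state and parameters:
#' `dt*/dq = -(dj/dx . dx-/dq + dj/dp) / (dj/dx . f- + dj/dt)`.  For the LIF
#' jump condition `dj/dx` has a single non-zero entry, so `dt*/dx-` is
#' sparse: `-1 / f_V,i` at the crossing neuron's membrane coordinate and
#' zero elsewhere.  A vanishing denominator (grazing, tangential crossing)
#' is flagged rather than smoothed.
#'
#' @param rec one event record from [forward_hybrid()] (`type == "spike"`).
#' @param sys the [lif_system()].
#' @param eps_graze grazing tolerance for the denominator (V/s).
#' @return A list with `denom`, `dt_dV` (the non-zero entry of `dt*/dx-`),
#'   `neuron`, `dt_dvth` (derivative w.r.t. the threshold parameter) and
#'   `grazing` (logical).
#' @export
event_time_derivative <- function(rec, sys, eps_graze = 1e-9) {
  stopifnot(identical(rec$type, "spike"))
  i <- rec$neuron
  denom <- rec$f_minus$V[i]          # dj/dx . f- (dj/dt = 0)
  grazing <- abs(denom) < eps_graze
  list(denom = denom,
       dt_dV = if (grazing) NA_real_ else -1 / denom,
       neuron = i,
       dt_dvth = if (grazing) NA_real_ else 1 / denom,
       grazing = grazing)
}

#' Loss specification for adjoint gradients
#'
#' Supported terms: a differentiable terminal loss, sparse-observation
#' penalties `sum_i |P x(t_i) - xhat_i|^2` (Dirac contributions to the
#' adjoint at the observation times), an integrand `l(x, t)` accumulated by
#' trapezoidal quadrature, and direct event-time weights (`dL/dt*_k`, used
#' when composing subsystem gradients through spike times).
#'
#' @param terminal function `(V, I) -> value` evaluated at `T`.
#' @param terminal_grad function `(V, I) -> list(V =, I =)` gradient of the
#'   terminal loss.
#' @param observations list of `list(t =, P =, xhat =)` with `P` a
#'   projection matrix (k x 2n, state ordered `(V, I)`) and `xhat` length k.
#'   Observation times are snapped to the forward grid.
#' @param integrand optional function `(V, I, t) -> list(value =, dV =, dI =)`.
#' @param event_time_grad optional numeric vector: direct derivative of the
#'   loss w.r.t. each spike time (in forward event order).
#' @return An object of class `loss_spec`.
#' @export
loss_spec <- function(terminal = NULL, terminal_grad = NULL,
                      observations = NULL, integrand = NULL,
                      event_time_grad = NULL) {
  structure(list(terminal = terminal, terminal_grad = terminal_grad,
                 observations = observations, integrand = integrand,
                 event_time_grad = event_time_grad),
            class = "loss_spec")
}

#' Evaluate a loss specification on a forward trajectory
#'
#' @param sys the [lif_system()].
#' @param fwd result of [forward_hybrid()].
#' @param loss a [loss_spec()].
#' @return The scalar loss value.
#' @export
eval_loss <- function(sys, fwd, loss) {
  val <- 0
  nT <- length(fwd$time)
  if (!is.null(loss$terminal))
    val <- val + loss$terminal(fwd$V[nT, ], fwd$I[nT, ])
  if (!is.null(loss$observations)) {
    for (ob in loss$observations) {
      k <- which.min(abs(fwd$time - ob$t))
      x <- c(fwd$V[k, ], fwd$I[k, ])
      val <- val + sum((ob$P %*% x - ob$xhat)^2)
    }
  }
  if (!is.null(loss$integrand)) {
    lv <- vapply(seq_len(nT), function(k)
      loss$integrand(fwd$V[k, ], fwd$I[k, ], fwd$time[k])$value, numeric(1))
    val <- val + sum(diff(fwd$time) * (lv[-1] + lv[-nT]) / 2)
  }
  if (!is.null(loss$event_time_grad)) {
    sp <- Filter(function(e) e$type == "spike", fwd$events)
    val <- val + sum(loss$event_time_grad *
                       vapply(sp, `[[`, numeric(1), "time"))
  }
  val
}

#' Reverse-time adjoint gradients for a hybrid LIF system
#'
#' Integrates the adjoint state backward with the same closed-form
#' propagator as the forward pass (transposed), applies the adjoint event
#' jump
#' `lambda-' = lambda+' D`, `D = dT/dx- + (f+ - dT/dx- f-) (dt*/dx-)'`
#' at every spike, adds Dirac contributions `2 P'(P x - xhat)` at
#' observation times, and accumulates parameter gradients: transition
#' parameters (the weights) only at events — `dL/dW[j,i] += lambda+_{I_j}`
#' at each spike of neuron `i` — and flow parameters continuously by
#' Simpson quadrature of `lambda' df/dp` over each smooth segment (all
#' evaluation points are exact under the closed-form flow).
#'
#' @param sys the [lif_system()].
#' @param fwd result of [forward_hybrid()] for `sys`.
#' @param loss a [loss_spec()].
#' @param eps_graze grazing-event tolerance (V/s).
#' @return A list of gradients: `W` (matrix), `W_in` (or `NULL`), `I_ext`,
#'   `tau_m`, `tau_s`, `v_leak`, `R`, `v_reset`, `v_th`, plus
#'   `input_time_grad` (dL/d input spike times), `value` (the loss), and
#'   `grazing` (TRUE if any event was flagged unreliable).
#' @export
backward_adjoint <- function(sys, fwd, loss, eps_graze = 1e-9) {
  n <- sys$n
  nT <- length(fwd$time)
  lamV <- rep(0, n); lamI <- rep(0, n)
  if (!is.null(loss$terminal_grad)) {
    g <- loss$terminal_grad(fwd$V[nT, ], fwd$I[nT, ])
    lamV <- lamV + g$V; lamI <- lamI + g$I
  }
  obs_at <- function(tt) {
    if (is.null(loss$observations)) return(NULL)
    Filter(function(ob) abs(fwd$time[which.min(abs(fwd$time - ob$t))] - tt) <
             1e-15 + 1e-9 * max(fwd$time), loss$observations)
  }
  add_obs <- function(tt, k_grid) {
    for (ob in obs_at(tt)) {
      x <- c(fwd$V[k_grid, ], fwd$I[k_grid, ])
      gr <- 2 * t(ob$P) %*% (ob$P %*% x - ob$xhat)
      lamV <<- lamV + gr[seq_len(n)]
      lamI <<- lamI + gr[n + seq_len(n)]
    }
  }

  gW <- matrix(0, n, n)
  gWin <- if (is.null(sys$W_in)) NULL else matrix(0, n, ncol(sys$W_in))
  g <- list(tau_m = 0, tau_s = 0, v_leak = 0, R = 0, v_reset = 0, v_th = 0,
            I_ext = rep(0, n))
  grazing <- FALSE

  sp_events <- which(vapply(fwd$events, function(e) e$type == "spike",
                            logical(1)))
  etg <- loss$event_time_grad
  if (!is.null(etg)) stopifnot(length(etg) == length(sp_events))
  input_tg <- numeric(sum(vapply(fwd$events, function(e)
    e$type == "input", logical(1))))

  # df/dp accumulation at a trajectory sample (trapezoid weights handled
  # by the caller)
  dfdp_add <- function(V, I, wgt) {
    fV <- (sys$v_leak - V + sys$R * (I + sys$I_ext)) / sys$tau_m
    g$tau_m <<- g$tau_m + wgt * sum(lamV * (-fV / sys$tau_m))
    g$tau_s <<- g$tau_s + wgt * sum(lamI * (I / sys$tau_s^2))
    g$v_leak <<- g$v_leak + wgt * sum(lamV) / sys$tau_m
    g$R <<- g$R + wgt * sum(lamV * (I + sys$I_ext)) / sys$tau_m
    g$I_ext <<- g$I_ext + wgt * lamV * sys$R / sys$tau_m
  }

  # transpose of the closed-form state-transition matrix over interval d
  pullback <- function(d) {
    Em <- exp(-d / sys$tau_m); Es <- exp(-d / sys$tau_s)
    cc <- sys$R * sys$tau_s / (sys$tau_s - sys$tau_m)
    newI <- cc * (Es - Em) * lamV + Es * lamI
    lamV <<- Em * lamV
    lamI <<- newI
  }

  # flow-parameter quadrature over one smooth segment: Simpson's rule on
  # exact endpoint/midpoint states and adjoints (O(d^5) per segment)
  integrate_segment <- function(x_lo, x_hi, d) {
    if (d <= 0) return(invisible(NULL))
    dfdp_add(x_hi$V, x_hi$I, d / 6)
    pullback(d / 2)
    mid <- lif_flow(sys, x_lo$V, x_lo$I, d / 2)
    dfdp_add(mid$V, mid$I, 4 * d / 6)
    pullback(d / 2)
    dfdp_add(x_lo$V, x_lo$I, d / 6)
  }

  # walk backward over grid nodes; events partition the steps further
  ev_times <- vapply(fwd$events, `[[`, numeric(1), "time")
  ev_order <- order(ev_times)        # forward order
  ev_sorted <- rev(ev_order)         # backward processing order

  # map from event index to spike-order / input-order position
  spike_pos <- match(seq_along(fwd$events), sp_events)
  input_ids <- which(vapply(fwd$events, function(e) e$type == "input",
                            logical(1)))
  input_pos <- match(seq_along(fwd$events), input_ids)

  t_cur <- fwd$time[nT]
  add_obs(t_cur, nT)
  k_grid <- nT
  ev_ptr <- 1L
  n_ev <- length(ev_sorted)

  # state lookup along the stored grid for df/dp quadrature
  state_at <- function(k) list(V = fwd$V[k, ], I = fwd$I[k, ])

  while (k_grid > 1) {
    t_lo <- fwd$time[k_grid - 1]
    # events inside (t_lo, t_cur]
    while (ev_ptr <= n_ev && ev_times[ev_sorted[ev_ptr]] > t_lo &&
           ev_times[ev_sorted[ev_ptr]] <= t_cur + 1e-18) {
      eid <- ev_sorted[ev_ptr]
      ev <- fwd$events[[eid]]
      d_seg <- t_cur - ev$time
      integrate_segment(ev$x_plus, state_at(k_grid), d_seg)
      # adjoint transition at the event
      if (ev$type == "spike") {
        i <- ev$neuron
        etd <- event_time_derivative(ev, sys, eps_graze)
        if (etd$grazing) grazing <- TRUE
        # transition-parameter gradients: dL/dW[, i] += lambda_I
        gW[, i] <- gW[, i] + lamI
        g$v_reset <- g$v_reset + lamV[i]
        # h = f+ - dT/dx- f- : f- with the reset row zeroed
        hmV <- ev$f_minus$V; hmV[i] <- 0
        hV <- ev$f_plus$V - hmV
        hI <- ev$f_plus$I - ev$f_minus$I
        lam_dot_h <- sum(lamV * hV) + sum(lamI * hI)
        ci <- if (!is.null(etg)) etg[spike_pos[eid]] else 0
        if (!etd$grazing) {
          # dL/dv_th = (c_k - lambda+.h) * dt*/dv_th, dt*/dv_th = 1/denom
          g$v_th <- g$v_th + (ci - lam_dot_h) * etd$dt_dvth
          # lambda-_{V_i} = (lambda+.h - c_k) / denom  (the scalar reset
          # case lambda- = (f+/f-) lambda+ fixes the sign)
          new_lamVi <- (lam_dot_h - ci) / etd$denom
        } else {
          new_lamVi <- 0
        }
        # dT/dx-^T lambda+: V_i row of T is constant => lambda_{V_i} drops
        lamV[i] <- new_lamVi
      } else {
        # input event at a fixed time: lambda continuous, weight gradient
        src <- ev$src
        gWin[, src] <- gWin[, src] + lamI
        input_tg[input_pos[eid]] <-
          sum(lamV * (ev$f_minus$V - ev$f_plus$V)) +
          sum(lamI * (ev$f_minus$I - ev$f_plus$I))
      }
      # replace the stored grid state by the event's pre state for the next
      # quadrature segment
      fwd$V[k_grid, ] <- ev$x_minus$V
      fwd$I[k_grid, ] <- ev$x_minus$I
      fwd$time[k_grid] <- ev$time
      t_cur <- ev$time
      ev_ptr <- ev_ptr + 1L
    }
    d_seg <- t_cur - t_lo
    s_hi <- state_at(k_grid)
    k_grid <- k_grid - 1L
    s_lo <- state_at(k_grid)
    integrate_segment(s_lo, s_hi, d_seg)
    t_cur <- t_lo
    add_obs(t_cur, k_grid)
    # integrand contribution to the adjoint
    if (!is.null(loss$integrand)) {
      li <- loss$integrand(s_lo$V, s_lo$I, t_cur)
      lamV <- lamV + d_seg * li$dV
      lamI <- lamI + d_seg * li$dI
    }
  }

  list(W = gW, W_in = gWin, I_ext = g$I_ext, tau_m = g$tau_m,
       tau_s = g$tau_s, v_leak = g$v_leak, R = g$R,
       v_reset = g$v_reset, v_th = g$v_th,
       input_time_grad = input_tg,
       value = eval_loss(sys, fwd, loss), grazing = grazing)
}

# internal: flatten/unflatten the differentiable parameters of a lif_system
lif_param_vec <- function(sys) {
  c(tau_m = sys$tau_m, tau_s = sys$tau_s, v_leak = sys$v_leak, R = sys$R,
    v_reset = sys$v_reset, v_th = sys$v_th,
    stats::setNames(sys$I_ext, paste0("I_ext", seq_len(sys$n))),
    stats::setNames(as.numeric(sys$W),
                    paste0("W", seq_len(sys$n * sys$n))),
    if (!is.null(sys$W_in))
      stats::setNames(as.numeric(sys$W_in),
                      paste0("Win", seq_len(length(sys$W_in)))))
}

lif_param_set <- function(sys, vec) {
  n <- sys$n
  sys$tau_m <- vec[["tau_m"]]; sys$tau_s <- vec[["tau_s"]]
  sys$v_leak <- vec[["v_leak"]]; sys$R <- vec[["R"]]
  sys$v_reset <- vec[["v_reset"]]; sys$v_th <- vec[["v_th"]]
  sys$I_ext <- unname(vec[6 + seq_len(n)])
  sys$W <- matrix(unname(vec[6 + n + seq_len(n * n)]), n, n)
  if (!is.null(sys$W_in))
    sys$W_in <- matrix(unname(vec[6 + n + n * n + seq_len(length(sys$W_in))]),
                       n, ncol(sys$W_in))
  sys
}

# internal: adjoint gradient in the same flat layout
lif_grad_vec <- function(gr, sys) {
  c(tau_m = gr$tau_m, tau_s = gr$tau_s, v_leak = gr$v_leak, R = gr$R,
    v_reset = gr$v_reset, v_th = gr$v_th,
    stats::setNames(gr$I_ext, paste0("I_ext", seq_len(sys$n))),
    stats::setNames(as.numeric(gr$W), paste0("W", seq_len(sys$n^2))),
    if (!is.null(gr$W_in))
      stats::setNames(as.numeric(gr$W_in),
                      paste0("Win", seq_len(length(gr$W_in)))))
}

#' Central finite-difference gradient (verification oracle)
#'
#' Perturbs every differentiable parameter of the system by `+/- eps`
#' (relative where the parameter is non-zero), reruns the forward pass and
#' the loss, and forms central differences.  Coordinates whose perturbation
#' changes the event count are flagged non-differentiable at this point.
#'
#' @param sys a [lif_system()].
#' @param loss a [loss_spec()].
#' @param T,dt forward integration horizon and grid step (s).
#' @param x0 initial state (see [forward_hybrid()]).
#' @param eps base perturbation size.
#' @return A list with `grad` (named vector matching the flattened
#'   parameters), `flagged` (logical vector: event count changed) and
#'   `n_events` of the unperturbed run.
#' @export
finite_difference_gradient <- function(sys, loss, T, dt = 1e-7, x0 = NULL,
                                       eps = 1e-6) {
  p0 <- lif_param_vec(sys)
  if (is.null(x0))   # the initial state is data, not a function of v_leak
    x0 <- list(V = rep(sys$v_leak, sys$n), I = rep(0, sys$n))
  base <- forward_hybrid(sys, T, dt, x0)
  n_ev <- length(base$events)
  grad <- numeric(length(p0)); names(grad) <- names(p0)
  flagged <- logical(length(p0)); names(flagged) <- names(p0)
  for (k in seq_along(p0)) {
    h <- eps * max(abs(p0[k]), 1e-3)
    pp <- p0; pp[k] <- p0[k] + h
    pm <- p0; pm[k] <- p0[k] - h
    fp <- forward_hybrid(lif_param_set(sys, pp), T, dt, x0)
    fm <- forward_hybrid(lif_param_set(sys, pm), T, dt, x0)
    if (length(fp$events) != n_ev || length(fm$events) != n_ev)
      flagged[k] <- TRUE
    grad[k] <- (eval_loss(sys, fp, loss) - eval_loss(sys, fm, loss)) / (2 * h)
  }
  list(grad = grad, flagged = flagged, n_events = n_ev)
}

#' Adjoint gradient in the flat parameter layout of the oracle
#'
#' Convenience wrapper: runs [forward_hybrid()] and [backward_adjoint()] and
#' returns the gradient as a named vector aligned with
#' [finite_difference_gradient()].
#'
#' @inheritParams finite_difference_gradient
#' @return A list with `grad` (named vector), `value` and `grazing`.
#' @export
adjoint_gradient <- function(sys, loss, T, dt = 1e-7, x0 = NULL) {
  if (is.null(x0))
    x0 <- list(V = rep(sys$v_leak, sys$n), I = rep(0, sys$n))
  fwd <- forward_hybrid(sys, T, dt, x0)
  bk <- backward_adjoint(sys, fwd, loss)
  list(grad = lif_grad_vec(bk, sys), value = bk$value,
       grazing = bk$grazing, n_events = length(fwd$events))
}
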