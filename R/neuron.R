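#' AdEx neuron parameter set
#'
#' Constructs a validated parameter set for the adaptive exponential
#' integrate-and-fire (AdEx) neuron
#' \deqn{C_m \dot V = -g_l (V - E_l) + g_l \Delta_T
#'       \exp\!\left(\frac{V - V_T}{\Delta_T}\right) - w + I,}
#' \deqn{\tau_w \dot w = a (V - E_l) - w,}
#' with a hard firing threshold `V_th`: on crossing, the membrane is clamped
#' to the reset potential `V_r` for the refractory period `t_r` and the
#' adaptation current is incremented by `b`.  Feature switches mirror the
#' hardware's per-neuron digital configuration: disabling the exponential and
#' adaptation terms yields a leaky integrate-and-fire (LIF) neuron; disabling
#' also leak and threshold yields a pure charge integrator, the basis of the
#' analog matrix-multiply mode.
#'
#' All values are SI units.  The `domain` attribute records whether time
#' constants are expressed in the accelerated hardware time domain (the
#' internal convention, microsecond scale) or in biological time; use
#' [convert_biological_params()] to move between the two.
#'
#' @param C_m membrane capacitance (F); must be positive.
#' @param g_l leak conductance (S).
#' @param E_l leak (resting) potential (V).
#' @param Delta_T exponential slope (V); must be positive when `enable_exp`.
#' @param V_T soft (exponential-onset) threshold (V).
#' @param V_th hard firing threshold (V); defaults to `V_T + 5 * Delta_T`.
#' @param V_r reset potential (V).
#' @param t_r refractory period (s), non-negative.
#' @param a subthreshold adaptation conductance (S); may be negative.
#' @param b spike-triggered adaptation increment (A).
#' @param tau_w adaptation time constant (s); must be positive.
#' @param enable_exp,enable_adapt,enable_leak,enable_threshold feature
#'   switches for the exponential term, the adaptation current, the leak
#'   conductance and the hard threshold.
#' @param I_exp_max clamp on the exponential current (A); defaults to
#'   `50 * g_l * Delta_T`, mimicking the finite currents of the circuit.
#' @param domain `"hardware"` (default) or `"biological"` time domain.
#' @return An object of class `adex_params` (a named list).
#' @seealso [run_neuron()], [step_neuron()], [adex_pattern_sets()]
#' @export
adex_params <- function(C_m = 2e-13, g_l = 1e-8, E_l = -70e-3,
                        Delta_T = 2e-3, V_T = -50e-3, V_th = NULL,
                        V_r = -58e-3, t_r = 1e-6,
                        a = 0, b = 0, tau_w = 30e-6,
                        enable_exp = TRUE, enable_adapt = TRUE,
                        enable_leak = TRUE, enable_threshold = TRUE,
                        I_exp_max = NULL, domain = c("hardware", "biological")) {
  domain <- match.arg(domain)
  if (is.null(V_th)) V_th <- V_T + 5 * Delta_T
  if (is.null(I_exp_max)) I_exp_max <- 50 * g_l * Delta_T
  p <- list(C_m = C_m, g_l = g_l, E_l = E_l, Delta_T = Delta_T, V_T = V_T,
            V_th = V_th, V_r = V_r, t_r = t_r, a = a, b = b, tau_w = tau_w,
            enable_exp = isTRUE(enable_exp), enable_adapt = isTRUE(enable_adapt),
            enable_leak = isTRUE(enable_leak),
            enable_threshold = isTRUE(enable_threshold),
            I_exp_max = I_exp_max)
  class(p) <- "adex_params"
  attr(p, "domain") <- domain
  validate_adex_params(p)
  p
}

validate_adex_params <- function(p) {
  stopifnot(p$C_m > 0, p$tau_w > 0, p$t_r >= 0)
  if (p$enable_exp) {
    if (p$Delta_T <= 0) stop("Delta_T must be positive when enable_exp")
    if (p$V_th <= p$V_T) stop("V_th must exceed V_T when enable_exp")
  }
  invisible(p)
}

#' @export
print.adex_params <- function(x, ...) {
  cat(sprintf("AdEx parameter set (%s time domain)\n", attr(x, "domain")))
  cat(sprintf("  tau_m = C_m/g_l = %.3g s, tau_w = %.3g s, t_r = %.3g s\n",
              x$C_m / x$g_l, x$tau_w, x$t_r))
  cat(sprintf("  E_l = %.3g V, V_T = %.3g V, V_th = %.3g V, V_r = %.3g V\n",
              x$E_l, x$V_T, x$V_th, x$V_r))
  cat(sprintf("  a = %.3g S, b = %.3g A, Delta_T = %.3g V\n",
              x$a, x$b, x$Delta_T))
  cat(sprintf("  enables: exp=%s adapt=%s leak=%s threshold=%s\n",
              x$enable_exp, x$enable_adapt, x$enable_leak, x$enable_threshold))
  invisible(x)
}

#' Convert a biological-time parameter set to the hardware time domain
#'
#' The emulated dynamics run at an accelerated time scale (nominally 1000x
#' faster than biology).  Conversion divides all time constants (`tau_w`,
#' `t_r`) by the acceleration factor and rescales the capacitance so that the
#' derived membrane time constant `C_m / g_l` transforms identically;
#' voltages, conductances and currents are unchanged.
#'
#' @param params an [adex_params()] object.
#' @param acceleration positive acceleration factor (default 1000).
#' @return An `adex_params` object in the opposite time domain (for
#'   `acceleration = 1` the domain tag is preserved).
#' @export
convert_biological_params <- function(params, acceleration = 1000) {
  stopifnot(inherits(params, "adex_params"))
  if (!is.numeric(acceleration) || length(acceleration) != 1 ||
      !is.finite(acceleration) || acceleration <= 0)
    stop("acceleration must be a positive number")
  p <- params
  p$C_m <- p$C_m / acceleration
  p$tau_w <- p$tau_w / acceleration
  p$t_r <- p$t_r / acceleration
  p$I_exp_max <- params$I_exp_max
  if (acceleration != 1) {
    attr(p, "domain") <-
      if (identical(attr(params, "domain"), "biological")) "hardware"
      else "biological"
  }
  validate_adex_params(p)
  p
}

#' Neuron state
#'
#' @param V membrane potential (V).
#' @param w adaptation current (A).
#' @param refractory_until end of the current refractory clamp (s).
#' @param last_spike_time time of the most recent spike (s) or `NA`.
#' @return An object of class `neuron_state`.
#' @export
neuron_state <- function(V, w = 0, refractory_until = -Inf,
                         last_spike_time = NA_real_) {
  structure(list(V = V, w = w, refractory_until = refractory_until,
                 last_spike_time = last_spike_time),
            class = "neuron_state")
}

#' Step-current stimulus protocol
#'
#' A step current `I_stim = I_0 * theta(t - t_on) * theta(t_off - t)` over a
#' total duration `T`, the protocol used for firing-pattern replication.
#' Defaults follow the hardware experiment: onset at 50 us, offset at 400 us,
#' 450 us total (hardware time domain).
#'
#' @param I_0 step amplitude (A).
#' @param t_on,t_off step onset and offset times (s), `0 <= t_on < t_off <= T`.
#' @param T total duration (s).
#' @return An object of class `stim_protocol`.
#' @export
stim_protocol <- function(I_0, t_on = 50e-6, t_off = 400e-6, T = 450e-6) {
  stopifnot(t_on >= 0, t_on < t_off, t_off <= T)
  structure(list(I_0 = I_0, t_on = t_on, t_off = t_off, T = T),
            class = "stim_protocol")
}

# internal: parameter matrix in the column layout of the compiled core
par_matrix <- function(param_list) {
  if (inherits(param_list, "adex_params")) param_list <- list(param_list)
  m <- matrix(0, nrow = length(param_list), ncol = 19)
  for (i in seq_along(param_list)) {
    p <- param_list[[i]]
    m[i, ] <- c(p$C_m, p$g_l, p$E_l, p$Delta_T, p$V_T, p$V_th, p$V_r, p$t_r,
                p$a, p$b, p$tau_w,
                as.numeric(p$enable_exp), as.numeric(p$enable_adapt),
                as.numeric(p$enable_leak), as.numeric(p$enable_threshold),
                p$I_exp_max,
                as.numeric(isTRUE(p$plateau)),
                if (is.null(p$V_plateau)) 0 else p$V_plateau,
                if (is.null(p$t_plateau)) 0 else p$t_plateau)
  }
  m
}

#' Advance a neuron state by one integration step
#'
#' One exponential-Euler update of `(V, w)` under a constant total input
#' current `I_in` (synaptic plus stimulus).  The leak term is integrated
#' exactly; the exponential current (clamped to `I_exp_max`), the adaptation
#' current and `I_in` are held at their start-of-step values.  Disabled terms
#' contribute exactly zero.  While the state is refractory the membrane stays
#' clamped to `V_r`.  Threshold detection is handled by [run_neuron()], not
#' here.
#'
#' @param state a [neuron_state()].
#' @param params an [adex_params()] object (hardware time domain).
#' @param I_in total input current (A).
#' @param dt step size (s), positive.
#' @param t current time (s), used only for the refractory clamp.
#' @return The updated `neuron_state`.
#' @export
step_neuron <- function(state, params, I_in, dt, t = 0) {
  stopifnot(dt > 0)
  if (!is.finite(state$V) || !is.finite(state$w))
    stop(sprintf(
      "non-finite neuron state rejected: V = %g, w = %g", state$V, state$w))
  p <- params
  V <- state$V
  w <- state$w
  refractory <- t < state$refractory_until

  I_exp <- 0
  if (p$enable_exp && !refractory) {
    I_exp <- p$g_l * p$Delta_T * exp((V - p$V_T) / p$Delta_T)
    if (!is.finite(I_exp))
      stop("exponential current overflowed before clamping; check V and Delta_T")
    I_exp <- min(I_exp, p$I_exp_max)
  }
  if (p$enable_adapt) {
    w_inf <- p$a * (V - p$E_l)
    w <- w_inf + (state$w - w_inf) * exp(-dt / p$tau_w)
  }
  V_new <- if (refractory) {
    p$V_r
  } else if (p$enable_leak) {
    V_eff <- p$E_l + (I_exp - state$w + I_in) / p$g_l
    V_eff + (V - V_eff) * exp(-dt * p$g_l / p$C_m)
  } else {
    V + dt * (I_exp - state$w + I_in) / p$C_m
  }
  if (!is.finite(V_new))
    stop(sprintf(paste0(
      "membrane update overflowed: I_exp = %g A, w = %g A, I_in = %g A"),
      I_exp, state$w, I_in))
  neuron_state(V = V_new, w = w, refractory_until = state$refractory_until,
               last_spike_time = state$last_spike_time)
}

#' Simulate a single neuron under a step-current protocol
#'
#' Integrates the AdEx dynamics with exponential Euler at resolution `dt`,
#' records the membrane and adaptation traces, and emits spikes whenever `V`
#' crosses the hard threshold `V_th` (crossing times located by linear
#' interpolation within the step).  On a spike the membrane is reset to `V_r`
#' and clamped there for `t_r`, and `w` is incremented by `b`.
#'
#' @param params an [adex_params()] object in the hardware time domain.
#' @param protocol a [stim_protocol()].
#' @param dt integration step (s); default 0.1 us.
#' @param V0 initial membrane potential; defaults to `E_l`.
#' @param w0 initial adaptation current (A).
#' @return A list with `time`, `V`, `w` (traces sampled every `dt`) and
#'   `spikes` (vector of spike times, class `spike_train`).
#' @export
run_neuron <- function(params, protocol, dt = 1e-7, V0 = NULL, w0 = 0) {
  stopifnot(inherits(params, "adex_params"), inherits(protocol, "stim_protocol"))
  if (identical(attr(params, "domain"), "biological"))
    stop("params are in the biological time domain; convert first ",
         "(convert_biological_params)")
  if (is.null(V0)) V0 <- params$E_l
  stim <- matrix(c(protocol$I_0, protocol$t_on, protocol$t_off),
                 nrow = 1, ncol = 3)
  res <- .adex_mc_run(par_matrix(params), matrix(0, 1, 1), stim,
                      numeric(0), integer(0), numeric(0), 1e-6,
                      dt, protocol$T, V0, w0, TRUE)
  spikes <- structure(res$spike_time, class = "spike_train")
  list(time = res$time, V = res$V[, 1], w = res$w[, 1], spikes = spikes)
}

#' Classify the firing pattern of a spike train under a step stimulus
#'
#' Deterministic labelling from inter-spike-interval (ISI) statistics, in the
#' spirit of the classical AdEx firing-pattern taxonomy.  With stimulus
#' window `D = t_off - t_on`:
#' \itemize{
#'   \item `silent`: no spikes.
#'   \item `transient`: all spikes inside the first `transient_frac` of the
#'     window, silence thereafter.
#'   \item bursting family: the ISI distribution splits into short
#'     (intra-burst) and long (inter-burst) groups with
#'     `max(short) < theta_b * min(long)`.  Two or more bursts recurring
#'     until `t_off` give `regular_bursting`, or `delayed_regular_bursting`
#'     when the first spike is later than `delay_frac` of the window; a
#'     single leading burst followed by tonic spiking gives `initial_burst`.
#'   \item `tonic`: unimodal ISIs continuing until the stimulus ends.
#'   \item `other`: anything else.
#' }
#'
#' @param spikes numeric vector of spike times (s) or a `spike_train`.
#' @param protocol the [stim_protocol()] used.
#' @param transient_frac,delay_frac,theta_b classifier thresholds
#'   (configurable; defaults 0.2, 0.3 and 0.25).
#' @return A single label string.
#' @export
classify_firing_pattern <- function(spikes, protocol,
                                    transient_frac = 0.2, delay_frac = 0.3,
                                    theta_b = 0.25) {
  s <- sort(as.numeric(spikes))
  if (any(s < 0 | s > protocol$T))
    stop("spike times outside [0, T] rejected")
  if (length(s) == 0) return("silent")
  D <- protocol$t_off - protocol$t_on
  delayed <- (s[1] - protocol$t_on) > delay_frac * D
  if (all(s <= protocol$t_on + transient_frac * D)) return("transient")
  if (length(s) == 1) return("other")

  d <- diff(s)
  tail_gap <- protocol$t_off - s[length(s)]
  continuing <- tail_gap <= 2 * max(d)
  if (length(d) == 1) return(if (continuing && !delayed) "tonic" else "other")

  ds <- sort(d)
  ratios <- ds[-1] / ds[-length(ds)]
  k <- which.max(ratios)
  bimodal <- ds[k] < theta_b * ds[k + 1]

  if (bimodal) {
    thr <- sqrt(ds[k] * ds[k + 1])
    burst_id <- cumsum(c(TRUE, d > thr))
    sizes <- tabulate(burst_id)
    n_bursts <- length(sizes)
    if (sizes[1] >= 2 && all(sizes[-1] == 1) && continuing)
      return("initial_burst")
    if (sum(sizes >= 2) >= 2 && continuing)
      return(if (delayed) "delayed_regular_bursting" else "regular_bursting")
    return("other")
  }
  if (continuing && !delayed) return("tonic")
  "other"
}

#' Built-in AdEx firing-regime parameter sets
#'
#' Biological-time AdEx parameter sets for the classical firing regimes
#' (tonic spiking, adaptation, initial burst, regular bursting, delayed
#' accelerating, delayed regular bursting, transient spiking), following the
#' published AdEx firing-pattern taxonomy of Naud et al. (2008).  Each entry
#' carries the step-current amplitude `I_0` (A) used to elicit the pattern.
#' Sign and magnitude constraints characterise the regimes: transient spiking
#' needs a large spike-triggered increment `b` together with strong
#' subthreshold adaptation `a`; regular bursting and the initial burst use
#' small `a` and differ mainly in the reset `V_r` relative to `V_T` (above
#' for bursting); delayed patterns use inverted adaptation `a < 0`.
#'
#' @return A named list; each element has `params` ([adex_params()],
#'   biological domain) and `I_0`.
#' @export
adex_pattern_sets <- function() {
  mk <- function(C, gL, EL, VT, a, tauw, b, Vr, I0) {
    list(params = adex_params(C_m = C * 1e-12, g_l = gL * 1e-9,
                              E_l = EL * 1e-3, Delta_T = 2e-3,
                              V_T = VT * 1e-3, V_r = Vr * 1e-3,
                              t_r = 1e-3, a = a * 1e-9, b = b * 1e-12,
                              tau_w = tauw * 1e-3, domain = "biological"),
         I_0 = I0 * 1e-12)
  }
  list(
    tonic_spiking     = mk(200, 10, -70, -50,   2,  30,   0, -58, 500),
    adaptation        = mk(200, 12, -70, -50,   2, 300,  60, -58, 500),
    initial_burst     = mk(130, 18, -58, -50,   4, 150, 120, -50, 400),
    regular_bursting  = mk(200, 10, -58, -50,   2, 120, 100, -46, 250),
    delayed_accel     = mk(200, 12, -70, -50, -10, 300,   0, -58, 300),
    delayed_bursting  = mk(100, 10, -65, -50, -10,  90,  30, -47,  70),
    transient_spiking = mk(100, 10, -65, -50,  10,  90, 100, -47, 180)
  )
}
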