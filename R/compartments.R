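#' Multi-compartment neuron graph
#'
#' Builds a graph of neuron circuits joined by inter-compartment (axial)
#' conductances, emulating the hardware's resistor/switch interconnect
#' between neighbouring neuron circuits.  Each compartment carries its own
#' [adex_params()]; `role` controls its spiking semantics:
#' \itemize{
#'   \item `passive`: threshold disabled, pure cable-like integration,
#'   \item `somatic`: ordinary AdEx/LIF spiking,
#'   \item `plateau`: on crossing `V_th` the compartment is clamped to
#'     `V_plateau` for `t_plateau` (a dendritic plateau potential), then
#'     released; the adaptation current is not incremented.
#' }
#'
#' @param compartments list of [adex_params()] objects (one per compartment).
#' @param roles character vector, one of `"passive"`, `"plateau"`,
#'   `"somatic"` per compartment.
#' @param edges data frame with columns `i`, `j`, `g_ic` (1-based
#'   compartment indices and axial conductance in S, `g_ic >= 0`).
#' @param injections data frame with columns `comp`, `time`, `weight`:
#'   synaptic current injections (A, exponential kernel with `tau_syn`).
#' @param tau_syn synaptic time constant for injections (s).
#' @param V_plateau,t_plateau plateau clamp level (V) and duration (s) used
#'   by `plateau` compartments; defaults `V_th + 20 mV` and 10 us.
#' @return An object of class `compartment_graph`.
#' @export
compartment_graph <- function(compartments, roles = NULL, edges,
                              injections = NULL, tau_syn = 5e-6,
                              V_plateau = NULL, t_plateau = 10e-6) {
  n <- length(compartments)
  stopifnot(n >= 1)
  if (is.null(roles)) roles <- rep("passive", n)
  roles <- match.arg(roles, c("passive", "plateau", "somatic"),
                     several.ok = TRUE)
  stopifnot(length(roles) == n)
  if (any(edges$g_ic < 0)) stop("g_ic must be non-negative")
  # connectivity check (edges with g_ic = 0 still count as wired)
  if (n > 1) {
    adj <- matrix(FALSE, n, n)
    adj[cbind(edges$i, edges$j)] <- TRUE
    adj <- adj | t(adj)
    seen <- rep(FALSE, n); seen[1] <- TRUE; frontier <- 1L
    while (length(frontier)) {
      nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & !seen)
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    if (!all(seen)) stop("compartment graph is disconnected")
  }
  comps <- lapply(seq_len(n), function(i) {
    p <- compartments[[i]]
    p$enable_threshold <- roles[i] != "passive"
    p$plateau <- roles[i] == "plateau"
    if (p$plateau) {
      p$V_plateau <- if (is.null(V_plateau)) p$V_th + 20e-3 else V_plateau
      p$t_plateau <- t_plateau
    }
    p
  })
  structure(list(compartments = comps, roles = roles, edges = edges,
                 injections = injections, tau_syn = tau_syn),
            class = "compartment_graph")
}

#' @export
print.compartment_graph <- function(x, ...) {
  cat(sprintf("compartment_graph: %d compartments (%s), %d edges\n",
              length(x$compartments), paste(x$roles, collapse = ","),
              nrow(x$edges)))
  invisible(x)
}

#' Simulate a multi-compartment graph
#'
#' Each compartment integrates its AdEx dynamics plus explicit axial currents
#' `g_ic * (V_j - V_i)` from its neighbours, with the same exponential-Euler
#' scheme as [run_neuron()].  Plateau compartments clamp to `V_plateau` for
#' `t_plateau` upon threshold crossing.
#'
#' @param graph a [compartment_graph()].
#' @param dt integration step (s).
#' @param T total duration (s).
#' @return A list with `time`, `V` (matrix, one column per compartment), `w`,
#'   and `spikes` (data frame `time`, `comp` of dendritic/somatic spikes).
#' @export
simulate_compartments <- function(graph, dt = 1e-7, T = 100e-6) {
  stopifnot(inherits(graph, "compartment_graph"))
  n <- length(graph$compartments)
  g <- matrix(0, n, n)
  if (nrow(graph$edges))
    for (k in seq_len(nrow(graph$edges))) {
      i <- graph$edges$i[k]; j <- graph$edges$j[k]
      g[i, j] <- g[i, j] + graph$edges$g_ic[k]
      g[j, i] <- g[j, i] + graph$edges$g_ic[k]
    }
  stim <- matrix(0, n, 3)
  inj <- graph$injections
  if (is.null(inj) || nrow(inj) == 0) {
    ev_t <- numeric(0); ev_c <- integer(0); ev_a <- numeric(0)
  } else {
    o <- order(inj$time)
    ev_t <- inj$time[o]; ev_c <- as.integer(inj$comp[o] - 1L)
    ev_a <- inj$weight[o]
  }
  v0 <- vapply(graph$compartments, function(p) p$E_l, numeric(1))
  res <- .adex_mc_run(par_matrix(graph$compartments), g, stim,
                      ev_t, ev_c, ev_a, graph$tau_syn,
                      dt, T, v0, rep(0, n), TRUE)
  list(time = res$time, V = res$V, w = res$w,
       spikes = data.frame(time = res$spike_time, comp = res$spike_comp))
}

#' Measure an excitatory postsynaptic potential
#'
#' Amplitude is the trace maximum minus the mean over the baseline window;
#' full width at half maximum (FWHM) is found by linear interpolation at half
#' height on both flanks.
#'
#' @param time,V numeric vectors: trace sample times (s) and potentials (V).
#' @param baseline_until end of the baseline window (s).
#' @return A list with `amplitude` (V), `fwhm` (s, `NA` for a flat trace)
#'   and `peak_time` (s).
#' @export
measure_psp <- function(time, V, baseline_until) {
  base <- mean(V[time <= baseline_until])
  k <- which.max(V)
  amplitude <- V[k] - base
  if (amplitude <= 0 || !any(V > base + amplitude / 2 + 0 * amplitude)) {
    return(list(amplitude = max(0, amplitude), fwhm = NA_real_,
                peak_time = time[k]))
  }
  half <- base + amplitude / 2
  above <- V >= half
  cross <- function(i1, i2) {
    # linear interpolation of the half-height crossing between samples
    time[i1] + (half - V[i1]) * (time[i2] - time[i1]) / (V[i2] - V[i1])
  }
  first <- which(above)[1]
  last <- which(above)[length(which(above))]
  t_up <- if (first == 1) time[1] else cross(first - 1, first)
  t_dn <- if (last == length(V)) time[length(V)] else cross(last + 1, last)
  list(amplitude = amplitude, fwhm = t_dn - t_up, peak_time = time[k])
}

#' Default passive chain model
#'
#' A chain of `n` passive LIF compartments with uniform axial conductance,
#' the configuration used to demonstrate EPSP attenuation along a dendrite.
#'
#' @param n number of compartments.
#' @param g_ic axial conductance between neighbours (S).
#' @param inject_at compartment receiving the synaptic injection (1-based).
#' @param weight injection amplitude (A).
#' @param t_inject injection time (s).
#' @return A [compartment_graph()].
#' @export
passive_chain <- function(n = 4, g_ic = 2e-8, inject_at = 1,
                          weight = 2e-9, t_inject = 20e-6) {
  p <- adex_params(C_m = 2e-13, g_l = 1e-8, E_l = -70e-3,
                   enable_exp = FALSE, enable_adapt = FALSE)
  edges <- data.frame(i = seq_len(n - 1), j = seq_len(n - 1) + 1, g_ic = g_ic)
  inj <- data.frame(comp = inject_at, time = t_inject, weight = weight)
  compartment_graph(rep(list(p), n), rep("passive", n), edges, inj)
}

#' Default branched model with a plateau-spike initiation zone
#'
#' A short dendritic trunk that splits into two branches; compartment 1 (the
#' start of one branch) is configured as the spike-initiation zone
#' supporting plateau potentials.  Layout (1-based indices):
#' `1 - 2 - 3` (branch A, 1 is the initiation zone), trunk `3 - 4`,
#' second branch `3 - 5 - 6`.
#'
#' @param g_ic axial conductance (S).
#' @param V_th_plateau threshold of the initiation zone (V).
#' @return A [compartment_graph()] without injections (add per protocol).
#' @export
branched_plateau_model <- function(g_ic = 2.5e-8, V_th_plateau = -62e-3) {
  passive <- adex_params(C_m = 2e-13, g_l = 1e-8, E_l = -70e-3,
                         enable_exp = FALSE, enable_adapt = FALSE)
  zone <- adex_params(C_m = 2e-13, g_l = 1e-8, E_l = -70e-3,
                      V_T = V_th_plateau - 2e-3, V_th = V_th_plateau,
                      V_r = -70e-3, enable_exp = FALSE, enable_adapt = FALSE)
  comps <- c(list(zone), rep(list(passive), 5))
  roles <- c("plateau", rep("passive", 5))
  edges <- data.frame(i = c(1, 2, 3, 3, 5), j = c(2, 3, 4, 5, 6),
                      g_ic = g_ic)
  compartment_graph(comps, roles, edges)
}

#' Coincidence-detection protocol on a branched plateau model
#'
#' Injects two synaptic inputs at the given compartments with a fixed delay
#' and reports whether the spike-initiation zone fired a dendritic
#' (plateau) spike.  Deterministic given the parameters.
#'
#' @param graph a [compartment_graph()] with exactly one `plateau`
#'   compartment (the initiation zone).
#' @param site_pair integer vector of two injection compartments; the inputs
#'   arrive in the given order.
#' @param delay time between the first and second injection (s).
#' @param weight injection amplitude per input (A).
#' @param t0 time of the first injection (s).
#' @param dt,T integration step and duration (s).
#' @return A list with `fired` (logical), `spikes`, and the trace list.
#' @export
coincidence_protocol <- function(graph, site_pair, delay, weight = 0.7e-9,
                                 t0 = 20e-6, dt = 1e-7, T = 120e-6) {
  zone <- which(graph$roles == "plateau")
  if (length(zone) != 1)
    stop("graph must have exactly one plateau (spike-initiation) compartment")
  g <- graph
  g$injections <- data.frame(comp = site_pair,
                             time = c(t0, t0 + delay),
                             weight = weight)
  res <- simulate_compartments(g, dt = dt, T = T)
  fired <- any(res$spikes$comp == zone)
  list(fired = fired, spikes = res$spikes, trace = res, zone = zone)
}
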