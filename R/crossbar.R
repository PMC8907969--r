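#' Topology and quantization constants of the emulated analog core
#'
#' The full-scale core: four synaptic crossbar quadrants of 256 rows by 128
#' columns (512 neuron columns, 2^17 synapses in total), 6-bit synaptic
#' weights and 6-bit source addresses, 5-bit graded-spike payloads, an 8-bit
#' columnar ADC sampling at 1.7 us with 256 channels per quadrant row, 10-bit
#' analog parameter DACs serving 24 analog parameters per neuron, and a
#' nominal 1000-fold acceleration over biological time.
#'
#' @return A named list of constants.
#' @export
analog_core_config <- function() {
  list(quadrants = 4L, rows = 256L, cols = 128L,
       neurons = 512L, synapses = 2L^17L,
       weight_bits = 6L, address_bits = 6L,
       payload_max = 31L,
       cadc_bits = 8L, cadc_sampling_period = 1.7e-6, cadc_channels = 256L,
       dac_bits = 10L, n_analog_params = 24L,
       acceleration = 1000)
}

#' Synaptic crossbar array
#'
#' A quantized crossbar of 6-bit weights and 6-bit source address labels.
#' Row drivers carry a per-row sign (excitatory or inhibitory) and an enable
#' flag; the sign applies to the whole row.  The full-scale default is four
#' quadrants of 256 x 128 synapses.
#'
#' @param rows,cols synapses per quadrant.
#' @param quadrants number of quadrants.
#' @param weights,addresses integer matrices (`rows` x `cols`, values in
#'   0..63) used to initialise every quadrant, or `NULL` for zeros.
#' @param row_sign vector of `+1` (excitatory) / `-1` (inhibitory) per row.
#' @param row_enabled logical vector per row.
#' @return An object of class `synapse_array`.
#' @export
synapse_array <- function(rows = 256, cols = 128, quadrants = 4,
                          weights = NULL, addresses = NULL,
                          row_sign = rep(1L, rows),
                          row_enabled = rep(TRUE, rows)) {
  if (is.null(weights)) weights <- matrix(0L, rows, cols)
  if (is.null(addresses)) addresses <- matrix(0L, rows, cols)
  stopifnot(all(weights >= 0 & weights <= 63),
            all(addresses >= 0 & addresses <= 63),
            all(row_sign %in% c(-1L, 1L)), length(row_sign) == rows,
            length(row_enabled) == rows)
  q <- list(weights = weights, addresses = addresses,
            row_sign = as.integer(row_sign), row_enabled = row_enabled)
  structure(list(quadrants = rep(list(q), quadrants),
                 rows = rows, cols = cols),
            class = "synapse_array")
}

#' @export
print.synapse_array <- function(x, ...) {
  cat(sprintf("synapse_array: %d quadrant(s) of %d x %d 6-bit synapses\n",
              length(x$quadrants), x$rows, x$cols))
  invisible(x)
}

#' Spike-event packet
#'
#' An event entering a crossbar row: a 6-bit source label compared against
#' the per-synapse address, and a 5-bit graded payload (31 = full unit
#' pulse) scaling the injected charge — the encoding used both for spiking
#' operation and for graded-spike vector inputs in the matrix-multiply mode.
#'
#' @param time event time (s).
#' @param row target row (1-based).
#' @param label integer source address label in 0..63.
#' @param payload integer amplitude in 0..31.
#' @return An object of class `event_packet`.
#' @export
event_packet <- function(time, row, label, payload = 31L) {
  stopifnot(label >= 0, label <= 63, payload >= 0, payload <= 31)
  structure(list(time = time, row = as.integer(row),
                 label = as.integer(label), payload = as.integer(payload)),
            class = "event_packet")
}

#' Per-neuron synaptic input state
#'
#' Excitatory and inhibitory synaptic currents with independent exponential
#' time constants (the two kernels of the synaptic input circuit).
#'
#' @param n_neurons number of neuron columns.
#' @param tau_exc,tau_inh synaptic time constants (s), positive.
#' @return An object of class `synaptic_state`.
#' @export
synaptic_state <- function(n_neurons = 128, tau_exc = 5e-6, tau_inh = 5e-6) {
  stopifnot(tau_exc > 0, tau_inh > 0)
  structure(list(I_exc = numeric(n_neurons), I_inh = numeric(n_neurons),
                 tau_exc = tau_exc, tau_inh = tau_inh, dropped = 0L),
            class = "synaptic_state")
}

#' Deliver an address-matched event to a crossbar row
#'
#' Every synapse in the target row whose stored address equals the event's
#' label increments its column's excitatory or inhibitory current (per the
#' row sign) by `gamma * weight * payload / 31`; non-matching synapses
#' receive exactly zero.  Events on disabled rows are dropped and counted
#' (routing loss modelled as zero contribution).
#'
#' @param array a [synapse_array()].
#' @param state a [synaptic_state()] for the quadrant's neuron columns.
#' @param ev an [event_packet()].
#' @param quadrant quadrant index.
#' @param gamma global charge-scale constant (A per unit weight at full
#'   payload).
#' @return The updated `synaptic_state`.
#' @export
deliver_event <- function(array, state, ev, quadrant = 1, gamma = 1e-11) {
  q <- array$quadrants[[quadrant]]
  if (!q$row_enabled[ev$row]) {
    state$dropped <- state$dropped + 1L
    return(state)
  }
  match_cols <- q$addresses[ev$row, ] == ev$label
  inc <- gamma * q$weights[ev$row, ] * (ev$payload / 31) * match_cols
  if (q$row_sign[ev$row] > 0) {
    state$I_exc <- state$I_exc + inc
  } else {
    state$I_inh <- state$I_inh + inc
  }
  state
}

#' Decay synaptic currents analytically
#'
#' Multiplies each current by `exp(-dt / tau)` — the exact solution of the
#' exponential kernel, with no integration error.
#'
#' @param state a [synaptic_state()].
#' @param dt elapsed time (s), positive (0 allowed, a no-op).
#' @return The decayed `synaptic_state`.
#' @export
decay_currents <- function(state, dt) {
  stopifnot(dt >= 0)
  state$I_exc <- state$I_exc * exp(-dt / state$tau_exc)
  state$I_inh <- state$I_inh * exp(-dt / state$tau_inh)
  state
}

# internal: encode an analog vector in [0,1] as 5-bit graded payloads
encode_payload <- function(x) round(x * 31) / 31

#' Analog matrix-vector multiply (MAC mode)
#'
#' Emulates the non-spiking multiply-accumulate mode: inputs are encoded as
#' graded spikes (5-bit payloads), each signed weight occupies an
#' excitatory/inhibitory row pair, integrator-mode neurons (all feature
#' switches off) accumulate the synaptic charges, and the membrane
#' deflection is read out by the 8-bit columnar ADC.
#'
#' Output is reported in product units (`W %*% x` scale).  With
#' `quantize = FALSE` the path is ideal — continuous payloads, no readout
#' quantization — and returns the exact product.  With `quantize = TRUE`
#' payloads are rounded to 31 levels and the readout is quantized to 256
#' levels over `[-range, range]`; a single full-weight, full-payload event
#' deflects the integrator by 1/64 of the readout range, i.e.
#' `range = 64 * 63` product units.
#'
#' @param weights signed integer matrix (m x n, entries in -63..63);
#'   `n <= 128` signed inputs (each consumes one excitatory and one
#'   inhibitory row of the 256), `m <= 512` neuron columns.  Larger shapes
#'   go through [mac_tiled()].
#' @param x input vector in `[0, 1]^n`.
#' @param quantize apply payload and 8-bit readout quantization.
#' @param noise_sd optional additive Gaussian readout noise (product units).
#' @param range readout dynamic range (product units).
#' @return Numeric output vector of length m; when quantized, the LSB is
#'   attached as attribute `"lsb"`.
#' @export
mac_forward <- function(weights, x, quantize = TRUE, noise_sd = 0,
                        range = 64 * 63) {
  weights <- as.matrix(weights)
  if (any(x < 0 | x > 1)) stop("inputs x must lie in [0, 1]")
  if (any(weights < -63 | weights > 63) || any(weights != round(weights)))
    stop("weights must be integers in [-63, 63]")
  if (ncol(weights) > 128)
    stop("at most 128 signed inputs per pass; use mac_tiled()")
  if (nrow(weights) > 512)
    stop("at most 512 neuron columns per pass; use mac_tiled()")
  xq <- if (quantize) encode_payload(x) else x
  # signed weights via excitatory/inhibitory row pairs
  w_exc <- pmax(weights, 0)
  w_inh <- pmax(-weights, 0)
  v <- as.numeric(w_exc %*% xq) - as.numeric(w_inh %*% xq)
  if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
  if (quantize) {
    lsb <- 2 * range / 256
    v <- pmin(pmax(v, -range), range)
    v <- round(v / lsb) * lsb
    attr(v, "lsb") <- lsb
  }
  v
}

#' Tiled analog matrix-vector multiply
#'
#' Splits an arbitrarily shaped weight matrix into hardware-sized blocks
#' (at most 128 signed input rows by 512 columns), executes [mac_forward()]
#' per block, and accumulates the partial results digitally at full
#' precision.
#'
#' @inheritParams mac_forward
#' @return Numeric output vector of length `nrow(weights)`.
#' @export
mac_tiled <- function(weights, x, quantize = TRUE, noise_sd = 0,
                      range = 64 * 63) {
  weights <- as.matrix(weights)
  m <- nrow(weights); n <- ncol(weights)
  out <- numeric(m)
  row_blocks <- split(seq_len(m), ceiling(seq_len(m) / 512))
  col_blocks <- split(seq_len(n), ceiling(seq_len(n) / 128))
  for (rb in row_blocks) {
    acc <- numeric(length(rb))
    for (cb in col_blocks) {
      part <- mac_forward(weights[rb, cb, drop = FALSE], x[cb],
                          quantize = quantize, noise_sd = noise_sd,
                          range = range)
      acc <- acc + as.numeric(part)
    }
    out[rb] <- acc
  }
  out
}
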