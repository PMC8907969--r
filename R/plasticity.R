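#' Per-synapse correlation sensor array
#'
#' Each synapse carries two analog accumulators measuring exponentially
#' weighted pre/post spike-pair coincidences: `c_causal` accumulates
#' `eta_plus * exp(-(t_post - t_pre)/tau_plus)` on every postsynaptic spike
#' (nearest preceding presynaptic spike), and `c_acausal` symmetrically
#' accumulates `eta_plus * exp(-(t_pre - t_post)/tau_minus)` on every
#' presynaptic spike — the STDP observable read out row-parallel by the
#' CADC.
#'
#' @param rows,cols sensor array shape (one sensor per synapse).
#' @param eta_plus increment scale (arbitrary analog units).
#' @param tau_plus,tau_minus causal / anti-causal pairing time constants (s).
#' @param reset_on_read zero the accumulators after a CADC read.
#' @return An object of class `correlation_sensors`.
#' @export
correlation_sensors <- function(rows = 256, cols = 128, eta_plus = 1,
                                tau_plus = 10e-6, tau_minus = 10e-6,
                                reset_on_read = FALSE) {
  structure(list(c_causal = matrix(0, rows, cols),
                 c_acausal = matrix(0, rows, cols),
                 eta_plus = eta_plus, tau_plus = tau_plus,
                 tau_minus = tau_minus, reset_on_read = reset_on_read),
            class = "correlation_sensors")
}

#' Accumulate pair-wise spike correlations for one synapse
#'
#' Event-driven and exact: for each postsynaptic spike the causal
#' accumulator gains `eta_plus * exp(-dt / tau_plus)` where `dt` is the lag
#' to the nearest preceding presynaptic spike, and symmetrically for the
#' anti-causal accumulator on presynaptic spikes.  Pairings with no
#' preceding partner contribute nothing.
#'
#' @param sensors a [correlation_sensors()].
#' @param row,col synapse coordinates.
#' @param pre_times,post_times non-decreasing spike-time vectors (s).
#' @return The updated `correlation_sensors`.
#' @export
update_correlation <- function(sensors, row, col, pre_times, post_times) {
  stopifnot(!is.unsorted(pre_times), !is.unsorted(post_times))
  acc <- pair_accumulate(pre_times, post_times,
                         sensors$eta_plus, sensors$tau_plus, sensors$tau_minus)
  sensors$c_causal[row, col] <- sensors$c_causal[row, col] + acc$causal
  sensors$c_acausal[row, col] <- sensors$c_acausal[row, col] + acc$acausal
  sensors
}

# internal: nearest-preceding-spike pair sums (closed-form event arithmetic)
pair_accumulate <- function(pre, post, eta, tau_p, tau_m) {
  causal <- 0
  for (tp in post) {
    prev <- pre[pre <= tp]
    if (length(prev))
      causal <- causal + eta * exp(-(tp - prev[length(prev)]) / tau_p)
  }
  acausal <- 0
  for (tq in pre) {
    prev <- post[post <= tq]
    if (length(prev))
      acausal <- acausal + eta * exp(-(tq - prev[length(prev)]) / tau_m)
  }
  list(causal = causal, acausal = acausal)
}

#' Row-parallel quantized readout (CADC model)
#'
#' Maps analog values linearly to 8-bit codes in 0..255 with saturation at
#' the range edges, modelling the columnar ADC that digitizes one crossbar
#' row (256 channels) in parallel.  Optionally zeroes the read accumulators
#' afterwards (the sensors' reset-on-read mode).
#'
#' @param values numeric vector of analog values (one row).
#' @param v_min,v_max analog range mapped to codes 0 and 255.
#' @return Integer codes in 0..255.  If `values` came from a sensor array
#'   use [cadc_read_row()] to also apply reset-on-read.
#' @export
cadc_quantize <- function(values, v_min = 0, v_max = 1) {
  code <- round((values - v_min) / (v_max - v_min) * 255)
  as.integer(pmin(pmax(code, 0), 255))
}

#' De-quantize CADC codes back to analog values
#'
#' @param codes integer codes 0..255.
#' @inheritParams cadc_quantize
#' @return Numeric analog estimates (mid-rise reconstruction).
#' @export
cadc_dequantize <- function(codes, v_min = 0, v_max = 1) {
  v_min + codes / 255 * (v_max - v_min)
}

#' Read one sensor row through the CADC
#'
#' @param sensors a [correlation_sensors()].
#' @param row row index.
#' @param which `"causal"` or `"acausal"` accumulator bank.
#' @param v_min,v_max analog range of the converter.
#' @param reset zero the row's accumulators after the read (overrides the
#'   array's `reset_on_read` default if given).
#' @return A list with `codes` (integers 0..255) and the updated `sensors`.
#' @export
cadc_read_row <- function(sensors, row, which = c("causal", "acausal"),
                          v_min = 0, v_max = 1, reset = NULL) {
  which <- match.arg(which)
  if (is.null(reset)) reset <- sensors$reset_on_read
  bank <- if (which == "causal") sensors$c_causal else sensors$c_acausal
  codes <- cadc_quantize(bank[row, ], v_min, v_max)
  if (reset) {
    if (which == "causal") sensors$c_causal[row, ] <- 0
    else sensors$c_acausal[row, ] <- 0
  }
  list(codes = codes, sensors = sensors)
}

#' Plasticity rule
#'
#' A programmable rule executed periodically with row-parallel views, the
#' abstract semantics of the embedded plasticity processor: every `period`
#' the callback receives a consistent snapshot and returns new weights.
#'
#' @param period invocation period (s).
#' @param callback `function(view)` where `view` is a list with `time`,
#'   `weights` (rows x cols integer matrix), `addresses`, `corr_causal`,
#'   `corr_acausal` (CADC codes), and `rates` (per-column firing rates, Hz,
#'   when available).  Must return the full new weight matrix (clipped and
#'   rounded to the 6-bit range on application).
#' @return An object of class `plasticity_rule`.
#' @export
plasticity_rule <- function(period, callback) {
  stopifnot(is.function(callback), period > 0)
  structure(list(period = period, callback = callback),
            class = "plasticity_rule")
}

#' Run a plasticity schedule over a synaptic array
#'
#' Invokes the rule every `period` on a consistent snapshot of the weights
#' and correlation sensors, applies the returned weight writes (rounded and
#' clipped to 0..63, out-of-range writes counted), and keeps a full audit
#' log of every change.  Between invocations the scheduled pre/post spike
#' streams are fed into the correlation sensors event-by-event, so the rule
#' can never observe future events.
#'
#' @param weights integer weight matrix (rows x cols, 0..63).
#' @param addresses integer address matrix (defaults to zeros).
#' @param rule a [plasticity_rule()].
#' @param duration total schedule duration (s).
#' @param sensors a [correlation_sensors()] matching `weights`, or `NULL`.
#' @param pre_spikes data frame `time`, `row`: presynaptic events per row.
#' @param post_spikes data frame `time`, `col`: postsynaptic events per
#'   column (paired against every synapse of that column).
#' @param cadc_range analog range for the correlation CADC reads.
#' @return A list with `weights` (final), `log` (data frame `time`, `row`,
#'   `col`, `old`, `new`), `clipped` (count of out-of-range writes) and
#'   `sensors`.
#' @export
run_plasticity_schedule <- function(weights, rule, duration,
                                    addresses = NULL, sensors = NULL,
                                    pre_spikes = NULL, post_spikes = NULL,
                                    cadc_range = c(0, 10)) {
  stopifnot(inherits(rule, "plasticity_rule"), duration > 0)
  w <- weights
  if (is.null(addresses)) addresses <- matrix(0L, nrow(w), ncol(w))
  have_sensors <- !is.null(sensors)
  log <- list()
  clipped <- 0L
  n_periods <- floor(duration / rule$period + 1e-9)
  t_prev <- 0
  for (k in seq_len(n_periods)) {
    t_now <- k * rule$period
    if (have_sensors && !is.null(pre_spikes) && !is.null(post_spikes)) {
      # feed this period's events into the sensors (per affected synapse)
      pre_k <- pre_spikes[pre_spikes$time > t_prev & pre_spikes$time <= t_now, ]
      post_k <- post_spikes[post_spikes$time > t_prev & post_spikes$time <= t_now, ]
      rows <- unique(pre_k$row)
      for (r in rows) {
        pr <- sort(pre_k$time[pre_k$row == r])
        for (cl in seq_len(ncol(w))) {
          po <- sort(post_k$time[post_k$col == cl])
          if (length(po) || length(pr))
            sensors <- update_correlation(sensors, r, cl, pr, po)
        }
      }
    }
    corr_c <- corr_a <- NULL
    if (have_sensors) {
      corr_c <- t(vapply(seq_len(nrow(w)), function(r)
        cadc_quantize(sensors$c_causal[r, ], cadc_range[1], cadc_range[2]),
        integer(ncol(w))))
      corr_a <- t(vapply(seq_len(nrow(w)), function(r)
        cadc_quantize(sensors$c_acausal[r, ], cadc_range[1], cadc_range[2]),
        integer(ncol(w))))
    }
    view <- list(time = t_now, weights = w, addresses = addresses,
                 corr_causal = corr_c, corr_acausal = corr_a, rates = NULL)
    new_w <- rule$callback(view)
    stopifnot(identical(dim(new_w), dim(w)))
    new_w <- round(new_w)
    oob <- new_w < 0 | new_w > 63
    clipped <- clipped + sum(oob & new_w != w)
    new_w <- pmin(pmax(new_w, 0), 63)
    changed <- which(new_w != w, arr.ind = TRUE)
    if (nrow(changed))
      log[[length(log) + 1]] <- data.frame(
        time = t_now, row = changed[, 1], col = changed[, 2],
        old = w[changed], new = new_w[changed])
    w <- new_w
    t_prev <- t_now
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(time = numeric(0), row = integer(0), col = integer(0),
               old = integer(0), new = integer(0))
  list(weights = w, log = log, clipped = clipped, sensors = sensors)
}

#' Replay a weight audit log
#'
#' Reconstructs the final weight matrix from an initial state and the audit
#' log produced by [run_plasticity_schedule()].
#'
#' @param weights initial weight matrix.
#' @param log audit log data frame (`time`, `row`, `col`, `old`, `new`).
#' @return The reconstructed weight matrix.
#' @export
replay_weight_log <- function(weights, log) {
  if (nrow(log)) {
    o <- order(log$time)
    for (k in o) weights[log$row[k], log$col[k]] <- log$new[k]
  }
  weights
}

#' Homeostatic rate-control weight update
#'
#' Integer proportional control toward a target rate:
#' `dw_i = clip(round(lambda_h * (nu_target - nu_i) / nu_target),
#' -delta_max..delta_max)`.  A silent neuron receives the maximal positive
#' step `+lambda_h` (clipped); a neuron on target receives zero.
#'
#' @param rates per-neuron firing rates (Hz) over the preceding period.
#' @param nu_target target rate (Hz), positive.
#' @param lambda_h integer proportional gain.
#' @param delta_max clip magnitude for a single update.
#' @return Integer weight deltas, one per neuron.
#' @export
homeostatic_update <- function(rates, nu_target, lambda_h = 1L,
                               delta_max = 2L) {
  stopifnot(nu_target > 0)
  dw <- round(lambda_h * (nu_target - rates) / nu_target)
  as.integer(pmin(pmax(dw, -delta_max), delta_max))
}
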