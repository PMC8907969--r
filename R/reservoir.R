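#' Recurrent reservoir network with homeostatic regulation
#'
#' A desk-scale recurrent LIF network in the accelerated (hardware) time
#' domain: `N` neurons (80/20 excitatory/inhibitory), all-to-all recurrent
#' connectivity with 6-bit integer weights, and `n_sources` external Poisson
#' sources of which each neuron receives `K_ext` — the input strength that
#' controls the network's dynamical regime.  Homeostatic regulation (see
#' [homeostatic_update()]) acts on all excitatory afferents of each neuron,
#' external and recurrent alike: with weak external drive (low `K_ext`) the
#' input synapses saturate and the missing drive is built up by recurrence,
#' moving the collective dynamics toward criticality and long
#' autocorrelation times; with strong drive the input weights are trimmed
#' and recurrence stays weak.
#'
#' Membrane dynamics are in normalized units (leak level 0, threshold 1).
#' `kappa` converts one integer weight unit into membrane drive.
#'
#' @param N number of neurons.
#' @param K_ext external input connections per neuron (1..`n_sources`).
#' @param n_sources number of external Poisson sources.
#' @param frac_exc fraction of excitatory neurons.
#' @param w0_exc,w_inh initial excitatory / fixed inhibitory integer weight
#'   (0..63).
#' @param w_ext integer weight of external input synapses.
#' @param kappa membrane drive per integer weight unit (threshold units).
#' @param tau_m,tau_s,t_ref membrane / synaptic / refractory time constants
#'   (s, hardware domain).
#' @param nu_target homeostatic target rate (Hz, hardware domain).
#' @param nu_ext rate of each external source (Hz) at full drive.
#' @param seed RNG seed for the input wiring.
#' @return An object of class `reservoir_network`.
#' @export
reservoir_network <- function(N = 32, K_ext = 8, n_sources = 32,
                              frac_exc = 0.8, w0_exc = 10L, w_inh = 30L,
                              w_ext = 32L, kappa = 0.02,
                              tau_m = 20e-6, tau_s = 5e-6, t_ref = 2e-6,
                              nu_target = 20e3, nu_ext = 25e3, seed = 1) {
  stopifnot(N >= 1, K_ext >= 1, K_ext <= n_sources)
  n_exc <- round(frac_exc * N)
  is_exc <- c(rep(TRUE, n_exc), rep(FALSE, N - n_exc))
  W_int <- matrix(w0_exc, N, N)
  W_int[, !is_exc] <- w_inh
  diag(W_int) <- 0L
  set.seed(seed)
  ext_map <- matrix(FALSE, N, n_sources)
  for (i in seq_len(N))
    ext_map[i, sample.int(n_sources, K_ext)] <- TRUE
  W_ext_int <- matrix(0L, N, n_sources)
  W_ext_int[ext_map] <- as.integer(w_ext)
  structure(list(N = N, K_ext = K_ext, n_sources = n_sources,
                 is_exc = is_exc, W_int = W_int, ext_map = ext_map,
                 W_ext_int = W_ext_int, kappa = kappa,
                 tau_m = tau_m, tau_s = tau_s, t_ref = t_ref,
                 nu_target = nu_target, nu_ext = nu_ext,
                 v = rep(0, N), isyn = rep(0, N)),
            class = "reservoir_network")
}

#' @export
print.reservoir_network <- function(x, ...) {
  cat(sprintf(
    "reservoir_network: N = %d (%d exc / %d inh), K_ext = %d of %d sources\n",
    x$N, sum(x$is_exc), sum(!x$is_exc), x$K_ext, x$n_sources))
  invisible(x)
}

# internal: signed weight matrices in membrane-drive units
reservoir_weights <- function(net) {
  sign_col <- ifelse(net$is_exc, 1, -1)
  W <- net$kappa * sweep(net$W_int, 2, sign_col, `*`)
  Wext <- net$kappa * net$W_ext_int
  list(W = W, Wext = Wext)
}

#' Run a reservoir under continuous homeostatic regulation
#'
#' Simulates the network in chunks of `period`; after each chunk the
#' per-neuron rates are measured and [homeostatic_update()] deltas are
#' applied to the excitatory recurrent afferent weights (integer arithmetic,
#' clipped to 0..63).  External sources fire as independent Poisson
#' processes, optionally rate-modulated per chunk via `drive`.
#'
#' @param net a [reservoir_network()].
#' @param n_updates number of homeostatic update periods to run.
#' @param period update period (s).
#' @param dt integration step (s).
#' @param drive optional function `(chunk_index) -> [0, 1]^n_sources`
#'   multiplying each source's rate for that chunk (default: all ones).
#' @param lambda_h,delta_max homeostatic gain and per-update clip.
#' @param homeostasis apply the homeostatic updates (TRUE) or freeze the
#'   weights (FALSE).
#' @param homeo_every apply the update every this many chunks (rates are
#'   then averaged over the elapsed chunks); keeps the regulation slower
#'   than a fast stimulus schedule.
#' @param record_spikes keep the full spike list (memory heavy for long
#'   runs).
#' @param seed RNG seed for the Poisson input.
#' @return A list with the updated `net`, `rates` (matrix: update x
#'   neuron), `counts` per update, and optionally `spikes` (data frame
#'   `time`, `id`, global time).
#' @export
run_reservoir <- function(net, n_updates = 100, period = 250e-6, dt = 1e-7,
                          drive = NULL, lambda_h = 1L, delta_max = 2L,
                          homeostasis = TRUE, homeo_every = 1L,
                          record_spikes = FALSE, seed = 1) {
  set.seed(seed)
  N <- net$N
  rates <- matrix(0, n_updates, N)
  spikes <- if (record_spikes) vector("list", n_updates) else NULL
  exc_cols <- which(net$is_exc)
  for (k in seq_len(n_updates)) {
    wm <- reservoir_weights(net)
    mod <- if (is.null(drive)) rep(1, net$n_sources) else drive(k)
    ev <- poisson_events(net$nu_ext * mod, period)
    res <- .lif_net_run(wm$W, wm$Wext, ev$time, ev$src - 1L,
                        net$tau_m, net$tau_s, 1.0, 0.0, net$t_ref,
                        dt, period, net$v, net$isyn)
    net$v <- res$v_final
    net$isyn <- res$i_final
    rates[k, ] <- res$counts / period
    if (record_spikes && length(res$spike_time))
      spikes[[k]] <- data.frame(time = res$spike_time + (k - 1) * period,
                                id = res$spike_id)
    if (homeostasis && k %% homeo_every == 0) {
      r_avg <- colMeans(rates[seq(k - homeo_every + 1, k), , drop = FALSE])
      dw <- homeostatic_update(r_avg, net$nu_target, lambda_h, delta_max)
      for (i in seq_len(N)) {
        pre <- setdiff(exc_cols, i)
        net$W_int[i, pre] <- pmin(pmax(net$W_int[i, pre] + dw[i], 0L), 63L)
        src <- which(net$ext_map[i, ])
        net$W_ext_int[i, src] <-
          pmin(pmax(net$W_ext_int[i, src] + dw[i], 0L), 63L)
      }
    }
  }
  out <- list(net = net, rates = rates)
  if (record_spikes)
    out$spikes <- if (length(sp <- Filter(Negate(is.null), spikes)))
      do.call(rbind, sp) else data.frame(time = numeric(0), id = integer(0))
  out
}

#' Switch the input strength of a running reservoir
#'
#' Rewires the external input map to `K_ext` connections per neuron while
#' keeping membrane state, synaptic state and recurrent weights — the
#' protocol used to show that the collective time scale follows `K_ext`
#' under continuous homeostasis irrespective of the initial condition.
#' Newly wired synapses start from the current mean input weight.
#'
#' @param net a [reservoir_network()].
#' @param K_ext new input count per neuron.
#' @param seed RNG seed for the rewiring.
#' @return The rewired network.
#' @export
switch_K_ext <- function(net, K_ext, seed = 1) {
  stopifnot(K_ext >= 1, K_ext <= net$n_sources)
  set.seed(seed)
  w_start <- max(1L, as.integer(round(mean(net$W_ext_int[net$ext_map]))))
  ext_map <- matrix(FALSE, net$N, net$n_sources)
  W_ext_int <- matrix(0L, net$N, net$n_sources)
  for (i in seq_len(net$N)) {
    src <- sample.int(net$n_sources, K_ext)
    ext_map[i, src] <- TRUE
    old <- net$ext_map[i, ] & ext_map[i, ]
    W_ext_int[i, src] <- w_start
    W_ext_int[i, old] <- net$W_ext_int[i, old]
  }
  net$ext_map <- ext_map
  net$W_ext_int <- W_ext_int
  net$K_ext <- as.integer(K_ext)
  net
}

# internal: independent Poisson event streams for the external sources
poisson_events <- function(rates, T) {
  ts <- list(); src <- list()
  for (m in seq_along(rates)) {
    n <- stats::rpois(1, rates[m] * T)
    if (n > 0) {
      ts[[length(ts) + 1]] <- sort(stats::runif(n, 0, T))
      src[[length(src) + 1]] <- rep(m, n)
    }
  }
  if (!length(ts)) return(list(time = numeric(0), src = integer(0)))
  tt <- unlist(ts); ss <- unlist(src)
  o <- order(tt)
  list(time = tt[o], src = as.integer(ss[o]))
}

#' Estimate the autocorrelation time of a population-activity series
#'
#' Computes the empirical autocorrelation function of the binned population
#' rate and fits an exponential decay `r_k = A * exp(-k * bin / tau)` to the
#' initial positive lags by log-linear least squares.  A non-decaying or
#' immediately negative ACF is flagged unreliable; a memoryless series
#' yields `tau_ac` below the bin width.
#'
#' @param series numeric vector: population activity per bin.
#' @param bin bin width (s).
#' @param max_lag largest lag (bins) considered.
#' @return A list with `tau_ac` (s), `reliable` (logical), `acf` (the lag
#'   1..`max_lag` autocorrelations) and `n_lags_used`.
#' @export
estimate_autocorrelation_time <- function(series, bin, max_lag = 200) {
  stopifnot(length(series) > 10)
  max_lag <- min(max_lag, length(series) - 2)
  r <- stats::acf(series, lag.max = max_lag, plot = FALSE,
                  demean = TRUE)$acf[-1]
  if (r[1] <= 0)
    return(list(tau_ac = bin / -log(1e-3), reliable = FALSE, acf = r,
                n_lags_used = 0L))
  # fit over the first ~2 decay times (r > e^-2): later lags carry
  # correlated finite-sample noise that biases the log-linear fit
  stop_at <- which(r < 0.135)[1]
  L <- if (is.na(stop_at)) length(r) else max(stop_at - 1, 1)
  k <- seq_len(L)
  if (L >= 2) {
    fit <- stats::lm(log(r[k]) ~ k)
    slope <- stats::coef(fit)[["k"]]
    if (slope >= 0)
      return(list(tau_ac = max(r[1], 0) * Inf, reliable = FALSE, acf = r,
                  n_lags_used = L))
    tau <- -bin / slope
  } else {
    tau <- -bin / log(r[1])
  }
  list(tau_ac = tau, reliable = TRUE, acf = r, n_lags_used = as.integer(L))
}

#' Reservoir experiment description
#'
#' @param N neurons; `K_ext` external inputs per neuron; `nu_target`
#'   homeostatic target rate (Hz, hardware domain); `task` one of
#'   `"n_bit_parity"`, `"n_bit_sum"`; `n` memory depth (bits).
#' @param N,K_ext,nu_target,task,n see above.
#' @return An object of class `reservoir_experiment`.
#' @export
reservoir_experiment <- function(N = 32, K_ext = 8, nu_target = 20e3,
                                 task = c("n_bit_parity", "n_bit_sum"),
                                 n = 1) {
  task <- match.arg(task)
  stopifnot(N >= 1, K_ext >= 1, n >= 1)
  structure(list(N = N, K_ext = K_ext, nu_target = nu_target,
                 task = task, n = n),
            class = "reservoir_experiment")
}

#' Run a reservoir computing task
#'
#' Drives the homeostatically regulated reservoir with a random binary
#' input stream (each bit modulates the external source rates for one bit
#' period), reads out low-pass-filtered spike counts at each bit boundary,
#' and trains a ridge-regression readout on the memory task (`n`-bit parity
#' or `n`-bit sum of the most recent bits) with an 80/20 train/test split.
#' A degenerate all-silent reservoir is flagged and scored at chance.
#'
#' @param exp a [reservoir_experiment()].
#' @param seed RNG seed (wiring, input stream, Poisson draws).
#' @param n_bits length of the binary input stream.
#' @param bit_period presentation time per bit (s).
#' @param warmup_updates homeostatic warm-up updates before the stream.
#' @param filter_tau readout low-pass filter time constant (s).
#' @param ridge_lambda ridge penalty of the linear readout.
#' @param dt integration step (s).
#' @param off_drive source-rate multiplier for a 0 bit (1 bits use 1).
#' @return A list with `accuracy`, `chance`, `flagged`, `n`, `K_ext`.
#' @export
run_reservoir_task <- function(exp, seed = 1, n_bits = 400,
                               bit_period = 60e-6, warmup_updates = 150,
                               filter_tau = 30e-6, ridge_lambda = 1.0,
                               dt = 1e-7, off_drive = 0.2) {
  stopifnot(inherits(exp, "reservoir_experiment"))
  net <- reservoir_network(N = exp$N, K_ext = exp$K_ext,
                           nu_target = exp$nu_target, seed = seed)
  warm <- run_reservoir(net, n_updates = warmup_updates, seed = seed + 1)
  net <- warm$net

  set.seed(seed + 2)
  bits <- stats::rbinom(n_bits, 1, 0.5)
  drive <- function(k) rep(ifelse(bits[k] == 1, 1, off_drive), net$n_sources)
  homeo_every <- max(1L, round(250e-6 / bit_period))
  run <- run_reservoir(net, n_updates = n_bits, period = bit_period,
                       dt = dt, drive = drive, homeostasis = TRUE,
                       homeo_every = homeo_every,
                       record_spikes = TRUE, seed = seed + 3)
  sp <- run$spikes
  if (nrow(sp) == 0)
    return(list(accuracy = 0.5, chance = 0.5, flagged = TRUE,
                n = exp$n, K_ext = exp$K_ext))

  # low-pass filtered spike counts per neuron, sampled at mid-bit and at
  # the bit boundary (two snapshots capture the within-bit transient)
  feats <- matrix(0, n_bits, 2 * net$N)
  trace <- rep(0, net$N)
  t_prev <- 0
  sp <- sp[order(sp$time), ]
  idx <- 1L
  sample_at <- function(t_s) {
    while (idx <= nrow(sp) && sp$time[idx] <= t_s) {
      trace <<- trace * exp(-(sp$time[idx] - t_prev) / filter_tau)
      trace[sp$id[idx]] <<- trace[sp$id[idx]] + 1
      t_prev <<- sp$time[idx]
      idx <<- idx + 1L
    }
    out <- trace * exp(-(t_s - t_prev) / filter_tau)
    trace <<- out
    t_prev <<- t_s
    out
  }
  for (k in seq_len(n_bits)) {
    feats[k, seq_len(net$N)] <- sample_at((k - 0.5) * bit_period)
    feats[k, net$N + seq_len(net$N)] <- sample_at(k * bit_period)
  }

  target <- task_target(bits, exp$task, exp$n)
  keep <- seq(exp$n, n_bits)   # targets defined once n bits are available
  X <- feats[keep, , drop = FALSE]
  y <- target[keep]
  n_tr <- floor(0.8 * length(y))
  tr <- seq_len(n_tr); te <- seq(n_tr + 1, length(y))
  acc <- ridge_readout_accuracy(X[tr, , drop = FALSE], y[tr],
                                X[te, , drop = FALSE], y[te], ridge_lambda)
  chance <- max(table(y[te])) / length(te)
  list(accuracy = acc, chance = as.numeric(chance), flagged = FALSE,
       n = exp$n, K_ext = exp$K_ext)
}

# internal: memory-task targets from the bit stream
task_target <- function(bits, task, n) {
  m <- length(bits)
  out <- rep(NA_integer_, m)
  for (k in seq(n, m)) {
    win <- bits[(k - n + 1):k]
    out[k] <- if (task == "n_bit_parity") sum(win) %% 2 else sum(win)
  }
  out
}

# internal: ridge readout (one-vs-rest on indicator targets) and accuracy
ridge_readout_accuracy <- function(Xtr, ytr, Xte, yte, lambda) {
  classes <- sort(unique(ytr))
  if (length(classes) < 2) return(mean(yte == classes[1]))
  keep_col <- apply(Xtr, 2, stats::sd) > 0
  if (!any(keep_col)) return(max(table(yte)) / length(yte))
  Xtr <- Xtr[, keep_col, drop = FALSE]
  Xte <- Xte[, keep_col, drop = FALSE]
  scores <- matrix(0, nrow(Xte), length(classes))
  for (ci in seq_along(classes)) {
    yi <- as.numeric(ytr == classes[ci])
    fit <- MASS::lm.ridge(yi ~ Xtr, lambda = lambda)
    co <- stats::coef(fit)
    scores[, ci] <- co[1] + Xte %*% co[-1]
  }
  pred <- classes[max.col(scores)]
  mean(pred == yte)
}

#' Autocorrelation time as a function of input strength
#'
#' Warm-up under homeostasis, then a measurement run whose binned population
#' activity yields the autocorrelation time `tau_ac` — the experiment that
#' demonstrates control of the collective time scale by `K_ext`.
#'
#' @param K_ext input strength.
#' @param seed RNG seed.
#' @param N network size.
#' @param warmup_updates homeostatic warm-up updates.
#' @param measure_T measurement duration (s); homeostasis stays active.
#' @param bin activity bin width (s).
#' @param net optional pre-warmed [reservoir_network()] to continue from
#'   (then `warmup_updates` is still applied first).
#' @return A list with `tau_ac` (s), `reliable`, `rate` (mean rate, Hz) and
#'   the final `net`.
#' @export
measure_tau_ac <- function(K_ext, seed = 1, N = 32, warmup_updates = 200,
                           measure_T = 20e-3, bin = 5e-6, net = NULL) {
  if (is.null(net))
    net <- reservoir_network(N = N, K_ext = K_ext, seed = seed)
  warm <- run_reservoir(net, n_updates = warmup_updates, seed = seed + 10)
  net <- warm$net
  n_upd <- ceiling(measure_T / 250e-6)
  run <- run_reservoir(net, n_updates = n_upd, period = 250e-6,
                       record_spikes = TRUE, seed = seed + 20)
  sp <- run$spikes
  if (nrow(sp) < 50)
    return(list(tau_ac = NA_real_, reliable = FALSE, rate = 0, net = run$net))
  T_tot <- n_upd * 250e-6
  series <- tabulate(pmin(floor(sp$time / bin) + 1, ceiling(T_tot / bin)),
                     nbins = ceiling(T_tot / bin))
  est <- estimate_autocorrelation_time(series, bin)
  list(tau_ac = est$tau_ac, reliable = est$reliable,
       rate = nrow(sp) / T_tot / net$N, net = run$net)
}
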