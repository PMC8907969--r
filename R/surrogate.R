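#' Discrete-time LIF network for surrogate-gradient training
#'
#' A feed-forward spiking network modelled as a recurrent computation graph
#' at the CADC sampling period: hidden LIF units with decay factors
#' `alpha = exp(-dt/tau_m)` and `beta = exp(-dt/tau_s)`, multiplicative
#' reset, and non-spiking leaky-integrator readout units.  The graph
#' mirrors the trace-based training scheme: its forward state can be
#' overwritten by externally sampled (quantized) membrane traces so that
#' gradients are computed along the measured dynamics.
#'
#' @param n_in,n_hidden,n_out layer sizes.
#' @param dt sampling period (s), default the CADC period 1.7 us.
#' @param tau_m,tau_s membrane / synaptic time constants (s).
#' @param v_th hidden threshold (normalized units).
#' @param beta_s surrogate sharpness; the surrogate derivative is
#'   `1 / (1 + beta_s * |v - v_th|)^2` (SuperSpike form).
#' @param seed RNG seed for the weight initialisation.
#' @return An object of class `surrogate_net` with weights `W1`
#'   (`n_in x n_hidden`) and `W2` (`n_hidden x n_out`).
#' @export
surrogate_net <- function(n_in, n_hidden = 32, n_out = 2, dt = 1.7e-6,
                          tau_m = 10e-6, tau_s = 5e-6, v_th = 1,
                          beta_s = 10, seed = 1) {
  set.seed(seed)
  structure(list(
    n_in = n_in, n_hidden = n_hidden, n_out = n_out, dt = dt,
    alpha = exp(-dt / tau_m), beta = exp(-dt / tau_s),
    v_th = v_th, beta_s = beta_s,
    W1 = matrix(stats::rnorm(n_in * n_hidden, 0, 2 / sqrt(n_in)),
                n_in, n_hidden),
    W2 = matrix(stats::rnorm(n_hidden * n_out, 0, 1 / sqrt(n_hidden)),
                n_hidden, n_out)),
    class = "surrogate_net")
}

#' Forward pass of the discrete LIF graph
#'
#' @param net a [surrogate_net()].
#' @param X spike raster array `(T, batch, n_in)` of 0/1 inputs.
#' @param quantize_traces emulate 8-bit digitization of the hidden membrane
#'   traces over `trace_range` (the measured-trace path).
#' @param trace_range analog range of the trace ADC.
#' @return A list with `V_h`, `S_h`, `I_h` (arrays `(T, batch, n_hidden)`),
#'   `V_o` (`(T, batch, n_out)`), `y` (max-over-time readout, `(batch,
#'   n_out)`) and `argmax_t`.
#' @export
surrogate_forward <- function(net, X, quantize_traces = FALSE,
                              trace_range = c(-2, 3)) {
  Tn <- dim(X)[1]; B <- dim(X)[2]
  nh <- net$n_hidden; no <- net$n_out
  V_h <- array(0, c(Tn, B, nh)); S_h <- array(0, c(Tn, B, nh))
  I_h <- array(0, c(Tn, B, nh)); V_o <- array(0, c(Tn, B, no))
  vh <- matrix(0, B, nh); ih <- matrix(0, B, nh); sh <- matrix(0, B, nh)
  vo <- matrix(0, B, no); io <- matrix(0, B, no)
  for (t in seq_len(Tn)) {
    xt <- matrix(X[t, , ], B, net$n_in)
    ih <- net$beta * ih + xt %*% net$W1
    vh <- net$alpha * vh * (1 - sh) + (1 - net$alpha) * ih
    if (quantize_traces) {
      code <- pmin(pmax(round((vh - trace_range[1]) /
                                diff(trace_range) * 255), 0), 255)
      vh <- trace_range[1] + code / 255 * diff(trace_range)
    }
    sh <- (vh >= net$v_th) * 1
    io <- net$beta * io + sh %*% net$W2
    vo <- net$alpha * vo + (1 - net$alpha) * io
    V_h[t, , ] <- vh; S_h[t, , ] <- sh; I_h[t, , ] <- ih; V_o[t, , ] <- vo
  }
  y <- apply(V_o, c(2, 3), max)
  argmax_t <- apply(V_o, c(2, 3), which.max)
  list(V_h = V_h, S_h = S_h, I_h = I_h, V_o = V_o, y = y,
       argmax_t = argmax_t)
}

# internal: softmax cross-entropy and its gradient on the readout
softmax_xent <- function(y, labels) {
  B <- nrow(y)
  z <- y - apply(y, 1, max)
  p <- exp(z) / rowSums(exp(z))
  idx <- cbind(seq_len(B), labels)
  onehot <- matrix(0, B, ncol(y))
  onehot[idx] <- 1
  list(value = -mean(log(pmax(p[idx], 1e-12))),
       grad = (p - onehot) / B, p = p)
}

#' Backpropagation through the trace-aligned LIF graph
#'
#' Computes `dL/dW1`, `dL/dW2` by backpropagation through time with the
#' SuperSpike surrogate derivative at the hidden thresholds.  The forward
#' state is taken from `traces` and `spikes` (measured, possibly 8-bit
#' quantized, membrane samples and the emitted spikes), so the computation
#' graph is aligned with the observed dynamics rather than an idealized
#' simulation; gradients pass straight through the trace quantization.
#' The loss is softmax cross-entropy on the max-over-time readout, plus an
#' optional activity (sparsity) penalty `rho * mean(S_h)`.
#'
#' @param net a [surrogate_net()].
#' @param X input spike raster `(T, batch, n_in)`.
#' @param traces measured hidden membrane array `(T, batch, n_hidden)`.
#' @param spikes hidden spike array `(T, batch, n_hidden)` of 0/1.
#' @param labels integer class labels (1-based, length batch).
#' @param rho sparsity-penalty weight.
#' @return A list with `gW1`, `gW2`, `loss`, `accuracy`.
#' @export
surrogate_backward <- function(net, X, traces, spikes, labels, rho = 0) {
  Tn <- dim(X)[1]; B <- dim(X)[2]
  nh <- net$n_hidden; no <- net$n_out
  stopifnot(all(dim(traces) == c(Tn, B, nh)),
            all(dim(spikes) == c(Tn, B, nh)))
  # rebuild the readout along the measured hidden spikes
  V_o <- array(0, c(Tn, B, no))
  io <- matrix(0, B, no); vo <- matrix(0, B, no)
  for (t in seq_len(Tn)) {
    io <- net$beta * io + matrix(spikes[t, , ], B, nh) %*% net$W2
    vo <- net$alpha * vo + (1 - net$alpha) * io
    V_o[t, , ] <- vo
  }
  y <- apply(V_o, c(2, 3), max)
  argmax_t <- apply(V_o, c(2, 3), which.max)
  ce <- softmax_xent(y, labels)
  loss <- ce$value + rho * mean(spikes)
  acc <- mean(max.col(y) == labels)

  gW1 <- matrix(0, net$n_in, nh); gW2 <- matrix(0, nh, no)
  lam_vo <- matrix(0, B, no); lam_io <- matrix(0, B, no)
  lam_ih <- matrix(0, B, nh)
  lam_vh_next <- matrix(0, B, nh)
  g_sp <- rho / (Tn * B * nh)
  for (t in rev(seq_len(Tn))) {
    direct <- ce$grad * (argmax_t == t)       # max routes to its argmax step
    lam_vo <- net$alpha * lam_vo + direct
    lam_io <- net$beta * lam_io + (1 - net$alpha) * lam_vo
    sh_t <- matrix(spikes[t, , ], B, nh)
    vh_t <- matrix(traces[t, , ], B, nh)
    gW2 <- gW2 + t(sh_t) %*% lam_io
    # spike gradient: readout drive, next-step reset, sparsity penalty
    lam_sh <- lam_io %*% t(net$W2) + g_sp
    if (t < Tn)                                # V_h[t] feeds the t+1 reset
      lam_sh <- lam_sh - net$alpha * vh_t * lam_vh_next
    surr <- 1 / (1 + net$beta_s * abs(vh_t - net$v_th))^2
    lam_vh_new <- lam_sh * surr
    if (t < Tn)
      lam_vh_new <- lam_vh_new + net$alpha * (1 - sh_t) * lam_vh_next
    lam_vh_next <- lam_vh_new
    lam_ih <- net$beta * lam_ih + (1 - net$alpha) * lam_vh_new
    gW1 <- gW1 + t(matrix(X[t, , ], B, net$n_in)) %*% lam_ih
  }
  list(gW1 = gW1, gW2 = gW2, loss = loss, accuracy = acc)
}

#' Train a surrogate-gradient network on a latency-encoded task
#'
#' Emulates the in-the-loop training scheme: the forward pass runs on the
#' emulated substrate (the discrete graph, with 8-bit quantized membrane
#' samples at the CADC period), the sampled traces and spikes feed
#' [surrogate_backward()], and the weights are updated with Adam.
#'
#' @param images list of latency-encoded samples (see
#'   [generate_latency_dataset()]).
#' @param net a [surrogate_net()]; `n_in` must match the pixel count.
#' @param epochs training epochs (full-batch).
#' @param lr Adam learning rate.
#' @param rho sparsity-penalty weight.
#' @param t_max latency-encoding horizon (s).
#' @param quantize_traces sample traces through the 8-bit converter.
#' @param target_accuracy optional early-stop threshold on training
#'   accuracy.
#' @return A list with the trained `net`, `accuracy` (final training
#'   accuracy), `history` (per-epoch accuracy) and `epochs_run`.
#' @export
train_surrogate <- function(images, net, epochs = 200, lr = 5e-3, rho = 0,
                            t_max = 30e-6, quantize_traces = TRUE,
                            target_accuracy = NULL) {
  enc <- latency_raster(images, dt = net$dt, t_max = t_max)
  X <- enc$X; labels <- enc$labels
  mW1 <- vW1 <- matrix(0, nrow(net$W1), ncol(net$W1))
  mW2 <- vW2 <- matrix(0, nrow(net$W2), ncol(net$W2))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  hist <- numeric(0)
  for (ep in seq_len(epochs)) {
    fwd <- surrogate_forward(net, X, quantize_traces = quantize_traces)
    bk <- surrogate_backward(net, X, fwd$V_h, fwd$S_h, labels, rho = rho)
    hist <- c(hist, bk$accuracy)
    if (!is.null(target_accuracy) && bk$accuracy >= target_accuracy) break
    mW1 <- b1 * mW1 + (1 - b1) * bk$gW1
    vW1 <- b2 * vW1 + (1 - b2) * bk$gW1^2
    mW2 <- b1 * mW2 + (1 - b1) * bk$gW2
    vW2 <- b2 * vW2 + (1 - b2) * bk$gW2^2
    c1 <- 1 - b1^ep; c2 <- 1 - b2^ep
    net$W1 <- net$W1 - lr * (mW1 / c1) / (sqrt(vW1 / c2) + eps)
    net$W2 <- net$W2 - lr * (mW2 / c1) / (sqrt(vW2 / c2) + eps)
  }
  list(net = net, accuracy = hist[length(hist)], history = hist,
       epochs_run = length(hist))
}

#' Convert latency-encoded images to a spike raster
#'
#' One spike per active pixel at `t = t_max * (1 - intensity)`; pixels
#' below `threshold` stay silent.
#'
#' @param images list with elements `pixels` (vector in `[0, 1]`) and
#'   `label`.
#' @param dt raster time step (s).
#' @param t_max encoding horizon (s).
#' @param threshold intensity below which a pixel is silent.
#' @return A list with `X` (array `(T, batch, n_pixels)`) and `labels`.
#' @export
latency_raster <- function(images, dt = 1.7e-6, t_max = 30e-6,
                           threshold = 0.05) {
  B <- length(images)
  npx <- length(images[[1]]$pixels)
  Tn <- ceiling(t_max / dt) + 1
  X <- array(0, c(Tn, B, npx))
  labels <- integer(B)
  for (b in seq_len(B)) {
    px <- images[[b]]$pixels
    labels[b] <- images[[b]]$label
    active <- which(px >= threshold)
    tk <- pmin(floor(t_max * (1 - px[active]) / dt) + 1, Tn)
    for (j in seq_along(active)) X[tk[j], b, active[j]] <- 1
  }
  list(X = X, labels = labels)
}
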