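#' Fixed-pattern noise model for analog neuron instances
#'
#' Static per-circuit parameter deviations from manufacturing.  Analog
#' magnitude parameters (`g_l`, `tau_w`, `a`, `b`, `Delta_T`) receive
#' independent multiplicative log-normal distortions with coefficient of
#' variation `cv`; potentials (`E_l`, the threshold pair `V_T`/`V_th` as one
#' offset, `V_r`) receive independent additive Gaussian offsets with
#' standard deviation `voltage_sd`.  Digitally configured parameters
#' (`C_m`, `t_r`) carry no fixed-pattern noise.
#'
#' @param cv multiplicative coefficient of variation (dimensionless, >= 0).
#' @param voltage_sd additive offset scale for potentials (V); defaults to
#'   `cv * 50 mV`.
#' @return An object of class `fpn_model`.
#' @export
fixed_pattern_noise <- function(cv = 0.10, voltage_sd = NULL) {
  stopifnot(cv >= 0)
  if (is.null(voltage_sd)) voltage_sd <- cv * 50e-3
  structure(list(cv = cv, voltage_sd = voltage_sd), class = "fpn_model")
}

# bias-code transfer curves: monotone logistic-saturating, unity/zero at the
# mid code 512, 10-bit resolution
code_gain <- function(code, log_range = log(2), slope = 160) {
  z <- (code - 512) / slope
  exp(log_range * (2 / (1 + exp(-z)) - 1))
}
code_offset <- function(code, v_max = 40e-3, slope = 160) {
  z <- (code - 512) / slope
  v_max * (2 / (1 + exp(-z)) - 1)
}

# which bias code controls which parameter
CODE_NAMES <- c("gl", "tauw", "leak", "threshold", "reset", "refractory",
                "b_incr", "a_cond", "dT")

#' Sample a cohort of analog neuron instances
#'
#' Draws `n` instances around a nominal parameter set with hidden
#' fixed-pattern distortions; deterministic under `seed`.  The distortion
#' factors are hidden from calibration — they can only be probed through
#' [measure_observable()].
#'
#' @param nominal an [adex_params()] object (hardware domain).
#' @param noise a [fixed_pattern_noise()] model.
#' @param n cohort size.
#' @param seed RNG seed.
#' @return A list of `analog_instance` objects.
#' @export
sample_cohort <- function(nominal, noise, n, seed = 1) {
  stopifnot(inherits(noise, "fpn_model"), n >= 1)
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise$cv^2))
  lapply(seq_len(n), function(i) {
    dist <- list(
      g_l = stats::rlnorm(1, -sdlog^2 / 2, sdlog),
      tau_w = stats::rlnorm(1, -sdlog^2 / 2, sdlog),
      a = stats::rlnorm(1, -sdlog^2 / 2, sdlog),
      b = stats::rlnorm(1, -sdlog^2 / 2, sdlog),
      Delta_T = stats::rlnorm(1, -sdlog^2 / 2, sdlog),
      off_El = stats::rnorm(1, 0, noise$voltage_sd),
      off_thr = stats::rnorm(1, 0, noise$voltage_sd),
      off_Vr = stats::rnorm(1, 0, noise$voltage_sd))
    codes <- stats::setNames(rep(512L, length(CODE_NAMES)), CODE_NAMES)
    structure(list(nominal = nominal, .distortion = dist, codes = codes),
              class = "analog_instance")
  })
}

#' @export
print.analog_instance <- function(x, ...) {
  cat("analog_instance (distortions hidden); bias codes:\n")
  print(x$codes)
  invisible(x)
}

# internal: effective parameters = nominal x distortion x bias-code transfer.
# The only place the hidden distortions are read; everything above this goes
# through measured observables.
effective_params <- function(inst) {
  p <- inst$nominal
  d <- inst$.distortion
  cd <- inst$codes
  p$g_l <- p$g_l * d$g_l * code_gain(cd[["gl"]])
  p$tau_w <- p$tau_w * d$tau_w * code_gain(cd[["tauw"]])
  p$a <- p$a * d$a * code_gain(cd[["a_cond"]])
  p$b <- p$b * d$b * code_gain(cd[["b_incr"]])
  p$Delta_T <- p$Delta_T * d$Delta_T * code_gain(cd[["dT"]])
  p$E_l <- p$E_l + d$off_El + code_offset(cd[["leak"]])
  thr_shift <- d$off_thr + code_offset(cd[["threshold"]])
  p$V_T <- p$V_T + thr_shift
  p$V_th <- p$V_th + thr_shift
  p$V_r <- p$V_r + d$off_Vr + code_offset(cd[["reset"]])
  p$t_r <- p$t_r * code_gain(cd[["refractory"]])
  p$I_exp_max <- 50 * p$g_l * p$Delta_T
  p
}

#' Run a step-protocol on an analog instance
#'
#' Convenience wrapper: simulates the instance's effective dynamics (with
#' its current bias codes) under a [stim_protocol()].
#'
#' @param inst an `analog_instance`.
#' @param protocol a [stim_protocol()].
#' @param dt integration step (s).
#' @return As [run_neuron()].
#' @export
run_instance <- function(inst, protocol, dt = 1e-7) {
  run_neuron(effective_params(inst), protocol, dt = dt)
}

#' Measure one observable of an analog instance
#'
#' Minimal characterization experiments, each probing one observable at a
#' time through simulated traces or spike counts (never the hidden
#' distortion factors):
#' \describe{
#'   \item{tau_m}{LIF configuration, subthreshold current step; log-linear
#'     fit to the charging curve.}
#'   \item{tau_w}{adaptation enabled, subthreshold step; log-linear fit to
#'     the decay of `w` after stimulus offset.}
#'   \item{leak_potential}{no stimulus; mean resting potential.}
#'   \item{threshold}{LIF with threshold, suprathreshold step; maximum
#'     membrane value before reset.}
#'   \item{reset}{same protocol; mean potential during the refractory
#'     clamp.}
#'   \item{refractory}{strong drive; inter-spike interval minus the
#'     charging time predicted from the measured threshold/reset/tau_m.}
#'   \item{adaptation_b}{jump of the adaptation trace at a spike.}
#'   \item{adaptation_a}{steady-state adaptation current over membrane
#'     deflection under a subthreshold step.}
#'   \item{rheobase}{minimal step current eliciting a spike (pins the
#'     exponential slope once leak and threshold are calibrated).}
#'   \item{rate_at_I}{spike count per second at a probe current.}
#' }
#'
#' @param inst an `analog_instance`.
#' @param target one of the observable ids above.
#' @param I_probe probe current (A) for `rate_at_I`.
#' @param dt integration step (s).
#' @return The measured value (s, V or Hz); `NA` with attribute
#'   `"flag" = "unmeasurable"` when the protocol yields no signal.
#' @export
measure_observable <- function(inst, target = c("tau_m", "tau_w",
                                                "leak_potential", "threshold",
                                                "reset", "refractory",
                                                "adaptation_b",
                                                "adaptation_a", "rheobase",
                                                "rate_at_I"),
                               I_probe = NULL, dt = 1e-7) {
  target <- match.arg(target)
  p <- effective_params(inst)
  lif <- p
  lif$enable_exp <- FALSE; lif$enable_adapt <- FALSE
  lif$enable_leak <- TRUE

  if (target == "leak_potential") {
    lif$enable_threshold <- FALSE
    res <- run_neuron(lif, stim_protocol(0, 10e-6, 20e-6, 50e-6), dt = dt)
    return(mean(res$V[res$time > 25e-6]))
  }
  if (target == "tau_m") {
    lif$enable_threshold <- FALSE
    prot <- stim_protocol(2e-10, 20e-6, 120e-6, 120e-6)
    res <- run_neuron(lif, prot, dt = dt)
    sel <- res$time > prot$t_on + dt & res$time < prot$t_on + 60e-6
    v_inf <- res$V[length(res$V)]
    dv <- v_inf - res$V[sel]
    ok <- dv > 1e-5
    if (sum(ok) < 10) return(structure(NA_real_, flag = "unmeasurable"))
    fit <- stats::lm(log(dv[ok]) ~ res$time[sel][ok])
    return(-1 / stats::coef(fit)[[2]])
  }
  if (target == "tau_w") {
    pw <- p
    pw$enable_exp <- FALSE; pw$enable_threshold <- FALSE
    pw$enable_adapt <- TRUE
    prot <- stim_protocol(2e-10, 10e-6, 60e-6, 500e-6)
    res <- run_neuron(pw, prot, dt = dt)
    sel <- res$time > prot$t_off + 20e-6
    w <- res$w[sel]
    ok <- abs(w) > max(abs(w)) * 1e-3
    if (sum(ok) < 10) return(structure(NA_real_, flag = "unmeasurable"))
    fit <- stats::lm(log(abs(w[ok])) ~ res$time[sel][ok])
    return(-1 / stats::coef(fit)[[2]])
  }
  if (target == "threshold") {
    # probe with the reset bias at its low end so the reset potential sits
    # safely below any probed threshold; otherwise a probe configuration
    # with V_r > V_th degenerates the spike train and the measurement
    # stops tracking the threshold
    safe <- inst
    safe$codes[["reset"]] <- 0L
    lif <- effective_params(safe)
    lif$enable_exp <- FALSE; lif$enable_adapt <- FALSE
    lif$enable_threshold <- TRUE
    I_str <- 2 * lif$g_l * max(lif$V_th - lif$E_l + 10e-3, 10e-3)
    prot <- stim_protocol(I_str, 5e-6, 200e-6, 200e-6)
    res <- run_neuron(lif, prot, dt = dt)
    if (length(res$spikes) < 3)
      return(structure(NA_real_, flag = "unmeasurable"))
    return(max(res$V))
  }
  if (target == "reset") {
    lif$enable_threshold <- TRUE
    # moderate drive: keeps the pre-threshold slope (and hence the sampling
    # bias of the peak) small while still eliciting a regular spike train
    I_str <- 2 * lif$g_l * max(lif$V_th - lif$E_l + 10e-3, 10e-3)
    prot <- stim_protocol(I_str, 5e-6, 200e-6, 200e-6)
    res <- run_neuron(lif, prot, dt = dt)
    if (length(res$spikes) < 3)
      return(structure(NA_real_, flag = "unmeasurable"))
    s1 <- res$spikes[1]
    sel <- res$time > s1 + dt & res$time < s1 + 0.8 * lif$t_r
    if (!any(sel)) return(structure(NA_real_, flag = "unmeasurable"))
    return(mean(res$V[sel]))
  }
  if (target == "refractory") {
    # two-drive extrapolation: ISI = t_r + t_charge and the charging time is
    # ~inversely proportional to the drive, so t_r ~ 2 ISI(2I) - ISI(I);
    # uses only measured spike trains, never hidden parameters
    lif$enable_threshold <- TRUE
    I1 <- 20 * lif$g_l * (lif$V_th - lif$E_l + 10e-3)
    isi <- vapply(c(I1, 2 * I1), function(I) {
      res <- run_neuron(lif, stim_protocol(I, 5e-6, 200e-6, 200e-6), dt = dt)
      if (length(res$spikes) < 5) return(NA_real_)
      mean(diff(res$spikes))
    }, numeric(1))
    if (anyNA(isi)) return(structure(NA_real_, flag = "unmeasurable"))
    return(2 * isi[2] - isi[1])
  }
  if (target == "rheobase") {
    # minimal step current eliciting a spike, by bisection over the drive;
    # with leak/threshold already calibrated this pins the exponential slope
    fires <- function(I) {
      res <- run_neuron(p, stim_protocol(I, 10e-6, 160e-6, 160e-6), dt = dt)
      length(res$spikes) > 0
    }
    I_hi <- 4 * p$g_l * max(p$V_th - p$E_l, 10e-3)
    if (!fires(I_hi)) return(structure(NA_real_, flag = "unmeasurable"))
    I_lo <- 0
    for (k in 1:12) {
      mid <- (I_lo + I_hi) / 2
      if (fires(mid)) I_hi <- mid else I_lo <- mid
    }
    return((I_lo + I_hi) / 2)
  }
  if (target == "adaptation_b") {
    # spike-triggered increment: jump of the adaptation trace at a spike
    pb <- p
    pb$enable_exp <- FALSE; pb$enable_adapt <- TRUE
    pb$enable_threshold <- TRUE
    I_str <- 2 * pb$g_l * max(pb$V_th - pb$E_l + 10e-3, 10e-3) +
      2 * abs(pb$b)
    res <- run_neuron(pb, stim_protocol(I_str, 5e-6, 200e-6, 200e-6),
                      dt = dt)
    if (length(res$spikes) < 1)
      return(structure(NA_real_, flag = "unmeasurable"))
    k <- findInterval(res$spikes[1], res$time)
    return(res$w[k + 1] - res$w[k])
  }
  if (target == "adaptation_a") {
    # subthreshold conductance: steady-state w over membrane deflection
    pa <- p
    pa$enable_exp <- FALSE; pa$enable_adapt <- TRUE
    pa$enable_threshold <- FALSE
    T_ss <- max(6 * pa$tau_w, 200e-6)
    prot <- stim_protocol(1e-10, 50e-6, 50e-6 + T_ss, 50e-6 + T_ss)
    res <- run_neuron(pa, prot, dt = dt)
    v_base <- mean(res$V[res$time < 45e-6])
    nT <- length(res$time)
    v_ss <- mean(res$V[seq(nT - 100, nT)])
    w_ss <- mean(res$w[seq(nT - 100, nT)])
    if (abs(v_ss - v_base) < 1e-4)
      return(structure(NA_real_, flag = "unmeasurable"))
    return(w_ss / (v_ss - v_base))
  }
  # rate_at_I
  if (is.null(I_probe)) I_probe <- 2 * p$g_l * (p$V_th - p$E_l)
  prot <- stim_protocol(I_probe, 0, 400e-6, 400e-6)
  res <- run_neuron(p, prot, dt = dt)
  if (length(res$spikes) == 0)
    return(structure(0, flag = "silent"))
  length(res$spikes) / prot$t_off
}

# observable -> controlling bias code
TARGET_CODE <- c(tau_m = "gl", tau_w = "tauw", leak_potential = "leak",
                 threshold = "threshold", reset = "reset",
                 refractory = "refractory",
                 adaptation_b = "b_incr", adaptation_a = "a_cond",
                 rheobase = "dT")

#' Calibration target
#'
#' @param observable one of `"tau_m"`, `"tau_w"`, `"leak_potential"`,
#'   `"threshold"`, `"reset"`, `"refractory"`, `"rate_at_I"`.
#' @param value target value (s, V or Hz).
#' @param tolerance absolute tolerance, positive.
#' @return An object of class `calibration_target`.
#' @export
calibration_target <- function(observable, value, tolerance) {
  stopifnot(tolerance > 0, observable %in% names(TARGET_CODE) ||
              observable == "rate_at_I")
  structure(list(observable = observable, value = value,
                 tolerance = tolerance),
            class = "calibration_target")
}

#' Calibrate an analog instance toward a set of observable targets
#'
#' Iterative measurement-based calibration: per target, a bisection search
#' on the controlling 10-bit bias code (the transfer curves are monotone)
#' until the measured observable is within tolerance or the code interval
#' is exhausted.  Because the observables are weakly coupled (e.g. the
#' adaptation decay fit shifts with the calibrated leak), the whole target
#' list is swept `passes` times; later passes start near the solution and
#' converge in a few measurements.  Measurement-only: the hidden
#' distortions are never read.
#'
#' @param inst an `analog_instance`.
#' @param targets list of [calibration_target()]s.
#' @param max_iter iteration cap per target and pass.
#' @param passes sweeps over the target list.
#' @param dt measurement integration step (s).
#' @return A list with the calibrated `inst`, `report` (data frame of the
#'   final pass: observable, code, measured, residual, iterations,
#'   converged) and `converged` (all targets within tolerance).
#' @export
calibrate_instance <- function(inst, targets, max_iter = 14, passes = 2,
                               dt = 1e-7) {
  rows <- list()
  for (tg in rep(targets, passes)) {
    code_name <- TARGET_CODE[[tg$observable]]
    measure <- function(code) {
      probe <- inst
      probe$codes[[code_name]] <- as.integer(round(code))
      measure_observable(probe, tg$observable, dt = dt)
    }
    m0 <- measure(inst$codes[[code_name]])
    iter <- 1L
    if (!is.na(m0) && abs(m0 - tg$value) <= tg$tolerance) {
      best_code <- inst$codes[[code_name]]; best_m <- m0
    } else {
      lo <- 0; hi <- 1023
      m_lo <- measure(lo); m_hi <- measure(hi)
      iter <- iter + 2L
      increasing <- isTRUE(m_hi > m_lo)
      best_code <- inst$codes[[code_name]]; best_m <- m0
      while (hi - lo > 1 && iter < max_iter + 3L) {
        mid <- floor((lo + hi) / 2)
        m <- measure(mid)
        iter <- iter + 1L
        if (is.na(m)) break
        if (is.na(best_m) || abs(m - tg$value) < abs(best_m - tg$value)) {
          best_m <- m; best_code <- mid
        }
        if (abs(m - tg$value) <= tg$tolerance) break
        if ((m < tg$value) == increasing) lo <- mid else hi <- mid
      }
    }
    inst$codes[[code_name]] <- as.integer(best_code)
    rows[[length(rows) + 1]] <- data.frame(
      observable = tg$observable, code = as.integer(best_code),
      measured = best_m, residual = best_m - tg$value,
      iterations = iter,
      converged = !is.na(best_m) && abs(best_m - tg$value) <= tg$tolerance)
  }
  report <- do.call(rbind, rows)
  # keep the final pass per observable
  report <- report[!duplicated(report$observable, fromLast = TRUE), ]
  rownames(report) <- NULL
  list(inst = inst, report = report, converged = all(report$converged))
}

#' Default calibration targets for a parameter set
#'
#' Builds the standard target list (tau_m, tau_w, leak, threshold, reset)
#' from the observables of a nominal parameter set.
#'
#' @param params the nominal [adex_params()] (hardware domain).
#' @param rel_tol relative tolerance for time constants.
#' @param v_tol absolute tolerance for potentials (V).
#' @return A list of [calibration_target()]s.
#' @export
default_targets <- function(params, rel_tol = 0.02, v_tol = 0.25e-3) {
  # target values are the observables MEASURED on a distortion-free
  # reference instance of the nominal set, so that any systematic bias of
  # an estimator (e.g. the adaptation coupling folded into the tau_w decay
  # fit) cancels between reference and device
  ref <- reference_instance(params)
  mk <- function(obs, tol) {
    v <- measure_observable(ref, obs)
    calibration_target(obs, as.numeric(v), tol(abs(as.numeric(v))))
  }
  tg <- list(mk("tau_m", function(v) rel_tol * v),
             mk("tau_w", function(v) 0.5 * rel_tol * v),
             mk("leak_potential", function(v) v_tol),
             mk("threshold", function(v) v_tol),
             mk("reset", function(v) v_tol))
  if (params$enable_adapt && params$b > 0)
    tg <- c(tg, list(mk("adaptation_b", function(v) rel_tol * v)))
  if (params$enable_adapt && params$a != 0)
    tg <- c(tg, list(mk("adaptation_a", function(v) rel_tol * v)))
  # rheobase is deliberately not targeted by default: its value aliases
  # sub-tolerance leak/threshold residuals into the exponential-slope code
  tg
}

# distortion-free instance of a nominal parameter set (all codes neutral)
reference_instance <- function(params) {
  dist <- list(g_l = 1, tau_w = 1, a = 1, b = 1, Delta_T = 1,
               off_El = 0, off_thr = 0, off_Vr = 0)
  codes <- stats::setNames(rep(512L, length(CODE_NAMES)), CODE_NAMES)
  structure(list(nominal = params, .distortion = dist, codes = codes),
            class = "analog_instance")
}

#' Calibrate a cohort and summarise the before/after spread
#'
#' Samples a cohort from the fixed-pattern noise model and calibrates each
#' instance toward the targets.  The "before" characterization uses the
#' uncalibrated common setting — every bias code set to the median of the
#' calibrated codes across the cohort — and the "after" characterization
#' uses each instance's own calibrated codes; the narrowing of the
#' per-observable distributions quantifies what calibration buys.
#'
#' @param nominal nominal [adex_params()] (hardware domain).
#' @param n cohort size.
#' @param cv fixed-pattern noise CV.
#' @param targets target list; defaults to [default_targets()] of
#'   `nominal`.
#' @param seed RNG seed.
#' @param dt measurement step (s).
#' @return A list with `instances` (calibrated), `pre`, `post` (matrices of
#'   measured observables), `iqr_ratio` (post/pre IQR per observable) and
#'   `converged` (per instance).
#' @export
calibrate_cohort <- function(nominal, n = 128, cv = 0.10, targets = NULL,
                             seed = 1, dt = 1e-7) {
  if (is.null(targets)) targets <- default_targets(nominal)
  cohort <- sample_cohort(nominal, fixed_pattern_noise(cv), n, seed = seed)
  obs <- vapply(targets, function(t) t$observable, character(1))
  pre <- matrix(NA_real_, n, length(obs), dimnames = list(NULL, obs))
  post <- pre
  converged <- logical(n)
  for (i in seq_len(n)) {
    cal <- calibrate_instance(cohort[[i]], targets, dt = dt)
    cohort[[i]] <- cal$inst
    converged[i] <- cal$converged
    for (j in seq_along(obs))
      post[i, j] <- measure_observable(cohort[[i]], obs[j], dt = dt)
  }
  codes <- do.call(rbind, lapply(cohort, `[[`, "codes"))
  median_codes <- as.integer(round(apply(codes, 2, stats::median)))
  names(median_codes) <- colnames(codes)
  for (i in seq_len(n)) {
    common <- cohort[[i]]
    common$codes <- median_codes
    for (j in seq_along(obs))
      pre[i, j] <- measure_observable(common, obs[j], dt = dt)
  }
  iqr_ratio <- vapply(seq_along(obs), function(j) {
    pr <- stats::IQR(pre[, j], na.rm = TRUE)
    po <- stats::IQR(post[, j], na.rm = TRUE)
    if (pr == 0) NA_real_ else po / pr
  }, numeric(1))
  names(iqr_ratio) <- obs
  list(instances = cohort, pre = pre, post = post,
       iqr_ratio = iqr_ratio, converged = converged)
}
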