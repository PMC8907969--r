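#' Run a named experiment from a configuration
#'
#' Dispatches to one of the built-in experiment drivers, seeds every source
#' of randomness from the configuration, and (optionally) writes a results
#' JSON with provenance (configuration hash, seed, package version).
#'
#' Available experiments: `firing-patterns` (regime grid under the step
#' protocol), `chain` (EPSP attenuation along a passive chain),
#' `coincidence` (plateau-spike coincidence detection), `criticality`
#' (autocorrelation time vs input strength), `mac` (analog matrix-multiply
#' fidelity), `calibrate-cohort` (fixed-pattern-noise calibration),
#' `train-surrogate` (latency-task training) and `gradcheck` (adjoint
#' vs finite-difference oracle table).
#'
#' @param config path to a YAML configuration file, or an equivalent named
#'   list with at least `experiment:`; further keys override driver
#'   defaults.
#' @param seed overrides `config$seed`.
#' @param out_dir optional output directory for `results.json`.
#' @return The results list (invisibly also written to `out_dir`).
#' @export
run_experiment <- function(config, seed = NULL, out_dir = NULL) {
  if (is.character(config)) {
    cfg_hash <- unname(tools::md5sum(config))
    config <- yaml::read_yaml(config)
  } else {
    tf <- tempfile(fileext = ".yaml")
    yaml::write_yaml(config, tf)
    cfg_hash <- unname(tools::md5sum(tf))
    unlink(tf)
  }
  if (!is.list(config) || is.null(config$experiment))
    stop("invalid configuration: missing key 'experiment'")
  if (!is.null(seed)) config$seed <- seed
  if (is.null(config$seed)) config$seed <- 1
  drivers <- list(
    "firing-patterns" = exp_firing_patterns,
    "chain" = exp_chain,
    "coincidence" = exp_coincidence,
    "criticality" = exp_criticality,
    "mac" = exp_mac,
    "calibrate-cohort" = exp_calibrate_cohort,
    "train-surrogate" = exp_train_surrogate,
    "gradcheck" = exp_gradcheck)
  if (!config$experiment %in% names(drivers))
    stop(sprintf("unknown experiment '%s'; offending key: experiment (one of %s)",
                 config$experiment, paste(names(drivers), collapse = ", ")))
  res <- drivers[[config$experiment]](config)
  res$provenance <- list(experiment = config$experiment,
                         config_md5 = cfg_hash, seed = config$seed,
                         package_version =
                           as.character(utils::packageVersion("analognet")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(res, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(res)
}

# default value helper
cfg_get <- function(config, key, default) {
  if (is.null(config[[key]])) default else config[[key]]
}

exp_firing_patterns <- function(config) {
  accel <- cfg_get(config, "acceleration", 1000)
  dt <- cfg_get(config, "dt", 1e-7)
  sets <- adex_pattern_sets()
  labels <- list()
  for (nm in names(sets)) {
    hw <- convert_biological_params(sets[[nm]]$params, accel)
    prot <- stim_protocol(sets[[nm]]$I_0)
    res <- run_neuron(hw, prot, dt = dt)
    labels[[nm]] <- list(label = classify_firing_pattern(res$spikes, prot),
                         n_spikes = length(res$spikes))
  }
  list(patterns = labels,
       distinct_labels = unique(vapply(labels, `[[`, character(1), "label")))
}

exp_chain <- function(config) {
  n <- cfg_get(config, "n_compartments", 4)
  g_ic <- cfg_get(config, "g_ic", 2e-8)
  out <- list()
  for (site in seq_len(n)) {
    graph <- passive_chain(n = n, g_ic = g_ic, inject_at = site)
    res <- simulate_compartments(graph, T = 120e-6)
    psp <- lapply(seq_len(n), function(j)
      measure_psp(res$time, res$V[, j], baseline_until = 15e-6))
    out[[paste0("inject_", site)]] <- list(
      amplitude = vapply(psp, `[[`, numeric(1), "amplitude"),
      fwhm = vapply(psp, `[[`, numeric(1), "fwhm"))
  }
  out
}

exp_coincidence <- function(config) {
  delays <- cfg_get(config, "delays", seq(0, 10e-6, by = 2e-6))
  graph <- branched_plateau_model()
  proximal <- c(1, 2)   # at / next to the initiation zone
  distal <- c(4, 6)     # far ends of trunk and second branch
  res <- list()
  for (d in delays) {
    res[[sprintf("delay_%g", d)]] <- list(
      proximal = coincidence_protocol(graph, proximal, d)$fired,
      distal = coincidence_protocol(graph, distal, d)$fired,
      distal_first = coincidence_protocol(graph, c(3, 1), d)$fired,
      proximal_first = coincidence_protocol(graph, c(1, 3), d)$fired)
  }
  list(delays = delays, results = res)
}

exp_criticality <- function(config) {
  grid <- cfg_get(config, "K_ext", c(4, 8, 16, 32))
  seeds <- config$seed + seq_len(cfg_get(config, "n_seeds", 5)) - 1
  N <- cfg_get(config, "N", 32)
  tau <- matrix(NA_real_, length(seeds), length(grid),
                dimnames = list(NULL, paste0("K", grid)))
  rate <- tau
  for (si in seq_along(seeds))
    for (ki in seq_along(grid)) {
      m <- measure_tau_ac(grid[ki], seed = seeds[si], N = N)
      tau[si, ki] <- m$tau_ac
      rate[si, ki] <- m$rate
    }
  list(K_ext = grid, tau_ac = tau, rates = rate,
       tau_median = apply(tau, 2, stats::median, na.rm = TRUE))
}

exp_mac <- function(config) {
  set.seed(config$seed)
  n <- cfg_get(config, "size", 64)
  W <- matrix(sample(-63:63, n * n, replace = TRUE), n, n)
  x <- stats::runif(n)
  ideal <- as.numeric(W %*% x)
  ideal_payload <- as.numeric(W %*% (round(x * 31) / 31))
  analog <- mac_forward(W, x, quantize = FALSE)
  quant <- mac_forward(W, x, quantize = TRUE)
  list(r_unquantized = stats::cor(analog, ideal),
       max_readout_err = max(abs(as.numeric(quant) - ideal_payload)),
       max_total_err = max(abs(as.numeric(quant) - ideal)),
       lsb = attr(quant, "lsb"))
}

exp_calibrate_cohort <- function(config) {
  n <- cfg_get(config, "n", 128)
  cv <- cfg_get(config, "cv", 0.10)
  sets <- adex_pattern_sets()
  regime <- cfg_get(config, "regime", "regular_bursting")
  nominal <- convert_biological_params(sets[[regime]]$params,
                                       cfg_get(config, "acceleration", 1000))
  cal <- calibrate_cohort(nominal, n = n, cv = cv, seed = config$seed)
  prot <- stim_protocol(sets[[regime]]$I_0)
  labels <- vapply(cal$instances, function(inst)
    classify_firing_pattern(run_instance(inst, prot)$spikes, prot),
    character(1))
  list(iqr_ratio = cal$iqr_ratio,
       n_converged = sum(cal$converged),
       labels = table(labels),
       n_regular_bursting = sum(labels == "regular_bursting"),
       n_instances = n)
}

exp_train_surrogate <- function(config) {
  seeds <- config$seed + seq_len(cfg_get(config, "n_seeds", 3)) - 1
  acc <- numeric(length(seeds))
  epochs <- integer(length(seeds))
  for (si in seq_along(seeds)) {
    imgs <- generate_latency_dataset(
      n_per_class = cfg_get(config, "n_per_class", 100),
      classes = 2, separation = 1, seed = seeds[si])
    net <- surrogate_net(n_in = 256,
                         n_hidden = cfg_get(config, "n_hidden", 32),
                         n_out = 2, seed = seeds[si])
    tr <- train_surrogate(imgs, net,
                          epochs = cfg_get(config, "epochs", 200),
                          target_accuracy = cfg_get(config, "target", 0.95))
    acc[si] <- tr$accuracy
    epochs[si] <- tr$epochs_run
  }
  list(seeds = seeds, accuracy = acc, epochs_run = epochs)
}

exp_gradcheck <- function(config) {
  tab <- gradcheck_suite(seed = config$seed,
                         tol = cfg_get(config, "tol", 1e-3))
  list(table = tab, all_pass = all(tab$pass))
}
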