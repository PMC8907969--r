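test_that("Poisson input generation is reproducible and statistically sound", {
  expect_equal(nrow(generate_poisson_inputs(0, 1e-3, seed = 1)), 0)
  e1 <- generate_poisson_inputs(c(1e4, 2e4), 1e-3, seed = 5)
  e2 <- generate_poisson_inputs(c(1e4, 2e4), 1e-3, seed = 5)
  expect_identical(e1, e2)
  expect_false(is.unsorted(e1$time_s))

  # counts within 4 sigma over 100 seeds; ISIs pass a KS test vs exponential
  rate <- 2e4; T <- 2e-3
  counts <- vapply(1:100, function(sd)
    nrow(generate_poisson_inputs(rate, T, seed = sd)), numeric(1))
  expect_lt(abs(mean(counts) - rate * T), 4 * sqrt(rate * T / 100))
  isis <- diff(generate_poisson_inputs(rate, 0.05, seed = 9)$time_s)
  ks <- stats::ks.test(isis, "pexp", rate)
  expect_gt(ks$p.value, 0.01)
})

test_that("latency datasets are separable exactly when they should be", {
  imgs <- generate_latency_dataset(n_per_class = 100, classes = 2,
                                   separation = 1, seed = 2)
  expect_gte(attr(imgs, "probe_accuracy"), 0.99)
  expect_true(all(vapply(imgs, function(s)
    sum(s$pixels >= 0.05) <= 256, logical(1))))

  # separation = 0: true labels are as uninformative as shuffled ones
  imgs0 <- generate_latency_dataset(n_per_class = 60, classes = 2,
                                    separation = 0, seed = 2, verify = FALSE)
  X <- t(vapply(imgs0, `[[`, numeric(256), "pixels"))
  y <- vapply(imgs0, `[[`, numeric(1), "label")
  half <- seq_len(60)
  acc_true <- analognet:::ridge_readout_accuracy(X[half, ], y[half],
                                                 X[-half, ], y[-half], 1)
  set.seed(3)
  acc_shuf <- analognet:::ridge_readout_accuracy(X[half, ], sample(y[half]),
                                                 X[-half, ], y[-half], 1)
  expect_lt(abs(acc_true - acc_shuf), 0.15)
  expect_lt(acc_true, 0.65)
})

test_that("parameter, trace, spike and event files round-trip", {
  tmp <- tempfile(fileext = ".cfg")
  p <- adex_params(a = -2e-9, b = 5e-11, domain = "biological")
  write_params(p, tmp)
  q <- read_params(tmp)
  expect_equal(unclass(q), unclass(p), tolerance = 1e-12)
  expect_identical(attr(q, "domain"), "biological")

  rb <- regular_bursting_hw()
  res <- run_neuron(rb$params, stim_protocol(rb$I_0))
  tf <- tempfile(fileext = ".csv")
  write_traces(res$time, res$V, res$w, tf)
  tr <- read_traces(tf)
  expect_named(tr, c("time_s", "neuron_id", "V", "w"))
  expect_equal(tr$V, res$V, tolerance = 1e-6)

  sf <- tempfile(fileext = ".csv")
  write_spikes(as.numeric(res$spikes), 1, sf)
  sp <- read_spikes(sf)
  expect_equal(sp$time_s, as.numeric(res$spikes), tolerance = 1e-9)

  ef <- tempfile(fileext = ".csv")
  ev <- data.frame(time_s = c(2e-6, 1e-6), row = c(1, 2), label = c(3, 4),
                   payload = c(31, 15))
  write_events(ev, ef)
  back <- read_events(ef)
  expect_false(is.unsorted(back$time_s))
  expect_equal(sort(back$label), c(3, 4))
})

test_that("experiments dispatch, validate config and reproduce exactly", {
  expect_error(run_experiment(list(seed = 1)), "experiment")
  expect_error(run_experiment(list(experiment = "nope")), "unknown")

  out1 <- tempfile(); out2 <- tempfile()
  r1 <- run_experiment(list(experiment = "mac", size = 16), seed = 3,
                       out_dir = out1)
  r2 <- run_experiment(list(experiment = "mac", size = 16), seed = 3,
                       out_dir = out2)
  expect_equal(r1$r_unquantized, r2$r_unquantized)
  j1 <- jsonlite::read_json(file.path(out1, "results.json"))
  j2 <- jsonlite::read_json(file.path(out2, "results.json"))
  expect_equal(j1, j2)   # identical config + seed: byte-identical results
  expect_identical(j1$provenance$seed, 3L)
  expect_true(nzchar(j1$provenance$config_md5))
})

test_that("the gradcheck driver reports an all-pass table", {
  r <- run_experiment(list(experiment = "gradcheck"), seed = 42)
  expect_true(r$all_pass)
  expect_equal(nrow(r$table), 6)
})
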