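#' Generate independent Poisson input spike trains
#'
#' Software stand-in for the on-chip Poisson sources: one homogeneous
#' Poisson process per source, reproducible under `seed`.
#'
#' @param rates per-source rates (Hz), non-negative.
#' @param T duration (s).
#' @param seed RNG seed.
#' @return A data frame with columns `time_s` and `source` (1-based),
#'   sorted by time.
#' @export
generate_poisson_inputs <- function(rates, T, seed = 1) {
  stopifnot(all(rates >= 0), T > 0)
  set.seed(seed)
  ev <- poisson_events(rates, T)
  data.frame(time_s = ev$time, source = ev$src)
}

#' Generate a synthetic latency-encoded image dataset
#'
#' Two or more classes of 16 x 16 intensity images built from distinct
#' random blob templates plus per-sample pixel noise; `separation` scales
#' the template contrast so that `separation >= 1` guarantees linear
#' separability of the raw pixels (verified at generation time with a
#' logistic probe when `verify = TRUE`).  Latency encoding: each pixel with
#' intensity above threshold spikes once at `t = t_max * (1 - intensity)`.
#'
#' @param n_per_class samples per class.
#' @param classes number of classes (k >= 2).
#' @param separation template contrast scale (0 = pure noise, classes
#'   indistinguishable).
#' @param seed RNG seed.
#' @param size image edge length (pixels).
#' @param noise_sd per-pixel noise standard deviation.
#' @param verify check linear separability for `separation >= 1`.
#' @return A list of samples, each `list(pixels, label, image)` with
#'   `pixels` in `[0, 1]`; attribute `"templates"` holds the class
#'   templates.
#' @export
generate_latency_dataset <- function(n_per_class = 100, classes = 2,
                                     separation = 1, seed = 1, size = 16,
                                     noise_sd = 0.05, verify = TRUE) {
  stopifnot(classes >= 2, separation >= 0)
  set.seed(seed)
  npx <- size * size
  # distinct random blob templates: a few Gaussian bumps per class
  templates <- lapply(seq_len(classes), function(k) {
    tpl <- matrix(0, size, size)
    for (bump in 1:3) {
      cx <- stats::runif(1, 3, size - 2); cy <- stats::runif(1, 3, size - 2)
      s <- stats::runif(1, 1.5, 3)
      g <- outer(seq_len(size), seq_len(size), function(i, j)
        exp(-((i - cx)^2 + (j - cy)^2) / (2 * s^2)))
      tpl <- tpl + g
    }
    tpl / max(tpl)
  })
  samples <- list()
  for (k in seq_len(classes)) {
    for (s in seq_len(n_per_class)) {
      img <- separation * 0.5 * templates[[k]] +
        matrix(stats::rnorm(npx, 0.25, noise_sd), size, size)
      img <- pmin(pmax(img, 0), 1)
      samples[[length(samples) + 1]] <-
        list(pixels = as.numeric(img), label = k, image = img)
    }
  }
  samples <- samples[sample.int(length(samples))]
  if (verify && separation >= 1) {
    X <- t(vapply(samples, `[[`, numeric(npx), "pixels"))
    y <- vapply(samples, `[[`, numeric(1), "label")
    acc <- linear_probe_accuracy(X, y)
    if (acc < 0.99)
      warning(sprintf(
        "latency dataset linear probe reached only %.1f%% accuracy", 100 * acc))
    attr(samples, "probe_accuracy") <- acc
  }
  attr(samples, "templates") <- templates
  samples
}

# internal: ridge-based linear probe (train = test; construction check)
linear_probe_accuracy <- function(X, y) {
  classes <- sort(unique(y))
  keep <- apply(X, 2, stats::sd) > 0
  X <- X[, keep, drop = FALSE]
  scores <- matrix(0, nrow(X), length(classes))
  for (ci in seq_along(classes)) {
    yi <- as.numeric(y == classes[ci])
    fit <- MASS::lm.ridge(yi ~ X, lambda = 1e-3)
    co <- stats::coef(fit)
    scores[, ci] <- co[1] + X %*% co[-1]
  }
  mean(classes[max.col(scores)] == y)
}
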