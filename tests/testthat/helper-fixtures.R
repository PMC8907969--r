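# shared fixtures: small parameter sets in the hardware time domain

lif_hw_params <- function(...) {
  adex_params(enable_exp = FALSE, enable_adapt = FALSE, ...)
}

regular_bursting_hw <- function() {
  s <- adex_pattern_sets()$regular_bursting
  list(params = convert_biological_params(s$params), I_0 = s$I_0)
}

# tiny random synapse array (one quadrant) for crossbar tests
small_array <- function(rows = 8, cols = 6, seed = 1) {
  set.seed(seed)
  synapse_array(rows = rows, cols = cols, quadrants = 1,
                weights = matrix(sample(0:63, rows * cols, TRUE), rows, cols),
                addresses = matrix(sample(0:63, rows * cols, TRUE), rows, cols))
}
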