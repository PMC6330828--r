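# Shared fixture builders for the test suite. All fixtures are generated in
# code; sizes are kept tiny except where a check is explicitly statistical.

tiny_sim_args <- function(...) {
  utils::modifyList(
    list(days = 3, M = 40, N = 60, P = 20, nu = 0.2, f = 0.1,
         test_instances = 2, seed = 42),
    list(...)
  )
}

# A trained single-output setup at moderate size, reused by several tests.
trained_setup <- function(seed = 7, M = 200, N = 500, P = 100, nu = 0.2,
                          f = 0.04) {
  ens <- generate_context_set(M, P, n_contexts = 2, C = 1, nu = nu,
                              seed = seed)
  layer <- init_input_weights(N, M, seed = seed + 1)
  theta <- calibrate_threshold(layer$M_effective, f)
  A <- mean_dg_activity(dg_currents(layer, ens$prototypes), theta, nu,
                        layer$M_effective)
  readout <- train_readout(A, ens$labels)
  list(ens = ens, layer = layer, theta = theta, A = A, readout = readout)
}

# Brute-force current oracle: explicit double loop over units and afferents.
loop_currents <- function(J, patterns) {
  out <- matrix(0, nrow(J), ncol(patterns))
  for (i in seq_len(nrow(J))) {
    for (mu in seq_len(ncol(patterns))) {
      acc <- 0
      for (j in seq_len(ncol(J))) acc <- acc + J[i, j] * patterns[j, mu]
      out[i, mu] <- acc
    }
  }
  out
}
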