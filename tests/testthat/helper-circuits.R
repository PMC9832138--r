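# Shared fixtures for the test suite: small, fast configurations.

default_circuit <- function(...) circuit_params(...)

# short schedule for speed where full epochs are not needed
quick_schedule <- function() trial_schedule(t_pre = 0.3, t_stim = 0.8, t_post = 0.4)

tiny_rnn_params <- function(...) {
  rnn_params(N_E = 8, N_I = 4, N_time = 24, seed_stim_len = 8,
             min_pre = 5, min_post = 5, ...)
}

# The network-replication experiment is used by two acceptance blocks; train
# the networks once per test run.
rnn_replication_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_experiment("rnn_replication", seed = 2024, n_networks = 3)
    }
    cache
  }
})
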