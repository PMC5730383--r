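# Small fixture builders shared across test files. All fixtures are
# generated in code under fixed seeds; sizes are kept small so the whole
# suite stays fast.

tiny_network <- function(n_cmd = 30, n_rec = 40, nc = 2, nd = 2,
                         r1 = 0.2, r2 = 1, k = 10, seed = 42, ...) {
  set.seed(seed)
  follow_network(n_cmd, n_rec, nc, nd, r1, r2, k = k, ...)
}

# constant-current drive expressed as a command series that produces a
# given current is awkward; tests drive lif_step directly instead
sim_constant_current_rate <- function(J, duration = 2, dt = 1e-3,
                                      params = lif_params()) {
  st <- lif_state(length(J))
  counts <- numeric(length(J))
  for (i in seq_len(round(duration / dt))) {
    r <- lif_step(st, J, dt, params)
    st <- r$state
    counts <- counts + r$spiked
  }
  counts / duration
}

small_linear_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- follow("linear", n_neurons = 300, t_pre = 2, t_learn = 24,
                       t_test = 4, seed = 7, verbose = FALSE)
    cache
  }
})
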