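# Shared fixtures: small fast networks and canned scenario pieces.

tiny_top <- function(f_b = 0.031, f_r = 0.05, i0 = 4L, N = 30L, n = 10L,
                     allow_equal = FALSE) {
  build_loop_branch(N, n, i0,
                    het_two_constant(f_b, f_r, allow_equal = allow_equal))
}

default_top <- function() build_loop_branch(150, 30, 10,
                                            het_two_constant(0.031, 0.05))

# a synthetic perfectly periodic raster: `reps` repetitions of the ISI
# motif at each listed node, offset per node by `hop`
synthetic_raster <- function(motif, reps, nodes, N, t0 = 100, hop = 1,
                             t_end = NULL) {
  period <- sum(motif)
  spikes <- vector("list", N)
  for (k in seq_along(nodes)) {
    base <- t0 + (k - 1) * hop +
      as.vector(outer(cumsum(c(0, motif[-length(motif)])),
                      period * (seq_len(reps) - 1), "+"))
    spikes[[nodes[k]]] <- sort(base)
  }
  for (i in seq_len(N)) if (is.null(spikes[[i]])) spikes[[i]] <- numeric(0)
  te <- if (is.null(t_end)) t0 + reps * period + 100 else t_end
  structure(list(spikes = spikes, N = as.integer(N), t_end = te,
                 dt = 0.005, debounce = 5),
            class = "spike_raster")
}
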