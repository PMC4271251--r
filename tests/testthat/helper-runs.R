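# Memoised full-size scenario runs shared across acceptance-criterion
# tests, so each expensive simulation happens at most once per suite run.
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, expr) {
  if (!exists(key, envir = .run_cache))
    assign(key, force(expr), envir = .run_cache)
  get(key, envir = .run_cache)
}

std_top <- function() cached_run("std_top",
  build_loop_branch(150, 30, 10, het_two_constant(0.031, 0.05)))

ident_top <- function() cached_run("ident_top",
  build_loop_branch(150, 30, 10,
                    het_two_constant(0.031, 0.031, allow_equal = TRUE)))

# the headline switch-off scenario at production resolution
headline_sim <- function() cached_run("headline",
  simulate_network(std_top(), fhn_params(), synapse_params(),
                   stimulus_protocol(1, 1.2, 0.5, T0 = 1600),
                   sim_config(dt = 0.005, t_end = 4600)))

persistent_sim <- function(omega) cached_run(paste0("persist", omega),
  simulate_network(std_top(), fhn_params(), synapse_params(),
                   stimulus_protocol(1, 1.2, omega, T0 = Inf),
                   sim_config(dt = 0.005, t_end = 1200)))

ident_sim <- function(omega) cached_run(paste0("ident", omega),
  simulate_network(ident_top(), fhn_params(), synapse_params(),
                   stimulus_protocol(1, 1.2, omega, T0 = 1600),
                   sim_config(dt = 0.005, t_end = 3300)))

group_median_isi <- function(sim, nodes, window = c(500, 1200)) {
  per <- vapply(nodes, function(i) {
    x <- interspike_intervals(sim$raster, i, window)
    if (length(x)) median(x) else NA_real_
  }, numeric(1))
  median(per, na.rm = TRUE)
}
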