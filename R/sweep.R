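#' Canned scenario configurations
#'
#' Returns a complete scenario (topology, neuron, synapse, stimulus and
#' simulation configuration) for three standard setups:
#' \describe{
#'   \item{`tiny`}{`N = 30`, `n = 10`, `i0 = 4` with shortened horizons —
#'     a fast network for tests.}
#'   \item{`default`}{the full `N = 150`, `n = 30`, `i0 = 10` scenario
#'     with `f_b = 0.031`, `f_r = 0.05` and the standard stimulus.}
#'   \item{`gaussian`}{as `default` but with Gaussian-distributed `f`
#'     (`E = 0.06`, `sigma = 0.01`).}
#' }
#'
#' @param kind `"tiny"`, `"default"` or `"gaussian"`.
#' @param seed seed for the Gaussian variant.
#' @return Named list with elements `top`, `fhn`, `syn`, `stim`, `cfg`.
#' @export
generate_fixture <- function(kind = c("tiny", "default", "gaussian"),
                             seed = 1L) {
  kind <- match.arg(kind)
  fhn <- fhn_params()
  syn <- synapse_params()
  switch(kind,
    tiny = list(
      top = build_loop_branch(30, 10, 4, het_two_constant(0.031, 0.05)),
      fhn = fhn, syn = syn,
      stim = stimulus_protocol(1, 1.2, 0.5, T0 = 300),
      cfg = sim_config(t_end = 1800, settle = 100)),
    default = list(
      top = build_loop_branch(150, 30, 10, het_two_constant(0.031, 0.05)),
      fhn = fhn, syn = syn,
      stim = stimulus_protocol(1, 1.2, 0.5, T0 = 1600),
      cfg = sim_config(t_end = 4600)),
    gaussian = list(
      top = build_loop_branch(150, 30, 10,
                              het_gaussian_f(E = 0.06, sigma = 0.01,
                                             seed = seed)),
      fhn = fhn, syn = syn,
      stim = stimulus_protocol(1, 1.2, 0.5, T0 = 1600),
      cfg = sim_config(t_end = 4600, seed = seed)))
}

#' Parameter sweep of the saturated spiking number
#'
#' Runs simulate-plus-analyse over a grid of one varying parameter,
#' holding the rest of the scenario fixed, and records `S_p`, the STM/LTM
#' label and the pattern period per grid point (and per replicate seed for
#' Gaussian schemes). Failures of individual runs are recorded per row and
#' the sweep continues.
#'
#' @param varying one of `"T0"`, `"i0"`, `"omega"`, `"delta_f"`, `"E"`,
#'   `"sigma"`.
#' @param grid strictly increasing values of the varying parameter.
#' @param scenario a fixture list as returned by [generate_fixture()];
#'   its elements are the fixed part of the sweep.
#' @param replicates replicate count (>= 1; only meaningful for Gaussian
#'   schemes, where each replicate redraws the conductances).
#' @param seed_base integer; replicate `r` at grid point `g` uses seed
#'   `seed_base + 1000 * (g - 1) + r`.
#' @return A data frame of class `"sweep_result"` with columns
#'   `varying`, `value`, `seed`, `S_p`, `label`, `period`, `error`.
#' @export
sweep_saturated_sp <- function(varying = c("T0", "i0", "omega", "delta_f",
                                           "E", "sigma"),
                               grid, scenario = generate_fixture("default"),
                               replicates = 1L, seed_base = 1L) {
  varying <- match.arg(varying)
  stopifnot(length(grid) >= 1, !is.unsorted(grid, strictly = TRUE),
            replicates >= 1)
  rows <- vector("list", length(grid) * replicates)
  k <- 0L
  for (g in seq_along(grid)) {
    val <- grid[g]
    for (r in seq_len(replicates)) {
      seed <- as.integer(seed_base + 1000L * (g - 1L) + r)
      k <- k + 1L
      rows[[k]] <- tryCatch({
        sc <- apply_sweep_value(scenario, varying, val, seed)
        sim <- simulate_network(sc$top, sc$fhn, sc$syn, sc$stim, sc$cfg)
        ps <- pattern_summary(sim)
        data.frame(varying = varying, value = val, seed = seed,
                   S_p = as.integer(ps$S_p), label = ps$label,
                   period = if (is.null(ps$period)) NA_real_ else ps$period,
                   error = NA_character_)
      }, error = function(e)
        data.frame(varying = varying, value = val, seed = seed,
                   S_p = NA_integer_, label = NA_character_,
                   period = NA_real_, error = conditionMessage(e)))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

# rebuild the scenario with one parameter replaced
apply_sweep_value <- function(sc, varying, val, seed) {
  top <- sc$top; stim <- sc$stim; cfg <- sc$cfg
  scheme <- top$scheme
  g_default <- max(top$gmax)
  switch(varying,
    T0 = {
      stim <- stimulus_protocol(stim$A, stim$B, stim$omega, T0 = val,
                                target = stim$target)
      cfg <- sim_config(dt = cfg$dt, t_end = val + 3000, settle = cfg$settle,
                        record_stride = cfg$record_stride, seed = seed)
    },
    i0 = {
      top <- build_loop_branch(top$N, top$n, as.integer(val),
                               scheme = reseed(scheme, seed),
                               g_max = g_default)
    },
    omega = {
      stim <- stimulus_protocol(stim$A, stim$B, val, T0 = stim$T0,
                                target = stim$target)
    },
    delta_f = {
      if (scheme$variant != "two_constant")
        stop("delta_f sweep requires a two_constant scheme", call. = FALSE)
      top <- build_loop_branch(top$N, top$n, top$i0,
                               scheme = het_two_constant(scheme$f_b,
                                                         scheme$f_b + val,
                                                         allow_equal = TRUE),
                               g_max = g_default)
    },
    E = {
      if (scheme$variant == "two_constant")
        stop("E sweep requires a gaussian scheme", call. = FALSE)
      sch <- scheme; sch$E <- val; sch$seed <- seed
      top <- build_loop_branch(top$N, top$n, top$i0, scheme = sch,
                               g_max = g_default)
    },
    sigma = {
      if (scheme$variant == "two_constant")
        stop("sigma sweep requires a gaussian scheme", call. = FALSE)
      sch <- scheme; sch$sigma <- val; sch$seed <- seed
      top <- build_loop_branch(top$N, top$n, top$i0, scheme = sch,
                               g_max = g_default)
    })
  list(top = top, fhn = sc$fhn, syn = sc$syn, stim = stim, cfg = cfg)
}

reseed <- function(scheme, seed) {
  scheme$seed <- as.integer(seed)
  scheme
}

#' Write a spike raster as CSV
#'
#' Long-format CSV with columns `node` (1-based) and `spike_time`
#' (4 decimals).
#'
#' @param raster a `"spike_raster"` (or `"fhn_sim"`).
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_raster_csv <- function(raster, file) {
  if (inherits(raster, "fhn_sim")) raster <- raster$raster
  stopifnot(inherits(raster, "spike_raster"))
  df <- data.frame(
    node = rep.int(seq_along(raster$spikes), lengths(raster$spikes)),
    spike_time = sprintf("%.4f", unlist(raster$spikes, use.names = FALSE)))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_raster_csv
#' @param N,t_end,dt raster metadata (not stored in the CSV).
#' @export
read_raster_csv <- function(file, N, t_end, dt = 0.005) {
  df <- utils::read.csv(file)
  spikes <- lapply(seq_len(N), function(i)
    sort(df$spike_time[df$node == i]))
  structure(list(spikes = spikes, N = as.integer(N), t_end = t_end,
                 dt = dt, debounce = NA_real_),
            class = "spike_raster")
}
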