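test_that("quiescent network stays quiescent without stimulus", {
  top <- tiny_top()
  sim <- simulate_network(top,
                          stim = stimulus_protocol(A = 0, B = 0,
                                                   omega = 0.5, T0 = Inf),
                          cfg = sim_config(t_end = 2000))
  expect_equal(sum(lengths(sim$raster$spikes)), 0L)
  # final state near the coupled rest point, left branch
  expect_true(all(sim$final$u < -1))
})

test_that("simulation is deterministic and respects raster invariants", {
  fx <- generate_fixture("tiny")
  s1 <- simulate_network(fx$top, fx$fhn, fx$syn, fx$stim, fx$cfg)
  s2 <- simulate_network(fx$top, fx$fhn, fx$syn, fx$stim, fx$cfg)
  expect_identical(s1$raster$spikes, s2$raster$spikes)
  for (i in seq_len(fx$top$N)) {
    s <- spike_times(s1, i)
    if (length(s) > 1) {
      expect_true(all(diff(s) >= fx$syn$debounce))
      expect_true(all(diff(s) >= 10))   # refractory margin
    }
    expect_true(all(s >= 0 & s <= fx$cfg$t_end))
  }
  expect_gt(sum(lengths(s1$raster$spikes)), 0L)
})

test_that("compiled core matches the pure-R closed-form-gating reference", {
  top <- build_loop_branch(6, 4, 3, het_two_constant(0.031, 0.05))
  fhn <- fhn_params()
  syn <- synapse_params()
  stim <- stimulus_protocol(1, 1.2, 0.5, T0 = Inf)
  sim <- simulate_network(top, fhn, syn, stim,
                          cfg = sim_config(t_end = 60, settle = 50))
  ref <- reference_simulation(top, fhn, syn, stim, dt = 0.005, t_end = 60,
                              settle = 50)
  expect_equal(lengths(sim$raster$spikes), lengths(ref))
  for (i in seq_len(top$N))
    if (length(ref[[i]]))
      expect_lt(max(abs(spike_times(sim, i) - ref[[i]])), 0.02)
})

test_that("normalized gating variant matches its reference too", {
  top <- build_loop_branch(6, 4, 3, het_two_constant(0.031, 0.05))
  fhn <- fhn_params()
  syn <- synapse_params(normalize = TRUE)
  stim <- stimulus_protocol(1, 1.2, 0.5, T0 = Inf)
  sim <- simulate_network(top, fhn, syn, stim,
                          cfg = sim_config(t_end = 60, settle = 50))
  ref <- reference_simulation(top, fhn, syn, stim, dt = 0.005, t_end = 60,
                              settle = 50)
  expect_equal(lengths(sim$raster$spikes), lengths(ref))
  for (i in seq_len(top$N))
    if (length(ref[[i]]))
      expect_lt(max(abs(spike_times(sim, i) - ref[[i]])), 0.02)
})

test_that("wave causality holds on the branch during the first episode", {
  fx <- generate_fixture("tiny")
  sim <- simulate_network(fx$top, fx$fhn, fx$syn, fx$stim, fx$cfg)
  pc <- predicted_collision_nodes(fx$top)
  first <- vapply(fx$top$n + seq_len(pc$i_m2 - fx$top$n),
                  function(i) spike_times(sim, i)[1], numeric(1))
  # outward wave: arrival strictly increasing from n+1 to the collision node
  expect_true(all(diff(first) > 0))
})

test_that("first-episode annihilation happens at the predicted nodes", {
  top <- tiny_top(0.031, 0.031, allow_equal = TRUE)
  sim <- simulate_network(top,
                          stim = stimulus_protocol(1, 1.2, 0.5, T0 = Inf),
                          cfg = sim_config(t_end = 120))
  first <- vapply(seq_len(top$N),
                  function(i) spike_times(sim, i)[1], numeric(1))
  episode <- c(0, max(first) + 1)
  obs <- observed_collision_nodes(sim, top, episode)
  pc <- predicted_collision_nodes(top)
  expect_equal(obs$i_m1, pc$i_m1)
  expect_equal(obs$i_m2, pc$i_m2)
})

test_that("step-size control and convergence behave", {
  expect_error(
    simulate_network(tiny_top(), cfg = sim_config(dt = 0.02)),
    "dt")
  expect_error(sim_config(dt = 0.05), "dt")
  # dead network converges trivially with zero deviation
  top <- tiny_top()
  rep0 <- convergence_report(top,
                             stim = stimulus_protocol(0, 0, 0.5, Inf),
                             dt_list = c(0.01, 0.005), t_end = 100,
                             settle = 20)
  expect_true(all(rep0$matched))
  expect_equal(rep0$max_dev, 0)
  # live tiny scenario: spike times stable under refinement
  rep1 <- convergence_report(top,
                             stim = stimulus_protocol(1, 1.2, 0.5, 150),
                             dt_list = c(0.01, 0.005, 0.0025),
                             t_end = 300, settle = 100)
  expect_true(all(rep1$matched))
  expect_true(all(rep1$max_dev < 0.5))
  expect_true(rep1$max_dev[2] <= rep1$max_dev[1] + 1e-6)
})

test_that("raster CSV round-trips through the writer", {
  fx <- generate_fixture("tiny")
  sim <- simulate_network(fx$top, fx$fhn, fx$syn, fx$stim, fx$cfg)
  f <- tempfile(fileext = ".csv")
  write_raster_csv(sim, f)
  back <- read_raster_csv(f, N = fx$top$N, t_end = fx$cfg$t_end)
  for (i in seq_len(fx$top$N))
    expect_equal(back$spikes[[i]], round(spike_times(sim, i), 4))
  unlink(f)
})
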