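test_that("inter-spike intervals are plain successive differences", {
  r <- synthetic_raster(motif = c(50), reps = 3, nodes = 1, N = 5)
  expect_equal(interspike_intervals(r, 1), c(50, 50))
  r1 <- synthetic_raster(motif = c(40), reps = 1, nodes = 1, N = 5)
  expect_equal(interspike_intervals(r1, 1), numeric(0))
  expect_equal(interspike_intervals(r, 2), numeric(0))
})

test_that("memory classification keys on post-switch-off survival", {
  empty <- synthetic_raster(c(10), reps = 0, nodes = 1, N = 3, t_end = 3100)
  empty$spikes[[1]] <- numeric(0)
  expect_equal(classify_memory(empty, T0 = 1600), "none")
  # spikes end before T0 + window -> STM
  stm <- synthetic_raster(c(40), reps = 10, nodes = 1, N = 3, t0 = 1500,
                          t_end = 3100)
  expect_equal(classify_memory(stm, T0 = 1600), "STM")
  # spikes persisting past T0 + window -> LTM
  ltm <- synthetic_raster(c(40), reps = 40, nodes = 1, N = 3, t0 = 1500,
                          t_end = 3200)
  expect_equal(classify_memory(ltm, T0 = 1600), "LTM")
  expect_error(classify_memory(ltm, T0 = 2600), "t_end")
})

test_that("pattern period recovers a constructed motif", {
  r <- synthetic_raster(motif = c(40, 60), reps = 8, nodes = 1, N = 2)
  expect_equal(pattern_period(r, 1, t_start = 0), 100, tolerance = 1e-9)
  # uniform train: period equals the single interval
  ru <- synthetic_raster(motif = c(35), reps = 12, nodes = 1, N = 2)
  expect_equal(pattern_period(ru, 1, t_start = 0), 35)
  # extinct train
  r0 <- synthetic_raster(motif = c(40), reps = 1, nodes = 1, N = 2)
  expect_null(pattern_period(r0, 1, t_start = 0))
  # jittered beyond tolerance -> no period
  rj <- synthetic_raster(motif = c(40, 60), reps = 8, nodes = 1, N = 2)
  set.seed(1)
  rj$spikes[[1]] <- sort(rj$spikes[[1]] + runif(16, -3, 3))
  expect_null(pattern_period(rj, 1, t_start = 0, tol = 1))
})

test_that("spiking number counts reference-node spikes per period", {
  top <- tiny_top()
  # k-spike motif repeating at the reference node => S_p = k
  for (k in c(2, 5, 11)) {
    motif <- c(rep(37.5, k - 1), 400 - 37.5 * (k - 1))
    r <- synthetic_raster(motif, reps = 10, nodes = top$i0, N = top$N,
                          t0 = 2100, t_end = 6200)
    expect_equal(spiking_number(r, top, T0 = 1600), k)
  }
  # STM raster => 0 by definition
  stm <- synthetic_raster(c(40), reps = 5, nodes = top$i0, N = top$N,
                          t0 = 1500, t_end = 3100)
  expect_identical(spiking_number(stm, top, T0 = 1600), 0L)
  # persistent but aperiodic => NA (irregular flag)
  set.seed(42)
  irr <- synthetic_raster(c(40), reps = 2, nodes = top$i0, N = top$N,
                          t0 = 2100, t_end = 6200)
  irr$spikes[[top$i0]] <- sort(2100 + cumsum(runif(40, 20, 80)))
  expect_true(is.na(spiking_number(irr, top, T0 = 1600)))
})

test_that("spiking number is invariant to time translation", {
  top <- tiny_top()
  motif <- c(37.5, 37.5, 300)
  r1 <- synthetic_raster(motif, reps = 10, nodes = top$i0, N = top$N,
                         t0 = 2100, t_end = 6200)
  r2 <- synthetic_raster(motif, reps = 10, nodes = top$i0, N = top$N,
                         t0 = 2229.3, t_end = 6400)
  expect_equal(spiking_number(r1, top, T0 = 1600),
               spiking_number(r2, top, T0 = 1600))
})

test_that("locking profile reduces group medians to integer ratios", {
  top <- tiny_top()
  loop_nodes <- seq_len(top$n)
  branch_nodes <- seq(top$n + 1, top$N)
  r <- synthetic_raster(c(75), reps = 10, nodes = loop_nodes, N = top$N,
                        t0 = 100, t_end = 1000)
  rb <- synthetic_raster(c(37.5), reps = 20, nodes = branch_nodes,
                         N = top$N, t0 = 100, t_end = 1000)
  for (i in branch_nodes) r$spikes[[i]] <- rb$spikes[[i]]
  lp <- locking_profile(r, top, window = c(0, 900))
  expect_equal(lp$loop_isi, 75)
  expect_equal(lp$branch_isi, 37.5)
  expect_equal(lp$ratio, "2:1")
  # homogeneous case
  rh <- synthetic_raster(c(50), reps = 12, nodes = seq_len(top$N),
                         N = top$N, t0 = 100, t_end = 1000)
  expect_equal(locking_profile(rh, top, c(0, 900))$ratio, "1:1")
  # empty window errors
  expect_error(locking_profile(r, top, window = c(2000, 2100)),
               "insufficient")
})

test_that("collision localisation finds the latest-firing cycle node", {
  top <- tiny_top()                       # N = 30, n = 10, i0 = 4
  pc <- predicted_collision_nodes(top)
  cyc <- fhnmem:::cycle_nodes(top)
  # build one synthetic episode: fronts spread from node 1 at unit speed
  r <- synthetic_raster(c(10), reps = 0, nodes = 1, N = top$N,
                        t_end = 200)
  for (loop in cyc) {
    L <- length(loop)
    pos <- seq_along(loop) - 1L
    arrival <- pmin(pos, L - pos)
    for (k in seq_along(loop))
      r$spikes[[loop[k]]] <- sort(unique(c(r$spikes[[loop[k]]],
                                           100 + arrival[k])))
  }
  obs <- observed_collision_nodes(r, top, episode = c(95, 130))
  expect_equal(obs$i_m1, pc$i_m1)
  expect_equal(obs$i_m2, pc$i_m2)
})

test_that("path firing counts see discrete wavefronts", {
  top <- tiny_top()
  # dead raster
  dead <- synthetic_raster(c(10), reps = 0, nodes = 1, N = top$N,
                           t_end = 100)
  pf <- path_firing_counts(dead, top, 50)
  expect_equal(c(pf$l1, pf$l2), c(0L, 0L))
  # one outward episode from node 1, unit speed, before any collision
  r <- dead
  pcn <- predicted_collision_nodes(top)
  for (j in seq(top$n + 1, pcn$i_m2)) r$spikes[[j]] <- 10 + (j - top$n)
  for (j in 2:top$i0) r$spikes[[j]] <- 10 + (j - 1)
  pf2 <- path_firing_counts(r, top, 14)
  expect_equal(c(pf2$l1, pf2$l2), c(1L, 1L))
})
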