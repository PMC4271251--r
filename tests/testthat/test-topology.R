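test_that("default topology realises the wiring rules", {
  top <- default_top()
  expect_equal(neighbors(top, 1), c(2L, 30L, 31L))
  expect_equal(neighbors(top, 10), c(9L, 11L, 150L))
  expect_equal(neighbors(top, 31), c(1L, 32L))
  expect_equal(neighbors(top, 150), c(10L, 149L))
  expect_equal(neighbors(top, 16), c(15L, 17L))
  expect_equal(neighbors(top, 30), c(1L, 29L))
  deg <- lengths(top$adj)
  expect_equal(sort(which(deg == 3)), c(1L, 10L))
  expect_true(all(deg[-c(1, 10)] == 2))
  # N + 1 undirected edges
  expect_equal(nrow(edge_list(top)), top$N + 1L)
})

test_that("adjacency is symmetric on assorted topologies", {
  for (p in list(c(30, 10, 4), c(150, 30, 10), c(40, 17, 9), c(12, 5, 3))) {
    top <- build_loop_branch(p[1], p[2], p[3],
                             het_two_constant(0.031, 0.05))
    for (i in seq_len(top$N))
      for (j in neighbors(top, i))
        expect_true(i %in% neighbors(top, j))
    expect_equal(nrow(edge_list(top)), top$N + 1L)
  }
})

test_that("degenerate and invalid topologies are rejected", {
  expect_equal(sort(lengths(build_loop_branch(5, 3, 2,
    het_two_constant(0, 0, allow_equal = TRUE))$adj), decreasing = TRUE),
    c(3L, 3L, 2L, 2L, 2L))
  expect_error(build_loop_branch(150, 30, 31), "loop interior")
  expect_error(build_loop_branch(150, 30, 1), "loop interior")
  expect_error(build_loop_branch(150, 30, 30), "loop interior")
  expect_error(build_loop_branch(30, 30, 10), "n < N")
  expect_error(neighbors(default_top(), 151), "out of range")
  expect_error(neighbors(default_top(), 0), "out of range")
})

test_that("collision-node formulas match the printed values and arithmetic", {
  expect_equal(predicted_collision_nodes(default_top())[c("i_m1", "i_m2")],
               list(i_m1 = 16L, i_m2 = 95L))
  top12 <- build_loop_branch(150, 30, 12, het_two_constant(0.031, 0.05))
  expect_equal(predicted_collision_nodes(top12)$i_m2, 96L)
  expect_equal(predicted_collision_nodes(top12)$i_m1, 16L)
  odd <- build_loop_branch(150, 31, 10, het_two_constant(0.031, 0.05))
  pc <- predicted_collision_nodes(odd)
  expect_equal(pc$i_m1_frac, 16.5)
  expect_equal(pc$i_m1, 16L)
})

test_that("collision formula agrees with the equal-distance front oracle", {
  for (N in c(8, 12, 17, 23, 30, 40)) {
    for (n in c(4, 6, 9)) {
      if (n >= N - 1) next
      for (i0 in seq(2L, n - 1L)) {
        top <- build_loop_branch(N, n, i0,
                                 het_two_constant(0, 0, allow_equal = TRUE))
        pc <- predicted_collision_nodes(top)
        cyc <- fhnmem:::cycle_nodes(top)
        expect_identical(pc$i_m1, fhnmem:::bfs_collision_node(cyc$small)$node,
                         info = sprintf("small loop N=%d n=%d i0=%d", N, n, i0))
        expect_identical(pc$i_m2, fhnmem:::bfs_collision_node(cyc$large)$node,
                         info = sprintf("large loop N=%d n=%d i0=%d", N, n, i0))
      }
    }
  }
})

test_that("conductance assignment follows the scheme", {
  top <- default_top()
  expect_equal(top$f[c(1, 30)], c(0.031, 0.031))
  expect_equal(top$f[c(31, 150)], c(0.05, 0.05))
  expect_true(all(top$gmax == 0.35))

  g <- assign_baseline_conductance(150, 30,
                                   het_gaussian_f(E = 0.06, sigma = 0.01,
                                                  seed = 11))
  expect_true(all(g$f > 0))
  expect_lt(abs(mean(g$f) - 0.06), 3 * 0.01 / sqrt(150))
  # deterministic under the seed
  g2 <- assign_baseline_conductance(150, 30,
                                    het_gaussian_f(E = 0.06, sigma = 0.01,
                                                   seed = 11))
  expect_identical(g$f, g2$f)

  gg <- assign_baseline_conductance(150, 30,
                                    het_gaussian_gmax(E = 0.5, sigma = 0.04,
                                                      f_const = 0.03,
                                                      seed = 2))
  expect_true(all(gg$f == 0.03))
  expect_true(all(gg$gmax > 0))
})

test_that("scheme validation enforces the conventions", {
  expect_error(het_two_constant(0.05, 0.031), "f_b < f_r")
  expect_error(het_two_constant(0.03, 0.03), "f_b < f_r")
  expect_silent(het_two_constant(0.03, 0.03, allow_equal = TRUE))
  expect_error(het_gaussian_f(E = 0.06, sigma = -0.01), "sigma")
  expect_error(het_gaussian_gmax(E = -0.5, sigma = 0.04, f_const = 0.03),
               "positive")
})

test_that("Cayley growth preserves the core and adds uniform leaves", {
  top <- tiny_top()
  g0 <- grow_cayley(top, branching = 2, depth = 0)
  expect_equal(g0$N, top$N)
  expect_identical(g0$adj[seq_len(top$N)], top$adj)
  g1 <- grow_cayley(top, branching = 2, depth = 1)
  expect_equal(g1$N, top$N + 2 * top$N)
  # former degree-2 core node gains exactly `branching` leaves
  expect_equal(length(g1$adj[[5]]), 2 + 2)
  # leaves inherit the attachment point's conductance
  leaf <- top$N + 1L
  parent <- g1$adj[[leaf]][1]
  expect_equal(g1$f[leaf], g1$f[parent])
  g2 <- grow_cayley(top, branching = 3, depth = 2)
  expect_equal(g2$N, top$N + 3 * top$N + 3 * (3 * top$N))
})

test_that("topology CSV round-trips", {
  top <- tiny_top()
  ef <- tempfile(fileext = ".csv"); nf <- tempfile(fileext = ".csv")
  write_topology_csv(top, ef, nf)
  back <- read_topology_csv(ef, nf)
  expect_equal(back$N, top$N)
  expect_identical(back$adj, top$adj)
  expect_equal(back$f, top$f)
  expect_equal(back$gmax, top$gmax)
  unlink(c(ef, nf))
})
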