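#' Heterogeneity scheme for the baseline conductance
#'
#' Describes how the per-node baseline conductance `f` (and optionally the
#' maximal conductance `g_max`) are assigned across the network. Three
#' variants are supported:
#' \describe{
#'   \item{`two_constant`}{`f = f_b` on the loop (nodes `1..n`) and
#'     `f = f_r` on the branch (nodes `n+1..N`), with the convention
#'     `f_b < f_r`; set `allow_equal = TRUE` for the identical-`f` control
#'     case `f_b = f_r`.}
#'   \item{`gaussian_f`}{each node draws `f` independently from a Gaussian
#'     with mean `E` and standard deviation `sigma`, truncated to positive
#'     values by resampling; `g_max` is constant.}
#'   \item{`gaussian_gmax`}{`f = f_const` everywhere and each node draws
#'     its (presynaptic) `g_max` from a truncated Gaussian with mean `E`
#'     and standard deviation `sigma`.}
#' }
#'
#' @param variant one of `"two_constant"`, `"gaussian_f"`,
#'   `"gaussian_gmax"`.
#' @param f_b,f_r loop and branch baseline conductances (two_constant).
#' @param E,sigma mean and standard deviation of the Gaussian draw.
#' @param f_const shared baseline conductance when `g_max` is distributed.
#' @param seed integer seed for the Gaussian draws.
#' @param allow_equal permit `f_b == f_r` (the homogeneous control case).
#' @return An object of class `"het_scheme"`. For `two_constant` the
#'   derived difference `delta_f = f_r - f_b` is stored.
#' @examples
#' het_two_constant(0.031, 0.05)
#' het_gaussian_f(E = 0.06, sigma = 0.01, seed = 7)
#' @export
het_scheme <- function(variant = c("two_constant", "gaussian_f", "gaussian_gmax"),
                       f_b = 0.031, f_r = 0.05, E = NULL, sigma = NULL,
                       f_const = NULL, seed = 1L, allow_equal = FALSE) {
  variant <- match.arg(variant)
  out <- list(variant = variant, seed = as.integer(seed))
  if (variant == "two_constant") {
    stopifnot(is.finite(f_b), is.finite(f_r))
    if (f_b < 0 || f_r < 0)
      stop("baseline conductances must be nonnegative", call. = FALSE)
    if (f_b > f_r || (f_b == f_r && !allow_equal))
      stop("two_constant requires f_b < f_r (use allow_equal = TRUE for the ",
           "identical-f control case)", call. = FALSE)
    out$f_b <- f_b; out$f_r <- f_r; out$delta_f <- f_r - f_b
  } else {
    if (is.null(E) || is.null(sigma))
      stop("gaussian variants require E and sigma", call. = FALSE)
    if (sigma < 0) stop("'sigma' must be nonnegative", call. = FALSE)
    if (variant == "gaussian_gmax") {
      if (E <= 0) stop("'E' must be positive for gaussian_gmax", call. = FALSE)
      if (is.null(f_const) || f_const < 0)
        stop("gaussian_gmax requires a nonnegative f_const", call. = FALSE)
      out$f_const <- f_const
    }
    out$E <- E; out$sigma <- sigma
  }
  class(out) <- "het_scheme"
  out
}

#' @rdname het_scheme
#' @export
het_two_constant <- function(f_b = 0.031, f_r = 0.05, allow_equal = FALSE)
  het_scheme("two_constant", f_b = f_b, f_r = f_r, allow_equal = allow_equal)

#' @rdname het_scheme
#' @export
het_gaussian_f <- function(E, sigma, seed = 1L)
  het_scheme("gaussian_f", E = E, sigma = sigma, seed = seed)

#' @rdname het_scheme
#' @export
het_gaussian_gmax <- function(E, sigma, f_const, seed = 1L)
  het_scheme("gaussian_gmax", E = E, sigma = sigma, f_const = f_const,
             seed = seed)

#' @export
print.het_scheme <- function(x, ...) {
  cat("Heterogeneity scheme:", x$variant, "\n")
  if (x$variant == "two_constant")
    cat(sprintf("  f_b = %g, f_r = %g (delta_f = %g)\n", x$f_b, x$f_r,
                x$delta_f))
  else if (x$variant == "gaussian_f")
    cat(sprintf("  f ~ N+(%g, %g^2), seed %d\n", x$E, x$sigma, x$seed))
  else
    cat(sprintf("  g_max ~ N+(%g, %g^2), f = %g, seed %d\n", x$E, x$sigma,
                x$f_const, x$seed))
  invisible(x)
}

# positive truncated-normal draws by resampling nonpositive values
rtruncnorm_pos <- function(k, mean, sd) {
  x <- stats::rnorm(k, mean, sd)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Assign per-node baseline and maximal conductances
#'
#' Realises a heterogeneity scheme on a topology of `N` nodes, `n` of which
#' form the loop. Gaussian draws are truncated positive (nonpositive draws
#' resampled) and reproducible under the scheme's seed.
#'
#' @param N,n total and loop node counts.
#' @param scheme a [het_scheme()].
#' @param g_max default maximal conductance used wherever the scheme does
#'   not distribute it.
#' @return A list with numeric vectors `f` and `gmax` of length `N`.
#' @export
assign_baseline_conductance <- function(N, n, scheme, g_max = 0.35) {
  stopifnot(inherits(scheme, "het_scheme"), N >= 1, n >= 1, n <= N)
  switch(scheme$variant,
    two_constant = list(
      f = c(rep(scheme$f_b, n), rep(scheme$f_r, N - n)),
      gmax = rep(g_max, N)),
    gaussian_f = {
      set.seed(scheme$seed)
      list(f = rtruncnorm_pos(N, scheme$E, scheme$sigma),
           gmax = rep(g_max, N))
    },
    gaussian_gmax = {
      set.seed(scheme$seed)
      list(f = rep(scheme$f_const, N),
           gmax = rtruncnorm_pos(N, scheme$E, scheme$sigma))
    })
}

#' Build the loop-plus-branch memory network
#'
#' Constructs the core topology: nodes `1..n` form a closed loop, nodes
#' `n+1..N` form a linear branch whose first node `n+1` attaches to the
#' sensory node 1 and whose last node `N` attaches back to the junction
#' node `i0` on the loop. Exactly two nodes (1 and `i0`) have degree 3;
#' all others have degree 2. Node 1 receives the external stimulus.
#'
#' @param N total node count.
#' @param n loop node count; `3 <= n < N`.
#' @param i0 junction node index; must lie strictly inside the loop,
#'   `2 <= i0 <= n - 1`.
#' @param scheme a [het_scheme()] assigning per-node conductances.
#' @param g_max default maximal conductance (used unless the scheme
#'   distributes it).
#' @return An object of class `"fhn_topology"`: a list with `N`, `n`,
#'   `i0`, `adj` (list of 1-based neighbour vectors), `f`, `gmax`,
#'   and the `scheme`.
#' @examples
#' top <- build_loop_branch(150, 30, 10, het_two_constant(0.031, 0.05))
#' neighbors(top, 1)    # 2, 30, 31
#' neighbors(top, 10)   # 9, 11, 150
#' @export
build_loop_branch <- function(N = 150, n = 30, i0 = 10,
                              scheme = het_two_constant(), g_max = 0.35) {
  N <- as.integer(N); n <- as.integer(n); i0 <- as.integer(i0)
  if (!(n >= 3 && n < N))
    stop("need 3 <= n < N", call. = FALSE)
  if (!(i0 >= 2 && i0 <= n - 1))
    stop("junction 'i0' must lie on the loop interior: 2 <= i0 <= n-1",
         call. = FALSE)
  adj <- vector("list", N)
  for (i in seq_len(n)) {                       # loop, cyclic in 1..n
    left <- if (i == 1L) n else i - 1L
    right <- if (i == n) 1L else i + 1L
    adj[[i]] <- c(left, right)
  }
  adj[[1L]] <- c(2L, n, n + 1L)                 # sensory node
  if (N - n >= 2L) {
    adj[[n + 1L]] <- c(1L, n + 2L)
    for (i in seq(n + 2L, length.out = max(0L, N - n - 2L)))
      adj[[i]] <- c(i - 1L, i + 1L)
    adj[[N]] <- c(N - 1L, i0)
  } else {
    adj[[n + 1L]] <- c(1L, i0)                  # single-node branch
  }
  adj[[i0]] <- c(i0 - 1L, i0 + 1L, N)
  adj <- lapply(adj, sort)
  cond <- assign_baseline_conductance(N, n, scheme, g_max = g_max)
  if (any(!is.finite(cond$f)) || any(cond$f < 0))
    stop("baseline conductances must be finite and nonnegative", call. = FALSE)
  if (any(cond$gmax <= 0))
    stop("maximal conductances must be positive", call. = FALSE)
  structure(list(N = N, n = n, i0 = i0, adj = adj,
                 f = cond$f, gmax = cond$gmax, scheme = scheme),
            class = "fhn_topology")
}

#' Neighbours of a node
#'
#' @param top an `"fhn_topology"`.
#' @param node 1-based node index.
#' @return Sorted integer vector of neighbour indices.
#' @export
neighbors <- function(top, node) {
  stopifnot(inherits(top, "fhn_topology"))
  node <- as.integer(node)
  if (node < 1L || node > top$N)
    stop("node index out of range", call. = FALSE)
  top$adj[[node]]
}

#' @export
print.fhn_topology <- function(x, ...) {
  cat(sprintf(
    "Loop-plus-branch network: N = %d nodes (loop 1..%d, junction i0 = %d)\n",
    x$N, x$n, x$i0))
  cat(sprintf("  edges: %d; degree-3 nodes: 1 and %d\n",
              sum(lengths(x$adj)) / 2L, x$i0))
  print(x$scheme)
  invisible(x)
}

#' Edge list of a topology
#'
#' @param top an `"fhn_topology"`.
#' @return A data frame with 1-based columns `source < target`, one row
#'   per undirected edge.
#' @export
edge_list <- function(top) {
  stopifnot(inherits(top, "fhn_topology"))
  src <- rep.int(seq_len(top$N), lengths(top$adj))
  tgt <- unlist(top$adj, use.names = FALSE)
  keep <- src < tgt
  df <- data.frame(source = src[keep], target = tgt[keep])
  df[order(df$source, df$target), , drop = FALSE]
}

#' Predicted wavefront collision nodes
#'
#' A firing elicited at the sensory node 1 spreads along both directions of
#' the small loop (`1 -> 2 -> ... -> i_m1 <- ... <- n <- 1`) and of the
#' large loop through the branch; the counter-propagating fronts annihilate
#' where the arc distances from node 1 are equal. The midpoints are
#' \deqn{i_{m1} = 2 + (n - 2)/2, \qquad
#'       i_{m2} = n + 1 + [N - (n+1) + 1 + (i_0 - 2)]/2.}
#' For odd arc lengths the meeting point falls on an edge; the fractional
#' midpoint is reported and the nodal value is rounded half-down (the
#' lower-indexed endpoint annihilates first under synchronous update).
#'
#' @param top an `"fhn_topology"`.
#' @return A list with integer `i_m1`, `i_m2` and the exact fractional
#'   midpoints `i_m1_frac`, `i_m2_frac`.
#' @examples
#' top <- build_loop_branch(150, 30, 10)
#' predicted_collision_nodes(top)  # i_m1 = 16, i_m2 = 95
#' @export
predicted_collision_nodes <- function(top) {
  stopifnot(inherits(top, "fhn_topology"))
  m1 <- 2 + (top$n - 2) / 2
  m2 <- top$n + 1 + (top$N - (top$n + 1) + 1 + (top$i0 - 2)) / 2
  # the fronts enter the small arc at nodes 2 and n and the large arc at
  # nodes n+1 and 2 one step after node 1 fires; the nodal meeting point is
  # read off the arc walk (for odd arc lengths the pair meets on an edge and
  # the lower-indexed endpoint is reported)
  node_at <- function(path, q) {
    lo <- path[1L + floor(q)]
    hi <- path[1L + ceiling(q)]
    min(lo, hi)
  }
  small_path <- seq(2L, top$n)
  large_path <- c(seq(top$n + 1L, top$N), seq(top$i0, 2L))
  list(i_m1 = node_at(small_path, (top$n - 2) / 2),
       i_m2 = node_at(large_path, (length(large_path) - 1) / 2),
       i_m1_frac = m1, i_m2_frac = m2)
}

#' Grow a Cayley-tree periphery around the core network
#'
#' Attaches `branching` new leaves to every existing node, layer by layer
#' for `depth` generations (layer 1 grows from every core node; each later
#' layer grows only from the previous layer's leaves), emulating how the
#' small loop-plus-branch core can sit inside a larger tree-like network.
#' Core node indices are preserved; new nodes inherit the `f` and `g_max`
#' of their attachment point.
#'
#' @param top an `"fhn_topology"`.
#' @param branching leaves added per parent node (>= 1).
#' @param depth number of growth layers (>= 0; 0 returns the topology
#'   unchanged).
#' @return A list of class `"fhn_grown_topology"` with the enlarged
#'   adjacency, conductances, the core size, and `layers` giving each
#'   node's growth generation (0 for core nodes).
#' @export
grow_cayley <- function(top, branching, depth) {
  stopifnot(inherits(top, "fhn_topology"))
  branching <- as.integer(branching); depth <- as.integer(depth)
  if (branching < 1L) stop("'branching' must be >= 1", call. = FALSE)
  if (depth < 0L) stop("'depth' must be >= 0", call. = FALSE)
  adj <- top$adj; f <- top$f; gmax <- top$gmax
  layer <- rep(0L, top$N)
  frontier <- seq_len(top$N)
  for (k in seq_len(depth)) {
    new_frontier <- integer(0)
    for (p in frontier) {
      kids <- length(adj) + seq_len(branching)
      for (kid in kids) adj[[kid]] <- p
      adj[[p]] <- sort(c(adj[[p]], kids))
      f <- c(f, rep(f[p], branching))
      gmax <- c(gmax, rep(gmax[p], branching))
      layer <- c(layer, rep(k, branching))
      new_frontier <- c(new_frontier, kids)
    }
    frontier <- new_frontier
  }
  structure(list(N = length(adj), core = top, adj = adj, f = f,
                 gmax = gmax, layers = layer),
            class = "fhn_grown_topology")
}

#' @export
print.fhn_grown_topology <- function(x, ...) {
  cat(sprintf("Cayley-grown network: %d nodes (%d core + %d periphery)\n",
              x$N, x$core$N, x$N - x$core$N))
  invisible(x)
}

#' Write / read a topology as plain-text CSV
#'
#' Serialises a topology as two CSV files: an edge list (`source,target`)
#' and a node-attribute table (`node,f,gmax`), both 1-based.
#'
#' @param top an `"fhn_topology"`.
#' @param edge_file,node_file output paths.
#' @return `write_topology_csv` returns the paths invisibly;
#'   `read_topology_csv` reconstructs a validated `"fhn_topology"` (the
#'   loop/branch structure is re-derived from `N`, `n`, `i0` stored in a
#'   comment header of the node file).
#' @export
write_topology_csv <- function(top, edge_file, node_file) {
  stopifnot(inherits(top, "fhn_topology"))
  utils::write.csv(edge_list(top), edge_file, row.names = FALSE)
  con <- file(node_file, "w")
  writeLines(sprintf("# N=%d n=%d i0=%d", top$N, top$n, top$i0), con)
  utils::write.csv(
    data.frame(node = seq_len(top$N), f = top$f, gmax = top$gmax),
    con, row.names = FALSE)
  close(con)
  invisible(c(edge_file, node_file))
}

#' @rdname write_topology_csv
#' @export
read_topology_csv <- function(edge_file, node_file) {
  hdr <- readLines(node_file, n = 1L)
  m <- regmatches(hdr, regexec("N=(\\d+) n=(\\d+) i0=(\\d+)", hdr))[[1]]
  if (length(m) != 4L)
    stop("node file lacks the '# N=.. n=.. i0=..' header", call. = FALSE)
  dims <- as.integer(m[2:4])
  nodes <- utils::read.csv(node_file, comment.char = "#")
  top <- build_loop_branch(dims[1], dims[2], dims[3],
                           scheme = het_two_constant(allow_equal = TRUE,
                                                     f_b = 0, f_r = 0))
  top$f <- nodes$f[order(nodes$node)]
  top$gmax <- nodes$gmax[order(nodes$node)]
  edges <- utils::read.csv(edge_file)
  stored <- edge_list(top)
  got <- edges[order(edges$source, edges$target), ]
  if (!identical(unname(as.matrix(got)), unname(as.matrix(stored))))
    stop("edge list does not match a loop-plus-branch topology with the ",
         "declared N, n, i0", call. = FALSE)
  top
}

# Node sequences of the two cycles, starting at node 1.
# small: 1,2,...,n; large: 1,2,...,i0,N,N-1,...,n+1.
cycle_nodes <- function(top) {
  list(small = seq_len(top$n),
       large = c(seq_len(top$i0), seq(top$N, top$n + 1L)))
}

# Breadth-first equal-distance oracle for the collision midpoint of one
# cycle: two unit-speed fronts leave node 1 in opposite directions; the
# last node reached (ties broken toward the lower index, matching
# annihilation on an edge) is the collision node.
bfs_collision_node <- function(cyc) {
  L <- length(cyc)                       # cycle length in edges
  pos <- seq_along(cyc) - 1L
  arrival <- pmin(pos, L - pos)
  cand <- cyc[arrival == max(arrival)]
  list(node = min(cand), frac_steps = L / 2)
}
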