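#' Inter-spike intervals of a node
#'
#' @param raster a `"spike_raster"` (or `"fhn_sim"`).
#' @param node 1-based node index.
#' @param window optional `c(from, to)` time window.
#' @return Numeric vector of successive spike-time differences (empty with
#'   fewer than two spikes).
#' @export
interspike_intervals <- function(raster, node, window = NULL) {
  s <- spike_times(raster, node)
  if (!is.null(window)) s <- s[s >= window[1] & s <= window[2]]
  if (length(s) < 2) numeric(0) else diff(s)
}

#' Classify a raster as no-memory, STM or LTM
#'
#' A raster with no spikes at all is `"none"`. Activity that outlives the
#' stimulus by more than `persistence_window` (any spike in
#' `[T0 + persistence_window, t_end]`) is a self-sustained long-term-memory
#' (LTM) pattern; activity that dies out within the window after switch-off
#' is short-term memory (STM).
#'
#' @param raster a `"spike_raster"` (or `"fhn_sim"`).
#' @param T0 stimulus switch-off time.
#' @param persistence_window survival margin after `T0` (model time units).
#' @return `"none"`, `"STM"` or `"LTM"`.
#' @export
classify_memory <- function(raster, T0, persistence_window = 700) {
  if (inherits(raster, "fhn_sim")) raster <- raster$raster
  stopifnot(inherits(raster, "spike_raster"))
  if (raster$t_end < T0 + 2 * persistence_window)
    stop("t_end must reach at least T0 + 2*persistence_window for a ",
         "reliable STM/LTM call", call. = FALSE)
  all_sp <- unlist(raster$spikes, use.names = FALSE)
  if (length(all_sp) == 0) return("none")
  if (any(all_sp >= T0 + persistence_window)) "LTM" else "STM"
}

#' Repetition period of a self-sustained spike train
#'
#' Finds the smallest period `P > 0` such that the node's post-transient
#' spike train, shifted by `P`, matches itself with every spike paired
#' within `tol`. Candidate periods are the cumulative sums of the observed
#' inter-spike intervals.
#'
#' @param raster a `"spike_raster"` (or `"fhn_sim"`).
#' @param node reference node.
#' @param t_start start of the search window (past the post-switch-off
#'   transient).
#' @param tol spike-pairing jitter tolerance (model time units).
#' @param min_reps minimum number of full repetitions that must fit in the
#'   record for a period to be accepted.
#' @return The period, or `NULL` when none is found (or fewer than 3
#'   spikes).
#' @export
pattern_period <- function(raster, node, t_start, tol = 1.0, min_reps = 2) {
  s <- spike_times(raster, node)
  s <- s[s >= t_start]
  if (length(s) < 3) return(NULL)
  span <- s[length(s)] - s[1]
  cand <- cumsum(diff(s))
  cand <- cand[cand > tol & cand <= span / min_reps]
  for (P in cand) {
    a <- s[s <= s[length(s)] - P + tol]
    b <- s[s >= s[1] + P - tol]
    if (length(a) < 2 || length(a) != length(b)) next
    if (all(abs(a + P - b) <= tol)) return(P)
  }
  NULL
}

#' Spikes per pattern period (S_p)
#'
#' The stabilised spiking number of a long-term-memory pattern: the number
#' of spikes the reference node fires within one repetition period of the
#' self-sustained pattern. Zero when the pattern is extinct (STM or none);
#' `NA` when activity persists but no clean period is detected (flagged
#' irregular).
#'
#' @param raster a `"spike_raster"` (or `"fhn_sim"`).
#' @param top the `"fhn_topology"` (supplies the default reference node,
#'   the junction `i0`, which becomes the new source after switch-off).
#' @param T0 stimulus switch-off time.
#' @param reference_node override the reference node.
#' @param transient time excluded after `T0` before the period search.
#' @param persistence_window as in [classify_memory()].
#' @param tol period-matching jitter tolerance.
#' @return Integer count, 0, or `NA` (irregular persistent activity).
#' @export
spiking_number <- function(raster, top, T0, reference_node = top$i0,
                           transient = 400, persistence_window = 700,
                           tol = 1.0) {
  if (inherits(raster, "fhn_sim")) raster <- raster$raster
  label <- classify_memory(raster, T0, persistence_window)
  if (label != "LTM") return(0L)
  t_start <- T0 + transient
  P <- pattern_period(raster, reference_node, t_start, tol = tol)
  if (is.null(P)) return(NA_integer_)
  s <- spike_times(raster, reference_node)
  s <- s[s >= t_start]
  sum(s >= s[1] & s < s[1] + P - tol / 2)
}

#' Phase-locking profile of loop and branch groups
#'
#' Median inter-spike interval over the loop nodes (`1..n`) and the branch
#' nodes (`n+1..N`) within a steady-state window, and their locking ratio
#' reduced to small integers when the two medians are within `ratio_tol`
#' of an integer multiple (`"irregular"` otherwise).
#'
#' @param raster a `"spike_raster"` (or `"fhn_sim"`).
#' @param top the `"fhn_topology"`.
#' @param window `c(from, to)` within the stimulus-on steady state.
#' @param ratio_tol relative tolerance for integer locking ratios.
#' @return List with `loop_isi`, `branch_isi`, `ratio` (e.g. `"2:1"`), and
#'   the per-node medians.
#' @export
locking_profile <- function(raster, top, window, ratio_tol = 0.1) {
  if (inherits(raster, "fhn_sim")) raster <- raster$raster
  per_node <- vapply(seq_len(top$N), function(i) {
    x <- interspike_intervals(raster, i, window)
    if (length(x)) stats::median(x) else NA_real_
  }, numeric(1))
  loop <- stats::median(per_node[seq_len(top$n)], na.rm = TRUE)
  branch <- stats::median(per_node[seq(top$n + 1L, top$N)], na.rm = TRUE)
  if (!is.finite(loop) || !is.finite(branch))
    stop("insufficient spikes in the window for a locking profile",
         call. = FALSE)
  hi <- max(loop, branch); lo <- min(loop, branch)
  mult <- hi / lo
  ratio <- if (abs(mult - round(mult)) <= ratio_tol * round(mult)) {
    k <- round(mult)
    if (loop >= branch) sprintf("%d:1", k) else sprintf("1:%d", k)
  } else "irregular"
  list(loop_isi = loop, branch_isi = branch, ratio = ratio,
       per_node = per_node)
}

#' Observed wavefront collision nodes
#'
#' For one wavefront-pair episode per cycle, locates the annihilation
#' node: the cycle node with the latest spike inside the episode, whose
#' neighbours on the cycle both spiked earlier (the two fronts arrive and
#' stop there).
#'
#' @param raster a `"spike_raster"` (or `"fhn_sim"`).
#' @param top the `"fhn_topology"`.
#' @param episode `c(from, to)` containing exactly one wavefront pair per
#'   cycle.
#' @return List with `i_m1` (small loop) and `i_m2` (large loop); `NA` for
#'   a cycle with no spikes in the episode.
#' @export
observed_collision_nodes <- function(raster, top, episode) {
  if (inherits(raster, "fhn_sim")) raster <- raster$raster
  cyc <- cycle_nodes(top)
  locate <- function(nodes) {
    tt <- vapply(nodes, function(i) {
      s <- spike_times(raster, i)
      s <- s[s >= episode[1] & s <= episode[2]]
      if (length(s)) s[1] else NA_real_
    }, numeric(1))
    if (all(is.na(tt))) return(NA_integer_)
    if (anyNA(tt))
      stop("episode window does not cover a full wavefront pair",
           call. = FALSE)
    nodes[which.max(tt)]
  }
  list(i_m1 = locate(cyc$small), i_m2 = locate(cyc$large))
}

#' Wavefront counts along the two large-loop paths
#'
#' Counts distinct active wavefronts at time `t` on the two paths of the
#' large loop: `l1` along `1 -> n+1 -> ... -> i_m2` (the branch side) and
#' `l2` along `1 -> 2 -> ... -> i0 -> N -> ... -> i_m2`. A node is at a
#' front when its latest spike lies within one transit time of `t`;
#' maximal runs of such nodes along a path count as one front each. The
#' transit time is the median nearest-neighbour spike-time difference
#' along the path near `t`.
#'
#' @param raster a `"spike_raster"` (or `"fhn_sim"`).
#' @param top the `"fhn_topology"`.
#' @param t evaluation time.
#' @return List with `l1`, `l2` and the transit-time estimate.
#' @export
path_firing_counts <- function(raster, top, t) {
  if (inherits(raster, "fhn_sim")) raster <- raster$raster
  pred <- predicted_collision_nodes(top)
  path1 <- seq(top$n + 1L, max(top$n + 1L, pred$i_m2))
  path2 <- c(seq_len(top$i0), seq(top$N, max(pred$i_m2, top$n + 1L)))
  last_before <- function(i) {
    s <- spike_times(raster, i)
    s <- s[s <= t]
    if (length(s)) s[length(s)] else -Inf
  }
  transit_est <- function(path) {
    lt <- vapply(path, last_before, numeric(1))
    d <- abs(diff(lt))
    d <- d[is.finite(d) & d > 0]
    if (length(d)) stats::median(d) else NA_real_
  }
  count_fronts <- function(path, transit) {
    lt <- vapply(path, last_before, numeric(1))
    if (!is.finite(transit)) return(0L)
    active <- (t - lt) <= 2 * transit
    r <- rle(active)
    sum(r$values)
  }
  tr <- stats::median(c(transit_est(path1), transit_est(path2)), na.rm = TRUE)
  list(l1 = count_fronts(path1, tr), l2 = count_fronts(path2, tr),
       transit = tr)
}

#' Full pattern summary of a simulation
#'
#' Bundles the memory observables of one switch-off run: STM/LTM label,
#' spikes per period `S_p`, pattern period, and (when a stimulus-on steady
#' window is available) the locking profile.
#'
#' @param sim an `"fhn_sim"` from a run with finite `T0`.
#' @param reference_node node whose train defines `S_p` (default: the
#'   junction `i0`, the post-switch-off source).
#' @param persistence_window,transient,tol as in the component functions.
#' @return An object of class `"pattern_summary"`.
#' @export
pattern_summary <- function(sim, reference_node = sim$top$i0,
                            persistence_window = 700, transient = 400,
                            tol = 1.0) {
  stopifnot(inherits(sim, "fhn_sim"))
  T0 <- sim$stim$T0
  if (!is.finite(T0))
    stop("pattern_summary needs a finite switch-off time T0", call. = FALSE)
  label <- classify_memory(sim$raster, T0, persistence_window)
  P <- if (label == "LTM")
    pattern_period(sim$raster, reference_node, T0 + transient, tol = tol)
  else NULL
  sp <- spiking_number(sim$raster, sim$top, T0,
                       reference_node = reference_node,
                       transient = transient,
                       persistence_window = persistence_window, tol = tol)
  lock <- tryCatch(
    locking_profile(sim$raster, sim$top,
                    window = c(max(0, T0 - 600), T0)),
    error = function(e) NULL)
  structure(list(label = label, S_p = sp, period = P,
                 reference_node = reference_node, locking = lock,
                 T0 = T0),
            class = "pattern_summary")
}

#' @export
print.pattern_summary <- function(x, ...) {
  cat(sprintf("Memory pattern: %s (stimulus off at T0 = %g)\n", x$label,
              x$T0))
  if (x$label == "LTM") {
    if (!is.null(x$period))
      cat(sprintf("  period %.2f, S_p = %s at node %d\n", x$period,
                  format(x$S_p), x$reference_node))
    else cat("  persistent but irregular (no clean period)\n")
  }
  if (!is.null(x$locking))
    cat(sprintf("  stimulus-on locking: loop ISI %.2f, branch ISI %.2f (%s)\n",
                x$locking$loop_isi, x$locking$branch_isi, x$locking$ratio))
  invisible(x)
}
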