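#' Recovery nullcline
#'
#' The slow-variable nullcline of the excitable neuron,
#' \eqn{\dot v = 0 \Rightarrow v = -(a u + d)/b}.
#'
#' @param u fast-variable value(s).
#' @param fhn an [fhn_params()].
#' @return Recovery value(s) on the nullcline.
#' @examples
#' v_nullcline(c(-1, 1))  # -0.375, 2.125
#' @export
v_nullcline <- function(u, fhn = fhn_params()) {
  stopifnot(inherits(fhn, "fhn_params"))
  if (fhn$b == 0) stop("'b' must be nonzero", call. = FALSE)
  -(fhn$a * u + fhn$d) / fhn$b
}

#' Current on the fast nullcline
#'
#' The input current that zeroes the fast equation at `(u, v)`:
#' \eqn{I = v - (u - u^3/3)}.
#'
#' @param u,v phase-plane point(s).
#' @return Current value(s).
#' @examples
#' u_nullcline_current(-1, -0.375)  # 0.29166... = I_L
#' @export
u_nullcline_current <- function(u, v) {
  v - (u - u^3 / 3)
}

#' Knee points of the cubic nullcline
#'
#' The fast nullcline \eqn{v = u - u^3/3 + I} has fold (knee) points at
#' \eqn{u = \mp 1} regardless of the recovery parameters. Evaluating the
#' recovery nullcline there gives \eqn{v_L, v_R}, and substituting back
#' gives the boundary currents \eqn{I_L, I_R} of the firing window: a
#' constant input elicits firing iff \eqn{I_L < I < I_R}. With the default
#' parameters \eqn{(v_L, v_R, I_L, I_R) = (-0.375, 2.125, 0.2917, 1.4583)}.
#'
#' @param fhn an [fhn_params()].
#' @return An object of class `"nullcline_summary"` with fields `v_L`,
#'   `v_R`, `I_L`, `I_R`, the interval `I_range`, the uncoupled rest state
#'   `u_rest`, `v_rest`, and `f_max` (see [max_baseline_f()]).
#' @examples
#' knee_points()
#' @export
knee_points <- function(fhn = fhn_params()) {
  stopifnot(inherits(fhn, "fhn_params"))
  v_L <- v_nullcline(-1, fhn)
  v_R <- v_nullcline(+1, fhn)
  I_L <- u_nullcline_current(-1, v_L)
  I_R <- u_nullcline_current(+1, v_R)
  rest <- rest_state(fhn, f_total = 0)
  structure(list(v_L = v_L, v_R = v_R, I_L = I_L, I_R = I_R,
                 I_range = c(I_L, I_R),
                 u_rest = rest$u, v_rest = rest$v,
                 f_max = max_baseline_f(fhn)),
            class = "nullcline_summary")
}

#' @export
print.nullcline_summary <- function(x, ...) {
  cat("Nullcline knee analysis\n")
  cat(sprintf("  v_L = %.4f, v_R = %.4f\n", x$v_L, x$v_R))
  cat(sprintf("  firing window I_range = [%.4f, %.4f]\n", x$I_L, x$I_R))
  cat(sprintf("  uncoupled rest state (u*, v*) = (%.4f, %.4f)\n",
              x$u_rest, x$v_rest))
  cat(sprintf("  f_max = %.4f\n", x$f_max))
  invisible(x)
}

#' Firing window
#'
#' @param fhn an [fhn_params()].
#' @return Numeric `c(I_L, I_R)`: a constant input current elicits firing
#'   iff it lies strictly inside this open interval.
#' @export
firing_window <- function(fhn = fhn_params()) {
  k <- knee_points(fhn)
  c(I_L = k$I_L, I_R = k$I_R)
}

#' @rdname firing_window
#' @param I current(s) to test.
#' @return `in_firing_window` returns a logical: strictly inside the window.
#' @export
in_firing_window <- function(I, fhn = fhn_params()) {
  w <- firing_window(fhn)
  I > w[[1]] & I < w[[2]]
}

#' Maximal baseline conductance
#'
#' A quiescent node of degree `k` receives the resting current
#' \eqn{-\sum f_j u_j \approx k f |u_{rest}|}; excitability (no spontaneous
#' firing) requires it below \eqn{I_L}, giving per-neighbour
#' \deqn{f_{max} = \frac{I_L / k}{|u_{rest}|}.}
#' With the empirical rest magnitude 1.5 and the degree-3 sensory node this
#' is \eqn{0.0972 / 1.5 \approx 0.065}. The literal variant uses the
#' supplied `u_rest_mag`; set `self_consistent = TRUE` to substitute the
#' computed uncoupled rest magnitude instead.
#'
#' @param fhn an [fhn_params()].
#' @param u_rest_mag magnitude of the rest-state fast variable (the
#'   simulation-derived value 1.5 by default).
#' @param degree node degree (3 for the sensory and junction nodes).
#' @param self_consistent replace `u_rest_mag` by `|u*|` of the computed
#'   uncoupled fixed point.
#' @return `f_max` (same units as `f` and `g_max`).
#' @examples
#' max_baseline_f()                     # ~ 0.0648
#' max_baseline_f(self_consistent = TRUE)
#' @export
max_baseline_f <- function(fhn = fhn_params(), u_rest_mag = 1.5, degree = 3,
                           self_consistent = FALSE) {
  stopifnot(degree >= 1, u_rest_mag > 0)
  if (self_consistent)
    u_rest_mag <- abs(rest_state(fhn, 0)$u)
  v_L <- v_nullcline(-1, fhn)
  I_L <- u_nullcline_current(-1, v_L)
  (I_L / degree) / u_rest_mag
}

#' Rest state of a (possibly coupled) quiescent neuron
#'
#' Solves for the left-branch fixed point of
#' \eqn{u - u^3/3 - v - f_{tot} u = 0} jointly with the recovery nullcline,
#' where `f_total` is the summed baseline conductance of the incident
#' synapses (with reversal potential 0, quiescent neighbours at the same
#' rest value contribute the leak term \eqn{-f_{tot} u}). With `f_total =
#' 0` this is the uncoupled fixed point, \eqn{(u^*, v^*) \approx (-1.1994,
#' -0.6243)} at the default parameters.
#'
#' @param fhn an [fhn_params()].
#' @param f_total summed incident baseline conductance (>= 0).
#' @return List with `u`, `v` and the two nullcline residuals.
#' @export
rest_state <- function(fhn = fhn_params(), f_total = 0) {
  stopifnot(inherits(fhn, "fhn_params"), f_total >= 0)
  g <- function(u)
    u - u^3 / 3 - v_nullcline(u, fhn) - f_total * u
  # left branch: u < -1; bracket generously
  lo <- -10
  if (g(lo) * g(-1) > 0)
    stop("no left-branch fixed point for these parameters", call. = FALSE)
  r <- stats::uniroot(g, c(lo, -1), tol = 1e-14)
  u <- r$root
  v <- v_nullcline(u, fhn)
  list(u = u, v = v,
       residual_fast = u - u^3 / 3 - v - f_total * u,
       residual_slow = fhn$a * u + fhn$b * v + fhn$d)
}

#' Stimulus feasibility for the sensory node
#'
#' For the sensory node at rest (fast variable near \eqn{-1.5}) with
#' neighbour baseline conductances \eqn{f_b, f_b, f_r}, the sinusoidal
#' drive \eqn{A \sin(\omega t) + B} can push the total input past the left
#' knee iff \eqn{B > I_L - 1.5 (2 f_b + f_r)} (for any `A`), or failing
#' that \eqn{A > I_L - 1.5 (2 f_b + f_r) - B}.
#'
#' @param A,B stimulus amplitude and offset.
#' @param f_b,f_r loop and branch baseline conductances.
#' @param fhn an [fhn_params()].
#' @param u_rest_mag rest-state magnitude used in the resting-current
#'   estimate.
#' @return List with logical `feasible`, which condition holds
#'   (`"offset"`, `"amplitude"` or `"none"`), and the `threshold`
#'   \eqn{I_L - 1.5(2 f_b + f_r)}.
#' @examples
#' stimulus_feasible(A = 1, B = 1.2, f_b = 0.031, f_r = 0.05)
#' @export
stimulus_feasible <- function(A, B, f_b, f_r, fhn = fhn_params(),
                              u_rest_mag = 1.5) {
  stopifnot(A >= 0, f_b >= 0, f_r >= 0)
  v_L <- v_nullcline(-1, fhn)
  I_L <- u_nullcline_current(-1, v_L)
  threshold <- I_L - u_rest_mag * (2 * f_b + f_r)
  by <- if (B > threshold) "offset"
        else if (A > threshold - B) "amplitude"
        else "none"
  list(feasible = by != "none", condition = by, threshold = threshold)
}
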