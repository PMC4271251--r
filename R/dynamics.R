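#' FitzHugh-Nagumo right-hand side
#'
#' The single-neuron vector field
#' \deqn{\dot u = (u - u^3/3 - v + I_{sum})/\epsilon, \qquad
#'       \dot v = a u + b v + d.}
#' These pure-R dynamics primitives mirror the compiled integrator exactly
#' and serve as its reference implementation in tests.
#'
#' @param u,v state variables.
#' @param fhn an [fhn_params()].
#' @param I_sum total input current.
#' @return Named numeric `c(du, dv)`.
#' @examples
#' fhn_derivatives(-1, -0.375, I_sum = 7/24)  # du = 0 at the left knee
#' @export
fhn_derivatives <- function(u, v, fhn = fhn_params(), I_sum = 0) {
  stopifnot(is.finite(u), is.finite(v), is.finite(I_sum))
  c(du = (u - u^3 / 3 - v + I_sum) / fhn$epsilon,
    dv = fhn$a * u + fhn$b * v + fhn$d)
}

# peak time and height of the raw dual-exponential transient
dual_exp_peak <- function(syn) {
  tstar <- syn$tau_d * syn$tau_r / (syn$tau_d - syn$tau_r) *
    log(syn$tau_d / syn$tau_r)
  list(t = tstar,
       value = exp(-tstar / syn$tau_d) - exp(-tstar / syn$tau_r))
}

#' Synaptic gating value
#'
#' The dimensionless conductance transient of one presynaptic neuron at
#' time `t`, summed additively over its past spikes:
#' \deqn{s(t) = \sum_{t_k : t > t_k + \tau}
#'   \left[e^{-(t - t_k - \tau)/\tau_d} - e^{-(t - t_k - \tau)/\tau_r}\right].}
#' A spike contributes nothing until its transient matures at
#' \eqn{t_k + \tau}. With `normalize = TRUE` in the synapse parameters each
#' transient is rescaled to unit peak.
#'
#' @param spike_times ascending presynaptic spike times.
#' @param t evaluation time(s).
#' @param syn a [synapse_params()].
#' @return Nonnegative gating value(s).
#' @export
gating_value <- function(spike_times, t, syn = synapse_params()) {
  stopifnot(!is.unsorted(spike_times))
  scale <- if (syn$normalize) 1 / dual_exp_peak(syn)$value else 1
  vapply(t, function(tt) {
    dt <- tt - spike_times - syn$tau
    dt <- dt[dt > 0]
    scale * sum(exp(-dt / syn$tau_d) - exp(-dt / syn$tau_r))
  }, numeric(1))
}

#' Synaptic current onto a postsynaptic neuron
#'
#' \deqn{I = (f_{pre} + g_{max,pre}\, s_{pre})\,(u_{syn} - u_{post}).}
#' At rest (`s = 0`, `u_syn = 0`) this reduces to the baseline leak
#' \eqn{-f_{pre} u_{post}}.
#'
#' @param f_pre presynaptic baseline conductance.
#' @param s_pre presynaptic gating value.
#' @param u_post postsynaptic fast variable.
#' @param syn a [synapse_params()].
#' @param gmax_pre presynaptic maximal conductance (defaults to the
#'   synapse parameter).
#' @return Current.
#' @export
synaptic_current <- function(f_pre, s_pre, u_post, syn = synapse_params(),
                             gmax_pre = syn$g_max) {
  stopifnot(all(s_pre >= 0))
  (f_pre + gmax_pre * s_pre) * (syn$u_syn - u_post)
}

#' Total input current of a node
#'
#' Sums the synaptic currents from all neighbours (using each neighbour's
#' presynaptic `f` and `g_max`) plus the external stimulus when the node is
#' the stimulus target.
#'
#' @param node 1-based node index.
#' @param u_all per-node fast variables.
#' @param s_all per-node gating values.
#' @param top an `"fhn_topology"`.
#' @param syn a [synapse_params()].
#' @param I_ext_t external current at the evaluation time.
#' @param target stimulated node.
#' @return Current `I_sum`.
#' @export
total_input <- function(node, u_all, s_all, top, syn = synapse_params(),
                        I_ext_t = 0, target = 1L) {
  nb <- neighbors(top, node)
  I <- sum(synaptic_current(top$f[nb], s_all[nb], u_all[node], syn,
                            gmax_pre = top$gmax[nb]))
  if (node == target) I <- I + I_ext_t
  I
}

#' Linear-interpolation spike detector
#'
#' Reports the upward crossing time of the threshold between two
#' consecutive samples, or `NULL` when no upward crossing occurs.
#'
#' @param u_prev,u_next fast-variable samples at `t_prev` and
#'   `t_prev + dt`.
#' @param t_prev,dt sample time and step.
#' @param u_th threshold.
#' @return Crossing time, or `NULL`.
#' @export
detect_spike_crossing <- function(u_prev, u_next, t_prev, dt, u_th = 0) {
  stopifnot(is.finite(u_prev), is.finite(u_next))
  if (u_prev < u_th && u_next >= u_th)
    t_prev + dt * (u_th - u_prev) / (u_next - u_prev)
  else NULL
}
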