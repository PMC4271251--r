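#' FitzHugh-Nagumo neuron parameters
#'
#' Parameters of the two-variable excitable neuron
#' \deqn{\epsilon \dot u = u - u^3/3 - v + I_{sum}, \qquad
#'       \dot v = a u + b v + d,}
#' where \eqn{u} is the fast (voltage-like) variable and \eqn{v} the slow
#' recovery variable. The defaults place the uncoupled fixed point on the
#' left stable branch of the cubic nullcline, so an isolated neuron is
#' excitable: it fires once when pushed past the left knee and is silent
#' otherwise.
#'
#' @param epsilon fast/slow time-scale separation; must lie in (0, 0.1].
#' @param a,b,d recovery-equation coefficients; `b` must be negative in the
#'   default excitable regime.
#' @return An object of class `"fhn_params"`.
#' @examples
#' fhn_params()
#' @export
fhn_params <- function(epsilon = 0.01, a = 0.08, b = -0.064, d = 0.056) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, is.finite(epsilon))
  if (epsilon <= 0 || epsilon > 0.1)
    stop("'epsilon' must lie in (0, 0.1]", call. = FALSE)
  if (!is.finite(a) || !is.finite(b) || !is.finite(d))
    stop("'a', 'b', 'd' must be finite", call. = FALSE)
  if (b >= 0)
    stop("'b' must be negative (recovery decay) in the excitable regime",
         call. = FALSE)
  structure(list(epsilon = epsilon, a = a, b = b, d = d),
            class = "fhn_params")
}

#' @export
print.fhn_params <- function(x, ...) {
  cat("FitzHugh-Nagumo parameters\n")
  cat(sprintf("  epsilon = %g, a = %g, b = %g, d = %g\n",
              x$epsilon, x$a, x$b, x$d))
  invisible(x)
}

#' Chemical synapse parameters
#'
#' The synaptic conductance seen by a postsynaptic neuron from presynaptic
#' neuron \eqn{j} is \eqn{g_{syn}(t) = f_j + g_{max} s_j(t)} where
#' \eqn{f_j} is the baseline (steady-state open-channel) conductance and
#' \deqn{s_j(t) = \sum_k \left[e^{-(t - t_k - \tau)/\tau_d}
#'   - e^{-(t - t_k - \tau)/\tau_r}\right] \Theta(t - t_k - \tau)}
#' is the delayed dual-exponential transient summed over presynaptic spike
#' times \eqn{t_k}. The synaptic current is
#' \eqn{I = g_{syn} (u_{syn} - u_{post})}.
#'
#' @param g_max maximal synaptic conductance (mS/cm^2).
#' @param u_syn synaptic reversal potential.
#' @param tau axonal/synaptic delay between a presynaptic spike and the
#'   onset of the conductance transient (model time units).
#' @param tau_d,tau_r decay and rise time constants of the transient;
#'   `tau_r < tau_d` required.
#' @param u_th presynaptic spike-detection threshold on the fast variable.
#' @param debounce minimum separation between detected spikes of one
#'   neuron (model time units); well below any observed inter-spike
#'   interval.
#' @param normalize if `TRUE` (the default) the dual-exponential is
#'   rescaled so its peak equals exactly 1, making `g_max` the peak
#'   transient conductance; `FALSE` keeps the raw difference of
#'   exponentials (peak about 0.774). The normalized form is the package's
#'   calibrated choice: with the raw form at the standard parameters the
#'   network produces no self-sustained patterns at all (see the methods
#'   vignette).
#' @return An object of class `"synapse_params"`.
#' @examples
#' synapse_params()
#' @export
synapse_params <- function(g_max = 0.35, u_syn = 0, tau = 0.5,
                           tau_d = 10, tau_r = 1,
                           u_th = 0, debounce = 5, normalize = TRUE) {
  stopifnot(is.numeric(g_max), is.numeric(tau), is.numeric(tau_d),
            is.numeric(tau_r))
  if (g_max <= 0) stop("'g_max' must be positive", call. = FALSE)
  if (tau < 0) stop("'tau' must be nonnegative", call. = FALSE)
  if (!(tau_r > 0 && tau_r < tau_d))
    stop("need 0 < tau_r < tau_d", call. = FALSE)
  if (debounce <= 0) stop("'debounce' must be positive", call. = FALSE)
  structure(list(g_max = g_max, u_syn = u_syn, tau = tau,
                 tau_d = tau_d, tau_r = tau_r,
                 u_th = u_th, debounce = debounce,
                 normalize = isTRUE(normalize)),
            class = "synapse_params")
}

#' @export
print.synapse_params <- function(x, ...) {
  cat("Chemical synapse parameters\n")
  cat(sprintf("  g_max = %g, u_syn = %g, tau = %g, tau_d = %g, tau_r = %g\n",
              x$g_max, x$u_syn, x$tau, x$tau_d, x$tau_r))
  cat(sprintf("  spike threshold u_th = %g, debounce = %g%s\n",
              x$u_th, x$debounce,
              if (x$normalize) ", peak-normalized transient" else ""))
  invisible(x)
}

#' Simulation configuration
#'
#' @param dt integration step (model time units); must satisfy
#'   `dt <= epsilon` of the neuron parameters and `dt <= 0.01`.
#' @param t_end end time of the recorded simulation (stimulus onset is
#'   `t = 0`).
#' @param settle pre-stimulus settling duration: the network is integrated
#'   with full coupling and no stimulus for `t` in `[-settle, 0)`;
#'   excluded from all analyses.
#' @param record_stride decimation factor for trajectory recording.
#' @param seed integer seed; consumed only by Gaussian heterogeneity
#'   schemes.
#' @param blowup_bound hard bound on `|u|`; an excursion beyond it aborts
#'   the run (it signals a mis-specified model, not a numerical issue).
#' @return An object of class `"sim_config"`.
#' @examples
#' sim_config(t_end = 500)
#' @export
sim_config <- function(dt = 0.005, t_end = 3000, settle = 200,
                       record_stride = 100L, seed = 1L,
                       blowup_bound = 5) {
  if (!(dt > 0 && dt <= 0.01)) stop("need 0 < dt <= 0.01", call. = FALSE)
  if (t_end <= 0) stop("'t_end' must be positive", call. = FALSE)
  if (settle < 0) stop("'settle' must be nonnegative", call. = FALSE)
  record_stride <- as.integer(record_stride)
  if (record_stride < 1L) stop("'record_stride' must be >= 1", call. = FALSE)
  structure(list(dt = dt, t_end = t_end, settle = settle,
                 record_stride = record_stride, seed = as.integer(seed),
                 blowup_bound = blowup_bound),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: dt = %g, t_end = %g, settle = %g, stride = %d, seed = %d\n",
    x$dt, x$t_end, x$settle, x$record_stride, x$seed))
  invisible(x)
}
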