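#' Sensory-node stimulus protocol
#'
#' The external drive applied to the sensory node:
#' \eqn{I_{ext}(t) = A \sin(\omega t) + B} for \eqn{0 \le t < T_0} and
#' exactly 0 from the switch-off time \eqn{T_0} on. Stimulus onset defines
#' `t = 0`; the network is settled at rest beforehand.
#'
#' @param A amplitude (>= 0).
#' @param B offset.
#' @param omega angular frequency (radians per model time unit, > 0).
#' @param T0 switch-off time; `Inf` for a persistent stimulus.
#' @param target stimulated node index (the sensory node, 1).
#' @return An object of class `"stimulus_protocol"`.
#' @examples
#' p <- stimulus_protocol(A = 1, B = 1.2, omega = 0.5, T0 = 1600)
#' external_current(p, c(0, pi, 1600))
#' @export
stimulus_protocol <- function(A = 1, B = 1.2, omega = 0.5, T0 = Inf,
                              target = 1L) {
  stopifnot(is.numeric(A), is.numeric(B), is.numeric(omega))
  if (A < 0) stop("'A' must be nonnegative", call. = FALSE)
  if (omega <= 0) stop("'omega' must be positive", call. = FALSE)
  if (!(T0 > 0)) stop("'T0' must be positive (or Inf)", call. = FALSE)
  structure(list(A = A, B = B, omega = omega, T0 = T0,
                 target = as.integer(target)),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("Stimulus on node %d: I_ext(t) = %g sin(%g t) + %g", x$target,
              x$A, x$omega, x$B))
  if (is.finite(x$T0)) cat(sprintf(", switched off at t = %g", x$T0))
  cat("\n")
  invisible(x)
}

#' Evaluate the external current
#'
#' @param p a [stimulus_protocol()].
#' @param t time(s), >= 0.
#' @return \eqn{A \sin(\omega t) + B} for `t < T0`, 0 for `t >= T0`.
#' @export
external_current <- function(p, t) {
  stopifnot(inherits(p, "stimulus_protocol"), all(t >= 0))
  ifelse(t < p$T0, p$A * sin(p$omega * t) + p$B, 0)
}
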