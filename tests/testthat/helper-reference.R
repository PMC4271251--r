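# Slow pure-R reference integrator: RK4 over the same network equations,
# with synaptic gating evaluated by the closed-form gating_value() sum at
# every stage time (no incremental accumulators, no event queue). Used to
# validate the compiled core on tiny problems.
reference_simulation <- function(top, fhn, syn, stim, dt, t_end,
                                 settle = 50) {
  N <- top$N
  rest <- rest_state(fhn, 0)
  u <- rep(rest$u, N); v <- rep(rest$v, N)
  spikes <- vector("list", N)
  for (i in seq_len(N)) spikes[[i]] <- numeric(0)
  last <- rep(-Inf, N)
  nb <- top$adj
  scale <- if (syn$normalize) 1 / fhnmem:::dual_exp_peak(syn)$value else 1

  gate <- function(i, t) {
    s <- spikes[[i]]
    if (!length(s)) return(0)
    d <- t - s - syn$tau
    d <- d[d > 0]
    scale * sum(exp(-d / syn$tau_d) - exp(-d / syn$tau_r))
  }
  deriv <- function(u, v, t) {
    sgl <- vapply(seq_len(N), gate, numeric(1), t = t)
    du <- numeric(N); dv <- numeric(N)
    Iext <- if (t >= 0 && t < stim$T0) stim$A * sin(stim$omega * t) + stim$B
            else 0
    for (i in seq_len(N)) {
      I <- sum((top$f[nb[[i]]] + top$gmax[nb[[i]]] * sgl[nb[[i]]]) *
                 (syn$u_syn - u[i]))
      if (i == stim$target) I <- I + Iext
      du[i] <- (u[i] - u[i]^3 / 3 - v[i] + I) / fhn$epsilon
      dv[i] <- fhn$a * u[i] + fhn$b * v[i] + fhn$d
    }
    list(du = du, dv = dv)
  }

  nstep <- round((t_end + settle) / dt)
  for (st in seq_len(nstep)) {
    t <- (st - 1) * dt - settle
    k1 <- deriv(u, v, t)
    k2 <- deriv(u + dt / 2 * k1$du, v + dt / 2 * k1$dv, t + dt / 2)
    k3 <- deriv(u + dt / 2 * k2$du, v + dt / 2 * k2$dv, t + dt / 2)
    k4 <- deriv(u + dt * k3$du, v + dt * k3$dv, t + dt)
    un <- u + dt / 6 * (k1$du + 2 * k2$du + 2 * k3$du + k4$du)
    vn <- v + dt / 6 * (k1$dv + 2 * k2$dv + 2 * k3$dv + k4$dv)
    for (i in seq_len(N)) {
      tc <- detect_spike_crossing(u[i], un[i], t, dt, syn$u_th)
      if (!is.null(tc) && tc - last[i] >= syn$debounce) {
        last[i] <- tc
        spikes[[i]] <- c(spikes[[i]], tc)
      }
    }
    u <- un; v <- vn
  }
  lapply(spikes, function(s) s[s >= 0])
}
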