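# Independent oracles and shared fixtures for the test suite.

# Exact mean first-passage time to exit for the contact-network chain:
# dense generator over the 2^n contact configurations plus an absorbing
# exit from the all-unbound state, solved as a linear system.  Written
# independently of the package's simulator.
mfpt_contact_oracle <- function(local_off, local_on, escape) {
  n <- length(local_off)
  ns <- 2L^n
  Q <- matrix(0, ns, ns)
  for (s in seq_len(ns)) {
    for (j in seq_len(n)) {
      unbound <- bitwAnd(s - 1L, bitwShiftL(1L, j - 1L)) > 0L
      tgt <- s + if (unbound) -bitwShiftL(1L, j - 1L) else
        bitwShiftL(1L, j - 1L)
      Q[s, tgt] <- if (unbound) local_on[j] else local_off[j]
    }
  }
  exit <- numeric(ns)
  exit[ns] <- escape
  diag(Q) <- -(rowSums(Q) + exit)
  # E[T] from each transient state: -Q %*% T = 1; start = all-bound (1)
  solve(-Q, rep(1, ns))[1L]
}

# default K+ concentration grid used by the titration generator
titration_grid <- c(0, 0.1, 0.3, 1, 3, 10, 30, 100)

# trace-ratio pipeline: trace pairs -> per-voltage (tau, asymptote) ->
# averaged solve -> voltage dependence of k_off (and k_on)
ratio_pipeline <- function(pairs, toxin_conc, guard = 0.1,
                           constants = phys_constants()) {
  pts <- do.call(rbind, lapply(pairs, function(p) {
    rr <- trace_ratio(p, guard)
    ff <- fit_monoexponential(rr$time, rr$ratio, weights = rr$control^2)
    if (ff$no_relaxation) return(NULL)
    data.frame(voltage = p$step_voltage, tau = ff$tau / 1000,
               asymptote = ff$baseline)
  }))
  solved <- average_then_solve(pts, toxin_conc)
  list(
    solved = solved,
    vd_off = fit_voltage_dependence(solved$voltage, solved$k_off,
                                    constants),
    vd_on = fit_voltage_dependence(solved$voltage, solved$k_on,
                                   constants)
  )
}
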