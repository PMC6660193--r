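#' Eyring activation energy from a dissociation rate
#'
#' Inverts `k_off = A0 * exp(-dG / RT)`: given the macroscopic
#' dissociation rate and an attempt frequency `A0` (default 6e12 s^-1,
#' the transition-state-theory frequency factor with transmission
#' coefficient 1), returns the activation energy `dG = RT * ln(A0/k_off)`
#' in kJ/mol.
#'
#' @param k_off Dissociation rate, s^-1 (0 < k_off <= a0).
#' @param a0 Attempt frequency, s^-1.
#' @param constants A [phys_constants()] bundle.
#'
#' @return Activation energy, kJ/mol.
#' @examples
#' barrier_from_rate(3.3)     # ~70 kJ/mol
#' barrier_from_rate(0.0061)  # ~85 kJ/mol
#' @export
barrier_from_rate <- function(k_off, a0 = 6e12,
                              constants = phys_constants()) {
  .check_scalar(k_off, "k_off", positive = TRUE)
  .check_scalar(a0, "a0", positive = TRUE)
  if (k_off > a0) {
    stop("negative barrier: k_off exceeds the attempt frequency")
  }
  rt_kj(constants) * log(a0 / k_off)
}

#' @describeIn barrier_from_rate Forward Eyring evaluation
#'   `k_off = a0 * exp(-barrier/RT)` (barrier in kJ/mol).
#' @param barrier Activation energy, kJ/mol (>= 0).
#' @export
rate_from_barrier <- function(barrier, a0 = 6e12,
                              constants = phys_constants()) {
  .check_scalar(barrier, "barrier", nonneg = TRUE)
  .check_scalar(a0, "a0", positive = TRUE)
  a0 * exp(-barrier / rt_kj(constants))
}

#' Per-contact energy under equal partitioning
#'
#' Splits a total activation energy evenly over `n` independent,
#' energetically identical contacts, returning the per-contact energy in
#' kT units and the fraction of time each contact spends unbound,
#' `exp(-energy_kT)`.
#'
#' @param barrier Total activation energy, kJ/mol.
#' @param n Number of contacts (>= 1).
#' @param constants A [phys_constants()] bundle.
#'
#' @return List with `energy_kT` and `p_unbound`.
#' @examples
#' per_contact_energy(70, 10)  # ~2.8 kT, unbound ~6% of the time
#' @export
per_contact_energy <- function(barrier, n, constants = phys_constants()) {
  .check_scalar(barrier, "barrier", nonneg = TRUE)
  .check_scalar(n, "n", positive = TRUE)
  if (n < 1 || n != round(n)) stop("'n' must be a positive integer")
  e_kt <- barrier / n / rt_kj(constants)
  list(energy_kT = e_kt, p_unbound = exp(-e_kt))
}

#' A single contact-point equilibrium
#'
#' One contact of the toxin-channel interaction surface, described by a
#' local unbound/bound equilibrium constant `k_eq` (optionally realized
#' as a local dissociation rate `local_off` over a rebinding rate
#' `local_on`) and an effective valence for voltage-sensitive contacts
#' (zero for insensitive ones).
#'
#' @param k_eq Dimensionless equilibrium constant
#'   (`local_off/local_on`).  May be omitted when both rates are given.
#' @param local_off Local dissociation rate, s^-1.
#' @param local_on Local rebinding rate, s^-1.
#' @param valence Effective valence z_j, elementary charges.
#' @param label Optional text label (e.g. a residue name).
#'
#' @return An object of class `contact_equilibrium`.
#' @examples
#' contact_equilibrium(local_off = 1e3, local_on = 2e4, valence = 0.47)
#' @export
contact_equilibrium <- function(k_eq = NULL, local_off = NULL,
                                local_on = NULL, valence = 0,
                                label = NA_character_) {
  .check_scalar(valence, "valence")
  if (!is.null(local_off)) .check_scalar(local_off, "local_off", positive = TRUE)
  if (!is.null(local_on)) .check_scalar(local_on, "local_on", positive = TRUE)
  if (is.null(k_eq)) {
    if (is.null(local_off) || is.null(local_on)) {
      stop("supply 'k_eq' or both 'local_off' and 'local_on'")
    }
    k_eq <- local_off / local_on
  } else {
    .check_scalar(k_eq, "k_eq", positive = TRUE)
    if (!is.null(local_off) && !is.null(local_on) &&
        abs(k_eq - local_off / local_on) > 1e-8 * k_eq) {
      stop("'k_eq' is inconsistent with local_off/local_on")
    }
  }
  structure(
    list(k_eq = k_eq, local_off = local_off, local_on = local_on,
         valence = valence, label = label),
    class = "contact_equilibrium"
  )
}

#' A network of independent contact equilibria
#'
#' The wobbling model of unbinding: `n` independent contact equilibria
#' plus an escape frequency taken while all contacts are simultaneously
#' unbound.
#'
#' @param contacts List of [contact_equilibrium()] objects (>= 1).
#' @param escape_frequency Exit attempt frequency from the all-unbound
#'   configuration, s^-1.
#' @param voltage Membrane voltage, mV.
#'
#' @return An object of class `contact_network`.
#' @export
contact_network <- function(contacts, escape_frequency, voltage = 0) {
  if (inherits(contacts, "contact_equilibrium")) contacts <- list(contacts)
  if (!length(contacts) ||
      !all(vapply(contacts, inherits, TRUE, "contact_equilibrium"))) {
    stop("'contacts' must be a non-empty list of contact_equilibrium objects")
  }
  .check_scalar(escape_frequency, "escape_frequency", positive = TRUE)
  .check_scalar(voltage, "voltage")
  structure(
    list(contacts = contacts, escape_frequency = escape_frequency,
         voltage = voltage),
    class = "contact_network"
  )
}

#' Voltage-dependent contact equilibrium constant
#'
#' `K_j(V) = K_j * exp(z_j F V / RT)`, realized physically as
#' voltage-dependent rebinding (`local_on * exp(-z_j F V / RT)`) with a
#' voltage-independent local dissociation rate.
#'
#' @param contact A [contact_equilibrium()].
#' @param v Voltage(s), mV (vectorized).
#' @param constants A [phys_constants()] bundle.
#'
#' @return K_j at `v`.
#' @export
contact_kj_voltage <- function(contact, v, constants = phys_constants()) {
  if (!inherits(contact, "contact_equilibrium")) {
    stop("'contact' must be a contact_equilibrium")
  }
  contact$k_eq * exp(contact$valence * v / thermal_voltage(constants))
}

#' Composite dissociation rate of a contact network
#'
#' The macroscopic dissociation rate of the multi-contact model:
#' `k_off = A0 * prod(K_i) * exp(sum(z_j) F V / RT)`, the escape
#' frequency times the compound probability that all contacts are
#' simultaneously unbound (independence makes per-contact energies
#' additive, which is exactly the product of the K_i).
#'
#' @param network A [contact_network()].
#' @param constants A [phys_constants()] bundle.
#'
#' @return Composite dissociation rate, s^-1.
#' @examples
#' net <- contact_network(
#'   replicate(10, contact_equilibrium(k_eq = exp(-2.824)),
#'             simplify = FALSE),
#'   escape_frequency = 6e12)
#' composite_koff(net)  # ~3.3 s^-1
#' @export
composite_koff <- function(network, constants = phys_constants()) {
  if (!inherits(network, "contact_network")) {
    stop("'network' must be a contact_network")
  }
  keq <- vapply(network$contacts, `[[`, 0, "k_eq")
  zs <- vapply(network$contacts, `[[`, 0, "valence")
  network$escape_frequency * prod(keq) *
    exp(sum(zs) * network$voltage / thermal_voltage(constants))
}

#' Stochastic simulation of the contact network
#'
#' Continuous-time Markov (Gillespie) simulation over the 2^n
#' contact-configuration states.  Each bound contact unbinds at its
#' local dissociation rate; each unbound contact rebinds at its local
#' rebinding rate (scaled by `exp(-z_j F V / RT)` under the default
#' `voltage_mode = "rebinding"`; `"unbinding"` puts the voltage factor on
#' the local dissociation rate instead).  While all contacts are
#' simultaneously unbound, an absorbing exit is taken at the escape
#' frequency.  The complex lifetime is the first-passage time to exit
#' from the all-bound configuration.
#'
#' The analytic product formula [composite_koff()] assumes the contact
#' dynamics are much faster than dissociation; the simulation refuses to
#' run (error) when any local rate is below `min_separation` times the
#' predicted composite rate, since outside that regime the formula it is
#' meant to probe does not apply.  Pass a smaller `min_separation` to
#' study the crossover deliberately.
#'
#' @param network A [contact_network()] whose contacts all carry local
#'   rate pairs.
#' @param n_events Number of dissociation events to simulate (>= 100).
#' @param seed Mandatory RNG seed (integer).
#' @param constants A [phys_constants()] bundle.
#' @param min_separation Required ratio of the slowest local rate to the
#'   composite rate (default 1000).
#' @param voltage_mode `"rebinding"` (default) or `"unbinding"`.
#'
#' @return List of class `contact_sim`: `mean_lifetime` (s),
#'   `se_mean_lifetime`, `lifetimes` (length `n_events`),
#'   `exposure_fraction` (per contact, time-weighted fraction unbound),
#'   `composite_koff` (the analytic prediction), `n_events`, `seed`.
#'
#' @export
simulate_contact_network <- function(network, n_events, seed,
                                     constants = phys_constants(),
                                     min_separation = 1000,
                                     voltage_mode = c("rebinding",
                                                      "unbinding")) {
  voltage_mode <- match.arg(voltage_mode)
  if (!inherits(network, "contact_network")) {
    stop("'network' must be a contact_network")
  }
  if (missing(seed)) stop("'seed' is mandatory for stochastic simulation")
  .check_scalar(seed, "seed")
  .check_scalar(n_events, "n_events", positive = TRUE)
  if (n_events < 100) stop("'n_events' must be >= 100")
  n <- length(network$contacts)
  if (n > 16L) stop("state space too large: n must be <= 16")
  has_rates <- vapply(network$contacts, function(cc) {
    !is.null(cc$local_off) && !is.null(cc$local_on)
  }, TRUE)
  if (!all(has_rates)) {
    stop("every contact needs both 'local_off' and 'local_on'")
  }
  vt <- thermal_voltage(constants)
  v <- network$voltage
  off <- vapply(network$contacts, `[[`, 0, "local_off")
  on <- vapply(network$contacts, `[[`, 0, "local_on")
  z <- vapply(network$contacts, `[[`, 0, "valence")
  if (voltage_mode == "rebinding") {
    on <- on * exp(-z * v / vt)
  } else {
    off <- off * exp(z * v / vt)
  }
  k_pred <- network$escape_frequency * prod(off / on)
  sep <- min(c(off, on)) / k_pred
  if (sep < min_separation * (1 - 1e-9)) {
    stop(sprintf(
      paste0("timescale separation violated: slowest local rate is only ",
             "%.3g x the composite rate (need >= %g); the product formula ",
             "does not apply in this regime"),
      sep, min_separation
    ))
  }

  # precompute the 2^n-state transition tables; bit j set = contact j unbound
  ns <- 2L^n
  bits <- matrix(FALSE, ns, n)
  for (j in seq_len(n)) {
    bits[, j] <- bitwAnd(seq_len(ns) - 1L, bitwShiftL(1L, j - 1L)) > 0L
  }
  rates <- matrix(0, ns, n + 1L)
  target <- matrix(1L, ns, n)
  for (s in seq_len(ns)) {
    for (j in seq_len(n)) {
      rates[s, j] <- if (bits[s, j]) on[j] else off[j]
      target[s, j] <- s + if (bits[s, j]) -bitwShiftL(1L, j - 1L) else
        bitwShiftL(1L, j - 1L)
    }
  }
  rates[ns, n + 1L] <- network$escape_frequency
  total <- rowSums(rates)
  cum <- rates / total
  for (k in 2:(n + 1L)) cum[, k] <- cum[, k] + cum[, k - 1L]
  # guard against rounding: the last admissible column must close at 1
  if (ns > 1L) cum[seq_len(ns - 1L), n] <- 1
  cum[, n + 1L] <- 1

  set.seed(as.integer(seed))
  lifetimes <- numeric(n_events)
  state_time <- numeric(ns)
  exit_col <- n + 1L
  # per-state row vectors (faster lookup than matrix indexing) and a
  # buffered uniform stream keep the Gillespie loop lean
  cum_l <- lapply(seq_len(ns), function(s) cum[s, ])
  tgt_l <- lapply(seq_len(ns), function(s) target[s, ])
  buf_n <- 262144L
  buf <- stats::runif(buf_n)
  ip <- 1L
  for (ev in seq_len(n_events)) {
    s <- 1L
    t_ev <- 0
    repeat {
      if (ip > buf_n - 1L) {
        buf <- stats::runif(buf_n)
        ip <- 1L
      }
      dt <- -log(buf[ip]) / total[s]
      u <- buf[ip + 1L]
      ip <- ip + 2L
      t_ev <- t_ev + dt
      state_time[s] <- state_time[s] + dt
      cv <- cum_l[[s]]
      k <- 1L
      while (cv[k] < u) k <- k + 1L
      if (k == exit_col) break
      s <- tgt_l[[s]][k]
    }
    lifetimes[ev] <- t_ev
  }
  total_time <- sum(state_time)
  exposure <- vapply(seq_len(n), function(j) {
    sum(state_time[bits[, j]]) / total_time
  }, 0)
  structure(
    list(
      mean_lifetime = mean(lifetimes),
      se_mean_lifetime = stats::sd(lifetimes) / sqrt(n_events),
      lifetimes = lifetimes,
      exposure_fraction = exposure,
      composite_koff = k_pred,
      n_events = n_events,
      seed = as.integer(seed)
    ),
    class = "contact_sim"
  )
}

#' @export
print.contact_sim <- function(x, ...) {
  cat(sprintf(
    paste0("Contact-network simulation: %d events, mean lifetime ",
           "%.4g s (SE %.2g); analytic 1/k_off = %.4g s\n"),
    x$n_events, x$mean_lifetime, x$se_mean_lifetime, 1 / x$composite_koff
  ))
  invisible(x)
}
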