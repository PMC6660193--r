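#' Rate constants from wash-in/wash-out time constants
#'
#' For a 1:1 pore blocker, the wash-out relaxation obeys
#' `tau_off = 1/k_off` and the wash-in relaxation
#' `tau_on = 1/(k_on * [Tx] + k_off)`.  Inverting these gives
#' `k_off = 1/tau_off` and `k_on = (1/tau_on - k_off)/[Tx]`.
#'
#' @param tau_on Wash-in (block onset) time constant, s.
#' @param tau_off Wash-out (recovery) time constant, s.
#' @param toxin_conc Toxin concentration during wash-in, uM.
#'
#' @return A [rate_set()].
#'
#' @examples
#' rates_from_on_off(tau_on = 40.90, tau_off = 161.3, toxin_conc = 2.5e-4)
#' @export
rates_from_on_off <- function(tau_on, tau_off, toxin_conc) {
  .check_scalar(tau_on, "tau_on", positive = TRUE)
  .check_scalar(tau_off, "tau_off", positive = TRUE)
  .check_scalar(toxin_conc, "toxin_conc", positive = TRUE)
  k_off <- 1 / tau_off
  excess <- 1 / tau_on - k_off
  if (excess <= 0) {
    stop("on-relaxation slower than off: 1/tau_on must exceed 1/tau_off")
  }
  rate_set(k_on = excess / toxin_conc, k_off = k_off)
}

#' Paired control/toxin voltage-step traces
#'
#' Container for a control current trace and its +toxin partner recorded
#' on the same time base at the same step voltage, the input to the
#' trace-ratio relaxation analysis.
#'
#' @param times Sample times, ms (strictly increasing).
#' @param control_current Control-trace current, uA.
#' @param toxin_current +Toxin-trace current, uA (same grid).
#' @param step_voltage Test-pulse voltage, mV.
#' @param holding_voltage Holding voltage, mV.
#' @param toxin_conc Toxin concentration, uM.
#'
#' @return An object of class `trace_pair`.
#' @export
trace_pair <- function(times, control_current, toxin_current,
                       step_voltage, holding_voltage = -120,
                       toxin_conc = NA_real_) {
  if (length(times) != length(control_current) ||
      length(times) != length(toxin_current)) {
    stop("'times', 'control_current' and 'toxin_current' must share one grid")
  }
  if (length(times) < 2L || is.unsorted(times, strictly = TRUE)) {
    stop("'times' must be strictly increasing with length >= 2")
  }
  .check_scalar(step_voltage, "step_voltage")
  structure(
    list(
      times = as.numeric(times),
      control_current = as.numeric(control_current),
      toxin_current = as.numeric(toxin_current),
      step_voltage = step_voltage,
      holding_voltage = holding_voltage,
      toxin_conc = toxin_conc
    ),
    class = "trace_pair"
  )
}

#' Point-by-point toxin/control current ratio
#'
#' Divides the +toxin trace by its control partner sample-by-sample.  The
#' early segment, where the control current has not yet reached
#' `guard_fraction` of its steady-state magnitude (capacitive transient
#' and earliest activation, where the quotient is ill-defined), is
#' masked; the series starts at the first sample past the guard.
#'
#' @param pair A [trace_pair()].
#' @param guard_fraction Fraction of the steady-state control magnitude
#'   the control must reach before samples are kept, in (0, 1).
#'
#' @return A data frame with columns `time` (ms), `ratio` and `control`
#'   (the absolute control current, useful as an inverse-variance
#'   weighting basis for subsequent fits: the variance of a quotient
#'   scales as 1/control^2).
#'
#' @export
trace_ratio <- function(pair, guard_fraction = 0.10) {
  if (!inherits(pair, "trace_pair")) stop("'pair' must be a trace_pair")
  .check_scalar(guard_fraction, "guard_fraction")
  if (guard_fraction <= 0 || guard_fraction >= 1) {
    stop("'guard_fraction' must be in (0, 1)")
  }
  ctrl <- pair$control_current
  n <- length(ctrl)
  n_tail <- max(2L, ceiling(n / 10))
  steady <- mean(abs(ctrl[(n - n_tail + 1L):n]))
  if (steady == 0) stop("no analyzable window: control trace is zero")
  idx <- which(abs(ctrl) >= guard_fraction * steady)
  if (!length(idx)) {
    stop("no analyzable window: control never reaches the guard level")
  }
  keep <- idx[1L]:n
  data.frame(time = pair$times[keep],
             ratio = pair$toxin_current[keep] / ctrl[keep],
             control = abs(ctrl[keep]))
}

#' Rate constants from one open-channel relaxation
#'
#' The trace-ratio relaxation at one voltage gives a time constant
#' `tau = 1/(k_on * [Tx] + k_off)` and an asymptotic (equilibrium)
#' inhibition `(I_Tx/I_Con)_inf = k_off/(k_on * [Tx] + k_off)`.  These two
#' equations in two unknowns invert algebraically (no iteration):
#' `k_off = asymptote/tau` and `k_on = (1 - asymptote)/(tau * [Tx])`.
#'
#' @param tau Relaxation time constant, s.
#' @param asymptote Equilibrium current ratio, strictly inside (0, 1).
#' @param toxin_conc Toxin concentration, uM.
#'
#' @return A [rate_set()].
#'
#' @examples
#' rates_from_relaxation(tau = 0.1412, asymptote = 0.4266,
#'                       toxin_conc = 0.005)
#' @export
rates_from_relaxation <- function(tau, asymptote, toxin_conc) {
  .check_scalar(tau, "tau", positive = TRUE)
  .check_scalar(asymptote, "asymptote")
  .check_scalar(toxin_conc, "toxin_conc", positive = TRUE)
  if (asymptote <= 0) {
    stop("'asymptote' must be > 0 (complete block leaves k_off unresolved)")
  }
  if (asymptote >= 1) {
    stop("'asymptote' must be < 1 (no equilibrium block leaves k_on unresolved)")
  }
  rate_set(
    k_on = (1 - asymptote) / (tau * toxin_conc),
    k_off = asymptote / tau
  )
}

#' Voltage dependence of a rate constant
#'
#' Fits `k(V) = k(V = 0) * exp(z_delta * F * V / (R * T))` by least
#' squares in log-rate space (linear in V), returning the zero-voltage
#' rate and the effective valence `z_delta` (elementary charges;
#' positive when the rate grows with depolarization).
#'
#' @param voltage Voltages, mV (at least 2 distinct values).
#' @param rate Rates at those voltages (all > 0; s^-1 or uM^-1 s^-1).
#' @param constants A [phys_constants()] bundle.
#'
#' @return An object of class `voltage_dependence`: list with
#'   `k_at_zero`, `z_delta`, `se_k_at_zero`, `se_z_delta`, `n`.
#'
#' @examples
#' co <- phys_constants()
#' v <- c(0, 25, 50)
#' fit_voltage_dependence(v, 3.02 * exp(0.47 * v / thermal_voltage(co)), co)
#' @export
fit_voltage_dependence <- function(voltage, rate,
                                   constants = phys_constants()) {
  if (length(voltage) != length(rate)) {
    stop("'voltage' and 'rate' must have equal length")
  }
  if (length(unique(voltage)) < 2L) {
    stop("need rates at >= 2 distinct voltages")
  }
  if (any(rate <= 0)) stop("all rates must be > 0")
  vt <- thermal_voltage(constants)
  fit <- stats::lm(log(rate) ~ voltage)
  cf <- stats::coef(fit)
  se <- tryCatch(
    suppressWarnings(summary(fit)$coefficients[, "Std. Error"]),
    error = function(e) rep(NA_real_, 2L)
  )
  if (length(se) < 2L || any(!is.finite(se))) se <- c(NA_real_, NA_real_)
  k0 <- exp(unname(cf[1L]))
  structure(
    list(
      k_at_zero = k0,
      z_delta = unname(cf[2L]) * vt,
      se_k_at_zero = k0 * unname(se[1L]),
      se_z_delta = unname(se[2L]) * vt,
      n = length(rate)
    ),
    class = "voltage_dependence"
  )
}

#' @export
print.voltage_dependence <- function(x, ...) {
  cat(sprintf(
    "k(V=0) = %.4g (SE %.2g), z_delta = %.3g e0 (SE %.2g), n = %d\n",
    x$k_at_zero, x$se_k_at_zero, x$z_delta, x$se_z_delta, x$n
  ))
  invisible(x)
}

#' Average replicate relaxations per voltage, then solve for rates
#'
#' Multi-cell relaxation data are reduced in the order: average the time
#' constant and asymptotic inhibition across cells at each voltage
#' (mean +/- SEM), then solve the two-equation system at the means via
#' [rates_from_relaxation()].  Averaging first and solving second is the
#' default reduction; per-cell solves can be obtained by calling
#' [rates_from_relaxation()] row-wise instead.
#'
#' @param points Data frame with columns `voltage` (mV), `tau` (s) and
#'   `asymptote`; one row per cell and voltage.  An optional `toxin_conc`
#'   column must be constant within each voltage group.
#' @param toxin_conc Toxin concentration, uM (used when `points` carries
#'   no `toxin_conc` column).
#'
#' @return A data frame with one row per voltage: mean and SEM of `tau`
#'   and `asymptote`, the solved `k_on`, `k_off`, `k_d`, and `n_cells`.
#'
#' @export
average_then_solve <- function(points, toxin_conc = NULL) {
  need <- c("voltage", "tau", "asymptote")
  if (!is.data.frame(points) || !all(need %in% names(points))) {
    stop("'points' must be a data frame with columns voltage, tau, asymptote")
  }
  groups <- split(points, points$voltage)
  rows <- lapply(groups, function(g) {
    tx <- toxin_conc
    if ("toxin_conc" %in% names(g)) {
      utx <- unique(g$toxin_conc)
      if (length(utx) != 1L) {
        stop("mixed toxin concentrations within the group at ",
             g$voltage[1L], " mV")
      }
      tx <- utx
    }
    if (is.null(tx)) stop("toxin concentration not supplied")
    n <- nrow(g)
    sem <- function(x) if (n > 1L) stats::sd(x) / sqrt(n) else NA_real_
    rs <- rates_from_relaxation(mean(g$tau), mean(g$asymptote), tx)
    data.frame(
      voltage = g$voltage[1L],
      tau = mean(g$tau), tau_sem = sem(g$tau),
      asymptote = mean(g$asymptote), asymptote_sem = sem(g$asymptote),
      k_on = rs$k_on, k_off = rs$k_off, k_d = rs$k_d,
      n_cells = n
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$voltage), , drop = FALSE]
}
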