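#' Synthetic toxin wash-in/wash-out time course
#'
#' Integrates the 1:1 blocking kinetics
#' `dB/dt = k_on * [Tx] * (1 - B) - k_off * B` across a perfusion
#' schedule and samples the unblocked current fraction `1 - B` at every
#' voltage pulse (default one pulse every 3 s), optionally adding seeded
#' Gaussian noise.  With `perfusion_tau = 0` the solution exchange is
#' instantaneous and each schedule segment is an exact mono-exponential;
#' with `perfusion_tau > 0` the bath concentration relaxes first-order
#' toward the segment target and the system is integrated numerically.
#'
#' The schedule may switch rate constants between segments (e.g. a
#' wash-out into a different main cation), emulating protocols in which
#' the recovery rate is set solely by the solution currently perfused.
#'
#' @param k_on Association rate constant, uM^-1 s^-1.
#' @param k_off Dissociation rate constant, s^-1.
#' @param schedule Data frame with columns `start`, `end` (s) and
#'   `tx_conc` (uM); optional columns `k_on`, `k_off` override the
#'   defaults per segment, and `label` annotates the condition.
#'   Segments must not overlap.  Outside all segments the toxin
#'   concentration is zero.
#' @param t_end End of the recording, s (default: last segment end plus
#'   five off-relaxations).
#' @param pulse_interval Sampling (pulse) interval, s.
#' @param noise_sd Additive Gaussian noise SD on the normalized current.
#' @param seed RNG seed; mandatory when `noise_sd > 0`.
#' @param perfusion_tau First-order solution-exchange time constant, s
#'   (0 = instantaneous).
#'
#' @return An object of class `block_timecourse`: list with `times`,
#'   `amplitudes`, `schedule`, `k_on`, `k_off`, `noise_sd`,
#'   `perfusion_tau`, `seed`.
#'
#' @examples
#' sched <- data.frame(start = 30, end = 330, tx_conc = 2.5e-4)
#' tc <- gen_block_timecourse(73, 0.0062, sched, t_end = 900)
#' @export
gen_block_timecourse <- function(k_on, k_off, schedule, t_end = NULL,
                                 pulse_interval = 3, noise_sd = 0,
                                 seed = NULL, perfusion_tau = 0) {
  .check_scalar(k_on, "k_on", nonneg = TRUE)
  .check_scalar(k_off, "k_off", nonneg = TRUE)
  .check_scalar(pulse_interval, "pulse_interval", positive = TRUE)
  .check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  .check_scalar(perfusion_tau, "perfusion_tau", nonneg = TRUE)
  need <- c("start", "end", "tx_conc")
  if (!is.data.frame(schedule) || !all(need %in% names(schedule))) {
    stop("'schedule' must be a data frame with columns start, end, tx_conc")
  }
  schedule <- schedule[order(schedule$start), , drop = FALSE]
  if (any(schedule$end <= schedule$start)) {
    stop("schedule segments must have end > start")
  }
  if (nrow(schedule) > 1L &&
      any(schedule$start[-1L] < schedule$end[-nrow(schedule)])) {
    stop("schedule segments must not overlap")
  }
  if (noise_sd > 0 && is.null(seed)) {
    stop("'seed' is mandatory when noise_sd > 0")
  }
  if (is.null(t_end)) {
    t_end <- max(schedule$end) + 5 / max(k_off, 1e-6)
  }
  times <- seq(0, t_end, by = pulse_interval)

  seg_kon <- if ("k_on" %in% names(schedule)) schedule$k_on else
    rep(k_on, nrow(schedule))
  seg_koff <- if ("k_off" %in% names(schedule)) schedule$k_off else
    rep(k_off, nrow(schedule))

  # breakpoints partition [0, t_end] into constant-condition pieces
  brk <- sort(unique(c(0, schedule$start, schedule$end, t_end)))
  brk <- brk[brk >= 0 & brk <= t_end]
  seg_of <- function(t) {
    i <- which(schedule$start <= t & t < schedule$end)
    if (length(i)) i[1L] else NA_integer_
  }

  if (perfusion_tau == 0) {
    b <- 0
    amps <- numeric(length(times))
    done <- 0L
    for (p in seq_len(length(brk) - 1L)) {
      t0 <- brk[p]; t1 <- brk[p + 1L]
      i <- seg_of(t0)
      tx <- if (is.na(i)) 0 else schedule$tx_conc[i]
      kon_p <- if (is.na(i)) k_on else seg_kon[i]
      koff_p <- if (is.na(i)) k_off else seg_koff[i]
      lam <- kon_p * tx + koff_p
      beq <- if (lam > 0) kon_p * tx / lam else 0
      in_piece <- which(times >= t0 & (times < t1 | p == length(brk) - 1L))
      in_piece <- in_piece[in_piece > done]
      if (length(in_piece)) {
        amps[in_piece] <- 1 -
          (beq + (b - beq) * exp(-lam * (times[in_piece] - t0)))
        done <- max(in_piece)
      }
      b <- beq + (b - beq) * exp(-lam * (t1 - t0))
    }
  } else {
    target <- function(t) {
      i <- seg_of(t)
      if (is.na(i)) 0 else schedule$tx_conc[i]
    }
    deriv <- function(t, y, parms) {
      i <- seg_of(t)
      kon_p <- if (is.na(i)) k_on else seg_kon[i]
      koff_p <- if (is.na(i)) k_off else seg_koff[i]
      list(c(
        tx = (target(t) - y[["tx"]]) / perfusion_tau,
        b = kon_p * y[["tx"]] * (1 - y[["b"]]) - koff_p * y[["b"]]
      ))
    }
    sol <- deSolve::lsoda(
      y = c(tx = 0, b = 0), times = times, func = deriv, parms = NULL,
      rtol = 1e-10, atol = 1e-12
    )
    amps <- 1 - sol[, "b"]
  }

  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    amps <- amps + stats::rnorm(length(amps), sd = noise_sd)
  }
  structure(
    list(times = times, amplitudes = as.numeric(amps),
         schedule = schedule, k_on = k_on, k_off = k_off,
         noise_sd = noise_sd, perfusion_tau = perfusion_tau,
         seed = seed),
    class = "block_timecourse"
  )
}

#' Synthetic control/toxin voltage-step trace families
#'
#' Builds paired activation traces for a list of step voltages: the
#' control trace is `(1 - exp(-t/activation_tau))^power` (normalized
#' amplitude) and the toxin trace is the control multiplied by the
#' open-channel block relaxation
#' `U(t) = U_inf + (U_0 - U_inf) * exp(-t/tau(V))`, where `U_0` is the
#' resting unblocked fraction at the holding voltage (from the four-state
#' model) and `U_inf`, `tau(V)` follow from the voltage-dependent rates
#' `k_on(V) = kon0 * exp(zd_on * FV/RT)` (uM^-1 s^-1) and
#' `k_off(V) = koff0 * exp(zd_off * FV/RT)` (s^-1).
#'
#' @param voltages Step voltages, mV.
#' @param activation_tau Activation time constant(s), ms (recycled).
#' @param kon0,zd_on Zero-voltage association rate and its valence.
#' @param koff0,zd_off Zero-voltage dissociation rate and its valence.
#' @param toxin_conc Toxin concentration, uM.
#' @param kdc Closed-state dissociation constant, nM (sets `U_0`).
#' @param z_gate,v_half Gating Boltzmann used for the resting fraction.
#' @param holding_voltage Holding voltage, mV.
#' @param dt Sample interval, ms.
#' @param t_end Pulse length, ms.
#' @param power Activation exponent (4 = Hodgkin-Huxley-like, 1 =
#'   single exponential); the ratio analysis must not depend on it.
#' @param noise_sd Additive Gaussian noise SD relative to the control
#'   steady-state amplitude.
#' @param seed RNG seed; mandatory when `noise_sd > 0`.
#' @param constants A [phys_constants()] bundle.
#'
#' @return List of [trace_pair()] objects, one per voltage.
#' @export
gen_trace_family <- function(voltages, activation_tau, kon0, zd_on,
                             koff0, zd_off, toxin_conc, kdc,
                             z_gate, v_half, holding_voltage = -120,
                             dt = 0.1, t_end = 100, power = 4,
                             noise_sd = 0, seed = NULL,
                             constants = phys_constants()) {
  if (any(activation_tau <= 0)) stop("'activation_tau' must be > 0")
  .check_scalar(toxin_conc, "toxin_conc", positive = TRUE)
  if (noise_sd > 0 && is.null(seed)) {
    stop("'seed' is mandatory when noise_sd > 0")
  }
  vt <- thermal_voltage(constants)
  activation_tau <- rep_len(activation_tau, length(voltages))
  kdo0 <- 1000 * koff0 / kon0  # nM
  sch <- scheme_params(kdc = kdc, kdo0 = kdo0, z_tox = zd_off - zd_on,
                       z_gate = z_gate, v_half = v_half,
                       toxin_conc = 1000 * toxin_conc)
  u0 <- unblocked_fraction(holding_voltage, sch, constants)
  t_ms <- seq(0, t_end, by = dt)
  if (noise_sd > 0) set.seed(as.integer(seed))
  lapply(seq_along(voltages), function(i) {
    v <- voltages[i]
    kon_v <- kon0 * exp(zd_on * v / vt)
    koff_v <- koff0 * exp(zd_off * v / vt)
    lam <- kon_v * toxin_conc + koff_v           # s^-1
    tau_ms <- 1000 / lam
    u_inf <- koff_v / lam
    ctrl <- (1 - exp(-t_ms / activation_tau[i]))^power
    tox <- ctrl * (u_inf + (u0 - u_inf) * exp(-t_ms / tau_ms))
    if (noise_sd > 0) {
      sd_abs <- noise_sd * max(abs(ctrl))
      ctrl <- ctrl + stats::rnorm(length(t_ms), sd = sd_abs)
      tox <- tox + stats::rnorm(length(t_ms), sd = sd_abs)
    }
    trace_pair(t_ms, ctrl, tox, step_voltage = v,
               holding_voltage = holding_voltage,
               toxin_conc = toxin_conc)
  })
}

#' Synthetic K+ titration table
#'
#' Evaluates a Langmuir titration curve on a concentration grid and adds
#' multiplicative log-normal replicate noise (keeping values positive).
#'
#' @param params A [langmuir_params()] object (the true curve).
#' @param k_grid K+ concentrations, mM.  The default grid spans 0-100 mM
#'   with log-spaced interior points.
#' @param replicates Replicates per concentration.
#' @param noise_sd Log-normal sigma (roughly the relative SD).
#' @param seed RNG seed; mandatory when `noise_sd > 0`.
#'
#' @return Data frame with columns `k_mM`, `value`, `kind`, `cell_id`.
#' @export
gen_titration_table <- function(params,
                                k_grid = c(0, 0.1, 0.3, 1, 3, 10, 30, 100),
                                replicates = 1, noise_sd = 0,
                                seed = NULL) {
  if (!inherits(params, "langmuir_params")) {
    stop("'params' must be a langmuir_params object")
  }
  if (!length(k_grid)) stop("'k_grid' must be non-empty")
  .check_scalar(replicates, "replicates", positive = TRUE)
  .check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  if (noise_sd > 0 && is.null(seed)) {
    stop("'seed' is mandatory when noise_sd > 0")
  }
  conc <- rep(k_grid, each = replicates)
  value <- langmuir_eval(params, conc)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    value <- value * exp(stats::rnorm(length(value), sd = noise_sd))
  }
  data.frame(
    k_mM = conc,
    value = value,
    kind = if (is.na(params$kind)) "value" else params$kind,
    cell_id = sprintf("cell%02d", rep(seq_len(replicates),
                                      times = length(k_grid)))
  )
}

#' Synthetic tonic-inhibition table
#'
#' Evaluates the four-state steady-state unblocked fraction at resting
#' holding voltages (closed-channel regime) and at open-channel test
#' voltages (asymptotic inhibition), adding seeded Gaussian noise
#' truncated to [0, 1].
#'
#' @param scheme A [scheme_params()] object.
#' @param vh_list Resting holding voltages, mV.
#' @param v_open_list Open-channel test voltages, mV.
#' @param noise_sd Additive Gaussian noise SD.
#' @param seed RNG seed; mandatory when `noise_sd > 0`.
#' @param constants A [phys_constants()] bundle.
#'
#' @return Data frame with columns `v_mV`, `i_ratio`, `regime`.
#' @export
gen_tonic_table <- function(scheme, vh_list = seq(-120, -60, by = 10),
                            v_open_list = seq(-30, 50, by = 10),
                            noise_sd = 0, seed = NULL,
                            constants = phys_constants()) {
  if (!inherits(scheme, "scheme_params")) {
    stop("'scheme' must be a scheme_params object")
  }
  if (!length(vh_list) || !length(v_open_list)) {
    stop("voltage lists must be non-empty")
  }
  if (noise_sd > 0 && is.null(seed)) {
    stop("'seed' is mandatory when noise_sd > 0")
  }
  v <- c(vh_list, v_open_list)
  ratio <- unblocked_fraction(v, scheme, constants)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    ratio <- ratio + stats::rnorm(length(ratio), sd = noise_sd)
    ratio <- pmin(pmax(ratio, 0), 1)
  }
  data.frame(
    v_mV = v,
    i_ratio = ratio,
    regime = rep(c("resting", "open"),
                 c(length(vh_list), length(v_open_list)))
  )
}
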