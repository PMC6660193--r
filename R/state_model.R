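#' Four-state closed/open block model parameters
#'
#' Parameters of the thermodynamic cycle of closed and open channels with
#' and without bound toxin: closed-state dissociation constant `K_DC`,
#' open-state dissociation constant at zero voltage `K_DO(V=0)` with
#' effective toxin valence `z` (so `K_DO(V) = K_DO(0) * exp(zFV/RT)`),
#' and a Boltzmann open probability with gating valence `Z` and
#' half-activation voltage `Vo`.
#'
#' @param kdc Closed-state toxin dissociation constant, nM (> 0).
#' @param kdo0 Open-state dissociation constant at V = 0, nM (> 0).
#' @param z_tox Effective toxin valence, elementary charges.
#' @param z_gate Gating effective valence Z, elementary charges (> 0).
#' @param v_half Half-activation voltage Vo, mV.
#' @param toxin_conc Toxin concentration, nM (> 0).
#'
#' @return An object of class `scheme_params`.
#' @export
scheme_params <- function(kdc, kdo0, z_tox, z_gate, v_half, toxin_conc) {
  .check_scalar(kdc, "kdc", positive = TRUE)
  .check_scalar(kdo0, "kdo0", positive = TRUE)
  .check_scalar(z_tox, "z_tox")
  .check_scalar(z_gate, "z_gate", positive = TRUE)
  .check_scalar(v_half, "v_half")
  .check_scalar(toxin_conc, "toxin_conc", positive = TRUE)
  structure(
    list(kdc = kdc, kdo0 = kdo0, z_tox = z_tox, z_gate = z_gate,
         v_half = v_half, toxin_conc = toxin_conc),
    class = "scheme_params"
  )
}

#' @export
print.scheme_params <- function(x, ...) {
  cat(sprintf(
    "K_DC = %.4g nM, K_DO(0) = %.4g nM, z = %.3g, Z = %.3g, Vo = %.4g mV, [Tx] = %.4g nM\n",
    x$kdc, x$kdo0, x$z_tox, x$z_gate, x$v_half, x$toxin_conc
  ))
  invisible(x)
}

#' Boltzmann open probability
#'
#' `Po(V) = 1 / (1 + exp(-Z * F * (V - Vo) / (R * T)))`.
#'
#' @param v Membrane voltage(s), mV (vectorized).
#' @param z_gate Effective gating valence Z, elementary charges.
#' @param v_half Half-activation voltage Vo, mV.
#' @param constants A [phys_constants()] bundle.
#'
#' @return Open probability in (0, 1).
#' @examples
#' po_boltzmann(-67, 4, -67)  # 0.5
#' @export
po_boltzmann <- function(v, z_gate, v_half, constants = phys_constants()) {
  vt <- thermal_voltage(constants)
  1 / (1 + exp(-z_gate * (v - v_half) / vt))
}

#' Voltage-dependent open-state dissociation constant
#'
#' `K_DO(V) = K_DO(V = 0) * exp(z * F * V / (R * T))`.
#'
#' @param kdo0 Open-state dissociation constant at V = 0, nM.
#' @param z_tox Effective toxin valence, elementary charges.
#' @param v Voltage(s), mV (vectorized).
#' @param constants A [phys_constants()] bundle.
#'
#' @return K_DO at `v`, nM.
#' @examples
#' kdo_at_voltage(1.7, 0.29, 50)  # ~2.99 nM
#' @export
kdo_at_voltage <- function(kdo0, z_tox, v, constants = phys_constants()) {
  .check_scalar(kdo0, "kdo0", positive = TRUE)
  kdo0 * exp(z_tox * v / thermal_voltage(constants))
}

#' Fraction of toxin-free channels at equilibrium
#'
#' The intuitive form of the steady-state unblocked fraction of the
#' four-state model:
#' `U/Umax = 1 / (1 + [Tx]/K_DO(V) * Po(V) + [Tx]/K_DC * (1 - Po(V)))`.
#' It reduces to `1/(1 + [Tx]/K_DC)` as Po -> 0 (voltage independent)
#' and to `1/(1 + [Tx]/K_DO(V))` as Po -> 1 (fully voltage dependent);
#' in between, rising Po against a K_DO that itself grows with voltage
#' makes the curve biphasic.
#'
#' @param v Voltage(s), mV (vectorized).
#' @param scheme A [scheme_params()] object.
#' @param constants A [phys_constants()] bundle.
#'
#' @return Unblocked fraction(s) in (0, 1], interpretable as I_Tx/I_Con.
#' @examples
#' sch <- scheme_params(kdc = 1.84, kdo0 = 1.7, z_tox = 0.29,
#'                      z_gate = 3.9, v_half = -66, toxin_conc = 5)
#' unblocked_fraction(c(-120, -60, 50), sch)
#' @export
unblocked_fraction <- function(v, scheme, constants = phys_constants()) {
  if (!inherits(scheme, "scheme_params")) {
    stop("'scheme' must be a scheme_params object")
  }
  po <- po_boltzmann(v, scheme$z_gate, scheme$v_half, constants)
  kdo <- kdo_at_voltage(scheme$kdo0, scheme$z_tox, v, constants)
  tx <- scheme$toxin_conc
  1 / (1 + tx / kdo * po + tx / scheme$kdc * (1 - po))
}

#' Unblocked fraction in gating-equilibrium form
#'
#' Equivalent expression of the four-state steady state written with the
#' open/closed equilibrium constant `K_V1 = Po/(1 - Po)` of toxin-free
#' channels:
#' `U/Umax = (1 + K_V1) / (1 + K_V1 + [Tx] * (1/K_DC + K_V1/K_DO))`.
#' Exposed mainly so the algebraic identity with [unblocked_fraction()]
#' can be exercised directly.
#'
#' @param kv1 Open/closed equilibrium constant of toxin-free channels
#'   (>= 0; vectorized).
#' @param kdc Closed-state dissociation constant, nM.
#' @param kdo Open-state dissociation constant at the voltage of
#'   interest, nM.
#' @param toxin_conc Toxin concentration, nM.
#'
#' @return Unblocked fraction(s).
#' @export
unblocked_fraction_kv <- function(kv1, kdc, kdo, toxin_conc) {
  .check_scalar(kdc, "kdc", positive = TRUE)
  .check_scalar(kdo, "kdo", positive = TRUE)
  .check_scalar(toxin_conc, "toxin_conc", positive = TRUE)
  if (any(kv1 < 0)) stop("'kv1' must be >= 0")
  (1 + kv1) / (1 + kv1 + toxin_conc * (1 / kdc + kv1 / kdo))
}

#' Gating equilibrium of toxin-bound channels from cycle closure
#'
#' Microscopic reversibility around the four-state cycle fixes the
#' open/closed equilibrium constant of toxin-bound channels:
#' `K_V2 = K_V1 * K_DC / K_DO`.
#'
#' @param kv1 Open/closed equilibrium constant of toxin-free channels.
#' @param kdc Closed-state dissociation constant, nM.
#' @param kdo Open-state dissociation constant, nM.
#'
#' @return `K_V2` (dimensionless).
#' @examples
#' kv2_from_cycle(1, 2.81, 3.9)  # ~0.72
#' @export
kv2_from_cycle <- function(kv1, kdc, kdo) {
  .check_scalar(kv1, "kv1", positive = TRUE)
  .check_scalar(kdc, "kdc", positive = TRUE)
  .check_scalar(kdo, "kdo", positive = TRUE)
  kv1 * kdc / kdo
}

#' Predicted half-activation shift of toxin-bound channels
#'
#' With cycle closure, a toxin that binds open channels more weakly than
#' closed ones (`K_DO > K_DC`) displaces the half-activation voltage of
#' bound channels by `dV = (RT/(Z F)) * ln(K_DO/K_DC)` (mV, positive =
#' rightward).
#'
#' @param kdc Closed-state dissociation constant, nM.
#' @param kdo Open-state dissociation constant, nM.
#' @param z_gate Gating valence Z, elementary charges.
#' @param constants A [phys_constants()] bundle.
#'
#' @return Voltage shift, mV.
#' @examples
#' gating_shift(2.81, 3.9, 3.5)  # ~+2.4 mV
#' @export
gating_shift <- function(kdc, kdo, z_gate, constants = phys_constants()) {
  .check_scalar(kdc, "kdc", positive = TRUE)
  .check_scalar(kdo, "kdo", positive = TRUE)
  .check_scalar(z_gate, "z_gate", positive = TRUE)
  thermal_voltage(constants) / z_gate * log(kdo / kdc)
}

#' Fit the four-state model to tonic-inhibition data
#'
#' Joint least-squares fit (Levenberg-Marquardt) of the steady-state
#' unblocked fraction [unblocked_fraction()] to tonic inhibition I/Io
#' measured over voltage, combining resting-inhibition points (closed
#' channels, V <= -60 mV) and open-channel asymptotic inhibition
#' (V >= -30 mV) in one problem.  The data must span both regimes;
#' otherwise K_DC and K_DO cannot be separated.  Any subset of the five
#' parameters can be fixed.
#'
#' Bounds: dissociation constants in \[1e-3, 1e3\] nM, valences in
#' \[0, 8\] (gating valence floor 0.1), Vo in \[-150, +50\] mV.  Starts
#' are data driven: K_DC from the most negative voltages, K_DO from the
#' most positive, Vo from the steepest gradient of I/Io.
#'
#' @param voltage Voltages, mV.
#' @param ratio Tonic inhibition I/Io at those voltages, in \[0, 1\].
#' @param toxin_conc Toxin concentration, nM.
#' @param constants A [phys_constants()] bundle.
#' @param fixed Named list fixing any of `kdc`, `kdo0`, `z_tox`,
#'   `z_gate`, `v_half`.
#' @param start Optional named list overriding the automatic starts.
#'
#' @return An object of class `tonic_fit`: list with `scheme` (a
#'   [scheme_params()]), `se` (named SEs, NA for fixed parameters),
#'   `rss`, `n` and `fixed`.
#'
#' @export
fit_tonic_inhibition <- function(voltage, ratio, toxin_conc,
                                 constants = phys_constants(),
                                 fixed = list(), start = list()) {
  if (length(voltage) != length(ratio)) {
    stop("'voltage' and 'ratio' must have equal length")
  }
  .check_scalar(toxin_conc, "toxin_conc", positive = TRUE)
  if (any(ratio < 0 | ratio > 1)) stop("'ratio' must lie in [0, 1]")
  if (!any(voltage <= -60) || !any(voltage >= -30)) {
    stop("cannot separate K_DC from K_DO: need points in both the ",
         "resting (V <= -60 mV) and open (V >= -30 mV) regimes")
  }
  if (diff(range(ratio)) < 1e-10) {
    stop("flat inhibition curve: model parameters are not identifiable")
  }

  clamp <- function(x, lo, hi) min(max(x, lo), hi)
  vt <- thermal_voltage(constants)
  # starts
  r_rest <- mean(ratio[voltage <= stats::quantile(voltage, 0.2)])
  r_rest <- clamp(r_rest, 1e-3, 1 - 1e-3)
  kdc0 <- clamp(toxin_conc * r_rest / (1 - r_rest), 1e-3, 1e3)
  vmax <- max(voltage)
  r_open <- clamp(mean(ratio[voltage == vmax]), 1e-3, 1 - 1e-3)
  z0 <- 0.3
  kdo_vmax <- toxin_conc * r_open / (1 - r_open)
  kdo00 <- clamp(kdo_vmax * exp(-z0 * vmax / vt), 1e-3, 1e3)
  ord <- order(voltage)
  slope <- abs(diff(ratio[ord]) / diff(voltage[ord]))
  slope[!is.finite(slope)] <- 0
  vh0 <- clamp(mean(voltage[ord][which.max(slope) + c(0L, 1L)]), -150, 50)
  p0 <- list(kdc = kdc0, kdo0 = kdo00, z_tox = z0, z_gate = 4, v_half = vh0)
  p0[names(start)] <- start
  # deterministic multi-start over the half-activation voltage: noisy
  # data can put the steepest apparent gradient on the open-channel limb
  vh_starts <- unique(c(p0$v_half, -90, -70, -50))
  lower <- c(kdc = 1e-3, kdo0 = 1e-3, z_tox = 0, z_gate = 0.1,
             v_half = -150)
  upper <- c(kdc = 1e3, kdo0 = 1e3, z_tox = 8, z_gate = 8, v_half = 50)

  par_names <- setdiff(names(p0), names(fixed))
  if (!length(par_names)) stop("all parameters fixed; nothing to fit")
  full <- function(p) {
    q <- as.list(p)
    q[names(fixed)] <- fixed
    q
  }
  resid_fn <- function(p) {
    q <- full(p)
    sch <- scheme_params(q$kdc, q$kdo0, q$z_tox, q$z_gate, q$v_half,
                         toxin_conc)
    ratio - unblocked_fraction(voltage, sch, constants)
  }
  one_fit <- function(vh) {
    p_try <- p0
    if (!"v_half" %in% names(fixed)) p_try$v_half <- vh
    tryCatch(
      minpack.lm::nls.lm(
        par = unlist(p_try[par_names]),
        lower = lower[par_names], upper = upper[par_names],
        fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-12, ptol = 1e-12
        )
      ),
      error = function(e) NULL
    )
  }
  fits <- Filter(Negate(is.null), lapply(vh_starts, one_fit))
  if (!length(fits)) stop("tonic-inhibition fit failed to converge")
  rss_all <- vapply(fits, function(f) sum(resid_fn(f$par)^2), 0)
  fit <- fits[[which.min(rss_all)]]
  est <- full(fit$par)
  se_tab <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                     error = function(e) NULL)
  se <- c(kdc = NA_real_, kdo0 = NA_real_, z_tox = NA_real_,
          z_gate = NA_real_, v_half = NA_real_)
  if (!is.null(se_tab)) se[par_names] <- unname(se_tab)
  structure(
    list(
      scheme = scheme_params(est$kdc, est$kdo0, est$z_tox, est$z_gate,
                             est$v_half, toxin_conc),
      se = se,
      rss = sum(resid_fn(fit$par)^2),
      n = length(ratio),
      fixed = fixed
    ),
    class = "tonic_fit"
  )
}

#' @export
print.tonic_fit <- function(x, ...) {
  cat("Four-state tonic-inhibition fit (n =", x$n, ")\n")
  print(x$scheme)
  cat(sprintf("rss = %.4g\n", x$rss))
  invisible(x)
}

#' Fit a Boltzmann conductance-voltage curve
#'
#' Fits `G/Gmax = 1 / (1 + exp(-Z F (V - Vo)/RT))` to normalized
#' conductances, returning the half-activation voltage (where G/Gmax =
#' 0.5) and the effective gating valence.  Data that do not straddle the
#' transition midpoint yield an identifiability flag.
#'
#' @param voltage Voltages, mV (>= 4 points).
#' @param g_norm Normalized conductance G/Gmax in \[0, 1\].
#' @param constants A [phys_constants()] bundle.
#'
#' @return List of class `gv_fit` with `z_gate`, `v_half`, `se_z_gate`,
#'   `se_v_half`, `rss`, `n` and `poorly_identified`.
#'
#' @export
fit_gv <- function(voltage, g_norm, constants = phys_constants()) {
  if (length(voltage) != length(g_norm)) {
    stop("'voltage' and 'g_norm' must have equal length")
  }
  if (length(voltage) < 4L) stop("need >= 4 points")
  if (any(g_norm < 0 | g_norm > 1)) stop("'g_norm' must lie in [0, 1]")
  vt <- thermal_voltage(constants)
  spanning <- min(g_norm) < 0.4 && max(g_norm) > 0.6
  vh0 <- voltage[which.min(abs(g_norm - 0.5))]
  ord <- order(voltage)
  sl <- diff(g_norm[ord]) / diff(voltage[ord])
  z0 <- max(0.5, min(8, 4 * vt * max(sl, na.rm = TRUE)))
  df <- data.frame(v = voltage, g = g_norm)
  fit <- minpack.lm::nlsLM(
    g ~ 1 / (1 + exp(-z * (v - vh) / vt)),
    data = df, start = list(z = z0, vh = vh0),
    lower = c(0.1, -200), upper = c(16, 100),
    control = minpack.lm::nls.lm.control(
      maxiter = 500, ftol = 1e-12, ptol = 1e-12
    )
  )
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(z = NA_real_, vh = NA_real_))
  structure(
    list(
      z_gate = unname(cf[["z"]]), v_half = unname(cf[["vh"]]),
      se_z_gate = unname(se[["z"]]), se_v_half = unname(se[["vh"]]),
      rss = sum(stats::residuals(fit)^2), n = length(voltage),
      poorly_identified = !spanning
    ),
    class = "gv_fit"
  )
}

#' @export
print.gv_fit <- function(x, ...) {
  cat(sprintf(
    "Boltzmann G-V: Vo = %.4g mV (SE %.2g), Z = %.3g e0 (SE %.2g)%s\n",
    x$v_half, x$se_v_half, x$z_gate, x$se_z_gate,
    if (x$poorly_identified) " -- transition not spanned" else ""
  ))
  invisible(x)
}
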