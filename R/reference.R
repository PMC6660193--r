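#' Published CTX-Shaker parameter sets
#'
#' Reported parameter estimates for charybdotoxin (CTX) block of Shaker
#' K+ channels expressed in Xenopus oocytes, collected here so analyses
#' and demonstrations can be driven from the printed values without raw
#' recordings.  All entries follow the package unit conventions (k_on in
#' uM^-1 s^-1, k_off in s^-1, K_D in nM, concentrations in mM or nM as
#' labelled, voltages in mV).
#'
#' Contents:
#' \describe{
#'   \item{high_na, high_k}{Wash-in/wash-out rate constants of CTX on the
#'     high-affinity Shaker-F425G channel in normal-ionic-strength high
#'     Na+ and high K+ solutions.}
#'   \item{titration}{Langmuir fits of k_off, k_on and K_D versus
#'     external K+ (Shaker-F425G): limits at zero/saturating K+ and
#'     half-saturation constants K_K1 (enhancement site) and K_K2
#'     (association-antagonism site).}
#'   \item{low_ionic}{Zero-voltage rates and effective valences of CTX on
#'     wild-type Shaker in low-ionic-strength 10 mM Na+ ("na10") and
#'     10 mM K+ ("k10") solutions, from trace-ratio relaxation analysis
#'     at 5 nM CTX.}
#'   \item{scheme}{Four-state model fits to tonic inhibition versus
#'     voltage for the same two conditions: K_DC, K_DO(V=0), toxin
#'     valence z, gating valence Z, half-activation Vo; toxin
#'     concentration 5 nM.}
#'   \item{gv}{Boltzmann G-V midpoints in the two low-ionic-strength
#'     solutions.}
#'   \item{toxin_conc_low_ionic_uM}{The 5 nM working concentration, uM.}
#'   \item{attempt_frequency}{Transition-state-theory frequency factor
#'     A0 = 6e12 s^-1.}
#' }
#'
#' @return A nested list of parameter sets (see Details).
#' @examples
#' ref <- ctx_reference_params()
#' ref$high_na$k_on
#' @export
ctx_reference_params <- function() {
  list(
    high_na = list(k_on = 73, k_off = 0.0062, k_d = 0.086, n_cells = 7),
    high_k = list(k_on = 28, k_off = 0.013, k_d = 0.55),
    titration = list(
      k_off = langmuir_params(0.0061, 0.022, 135,
                              se_at_zero = 0.0002, se_at_sat = 0.007,
                              se_half_sat = 107, kind = "k_off"),
      k_on = langmuir_params(120, 56, 0.56,
                             se_at_zero = 11, se_at_sat = 8,
                             se_half_sat = 0.39, kind = "k_on"),
      K_D = langmuir_params(0.068, 0.65, 108,
                            se_at_zero = 0.008, se_at_sat = 0.18,
                            se_half_sat = 60, kind = "K_D")
    ),
    low_ionic = list(
      na10 = list(koff0 = 3.02, zd_off = 0.47, kon0 = 812, zd_on = 0.106),
      k10 = list(koff0 = 5.6, zd_off = 0.40, kon0 = 3572, zd_on = 0.133)
    ),
    scheme = list(
      na10 = scheme_params(kdc = 2.81, kdo0 = 3.9, z_tox = 0.36,
                           z_gate = 4.0, v_half = -67, toxin_conc = 5),
      k10 = scheme_params(kdc = 1.84, kdo0 = 1.7, z_tox = 0.29,
                          z_gate = 3.9, v_half = -66, toxin_conc = 5)
    ),
    gv = list(v_half_na10 = -22, v_half_k10 = -30),
    toxin_conc_low_ionic_uM = 0.005,
    attempt_frequency = 6e12
  )
}
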