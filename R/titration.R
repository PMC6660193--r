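#' Langmuir-isotherm parameters for an ion-titration curve
#'
#' Describes how a rate constant (or dissociation constant) of toxin
#' block depends on the external K+ concentration through single-site
#' saturation: the value moves from its zero-K+ limit `at_zero` to its
#' saturating-K+ limit `at_sat` with half-saturation constant `half_sat`
#' (mM).  One canonical algebraic form is used throughout:
#' `value([K]) = at_sat + (at_zero - at_sat) * half_sat/(half_sat + [K])`,
#' identical to `at_zero + (at_sat - at_zero) * [K]/(half_sat + [K])`.
#'
#' @param at_zero Value at zero K+, in the native unit of `kind`.
#' @param at_sat Value in the sole presence of K+ (saturation).
#' @param half_sat Half-saturation K+ concentration, mM.
#' @param se_at_zero,se_at_sat,se_half_sat Optional standard errors.
#' @param kind One of `"k_off"`, `"k_on"`, `"K_D"` (bookkeeping only).
#' @param poorly_identified Flag set by [fit_langmuir()] when
#'   `se(half_sat)/half_sat > 1`.
#'
#' @return An object of class `langmuir_params`.
#' @export
langmuir_params <- function(at_zero, at_sat, half_sat,
                            se_at_zero = NA_real_, se_at_sat = NA_real_,
                            se_half_sat = NA_real_, kind = NA_character_,
                            poorly_identified = FALSE) {
  .check_scalar(at_zero, "at_zero", positive = TRUE)
  .check_scalar(at_sat, "at_sat", positive = TRUE)
  .check_scalar(half_sat, "half_sat", positive = TRUE)
  structure(
    list(
      at_zero = at_zero, at_sat = at_sat, half_sat = half_sat,
      se_at_zero = se_at_zero, se_at_sat = se_at_sat,
      se_half_sat = se_half_sat, kind = kind,
      poorly_identified = isTRUE(poorly_identified)
    ),
    class = "langmuir_params"
  )
}

#' @export
print.langmuir_params <- function(x, ...) {
  cat(sprintf(
    "Langmuir%s: at_zero = %.4g (SE %.2g), at_sat = %.4g (SE %.2g), half_sat = %.4g mM (SE %.2g)%s\n",
    if (is.na(x$kind)) "" else paste0(" [", x$kind, "]"),
    x$at_zero, x$se_at_zero, x$at_sat, x$se_at_sat,
    x$half_sat, x$se_half_sat,
    if (x$poorly_identified) " -- half_sat poorly identified" else ""
  ))
  invisible(x)
}

#' Evaluate a Langmuir titration curve
#'
#' @param params A [langmuir_params()] object.
#' @param k_conc External K+ concentration(s), mM (>= 0; vectorized).
#'
#' @return Value(s) of the titration curve at `k_conc`.
#'
#' @examples
#' p <- langmuir_params(0.0061, 0.022, 135, kind = "k_off")
#' langmuir_eval(p, c(0, 100, 135))
#' @export
langmuir_eval <- function(params, k_conc) {
  if (!inherits(params, "langmuir_params")) {
    stop("'params' must be a langmuir_params object")
  }
  if (any(!is.finite(k_conc)) || any(k_conc < 0)) {
    stop("'k_conc' must be non-negative (mM)")
  }
  params$at_sat + (params$at_zero - params$at_sat) *
    params$half_sat / (params$half_sat + k_conc)
}

#' Fit a Langmuir isotherm to titration data
#'
#' Least-squares fit of the single-site saturation form to rate-constant
#' (or K_D) values measured over a range of external K+ concentrations.
#' Unweighted by default; `weighting = "relative"` applies 1/value^2
#' weights.  Starting values are data driven: `at_zero` from the smallest
#' concentration, `at_sat` from the largest, `half_sat` from the
#' geometric mean of the positive concentration span.
#'
#' When the design does not pin down the half-saturation constant
#' (relative SE above 1), the returned parameters carry the
#' `poorly_identified` flag rather than failing.
#'
#' @param k_conc K+ concentrations, mM.  At least 4 distinct values
#'   spanning at least one decade (a zero concentration anchors the low
#'   end).  May also be a data frame with columns `k_mM` and `value`.
#' @param value Measured values (all > 0).
#' @param kind One of `"k_off"`, `"k_on"`, `"K_D"` (bookkeeping).
#' @param weighting `"none"` (default) or `"relative"` (1/value^2).
#'
#' @return A [langmuir_params()] with standard errors and an `rss` field.
#'
#' @export
fit_langmuir <- function(k_conc, value = NULL,
                         kind = c("k_off", "k_on", "K_D"),
                         weighting = c("none", "relative")) {
  kind <- match.arg(kind)
  weighting <- match.arg(weighting)
  if (is.data.frame(k_conc)) {
    value <- k_conc$value
    k_conc <- k_conc$k_mM
  }
  if (length(k_conc) != length(value)) {
    stop("'k_conc' and 'value' must have equal length")
  }
  if (any(!is.finite(k_conc)) || any(k_conc < 0)) {
    stop("'k_conc' must be non-negative (mM)")
  }
  if (any(value <= 0)) stop("all values must be > 0")
  uconc <- sort(unique(k_conc))
  if (length(uconc) < 4L) {
    stop("need >= 4 distinct concentrations, have ", length(uconc))
  }
  pos <- uconc[uconc > 0]
  if (!length(pos) || (max(pos) / min(pos) < 10 && !any(uconc == 0))) {
    stop("concentrations must span at least one decade")
  }

  lo <- mean(value[k_conc == uconc[1L]])
  hi <- mean(value[k_conc == uconc[length(uconc)]])
  half0 <- sqrt(min(pos) * max(pos))
  w <- if (weighting == "relative") 1 / value^2 else rep(1, length(value))

  df <- data.frame(conc = k_conc, value = value)
  fit <- minpack.lm::nlsLM(
    value ~ at_sat + (at_zero - at_sat) * half_sat / (half_sat + conc),
    data = df, weights = w,
    start = list(at_zero = lo, at_sat = hi, half_sat = half0),
    lower = c(1e-12, 1e-12, 1e-9),
    control = minpack.lm::nls.lm.control(
      maxiter = 500, ftol = 1e-12, ptol = 1e-12
    )
  )
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3L))
  out <- langmuir_params(
    at_zero = unname(cf[["at_zero"]]),
    at_sat = unname(cf[["at_sat"]]),
    half_sat = unname(cf[["half_sat"]]),
    se_at_zero = unname(se[["at_zero"]]),
    se_at_sat = unname(se[["at_sat"]]),
    se_half_sat = unname(se[["half_sat"]]),
    kind = kind,
    poorly_identified = isTRUE(
      is.finite(se[["half_sat"]]) &&
        se[["half_sat"]] / cf[["half_sat"]] > 1
    )
  )
  out$rss <- sum(stats::residuals(fit)^2)
  out
}

#' Fold change between the K+ limits of a titration curve
#'
#' @param params A [langmuir_params()] object.
#' @return List with `sat_over_zero` (`at_sat/at_zero`) and its inverse
#'   `zero_over_sat`.
#' @examples
#' fold_changes(langmuir_params(0.068, 0.65, 108, kind = "K_D"))
#' @export
fold_changes <- function(params) {
  if (!inherits(params, "langmuir_params")) {
    stop("'params' must be a langmuir_params object")
  }
  list(sat_over_zero = params$at_sat / params$at_zero,
       zero_over_sat = params$at_zero / params$at_sat)
}

#' Lower bound on the external availability of the S1 site
#'
#' The ratio of the half-saturation constant for K+ antagonism of toxin
#' association (`K_K2`, toxin-free channel) over the one for K+
#' enhancement of dissociation (`K_K1`, toxin-bound channel) bounds from
#' below the fraction of time the outermost selectivity-filter site (S1)
#' is available to external K+ while the toxin is bound.
#'
#' @param half_sat_on `K_K2`, mM (> 0).
#' @param half_sat_off `K_K1`, mM (> 0).
#' @return The dimensionless ratio `K_K2 / K_K1`.
#' @examples
#' s1_availability(0.56, 135)  # ~0.004
#' @export
s1_availability <- function(half_sat_on, half_sat_off) {
  .check_scalar(half_sat_on, "half_sat_on", positive = TRUE)
  .check_scalar(half_sat_off, "half_sat_off", positive = TRUE)
  half_sat_on / half_sat_off
}

#' Cation selectivity summary of the dissociation-enhancement site
#'
#' Per-cation ratios of the toxin dissociation constant (relative to the
#' high-K+ reference) and of the dissociation rate (relative to the
#' high-Na+ control), the standard summary of how different external
#' cations fingerprint the enhancement site.
#'
#' @param rates Data frame with columns `cation`, `k_d` (nM) and
#'   `k_off` (s^-1), one row per external main cation.
#' @param reference_kd Cation naming the K_D reference row (default
#'   `"K"`).
#' @param reference_koff Cation naming the k_off reference row (default
#'   `"Na"`).
#'
#' @return Data frame with columns `cation`, `kd_ratio_vs_K` and
#'   `koff_ratio_vs_Na`.
#' @export
selectivity_table <- function(rates, reference_kd = "K",
                              reference_koff = "Na") {
  need <- c("cation", "k_d", "k_off")
  if (!is.data.frame(rates) || !all(need %in% names(rates))) {
    stop("'rates' must be a data frame with columns cation, k_d, k_off")
  }
  if (!reference_kd %in% rates$cation) {
    stop("missing K_D reference cation: ", reference_kd)
  }
  if (!reference_koff %in% rates$cation) {
    stop("missing k_off reference cation: ", reference_koff)
  }
  kd_ref <- rates$k_d[match(reference_kd, rates$cation)]
  koff_ref <- rates$k_off[match(reference_koff, rates$cation)]
  if (kd_ref <= 0 || koff_ref <= 0) stop("reference entries must be > 0")
  data.frame(
    cation = rates$cation,
    kd_ratio_vs_K = rates$k_d / kd_ref,
    koff_ratio_vs_Na = rates$k_off / koff_ref
  )
}
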