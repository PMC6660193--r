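#' Association/dissociation rate pair for a 1:1 blocker
#'
#' Container for a bimolecular association rate constant, a first-order
#' dissociation rate constant and the equilibrium dissociation constant
#' they imply.  Units follow the package conventions: `k_on` in
#' uM^-1 s^-1, `k_off` in s^-1 and `k_d` in nM, so
#' `k_d = 1000 * k_off / k_on`.
#'
#' @param k_on Association rate constant (uM^-1 s^-1), >= 0.
#' @param k_off Dissociation rate constant (s^-1), >= 0.
#' @param se_k_on,se_k_off Optional standard errors (same units).
#' @param n_cells Optional number of cells/oocytes the estimate pools.
#'
#' @return An object of class `rate_set` with fields `k_on`, `k_off`,
#'   `k_d`, `se_k_on`, `se_k_off`, `se_k_d` and `n_cells`.  `se_k_d` is
#'   propagated from the rate SEs assuming independence.
#'
#' @examples
#' rate_set(k_on = 73, k_off = 0.0062)  # K_D ~0.085 nM
#' @export
rate_set <- function(k_on, k_off, se_k_on = NA_real_, se_k_off = NA_real_,
                     n_cells = NA_integer_) {
  .check_scalar(k_on, "k_on", nonneg = TRUE)
  .check_scalar(k_off, "k_off", nonneg = TRUE)
  k_d <- if (k_on > 0) 1000 * k_off / k_on else NA_real_
  se_k_d <- NA_real_
  if (is.finite(se_k_on) && is.finite(se_k_off) && k_on > 0 && k_off > 0) {
    se_k_d <- k_d * sqrt((se_k_on / k_on)^2 + (se_k_off / k_off)^2)
  }
  structure(
    list(
      k_on = k_on, k_off = k_off, k_d = k_d,
      se_k_on = se_k_on, se_k_off = se_k_off, se_k_d = se_k_d,
      n_cells = n_cells
    ),
    class = "rate_set"
  )
}

#' @export
print.rate_set <- function(x, ...) {
  cat(sprintf(
    "k_on  = %.4g uM^-1 s^-1%s\nk_off = %.4g s^-1%s\nK_D   = %.4g nM%s\n",
    x$k_on, if (is.finite(x$se_k_on)) sprintf(" (SE %.2g)", x$se_k_on) else "",
    x$k_off, if (is.finite(x$se_k_off)) sprintf(" (SE %.2g)", x$se_k_off) else "",
    x$k_d, if (is.finite(x$se_k_d)) sprintf(" (SE %.2g)", x$se_k_d) else ""
  ))
  invisible(x)
}
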