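#' Fit a single-exponential relaxation
#'
#' Least-squares fit of `y(t) = baseline + amplitude * exp(-(t - t0)/tau)`
#' to a block/unblock time course or a trace-ratio series, where `t0` is
#' the start of the fit window.  This is the workhorse behind both the
#' wash-in/wash-out analysis and the trace-ratio relaxation analysis.
#'
#' Starting values are deterministic: the baseline starts at the mean of
#' the last decile of the window, the amplitude at the first sample minus
#' that baseline, and tau at the time taken to cover (1 - 1/e) of the
#' span, refined by damped (Levenberg-Marquardt) least squares with tau
#' bounded to `[dt, 100 * span]`.
#'
#' If the fitted amplitude is indistinguishable from zero (|amplitude| <
#' 3 x its standard error from the fit covariance; when no SE is
#' available, 3 x the robust noise scale, 1.4826 x the median absolute
#' deviation of the data about a constant fit), the series is declared to
#' have no resolvable relaxation: `no_relaxation` is `TRUE` and `tau` is
#' `NA`, rather than an error.  The SE-based criterion accounts for the
#' number of samples: a shallow relaxation sampled densely is still a
#' relaxation.
#'
#' @param times Sample times (seconds for time courses, ms for trace
#'   ratios; any single consistent unit).  May also be a two-column
#'   data frame (time, value) or a [gen_block_timecourse()] object, in
#'   which case `values` is ignored.
#' @param values Sampled amplitudes (normalized current or current ratio).
#' @param window Length-2 numeric `[t0, t1]` restricting the fit; defaults
#'   to the full span.  At least 5 samples must fall inside.
#' @param weights Optional relative weights (one per sample of the input
#'   series).  For trace-ratio series, `control^2` from [trace_ratio()]
#'   is the inverse-variance choice, since dividing by a small control
#'   current inflates the quotient noise.
#'
#' @return An object of class `exp_fit`: a list with `amplitude`, `tau`,
#'   `baseline`, `se_tau`, `rss`, `no_relaxation`, `window`, `t0` and `n`.
#'   `tau` carries the unit of `times`.
#'
#' @examples
#' t <- seq(0, 300, by = 3)
#' y <- 0.3 + 0.7 * exp(-t / 30)
#' fit_monoexponential(t, y)$tau  # 30
#' @export
fit_monoexponential <- function(times, values = NULL, window = NULL,
                                weights = NULL) {
  if (inherits(times, "block_timecourse")) {
    values <- times$amplitudes
    times <- times$times
  } else if (is.data.frame(times)) {
    values <- times[[2L]]
    times <- times[[1L]]
  }
  if (length(times) != length(values)) {
    stop("'times' and 'values' must have equal length")
  }
  if (!is.null(weights)) {
    if (length(weights) != length(times) || any(weights < 0)) {
      stop("'weights' must be non-negative, one per sample")
    }
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("'times' must be strictly increasing")
  }
  if (is.null(window)) window <- range(times)
  if (length(window) != 2L || window[1] >= window[2]) {
    stop("'window' must be [t0, t1] with t0 < t1")
  }
  if (window[1] < min(times) || window[2] > max(times)) {
    stop("'window' must lie inside the sampled span")
  }
  keep <- times >= window[1] & times <= window[2]
  if (sum(keep) < 5L) {
    stop("too few samples in window: need at least 5, have ", sum(keep))
  }
  t <- times[keep]
  y <- values[keep]
  w <- if (is.null(weights)) rep(1, sum(keep)) else weights[keep]
  n <- length(y)
  t0 <- t[1L]

  # noise scale: MAD of residuals about a constant (median) fit
  noise <- stats::mad(y)

  # deterministic starts from a running-median smoothed copy (the raw
  # first samples of a ratio series can be very noisy)
  ys <- if (n >= 7L) stats::runmed(y, 5L) else y
  n_tail <- max(2L, ceiling(n / 10))
  b0 <- mean(ys[(n - n_tail + 1L):n])
  a0 <- ys[1L] - b0
  span <- t[n] - t0
  dt <- min(diff(t))
  tau0 <- span / 3
  if (abs(a0) > 0) {
    # first time the smoothed trace covers (1 - 1/e) of its excursion
    frac <- abs(ys - ys[1L]) / abs(a0)
    hit <- which(frac >= (1 - exp(-1)))
    if (length(hit)) tau0 <- max(t[hit[1L]] - t0, dt)
  }
  tau0 <- min(max(tau0, dt), 100 * span)

  no_relax <- function() {
    structure(
      list(
        amplitude = NA_real_, tau = NA_real_, baseline = mean(y),
        se_tau = NA_real_, rss = sum((y - mean(y))^2),
        no_relaxation = TRUE, window = window, t0 = t0, n = n
      ),
      class = "exp_fit"
    )
  }
  if (abs(a0) <= 3 * noise && noise == 0) return(no_relax())

  # deterministic multi-start over tau guards against collapse onto the
  # lower tau bound when early samples are noisy
  one_fit <- function(tau_start) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ baseline + amplitude * exp(-(t - t0) / tau),
        start = list(baseline = b0, amplitude = a0, tau = tau_start),
        weights = w,
        lower = c(-Inf, -Inf, dt),
        upper = c(Inf, Inf, 100 * span),
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-12, ptol = 1e-12
        )
      ),
      error = function(e) NULL
    )
  }
  tau_starts <- unique(pmin(pmax(c(tau0, span / 10, span / 3, span), dt),
                            100 * span))
  fits <- Filter(Negate(is.null), lapply(tau_starts, one_fit))
  if (!length(fits)) return(no_relax())
  rss_all <- vapply(fits, function(f) sum(stats::residuals(f)^2), 0)
  fit <- fits[[which.min(rss_all)]]

  cf <- stats::coef(fit)
  se <- tryCatch(
    suppressWarnings(summary(fit)$coefficients[, "Std. Error"]),
    error = function(e) c(tau = NA_real_, amplitude = NA_real_)
  )
  se_amp <- if ("amplitude" %in% names(se)) se[["amplitude"]] else NA_real_
  amp_floor <- if (is.finite(se_amp)) 3 * se_amp else 3 * noise
  if (abs(cf[["amplitude"]]) < amp_floor) return(no_relax())
  structure(
    list(
      amplitude = unname(cf[["amplitude"]]),
      tau = unname(cf[["tau"]]),
      baseline = unname(cf[["baseline"]]),
      se_tau = unname(if ("tau" %in% names(se)) se[["tau"]] else NA_real_),
      rss = sum(stats::residuals(fit)^2),
      no_relaxation = FALSE, window = window, t0 = t0, n = n
    ),
    class = "exp_fit"
  )
}

#' @export
print.exp_fit <- function(x, ...) {
  if (x$no_relaxation) {
    cat(sprintf("exp_fit: no resolvable relaxation (baseline %.4g, n = %d)\n",
                x$baseline, x$n))
  } else {
    cat(sprintf(
      "exp_fit: tau = %.6g (SE %.2g), amplitude = %.4g, baseline = %.4g, rss = %.3g, n = %d\n",
      x$tau, x$se_tau, x$amplitude, x$baseline, x$rss, x$n
    ))
  }
  invisible(x)
}
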