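#' Run the simulate-fit-energetics pipeline from a configuration
#'
#' Executes the configured stages end-to-end on synthetic data and
#' collects every fitted parameter and derived quantity into one report
#' suitable for JSON serialization.  Stages (all optional, at least one
#' required):
#'
#' \describe{
#'   \item{timecourse}{`list(k_on, k_off, tx_conc_uM, app_start_s,
#'     app_end_s, t_end_s, pulse_interval_s = 3, noise_sd = 0.01)` --
#'     simulates a wash-in/wash-out experiment, fits the on and off
#'     phases and converts them to rate constants.}
#'   \item{relaxation}{`list(kon0, zd_on, koff0, zd_off, tx_conc_uM,
#'     kdc_nM, z_gate, v_half, voltages, activation_tau_ms = 2,
#'     t_end_ms = 100, noise_sd = 0.02, guard_fraction = 0.1)` --
#'     simulates trace families, runs the trace-ratio pipeline and fits
#'     the voltage dependence of both rates.}
#'   \item{titration}{`list(k_off = list(at_zero, at_sat, half_sat),
#'     k_on = ..., noise_sd = 0.1, replicates = 3)` -- simulates and
#'     refits Langmuir titrations, reporting fold changes and the
#'     K_K2/K_K1 availability bound.}
#'   \item{tonic}{`list(kdc, kdo0, z_tox, z_gate, v_half, tx_conc_nM,
#'     noise_sd = 0.03)` -- simulates tonic inhibition versus voltage and
#'     refits the four-state model.}
#'   \item{energetics}{`list(koff_values, a0 = 6e12, n_contacts = 10)` --
#'     Eyring barriers and per-contact energies.}
#' }
#'
#' @param config List with `seed` (mandatory), optional `temperature_K`,
#'   and stage blocks as above.  Unknown top-level keys are rejected.
#'
#' @return A list of class `pipeline_report` with one element per stage
#'   plus `seed`, `temperature_K` and `package_version`.
#'
#' @seealso [write_report()]
#' @export
run_pipeline <- function(config) {
  known <- c("seed", "temperature_K", "timecourse", "relaxation",
             "titration", "tonic", "energetics")
  if (!is.list(config) || !length(config)) {
    stop("'config' must be a non-empty list")
  }
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$seed)) stop("'config$seed' is mandatory")
  seed <- as.integer(config$seed)
  constants <- phys_constants(
    if (is.null(config$temperature_K)) 298.15 else config$temperature_K
  )
  stages <- intersect(names(config), known[-(1:2)])
  if (!length(stages)) stop("config defines no stages to run")
  getd <- function(block, key, default) {
    if (is.null(block[[key]])) default else block[[key]]
  }
  report <- list(seed = seed, temperature_K = constants$temperature,
                 package_version = as.character(
                   utils::packageVersion("poreblock")))

  if ("timecourse" %in% stages) {
    b <- config$timecourse
    sched <- data.frame(start = b$app_start_s, end = b$app_end_s,
                        tx_conc = b$tx_conc_uM)
    tc <- gen_block_timecourse(
      b$k_on, b$k_off, sched, t_end = b$t_end_s,
      pulse_interval = getd(b, "pulse_interval_s", 3),
      noise_sd = getd(b, "noise_sd", 0.01), seed = seed
    )
    on_fit <- fit_monoexponential(tc$times, tc$amplitudes,
                                  window = c(b$app_start_s, b$app_end_s))
    off_fit <- fit_monoexponential(tc$times, tc$amplitudes,
                                   window = c(b$app_end_s, max(tc$times)))
    rates <- rates_from_on_off(on_fit$tau, off_fit$tau, b$tx_conc_uM)
    report$timecourse <- list(
      tau_on_s = on_fit$tau, tau_off_s = off_fit$tau,
      k_on = rates$k_on, k_off = rates$k_off, k_d_nM = rates$k_d
    )
  }

  if ("relaxation" %in% stages) {
    b <- config$relaxation
    pairs <- gen_trace_family(
      voltages = b$voltages,
      activation_tau = getd(b, "activation_tau_ms", 2),
      kon0 = b$kon0, zd_on = b$zd_on, koff0 = b$koff0, zd_off = b$zd_off,
      toxin_conc = b$tx_conc_uM, kdc = b$kdc_nM,
      z_gate = b$z_gate, v_half = b$v_half,
      t_end = getd(b, "t_end_ms", 100),
      noise_sd = getd(b, "noise_sd", 0.02), seed = seed,
      constants = constants
    )
    pts <- do.call(rbind, lapply(pairs, function(p) {
      rr <- trace_ratio(p, getd(b, "guard_fraction", 0.1))
      ff <- fit_monoexponential(rr$time, rr$ratio,
                                weights = rr$control^2)
      # a voltage where block at rest already equals the open-channel
      # equilibrium has no measurable relaxation; skip it
      if (ff$no_relaxation) return(NULL)
      data.frame(voltage = p$step_voltage, tau = ff$tau / 1000,
                 asymptote = ff$baseline)
    }))
    solved <- average_then_solve(pts, toxin_conc = b$tx_conc_uM)
    vd_off <- fit_voltage_dependence(solved$voltage, solved$k_off,
                                     constants)
    vd_on <- fit_voltage_dependence(solved$voltage, solved$k_on,
                                    constants)
    report$relaxation <- list(
      per_voltage = solved,
      koff0 = vd_off$k_at_zero, zd_off = vd_off$z_delta,
      kon0 = vd_on$k_at_zero, zd_on = vd_on$z_delta
    )
  }

  if ("titration" %in% stages) {
    b <- config$titration
    fits <- list()
    for (kind in intersect(c("k_off", "k_on", "K_D"), names(b))) {
      p <- b[[kind]]
      true <- langmuir_params(p$at_zero, p$at_sat, p$half_sat,
                              kind = kind)
      tab <- gen_titration_table(
        true, replicates = getd(b, "replicates", 3),
        noise_sd = getd(b, "noise_sd", 0.1), seed = seed
      )
      ft <- fit_langmuir(tab$k_mM, tab$value, kind = kind)
      fits[[kind]] <- list(
        at_zero = ft$at_zero, at_sat = ft$at_sat,
        half_sat = ft$half_sat,
        fold_change = fold_changes(ft)$sat_over_zero,
        poorly_identified = ft$poorly_identified
      )
    }
    if (all(c("k_on", "k_off") %in% names(fits))) {
      fits$s1_availability <- s1_availability(
        fits$k_on$half_sat, fits$k_off$half_sat
      )
    }
    report$titration <- fits
  }

  if ("tonic" %in% stages) {
    b <- config$tonic
    sch <- scheme_params(b$kdc, b$kdo0, b$z_tox, b$z_gate, b$v_half,
                         b$tx_conc_nM)
    tab <- gen_tonic_table(sch, noise_sd = getd(b, "noise_sd", 0.03),
                           seed = seed, constants = constants)
    ft <- fit_tonic_inhibition(tab$v_mV, tab$i_ratio, b$tx_conc_nM,
                               constants)
    report$tonic <- list(
      kdc_nM = ft$scheme$kdc, kdo0_nM = ft$scheme$kdo0,
      z_tox = ft$scheme$z_tox, z_gate = ft$scheme$z_gate,
      v_half_mV = ft$scheme$v_half, rss = ft$rss,
      kv2_over_kv1 = kv2_from_cycle(1, ft$scheme$kdc, ft$scheme$kdo0)
    )
  }

  if ("energetics" %in% stages) {
    b <- config$energetics
    a0 <- getd(b, "a0", 6e12)
    nn <- getd(b, "n_contacts", 10)
    report$energetics <- lapply(b$koff_values, function(k) {
      bar <- barrier_from_rate(k, a0, constants)
      pc <- per_contact_energy(bar, nn, constants)
      list(k_off = k, barrier_kJ_mol = bar,
           per_contact_kT = pc$energy_kT,
           per_contact_p_unbound = pc$p_unbound)
    })
  }

  class(report) <- "pipeline_report"
  report
}

#' Serialize a pipeline report to JSON
#'
#' Numbers are written at full (17 significant digit) precision; the
#' report embeds the seed and package version needed to reproduce it.
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  report$report_schema <- "poreblock-report/1"
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}
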