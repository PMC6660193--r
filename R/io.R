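# Delimited-text readers/writers.  Dialect is fixed, not sniffed:
# comma-separated, '.' decimal, UTF-8, '#'-prefixed `key=value` metadata
# header lines before the column header.

#' Read a CSV file with `# key=value` metadata header lines
#'
#' @param path File path.
#' @param required_meta Metadata keys that must be present.
#' @param required_cols Column names that must be present.
#' @param numeric_cols Columns validated as fully numeric; offending rows
#'   are reported with their file line numbers.
#'
#' @return List with `data` (data frame) and `meta` (named character
#'   vector; values parse as numbers where possible via
#'   `meta_num()`-style access by the typed readers).
#' @export
read_annotated_csv <- function(path, required_meta = character(),
                               required_cols = character(),
                               numeric_cols = required_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^#", lines)
  n_meta <- if (any(!is_meta)) which(!is_meta)[1L] - 1L else length(lines)
  meta_lines <- lines[seq_len(n_meta)]
  meta <- character()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    if (!grepl("=", kv)) next
    key <- trimws(sub("=.*$", "", kv))
    val <- trimws(sub("^[^=]*=", "", kv))
    meta[key] <- val
  }
  missing_meta <- setdiff(required_meta, names(meta))
  if (length(missing_meta)) {
    stop("missing mandatory metadata key(s): ",
         paste(missing_meta, collapse = ", "))
  }
  body <- if (n_meta > 0L) lines[-seq_len(n_meta)] else lines
  if (!length(body)) stop("no data rows in ", path)
  df <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required_cols, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (cc in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (length(bad)) {
      stop(sprintf("non-numeric value in column '%s' at file line(s) %s",
                   cc,
                   paste(bad + n_meta + 1L, collapse = ", ")))
    }
    if (anyNA(df[[cc]])) {
      stop(sprintf("missing value in column '%s' at file line(s) %s",
                   cc,
                   paste(which(is.na(df[[cc]])) + n_meta + 1L,
                         collapse = ", ")))
    }
    df[[cc]] <- v
  }
  list(data = df, meta = meta)
}

#' Write a CSV file with `# key=value` metadata header lines
#'
#' @param data Data frame to write.
#' @param path Output path.
#' @param meta Named list/vector of metadata values.
#' @return `path`, invisibly.
#' @export
write_annotated_csv <- function(data, path, meta = list()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (key in names(meta)) {
    writeLines(sprintf("# %s=%s", key, format(meta[[key]], digits = 17)),
               con)
  }
  utils::write.csv(data, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.meta_num <- function(meta, key) {
  v <- suppressWarnings(as.numeric(meta[[key]]))
  if (is.na(v)) stop("metadata key '", key, "' is not numeric")
  v
}

#' Read a block time-course CSV
#'
#' Schema: columns `t_s`, `i_norm`; metadata `tx_conc_uM`,
#' `application_start_s`, `application_end_s`, `condition`.
#'
#' @param path File path.
#' @return A `block_timecourse`-like list with `times`, `amplitudes`,
#'   `toxin_conc` (uM), `application_window` (s) and `condition`.
#' @export
read_timecourse_csv <- function(path) {
  x <- read_annotated_csv(
    path,
    required_meta = c("tx_conc_uM", "application_start_s",
                      "application_end_s", "condition"),
    required_cols = c("t_s", "i_norm")
  )
  tt <- x$data$t_s
  if (is.unsorted(tt, strictly = TRUE)) {
    stop("non-monotone time column 't_s' in ", path)
  }
  win <- c(.meta_num(x$meta, "application_start_s"),
           .meta_num(x$meta, "application_end_s"))
  if (win[1L] < min(tt) || win[2L] > max(tt)) {
    stop("application window lies outside the recorded span")
  }
  structure(
    list(times = tt, amplitudes = x$data$i_norm,
         toxin_conc = .meta_num(x$meta, "tx_conc_uM"),
         application_window = win,
         condition = x$meta[["condition"]]),
    class = "block_timecourse"
  )
}

#' @describeIn read_timecourse_csv Writer counterpart; `tc` needs
#'   `times`, `amplitudes`, `toxin_conc`, `application_window`,
#'   `condition`.
#' @param tc Time-course object.
#' @export
write_timecourse_csv <- function(tc, path) {
  write_annotated_csv(
    data.frame(t_s = tc$times, i_norm = tc$amplitudes),
    path,
    meta = list(
      tx_conc_uM = tc$toxin_conc,
      application_start_s = tc$application_window[1L],
      application_end_s = tc$application_window[2L],
      condition = tc$condition
    )
  )
}

#' Read a paired voltage-step trace CSV
#'
#' Schema: columns `t_ms`, `i_ctrl_uA`, `i_tx_uA`; metadata `v_mV`,
#' `vh_mV`, `tx_conc_uM`.
#'
#' @param path File path.
#' @return A [trace_pair()].
#' @export
read_trace_csv <- function(path) {
  x <- read_annotated_csv(
    path,
    required_meta = c("v_mV", "vh_mV", "tx_conc_uM"),
    required_cols = c("t_ms", "i_ctrl_uA", "i_tx_uA")
  )
  if (is.unsorted(x$data$t_ms, strictly = TRUE)) {
    stop("non-monotone time column 't_ms' in ", path)
  }
  trace_pair(
    x$data$t_ms, x$data$i_ctrl_uA, x$data$i_tx_uA,
    step_voltage = .meta_num(x$meta, "v_mV"),
    holding_voltage = .meta_num(x$meta, "vh_mV"),
    toxin_conc = .meta_num(x$meta, "tx_conc_uM")
  )
}

#' @describeIn read_trace_csv Writer counterpart.
#' @param pair A [trace_pair()].
#' @export
write_trace_csv <- function(pair, path) {
  write_annotated_csv(
    data.frame(t_ms = pair$times, i_ctrl_uA = pair$control_current,
               i_tx_uA = pair$toxin_current),
    path,
    meta = list(v_mV = pair$step_voltage, vh_mV = pair$holding_voltage,
                tx_conc_uM = pair$toxin_conc)
  )
}

#' Read a K+ titration CSV
#'
#' Schema: columns `k_mM`, `value`, `kind`, `cell_id`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_titration_csv <- function(path) {
  x <- read_annotated_csv(
    path,
    required_cols = c("k_mM", "value", "kind", "cell_id"),
    numeric_cols = c("k_mM", "value")
  )
  x$data
}

#' Read a tonic-inhibition CSV
#'
#' Schema: columns `v_mV`, `i_ratio`, `regime`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_tonic_csv <- function(path) {
  x <- read_annotated_csv(
    path,
    required_cols = c("v_mV", "i_ratio", "regime"),
    numeric_cols = c("v_mV", "i_ratio")
  )
  if (any(x$data$i_ratio < 0 | x$data$i_ratio > 1)) {
    stop("'i_ratio' values must lie in [0, 1]")
  }
  x$data
}
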