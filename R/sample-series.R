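#' Synchronized flow / PCO2 sample record
#'
#' The universal input of the pipeline: a two-channel time series of airflow
#' and CO2 partial pressure on an exact uniform grid (default 10 ms, the
#' acquisition interval of mainstream capnographs whose CO2 sensor tops out
#' at 100 Hz). Timestamps are stored as integer milliseconds so the grid
#' invariant is exact and needs no floating-point comparison.
#'
#' Sign convention: positive flow is expiration. Recordings with the opposite
#' polarity are handled at read time via `invert_flow` (see [read_series()]).
#'
#' @param t_ms Integer timestamps in ms from record start, strictly
#'   increasing with constant spacing `dt_ms`.
#' @param flow_lpm Signed airflow in L/min (positive = expiration).
#' @param pco2_mmhg CO2 partial pressure in mmHg; must be in `[0, 150]`
#'   (the sensor is characterized to 100 mmHg; values above 150 are
#'   physically implausible and rejected).
#' @param dt_ms Nominal sampling interval in ms (default 10).
#'
#' @return An object of class `sample_series`: a list with fields `t_ms`,
#'   `flow_lpm`, `pco2_mmhg`, `dt_ms`.
#' @seealso [read_series()], [write_series()], [segment_breaths()]
#' @export
#' @examples
#' s <- sample_series(c(0, 10, 20), c(0, 5, -5), c(0, 1, 38))
#' length(s$t_ms)
sample_series <- function(t_ms, flow_lpm, pco2_mmhg, dt_ms = 10L) {
  dt_ms <- as.integer(dt_ms)
  vc_assert(length(dt_ms) == 1L && !is.na(dt_ms) && dt_ms > 0L,
            "dt_ms must be a single positive integer")
  t_int <- as.integer(round(t_ms))
  vc_assert(!anyNA(t_int) && !anyNA(flow_lpm) && !anyNA(pco2_mmhg),
            "t_ms, flow_lpm and pco2_mmhg must not contain NA",
            "volcap_format_error")
  n <- length(t_int)
  if (n < 2L || length(flow_lpm) != n || length(pco2_mmhg) != n)
    vc_stop("t_ms, flow_lpm and pco2_mmhg must have identical length >= 2",
            "volcap_format_error")
  d <- diff(t_int)
  bad <- which(d != dt_ms)
  if (length(bad))
    vc_stop(sprintf(
      "non-uniform timestamp grid: expected spacing %d ms, first violation at index %d (t = %d ms)",
      dt_ms, bad[1] + 1L, t_int[bad[1] + 1L]), "volcap_grid_error")
  if (any(pco2_mmhg < 0))
    vc_stop("pco2_mmhg must be >= 0 everywhere", "volcap_format_error")
  if (any(pco2_mmhg > 150))
    vc_stop("pco2_mmhg above 150 mmHg is physically implausible for this instrument",
            "volcap_format_error")
  structure(list(t_ms = t_int,
                 flow_lpm = as.double(flow_lpm),
                 pco2_mmhg = as.double(pco2_mmhg),
                 dt_ms = dt_ms),
            class = "sample_series")
}

#' @export
print.sample_series <- function(x, ...) {
  dur_s <- (x$t_ms[length(x$t_ms)] - x$t_ms[1]) / 1000
  cat(sprintf("<sample_series> %d samples @ %d ms (%.1f s)\n",
              length(x$t_ms), x$dt_ms, dur_s))
  cat(sprintf("  flow  [%.2f, %.2f] L/min\n", min(x$flow_lpm), max(x$flow_lpm)))
  cat(sprintf("  pco2  [%.2f, %.2f] mmHg\n", min(x$pco2_mmhg), max(x$pco2_mmhg)))
  invisible(x)
}

#' @export
length.sample_series <- function(x) length(x$t_ms)

# default CSV dialect of the acquisition software
.vc_default_cols <- c(time = "t_ms", flow = "flow_lpm", pco2 = "pco2_mmhg")

#' Read a device CSV recording
#'
#' Reads the comma-separated dialect written by the acquisition software
#' (UTF-8, header `t_ms,flow_lpm,pco2_mmhg`, LF line endings, no quoting)
#' and returns a validated [sample_series()]. Rows with unparseable fields
#' are rejected with an error naming the row — never silently dropped.
#'
#' @param path Path to the CSV file.
#' @param config Optional named list of dialect options:
#'   \describe{
#'     \item{col_time, col_flow, col_pco2}{column names if they differ from
#'       the defaults `t_ms`, `flow_lpm`, `pco2_mmhg`.}
#'     \item{dt_ms}{expected sampling interval (default 10).}
#'     \item{invert_flow}{logical; multiply flow by -1 on read so that
#'       positive flow is expiration (default `FALSE`).}
#'   }
#' @return A `sample_series`.
#' @export
read_series <- function(path, config = list()) {
  vc_assert(is.character(path) && length(path) == 1L && nzchar(path),
            "path must be a non-empty string", "volcap_io_error")
  if (!file.exists(path))
    vc_stop(sprintf("file not found: %s", path), "volcap_io_error")
  cols <- c(time = config$col_time %||% .vc_default_cols[["time"]],
            flow = config$col_flow %||% .vc_default_cols[["flow"]],
            pco2 = config$col_pco2 %||% .vc_default_cols[["pco2"]])
  dt_ms <- config$dt_ms %||% 10L
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  for (nm in cols)
    if (!nm %in% names(raw))
      vc_stop(sprintf("missing required column '%s' in %s", nm, path),
              "volcap_format_error")
  parse_num <- function(column, label) {
    v <- suppressWarnings(as.numeric(raw[[column]]))
    bad <- which(is.na(v))
    if (length(bad))
      vc_stop(sprintf("unparseable %s value '%s' at data row %d of %s",
                      label, raw[[column]][bad[1]], bad[1], path),
              "volcap_format_error")
    v
  }
  flow <- parse_num(cols[["flow"]], "flow")
  if (isTRUE(config$invert_flow)) flow <- -flow
  sample_series(t_ms = parse_num(cols[["time"]], "time"),
                flow_lpm = flow,
                pco2_mmhg = parse_num(cols[["pco2"]], "pco2"),
                dt_ms = dt_ms)
}

#' Write a sample record to CSV
#'
#' Serializes with the fixed device dialect: integer ms timestamps and three
#' decimals for flow and PCO2 (exceeds sensor resolution; keeps files
#' diff-stable), LF line endings. [read_series()] of the result reproduces
#' the series exactly at that precision.
#'
#' @param series A [sample_series()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_series <- function(series, path) {
  vc_assert(inherits(series, "sample_series"), "series must be a sample_series",
            "volcap_contract_error")
  vc_assert(is.character(path) && length(path) == 1L && nzchar(path),
            "path must be a non-empty string", "volcap_io_error")
  lines <- c("t_ms,flow_lpm,pco2_mmhg",
             sprintf("%d,%.3f,%.3f", series$t_ms, series$flow_lpm,
                     series$pco2_mmhg))
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) vc_stop(
                    sprintf("cannot open '%s' for writing: %s", path,
                            conditionMessage(e)), "volcap_io_error"))
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Native-resolution flow stream
#'
#' The differential-pressure flow channel samples at a finer native interval
#' (0.5 ms) than the 10 ms record grid; the firmware emits per-window means.
#' This constructor holds the native stream for [downsample_flow()].
#'
#' @param t_native_ms Timestamps in ms, uniform spacing (e.g. 0.5).
#' @param flow_native_lpm Flow in L/min at those timestamps.
#' @return An object of class `raw_flow_stream`.
#' @export
raw_flow_stream <- function(t_native_ms, flow_native_lpm) {
  n <- length(t_native_ms)
  vc_assert(n >= 2L && length(flow_native_lpm) == n,
            "t_native_ms and flow_native_lpm must have identical length >= 2",
            "volcap_format_error")
  d <- diff(t_native_ms)
  if (any(abs(d - d[1]) > 1e-9))
    vc_stop("native timestamps must be uniformly spaced", "volcap_grid_error")
  structure(list(t_native_ms = as.double(t_native_ms),
                 flow_native_lpm = as.double(flow_native_lpm),
                 spacing_ms = d[1]),
            class = "raw_flow_stream")
}

#' Downsample a native flow stream onto the record grid
#'
#' Emulates the firmware: each output sample is the arithmetic mean of the
#' native samples whose timestamps fall in the window
#' `[k*dt_ms, (k+1)*dt_ms)`. A trailing partial window is dropped, not
#' averaged short, so window statistics stay homogeneous.
#'
#' @param raw A [raw_flow_stream()].
#' @param dt_ms Output interval in ms; the native spacing must divide it
#'   exactly (0.5 ms into 10 ms gives 20 samples per window).
#' @return Numeric vector of window means (L/min), length
#'   `floor(native duration / dt_ms)`.
#' @export
downsample_flow <- function(raw, dt_ms = 10) {
  vc_assert(inherits(raw, "raw_flow_stream"), "raw must be a raw_flow_stream",
            "volcap_contract_error")
  ratio <- dt_ms / raw$spacing_ms
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1)
    vc_stop(sprintf(
      "native spacing %.3g ms does not divide dt_ms = %.3g ms exactly",
      raw$spacing_ms, dt_ms), "volcap_config_error")
  ratio <- as.integer(round(ratio))
  nwin <- length(raw$flow_native_lpm) %/% ratio
  if (nwin == 0L) return(numeric(0))
  m <- matrix(raw$flow_native_lpm[seq_len(nwin * ratio)], nrow = ratio)
  .colMeans(m, ratio, nwin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
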