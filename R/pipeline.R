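#' Run the end-to-end demo pipeline
#'
#' simulate -> segment -> metrics -> capnogram -> compare, with every
#' intermediate artifact written to `out_dir`:
#' \itemize{
#'   \item `rec.csv` — the simulated recording (device CSV dialect)
#'   \item `truth.csv` — the simulator's ground-truth table
#'   \item `cycles.csv` — segmented cycles with Ti/Te
#'   \item `metrics.csv` — per-cycle ventilatory parameters
#'   \item `capnogram.csv` + `capnogram_fit.json` — volumetric capnogram and
#'     phase III fit of the first complete cycle
#'   \item `comparison.csv` — first half of the record vs second half
#'     (a null comparison; both halves come from the same simulated subject)
#'   \item `provenance.json` — package version, seed, config and its hash
#' }
#' All outputs are deterministic functions of the config and seed (no
#' timestamps), so repeated runs are byte-identical.
#'
#' @param config Named list as returned by [read_run_config()] (defaults
#'   used for missing entries).
#' @param out_dir Output directory; created if absent.
#' @param seed Optional seed overriding `config$seed`.
#' @return Invisibly, a named character vector of artifact paths.
#' @export
run_pipeline <- function(config = read_run_config(), out_dir, seed = NULL) {
  config <- utils::modifyList(read_run_config(), config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  vc_assert(is.character(out_dir) && length(out_dir) == 1L && nzchar(out_dir),
            "out_dir must be a non-empty string", "volcap_io_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  scfg <- sim_config(n_breaths = config$n_breaths,
                     vt_ml_mean = config$vt_ml_mean, vt_cv = config$vt_cv,
                     ti_s_mean = config$ti_s_mean,
                     te_s_mean = config$te_s_mean, time_cv = config$time_cv,
                     etco2_mmhg_mean = config$etco2_mmhg_mean,
                     etco2_sd = config$etco2_sd,
                     slope3_mmhg_per_l_mean = config$slope3_mmhg_per_l_mean,
                     slope3_cv = config$slope3_cv,
                     noise_flow_sd_lpm = config$noise_flow_sd_lpm,
                     noise_pco2_sd_mmhg = config$noise_pco2_sd_mmhg,
                     dt_ms = config$dt_ms, seed = config$seed)
  sim <- simulate_breathing(scfg)
  art <- c(rec = file.path(out_dir, "rec.csv"),
           truth = file.path(out_dir, "truth.csv"),
           cycles = file.path(out_dir, "cycles.csv"),
           metrics = file.path(out_dir, "metrics.csv"),
           capnogram = file.path(out_dir, "capnogram.csv"),
           capnogram_fit = file.path(out_dir, "capnogram_fit.json"),
           comparison = file.path(out_dir, "comparison.csv"),
           provenance = file.path(out_dir, "provenance.json"))
  write_series(sim$series, art[["rec"]])
  .write_csv(sim$truth, art[["truth"]])

  cycles <- segment_breaths(sim$series, deadband_lpm = config$deadband_lpm,
                            min_phase_ms = config$min_phase_ms,
                            apnea_ms = config$apnea_ms)
  .write_csv(phase_times(cycles, sim$series), art[["cycles"]])

  metrics <- metrics_for_record(sim$series, cycles,
                                patm_mmhg = config$patm_mmhg)
  .write_csv(metrics, art[["metrics"]])

  first <- which(metrics$complete)[1]
  if (is.na(first))
    vc_stop("pipeline produced no complete cycle to build a capnogram from",
            "volcap_numeric_error")
  cap <- build_capnogram(sim$series, cycles[first, ])
  fit <- fit_slope3(cap, config$slope3_window[1], config$slope3_window[2])
  .write_csv(data.frame(v_ml = cap$v_ml, pco2_mmhg = cap$pco2_mmhg),
             art[["capnogram"]])
  .write_json(unclass(fit), art[["capnogram_fit"]])

  ok <- metrics[isTRUE_vec(metrics$complete), ]
  half <- floor(nrow(ok) / 2)
  if (half >= 1) {
    cmp <- compare_tables(ok[seq_len(half), ], ok[(half + 1):nrow(ok), ])
    .write_csv(cmp, art[["comparison"]])
  } else {
    .write_csv(data.frame(parameter = character(0)), art[["comparison"]])
  }

  .write_json(.provenance(config, config$seed), art[["provenance"]])
  invisible(art)
}

.write_csv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

.write_json <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                              na = "null", pretty = TRUE), con)
  invisible(path)
}
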