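# Run configuration: plain-text `key: value` files (Debian-control style,
# parsed with base read.dcf). The documented schema is the union of the
# signal-processing options and the simulator parameters.

.vc_config_schema <- list(
  # signal processing
  dt_ms          = list(parse = as.numeric,  default = 10),
  invert_flow    = list(parse = function(x) as.logical(toupper(x)),
                        default = FALSE),
  patm_mmhg      = list(parse = as.numeric,  default = 760),
  deadband_lpm   = list(parse = as.numeric,  default = 0.5),
  min_phase_ms   = list(parse = as.numeric,  default = 150),
  apnea_ms       = list(parse = as.numeric,  default = 2000),
  slope3_window  = list(parse = function(x) {
    v <- as.numeric(strsplit(x, ",")[[1]])
    if (length(v) != 2 || anyNA(v)) vc_stop(
      "slope3_window must be two comma-separated fractions, e.g. '0.40,0.80'",
      "volcap_config_error")
    v
  }, default = c(0.40, 0.80)),
  # simulator
  n_breaths              = list(parse = as.integer, default = 20L),
  vt_ml_mean             = list(parse = as.numeric, default = 500),
  vt_cv                  = list(parse = as.numeric, default = 0.12),
  ti_s_mean              = list(parse = as.numeric, default = 1.8),
  te_s_mean              = list(parse = as.numeric, default = 2.4),
  time_cv                = list(parse = as.numeric, default = 0.08),
  etco2_mmhg_mean        = list(parse = as.numeric, default = 34.9),
  etco2_sd               = list(parse = as.numeric, default = 0.8),
  slope3_mmhg_per_l_mean = list(parse = as.numeric, default = 10),
  slope3_cv              = list(parse = as.numeric, default = 0.30),
  noise_flow_sd_lpm      = list(parse = as.numeric, default = 0.2),
  noise_pco2_sd_mmhg     = list(parse = as.numeric, default = 0.3),
  seed                   = list(parse = as.integer, default = 1L)
)

#' Read a run configuration file
#'
#' Configuration files are plain text, one `key: value` per line. Unknown
#' keys are an error (naming the key), so typos never silently fall back to
#' defaults. See `volcap:::.vc_config_schema` for the full schema; every key
#' is optional and the file itself may be omitted entirely.
#'
#' Recognized keys: `dt_ms`, `invert_flow`, `patm_mmhg`, `deadband_lpm`,
#' `min_phase_ms`, `apnea_ms`, `slope3_window` (two comma-separated
#' fractions), and the simulator parameters `n_breaths`, `vt_ml_mean`,
#' `vt_cv`, `ti_s_mean`, `te_s_mean`, `time_cv`, `etco2_mmhg_mean`,
#' `etco2_sd`, `slope3_mmhg_per_l_mean`, `slope3_cv`, `noise_flow_sd_lpm`,
#' `noise_pco2_sd_mmhg`, `seed`.
#'
#' @param path Path to the config file, or `NULL` for pure defaults.
#' @param overrides Named list applied on top of the file (e.g. from
#'   command-line flags); same keys as the file.
#' @return Named list with every schema key populated.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- lapply(.vc_config_schema, `[[`, "default")
  if (!is.null(path)) {
    if (!file.exists(path))
      vc_stop(sprintf("config file not found: %s", path), "volcap_io_error")
    m <- tryCatch(read.dcf(path), error = function(e)
      vc_stop(sprintf("cannot parse config file %s: %s", path,
                      conditionMessage(e)), "volcap_config_error"))
    if (nrow(m) > 0) {
      for (key in colnames(m)) {
        if (!key %in% names(.vc_config_schema))
          vc_stop(sprintf("unknown config key '%s' in %s", key, path),
                  "volcap_config_error")
        val <- m[1, key]
        if (!is.na(val)) {
          parsed <- suppressWarnings(.vc_config_schema[[key]]$parse(val))
          if (anyNA(parsed))
            vc_stop(sprintf("cannot parse config value '%s' for key '%s'",
                            val, key), "volcap_config_error")
          cfg[[key]] <- parsed
        }
      }
    }
  }
  for (key in names(overrides)) {
    if (!key %in% names(.vc_config_schema))
      vc_stop(sprintf("unknown config key '%s'", key), "volcap_config_error")
    if (!is.null(overrides[[key]])) cfg[[key]] <- overrides[[key]]
  }
  cfg
}

# deterministic provenance record written next to every pipeline output
.provenance <- function(cfg, seed) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tf)
  list(package = "volcap",
       version = as.character(utils::packageVersion("volcap")),
       seed = seed,
       config_md5 = unname(tools::md5sum(tf)),
       config = cfg)
}
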