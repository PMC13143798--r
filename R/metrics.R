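# Per-cycle ventilatory parameters.
#
# All integrals use the rectangular (left) rule at the record's own dt,
# mirroring the firmware's fixed-step integration; flow is converted
# L/min -> mL/ms (factor 1/60) so volumes come out in mL.

.lpm_to_ml_per_ms <- 1 / 60

.check_cycle <- function(series, cycle, need_complete = TRUE) {
  n <- length(series$t_ms)
  vc_assert(is.list(cycle) &&
              all(c("i_start", "i_rev", "i_end", "complete") %in% names(cycle)),
            "cycle must be a row of a breath_cycles data.frame",
            "volcap_contract_error")
  if (need_complete && !isTRUE(cycle$complete[1]))
    vc_stop("operation requires a complete cycle", "volcap_contract_error")
  i0 <- cycle$i_start[1]; ir <- cycle$i_rev[1]; ie <- cycle$i_end[1]
  vc_assert(i0 >= 1 && (is.na(ir) || (i0 < ir && ir <= ie)) && ie <= n,
            "cycle indices out of range for this series",
            "volcap_contract_error")
  list(i0 = i0, ir = ir, ie = ie)
}

#' Integrate flow into a volume over one phase
#'
#' Rectangular-rule volume of the (unsigned) flow over an index span lying
#' within a single respiratory phase:
#' `sum(|flow_k|) * dt / 60` mL with flow in L/min and dt in ms.
#'
#' @param series A [sample_series()].
#' @param from_idx,to_idx Inclusive 1-based index span.
#' @param check_phase If `TRUE` (default), raise a contract error when the
#'   span contains strong flow of both signs, i.e. crosses a phase boundary.
#' @param deadband_lpm Threshold used by the phase check.
#' @return Volume in mL (>= 0).
#' @export
#' @examples
#' s <- sample_series(seq(0, 990, 10), rep(30, 100), rep(40, 100))
#' integrate_volume(s, 1, 100)  # 30 L/min for 1 s = 500 mL
integrate_volume <- function(series, from_idx, to_idx, check_phase = TRUE,
                             deadband_lpm = 0.5) {
  vc_assert(inherits(series, "sample_series"), "series must be a sample_series",
            "volcap_contract_error")
  n <- length(series$t_ms)
  vc_assert(from_idx >= 1 && from_idx <= to_idx && to_idx <= n,
            "index span out of range", "volcap_contract_error")
  f <- series$flow_lpm[from_idx:to_idx]
  if (check_phase && any(f > deadband_lpm) && any(f < -deadband_lpm))
    vc_stop("index span crosses a phase boundary (strong flow of both signs)",
            "volcap_contract_error")
  sum(abs(f)) * .lpm_to_ml_per_ms * series$dt_ms
}

#' CO2 volume eliminated in one breath
#'
#' The flow-weighted CO2 integral over a full cycle, from the beginning of
#' inspiration to the end of expiration:
#' `sum(flow_k * pco2_k) / patm * dt`, with flow in mL/ms. Flow is signed,
#' so inspiratory samples enter with their (negative) sign; with inspired
#' PCO2 near zero — the mainstream, no-rebreathing case — their contribution
#' is negligible. The result is mL of CO2 at measurement conditions (no
#' BTPS/ATPS correction is applied).
#'
#' @param series A [sample_series()].
#' @param cycle One row of a `breath_cycles` data.frame (must be complete).
#' @param patm_mmhg Atmospheric pressure in mmHg (default 760).
#' @return CO2 volume in mL.
#' @export
vco2_per_breath <- function(series, cycle, patm_mmhg = 760) {
  vc_assert(is.numeric(patm_mmhg) && length(patm_mmhg) == 1L && patm_mmhg > 0,
            "patm_mmhg must be a single positive number")
  idx <- .check_cycle(series, cycle)
  span <- idx$i0:idx$ie
  f_mlms <- series$flow_lpm[span] * .lpm_to_ml_per_ms
  sum(f_mlms * series$pco2_mmhg[span]) / patm_mmhg * series$dt_ms
}

#' End-tidal CO2 of one cycle
#'
#' PCO2 at the sample where the cumulative expired volume reaches its
#' maximum (end of exhalation). Expiratory volume increments are clamped at
#' zero for negative-flow samples, so if flow dies before `i_end` while PCO2
#' keeps drifting, the value at the first sample of the volume plateau is
#' returned (ties break to the earliest maximal sample).
#'
#' @inheritParams vco2_per_breath
#' @return ETCO2 in mmHg.
#' @export
end_tidal_co2 <- function(series, cycle) {
  idx <- .check_cycle(series, cycle)
  span <- idx$ir:idx$ie
  v <- cumsum(pmax(series$flow_lpm[span], 0))
  series$pco2_mmhg[span][which.max(v)]
}

#' Peak expiratory flow of one cycle
#'
#' Maximum flow magnitude over the expiratory span, in L/min.
#'
#' @inheritParams vco2_per_breath
#' @return PEF in L/min.
#' @export
peak_expiratory_flow <- function(series, cycle) {
  idx <- .check_cycle(series, cycle)
  max(abs(series$flow_lpm[idx$ir:idx$ie]))
}

#' Per-cycle ventilatory parameter table
#'
#' Applies every per-cycle operation to each segmented cycle: Ti, Te
#' (see [phase_times()]), inspired and expired volumes Vi and Ve, ETCO2,
#' peak expiratory flow, and VCO2 per breath. Incomplete cycles yield
#' flagged rows with `NA` metrics; a per-cycle failure never aborts the
#' batch (the row is flagged instead).
#'
#' @param series A [sample_series()].
#' @param cycles A `breath_cycles` data.frame from [segment_breaths()].
#' @param patm_mmhg Atmospheric pressure in mmHg (default 760).
#' @return A data.frame of class `breath_metrics`, one row per cycle, with
#'   columns `cycle`, `i_start`, `i_rev`, `i_end`, `complete`, `ti_s`,
#'   `te_s`, `vi_ml`, `ve_ml`, `etco2_mmhg`, `pef_lpm`, `vco2_ml`,
#'   `patm_mmhg`.
#' @export
metrics_for_record <- function(series, cycles, patm_mmhg = 760) {
  cyc <- phase_times(cycles, series)
  nr <- nrow(cyc)
  vi <- ve <- et <- pef <- vco2 <- rep(NA_real_, nr)
  complete <- cyc$complete
  for (r in seq_len(nr)) {
    if (!isTRUE(complete[r])) next
    row <- cyc[r, , drop = FALSE]
    ok <- tryCatch({
      vi[r] <- integrate_volume(series, row$i_start, row$i_rev - 1L,
                                check_phase = FALSE)
      ve[r] <- integrate_volume(series, row$i_rev, row$i_end,
                                check_phase = FALSE)
      et[r] <- end_tidal_co2(series, row)
      pef[r] <- peak_expiratory_flow(series, row)
      vco2[r] <- vco2_per_breath(series, row, patm_mmhg)
      TRUE
    }, volcap_error = function(e) FALSE)
    if (!ok) complete[r] <- FALSE
  }
  out <- data.frame(cycle = seq_len(nr),
                    i_start = cyc$i_start, i_rev = cyc$i_rev,
                    i_end = cyc$i_end, complete = complete,
                    ti_s = cyc$ti_s, te_s = cyc$te_s,
                    vi_ml = vi, ve_ml = ve, etco2_mmhg = et,
                    pef_lpm = pef, vco2_ml = vco2,
                    patm_mmhg = rep(patm_mmhg, nr))
  class(out) <- c("breath_metrics", "data.frame")
  out
}
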