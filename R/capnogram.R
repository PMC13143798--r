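#' Build the volumetric capnogram of one expiration
#'
#' Plots of expired CO2 against expired volume (rather than time) are the
#' core object of volumetric capnography: cumulative rectangular integration
#' of the expiratory flow gives the volume axis, and PCO2 is read at the
#' same samples. Monotonicity of the volume axis is enforced by
#' construction: a negative-flow sample inside the expiration contributes a
#' zero increment and raises the `clamped` flag.
#'
#' @param series A [sample_series()].
#' @param cycle One complete row of a `breath_cycles` data.frame.
#' @return An object of class `volumetric_capnogram`: list with `v_ml`
#'   (non-decreasing cumulative expired volume), `pco2_mmhg`, `vt_ml`
#'   (total expired volume), `clamped` (logical), `dt_ms`.
#' @export
build_capnogram <- function(series, cycle) {
  idx <- .check_cycle(series, cycle)
  span <- idx$ir:idx$ie
  if (length(span) < 3L)
    vc_stop("degenerate capnogram: expiration shorter than 3 samples",
            "volcap_numeric_error")
  f <- series$flow_lpm[span]
  clamped <- any(f < 0)
  inc <- pmax(f, 0) * .lpm_to_ml_per_ms * series$dt_ms
  structure(list(v_ml = cumsum(inc),
                 pco2_mmhg = series$pco2_mmhg[span],
                 vt_ml = sum(inc),
                 clamped = clamped,
                 dt_ms = series$dt_ms),
            class = "volumetric_capnogram")
}

#' @export
print.volumetric_capnogram <- function(x, ...) {
  cat(sprintf("<volumetric_capnogram> %d samples, VT = %.1f mL, ETCO2 axis [%.1f, %.1f] mmHg%s\n",
              length(x$v_ml), x$vt_ml, min(x$pco2_mmhg), max(x$pco2_mmhg),
              if (x$clamped) " (clamped negative-flow samples)" else ""))
  invisible(x)
}

# ordinary least squares of p on v with the degenerate-response convention:
# zero-variance p gives slope 0 and r2 0 (with a warning), never NaN.
.ols_fit <- function(v, p) {
  vbar <- mean(v); pbar <- mean(p)
  sxx <- sum((v - vbar)^2)
  if (sxx <= 0)
    vc_stop("zero variance on the volume axis: cannot fit a slope",
            "volcap_numeric_error")
  slope <- sum((v - vbar) * (p - pbar)) / sxx
  intercept <- pbar - slope * vbar
  sst <- sum((p - pbar)^2)
  if (sst <= 0) {
    warning("zero-variance PCO2 in fit window; r2 defined as 0 by convention")
    r2 <- 0
  } else {
    r2 <- 1 - sum((p - (intercept + slope * v))^2) / sst
  }
  list(slope = slope, intercept = intercept, r2 = r2)
}

.slope_fit <- function(ols, v, p, vt_ml, lo_frac, hi_frac, kind) {
  slope_l <- ols$slope * 1000  # mmHg/mL -> mmHg/L
  mp <- mean(p)
  structure(list(slope_mmhg_per_l = slope_l,
                 intercept_mmhg = ols$intercept,
                 r2 = ols$r2,
                 lo_frac = lo_frac, hi_frac = hi_frac,
                 n_points = length(v),
                 normalized_slope = if (mp > 0) slope_l * (vt_ml / 1000) / mp
                                    else NA_real_,
                 vt_ml = vt_ml,
                 kind = kind),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("<slope_fit:%s> %.3f mmHg/L (intercept %.2f mmHg, r2 %.4f, n = %d, window %.0f%%-%.0f%% VT)\n",
              x$kind, x$slope_mmhg_per_l, x$intercept_mmhg, x$r2, x$n_points,
              100 * x$lo_frac, 100 * x$hi_frac))
  invisible(x)
}

#' Fit the phase III slope on a tidal-volume window
#'
#' Ordinary least-squares fit of PCO2 on expired volume over the samples
#' whose volume lies between `lo_frac` and `hi_frac` of total expired
#' volume (inclusive bounds), by default the conventional 40%-80% window.
#' The sample straddling a bound is included when its volume is within
#' bounds; no interpolation onto the exact fractional volumes is performed
#' (bias-free at 10 ms resolution). `normalized_slope` is the slope
#' multiplied by VT (in L) and divided by the mean window PCO2 —
#' dimensionless, the tidal-volume-normalized phase III slope of the
#' clinical literature.
#'
#' @param cap A [build_capnogram()] result.
#' @param lo_frac,hi_frac Window bounds as fractions of VT, `0 < lo < hi < 1`.
#' @return An object of class `slope_fit` with fields `slope_mmhg_per_l`,
#'   `intercept_mmhg`, `r2`, `lo_frac`, `hi_frac`, `n_points`,
#'   `normalized_slope`, `vt_ml`.
#' @export
fit_slope3 <- function(cap, lo_frac = 0.40, hi_frac = 0.80) {
  vc_assert(inherits(cap, "volumetric_capnogram"),
            "cap must be a volumetric_capnogram", "volcap_contract_error")
  vc_assert(lo_frac > 0 && hi_frac < 1 && lo_frac < hi_frac,
            "window fractions must satisfy 0 < lo_frac < hi_frac < 1")
  sel <- cap$v_ml >= lo_frac * cap$vt_ml & cap$v_ml <= hi_frac * cap$vt_ml
  if (sum(sel) < 3L)
    vc_stop(sprintf("insufficient window: %d samples in [%.0f%%, %.0f%%] of VT (need >= 3)",
                    sum(sel), 100 * lo_frac, 100 * hi_frac),
            "volcap_numeric_error", n_points = sum(sel))
  v <- cap$v_ml[sel]; p <- cap$pco2_mmhg[sel]
  .slope_fit(.ols_fit(v, p), v, p, cap$vt_ml, lo_frac, hi_frac, "slope3")
}

#' Fit the phase II slope (experimental convention)
#'
#' The steep CO2 upstroke has no standard fitting window; this function uses
#' an explicit, configurable, non-canonical convention: find the steepest
#' 3-sample central-difference gradient of PCO2 vs volume, expand the window
#' contiguously while the local gradient stays at or above `rel_threshold`
#' of that peak, and fit OLS on the result. On a capnogram with no distinct
#' upstroke (globally linear) the window spans the whole curve.
#'
#' @param cap A [build_capnogram()] result.
#' @param rel_threshold Fraction of the peak gradient at which the window
#'   stops expanding (default 0.5).
#' @param min_gradient Peak gradients at or below this (mmHg/mL) raise an
#'   insufficient-gradient error (flat capnogram).
#' @return A `slope_fit` (with `lo_frac`/`hi_frac` reporting the detected
#'   window as volume fractions).
#' @export
fit_slope2 <- function(cap, rel_threshold = 0.5, min_gradient = 1e-9) {
  vc_assert(inherits(cap, "volumetric_capnogram"),
            "cap must be a volumetric_capnogram", "volcap_contract_error")
  v <- cap$v_ml; p <- cap$pco2_mmhg
  n <- length(v)
  g <- rep(NA_real_, n)
  dv <- v[3:n] - v[1:(n - 2)]
  gc <- (p[3:n] - p[1:(n - 2)]) / ifelse(dv > 0, dv, NA_real_)
  g[2:(n - 1)] <- gc
  if (all(is.na(g)) || max(g, na.rm = TRUE) <= min_gradient)
    vc_stop("insufficient gradient: capnogram is flat, no phase II upstroke",
            "volcap_numeric_error")
  peak <- which.max(g)
  thr <- rel_threshold * g[peak]
  lo <- peak
  while (lo > 1L && !is.na(g[lo - 1L]) && g[lo - 1L] >= thr) lo <- lo - 1L
  hi <- peak
  while (hi < n && !is.na(g[hi + 1L]) && g[hi + 1L] >= thr) hi <- hi + 1L
  sel <- lo:hi
  if (length(sel) < 3L) sel <- max(1L, lo - 1L):min(n, hi + 1L)
  vv <- v[sel]; pp <- p[sel]
  .slope_fit(.ols_fit(vv, pp), vv, pp, cap$vt_ml,
             v[sel[1]] / cap$vt_ml, v[sel[length(sel)]] / cap$vt_ml, "slope2")
}

#' Cycle-to-cycle variability of fitted phase III slopes
#'
#' Mean, sample standard deviation (n - 1 denominator) and coefficient of
#' variation (%) of the phase III slope across the cycles of one record —
#' the quantity in which spontaneous breathing shows its characteristic
#' 25-50% intracycle variability.
#'
#' @param fits A list of `slope_fit` objects (>= 2).
#' @return A list with `n`, `mean_mmhg_per_l`, `sd_mmhg_per_l`, `cv_pct`.
#' @export
slope3_variability <- function(fits) {
  vc_assert(is.list(fits) && all(vapply(fits, inherits, TRUE, "slope_fit")),
            "fits must be a list of slope_fit objects", "volcap_contract_error")
  if (length(fits) < 2L)
    vc_stop("need at least 2 slope fits to assess variability",
            "volcap_numeric_error")
  s <- vapply(fits, function(f) f$slope_mmhg_per_l, numeric(1))
  m <- mean(s)
  sdv <- stats::sd(s)
  list(n = length(s), mean_mmhg_per_l = m, sd_mmhg_per_l = sdv,
       cv_pct = if (m != 0) 100 * sdv / m else NA_real_)
}
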