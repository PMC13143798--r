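# Static-bench sensor calibration: linear fit of measured on reference with
# R^2, a 95% CI on R^2 (Fisher z on r, then squared -- a stated convention,
# the bench literature does not define one), and the standard OLS 95%
# prediction band.

#' Reference designs of the static bench
#'
#' `flow_bench_design()`: flow set points 0-45 L/min in steps of 5
#' (10 levels), 5 repetitions per point in each of the two flow directions,
#' totalling 100 measurements. `co2_bench_design()`: CO2 set points
#' 0, 5, 10, 20, ..., 80, 100 mmHg (11 levels), 3 measurements per point at
#' each of 5 carrier flows (5, 10, 15, 20, 30 L/min), totalling 165.
#'
#' @return A data.frame with columns `reference` and a design label column
#'   (`direction` for flow, `carrier_flow_lpm` for CO2); `measured` is `NA`
#'   until filled by a bench run or [emulate_static_bench()].
#' @export
flow_bench_design <- function() {
  levels <- seq(0, 45, by = 5)
  d <- expand.grid(rep = 1:5, direction = c("inspiratory", "expiratory"),
                   reference = levels, stringsAsFactors = FALSE)
  data.frame(reference = d$reference, direction = d$direction,
             rep = d$rep, measured = NA_real_)
}

#' @rdname flow_bench_design
#' @export
co2_bench_design <- function() {
  levels <- c(0, 5, 10, 20, 30, 40, 50, 60, 70, 80, 100)
  d <- expand.grid(rep = 1:3, carrier_flow_lpm = c(5, 10, 15, 20, 30),
                   reference = levels)
  data.frame(reference = d$reference, carrier_flow_lpm = d$carrier_flow_lpm,
             rep = d$rep, measured = NA_real_)
}

#' Construct a linear calibration model directly
#'
#' For firmware-style use where the constants are known rather than fitted:
#' `corrected = correction_factor * (gain * raw + offset)`. The canonical
#' example is the flow-channel slope correction factor 1.438 applied with an
#' identity gain.
#'
#' @param gain Output units per input unit.
#' @param offset Additive offset in output units.
#' @param correction_factor Multiplicative slope correction (> 0).
#' @param r2,ci95_r2,prediction_band Optional fit diagnostics (filled by
#'   [fit_linear_calibration()]).
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(gain = 1, offset = 0, correction_factor = 1,
                              r2 = NA_real_, ci95_r2 = c(NA_real_, NA_real_),
                              prediction_band = NULL) {
  vc_assert(correction_factor > 0, "correction_factor must be > 0")
  if (!is.na(r2)) vc_assert(r2 >= 0 && r2 <= 1, "r2 must lie in [0, 1]")
  structure(list(gain = gain, offset = offset,
                 correction_factor = correction_factor,
                 r2 = r2, ci95_r2 = ci95_r2,
                 prediction_band = prediction_band),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> gain %.4f, offset %.4f, correction %.3f",
              x$gain, x$offset, x$correction_factor))
  if (!is.na(x$r2))
    cat(sprintf(", r2 %.4f (95%% CI %.4f-%.4f)", x$r2, x$ci95_r2[1], x$ci95_r2[2]))
  cat("\n")
  invisible(x)
}

#' Fit a linear sensor calibration to static-bench data
#'
#' OLS regression of `measured` on `reference` (the orientation is fixed and
#' documented: R^2 is orientation-invariant but the gain is not). Returns
#' the gain (slope), offset (intercept), R^2 with a 95% CI obtained by the
#' Fisher z-transform of r and squaring the transformed bounds, the standard
#' error of the gain, and per-point 95% prediction-interval half-widths from
#' the usual OLS prediction-variance formula.
#'
#' @param design A data.frame with numeric columns `reference` and
#'   `measured` (e.g. a filled [flow_bench_design()]); at least 3 distinct
#'   reference levels are required.
#' @param direction Optional: for flow designs with a `direction` column,
#'   restrict the fit to `"inspiratory"` or `"expiratory"` rows; the default
#'   pools both.
#' @return A `calibration_model` with additional fields `gain_se`, `sigma`,
#'   `n`, and `data` (the rows used).
#' @export
fit_linear_calibration <- function(design, direction = NULL) {
  vc_assert(is.data.frame(design) &&
              all(c("reference", "measured") %in% names(design)),
            "design must have 'reference' and 'measured' columns",
            "volcap_format_error")
  d <- design
  if (!is.null(direction)) {
    vc_assert("direction" %in% names(d),
              "design has no 'direction' column to subset on",
              "volcap_format_error")
    d <- d[d$direction == direction, , drop = FALSE]
  }
  d <- d[!is.na(d$measured), , drop = FALSE]
  x <- d$reference; y <- d$measured
  n <- length(x)
  vc_assert(n >= 3, "need at least 3 measurements", "volcap_numeric_error")
  if (length(unique(x)) < 2)
    vc_stop("all reference levels identical: design is rank-deficient",
            "volcap_numeric_error")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  gain <- unname(co[2]); offset <- unname(co[1])
  r <- stats::cor(x, y)
  r2 <- r^2
  # 95% CI on r via Fisher z, mapped through squaring (stated convention)
  if (n > 3 && abs(r) < 1) {
    z <- atanh(r); se_z <- 1 / sqrt(n - 3)
    rci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se_z)
    ci <- sort(rci^2)
  } else {
    ci <- c(r2, r2)
  }
  sm <- suppressWarnings(summary(fit))  # noiseless benches are legitimate
  sigma <- sm$sigma
  gain_se <- sm$coefficients[2, 2]
  xbar <- mean(x); sxx <- sum((x - xbar)^2)
  tq <- stats::qt(0.975, df = n - 2)
  band <- tq * sigma * sqrt(1 + 1 / n + (x - xbar)^2 / sxx)
  m <- calibration_model(gain = gain, offset = offset, correction_factor = 1,
                         r2 = min(1, max(0, r2)), ci95_r2 = ci,
                         prediction_band = band)
  m$gain_se <- gain_se
  m$sigma <- sigma
  m$n <- n
  m$data <- data.frame(reference = x, measured = y)
  m
}

#' Apply a calibration model to raw readings
#'
#' `corrected = correction_factor * (gain * raw + offset)`. With identity
#' gain and zero offset this is the firmware's multiplicative slope
#' correction (e.g. factor 1.438 on the flow channel).
#'
#' @param model A `calibration_model`.
#' @param raw Numeric vector of raw readings.
#' @return Corrected readings, same length as `raw`.
#' @export
apply_calibration <- function(model, raw) {
  vc_assert(inherits(model, "calibration_model"),
            "model must be a calibration_model", "volcap_contract_error")
  model$correction_factor * (model$gain * raw + model$offset)
}

#' Emulate a static calibration bench
#'
#' Generates `measured = true_gain * reference + N(0, noise_sd)` over a
#' bench design, seeded and reproducible — a synthetic stand-in for a
#' reference gas/flow bench, used to test gain recovery.
#'
#' @param true_gain True sensor gain.
#' @param noise_sd Measurement noise SD (>= 0), in measured units.
#' @param design `"flow"`, `"co2"`, or a data.frame with a `reference`
#'   column.
#' @param seed Integer RNG seed.
#' @param offset True additive offset (default 0).
#' @return The design data.frame with `measured` filled in.
#' @export
emulate_static_bench <- function(true_gain, noise_sd, design = "flow",
                                 seed = 1L, offset = 0) {
  vc_assert(noise_sd >= 0, "noise_sd must be >= 0")
  if (is.character(design)) {
    design <- switch(match.arg(design, c("flow", "co2")),
                     flow = flow_bench_design(),
                     co2 = co2_bench_design())
  }
  vc_assert(is.data.frame(design) && "reference" %in% names(design),
            "design must be 'flow', 'co2', or a data.frame with a 'reference' column",
            "volcap_format_error")
  with_preserved_seed(seed, {
    design$measured <- true_gain * design$reference + offset +
      stats::rnorm(nrow(design), 0, noise_sd)
  })
  design
}
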