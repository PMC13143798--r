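# A hand-built capnogram: constant expiratory flow so the volume axis is
# linear, with any PCO2(v) profile we want.
linear_capnogram_series <- function(pco2_of_v, vt_ml = 500, n = 100,
                                    flow_lpm = NULL) {
  # constant flow over n samples of 10 ms covering vt_ml
  flow_lpm <- flow_lpm %||% (vt_ml / (n * 10) * 60)  # L/min
  v <- cumsum(rep(flow_lpm / 60 * 10, n))
  s <- sample_series(seq(0, by = 10, length.out = 2 * n),
                     c(rep(-flow_lpm, n), rep(flow_lpm, n)),
                     c(rep(0, n), pco2_of_v(v)))
  list(series = s,
       cycle = data.frame(i_start = 1L, i_rev = n + 1L, i_end = 2L * n,
                          complete = TRUE))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("build_capnogram integrates volume and carries PCO2", {
  x <- linear_capnogram_series(function(v) 40 * v / 500, vt_ml = 500)
  cap <- build_capnogram(x$series, x$cycle)
  expect_s3_class(cap, "volumetric_capnogram")
  expect_equal(cap$vt_ml, 500)
  expect_equal(cap$v_ml, seq(5, 500, by = 5))
  expect_equal(cap$pco2_mmhg, 40 * cap$v_ml / 500)
  expect_false(cap$clamped)
  expect_true(all(diff(cap$v_ml) >= 0))
})

test_that("negative mid-expiration flow clamps to zero increment and flags", {
  n <- 50
  fl <- c(rep(-12, n), rep(12, n))
  fl[n + 25] <- -0.2
  s <- sample_series(seq(0, by = 10, length.out = 2 * n), fl, rep(30, 2 * n))
  cyc <- data.frame(i_start = 1L, i_rev = n + 1L, i_end = 2L * n,
                    complete = TRUE)
  cap <- build_capnogram(s, cyc)
  expect_true(cap$clamped)
  expect_equal(cap$v_ml[25] - cap$v_ml[24], 0)   # zero increment there
  expect_true(all(diff(cap$v_ml) >= 0))
  # degenerate expiration
  s3 <- sample_series(c(0, 10, 20, 30), c(-5, -5, -5, 5), rep(0, 4))
  cyc3 <- data.frame(i_start = 1L, i_rev = 4L, i_end = 4L, complete = TRUE)
  expect_error(build_capnogram(s3, cyc3), class = "volcap_numeric_error")
})

test_that("fit_slope3 recovers an exact line and honors the window", {
  x <- linear_capnogram_series(function(v) 25 + 8 * v / 1000, vt_ml = 800)
  cap <- build_capnogram(x$series, x$cycle)
  fit <- fit_slope3(cap)
  expect_equal(fit$slope_mmhg_per_l, 8, tolerance = 1e-10)
  expect_equal(fit$intercept_mmhg, 25, tolerance = 1e-10)
  expect_equal(fit$r2, 1)
  # every used sample satisfies the volume-fraction bounds; with inclusive
  # bounds on an 8 mL grid the window [320, 640] holds 41 samples
  expect_equal(fit$n_points, 41)
  # closed-form two-point oracle on exactly-linear input
  expect_equal(fit$normalized_slope, 8 * 0.8 / mean(cap$pco2_mmhg[
    cap$v_ml >= 0.4 * 800 & cap$v_ml <= 0.8 * 800]), tolerance = 1e-10)
})

test_that("fit_slope3 degenerate and windowing conventions", {
  x <- linear_capnogram_series(function(v) rep(36, length(v)))
  cap <- build_capnogram(x$series, x$cycle)
  expect_warning(fit <- fit_slope3(cap), "zero-variance")
  expect_equal(fit$slope_mmhg_per_l, 0)
  expect_equal(fit$r2, 0)
  # too few samples in the window (n = 4 leaves only 2 inside 40-80% VT)
  xx <- linear_capnogram_series(function(v) v / 20, n = 4)
  cap5 <- build_capnogram(xx$series, xx$cycle)
  expect_error(fit_slope3(cap5), class = "volcap_numeric_error")
  expect_error(fit_slope3(cap, lo_frac = 0.8, hi_frac = 0.4),
               class = "volcap_config_error")
})

test_that("window membership property on random capnograms", {
  set.seed(99)
  for (rep in 1:10) {
    lo <- runif(1, 0.2, 0.45); hi <- runif(1, 0.55, 0.9)
    n <- sample(60:200, 1)
    x <- linear_capnogram_series(function(v) 20 + cumsum(runif(length(v))),
                                 vt_ml = runif(1, 300, 1000), n = n)
    cap <- build_capnogram(x$series, x$cycle)
    sel <- cap$v_ml >= lo * cap$vt_ml & cap$v_ml <= hi * cap$vt_ml
    fit <- fit_slope3(cap, lo, hi)
    expect_equal(fit$n_points, sum(sel))
  }
})

test_that("fit_slope2 finds the sigmoid upstroke", {
  vt <- 600
  k <- 30  # sigmoid steepness in inverse VT fraction
  x <- linear_capnogram_series(function(v) 38 * plogis(k * (v / vt - 0.2)),
                               vt_ml = vt, n = 150)
  cap <- build_capnogram(x$series, x$cycle)
  fit <- fit_slope2(cap)
  # analytic max gradient at v* = 0.2 VT: 38 * k / (4 * vt) mmHg/mL
  g_max <- 38 * k / (4 * vt) * 1000  # mmHg/L
  mid_v <- (fit$lo_frac + fit$hi_frac) / 2 * vt
  expect_lt(abs(mid_v - 0.2 * vt), 2 * 4 + 1e-9)  # center within 2 samples of v*
  # analytic oracle for the OLS slope over the half-max-gradient window of a
  # logistic: window is |u| <= u0 with 4*s(1-s) = 1/2 at u0, and
  # slope = L*c * int u*(s(u)-1/2) du / int u^2 du (u = c*(v - v*))
  u0 <- log((1 + sqrt(0.5)) / (1 - sqrt(0.5)))  # logit((1 + sqrt(1/2)) / 2)
  i1 <- integrate(function(u) u * (plogis(u) - 0.5), -u0, u0)$value
  i2 <- 2 * u0^3 / 3
  slope_pred <- 38 * (k / vt) * i1 / i2 * 1000  # mmHg/L
  expect_equal(fit$slope_mmhg_per_l, slope_pred, tolerance = 0.03)
  expect_true(fit$slope_mmhg_per_l < g_max &&
                fit$slope_mmhg_per_l > 0.75 * g_max)
  # globally linear capnogram: window spans everything, slope = global slope
  xl <- linear_capnogram_series(function(v) 10 + 12 * v / 1000)
  capl <- build_capnogram(xl$series, xl$cycle)
  fl <- fit_slope2(capl)
  # central differences exist for interior samples only
  expect_equal(fl$n_points, length(capl$v_ml) - 2)
  expect_equal(fl$slope_mmhg_per_l, 12, tolerance = 1e-8)
  # flat capnogram
  xf <- linear_capnogram_series(function(v) rep(31, length(v)))
  expect_error(fit_slope2(build_capnogram(xf$series, xf$cycle)),
               class = "volcap_numeric_error")
})

test_that("slope3_variability: hand-computed CV and conventions", {
  mk <- function(sl) structure(list(slope_mmhg_per_l = sl), class = "slope_fit")
  same <- slope3_variability(list(mk(9), mk(9), mk(9)))
  expect_equal(same$cv_pct, 0)
  two <- slope3_variability(list(mk(8), mk(12)))
  expect_equal(two$mean_mmhg_per_l, 10)
  expect_equal(two$sd_mmhg_per_l, 2 * sqrt(2))  # sample SD convention
  expect_equal(two$cv_pct, 100 * 2 * sqrt(2) / 10, tolerance = 1e-12)
  expect_error(slope3_variability(list(mk(8))), class = "volcap_numeric_error")
})

test_that("simulator capnogram closes the loop: drawn slope III recovered", {
  cfg <- quiet_config(n_breaths = 6, slope3_mmhg_per_l_mean = 10, seed = 77)
  sim <- simulate_breathing(cfg)
  cy <- segment_breaths(sim$series)
  ok <- which(cy$complete)
  slopes <- vapply(seq_along(ok), function(i)
    fit_slope3(build_capnogram(sim$series, cy[ok[i], ]))$slope_mmhg_per_l,
    numeric(1))
  expect_true(all(abs(slopes - 10) / 10 < 0.02))  # discretization only
})
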