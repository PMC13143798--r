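# Seeded spontaneous-breathing simulator: the ground-truth-labelled test
# substrate for every other module.

# run expr with the given seed without disturbing the caller's RNG state
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration of the spontaneous-breathing simulator
#'
#' Defaults describe a healthy adult at rest breathing through a mouthpiece
#' (the scale of resting spontaneous breathing: tidal volume ~500 mL,
#' Ti 1.8 s, Te 2.4 s, ETCO2 ~35 mmHg) with mild cycle-to-cycle variability
#' and white Gaussian sensor noise on both channels. Cycle parameters are
#' drawn per breath from normal distributions (clamped away from
#' non-physical values so the draw count — hence reproducibility — is
#' independent of the draws).
#'
#' @param n_breaths Number of breaths to generate.
#' @param vt_ml_mean,vt_cv Tidal volume mean (mL) and coefficient of
#'   variation.
#' @param ti_s_mean,te_s_mean,time_cv Inspiratory/expiratory time means (s)
#'   and their common CV.
#' @param etco2_mmhg_mean,etco2_sd End-tidal CO2 mean and SD (mmHg).
#' @param slope3_mmhg_per_l_mean,slope3_cv Phase III slope mean (mmHg/L)
#'   and CV.
#' @param phase2_sharpness Sigmoid steepness of the CO2 upstroke (in units
#'   of inverse VT fraction; larger = sharper phase II).
#' @param phase2_mid_frac VT fraction at the upstroke midpoint.
#' @param insp_pco2_tau_ms Time constant of the inspiratory PCO2 washout
#'   toward 0 mmHg (mainstream sensor, no rebreathing).
#' @param noise_flow_sd_lpm,noise_pco2_sd_mmhg Channel noise SDs.
#' @param dt_ms Sampling interval of the generated record (default 10).
#' @param seed Integer seed; fixes the full output bit-for-bit.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_breaths = 20,
                       vt_ml_mean = 500, vt_cv = 0.12,
                       ti_s_mean = 1.8, te_s_mean = 2.4, time_cv = 0.08,
                       etco2_mmhg_mean = 34.9, etco2_sd = 0.8,
                       slope3_mmhg_per_l_mean = 10, slope3_cv = 0.30,
                       phase2_sharpness = 40, phase2_mid_frac = 0.15,
                       insp_pco2_tau_ms = 120,
                       noise_flow_sd_lpm = 0.2, noise_pco2_sd_mmhg = 0.3,
                       dt_ms = 10, seed = 1L) {
  cfg <- list(n_breaths = as.integer(n_breaths),
              vt_ml_mean = vt_ml_mean, vt_cv = vt_cv,
              ti_s_mean = ti_s_mean, te_s_mean = te_s_mean, time_cv = time_cv,
              etco2_mmhg_mean = etco2_mmhg_mean, etco2_sd = etco2_sd,
              slope3_mmhg_per_l_mean = slope3_mmhg_per_l_mean,
              slope3_cv = slope3_cv,
              phase2_sharpness = phase2_sharpness,
              phase2_mid_frac = phase2_mid_frac,
              insp_pco2_tau_ms = insp_pco2_tau_ms,
              noise_flow_sd_lpm = noise_flow_sd_lpm,
              noise_pco2_sd_mmhg = noise_pco2_sd_mmhg,
              dt_ms = dt_ms, seed = as.integer(seed))
  vc_assert(cfg$n_breaths >= 1, "n_breaths must be >= 1")
  means <- c(cfg$vt_ml_mean, cfg$ti_s_mean, cfg$te_s_mean,
             cfg$etco2_mmhg_mean, cfg$slope3_mmhg_per_l_mean)
  vc_assert(all(means > 0), "all simulator means must be > 0")
  cvs <- c(cfg$vt_cv, cfg$time_cv, cfg$slope3_cv, cfg$etco2_sd,
           cfg$noise_flow_sd_lpm, cfg$noise_pco2_sd_mmhg)
  vc_assert(all(cvs >= 0), "CVs and noise SDs must be >= 0")
  vc_assert(cfg$dt_ms > 0, "dt_ms must be > 0")
  if (min(cfg$ti_s_mean, cfg$te_s_mean) * 1000 < 3 * cfg$dt_ms)
    vc_stop("configuration implies a phase shorter than 3 samples",
            "volcap_config_error")
  class(cfg) <- "sim_config"
  cfg
}

# analytic single-breath waveform, vectorized over sample times within one
# breath (s = time since breath start, in seconds). Exported logic shared
# with the fine-grid oracle used in tests via simulate_breathing(dt_ms=...).
.breath_waveform <- function(s, vt, ti, te, etco2, slope3, k, mid, tau_s,
                             p_prev) {
  insp <- s < ti
  flow <- numeric(length(s))
  pco2 <- numeric(length(s))
  # half-sine flow, scaled so each phase integral equals VT:
  # amplitude = VT * pi / (2 * T) [mL/s] -> L/min via * 60/1000
  amp_i <- vt * pi / (2 * ti) * 0.06
  amp_e <- vt * pi / (2 * te) * 0.06
  flow[insp] <- -amp_i * sin(pi * s[insp] / ti)
  u <- s[!insp] - ti
  flow[!insp] <- amp_e * sin(pi * u / te)
  # inspiration: washout of the previous plateau toward 0 mmHg
  pco2[insp] <- p_prev * exp(-s[insp] / tau_s)
  # expiration: sigmoid phase II onto a phase III linear in expired volume;
  # the sigmoid is normalized to 1 at v = VT so the plateau end equals the
  # drawn ETCO2 exactly
  vfrac <- (1 - cos(pi * u / te)) / 2
  p3 <- etco2 - slope3 * vt * (1 - vfrac) / 1000
  sg <- stats::plogis(k * (vfrac - mid)) / stats::plogis(k * (1 - mid))
  pco2[!insp] <- p3 * sg
  list(flow = flow, pco2 = pco2)
}

#' Simulate a spontaneous-breathing recording with ground truth
#'
#' Generates a [sample_series()] of `n_breaths` spontaneous breaths plus a
#' ground-truth table of every drawn per-breath parameter and the continuous
#' (not grid-snapped) phase switch times. Flow is a half-sine per phase
#' scaled so each phase's integral equals the drawn tidal volume; expiratory
#' PCO2 is a sigmoid phase II upstroke joining a phase III that is linear in
#' expired volume and ends exactly at the drawn ETCO2; inspiratory PCO2
#' decays exponentially to 0 (no rebreathing). White Gaussian noise is added
#' per channel after waveform construction; PCO2 is clamped at 0 from below.
#'
#' @param config A [sim_config()].
#' @return A list of class `volcap_sim` with elements `series`
#'   (a `sample_series`), `truth` (data.frame: `breath`, `vt_ml`, `ti_s`,
#'   `te_s`, `etco2_mmhg`, `slope3_mmhg_per_l`, `t_start_s`, `t_rev_s`,
#'   `t_end_s`), and `config`.
#' @export
#' @examples
#' sim <- simulate_breathing(sim_config(n_breaths = 3, seed = 42))
#' sim$truth$vt_ml
simulate_breathing <- function(config = sim_config()) {
  vc_assert(inherits(config, "sim_config"), "config must be a sim_config",
            "volcap_contract_error")
  cfg <- config
  nb <- cfg$n_breaths
  with_preserved_seed(cfg$seed, {
    vt <- pmax(stats::rnorm(nb, cfg$vt_ml_mean, cfg$vt_cv * cfg$vt_ml_mean),
               0.2 * cfg$vt_ml_mean)
    ti <- pmax(stats::rnorm(nb, cfg$ti_s_mean, cfg$time_cv * cfg$ti_s_mean),
               max(0.3 * cfg$ti_s_mean, 3 * cfg$dt_ms / 1000))
    te <- pmax(stats::rnorm(nb, cfg$te_s_mean, cfg$time_cv * cfg$te_s_mean),
               max(0.3 * cfg$te_s_mean, 3 * cfg$dt_ms / 1000))
    et <- pmax(stats::rnorm(nb, cfg$etco2_mmhg_mean, cfg$etco2_sd), 5)
    s3 <- pmax(stats::rnorm(nb, cfg$slope3_mmhg_per_l_mean,
                            cfg$slope3_cv * cfg$slope3_mmhg_per_l_mean), 0)
    t_start <- cumsum(c(0, (ti + te)[-nb]))
    t_rev <- t_start + ti
    t_end <- t_start + ti + te
    total_s <- t_end[nb]
    dt_s <- cfg$dt_ms / 1000
    nsamp <- floor(total_s / dt_s) + 1L
    tt <- (seq_len(nsamp) - 1L) * dt_s
    b <- findInterval(tt, t_start)  # breath index per sample
    flow <- numeric(nsamp); pco2 <- numeric(nsamp)
    tau_s <- cfg$insp_pco2_tau_ms / 1000
    for (i in seq_len(nb)) {
      sel <- b == i
      if (!any(sel)) next
      w <- .breath_waveform(tt[sel] - t_start[i], vt[i], ti[i], te[i],
                            et[i], s3[i], cfg$phase2_sharpness,
                            cfg$phase2_mid_frac, tau_s,
                            p_prev = if (i == 1) 0 else et[i - 1])
      flow[sel] <- w$flow
      pco2[sel] <- w$pco2
    }
    if (cfg$noise_flow_sd_lpm > 0)
      flow <- flow + stats::rnorm(nsamp, 0, cfg$noise_flow_sd_lpm)
    if (cfg$noise_pco2_sd_mmhg > 0)
      pco2 <- pco2 + stats::rnorm(nsamp, 0, cfg$noise_pco2_sd_mmhg)
    pco2 <- pmax(pco2, 0)
    series <- sample_series(t_ms = round(tt * 1000), flow_lpm = flow,
                            pco2_mmhg = pco2, dt_ms = cfg$dt_ms)
    truth <- data.frame(breath = seq_len(nb), vt_ml = vt, ti_s = ti,
                        te_s = te, etco2_mmhg = et, slope3_mmhg_per_l = s3,
                        t_start_s = t_start, t_rev_s = t_rev, t_end_s = t_end)
    structure(list(series = series, truth = truth, config = cfg),
              class = "volcap_sim")
  })
}

#' @export
print.volcap_sim <- function(x, ...) {
  cat(sprintf("<volcap_sim> %d breaths, %d samples @ %g ms, seed %d\n",
              nrow(x$truth), length(x$series$t_ms), x$config$dt_ms,
              x$config$seed))
  invisible(x)
}
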