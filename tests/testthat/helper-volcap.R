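# Shared fixtures and independent oracles. Everything here is built in code
# at test time; nothing is loaded from disk.

# A minimal hand-built series: one clean square-wave breath.
# Inspiration: flow -flow_lpm, pco2 0; expiration: +flow_lpm, pco2 plateau.
square_breath_series <- function(flow_lpm = 30, pco2 = 40, phase_s = 1,
                                 dt_ms = 10) {
  n <- round(phase_s * 1000 / dt_ms)
  sample_series(t_ms = seq(0, by = dt_ms, length.out = 2 * n),
                flow_lpm = c(rep(-flow_lpm, n), rep(flow_lpm, n)),
                pco2_mmhg = c(rep(0, n), rep(pco2, n)),
                dt_ms = dt_ms)
}

square_cycle <- function(series) {
  n <- length(series$t_ms)
  data.frame(i_start = 1L, i_rev = n / 2 + 1L, i_end = n, complete = TRUE)
}

# Fine-grid (0.1 ms) independent oracle for the per-breath CO2 volume:
# re-derives the analytic waveform from the ground-truth parameters and
# integrates flow * pco2 / patm by brute force, never touching the package's
# integrators.
oracle_vco2_ml <- function(truth_row, cfg, patm = 760, p_prev = 0,
                           dt_fine_s = 1e-4) {
  vt <- truth_row$vt_ml; ti <- truth_row$ti_s; te <- truth_row$te_s
  et <- truth_row$etco2_mmhg; s3 <- truth_row$slope3_mmhg_per_l
  k <- cfg$phase2_sharpness; mid <- cfg$phase2_mid_frac
  tau <- cfg$insp_pco2_tau_ms / 1000
  # inspiration: flow [mL/s] negative half-sine, pco2 washout
  si <- seq(0, ti, by = dt_fine_s); si <- si[si < ti]
  fi <- -(vt * pi / (2 * ti)) * sin(pi * si / ti)
  pi_co2 <- p_prev * exp(-si / tau)
  # expiration
  se <- seq(0, te, by = dt_fine_s)
  fe <- (vt * pi / (2 * te)) * sin(pi * se / te)
  vfrac <- (1 - cos(pi * se / te)) / 2
  pe <- (et - s3 * vt * (1 - vfrac) / 1000) *
    plogis(k * (vfrac - mid)) / plogis(k * (1 - mid))
  (sum(fi * pi_co2) + sum(fe * pe)) * dt_fine_s / patm
}

# brute-force window means for the downsampler oracle
oracle_window_means <- function(flow, spacing_ms, dt_ms) {
  ratio <- round(dt_ms / spacing_ms)
  nwin <- length(flow) %/% ratio
  vapply(seq_len(nwin),
         function(k) mean(flow[((k - 1) * ratio + 1):(k * ratio)]),
         numeric(1))
}

# noiseless simulator config helper (explicit arguments win)
quiet_config <- function(...) {
  args <- utils::modifyList(
    list(noise_flow_sd_lpm = 0, noise_pco2_sd_mmhg = 0,
         vt_cv = 0, time_cv = 0, etco2_sd = 0, slope3_cv = 0),
    list(...))
  do.call(sim_config, args)
}
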