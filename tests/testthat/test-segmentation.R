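test_that("a single clean reversal yields one complete cycle", {
  s <- sample_series(seq(0, 50, 10), c(-5, -5, -5, 5, 5, 5), rep(0, 6))
  cy <- segment_breaths(s, deadband_lpm = 1, min_phase_ms = 20)
  expect_equal(nrow(cy), 1L)
  expect_equal(cy$i_start, 1L)
  expect_equal(cy$i_rev, 4L)
  expect_equal(cy$i_end, 6L)
  expect_true(cy$complete)
})

test_that("sub-deadband excursions do not split a phase", {
  s <- sample_series(seq(0, 60, 10), c(-5, -5, 0.5, -5, 5, 5, 5), rep(0, 7))
  cy <- segment_breaths(s, deadband_lpm = 1, min_phase_ms = 20)
  expect_equal(nrow(cy), 1L)
  expect_equal(cy$i_rev, 5L)  # the +0.5 blip at index 3 is absorbed
})

test_that("degenerate inputs give empty cycle lists", {
  quiet <- sample_series(seq(0, 990, 10), rep(0, 100), rep(0, 100))
  expect_equal(nrow(segment_breaths(quiet)), 0L)
  short <- sample_series(c(0, 10, 20), c(-5, -5, -5), c(0, 0, 0))
  expect_equal(nrow(segment_breaths(short, min_phase_ms = 150)), 0L)
})

test_that("leading partial expiration and trailing inspiration are flagged", {
  fl <- c(5, 5, 5, 5, -5, -5, -5, -5, 5, 5, 5, 5, -5, -5)
  s <- sample_series(seq(0, by = 10, length.out = length(fl)), fl,
                     rep(0, length(fl)))
  cy <- segment_breaths(s, deadband_lpm = 1, min_phase_ms = 20)
  expect_equal(nrow(cy), 3L)
  expect_false(cy$complete[1])        # leading expiration
  expect_true(is.na(cy$i_rev[1]))
  expect_true(cy$complete[2])         # full cycle
  expect_false(cy$complete[3])        # trailing inspiration, no expiration
  # tiling: segments partition the record
  expect_equal(cy$i_start[-1], head(cy$i_end, -1) + 1L)
  expect_equal(sum(cy$i_end - cy$i_start + 1L), length(fl))
})

test_that("segmentation recovers simulator cycles and boundaries (noiseless)", {
  cfg <- quiet_config(n_breaths = 12, ti_s_mean = 2.1, te_s_mean = 2.9,
                      vt_cv = 0.1, time_cv = 0.1, seed = 101)
  sim <- simulate_breathing(cfg)
  cy <- segment_breaths(sim$series)
  expect_equal(sum(cy$complete), 12L)
  ok <- cy[cy$complete, ]
  dt_s <- sim$series$dt_ms / 1000
  t_s <- sim$series$t_ms / 1000
  # boundaries within one sample of the continuous ground-truth switch times
  expect_true(all(abs(t_s[ok$i_rev] - sim$truth$t_rev_s) <= dt_s + 1e-9))
  expect_true(all(abs(t_s[ok$i_start] - sim$truth$t_start_s) <= dt_s + 1e-9))
})

test_that("time is conserved across segments (property, seeded)", {
  for (seed in 1:5) {
    sim <- simulate_breathing(sim_config(n_breaths = 8, seed = seed,
                                         noise_flow_sd_lpm = 0.4))
    cy <- segment_breaths(sim$series)
    expect_gt(nrow(cy), 0)
    expect_equal(cy$i_start[1], 1L)
    expect_equal(cy$i_end[nrow(cy)], length(sim$series$t_ms))
    if (nrow(cy) > 1)
      expect_equal(cy$i_start[-1], head(cy$i_end, -1) + 1L)
    # determinism / idempotence
    expect_identical(cy, segment_breaths(sim$series))
  }
})

test_that("increasing the deadband never increases the cycle count", {
  for (seed in 1:5) {
    sim <- simulate_breathing(sim_config(n_breaths = 10, seed = seed,
                                         noise_flow_sd_lpm = 0.5))
    counts <- vapply(c(0.2, 0.5, 1, 2, 4),
                     function(db) sum(segment_breaths(sim$series,
                                                      deadband_lpm = db)$complete),
                     numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("apneic gaps terminate the cycle instead of stretching Te", {
  dt <- 10
  breath <- function() c(rep(-10, 30), rep(10, 30))
  fl <- c(breath(), rep(0, 300), breath())  # 3 s of quiet between breaths
  s <- sample_series(seq(0, by = dt, length.out = length(fl)), fl,
                     rep(0, length(fl)))
  cy <- segment_breaths(s, deadband_lpm = 1, min_phase_ms = 100,
                        apnea_ms = 2000)
  expect_equal(sum(cy$complete), 2L)
  ok <- cy[cy$complete, ]
  # first cycle must end at most apnea_ms after its last strong sample
  expect_lte(ok$i_end[1], 60 + 2000 / dt + 1)
  # the gap row between them is incomplete with no reversal
  gap <- cy[!cy$complete, , drop = FALSE]
  expect_equal(nrow(gap), 1L)
  expect_true(is.na(gap$i_rev))
})

test_that("phase_times matches index arithmetic and flags incomplete cycles", {
  s <- sample_series(seq(0, 50, 10), c(-5, -5, -5, 5, 5, 5), rep(0, 6))
  cy <- segment_breaths(s, deadband_lpm = 1, min_phase_ms = 20)
  pt <- phase_times(cy, s)
  expect_equal(pt$ti_s, 0.02)
  expect_equal(pt$te_s, 0.02)
  cy$complete <- FALSE
  pt <- phase_times(cy, s)
  expect_true(is.na(pt$ti_s))
})

test_that("noisy boundary recovery: >= 95% of cycles within 2 samples", {
  # the continuous switch time lies off-grid, so a detector is scored by its
  # index distance to the ideal grid boundary (first sample strictly inside
  # the new phase)
  idx_err <- c()
  for (seed in 1:4) {
    cfg <- sim_config(n_breaths = 25, noise_flow_sd_lpm = 0.5,
                      noise_pco2_sd_mmhg = 0.3, seed = 200 + seed)
    sim <- simulate_breathing(cfg)
    cy <- segment_breaths(sim$series)
    ok <- cy[cy$complete, ]
    expect_equal(nrow(ok), 25)  # every breath recovered as one cycle
    dt_s <- sim$series$dt_ms / 1000
    idx_err <- c(idx_err,
                 ok$i_rev - (floor(sim$truth$t_rev_s / dt_s) + 2L),
                 ok$i_start - (floor(sim$truth$t_start_s / dt_s) + 2L))
  }
  expect_gte(mean(abs(idx_err) <= 2), 0.95)
})
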