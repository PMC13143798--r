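#' Segment a recording into respiratory cycles by flow reversal
#'
#' Partitions a [sample_series()] into inspiration-first respiratory cycles.
#' A raw sign change of the flow signal is accepted as a phase reversal only
#' when the new phase reaches beyond the `deadband_lpm` hysteresis threshold
#' and persists for at least `min_phase_ms` (Schmitt-trigger with debounce);
#' sub-threshold excursions around zero — sensor noise — never split a phase.
#'
#' Conventions (all deterministic and index-exact):
#' \itemize{
#'   \item Positive flow is expiration; a cycle is inspiration (`i_start` to
#'     `i_rev - 1`) followed by expiration (`i_rev` to `i_end`).
#'   \item The reversal index is the first sample whose flow is strictly of
#'     the new sign; exact-zero samples at a boundary stay with the phase
#'     being exited.
#'   \item Consecutive cycles tile the record: the next cycle starts at
#'     `i_end + 1` of the previous one.
#'   \item A record that begins mid-expiration contributes a leading partial
#'     (`complete = FALSE`, `i_rev = NA`); a trailing inspiration with no
#'     confirmed expiration is likewise partial. Cycles whose phases are
#'     shorter than `min_phase_ms` are flagged incomplete.
#'   \item Near-zero flow (`|flow| <= deadband`) lasting longer than
#'     `apnea_ms` terminates the current cycle instead of extending it
#'     indefinitely; the apneic gap beyond that limit is reported as an
#'     incomplete gap row (`i_rev = NA`).
#' }
#'
#' All indices are 1-based R indices into the series.
#'
#' @param series A [sample_series()].
#' @param deadband_lpm Hysteresis half-width in L/min (default 0.5).
#' @param min_phase_ms Minimum persistence of a new phase in ms (default 150).
#' @param apnea_ms Near-zero-flow duration that terminates a cycle
#'   (default 2000).
#' @return A data.frame of class `breath_cycles` with columns `i_start`,
#'   `i_rev`, `i_end`, `complete`. Returns zero rows for all-quiet records or
#'   records shorter than one `min_phase_ms`.
#' @export
#' @examples
#' s <- sample_series(seq(0, 50, 10), c(-5, -5, -5, 5, 5, 5), rep(0, 6))
#' segment_breaths(s, deadband_lpm = 1, min_phase_ms = 20)
segment_breaths <- function(series, deadband_lpm = 0.5, min_phase_ms = 150,
                            apnea_ms = 2000) {
  vc_assert(inherits(series, "sample_series"), "series must be a sample_series",
            "volcap_contract_error")
  vc_assert(deadband_lpm >= 0, "deadband_lpm must be >= 0")
  vc_assert(min_phase_ms >= series$dt_ms,
            "min_phase_ms must be >= the sampling interval")
  flow <- series$flow_lpm
  n <- length(flow)
  dt <- series$dt_ms
  mp <- max(1L, as.integer(ceiling(min_phase_ms / dt)))
  ap <- max(1L, as.integer(ceiling(apnea_ms / dt)))

  empty <- data.frame(i_start = integer(0), i_rev = integer(0),
                      i_end = integer(0), complete = logical(0))
  class(empty) <- c("breath_cycles", "data.frame")
  if (n < mp) return(empty)

  rsign <- sign(flow)
  strong <- ifelse(abs(flow) > deadband_lpm, rsign, 0)
  if (all(strong == 0)) return(empty)

  # state machine over samples
  seg_start <- integer(0); seg_end <- integer(0); seg_sign <- integer(0)
  push <- function(s, e, sg) {
    seg_start[[length(seg_start) + 1L]] <<- s
    seg_end[[length(seg_end) + 1L]] <<- e
    seg_sign[[length(seg_sign) + 1L]] <<- sg
  }
  cur_sign <- 0L; cur_start <- 1L
  cand <- NA_integer_       # first raw-sign-change sample of a tentative phase
  j_strong <- NA_integer_   # first sample beyond the deadband in the new phase
  lso <- 0L                 # most recent strong sample of the current phase
  weak_run <- 0L
  in_gap <- FALSE
  for (k in seq_len(n)) {
    if (strong[k] == 0) weak_run <- weak_run + 1L else weak_run <- 0L
    if (cur_sign == 0L) {
      if (strong[k] != 0L) {
        if (in_gap) {
          # close the apneic gap as its own segment; the new phase starts at
          # its first strong sample
          push(cur_start, k - 1L, 0L)
          cur_start <- k
          in_gap <- FALSE
        }
        cur_sign <- as.integer(strong[k])
      }
      next
    }
    if (weak_run > ap) {
      # apnea: close the cycle; the first apnea_ms of quiet stays with the
      # exited phase, the remainder becomes a gap
      push(cur_start, k, cur_sign)
      cur_start <- k + 1L; cur_sign <- 0L
      cand <- NA_integer_; j_strong <- NA_integer_
      in_gap <- TRUE
      next
    }
    if (rsign[k] == -cur_sign) {
      if (is.na(cand)) cand <- k
      if (strong[k] == -cur_sign && is.na(j_strong)) j_strong <- k
    } else if (strong[k] == cur_sign) {
      cand <- NA_integer_; j_strong <- NA_integer_
      lso <- k
    }
    if (!is.na(cand) && !is.na(j_strong) && (k - cand + 1L) >= mp) {
      b <- .refine_boundary(flow, cand, cur_start, lso, j_strong, k,
                            -cur_sign)
      push(cur_start, b - 1L, cur_sign)
      cur_start <- b
      cur_sign <- -cur_sign
      cand <- NA_integer_; j_strong <- NA_integer_
    }
  }
  if (cur_start <= n) push(cur_start, n, cur_sign)

  # assemble inspiration(-1) + expiration(+1) pairs into cycles
  out <- list()
  i <- 1L
  nseg <- length(seg_start)
  while (i <= nseg) {
    sg <- seg_sign[i]
    if (sg == -1L && i < nseg && seg_sign[i + 1L] == 1L) {
      insp_len <- seg_end[i] - seg_start[i] + 1L
      exp_len <- seg_end[i + 1L] - seg_start[i + 1L] + 1L
      out[[length(out) + 1L]] <- data.frame(
        i_start = seg_start[i], i_rev = seg_start[i + 1L],
        i_end = seg_end[i + 1L],
        complete = insp_len >= mp && exp_len >= mp)
      i <- i + 2L
    } else {
      # leading expiration, trailing inspiration, or apneic gap
      out[[length(out) + 1L]] <- data.frame(
        i_start = seg_start[i], i_rev = NA_integer_, i_end = seg_end[i],
        complete = FALSE)
      i <- i + 1L
    }
  }
  cycles <- do.call(rbind, out)
  rownames(cycles) <- NULL
  class(cycles) <- c("breath_cycles", "data.frame")
  cycles
}

# Place the confirmed reversal at the extremum of the running volume
# (signed cumulative flow) in a window around the first raw sign change:
# the reversal is, physically, where lung volume turns around, and the
# integration averages sensor noise out. This is exact on noiseless data
# (the extremum sits on the last sample before the zero crossing) and
# immune to the slope discontinuity at the reversal that biases line-fit
# approaches. Clamps keep the deterministic conventions exact: the boundary
# never precedes the sample after the old phase's last beyond-deadband
# sample (so sub-deadband blips and exact zeros stay with the phase being
# exited) and never follows the first beyond-deadband sample of the new
# phase.
.refine_boundary <- function(flow, cand, phase_start, last_strong_old,
                             first_strong_new, k, new_sign) {
  w0 <- max(phase_start, cand - (k - cand + 1L))
  cs <- cumsum(flow[w0:k] * new_sign)
  # last minimum = last sample still on the old side of the reversal; on
  # noiseless data this is exactly the sample before the zero crossing, and
  # the integration averages noise out around it
  b <- w0 + max(which(cs == min(cs)))
  b <- max(b, last_strong_old + 1L, phase_start + 1L)
  min(b, first_strong_new)
}

#' Inspiratory and expiratory times of segmented cycles
#'
#' Computes Ti and Te as the time difference between the last and first
#' samples of each phase: `Ti = t[i_rev - 1] - t[i_start]` and
#' `Te = t[i_end] - t[i_rev]`, both converted to seconds. Note that a phase
#' containing n samples spans `(n - 1) * dt`, so this estimator carries a
#' deterministic one-sample (-dt) bias relative to the continuous phase
#' duration; see the methods vignette.
#'
#' Incomplete cycles yield `NA` and are excluded from summaries downstream.
#'
#' @param cycles A `breath_cycles` data.frame from [segment_breaths()].
#' @param series The [sample_series()] the cycles index into.
#' @return `cycles` with numeric columns `ti_s` and `te_s` appended.
#' @export
phase_times <- function(cycles, series) {
  vc_assert(inherits(series, "sample_series"), "series must be a sample_series",
            "volcap_contract_error")
  vc_assert(is.data.frame(cycles) &&
              all(c("i_start", "i_rev", "i_end", "complete") %in% names(cycles)),
            "cycles must come from segment_breaths()", "volcap_contract_error")
  t <- series$t_ms
  n <- length(t)
  ti <- te <- rep(NA_real_, nrow(cycles))
  for (r in seq_len(nrow(cycles))) {
    if (!isTRUE(cycles$complete[r])) next
    i0 <- cycles$i_start[r]; ir <- cycles$i_rev[r]; ie <- cycles$i_end[r]
    vc_assert(i0 >= 1L && i0 < ir && ir <= ie && ie <= n,
              sprintf("cycle %d has invalid indices", r),
              "volcap_contract_error")
    ti[r] <- (t[ir - 1L] - t[i0]) / 1000
    te[r] <- (t[ie] - t[ir]) / 1000
  }
  cycles$ti_s <- ti
  cycles$te_s <- te
  cycles
}
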