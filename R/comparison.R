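# Two-device comparison of per-breath parameter tables: unpaired two-sided
# Mann-Whitney tests plus mean +/- SD summaries.

# exact null distribution of the Mann-Whitney U statistic: counts[u + 1] is
# the number of the choose(nx+ny, nx) rank arrangements with U = u.
# Recurrence N(u; n, m) = N(u - m; n - 1, m) + N(u; n, m - 1).
.u_counts <- function(nx, ny) {
  tab <- vector("list", (nx + 1L) * (ny + 1L))
  idx <- function(i, j) i * (ny + 1L) + j + 1L
  for (j in 0:ny) tab[[idx(0L, j)]] <- 1
  for (i in seq_len(nx)) {
    tab[[idx(i, 0L)]] <- 1
    for (j in seq_len(ny)) {
      a <- tab[[idx(i - 1L, j)]]
      b <- tab[[idx(i, j - 1L)]]
      len <- i * j + 1L
      va <- numeric(len); va[(j + 1L):(j + length(a))] <- a
      vb <- numeric(len); vb[seq_along(b)] <- b
      tab[[idx(i, j)]] <- va + vb
    }
  }
  tab[[idx(nx, ny)]]
}

#' Mann-Whitney U test
#'
#' Two-sided unpaired rank test. The p-value is exact — computed from the
#' full enumeration of the U null distribution — when there are no ties and
#' `nx * ny <= exact_max`; otherwise the normal approximation with tie
#' correction and a continuity correction is used. `U_x + U_y = nx * ny` is
#' asserted on every call.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact path;
#'   `NULL` (default) selects automatically. Forcing `TRUE` with ties is an
#'   error: the enumeration assumes distinct ranks.
#' @param exact_max Automatic-exact threshold on `nx * ny` (default 400).
#' @return A list with `u` (U of `x`), `u_y`, `p_value`, and `method`
#'   (`"exact"` or `"normal_approx"`).
#' @export
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
mann_whitney <- function(x, y, exact = NULL, exact_max = 400) {
  vc_assert(length(x) >= 1 && length(y) >= 1 && !anyNA(x) && !anyNA(y),
            "x and y must be non-empty samples without NA")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  ux <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  uy <- nx * ny - ux
  stopifnot(isTRUE(all.equal(ux + uy, nx * ny)))
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- if (is.null(exact)) !ties && nx * ny <= exact_max else exact
  if (use_exact && ties)
    vc_stop("exact Mann-Whitney p-value requested but the data contain ties",
            "volcap_config_error")
  if (use_exact) {
    cnt <- .u_counts(nx, ny)
    total <- sum(cnt)
    u <- round(ux)
    lo <- sum(cnt[seq_len(u + 1L)]) / total          # P(U <= u)
    hi <- sum(cnt[(u + 1L):length(cnt)]) / total     # P(U >= u)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    mu <- nx * ny / 2
    nn <- nx + ny
    tie_tab <- table(c(x, y))
    tie_term <- sum(tie_tab^3 - tie_tab)
    s2 <- nx * ny / 12 * ((nn + 1) - tie_term / (nn * (nn - 1)))
    if (s2 <= 0) {
      p <- 1
    } else {
      z <- max(0, abs(ux - mu) - 0.5) / sqrt(s2)
      p <- 2 * stats::pnorm(-z)
    }
    method <- "normal_approx"
  }
  list(u = ux, u_y = uy, p_value = p, method = method)
}

#' Parameter-wise comparison of two per-breath metric tables
#'
#' Builds the familiar device-comparison layout: one row per ventilatory
#' parameter with mean and SD (sample SD, n - 1) in each group and the
#' unpaired two-sided Mann-Whitney U and p. Only complete cycles enter.
#' No multiple-testing correction is applied by default (`holm = TRUE`
#' adjusts the p column with Holm's method).
#'
#' @param metrics_a,metrics_b [metrics_for_record()] tables (or any
#'   data.frames with the requested numeric columns and, optionally, a
#'   `complete` column).
#' @param parameters Character vector of column names to compare; defaults
#'   to the seven standard parameters.
#' @param holm Apply Holm adjustment to the p-values (default `FALSE`).
#' @return A data.frame of class `device_comparison` with columns
#'   `parameter`, `n_a`, `n_b`, `mean_a`, `sd_a`, `mean_b`, `sd_b`,
#'   `u_statistic`, `p_value`.
#' @export
compare_tables <- function(metrics_a, metrics_b,
                           parameters = c("etco2_mmhg", "ti_s", "te_s",
                                          "vi_ml", "ve_ml", "pef_lpm",
                                          "vco2_ml"),
                           holm = FALSE) {
  take <- function(m, p) {
    if (!p %in% names(m))
      vc_stop(sprintf("unknown parameter '%s'; available: %s", p,
                      paste(names(m)[vapply(m, is.numeric, TRUE)],
                            collapse = ", ")),
              "volcap_config_error")
    v <- m[[p]]
    if ("complete" %in% names(m)) v <- v[isTRUE_vec(m$complete)]
    v <- v[!is.na(v)]
    if (length(v) < 1)
      vc_stop(sprintf("no complete cycles with values for '%s'", p),
              "volcap_numeric_error")
    v
  }
  rows <- lapply(parameters, function(p) {
    a <- take(metrics_a, p); b <- take(metrics_b, p)
    mw <- mann_whitney(a, b)
    data.frame(parameter = p, n_a = length(a), n_b = length(b),
               mean_a = mean(a), sd_a = if (length(a) > 1) stats::sd(a) else 0,
               mean_b = mean(b), sd_b = if (length(b) > 1) stats::sd(b) else 0,
               u_statistic = mw$u, p_value = mw$p_value)
  })
  out <- do.call(rbind, rows)
  if (holm) out$p_value <- stats::p.adjust(out$p_value, method = "holm")
  rownames(out) <- NULL
  class(out) <- c("device_comparison", "data.frame")
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Render a comparison table as Markdown
#'
#' Mean ± SD formatting: one decimal for pressures and times, integers for
#' volumes, two decimals for p.
#'
#' @param comparison A [compare_tables()] result.
#' @return Character vector of Markdown lines.
#' @export
format_comparison_md <- function(comparison) {
  vc_assert(inherits(comparison, "device_comparison"),
            "comparison must come from compare_tables()",
            "volcap_contract_error")
  fmt <- function(m, s, p) {
    if (grepl("_ml$", p) && !grepl("vco2", p))
      sprintf("%.0f ± %.0f", m, s)
    else sprintf("%.1f ± %.1f", m, s)
  }
  c("| Parameter | A (mean ± SD) | B (mean ± SD) | U | p |",
    "|---|---|---|---|---|",
    vapply(seq_len(nrow(comparison)), function(i) {
      r <- comparison[i, ]
      sprintf("| %s | %s | %s | %.0f | %.2f |", r$parameter,
              fmt(r$mean_a, r$sd_a, r$parameter),
              fmt(r$mean_b, r$sd_b, r$parameter),
              r$u_statistic, r$p_value)
    }, character(1)))
}
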