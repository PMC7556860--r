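#' Full Experiment-1-style inference chain
#'
#' Given a cohort table (from [generate_cohort()]) or a list of figure
#' source-data tables (from [read_source_data()]), computes the complete
#' correlation chain with the declared one-tailed directions and Holm
#' families:
#'
#' * hearing loss vs masking slopes (family of 2: negative for the low
#'   slope, positive for the high slope);
#' * the six pairwise modulation-threshold correlations (family of 6, all
#'   one-tailed positive);
#' * the eight FM-slope correlations — four zero-order and four partial,
#'   controlling for age, 1-kHz threshold and the rate-matched AM
#'   threshold (family of 8; negative for low-slope pairs, positive for
#'   high-slope pairs);
#' * the four slope-AM correlations (family of 4);
#' * Steiger Z comparisons: FM-vs-AM attachment to the low slope at each
#'   rate, and low-vs-high slope attachment to FM at each rate;
#' * hierarchical OLS per FM rate with entry order 1-kHz threshold, age,
#'   rate-matched AM, low slope, high slope (cohort input only — the
#'   published residual files carry no age column), plus the
#'   slopes-entered-first decomposition whose first increment equals the
#'   squared zero-order correlation.
#'
#' When the input is a source-data list, the partial correlations are
#' computed from the figure-5 residual columns (correlating residuals
#' directly, with df reduced by the 3 covariates used to form them).
#'
#' @param data a `cohort_table`, or a named list with elements `fig2`,
#'   `fig3`, `fig4` and optionally `fig5` as returned by
#'   [read_source_data()].
#' @return A `stat_report` list of data.frames (`fig2`, `fig3`,
#'   `fm_slopes`, `am_slopes`, `steiger`, and per-rate `hierarchical`
#'   fits when age is available).
#' @export
analyze_exp1 <- function(data) {
  if (inherits(data, "cohort_table")) {
    d <- data
    has_age <- TRUE
    partial_mode <- "covariates"
  } else {
    stopifnot(is.list(data), all(c("fig2", "fig3", "fig4") %in% names(data)))
    d <- cbind(data$fig2[c("thresh_1k", "low_slope", "high_slope")],
               data$fig3[c("slow_fm", "fast_fm", "slow_am", "fast_am")])
    names(d)[names(d) == "thresh_1k"] <- "abs_thresh_1k"
    d$subject <- data$fig2$subject
    has_age <- FALSE
    partial_mode <- if ("fig5" %in% names(data)) "residuals" else "none"
  }
  ct <- function(x, y, tail, fam) pearson_ci(d[[x]], d[[y]], tail = tail,
                                             family_id = fam)
  row_of <- function(label, cr) data.frame(
    pair = label, r = cr$r, n = cr$n, p_raw = cr$p_raw,
    ci_lo = cr$ci95[1], ci_hi = cr$ci95[2], tail = cr$tail,
    stringsAsFactors = FALSE)
  finish <- function(rows) {
    out <- do.call(rbind, rows)
    out$p_holm <- holm_adjust(out$p_raw)
    out
  }
  # family 1: hearing loss vs slopes (2 comparisons)
  fig2 <- finish(list(
    row_of("thresh_1k ~ low_slope",
           ct("abs_thresh_1k", "low_slope", "negative", "fig2")),
    row_of("thresh_1k ~ high_slope",
           ct("abs_thresh_1k", "high_slope", "positive", "fig2"))))
  # family 2: the six modulation-threshold correlations
  mods <- c("slow_fm", "fast_fm", "slow_am", "fast_am")
  prs <- utils::combn(mods, 2)
  fig3 <- finish(lapply(seq_len(ncol(prs)), function(j)
    row_of(paste(prs[1, j], "~", prs[2, j]),
           ct(prs[1, j], prs[2, j], "positive", "fig3"))))
  # family 3: FM vs slopes, zero-order + partial (8 comparisons)
  tail_for <- function(slope) if (slope == "low_slope") "negative" else "positive"
  fm_rows <- list()
  for (slope in c("low_slope", "high_slope")) for (fm in c("slow_fm", "fast_fm")) {
    fm_rows[[paste(slope, fm)]] <-
      row_of(paste(slope, "~", fm), ct(slope, fm, tail_for(slope), "fm_slopes"))
  }
  if (partial_mode == "covariates") {
    for (slope in c("low_slope", "high_slope")) for (fm in c("slow_fm", "fast_fm")) {
      am <- if (fm == "slow_fm") "slow_am" else "fast_am"
      cr <- partial_correlation(d[[slope]], d[[fm]],
                                covariates = d[c("age", "abs_thresh_1k", am)],
                                tail = tail_for(slope), family_id = "fm_slopes")
      fm_rows[[paste(slope, fm, "partial")]] <-
        row_of(paste(slope, "~", fm, "| age, thresh, AM"), cr)
    }
  } else if (partial_mode == "residuals") {
    f5 <- data$fig5
    pc_from_res <- function(xr, yr, tail) {
      cr <- pearson_ci(f5[[xr]], f5[[yr]], tail = tail, family_id = "fm_slopes")
      # df and CI must reflect the 3 covariates already regressed out
      k <- 3; n <- cr$n; r <- cr$r
      df <- n - 2 - k
      tstat <- r * sqrt(df / (1 - r^2))
      cr$df <- df; cr$t <- tstat
      cr$p_raw <- switch(tail,
                         two = 2 * stats::pt(-abs(tstat), df),
                         positive = stats::pt(tstat, df, lower.tail = FALSE),
                         negative = stats::pt(tstat, df))
      cr$ci95 <- tanh(atanh(r) + c(-1, 1) * stats::qnorm(.975) / sqrt(n - 3 - k))
      cr
    }
    fm_rows[["low slow partial"]] <- row_of(
      "low_slope ~ slow_fm | residual file",
      pc_from_res("low_slope_res_slow", "slow_fm_res", "negative"))
    fm_rows[["low fast partial"]] <- row_of(
      "low_slope ~ fast_fm | residual file",
      pc_from_res("low_slope_res_fast", "fast_fm_res", "negative"))
    fm_rows[["high slow partial"]] <- row_of(
      "high_slope ~ slow_fm | residual file",
      pc_from_res("high_slope_res_slow", "slow_fm_res", "positive"))
    fm_rows[["high fast partial"]] <- row_of(
      "high_slope ~ fast_fm | residual file",
      pc_from_res("high_slope_res_fast", "fast_fm_res", "positive"))
  }
  fm_slopes <- finish(fm_rows)
  # family 4: AM vs slopes (4 comparisons)
  am_rows <- list()
  for (slope in c("low_slope", "high_slope")) for (am in c("slow_am", "fast_am")) {
    am_rows[[paste(slope, am)]] <-
      row_of(paste(slope, "~", am), ct(slope, am, tail_for(slope), "am_slopes"))
  }
  am_slopes <- finish(am_rows)
  # Steiger comparisons (dependent overlapping correlations)
  stg <- list()
  for (rate in c("slow", "fast")) {
    fm <- paste0(rate, "_fm"); am <- paste0(rate, "_am")
    z1 <- steiger_z(stats::cor(d$low_slope, d[[fm]]),
                    stats::cor(d$low_slope, d[[am]]),
                    stats::cor(d[[fm]], d[[am]]), n = nrow(d))
    stg[[paste0(rate, "_fm_vs_am")]] <- data.frame(
      comparison = sprintf("low_slope: %s FM vs %s AM", rate, rate),
      z = z1$z, p = z1$p, stringsAsFactors = FALSE)
    z2 <- steiger_z(stats::cor(d[[fm]], d$low_slope),
                    stats::cor(d[[fm]], d$high_slope),
                    stats::cor(d$low_slope, d$high_slope), n = nrow(d))
    stg[[paste0(rate, "_low_vs_high")]] <- data.frame(
      comparison = sprintf("%s FM: low vs high slope", rate),
      z = z2$z, p = z2$p, stringsAsFactors = FALSE)
  }
  steiger <- do.call(rbind, stg)
  out <- list(fig2 = fig2, fig3 = fig3, fm_slopes = fm_slopes,
              am_slopes = am_slopes, steiger = steiger, n = nrow(d))
  if (has_age) {
    out$hierarchical <- lapply(c(slow = "slow", fast = "fast"), function(rate) {
      fm <- paste0(rate, "_fm"); am <- paste0(rate, "_am")
      preds <- d[c("abs_thresh_1k", "age", am, "low_slope", "high_slope")]
      list(conservative = hierarchical_ols(d[[fm]], preds),
           slopes_first = hierarchical_ols(
             d[[fm]], preds[c("low_slope", "high_slope", "abs_thresh_1k",
                              "age", am)]))
    })
  }
  class(out) <- "stat_report"
  out
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("Experiment-1 statistics (n = %d)\n", x$n))
  for (nm in c("fig2", "fig3", "fm_slopes", "am_slopes")) {
    cat("\n--", nm, "family --\n")
    print(format(x[[nm]], digits = 3), row.names = FALSE)
  }
  cat("\n-- dependent-correlation comparisons --\n")
  print(format(x$steiger, digits = 3), row.names = FALSE)
  invisible(x)
}
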