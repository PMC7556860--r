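#' Default generator parameters for the Experiment-2-style cohort
#'
#' Cell-mean templates for the AM-dyad discrimination task (thresholds in
#' 20log10(m) dB over 3 center frequencies x 2 rates x 2 separations) and
#' the complex-AM detection task (d-prime over the same cells x 2 modulator
#' phase relations), with subject random intercepts. The discrimination
#' template builds in the center-frequency x rate interaction (a slow-rate
#' advantage at 500 and 1500 Hz that vanishes at 7000 Hz) through a
#' product-form interaction that can be scaled or zeroed with
#' `interaction_scale`; the detection template carries an opposite-phase
#' benefit confined to slow rates at low center frequencies, scaled by
#' `phase_boost_scale`.
#'
#' @param ... named overrides.
#' @return list of parameters.
#' @export
exp2_params <- function(...) {
  p <- list(
    centers = c(500, 1500, 7000),
    rates = c("slow", "fast"),
    separations = c("nrw", "wide"),
    # discrimination thresholds, 20log10(m) dB
    disc_base = -4.5,
    disc_center = c(`500` = -0.5, `1500` = -1.5, `7000` = 2),
    disc_rate = c(slow = -5 / 6, fast = 5 / 6),
    # product interaction: g(center) * h(rate); slow-fast difference per
    # center = 2*rate diff + 2*g = (-2, -3, 0) at the default scale
    disc_interaction_g = c(`500` = 1 / 6, `1500` = 2 / 3, `7000` = -5 / 6),
    interaction_scale = 1,
    disc_sep = c(nrw = 0.5, wide = -0.5),
    disc_sep_center = c(`500` = -0.4, `1500` = 0.8, `7000` = -0.4),
    disc_subject_sd = 1.2,
    disc_run_sd = 2.4, disc_runs = 4,
    # detection d-prime
    det_base = 1.0,
    det_center = c(`500` = 0.1, `1500` = 0.1, `7000` = -0.2),
    det_rate = c(slow = 0.05, fast = -0.05),
    det_phase_boost = matrix(c(0.8, 0, 0.5, 0, 0, 0), nrow = 3, byrow = TRUE,
                             dimnames = list(c("500", "1500", "7000"),
                                             c("slow", "fast"))),
    phase_boost_scale = 1,
    det_subject_sd = 0.3,
    det_trials = 100
  )
  utils::modifyList(p, list(...))
}

#' Generate a synthetic Experiment-2-style cohort
#'
#' Produces tidy discrimination-threshold and complex-AM-detection tables
#' for `n` subjects under the [exp2_params()] cell-mean model.
#' Discrimination thresholds are the mean of `disc_runs` simulated runs
#' (cell mean + subject effect + run noise); detection performance is
#' simulated as `det_trials` Bernoulli trials at the probability implied by
#' the true cell d-prime (`pc = pnorm(dprime/sqrt(2))`, 2AFC) and converted
#' back to d-prime from the observed proportion correct with
#' [pc_to_dprime()].
#'
#' @param n number of subjects (>= 5; default 20).
#' @param params an [exp2_params()] list.
#' @param seed integer seed.
#' @return list with `discrimination` (subject, center, rate, separation,
#'   threshold) and `detection` (subject, center, rate, separation, phase,
#'   p_correct, d_prime, n_trials) data.frames.
#' @export
generate_exp2_cohort <- function(n = 20, params = exp2_params(), seed = 1) {
  if (n < 5) stop("n must be >= 5")
  set.seed(seed)
  p <- params
  cells <- expand.grid(center = p$centers, rate = p$rates,
                       separation = p$separations,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  h_rate <- c(slow = -1, fast = 1)
  disc_mu <- p$disc_base +
    p$disc_center[as.character(cells$center)] +
    p$disc_rate[cells$rate] +
    p$interaction_scale * p$disc_interaction_g[as.character(cells$center)] *
      h_rate[cells$rate] +
    p$disc_sep[cells$separation] +
    p$disc_sep_center[as.character(cells$center)] *
      ifelse(cells$separation == "wide", -1, 1)
  disc <- do.call(rbind, lapply(seq_len(n), function(i) {
    subj_eff <- stats::rnorm(1, 0, p$disc_subject_sd)
    thr <- vapply(disc_mu, function(mu) {
      mean(stats::rnorm(p$disc_runs, mu + subj_eff, p$disc_run_sd))
    }, numeric(1))
    data.frame(subject = sprintf("P%02d", i), cells, threshold = thr,
               stringsAsFactors = FALSE)
  }))
  det_cells <- expand.grid(center = p$centers, rate = p$rates,
                           separation = p$separations,
                           phase = c("in", "out"),
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  det_mu <- p$det_base +
    p$det_center[as.character(det_cells$center)] +
    p$det_rate[det_cells$rate] +
    p$phase_boost_scale *
      p$det_phase_boost[cbind(as.character(det_cells$center),
                              det_cells$rate)] *
      ifelse(det_cells$phase == "out", 1, 0)
  det <- do.call(rbind, lapply(seq_len(n), function(i) {
    subj_eff <- stats::rnorm(1, 0, p$det_subject_sd)
    d_true <- det_mu + subj_eff
    pc_true <- stats::pnorm(d_true / sqrt(2))
    pc_obs <- stats::rbinom(length(pc_true), p$det_trials, pc_true) /
      p$det_trials
    data.frame(subject = sprintf("P%02d", i), det_cells,
               p_correct = pc_obs,
               d_prime = pc_to_dprime(pc_obs, p$det_trials),
               n_trials = p$det_trials, stringsAsFactors = FALSE)
  }))
  list(discrimination = disc, detection = det)
}

#' Convert proportion correct to d-prime (2AFC)
#'
#' `d' = sqrt(2) * qnorm(pc)`, the standard two-alternative forced-choice
#' transform (Macmillan & Creelman). Extreme rates are clamped to
#' `1/(2*n_trials)` and `1 - 1/(2*n_trials)` so the transform stays finite.
#'
#' @param p_correct proportion(s) correct in [0, 1].
#' @param n_trials number of trials behind each proportion.
#' @return d-prime value(s).
#' @export
pc_to_dprime <- function(p_correct, n_trials) {
  if (n_trials <= 0) stop("n_trials must be > 0")
  if (any(p_correct < 0 | p_correct > 1))
    stop("p_correct must lie in [0, 1]")
  eps <- 1 / (2 * n_trials)
  sqrt(2) * stats::qnorm(pmin(pmax(p_correct, eps), 1 - eps))
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Type-III repeated-measures ANOVA over fully-within-subject factors,
#' built on `car::Anova` with an identity between-subject model. Mauchly's
#' sphericity test is run per effect with more than one numerator df; when
#' it is violated (p < `mauchly_alpha`) the Greenhouse-Geisser epsilon is
#' applied to the degrees of freedom and the corrected p-value is reported.
#'
#' @param table tidy data.frame, one row per subject x cell.
#' @param within_factors character vector of within-subject factor columns.
#' @param dv name of the dependent-variable column.
#' @param subject name of the subject id column (default `"subject"`).
#' @param mauchly_alpha threshold for triggering the correction (.05).
#' @return data.frame with one row per effect: `effect`, `df_num`,
#'   `df_den`, `F`, `p`, `epsilon_gg`, `mauchly_p`, `gg_applied`.
#' @export
rm_anova_gg <- function(table, within_factors, dv, subject = "subject",
                        mauchly_alpha = 0.05) {
  stopifnot(all(c(within_factors, dv, subject) %in% names(table)))
  cells <- expand.grid(lapply(table[within_factors], function(col)
    unique(col)), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cell_key <- do.call(paste, c(cells, sep = "|"))
  row_key <- do.call(paste, c(table[within_factors], sep = "|"))
  subjects <- unique(table[[subject]])
  Y <- matrix(NA_real_, length(subjects), nrow(cells),
              dimnames = list(subjects, cell_key))
  for (i in seq_len(nrow(table))) {
    Y[as.character(table[[subject]][i]), row_key[i]] <- table[[dv]][i]
  }
  if (anyNA(Y)) stop("missing cells in the within-subject design")
  idata <- as.data.frame(lapply(cells, factor))
  names(idata) <- within_factors
  idesign <- stats::as.formula(paste("~", paste(within_factors, collapse = "*")))
  terms_all <- attr(stats::terms(idesign), "term.labels")
  if (stats::var(as.vector(Y)) == 0) {
    # degenerate constant response: every effect and error SS is zero
    nlev <- vapply(idata, nlevels, integer(1))
    df1 <- vapply(strsplit(terms_all, ":"), function(fs)
      prod(nlev[fs] - 1), numeric(1))
    return(data.frame(effect = terms_all, df_num = df1,
                      df_den = (nrow(Y) - 1) * df1, F = 0, p = 1,
                      epsilon_gg = NA_real_, mauchly_p = NA_real_,
                      gg_applied = FALSE, stringsAsFactors = FALSE))
  }
  fit <- stats::lm(Y ~ 1)
  av <- car::Anova(fit, idata = idata, idesign = idesign, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  ut <- s$univariate.tests
  effects <- setdiff(rownames(ut), "(Intercept)")
  gg <- s$pval.adjustments     # rows: effects with >1 num df
  sph <- s$sphericity.tests
  out <- lapply(effects, function(e) {
    Fv <- ut[e, "F value"]; p <- ut[e, "Pr(>F)"]
    df1 <- ut[e, "num Df"]; df2 <- ut[e, "den Df"]
    if (ut[e, "Sum Sq"] == 0) { Fv <- 0; p <- 1 }
    eps <- NA_real_; mp <- NA_real_; applied <- FALSE
    if (!is.null(gg) && e %in% rownames(gg) && is.finite(gg[e, "GG eps"]) &&
        !is.null(sph) && e %in% rownames(sph)) {
      eps <- gg[e, "GG eps"]
      mp <- sph[e, "p-value"]
      if (is.finite(mp) && mp < mauchly_alpha) {
        applied <- TRUE
        df1 <- df1 * eps; df2 <- df2 * eps
        p <- gg[e, "Pr(>F[GG])"]
      }
    }
    data.frame(effect = e, df_num = df1, df_den = df2, F = Fv, p = p,
               epsilon_gg = eps, mauchly_p = mp, gg_applied = applied,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Holm-corrected simple effects after a significant interaction
#'
#' Paired contrasts between the two levels of `factor` within each level of
#' `by`, collapsing (averaging) over any remaining within-subject factors,
#' with Holm adjustment over the declared family.
#'
#' @param table tidy data.frame, one row per subject x cell.
#' @param dv dependent-variable column name.
#' @param factor two-level factor to contrast (e.g. rate).
#' @param by factor whose levels define the simple-effect family
#'   (e.g. center frequency).
#' @param subject subject id column.
#' @param tail `"two"` (default) or a one-tailed direction for
#'   `level1 - level2` of `factor`.
#' @return data.frame per `by` level: mean difference, t, df, `p_raw`,
#'   `p_holm`.
#' @export
holm_simple_effects <- function(table, dv, factor, by, subject = "subject",
                                tail = c("two", "positive", "negative")) {
  tail <- match.arg(tail)
  lv <- unique(table[[factor]])
  if (length(lv) != 2) stop("`factor` must have exactly two levels")
  res <- lapply(unique(table[[by]]), function(b) {
    sub <- table[table[[by]] == b, ]
    m <- tapply(sub[[dv]], list(sub[[subject]], sub[[factor]]), mean)
    d <- m[, as.character(lv[1])] - m[, as.character(lv[2])]
    if (anyNA(d)) stop("unmatched pairs for level ", b)
    tt <- stats::t.test(d)
    p <- switch(tail,
                two = tt$p.value,
                positive = stats::pt(tt$statistic, tt$parameter,
                                     lower.tail = FALSE),
                negative = stats::pt(tt$statistic, tt$parameter))
    data.frame(by = b, contrast = paste(lv[1], "-", lv[2]),
               mean_diff = unname(tt$estimate), t = unname(tt$statistic),
               df = unname(tt$parameter), p_raw = unname(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_holm <- holm_adjust(out$p_raw)
  out
}

#' Opposite-phase minus in-phase detection benefit
#'
#' For a complex-AM detection table with both modulator phase relations per
#' cell, computes the per-cell paired difference in d-prime (out-of-phase
#' minus in-phase) with Holm-corrected paired t-tests across the declared
#' family of cells.
#'
#' @param table detection data.frame from [generate_exp2_cohort()] (or the
#'   figure source-data layout read by [read_source_data()]), with columns
#'   `subject`, `center`, `rate`, `separation`, `phase`, `d_prime`.
#' @param by cell definition for the family (default center x rate x
#'   separation; the published analysis collapses separation, i.e.
#'   `c("center", "rate")`).
#' @param tail test direction for out - in (default `"positive"`: a
#'   place-coding benefit predicts better sensitivity out of phase).
#' @return data.frame per cell: `mean_diff`, `t`, `df`, `p_raw`, `p_holm`.
#' @export
detection_phase_benefit <- function(table,
                                    by = c("center", "rate", "separation"),
                                    tail = c("positive", "two", "negative")) {
  tail <- match.arg(tail)
  stopifnot(all(c(by, "phase", "d_prime", "subject") %in% names(table)))
  key <- interaction(table[by], drop = TRUE, sep = " / ")
  res <- lapply(levels(key), function(cell) {
    sub <- table[key == cell, ]
    m <- tapply(sub$d_prime, list(sub$subject, sub$phase), mean)
    if (!all(c("in", "out") %in% colnames(m)) || anyNA(m))
      stop("unmatched phase pairs in cell ", cell)
    d <- m[, "out"] - m[, "in"]
    tt <- stats::t.test(d)
    p <- switch(tail,
                two = tt$p.value,
                positive = stats::pt(tt$statistic, tt$parameter,
                                     lower.tail = FALSE),
                negative = stats::pt(tt$statistic, tt$parameter))
    data.frame(cell = cell, mean_diff = unname(tt$estimate),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = unname(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_holm <- holm_adjust(out$p_raw)
  out
}

#' Full Experiment-2-style analysis
#'
#' Runs the discrimination repeated-measures ANOVA (center x rate x
#' separation with Greenhouse-Geisser correction), the slow-vs-fast
#' Holm-corrected simple effects per center frequency, the detection ANOVA
#' (phase x center x rate x separation), and the opposite-phase benefit
#' tests.
#'
#' @param exp2 list with `discrimination` and `detection` tables, as
#'   returned by [generate_exp2_cohort()] or assembled from source data.
#' @return list of result tables.
#' @export
analyze_exp2 <- function(exp2) {
  disc_anova <- rm_anova_gg(exp2$discrimination,
                            c("center", "rate", "separation"), "threshold")
  simple <- holm_simple_effects(exp2$discrimination, "threshold",
                                factor = "rate", by = "center")
  det_anova <- rm_anova_gg(exp2$detection,
                           c("phase", "center", "rate", "separation"),
                           "d_prime")
  benefit <- detection_phase_benefit(exp2$detection)
  list(discrimination_anova = disc_anova,
       rate_simple_effects = simple,
       detection_anova = det_anova,
       phase_benefit = benefit)
}
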