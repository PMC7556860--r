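# Canonical column names and aliases for the figure source-data layouts.
# Aliases are matched case-insensitively after stripping non-alphanumerics
# and normalizing unicode minus signs.
source_data_schemas <- function() {
  list(
    fig2 = list(
      columns = c(thresh_1k = "1-kHz absolute threshold (dB SPL)",
                  low_slope = "low masking slope (dB/octave)",
                  high_slope = "high masking slope (dB/octave)"),
      aliases = list(
        thresh_1k = c("thresh1khz", "thresh1k", "absthresh1k", "threshold1khz",
                      "absolutethreshold", "1khzthreshold", "thresh"),
        low_slope = c("lowslope", "lowerslope", "low"),
        high_slope = c("highslope", "upperslope", "high"))),
    fig3 = list(
      columns = c(slow_fm = "slow FM threshold, 10log10(2*delta-f %)",
                  fast_fm = "fast FM threshold, 10log10(2*delta-f %)",
                  slow_am = "slow AM threshold, 20log10(m) dB",
                  fast_am = "fast AM threshold, 20log10(m) dB"),
      aliases = list(
        slow_fm = c("slowfm", "fmslow", "fm1hz"),
        fast_fm = c("fastfm", "fmfast", "fm20hz"),
        slow_am = c("slowam", "amslow", "am1hz"),
        fast_am = c("fastam", "amfast", "am20hz"))),
    fig4 = list(
      columns = c(low_slope = "low masking slope (dB/octave)",
                  high_slope = "high masking slope (dB/octave)",
                  slow_fm = "slow FM threshold",
                  fast_fm = "fast FM threshold"),
      aliases = list(
        low_slope = c("lowslope", "low"),
        high_slope = c("highslope", "high"),
        slow_fm = c("slowfm", "fmslow"),
        fast_fm = c("fastfm", "fmfast"))),
    fig5 = list(
      columns = c(low_slope_res_slow = "low-slope residual (slow-FM covariates)",
                  high_slope_res_slow = "high-slope residual (slow-FM covariates)",
                  slow_fm_res = "slow-FM residual",
                  low_slope_res_fast = "low-slope residual (fast-FM covariates)",
                  high_slope_res_fast = "high-slope residual (fast-FM covariates)",
                  fast_fm_res = "fast-FM residual"),
      aliases = list(
        low_slope_res_slow = c("lowsloperesslow", "lowslowres", "reslowslopeslow"),
        high_slope_res_slow = c("highsloperesslow", "highslowres"),
        slow_fm_res = c("slowfmres", "resslowfm", "slowfmresidual"),
        low_slope_res_fast = c("lowsloperesfast", "lowfastres"),
        high_slope_res_fast = c("highsloperesfast", "highfastres"),
        fast_fm_res = c("fastfmres", "resfastfm", "fastfmresidual")))
  )
}

normalize_header <- function(x) {
  x <- gsub("−|–|—", "-", x)   # unicode minus/dashes
  tolower(gsub("[^[:alnum:]]", "", x))
}

#' Read a figure source-data CSV
#'
#' Loads one of the per-subject source-data tables (rows = subjects) with
#' alias-tolerant header matching: headers are compared case-insensitively
#' after stripping punctuation and normalizing unicode minus signs, against
#' the documented aliases (e.g. `Slow`/`Fast` rate tags, `Nrw`/`Wide`
#' separation tags, `In`/`Out` phase tags for figure 6). Figures 2-5
#' return a data.frame with canonical column names and unit annotations;
#' figure 6 returns the tidy `discrimination` + `detection` pair.
#'
#' @param path CSV file path.
#' @param figure_id integer 2-6.
#' @param strict if `TRUE`, only exact canonical names are accepted.
#' @return data.frame (figures 2-5) or list (figure 6).
#' @export
read_source_data <- function(path, figure_id, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!figure_id %in% 2:6) stop("figure_id must be 2..6")
  raw <- utils::read.csv(path, check.names = FALSE)
  if (figure_id == 6) return(parse_fig6(raw))
  schema <- source_data_schemas()[[paste0("fig", figure_id)]]
  hdr <- normalize_header(names(raw))
  out <- list()
  for (canon in names(schema$columns)) {
    cands <- c(normalize_header(canon),
               if (!strict) normalize_header(schema$aliases[[canon]]))
    hit <- which(hdr %in% cands)
    if (length(hit) == 0)
      stop(sprintf("schema error (figure %d): missing column '%s' (%s)",
                   figure_id, canon, schema$columns[[canon]]))
    col <- raw[[hit[1]]]
    if (!is.numeric(col)) {
      col2 <- suppressWarnings(as.numeric(gsub("−", "-", col)))
      bad <- which(!is.na(col) & is.na(col2))
      if (length(bad))
        stop(sprintf("parse error (figure %d): non-numeric cell in '%s', row %d",
                     figure_id, canon, bad[1]))
      col <- col2
    }
    out[[canon]] <- col
  }
  df <- as.data.frame(out)
  subj_hit <- which(hdr %in% c("subject", "subjectid", "id", "participant"))
  df$subject <- if (length(subj_hit)) as.character(raw[[subj_hit[1]]])
                else sprintf("S%02d", seq_len(nrow(df)))
  attr(df, "units") <- schema$columns
  attr(df, "figure_id") <- figure_id
  df
}

parse_fig6 <- function(raw) {
  hdr <- names(raw)
  subj <- sprintf("P%02d", seq_len(nrow(raw)))
  disc <- list(); det <- list()
  for (j in seq_along(hdr)) {
    h <- normalize_header(hdr[j])
    sep <- if (grepl("nrw|narrow", h)) "nrw"
           else if (grepl("wide", h)) "wide" else NA
    rate <- if (grepl("slow", h)) "slow"
            else if (grepl("fast", h)) "fast" else NA
    center <- regmatches(h, regexpr("500|1500|7000", h))
    center <- if (length(center)) as.numeric(center) else NA
    phase <- if (grepl("out", h)) "out" else if (grepl("in", h)) "in" else NA
    if (any(is.na(c(sep, rate))) || is.na(center)) next
    col <- as.numeric(raw[[j]])
    rec <- data.frame(subject = subj, center = center, rate = rate,
                      separation = sep, value = col,
                      stringsAsFactors = FALSE)
    if (is.na(phase)) disc[[length(disc) + 1]] <- rec
    else { rec$phase <- phase; det[[length(det) + 1]] <- rec }
  }
  disc <- do.call(rbind, disc); det <- do.call(rbind, det)
  if (!is.null(disc)) names(disc)[names(disc) == "value"] <- "threshold"
  if (!is.null(det)) names(det)[names(det) == "value"] <- "d_prime"
  list(discrimination = disc, detection = det)
}

#' Export a synthetic cohort in the figure source-data layouts
#'
#' Writes one CSV per figure: figure 2 (1-kHz threshold and masking
#' slopes), figure 3 (the four modulation thresholds), figure 4 (slopes +
#' FM thresholds), figure 5 (the residual columns used for the partial
#' correlations, computed here by regressing each variable on age, 1-kHz
#' threshold, and the rate-matched AM threshold), and, when an
#' Experiment-2 cohort is supplied, figure 6 (wide layout: 12
#' discrimination columns `Sep_Rate_Center` and 24 detection columns
#' `Sep_Rate_Center_Phase`).
#'
#' @param cohort a [generate_cohort()] table.
#' @param outdir output directory (created if needed).
#' @param exp2 optional [generate_exp2_cohort()] list.
#' @return invisible character vector of the written file paths.
#' @export
export_source_data <- function(cohort, outdir, exp2 = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(data.frame(Subject = cohort$subject,
                Thresh1kHz = cohort$abs_thresh_1k,
                LowSlope = cohort$low_slope,
                HighSlope = cohort$high_slope),
     "figure2_source_data.csv")
  wr(data.frame(Subject = cohort$subject,
                SlowFM = cohort$slow_fm, FastFM = cohort$fast_fm,
                SlowAM = cohort$slow_am, FastAM = cohort$fast_am),
     "figure3_source_data.csv")
  wr(data.frame(Subject = cohort$subject,
                LowSlope = cohort$low_slope, HighSlope = cohort$high_slope,
                SlowFM = cohort$slow_fm, FastFM = cohort$fast_fm),
     "figure4_source_data.csv")
  res <- fig5_residuals(cohort)
  wr(data.frame(Subject = cohort$subject,
                LowSlopeResSlow = res$low_slope_res_slow,
                HighSlopeResSlow = res$high_slope_res_slow,
                SlowFMRes = res$slow_fm_res,
                LowSlopeResFast = res$low_slope_res_fast,
                HighSlopeResFast = res$high_slope_res_fast,
                FastFMRes = res$fast_fm_res),
     "figure5_source_data.csv")
  if (!is.null(exp2)) {
    disc <- exp2$discrimination
    disc_wide <- stats::reshape(
      transform(disc, col = paste0(tools::toTitleCase(separation), "_",
                                   tools::toTitleCase(rate), "_", center),
                center = NULL, rate = NULL, separation = NULL),
      idvar = "subject", timevar = "col", direction = "wide")
    names(disc_wide) <- sub("^threshold\\.", "", names(disc_wide))
    det <- exp2$detection
    det_wide <- stats::reshape(
      transform(det[, c("subject", "center", "rate", "separation", "phase",
                        "d_prime")],
                col = paste0(tools::toTitleCase(separation), "_",
                             tools::toTitleCase(rate), "_", center, "_",
                             tools::toTitleCase(phase)),
                center = NULL, rate = NULL, separation = NULL, phase = NULL),
      idvar = "subject", timevar = "col", direction = "wide")
    names(det_wide) <- sub("^d_prime\\.", "", names(det_wide))
    fig6 <- merge(disc_wide, det_wide, by = "subject")
    names(fig6)[names(fig6) == "subject"] <- "Subject"
    wr(fig6, "figure6_source_data.csv")
  }
  invisible(paths)
}

# residuals of slopes and FM thresholds on the partial-correlation
# covariate set (age, 1-kHz threshold, rate-matched AM threshold)
fig5_residuals <- function(cohort) {
  res_on <- function(y, am) stats::residuals(
    stats::lm(y ~ age + abs_thresh_1k + am,
              data = data.frame(cohort, am = am)))
  list(low_slope_res_slow = res_on(cohort$low_slope, cohort$slow_am),
       high_slope_res_slow = res_on(cohort$high_slope, cohort$slow_am),
       slow_fm_res = res_on(cohort$slow_fm, cohort$slow_am),
       low_slope_res_fast = res_on(cohort$low_slope, cohort$fast_am),
       high_slope_res_fast = res_on(cohort$high_slope, cohort$fast_am),
       fast_fm_res = res_on(cohort$fast_fm, cohort$fast_am))
}
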