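#' Transformed up-down staircase configuration
#'
#' Defines an adaptive track: a k-down-1-up rule, a step schedule keyed to
#' reversal counts, a start value, bounds, and the reversal-based threshold
#' estimator. Steps are multiplicative factors for tracks run in the log
#' domain (e.g. FM excursion in %) and dB offsets for additive tracks
#' (e.g. AM depth or level in dB).
#'
#' @param rule `"3-down-1-up"`, `"2-down-1-up"` or `"1-down-1-up"`.
#' @param n_alternatives number of forced-choice alternatives (2 or 3);
#'   sets the guessing rate of simulated observers.
#' @param step_schedule data.frame with columns `n_reversals` and `step`:
#'   step sizes (factors or dB) applied until the cumulative reversal quota
#'   of each row is filled. The final row must cover six reversals, over
#'   which the threshold is computed.
#' @param start_value starting stimulus value, task units.
#' @param step_mode `"factor"` (multiplicative, log-domain track) or
#'   `"db"` (additive dB offsets).
#' @param threshold_rule `"geometric-mean"` or `"arithmetic-mean"` over the
#'   final six reversal values.
#' @param bounds length-2 numeric, min and max stimulus value; the track is
#'   clamped at the bounds.
#' @param early_stop optional list `list(bound = "upper", max_hits = 15)`:
#'   terminate (threshold undefined) once the bound has been presented
#'   `max_hits` times.
#' @param max_trials safety cap on trial count (default 1000).
#' @return A `staircase_config` list.
#' @export
staircase_config <- function(rule = c("3-down-1-up", "2-down-1-up", "1-down-1-up"),
                             n_alternatives = 2,
                             step_schedule,
                             start_value,
                             step_mode = c("factor", "db"),
                             threshold_rule = c("geometric-mean", "arithmetic-mean"),
                             bounds = c(-Inf, Inf),
                             early_stop = NULL,
                             max_trials = 1000) {
  rule <- match.arg(rule)
  step_mode <- match.arg(step_mode)
  threshold_rule <- match.arg(threshold_rule)
  stopifnot(is.data.frame(step_schedule),
            all(c("n_reversals", "step") %in% names(step_schedule)),
            all(step_schedule$step > 0),
            all(step_schedule$n_reversals >= 1))
  if (utils::tail(step_schedule$n_reversals, 1) != 6)
    stop("final schedule segment must cover six reversals (threshold window)")
  if (step_mode == "factor" && any(step_schedule$step <= 1))
    stop("multiplicative steps must be factors > 1")
  if (step_mode == "factor" && (start_value <= 0 || bounds[1] < 0))
    stop("factor-mode tracks require positive values")
  structure(list(rule = rule, k_down = as.integer(substr(rule, 1, 1)),
                 n_alternatives = n_alternatives,
                 step_schedule = step_schedule, start_value = start_value,
                 step_mode = step_mode, threshold_rule = threshold_rule,
                 bounds = bounds, early_stop = early_stop,
                 max_trials = max_trials),
            class = "staircase_config")
}

#' Parametric simulated observer
#'
#' Cumulative-Gaussian psychometric function in transformed stimulus units:
#' `p(correct | x) = guess + (1 - guess - lapse) * pnorm((x - mu)/sigma)`,
#' where `x` is `10*log10(value)` for log-domain (factor-stepped) tasks and
#' the raw dB value for additive tasks.
#'
#' @param mu psychometric location in transformed units.
#' @param sigma psychometric spread in transformed units.
#' @param lapse lapse rate (default 0).
#' @param guess guessing rate; defaults to `1/n_alternatives` at response
#'   time if `NA`.
#' @param log_domain if `TRUE`, stimulus values are transformed by
#'   `10*log10` before evaluating the psychometric function.
#' @return A `sim_observer` list.
#' @export
sim_observer <- function(mu, sigma, lapse = 0, guess = NA, log_domain = FALSE) {
  stopifnot(sigma > 0, lapse >= 0, lapse < 0.5)
  structure(list(mu = mu, sigma = sigma, lapse = lapse, guess = guess,
                 log_domain = log_domain), class = "sim_observer")
}

observer_transform <- function(obs, value) {
  if (obs$log_domain) 10 * log10(value) else value
}

#' Analytic percent correct of an observer at a stimulus value
#'
#' @param obs a [sim_observer()].
#' @param value stimulus value in task units.
#' @param n_alternatives forced-choice alternatives, used when the
#'   observer's guess rate is `NA`.
#' @return probability correct.
#' @export
observer_p_correct <- function(obs, value, n_alternatives = 2) {
  g <- if (is.na(obs$guess)) 1 / n_alternatives else obs$guess
  x <- observer_transform(obs, value)
  g + (1 - g - obs$lapse) * stats::pnorm((x - obs$mu) / obs$sigma)
}

#' Stimulus value at which an observer reaches a given percent correct
#'
#' Inverse of [observer_p_correct()]; used as the analytic convergence
#' target for staircase simulations.
#'
#' @inheritParams observer_p_correct
#' @param p target probability correct (must lie between the guess rate and
#'   `1 - lapse`).
#' @return stimulus value in task units.
#' @export
observer_inverse <- function(obs, p, n_alternatives = 2) {
  g <- if (is.na(obs$guess)) 1 / n_alternatives else obs$guess
  if (p <= g || p >= 1 - obs$lapse) stop("p outside the attainable range")
  x <- obs$mu + obs$sigma * stats::qnorm((p - g) / (1 - g - obs$lapse))
  if (obs$log_domain) 10^(x / 10) else x
}

#' Single Bernoulli response from a simulated observer
#'
#' @inheritParams observer_p_correct
#' @return `TRUE` (correct) or `FALSE`.
#' @export
observer_response <- function(obs, value, n_alternatives = 2) {
  stats::runif(1) < observer_p_correct(obs, value, n_alternatives)
}

#' Theoretical convergence point of a transformed up-down rule
#'
#' A k-down-1-up track converges to the stimulus value where
#' `p(correct)^k = 0.5`, i.e. `0.5^(1/k)`: 79.4% for 3-down-1-up, 70.7%
#' for 2-down-1-up, 50% for 1-down-1-up.
#'
#' @param rule rule string as in [staircase_config()].
#' @return tracked proportion correct.
#' @export
theoretical_convergence <- function(rule) {
  k <- switch(rule,
              "3-down-1-up" = 3L, "2-down-1-up" = 2L, "1-down-1-up" = 1L,
              stop("unknown rule: ", rule))
  0.5^(1 / k)
}

#' Run one adaptive staircase against a simulated observer
#'
#' Implements the transformed up-down procedure: the stimulus value moves
#' down after `k` consecutive correct responses and up after any incorrect
#' response; step size follows the schedule indexed by the count of
#' completed reversals (the step switches the moment a segment's reversal
#' quota is filled); the track terminates when the schedule's total
#' reversal count is reached. The threshold is the (geometric or
#' arithmetic) mean of the final six reversal values. Values are clamped at
#' the bounds; bound presentations count trials, and the optional early-stop
#' rule aborts the run (threshold undefined) once the bound has been
#' presented `max_hits` times.
#'
#' @param cfg a [staircase_config()].
#' @param obs a [sim_observer()].
#' @return A `staircase_result` list with `trial_values`, `responses`,
#'   `reversal_values`, `threshold` (NA when terminated early),
#'   `terminated_early` and `n_trials`.
#' @export
run_staircase <- function(cfg, obs) {
  stopifnot(inherits(cfg, "staircase_config"), inherits(obs, "sim_observer"))
  sched <- cfg$step_schedule
  total_rev <- sum(sched$n_reversals)
  seg_upper <- cumsum(sched$n_reversals)   # reversal index covered per row
  value <- min(max(cfg$start_value, cfg$bounds[1]), cfg$bounds[2])
  k <- cfg$k_down
  g <- if (is.na(obs$guess)) 1 / cfg$n_alternatives else obs$guess
  sc <- (1 - g - obs$lapse)
  logdom <- obs$log_domain
  mult <- cfg$step_mode == "factor"
  vals <- numeric(cfg$max_trials)
  resp <- logical(cfg$max_trials)
  reversals <- numeric(total_rev)
  n_rev <- 0L
  n_corr <- 0L
  last_dir <- 0L
  bound_hits <- 0L
  es <- cfg$early_stop
  terminated <- FALSE
  i <- 0L
  while (i < cfg$max_trials) {
    i <- i + 1L
    vals[i] <- value
    if (!is.null(es)) {
      at_bound <- if (identical(es$bound, "upper")) value >= cfg$bounds[2]
                  else value <= cfg$bounds[1]
      if (at_bound) {
        bound_hits <- bound_hits + 1L
        if (bound_hits >= es$max_hits) { terminated <- TRUE; break }
      }
    }
    x <- if (logdom) 10 * log10(value) else value
    p <- g + sc * stats::pnorm((x - obs$mu) / obs$sigma)
    correct <- stats::runif(1) < p
    resp[i] <- correct
    move <- 0L
    if (correct) {
      n_corr <- n_corr + 1L
      if (n_corr == k) { move <- -1L; n_corr <- 0L }
    } else {
      move <- 1L
      n_corr <- 0L
    }
    if (move != 0L) {
      if (last_dir != 0L && move != last_dir) {
        n_rev <- n_rev + 1L
        reversals[n_rev] <- value
        if (n_rev >= total_rev) break
      }
      last_dir <- move
      step <- sched$step[which(n_rev < seg_upper)[1]]
      value <- if (mult) {
        if (move < 0) value / step else value * step
      } else {
        value + move * step
      }
      value <- min(max(value, cfg$bounds[1]), cfg$bounds[2])
    }
  }
  complete <- n_rev >= total_rev && !terminated
  threshold <- NA_real_
  if (complete) {
    final6 <- reversals[(total_rev - 5):total_rev]
    threshold <- if (cfg$threshold_rule == "geometric-mean")
      exp(mean(log(final6))) else mean(final6)
  }
  structure(list(trial_values = vals[seq_len(i)],
                 responses = resp[seq_len(i)],
                 reversal_values = reversals[seq_len(n_rev)],
                 threshold = threshold,
                 terminated_early = !complete,
                 n_trials = i),
            class = "staircase_result")
}

#' Named staircase presets for the standard tasks
#'
#' Task configurations shipped with the package (registry stored as YAML in
#' `inst/extdata/staircase_presets.yaml`): `fm_1kHz` (FM excursion, factors
#' 2/1.4/1.19 from a 5.02% start, geometric-mean threshold), `am_1kHz`
#' (AM depth in dB, 6/2/1-dB steps from -8 dB), `abs_1kHz` (level in dB SPL,
#' 8/4/2-dB steps from 40 dB SPL, nine reversals), `pip_quiet` and
#' `forward_masking` (pip level, 8/4/2-dB steps), `exp2_discrim`
#' (2-down-1-up AM-phase discrimination with the 15-hit ceiling early stop),
#' `exp2_am_detect` (3-down-1-up AM detection) and `exp2_abs_screen`
#' (2-down-1-up level screening).
#'
#' @param name preset name.
#' @param start_value optional override of the preset start value (e.g. a
#'   sensation-level-dependent pip start).
#' @return A [staircase_config()].
#' @export
staircase_preset <- function(name, start_value = NULL) {
  reg <- staircase_registry()
  if (!name %in% names(reg))
    stop("unknown preset: ", name, "; available: ",
         paste(names(reg), collapse = ", "))
  p <- reg[[name]]
  if (!is.null(start_value)) p$start_value <- start_value
  staircase_config(rule = p$rule,
                   n_alternatives = p$n_alternatives,
                   step_schedule = data.frame(
                     n_reversals = as.numeric(p$n_reversals),
                     step = as.numeric(p$steps)),
                   start_value = p$start_value,
                   step_mode = p$step_mode,
                   threshold_rule = p$threshold_rule,
                   bounds = as.numeric(p$bounds),
                   early_stop = p$early_stop,
                   max_trials = if (is.null(p$max_trials)) 1000 else p$max_trials)
}

staircase_registry <- function() {
  path <- system.file("extdata", "staircase_presets.yaml", package = "placefm")
  if (nzchar(path)) return(yaml::read_yaml(path))
  # fallback when running from a source checkout
  yaml::read_yaml(file.path("inst", "extdata", "staircase_presets.yaml"))
}

#' Export a staircase trial track as CSV
#'
#' @param result a `staircase_result` from [run_staircase()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_staircase_track <- function(result, path) {
  utils::write.csv(data.frame(trial = seq_along(result$trial_values),
                              value = result$trial_values,
                              correct = result$responses),
                   path, row.names = FALSE)
  invisible(path)
}
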