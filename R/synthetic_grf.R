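#' Nominal two-peak stance curve parameters
#'
#' The six scalars that define one synthetic vertical GRF stance curve: the
#' loading-response peak (Fz1 at Tz1), the mid-stance valley (Fz2 at Tz2)
#' and the push-off peak (Fz3 at Tz3). Forces are in %BW, times in % of
#' stance. Defaults follow the population means reported for healthy
#' elderly walking (first peak around 114 %BW near 23 % stance, valley
#' around 75 %BW near 49 %, second peak around 110 %BW near 77 %).
#'
#' @param fz1,fz2,fz3 peak / valley / peak force magnitudes (%BW).
#' @param tz1,tz2,tz3 their times (% of stance), `0 < tz1 < tz2 < tz3 < 100`.
#' @param stance_duration_s stance duration in seconds (default 0.7).
#' @return A named list of class `curve_params`.
#' @export
curve_params <- function(fz1 = 114, tz1 = 23, fz2 = 75, tz2 = 49,
                         fz3 = 110, tz3 = 77, stance_duration_s = 0.7) {
  p <- list(fz1 = fz1, tz1 = tz1, fz2 = fz2, tz2 = tz2, fz3 = fz3,
            tz3 = tz3, stance_duration_s = stance_duration_s)
  if (!(0 < tz1 && tz1 < tz2 && tz2 < tz3 && tz3 < 100)) {
    abort("curve times must satisfy 0 < tz1 < tz2 < tz3 < 100",
          class = "gaitsym_domain_error")
  }
  if (fz1 <= 0 || fz2 <= 0 || fz3 <= 0 || stance_duration_s <= 0) {
    abort("curve amplitudes and stance duration must be positive",
          class = "gaitsym_domain_error")
  }
  if (fz2 >= min(fz1, fz3)) {
    abort("valley amplitude fz2 must be below both peaks",
          class = "gaitsym_domain_error")
  }
  structure(p, class = "curve_params")
}

# cubic Hermite evaluation on knots (t, f) with prescribed derivatives d
hermite_eval <- function(t, kt, kf, kd) {
  i <- findInterval(t, kt, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(kt) - 1L)
  h <- kt[i + 1L] - kt[i]
  s <- (t - kt[i]) / h
  (1 + 2 * s) * (1 - s)^2 * kf[i] +
    s * (1 - s)^2 * h * kd[i] +
    s^2 * (3 - 2 * s) * kf[i + 1L] +
    s^2 * (s - 1) * h * kd[i + 1L]
}

#' Evaluate a synthetic two-peak stance curve
#'
#' The waveform is a monotone cubic Hermite spline through the knots
#' `(0, 0)`, `(tz1, fz1)`, `(tz2, fz2)`, `(tz3, fz3)`, `(100, 0)` with zero
#' derivative at the three interior knots, so the curve's local extrema are
#' *exactly* the six nominal parameters, it is zero at foot-strike and
#' foot-off, and it is monotone between consecutive knots (endpoint slopes
#' are kept at 1.5 times the secant slope, inside the Fritsch-Carlson
#' monotonicity region). The shape is M-shaped by construction; it is not a
#' physiological model beyond its extrema.
#'
#' @param params a [curve_params()] object.
#' @param t evaluation times in % of stance, each in `[0, 100]`.
#' @return Numeric vector of forces in %BW.
#' @examples
#' grf_curve(curve_params(), c(0, 23, 49, 77, 100))
#' @export
grf_curve <- function(params, t) {
  stopifnot(inherits(params, "curve_params"))
  if (any(t < 0 | t > 100)) {
    abort("evaluation times must lie in [0, 100] % stance",
          class = "gaitsym_domain_error")
  }
  kt <- c(0, params$tz1, params$tz2, params$tz3, 100)
  kf <- c(0, params$fz1, params$fz2, params$fz3, 0)
  kd <- c(1.5 * params$fz1 / params$tz1, 0, 0, 0,
          -1.5 * params$fz3 / (100 - params$tz3))
  hermite_eval(t, kt, kf, kd)
}

#' Configuration for a synthetic gait cohort
#'
#' Defines the study conditions a simulated cohort is drawn under: cohort
#' size, trial count, population curve parameters, between-subject and
#' within-subject (trial-to-trial) variability, and the left-right
#' asymmetry injected on the right side.
#'
#' Variability is multiplicative and CV-scaled, matching how repeatability
#' is reported for discrete gait parameters. Default within-subject CVs are
#' per-parameter values in the 4-10 % range typical of healthy elderly
#' cohorts; between-subject CVs default to the same relative scale.
#'
#' @param n_subjects number of subjects (default 60).
#' @param trials_per_side trials per subject per side (default 10).
#' @param means named numeric: population means for `fz1`, `tz1`, `fz2`,
#'   `tz2`, `fz3`, `tz3` (units %BW / % stance).
#' @param within_cv named numeric, trial-to-trial CV (%) per parameter.
#' @param between_cv named numeric, between-subject CV (%) per parameter.
#' @param asymmetry named numeric, multiplicative deltas applied to the
#'   right side (`right = left * (1 + delta)`); each delta must be > -1.
#'   Default all zero (a symmetric cohort).
#' @param bodyweight_mean_n,bodyweight_sd_n bodyweight distribution (N).
#' @param stance_duration_s,stance_duration_sd_s stance duration draw (s).
#' @param sampling_rate_hz force platform sampling rate (default 400).
#' @param noise_sd_n additive white measurement noise SD in Newtons.
#' @param pad_samples zero-force padding samples rendered on each side of
#'   the contact, emulating platform recording before/after the step.
#' @param seed master seed for the cohort.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 60,
                          trials_per_side = 10,
                          means = c(fz1 = 114, tz1 = 23, fz2 = 75,
                                    tz2 = 49, fz3 = 110, tz3 = 77),
                          within_cv = c(fz1 = 8.4, tz1 = 10.1, fz2 = 6.4,
                                        tz2 = 5.3, fz3 = 9.5, tz3 = 5.1),
                          between_cv = within_cv,
                          asymmetry = c(fz1 = 0, tz1 = 0, fz2 = 0,
                                        tz2 = 0, fz3 = 0, tz3 = 0),
                          bodyweight_mean_n = 650,
                          bodyweight_sd_n = 65,
                          stance_duration_s = 0.7,
                          stance_duration_sd_s = 0.05,
                          sampling_rate_hz = 400,
                          noise_sd_n = 2,
                          pad_samples = 8,
                          seed = 1) {
  par_names <- c("fz1", "tz1", "fz2", "tz2", "fz3", "tz3")
  fill <- function(x, default = 0) {
    out <- stats::setNames(rep(default, 6), par_names)
    if (!is.null(names(x))) out[names(x)] <- x else out[] <- x
    out
  }
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    trials_per_side = as.integer(trials_per_side),
    means = fill(means), within_cv = fill(within_cv),
    between_cv = fill(between_cv), asymmetry = fill(asymmetry),
    bodyweight_mean_n = bodyweight_mean_n, bodyweight_sd_n = bodyweight_sd_n,
    stance_duration_s = stance_duration_s,
    stance_duration_sd_s = stance_duration_sd_s,
    sampling_rate_hz = sampling_rate_hz, noise_sd_n = noise_sd_n,
    pad_samples = as.integer(pad_samples), seed = as.integer(seed)
  )
  if (any(cfg$within_cv < 0) || any(cfg$between_cv < 0)) {
    abort("CVs must be non-negative", class = "gaitsym_domain_error")
  }
  if (any(cfg$asymmetry <= -1)) {
    abort("asymmetry deltas must be > -1", class = "gaitsym_domain_error")
  }
  if (cfg$n_subjects < 1 || cfg$trials_per_side < 1) {
    abort("n_subjects and trials_per_side must be >= 1",
          class = "gaitsym_domain_error")
  }
  structure(cfg, class = "cohort_config")
}

# clamp a jittered parameter set back into curve validity; returns the
# params plus how many components had to be moved
clamp_params <- function(p) {
  n_clamped <- 0L
  bump <- function(cond) if (cond) n_clamped <<- n_clamped + 1L
  for (nm in c("fz1", "fz2", "fz3")) {
    bump(p[[nm]] < 1); p[[nm]] <- max(p[[nm]], 1)
  }
  bump(p[["tz1"]] < 2); p[["tz1"]] <- max(p[["tz1"]], 2)
  bump(p[["tz2"]] <= p[["tz1"]] + 2); p[["tz2"]] <- max(p[["tz2"]], p[["tz1"]] + 2)
  bump(p[["tz3"]] <= p[["tz2"]] + 2); p[["tz3"]] <- max(p[["tz3"]], p[["tz2"]] + 2)
  bump(p[["tz3"]] > 98)
  if (p[["tz3"]] > 98) { # re-space the triple below 98 preserving order
    p[["tz3"]] <- 98
    p[["tz2"]] <- min(p[["tz2"]], 96)
    p[["tz1"]] <- min(p[["tz1"]], 94)
  }
  cap <- 0.95 * min(p[["fz1"]], p[["fz3"]])
  bump(p[["fz2"]] >= cap); p[["fz2"]] <- min(p[["fz2"]], cap)
  list(params = p, n_clamped = n_clamped)
}

#' Simulate a synthetic gait cohort
#'
#' Draws a cohort of subjects, each with a subject-level left-side curve
#' parameter set from the population distribution; the right-side set is
#' the left-side set scaled by `1 + asymmetry` per parameter. Each trial
#' jitters the subject parameters with the within-subject CV, renders the
#' curve at the configured sampling rate over a drawn stance duration,
#' converts %BW to Newtons via the subject's bodyweight, adds white
#' measurement noise and pads the contact with zero-force samples.
#'
#' Each subject consumes an independent seed sub-stream, so enlarging the
#' cohort never changes earlier subjects' draws.
#'
#' @param config a [cohort_config()].
#' @return A list with `trials` (a `grf_trials` tibble ready for
#'   [preprocess_trials()]) and `truth` (a tibble of the realized
#'   per-trial parameter values and the applied deltas).
#' @examples
#' cohort <- sample_cohort(cohort_config(n_subjects = 2, trials_per_side = 2))
#' nrow(cohort$trials)
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  par_names <- names(config$means)
  rows <- vector("list", config$n_subjects)
  truth <- vector("list", config$n_subjects)
  n_clamped <- 0L
  n_draws <- 0L

  for (i in seq_len(config$n_subjects)) {
    sid <- sprintf("S%03d", i)
    res <- withr::with_seed(substream_seed(config$seed, "subject", i), {
      bw <- max(rnorm(1, config$bodyweight_mean_n, config$bodyweight_sd_n),
                0.3 * config$bodyweight_mean_n)
      subj_left <- config$means *
        (1 + rnorm(6, 0, config$between_cv / 100))
      cl <- clamp_params(as.list(subj_left))
      subj_left <- unlist(cl$params[par_names])
      nc <- cl$n_clamped
      sides <- list(left = subj_left,
                    right = subj_left * (1 + config$asymmetry))
      trial_rows <- list(); truth_rows <- list()
      for (side in names(sides)) {
        for (k in seq_len(config$trials_per_side)) {
          p <- sides[[side]] * (1 + rnorm(6, 0, config$within_cv / 100))
          cl <- clamp_params(as.list(p))
          p <- unlist(cl$params[par_names]); nc <- nc + cl$n_clamped
          dur <- max(rnorm(1, config$stance_duration_s,
                           config$stance_duration_sd_s), 0.2)
          n_samp <- max(round(dur * config$sampling_rate_hz), 8) + 1L
          cp <- curve_params(p[["fz1"]], p[["tz1"]], p[["fz2"]], p[["tz2"]],
                             p[["fz3"]], p[["tz3"]], stance_duration_s = dur)
          f_pct <- grf_curve(cp, seq(0, 100, length.out = n_samp))
          f_n <- f_pct / 100 * bw
          pad <- rep(0, config$pad_samples)
          f_n <- c(pad, f_n, pad) +
            rnorm(n_samp + 2 * config$pad_samples, 0, config$noise_sd_n)
          tid <- sprintf("T%02d", k)
          trial_rows[[length(trial_rows) + 1L]] <- tibble::tibble(
            subject_id = sid, side = side, trial_id = tid,
            sampling_rate_hz = config$sampling_rate_hz,
            bodyweight_n = bw, units = "N", samples = list(f_n)
          )
          truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
            subject_id = sid, side = side, trial_id = tid,
            fz1 = p[["fz1"]], tz1 = p[["tz1"]], fz2 = p[["fz2"]],
            tz2 = p[["tz2"]], fz3 = p[["fz3"]], tz3 = p[["tz3"]],
            stance_duration_s = dur, bodyweight_n = bw
          )
        }
      }
      list(trials = dplyr::bind_rows(trial_rows),
           truth = dplyr::bind_rows(truth_rows), n_clamped = nc)
    })
    rows[[i]] <- res$trials
    truth[[i]] <- res$truth
    n_clamped <- n_clamped + res$n_clamped
    n_draws <- n_draws + (1L + 2L * config$trials_per_side) * 6L
  }

  if (n_clamped > 0.01 * n_draws) {
    warn(sprintf(
      "%.1f%% of parameter draws required clamping; configured ranges may be too wide",
      100 * n_clamped / n_draws))
  }
  trials <- validate_trials(dplyr::bind_rows(rows))
  truth <- dplyr::bind_rows(truth)
  truth$side <- factor(truth$side, levels = .side_levels)
  for (nm in par_names) {
    truth[[paste0("delta_", nm)]] <- config$asymmetry[[nm]]
  }
  list(trials = trials, truth = truth)
}
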