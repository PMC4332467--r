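#' Construct a table of vertical GRF force trials
#'
#' A *force trial* is one stance-phase vertical ground reaction force
#' recording from a single foot contact, with its metadata. Trials are kept
#' in a tibble with one row per trial and the sample vector in a
#' list-column, so ordinary dplyr verbs work on the metadata.
#'
#' @param subject_id character subject identifiers.
#' @param side `"left"`/`"right"` (tokens `L`/`l`/`R`/`r` accepted).
#' @param trial_id character trial identifiers.
#' @param samples list of numeric vectors, one per trial, vertical force.
#'   Units are Newtons on input; [normalize_bodyweight()] converts to %BW.
#' @param sampling_rate_hz positive sampling frequency (default 400).
#' @param bodyweight_n positive bodyweight in Newtons, recycled per trial.
#' @param units `"N"` (raw Newtons) or `"pct_bw"` (percent bodyweight).
#' @return A tibble of class `grf_trials` with columns `subject_id`, `side`,
#'   `trial_id`, `sampling_rate_hz`, `bodyweight_n`, `units`, `samples`.
#' @examples
#' force_trials("s1", "left", "t1", list(c(0, 700, 0)), bodyweight_n = 700)
#' @export
force_trials <- function(subject_id, side, trial_id, samples,
                         sampling_rate_hz = 400, bodyweight_n,
                         units = "N") {
  if (!is.list(samples)) samples <- list(samples)
  out <- tibble::tibble(
    subject_id = as.character(subject_id),
    side = normalize_side(side),
    trial_id = as.character(trial_id),
    sampling_rate_hz = as.numeric(sampling_rate_hz),
    bodyweight_n = as.numeric(bodyweight_n),
    units = units,
    samples = samples
  )
  validate_trials(out)
}

validate_trials <- function(trials) {
  stopifnot(is.data.frame(trials))
  need <- c("subject_id", "side", "trial_id", "sampling_rate_hz",
            "bodyweight_n", "units", "samples")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    abort(paste0("missing trial column(s): ", paste(miss, collapse = ", ")),
          class = "gaitsym_format_error")
  }
  key <- paste(trials$subject_id, trials$side, trials$trial_id)
  if (anyDuplicated(key)) {
    abort("duplicate (subject, side, trial) keys in trial table",
          class = "gaitsym_integrity_error")
  }
  if (any(trials$sampling_rate_hz <= 0) || any(trials$bodyweight_n <= 0)) {
    abort("sampling_rate_hz and bodyweight_n must be positive",
          class = "gaitsym_domain_error")
  }
  ok <- vapply(trials$samples,
               function(s) length(s) >= 4L && all(is.finite(s)), logical(1))
  if (!all(ok)) {
    abort(sprintf(
      "trial(s) %s have < 4 samples or non-finite force values",
      paste(trials$trial_id[!ok], collapse = ", ")
    ), class = "gaitsym_domain_error")
  }
  class(trials) <- unique(c("grf_trials", class(trials)))
  trials
}

#' Read force trials from a long-format CSV file
#'
#' The long dialect has one row per force sample with columns `subject_id`,
#' `side`, `trial_id`, `sample_index` (0-based), `force_n`, `bodyweight_n`
#' (constant per subject) and `sampling_rate_hz` (constant per file).
#'
#' @param path path to a CSV file.
#' @return A `grf_trials` tibble, one row per (subject, side, trial).
#' @seealso [write_trials()]
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("trial file not found: ", path), class = "gaitsym_io_error")
  }
  need <- c("subject_id", "side", "trial_id", "sample_index", "force_n",
            "bodyweight_n", "sampling_rate_hz")
  raw <- readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort(sprintf("file %s is missing required column(s): %s",
                  path, paste(miss, collapse = ", ")),
          class = "gaitsym_format_error")
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad) || anyNA(raw[[col]])) {
      row <- c(bad, which(is.na(raw[[col]])))[1]
      abort(sprintf("non-numeric value in column '%s' at data row %d of %s",
                    col, row, path), class = "gaitsym_parse_error")
    }
    v
  }
  raw$sample_index <- num("sample_index")
  raw$force_n <- num("force_n")
  raw$bodyweight_n <- num("bodyweight_n")
  raw$sampling_rate_hz <- num("sampling_rate_hz")
  raw$side <- normalize_side(raw$side)

  key <- paste(raw$subject_id, raw$side, raw$trial_id, raw$sample_index)
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate (subject, side, trial, sample_index) rows in %s",
                  path), class = "gaitsym_integrity_error")
  }
  trials <- raw |>
    dplyr::arrange(.data$subject_id, .data$side, .data$trial_id,
                   .data$sample_index) |>
    dplyr::group_by(.data$subject_id, .data$side, .data$trial_id) |>
    dplyr::summarise(
      sampling_rate_hz = .data$sampling_rate_hz[1],
      bodyweight_n = .data$bodyweight_n[1],
      samples = list(.data$force_n),
      .groups = "drop"
    ) |>
    dplyr::mutate(units = "N", .before = "samples")
  validate_trials(trials)
}

#' Write force trials to the long-format CSV dialect
#'
#' @param trials a `grf_trials` tibble (see [force_trials()]).
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  trials <- validate_trials(trials)
  long <- trials |>
    dplyr::mutate(side = as.character(.data$side)) |>
    tidyr::unnest_longer("samples", values_to = "force_n",
                         indices_to = "sample_index") |>
    dplyr::mutate(sample_index = .data$sample_index - 1L) |>
    dplyr::select("subject_id", "side", "trial_id", "sample_index",
                  "force_n", "bodyweight_n", "sampling_rate_hz")
  readr::write_csv(long, path, progress = FALSE)
  invisible(path)
}

#' Normalize trial forces by bodyweight
#'
#' Converts forces from Newtons to percent bodyweight (%BW), i.e.
#' `100 * force / bodyweight`. Negative raw forces (sensor noise around
#' foot-off) are clipped to zero by default, since vertical GRF is
#' physically non-negative.
#'
#' @param trials a `grf_trials` tibble in Newton units.
#' @param clip_negative clip negative forces to 0 (default `TRUE`).
#' @return The trials with `samples` in %BW and `units = "pct_bw"`.
#' @export
normalize_bodyweight <- function(trials, clip_negative = TRUE) {
  trials <- validate_trials(trials)
  if (any(trials$units != "N")) {
    abort("trials are already bodyweight-normalized",
          class = "gaitsym_domain_error")
  }
  trials$samples <- Map(function(s, bw) {
    out <- 100 * s / bw
    if (clip_negative) out <- pmax(out, 0)
    out
  }, trials$samples, trials$bodyweight_n)
  trials$units <- "pct_bw"
  trials
}

#' Crop trials to the stance phase
#'
#' Force-platform files may carry leading/trailing near-zero padding around
#' the actual foot contact. The stance segment is taken as the longest
#' contiguous run of samples at or above `threshold_pct_bw`, extended by one
#' sub-threshold sample on each side when available so that the onset and
#' offset ramps are retained.
#'
#' @param trials bodyweight-normalized `grf_trials` (units `"pct_bw"`).
#' @param threshold_pct_bw stance detection threshold in %BW (default 5).
#' @return The trials cropped to their stance segments.
#' @export
segment_stance <- function(trials, threshold_pct_bw = 5) {
  trials <- validate_trials(trials)
  if (any(trials$units != "pct_bw")) {
    abort("segment_stance expects bodyweight-normalized trials (%BW)",
          class = "gaitsym_domain_error")
  }
  if (threshold_pct_bw <= 0) {
    abort("threshold_pct_bw must be positive", class = "gaitsym_domain_error")
  }
  trials$samples <- Map(function(s, id) {
    above <- s >= threshold_pct_bw
    if (!any(above)) {
      abort(sprintf("trial %s: no sample reaches the %g %%BW stance threshold",
                    id, threshold_pct_bw), class = "gaitsym_empty_stance_error")
    }
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    lo <- max(starts[best] - 1L, 1L)        # one-sample margin each side
    hi <- min(ends[best] + 1L, length(s))
    if (hi - lo + 1L < 4L) {
      abort(sprintf("trial %s: stance segment shorter than 4 samples", id),
            class = "gaitsym_too_short_error")
    }
    s[lo:hi]
  }, trials$samples, trials$trial_id)
  trials
}

#' Time-normalize stance trials to 101-point gait patterns
#'
#' Linearly interpolates each stance-cropped, bodyweight-normalized trial
#' onto 101 equally spaced points spanning 0..100 % of stance duration
#' (1 % spacing, endpoints included). Index *i* of the resulting pattern is
#' the force at *i* % of stance; the values at 0 % and 100 % equal the first
#' and last stance samples exactly.
#'
#' @param trials stance-cropped `grf_trials` in %BW.
#' @return A `gait_patterns` tibble: columns `subject_id`, `side`,
#'   `trial_id`, `label` (+1 right, -1 left) and `v000`..`v100`.
#' @export
time_normalize <- function(trials) {
  trials <- validate_trials(trials)
  if (any(trials$units != "pct_bw")) {
    abort("time_normalize expects bodyweight-normalized trials (%BW)",
          class = "gaitsym_domain_error")
  }
  vals <- t(vapply(trials$samples, function(s) {
    approx(x = seq(0, 100, length.out = length(s)), y = s,
           xout = 0:100, method = "linear")$y
  }, numeric(101)))
  colnames(vals) <- pattern_cols()
  out <- dplyr::bind_cols(
    tibble::tibble(
      subject_id = trials$subject_id,
      side = trials$side,
      trial_id = trials$trial_id,
      label = side_label(trials$side)
    ),
    tibble::as_tibble(vals)
  )
  validate_patterns(out)
}

pattern_cols <- function() sprintf("v%03d", 0:100)

validate_patterns <- function(patterns) {
  stopifnot(is.data.frame(patterns))
  need <- c("subject_id", "side", "trial_id", "label", pattern_cols())
  miss <- setdiff(need, names(patterns))
  if (length(miss)) {
    abort(paste0("gait pattern table is missing column(s): ",
                 paste(head(miss, 5), collapse = ", "),
                 if (length(miss) > 5) sprintf(" (+%d more)", length(miss) - 5)),
          class = "gaitsym_format_error")
  }
  if (!all(patterns$label == side_label(patterns$side))) {
    abort("pattern label must be +1 for right and -1 for left",
          class = "gaitsym_integrity_error")
  }
  key <- paste(patterns$subject_id, patterns$side, patterns$trial_id)
  if (anyDuplicated(key)) {
    abort("duplicate (subject, side, trial) keys in pattern table",
          class = "gaitsym_integrity_error")
  }
  m <- pattern_matrix(patterns)
  if (!all(is.finite(m)) || any(m < 0)) {
    abort("pattern values must be finite and non-negative",
          class = "gaitsym_domain_error")
  }
  class(patterns) <- unique(c("gait_patterns", class(patterns)))
  patterns
}

#' Extract the n x 101 value matrix from a gait pattern table
#'
#' @param patterns a `gait_patterns` tibble.
#' @return A numeric matrix with one row per pattern and 101 columns.
#' @export
pattern_matrix <- function(patterns) {
  as.matrix(patterns[, pattern_cols(), drop = FALSE])
}

#' Full preprocessing pipeline: raw trials to gait patterns
#'
#' Convenience wrapper chaining [normalize_bodyweight()], [segment_stance()]
#' and [time_normalize()].
#'
#' @inheritParams normalize_bodyweight
#' @inheritParams segment_stance
#' @return A `gait_patterns` tibble.
#' @export
preprocess_trials <- function(trials, threshold_pct_bw = 5,
                              clip_negative = TRUE) {
  trials |>
    normalize_bodyweight(clip_negative = clip_negative) |>
    segment_stance(threshold_pct_bw = threshold_pct_bw) |>
    time_normalize()
}

#' Write / read gait pattern tables
#'
#' The pattern CSV dialect has columns `subject_id`, `side`, `trial_id`,
#' `label` and the 101 value columns `v000`..`v100` (%BW).
#'
#' @param patterns a `gait_patterns` tibble.
#' @param path CSV file path.
#' @return `write_patterns` returns `path` invisibly; `read_patterns`
#'   returns a `gait_patterns` tibble.
#' @export
write_patterns <- function(patterns, path) {
  patterns <- validate_patterns(patterns)
  out <- dplyr::mutate(patterns, side = as.character(.data$side))
  readr::write_csv(as.data.frame(out), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("pattern file not found: ", path), class = "gaitsym_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  raw$side <- normalize_side(raw$side)
  raw$label <- as.integer(raw$label)
  raw$subject_id <- as.character(raw$subject_id)
  raw$trial_id <- as.character(raw$trial_id)
  validate_patterns(tibble::as_tibble(raw))
}
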