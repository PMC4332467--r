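#' Extract the six discrete gait parameters from gait patterns
#'
#' For each 101-point pattern, finds the loading-response peak (Fz1, Tz1)
#' as the maximum within the first search window, the push-off peak
#' (Fz3, Tz3) as the maximum within the second window, and the mid-stance
#' valley (Fz2, Tz2) as the minimum strictly between Tz1 and Tz3. Ties are
#' broken by the earliest index. The defaults search the first peak in
#' 5-40 % of stance and the second in 60-95 %, wide margins around the
#' timings seen in healthy walking.
#'
#' @param patterns a `gait_patterns` tibble.
#' @param window1 integer range (% stance) searched for the first peak.
#' @param window3 integer range (% stance) searched for the second peak.
#' @return A tibble with columns `subject_id`, `side`, `trial_id`, `fz1`,
#'   `tz1`, `fz2`, `tz2`, `fz3`, `tz3` (%BW and % stance).
#' @export
extract_discrete_params <- function(patterns, window1 = c(5, 40),
                                    window3 = c(60, 95)) {
  patterns <- validate_patterns(patterns)
  m <- pattern_matrix(patterns)
  w1 <- seq(window1[1], window1[2])
  w3 <- seq(window3[1], window3[2])
  if (!length(w1) || !length(w3) || min(w1) < 0 || max(w3) > 100) {
    abort("search windows must be non-empty subsets of 0..100",
          class = "gaitsym_domain_error")
  }
  one <- function(v, id) {
    v <- as.numeric(v)
    tz1 <- w1[which.max(v[w1 + 1L])]          # which.max = earliest tie-break
    tz3 <- w3[which.max(v[w3 + 1L])]
    if (tz3 - tz1 < 2L) {
      abort(sprintf("trial %s: peaks too close, no valley interval", id),
            class = "gaitsym_extraction_error")
    }
    wv <- seq(tz1 + 1L, tz3 - 1L)             # strictly between the peaks
    tz2 <- wv[which.min(v[wv + 1L])]
    fz1 <- v[tz1 + 1L]; fz2 <- v[tz2 + 1L]; fz3 <- v[tz3 + 1L]
    if (fz2 > min(fz1, fz3)) {
      abort(sprintf(
        "trial %s: no valley below both peaks; curve is not M-shaped", id),
        class = "gaitsym_extraction_error")
    }
    c(fz1 = fz1, tz1 = tz1, fz2 = fz2, tz2 = tz2, fz3 = fz3, tz3 = tz3)
  }
  ids <- paste(patterns$subject_id, patterns$side, patterns$trial_id, sep = "/")
  res <- t(vapply(seq_len(nrow(m)), function(i) one(m[i, ], ids[i]),
                  numeric(6)))
  dplyr::bind_cols(
    patterns[, c("subject_id", "side", "trial_id")],
    tibble::as_tibble(res)
  )
}

#' Fit a PCA model to gait patterns
#'
#' Mean-centers the training patterns and eigendecomposes their sample
#' covariance (n-1 denominator). The number of retained components is the
#' smallest k whose cumulative explained-variance fraction reaches
#' `variance_fraction`.
#'
#' @param patterns training `gait_patterns` (or a numeric matrix with one
#'   pattern per row). Must come from the training folds only when used
#'   inside cross-validation.
#' @param variance_fraction target cumulative explained-variance fraction
#'   in (0, 1]; default 0.95.
#' @return A list of class `pca_model`: `mean` (length-101 vector),
#'   `components` (101 x r orthonormal matrix, all positive-variance
#'   components), `explained_variance` (non-increasing), `n_components_kept`.
#' @export
fit_pca <- function(patterns, variance_fraction = 0.95) {
  x <- if (is.matrix(patterns)) patterns else pattern_matrix(
    validate_patterns(patterns))
  if (nrow(x) < 2) {
    abort("PCA needs at least 2 training patterns",
          class = "gaitsym_fit_error")
  }
  if (!(variance_fraction > 0 && variance_fraction <= 1)) {
    abort("variance_fraction must be in (0, 1]", class = "gaitsym_domain_error")
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  keep_pos <- ev > max(ev) * 1e-12
  if (!any(keep_pos) || max(ev) == 0) {
    abort("patterns have zero total variance; PCA is degenerate",
          class = "gaitsym_degenerate_data_error")
  }
  ev <- ev[keep_pos]
  frac <- cumsum(ev) / sum(ev)
  k <- which(frac >= variance_fraction - 1e-12)[1]
  structure(list(
    mean = pc$center,
    components = pc$rotation[, keep_pos, drop = FALSE],
    explained_variance = ev,
    n_components_kept = as.integer(k)
  ), class = "pca_model")
}

#' Project gait patterns onto a fitted PCA basis
#'
#' @param model a [fit_pca()] model.
#' @param patterns `gait_patterns` tibble or numeric matrix (rows =
#'   patterns) of the same dimension the model was fitted on.
#' @param all_components project onto all positive-variance components
#'   instead of only the kept ones (used for reconstruction checks).
#' @return Numeric matrix of scores, one row per pattern,
#'   `n_components_kept` (or all) columns.
#' @export
transform_pca <- function(model, patterns, all_components = FALSE) {
  stopifnot(inherits(model, "pca_model"))
  x <- if (is.matrix(patterns)) patterns else pattern_matrix(
    validate_patterns(patterns))
  if (ncol(x) != length(model$mean)) {
    abort(sprintf("pattern dimension %d does not match model dimension %d",
                  ncol(x), length(model$mean)),
          class = "gaitsym_dimension_error")
  }
  k <- if (all_components) ncol(model$components) else model$n_components_kept
  sweep(x, 2, model$mean) %*% model$components[, seq_len(k), drop = FALSE]
}

#' Reconstruct patterns from PCA scores
#'
#' @param model a [fit_pca()] model.
#' @param scores score matrix from [transform_pca()].
#' @return Numeric matrix in the original pattern space.
#' @export
inverse_pca <- function(model, scores) {
  stopifnot(inherits(model, "pca_model"))
  k <- ncol(scores)
  sweep(scores %*% t(model$components[, seq_len(k), drop = FALSE]),
        2, model$mean, `+`)
}
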