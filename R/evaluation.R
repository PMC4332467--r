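#' Classification metrics from a confusion table
#'
#' With the right side as the positive class: accuracy
#' `(TP + TN) / (TP + FP + TN + FN)`, sensitivity `TP / (TP + FN)` (rate
#' of right-side patterns recognized) and specificity `TN / (TN + FP)`
#' (rate of left-side patterns recognized). A ratio with zero denominator
#' is reported as `NA` with its `*_defined` flag set to `FALSE`, never
#' silently zero.
#'
#' @param tp,fp,tn,fn non-negative confusion counts.
#' @return A list: `accuracy`, `sensitivity`, `specificity`,
#'   `sensitivity_defined`, `specificity_defined`.
#' @examples
#' metrics_from_confusion(tp = 9, fp = 2, tn = 8, fn = 1)
#' @export
metrics_from_confusion <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("confusion counts must be non-negative integers",
          class = "gaitsym_domain_error")
  }
  total <- sum(counts)
  if (total == 0) {
    abort("empty evaluation: all confusion counts are zero",
          class = "gaitsym_empty_evaluation_error")
  }
  sens_def <- (tp + fn) > 0
  spec_def <- (tn + fp) > 0
  list(
    accuracy = (tp + tn) / total,
    sensitivity = if (sens_def) tp / (tp + fn) else NA_real_,
    specificity = if (spec_def) tn / (tn + fp) else NA_real_,
    sensitivity_defined = sens_def,
    specificity_defined = spec_def
  )
}

#' Balanced fold assignment for left-right classification
#'
#' Splits a balanced pattern set into `k` folds each containing equally
#' many right- and left-side patterns. In `subject_paired` mode (default)
#' both sides of one subject land in the same fold, so a subject never
#' straddles train and test; `pattern_level` mode stratifies by side only.
#' The assignment is a deterministic function of `seed`.
#'
#' @param patterns a `gait_patterns` tibble (or any tibble with
#'   `subject_id` and `side` columns).
#' @param k number of folds.
#' @param pairing `"subject_paired"` or `"pattern_level"`.
#' @param seed integer seed controlling the shuffle.
#' @return Integer vector of fold ids (1..k), one per pattern row.
#' @export
make_balanced_folds <- function(patterns, k = 6,
                                pairing = c("subject_paired", "pattern_level"),
                                seed = 1) {
  pairing <- match.arg(pairing)
  side <- as.character(patterns$side)
  n_left <- sum(side == "left"); n_right <- sum(side == "right")
  if (n_left != n_right) {
    abort(sprintf(
      "dataset must be balanced: %d left vs %d right patterns (drop or average trials to balance)",
      n_left, n_right), class = "gaitsym_fold_error")
  }
  folds <- integer(nrow(patterns))
  if (pairing == "subject_paired") {
    subjects <- unique(patterns$subject_id)
    if (length(subjects) %% k != 0) {
      abort(sprintf(
        "%d subjects are not divisible into %d folds; choose k dividing the subject count or drop subjects",
        length(subjects), k), class = "gaitsym_fold_error")
    }
    order <- withr::with_seed(seed, sample(subjects))
    fold_of <- stats::setNames(rep(seq_len(k), each = length(subjects) / k),
                               order)
    folds <- unname(fold_of[patterns$subject_id])
  } else {
    if (n_left %% k != 0) {
      abort(sprintf(
        "%d patterns per side are not divisible into %d folds; adjust k or the trial count",
        n_left, k), class = "gaitsym_fold_error")
    }
    withr::with_seed(seed, {
      for (s in c("left", "right")) {
        idx <- which(side == s)
        folds[sample(idx)] <- rep(seq_len(k), each = length(idx) / k)
      }
    })
  }
  folds
}

#' Collapse repeated trials to one mean pattern per subject and side
#'
#' The classification unit is one gait pattern per subject per side: the
#' pointwise mean of that subject's repeated trials. A per-trial mode is
#' available in [cross_validate()] for sensitivity analyses.
#'
#' @param patterns a `gait_patterns` tibble.
#' @return A `gait_patterns` tibble with `trial_id = "mean"`.
#' @export
collapse_subject_means <- function(patterns) {
  patterns <- validate_patterns(patterns)
  out <- patterns |>
    dplyr::group_by(.data$subject_id, .data$side) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(pattern_cols()), mean),
                     .groups = "drop") |>
    dplyr::mutate(trial_id = "mean", label = side_label(.data$side),
                  .after = "side")
  validate_patterns(out)
}

resolve_features <- function(feature_mode, patterns) {
  m <- pattern_matrix(patterns)
  switch(feature_mode,
    all_101 = m,
    six_params = {
      p <- extract_discrete_params(patterns)
      as.matrix(p[, c("fz1", "tz1", "fz2", "tz2", "fz3", "tz3")])
    },
    pca = m, # projected per fold inside cross_validate
    abort("feature_mode must be all_101, six_params or pca",
          class = "gaitsym_parameter_error")
  )
}

#' Repeated balanced k-fold cross-validation of the left-right classifier
#'
#' The experiment engine: for each of `repeats` independent re-shufflings
#' of the balanced `k`-fold partition and each held-out fold, all
#' fold-dependent transforms (feature standardization and, in `pca` mode,
#' the PCA basis) are fitted on the training folds only, an SVM is trained
#' and the confusion counts are collected on the held-out fold. Metrics
#' are averaged over all `k * repeats` evaluations.
#'
#' Feature modes: `all_101` (the full 101-point pattern), `six_params`
#' (Fz1, Tz1, Fz2, Tz2, Fz3, Tz3 extracted per pattern) and `pca`
#' (PCA scores, basis fitted per training split).
#'
#' @param patterns a `gait_patterns` tibble.
#' @param feature_mode `"all_101"`, `"six_params"` or `"pca"`.
#' @param kernel a `kernel_spec`.
#' @param cost SVM penalty C.
#' @param k folds (default 6).
#' @param repeats partition re-shuffles (default 10).
#' @param seed master seed; folds and SMO draws use sub-streams.
#' @param pairing fold pairing mode, see [make_balanced_folds()].
#' @param collapse `"subject_mean"` (default: one averaged pattern per
#'   subject per side) or `"per_trial"`.
#' @param variance_fraction PCA retained-variance target (pca mode).
#' @param standardize z-score features using training-fold constants.
#' @return A list of class `cv_result`: `folds` (tibble with one row per
#'   repeat x fold: confusion counts and metrics), `predictions` (one row
#'   per pattern per repeat with its held-out decision value and label),
#'   `accuracy`, `sensitivity`, `specificity` (means over folds),
#'   `accuracy_sd`, and `config`.
#' @export
cross_validate <- function(patterns,
                           feature_mode = c("all_101", "six_params", "pca"),
                           kernel = rbf_kernel(), cost = 1,
                           k = 6, repeats = 10, seed = 1,
                           pairing = c("subject_paired", "pattern_level"),
                           collapse = c("subject_mean", "per_trial"),
                           variance_fraction = 0.95, standardize = TRUE) {
  feature_mode <- match.arg(feature_mode)
  pairing <- match.arg(pairing)
  collapse <- match.arg(collapse)
  patterns <- validate_patterns(patterns)
  if (collapse == "subject_mean") patterns <- collapse_subject_means(patterns)

  feats <- resolve_features(feature_mode, patterns)
  y <- patterns$label
  rows <- vector("list", repeats * k)
  pred_rows <- vector("list", repeats * k)
  r_i <- 0L
  for (rep_i in seq_len(repeats)) {
    folds <- make_balanced_folds(
      patterns, k = k, pairing = pairing,
      seed = substream_seed(seed, "folds", rep_i))
    for (fold_i in seq_len(k)) {
      test <- folds == fold_i
      x_tr <- feats[!test, , drop = FALSE]
      x_te <- feats[test, , drop = FALSE]
      if (feature_mode == "pca") {
        pca <- fit_pca(x_tr, variance_fraction = variance_fraction)
        x_tr <- transform_pca(pca, x_tr)
        x_te <- transform_pca(pca, x_te)
      }
      if (standardize) {
        std <- fit_standardizer(x_tr)
        x_tr <- apply_standardizer(std, x_tr)
        x_te <- apply_standardizer(std, x_te)
      }
      model <- train_svm(
        x_tr, y[!test], kernel = kernel, cost = cost,
        seed = substream_seed(seed, "smo", (rep_i - 1L) * k + fold_i))
      dv <- decision_value(model, x_te)
      pred <- ifelse(dv >= 0, 1L, -1L)
      truth <- y[test]
      tp <- sum(pred == 1 & truth == 1); fp <- sum(pred == 1 & truth == -1)
      tn <- sum(pred == -1 & truth == -1); fn <- sum(pred == -1 & truth == 1)
      met <- metrics_from_confusion(tp, fp, tn, fn)
      r_i <- r_i + 1L
      rows[[r_i]] <- tibble::tibble(
        repeat_id = rep_i, fold = fold_i, tp = tp, fp = fp, tn = tn, fn = fn,
        accuracy = met$accuracy, sensitivity = met$sensitivity,
        specificity = met$specificity)
      pred_rows[[r_i]] <- tibble::tibble(
        repeat_id = rep_i, fold = fold_i,
        subject_id = patterns$subject_id[test],
        side = patterns$side[test],
        trial_id = patterns$trial_id[test],
        label = truth, decision_value = dv, predicted = pred)
    }
  }
  folds_tab <- dplyr::bind_rows(rows)
  structure(list(
    folds = folds_tab,
    predictions = dplyr::bind_rows(pred_rows),
    accuracy = mean(folds_tab$accuracy),
    sensitivity = mean(folds_tab$sensitivity, na.rm = TRUE),
    specificity = mean(folds_tab$specificity, na.rm = TRUE),
    accuracy_sd = sd(folds_tab$accuracy),
    config = list(feature_mode = feature_mode, kernel = kernel, cost = cost,
                  k = k, repeats = repeats, seed = seed, pairing = pairing,
                  collapse = collapse, variance_fraction = variance_fraction,
                  standardize = standardize,
                  n_patterns = nrow(patterns))
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cfg <- x$config
  kern <- cfg$kernel$kind
  if (kern == "rbf") {
    kern <- if (is.null(cfg$kernel$sigma)) "rbf(auto width)" else
      sprintf("rbf(sigma=%g)", cfg$kernel$sigma)
  }
  if (kern == "poly") kern <- sprintf("poly(d=%d)", cfg$kernel$degree)
  cat(sprintf(
    "%d-fold CV x %d repeats | features: %s | kernel: %s | C=%g | n=%d\n",
    cfg$k, cfg$repeats, cfg$feature_mode, kern, cfg$cost, cfg$n_patterns))
  cat(sprintf("(ACC, SEN, SEP) = (%.3f, %.3f, %.3f)   accuracy SD %.3f\n",
              x$accuracy, x$sensitivity, x$specificity, x$accuracy_sd))
  invisible(x)
}

#' Grid search over kernels, penalties and feature modes
#'
#' Exhaustively cross-validates every combination and ranks results by
#' mean accuracy (ties by sensitivity, then specificity, then smaller C).
#'
#' @inheritParams cross_validate
#' @param kernels list of `kernel_spec` objects.
#' @param costs numeric vector of penalty values.
#' @param feature_modes character vector of feature modes.
#' @param ... further arguments passed to [cross_validate()].
#' @return A tibble of class `grid_result`, one ranked row per
#'   configuration: `feature_mode`, `kernel`, `kernel_param`, `cost`,
#'   `accuracy`, `sensitivity`, `specificity`, `accuracy_sd`, `rank`.
#' @export
grid_search <- function(patterns, kernels = list(linear_kernel()),
                        costs = 1, feature_modes = "all_101", seed = 1, ...) {
  if (!length(kernels) || !length(costs) || !length(feature_modes)) {
    abort("grids must be non-empty", class = "gaitsym_parameter_error")
  }
  grid <- expand.grid(ki = seq_along(kernels), cost = costs,
                      feature_mode = feature_modes,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    kern <- kernels[[grid$ki[g]]]
    cv <- cross_validate(patterns, feature_mode = grid$feature_mode[g],
                         kernel = kern, cost = grid$cost[g], seed = seed, ...)
    tibble::tibble(
      feature_mode = grid$feature_mode[g],
      kernel = kern$kind,
      kernel_param = switch(kern$kind, rbf = kern$sigma,
                            poly = as.numeric(kern$degree), NA_real_),
      cost = grid$cost[g],
      accuracy = cv$accuracy, sensitivity = cv$sensitivity,
      specificity = cv$specificity, accuracy_sd = cv$accuracy_sd)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$accuracy), dplyr::desc(.data$sensitivity),
                   dplyr::desc(.data$specificity), .data$cost) |>
    dplyr::mutate(rank = dplyr::row_number())
  class(out) <- unique(c("grid_result", class(out)))
  out
}

#' Classifier-based symmetry score with a permutation test
#'
#' Operationalizes the symmetry-as-classification premise: if left and
#' right patterns come from the same distribution, no classifier beats
#' chance. The score maps mean cross-validated accuracy `a` to
#' `1 - 2 * max(a - 0.5, 0)`, so 1 means fully symmetric (chance-level
#' discrimination) and 0 maximal asymmetry. Significance is assessed by
#' permuting side labels within subject pairs and recomputing the CV
#' accuracy: `p = (1 + #{permuted >= observed}) / (1 + n_permutations)`.
#'
#' @inheritParams cross_validate
#' @param n_permutations permutation count (values below 19 cannot reach
#'   p <= 0.05 and trigger a warning).
#' @param ... further arguments passed to [cross_validate()].
#' @return A list of class `symmetry_score`: `mean_accuracy`, `score`,
#'   `permutation_p`, `n_permutations`, `permuted_accuracies`.
#' @export
symmetry_score <- function(patterns, feature_mode = "all_101",
                           kernel = linear_kernel(), cost = 1,
                           k = 6, repeats = 1, n_permutations = 19,
                           seed = 1, ...) {
  if (n_permutations < 19) {
    warn("fewer than 19 permutations cannot resolve p <= 0.05")
  }
  patterns <- validate_patterns(patterns)
  observed <- cross_validate(patterns, feature_mode = feature_mode,
                             kernel = kernel, cost = cost, k = k,
                             repeats = repeats, seed = seed, ...)
  perm_acc <- vapply(seq_len(n_permutations), function(p) {
    permuted <- permute_sides(patterns,
                              seed = substream_seed(seed, "permutation", p))
    cross_validate(permuted, feature_mode = feature_mode, kernel = kernel,
                   cost = cost, k = k, repeats = repeats,
                   seed = substream_seed(seed, "perm-cv", p), ...)$accuracy
  }, numeric(1))
  acc <- observed$accuracy
  structure(list(
    mean_accuracy = acc,
    score = 1 - 2 * max(acc - 0.5, 0),
    permutation_p = (1 + sum(perm_acc >= acc)) / (1 + n_permutations),
    n_permutations = n_permutations,
    permuted_accuracies = perm_acc
  ), class = "symmetry_score")
}

#' @export
print.symmetry_score <- function(x, ...) {
  cat(sprintf(
    "symmetry score %.3f (mean CV accuracy %.3f), permutation p = %.4f (%d permutations)\n",
    x$score, x$mean_accuracy, x$permutation_p, x$n_permutations))
  invisible(x)
}

# swap the left/right labels of each subject's pattern pair with prob 1/2
permute_sides <- function(patterns, seed) {
  patterns <- validate_patterns(patterns)
  subjects <- unique(patterns$subject_id)
  flip <- withr::with_seed(seed,
                           stats::setNames(runif(length(subjects)) < 0.5,
                                           subjects))
  do_flip <- flip[patterns$subject_id]
  side <- as.character(patterns$side)
  side[do_flip] <- ifelse(side[do_flip] == "left", "right", "left")
  patterns$side <- factor(side, levels = .side_levels)
  patterns$label <- side_label(patterns$side)
  validate_patterns(patterns)
}

#' Export per-fold cross-validation results as CSV
#'
#' @param cv a `cv_result`.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_cv_results <- function(cv, path) {
  stopifnot(inherits(cv, "cv_result"))
  readr::write_csv(cv$folds, path, progress = FALSE)
  invisible(path)
}
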