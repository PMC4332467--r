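#' Coefficient of variation
#'
#' `CV = 100 * SD / mean`, with the sample (n-1) standard deviation. Used
#' to judge trial-to-trial repeatability of a discrete gait parameter; a
#' CV at or below 12.5 % is conventionally treated as acceptable.
#'
#' @param values numeric vector, length >= 2, non-zero mean.
#' @return CV in percent.
#' @examples
#' coefficient_of_variation(c(1, 2, 3)) # 50
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) {
    abort("CV needs at least 2 values", class = "gaitsym_sample_size_error")
  }
  m <- mean(values)
  if (m == 0) {
    abort("CV is undefined for zero-mean values",
          class = "gaitsym_domain_error")
  }
  100 * sd(values) / m
}

#' Robinson's absolute symmetry index
#'
#' `SI = 2 |X_R - X_L| / (X_R + X_L) * 100`. Zero means perfect left-right
#' symmetry; values under 10 % are conventionally acceptable. For positive
#' inputs SI is bounded by 200 and invariant under joint rescaling.
#'
#' @param x_right,x_left the right- and left-side parameter values (same
#'   units).
#' @return SI in percent (non-negative).
#' @examples
#' symmetry_index(3, 1) # 100
#' @export
symmetry_index <- function(x_right, x_left) {
  denom <- x_right + x_left
  if (any(denom == 0)) {
    abort("SI is undefined when x_right + x_left = 0",
          class = "gaitsym_domain_error")
  }
  200 * abs(x_right - x_left) / denom
}

#' Paired t-test for a left-right parameter difference
#'
#' Computes differences `d_i = right_i - left_i`, the statistic
#' `t = mean(d) / (SD(d) / sqrt(n))` and the two-sided p-value from the
#' Student-t distribution with n-1 degrees of freedom. When all
#' differences are exactly zero the test degenerates to `t = 0, p = 1`;
#' identical non-zero differences have zero variance and raise an error.
#'
#' @param left_values,right_values equal-length numeric vectors, n >= 2.
#' @return A list with `t_statistic`, `p_value`, `df`, `mean_difference`.
#' @export
paired_t_test <- function(left_values, right_values) {
  n <- length(left_values)
  if (n != length(right_values)) {
    abort("left and right value vectors must have equal length",
          class = "gaitsym_domain_error")
  }
  if (n < 2) {
    abort("paired t-test needs n >= 2 pairs",
          class = "gaitsym_sample_size_error")
  }
  d <- right_values - left_values
  s <- sd(d)
  if (s == 0) {
    if (mean(d) == 0) {
      return(list(t_statistic = 0, p_value = 1, df = n - 1,
                  mean_difference = 0))
    }
    abort("differences are identical and non-zero: zero variance, t undefined",
          class = "gaitsym_degenerate_variance_error")
  }
  t_stat <- mean(d) / (s / sqrt(n))
  list(t_statistic = t_stat,
       p_value = 2 * pt(abs(t_stat), df = n - 1, lower.tail = FALSE),
       df = n - 1,
       mean_difference = mean(d))
}

#' Build the classical per-parameter symmetry report
#'
#' The traditional protocol applied to the six discrete gait parameters:
#' per subject and side, parameter means over the repeated trials and a
#' trial-to-trial CV; per-side CVs and means averaged across subjects; a
#' symmetry index per subject from that subject's side means, averaged
#' across subjects (or, with `si_mode = "group_means"`, a single SI of the
#' group means); and a paired t-test across subjects on the subject-level
#' side means. Flags apply the conventional thresholds: CV acceptable at
#' <= 12.5 % on both sides, SI acceptable under 10 %, and a significant
#' left-right difference at p <= 0.05.
#'
#' @param params a discrete-parameter table from
#'   [extract_discrete_params()] (one row per subject/side/trial).
#' @param si_mode `"per_subject"` (default) or `"group_means"`.
#' @param cv_threshold,si_threshold,alpha the three decision thresholds.
#' @return A list of class `si_report`: `table` (one row per parameter in
#'   the order Fz1, Tz1, Fz2, Tz2, Fz3, Tz3 with columns `parameter`,
#'   `left_cv_pct`, `left_mean`, `right_cv_pct`, `right_mean`, `si_pct`,
#'   `p_value`, `cv_acceptable`, `si_acceptable`,
#'   `significant_difference`), plus `n_subjects` and the thresholds.
#' @export
build_si_report <- function(params, si_mode = c("per_subject", "group_means"),
                            cv_threshold = 12.5, si_threshold = 10,
                            alpha = 0.05) {
  si_mode <- match.arg(si_mode)
  par_names <- c("fz1", "tz1", "fz2", "tz2", "fz3", "tz3")
  stopifnot(all(c("subject_id", "side", par_names) %in% names(params)))

  complete <- params |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::filter(dplyr::n_distinct(.data$side) == 2) |>
    dplyr::ungroup()
  dropped <- setdiff(unique(params$subject_id), unique(complete$subject_id))
  if (length(dropped)) {
    warn(sprintf("excluding %d subject(s) missing one side: %s",
                 length(dropped), paste(dropped, collapse = ", ")))
  }
  n_trials <- complete |>
    dplyr::count(.data$subject_id, .data$side)
  if (any(n_trials$n < 2)) {
    abort("every subject needs >= 2 trials per side to compute a CV",
          class = "gaitsym_sample_size_error")
  }
  if (dplyr::n_distinct(complete$subject_id) < 2) {
    abort("report needs at least 2 complete subjects",
          class = "gaitsym_report_error")
  }

  per_subject <- complete |>
    dplyr::group_by(.data$subject_id, .data$side) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(par_names),
      list(mean = mean, cv = coefficient_of_variation)
    ), .groups = "drop")

  rows <- lapply(par_names, function(p) {
    mean_col <- paste0(p, "_mean"); cv_col <- paste0(p, "_cv")
    wide <- per_subject |>
      dplyr::select("subject_id", "side", dplyr::all_of(c(mean_col, cv_col))) |>
      tidyr::pivot_wider(names_from = "side",
                         values_from = dplyr::all_of(c(mean_col, cv_col)))
    l_mean <- wide[[paste0(mean_col, "_left")]]
    r_mean <- wide[[paste0(mean_col, "_right")]]
    si <- if (si_mode == "per_subject") {
      mean(symmetry_index(r_mean, l_mean))
    } else {
      symmetry_index(mean(r_mean), mean(l_mean))
    }
    tt <- paired_t_test(l_mean, r_mean)
    l_cv <- mean(wide[[paste0(cv_col, "_left")]])
    r_cv <- mean(wide[[paste0(cv_col, "_right")]])
    tibble::tibble(
      parameter = toupper(substr(p, 1, 1)) |>
        paste0(substr(p, 2, 2), substr(p, 3, 3)),
      left_cv_pct = l_cv, left_mean = mean(l_mean),
      right_cv_pct = r_cv, right_mean = mean(r_mean),
      si_pct = si, p_value = tt$p_value,
      cv_acceptable = l_cv <= cv_threshold && r_cv <= cv_threshold,
      si_acceptable = si < si_threshold,
      significant_difference = tt$p_value <= alpha
    )
  })

  structure(list(
    table = dplyr::bind_rows(rows),
    n_subjects = dplyr::n_distinct(complete$subject_id),
    si_mode = si_mode,
    cv_threshold = cv_threshold, si_threshold = si_threshold, alpha = alpha
  ), class = "si_report")
}

#' @export
print.si_report <- function(x, ...) {
  cat(sprintf(
    "Left-right symmetry report (%d subjects, SI mode: %s)\n",
    x$n_subjects, x$si_mode))
  tab <- x$table
  cat(sprintf("%-5s %8s %8s %8s %8s %7s %8s  %s\n",
              "Param", "CV_L(%)", "mean_L", "CV_R(%)", "mean_R",
              "SI(%)", "p", "flags"))
  for (i in seq_len(nrow(tab))) {
    flags <- paste0(
      if (!tab$cv_acceptable[i]) "CV!" else "",
      if (!tab$si_acceptable[i]) "SI!" else "",
      if (tab$significant_difference[i]) "p*" else "")
    cat(sprintf("%-5s %8.2f %8.2f %8.2f %8.2f %7.2f %8.4f  %s\n",
                tab$parameter[i], tab$left_cv_pct[i], tab$left_mean[i],
                tab$right_cv_pct[i], tab$right_mean[i], tab$si_pct[i],
                tab$p_value[i], flags))
  }
  invisible(x)
}

#' Export a symmetry report as CSV
#'
#' @param report an [build_si_report()] result.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_si_report <- function(report, path) {
  stopifnot(inherits(report, "si_report"))
  readr::write_csv(report$table, path, progress = FALSE)
  invisible(path)
}
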