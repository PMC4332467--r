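#' Kernel specifications
#'
#' Three kernels for the soft-margin SVM:
#' * linear: `K(x, z) = x . z`
#' * polynomial: `K(x, z) = ((x . z) + 1)^d`
#' * Gaussian RBF: `K(x, z) = exp(-||x - z||^2 / (2 sigma^2))`
#'
#' @param degree polynomial degree `d >= 1`.
#' @param sigma RBF width `sigma > 0`, or `NULL` (the default) to resolve
#'   it at training time by the median heuristic: the median pairwise
#'   Euclidean distance of the training features, a scale at which the
#'   Gram matrix is neither near-identity nor near-constant. The width
#'   must track the feature dimension (a width suited to 6 standardized
#'   features collapses the kernel on 101), so a fixed numeric default
#'   would be wrong for all but one feature set.
#' @return A list of class `kernel_spec`.
#' @examples
#' kernel_eval(poly_kernel(2), c(1, 0), c(1, 1)) # (1 + 1)^2 = 4
#' @name kernels
NULL

#' @rdname kernels
#' @export
linear_kernel <- function() {
  structure(list(kind = "linear"), class = "kernel_spec")
}

#' @rdname kernels
#' @export
poly_kernel <- function(degree = 2) {
  if (degree < 1 || degree != round(degree)) {
    abort("polynomial degree must be a positive integer",
          class = "gaitsym_parameter_error")
  }
  structure(list(kind = "poly", degree = as.integer(degree)),
            class = "kernel_spec")
}

#' @rdname kernels
#' @export
rbf_kernel <- function(sigma = NULL) {
  if (!is.null(sigma) && sigma <= 0) {
    abort("RBF width sigma must be positive",
          class = "gaitsym_parameter_error")
  }
  structure(list(kind = "rbf", sigma = sigma), class = "kernel_spec")
}

#' Median-heuristic RBF width
#'
#' The median pairwise Euclidean distance between training rows; the
#' conventional scale at which an RBF kernel discriminates without
#' degenerating toward the identity or the all-ones matrix.
#'
#' @param x numeric feature matrix, observations in rows.
#' @return A positive scalar width.
#' @export
median_heuristic_sigma <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  d <- stats::dist(x)
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m <= 0) 1 else m
}

# concretize an auto-width RBF spec against training features
resolve_kernel <- function(spec, x) {
  if (spec$kind == "rbf" && is.null(spec$sigma)) {
    spec$sigma <- median_heuristic_sigma(x)
  }
  spec
}

#' Evaluate a kernel on a pair of vectors
#'
#' @param spec a `kernel_spec`.
#' @param x,z equal-length finite numeric vectors.
#' @return The scalar kernel value.
#' @export
kernel_eval <- function(spec, x, z) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (length(x) != length(z)) {
    abort("kernel arguments must have equal length",
          class = "gaitsym_dimension_error")
  }
  drop(kernel_matrix(spec, matrix(x, 1), matrix(z, 1)))
}

#' Kernel Gram matrix between two sets of row vectors
#'
#' @param spec a `kernel_spec`.
#' @param x,z numeric matrices with observations in rows and matching
#'   column counts (`z` defaults to `x`).
#' @return The `nrow(x)` x `nrow(z)` kernel matrix.
#' @export
kernel_matrix <- function(spec, x, z = x) {
  stopifnot(inherits(spec, "kernel_spec"), is.matrix(x), is.matrix(z))
  if (ncol(x) != ncol(z)) {
    abort("kernel arguments must have matching dimensions",
          class = "gaitsym_dimension_error")
  }
  g <- tcrossprod(x, z)
  if (spec$kind == "rbf" && is.null(spec$sigma)) {
    abort("RBF width is unresolved; supply sigma or train via train_svm",
          class = "gaitsym_parameter_error")
  }
  switch(spec$kind,
    linear = g,
    poly = (g + 1)^spec$degree,
    rbf = {
      d2 <- outer(rowSums(x^2), rowSums(z^2), `+`) - 2 * g
      exp(-pmax(d2, 0) / (2 * spec$sigma^2))
    },
    abort("unknown kernel kind", class = "gaitsym_parameter_error")
  )
}

# dual objective W(beta) = sum(beta) - 1/2 (beta*y)' K (beta*y)
svm_dual_objective <- function(alpha, y, K) {
  ay <- alpha * y
  sum(alpha) - 0.5 * drop(crossprod(ay, K %*% ay))
}

#' Train a soft-margin kernel SVM by sequential minimal optimization
#'
#' Solves the standard box-constrained SVM dual
#' \deqn{\max_\beta \sum_i \beta_i - \tfrac12 \sum_{ij} \beta_i \beta_j
#'       y_i y_j K(x_i, x_j), \quad 0 \le \beta_i \le C, \; \sum_i \beta_i
#'       y_i = 0}
#' by SMO: repeated analytic optimization of one pair of dual variables
#' with clipping to the box, and a bias update per step. The first index
#' is any KKT violator (at `tol`); the second is chosen by the maximal
#' error difference among non-bound points, falling back to randomized
#' sweeps. Training stops when a full pass finds no violator, i.e. all KKT
#' conditions hold at `tol`.
#'
#' The decision function is `f(x) = sum_sv beta_i y_i K(x_i, x) + b`;
#' the predicted label is its sign (0 maps to +1).
#'
#' @param x numeric feature matrix, one training example per row.
#' @param y labels, +1 (right) / -1 (left); both classes must be present.
#' @param kernel a `kernel_spec` (default [rbf_kernel()], auto width).
#' @param cost misclassification penalty `C > 0`.
#' @param tol KKT violation tolerance (default 1e-3).
#' @param max_passes cap on outer passes over the working set.
#' @param seed integer seed for the randomized second-index fallback.
#' @param trace_objective record the dual objective after every pair
#'   update (diagnostic; off by default to keep training cheap).
#' @return A list of class `svm_model`: `support_vectors`, `coefficients`
#'   (`beta_i y_i` for the support vectors), `bias`, `kernel` (with any
#'   auto RBF width resolved), `cost`, `alpha` (full dual vector), `y`,
#'   and `diagnostics` (pair update count, optional monotone dual
#'   objective trace, final maximal KKT violation, the dual objective,
#'   slack values `xi_i = max(0, 1 - y_i f(x_i))`).
#' @export
train_svm <- function(x, y, kernel = rbf_kernel(), cost = 1, tol = 1e-3,
                      max_passes = 2000, seed = 0, trace_objective = FALSE) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!all(is.finite(x))) {
    abort("features must be finite", class = "gaitsym_domain_error")
  }
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1)) || length(unique(y)) < 2) {
    abort("labels must be +1/-1 with both classes present",
          class = "gaitsym_label_error")
  }
  if (length(y) != nrow(x)) {
    abort("x and y disagree in length", class = "gaitsym_dimension_error")
  }
  if (cost <= 0) {
    abort("cost C must be positive", class = "gaitsym_parameter_error")
  }

  n <- nrow(x)
  kernel <- resolve_kernel(kernel, x)
  K <- kernel_matrix(kernel, x)
  state <- new.env(parent = emptyenv())
  state$alpha <- numeric(n)
  state$b <- 0
  state$f <- rep(0, n)            # decision values incl. bias
  state$updates <- 0L
  state$obj_trace <- if (trace_objective)
    svm_dual_objective(state$alpha, y, K) else NULL
  eps <- 1e-12

  take_step <- function(i, j) {
    if (i == j) return(FALSE)
    a_i <- state$alpha[i]; a_j <- state$alpha[j]
    E_i <- state$f[i] - y[i]; E_j <- state$f[j] - y[j]
    s <- y[i] * y[j]
    if (s > 0) {
      L <- max(0, a_i + a_j - cost); H <- min(cost, a_i + a_j)
    } else {
      L <- max(0, a_j - a_i); H <- min(cost, cost + a_j - a_i)
    }
    if (H - L < eps) return(FALSE)
    eta <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (eta > eps) {
      a_j_new <- a_j + y[j] * (E_i - E_j) / eta
      a_j_new <- min(max(a_j_new, L), H)
    } else {
      # flat or concave direction: evaluate the dual at both box ends
      obj_at <- function(aj) {
        alpha2 <- state$alpha
        alpha2[j] <- aj
        alpha2[i] <- a_i + s * (a_j - aj)
        svm_dual_objective(alpha2, y, K)
      }
      a_j_new <- if (obj_at(L) > obj_at(H) + eps) L else H
    }
    if (abs(a_j_new - a_j) < eps * (a_j_new + a_j + eps)) return(FALSE)
    a_i_new <- a_i + s * (a_j - a_j_new)

    # bias from the KKT condition of whichever new alpha is unbound
    b1 <- state$b - E_i - y[i] * (a_i_new - a_i) * K[i, i] -
      y[j] * (a_j_new - a_j) * K[i, j]
    b2 <- state$b - E_j - y[i] * (a_i_new - a_i) * K[i, j] -
      y[j] * (a_j_new - a_j) * K[j, j]
    b_new <- if (a_i_new > eps && a_i_new < cost - eps) b1
             else if (a_j_new > eps && a_j_new < cost - eps) b2
             else (b1 + b2) / 2

    state$f <- state$f + y[i] * (a_i_new - a_i) * K[, i] +
      y[j] * (a_j_new - a_j) * K[, j] + (b_new - state$b)
    state$alpha[i] <- a_i_new
    state$alpha[j] <- a_j_new
    state$b <- b_new
    state$updates <- state$updates + 1L
    if (trace_objective) {
      state$obj_trace <- c(state$obj_trace,
                           svm_dual_objective(state$alpha, y, K))
    }
    TRUE
  }

  examine <- function(i) {
    E_i <- state$f[i] - y[i]
    r_i <- E_i * y[i]
    a_i <- state$alpha[i]
    if (!((r_i < -tol && a_i < cost - eps) || (r_i > tol && a_i > eps))) {
      return(FALSE)
    }
    nb <- which(state$alpha > eps & state$alpha < cost - eps)
    if (length(nb) > 1) {
      E_nb <- state$f[nb] - y[nb]
      j <- nb[which.max(abs(E_i - E_nb))]
      if (take_step(i, j)) return(TRUE)
    }
    if (length(nb)) {
      for (j in sample(nb, length(nb))) if (take_step(i, j)) return(TRUE)
    }
    for (j in sample(n, n)) if (take_step(i, j)) return(TRUE)
    FALSE
  }

  # reset the bias to the midpoint of the feasible KKT interval implied by
  # the box status of each point (the running SMO estimate can drift
  # outside it when every alpha ends at a bound, masking true violators)
  recompute_bias <- function() {
    alpha <- state$alpha
    g <- state$f - state$b
    unbound <- alpha > 1e-8 & alpha < cost - 1e-8
    if (any(unbound)) {
      b <- mean(y[unbound] - g[unbound])
    } else {
      lo <- suppressWarnings(max(
        ifelse(y > 0 & alpha < cost - 1e-8, 1 - g, -Inf),
        ifelse(y < 0 & alpha > 1e-8, -1 - g, -Inf)))
      hi <- suppressWarnings(min(
        ifelse(y > 0 & alpha > 1e-8, 1 - g, Inf),
        ifelse(y < 0 & alpha < cost - 1e-8, -1 - g, Inf)))
      b <- if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2
           else if (is.finite(lo)) lo
           else if (is.finite(hi)) hi
           else state$b
    }
    state$f <- g + b
    state$b <- b
  }

  kkt_violations <- function() {
    alpha <- state$alpha
    pmax(
      ifelse(alpha < cost - 1e-8, pmax(1 - y * state$f, 0), 0),
      ifelse(alpha > 1e-8, pmax(y * state$f - 1, 0), 0)
    )
  }

  withr::with_seed(seed, {
    passes <- 0L
    repeat {
      examine_all <- TRUE
      repeat {
        num_changed <- 0L
        idx <- if (examine_all) seq_len(n) else
          which(state$alpha > eps & state$alpha < cost - eps)
        for (i in idx) num_changed <- num_changed + examine(i)
        passes <- passes + 1L
        if (examine_all) {
          if (num_changed == 0L || passes >= max_passes) break
          examine_all <- FALSE
        } else if (num_changed == 0L) {
          examine_all <- TRUE
        }
        if (passes >= max_passes) break
      }
      # re-center the bias and re-enter if genuine violators surface
      recompute_bias()
      if (max(kkt_violations()) <= tol || passes >= max_passes) break
    }
  })

  alpha <- state$alpha
  f_raw <- state$f
  kkt <- kkt_violations()
  sv <- which(alpha > 1e-8)
  structure(list(
    support_vectors = x[sv, , drop = FALSE],
    coefficients = (alpha * y)[sv],
    bias = state$b,
    kernel = kernel,
    cost = cost,
    alpha = alpha,
    y = y,
    n_features = ncol(x),
    diagnostics = list(
      updates = state$updates,
      objective_trace = state$obj_trace,
      max_kkt_violation = max(kkt),
      xi = pmax(0, 1 - y * f_raw),
      dual_objective = svm_dual_objective(alpha, y, K)
    )
  ), class = "svm_model")
}

#' SVM decision values and predictions
#'
#' `decision_value` returns `f(x) = sum_sv beta_i y_i K(x_i, x) + b`;
#' `predict` returns its sign as a +1/-1 label, with `sign(0)` mapped to
#' +1 (documented tie rule).
#'
#' @param model a trained `svm_model`.
#' @param x numeric matrix (or single vector) of query points.
#' @return Numeric vector of decision values / integer labels.
#' @export
decision_value <- function(model, x) {
  stopifnot(inherits(model, "svm_model"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$n_features) {
    abort(sprintf("query dimension %d does not match model dimension %d",
                  ncol(x), model$n_features),
          class = "gaitsym_dimension_error")
  }
  if (nrow(model$support_vectors) == 0) {
    return(rep(model$bias, nrow(x)))
  }
  Kq <- kernel_matrix(model$kernel, x, model$support_vectors)
  drop(Kq %*% model$coefficients) + model$bias
}

#' @param object a trained `svm_model`.
#' @param ... unused.
#' @rdname decision_value
#' @export
predict.svm_model <- function(object, x, ...) {
  ifelse(decision_value(object, x) >= 0, 1L, -1L)
}

#' Feature standardization (z-score), fitted on training data only
#'
#' RBF and polynomial kernels are scale-sensitive; by default the
#' classification pipeline z-scores every feature using constants fitted
#' on the training folds. Zero-variance features are passed through
#' unscaled.
#'
#' @param x training feature matrix.
#' @return A list of class `standardizer` with `center` and `scale`.
#' @export
fit_standardizer <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  s <- apply(x, 2, sd)
  s[s == 0 | !is.finite(s)] <- 1
  structure(list(center = colMeans(x), scale = s), class = "standardizer")
}

#' @param std a fitted `standardizer`.
#' @rdname fit_standardizer
#' @export
apply_standardizer <- function(std, x) {
  stopifnot(inherits(std, "standardizer"))
  if (!is.matrix(x)) x <- as.matrix(x)
  sweep(sweep(x, 2, std$center), 2, std$scale, `/`)
}

#' Serialize / restore an SVM model as versioned JSON
#'
#' @param model a trained `svm_model`.
#' @param path JSON file path.
#' @return `save_svm` returns `path` invisibly; `load_svm` an `svm_model`.
#' @export
save_svm <- function(model, path) {
  stopifnot(inherits(model, "svm_model"))
  payload <- list(
    format = "gaitsym-svm", version = 1L,
    kernel = unclass(model$kernel),
    cost = model$cost,
    bias = model$bias,
    n_features = model$n_features,
    support_vectors = model$support_vectors,
    coefficients = model$coefficients
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_svm
#' @export
load_svm <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "gaitsym-svm")) {
    abort(paste0("not a gaitsym SVM model file: ", path),
          class = "gaitsym_format_error")
  }
  kernel <- structure(p$kernel, class = "kernel_spec")
  structure(list(
    support_vectors = matrix(p$support_vectors,
                             ncol = p$n_features),
    coefficients = p$coefficients,
    bias = p$bias,
    kernel = kernel,
    cost = p$cost,
    alpha = NULL, y = NULL,
    n_features = p$n_features,
    diagnostics = NULL
  ), class = "svm_model")
}
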