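# Shared fixtures and independent oracles, built in code at test time.

# Independent dense-QP oracle for the SVM dual: interior-point solve of
#   min -1'a + 1/2 a' (yy' o K) a   s.t.  y'a = 0,  0 <= a <= C
# via kernlab::ipop. Returns the maximized dual objective.
qp_oracle_dual <- function(K, y, cost) {
  n <- length(y)
  H <- (y %o% y) * K
  obj <- function(a) sum(a) - 0.5 * drop(crossprod(a, H %*% a))

  # candidate 1: kernlab's interior-point solver (tiny ridge + equality
  # slack keep its factorization well-posed)
  ipop_solve <- function() {
    sol <- kernlab::ipop(
      c = rep(-1, n), H = H + diag(1e-9, n),
      A = matrix(y, nrow = 1), b = -5e-7, r = 1e-6,
      l = rep(0, n), u = rep(cost, n),
      sigf = 8, maxiter = 100
    )
    kernlab::primal(sol)
  }
  a_ipop <- tryCatch(ipop_solve(), error = function(e) NULL)

  # validate: in-box, on the equality constraint, and first-order optimal
  # (projected gradient vanishes); silently diverged solves are rejected
  valid <- function(a) {
    if (is.null(a) || !all(is.finite(a))) return(FALSE)
    if (any(a < -1e-6) || any(a > cost + 1e-6)) return(FALSE)
    if (abs(sum(a * y)) > 1e-5 * max(1, cost)) return(FALSE)
    g <- 1 - H %*% a                       # dual gradient
    th <- (y * g)[a > 1e-6 & a < cost - 1e-6]
    th_ref <- if (length(th)) mean(th) else 0
    grad_shift <- g - th_ref * y           # reduced gradient
    up <- a < cost - 1e-6                  # may still increase
    dn <- a > 1e-6                         # may still decrease
    max(c(grad_shift[up], -grad_shift[dn], 0)) < 1e-5 * max(1, cost)
  }
  if (valid(a_ipop)) return(obj(a_ipop))

  # candidate 2: brute-force projected gradient ascent with exact
  # projection onto {0 <= a <= C, y'a = 0} (bisection on the multiplier)
  project <- function(v) {
    gfun <- function(th) sum(y * pmin(pmax(v - th * y, 0), cost))
    lo <- -(max(abs(v)) + cost + 1); hi <- -lo
    for (k in 1:80) {
      mid <- (lo + hi) / 2
      if (gfun(mid) > 0) lo <- mid else hi <- mid
    }
    pmin(pmax(v - (lo + hi) / 2 * y, 0), cost)
  }
  L <- max(abs(eigen(H, symmetric = TRUE, only.values = TRUE)$values)) + 1e-9
  a <- project(rep(min(cost / 2, 0.5), n))
  for (it in seq_len(50000)) {
    a_new <- project(a + (1 - H %*% a) / L)
    if (max(abs(a_new - a)) < 1e-12) { a <- a_new; break }
    a <- a_new
  }
  obj(a)
}

# maximal KKT violation of a trained model on its training set
max_kkt_violation <- function(model, x, y) {
  f <- decision_value(model, x)
  a <- model$alpha
  cost <- model$cost
  viol_lo <- ifelse(a < cost - 1e-8, pmax(1 - y * f, 0), 0) # should have yf >= 1
  viol_hi <- ifelse(a > 1e-8, pmax(y * f - 1, 0), 0)        # should have yf <= 1
  max(pmax(viol_lo, viol_hi))
}

# random small 2-class training set; guarantees both classes present
random_training_set <- function(n, d, seed) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * d), n, d)
    y <- c(1, -1, sample(c(-1, 1), n - 2, replace = TRUE))
    # mild class separation so problems vary between easy and hard
    x[y == 1, 1] <- x[y == 1, 1] + runif(1, 0, 2)
    list(x = x, y = y)
  })
}

# build a gait_patterns tibble directly from a list of length-101 curves
patterns_from_curves <- function(curves, sides, subjects = NULL,
                                 trials = NULL) {
  n <- length(curves)
  if (is.null(subjects)) subjects <- sprintf("S%02d", seq_len(n))
  if (is.null(trials)) trials <- rep("T01", n)
  vals <- do.call(rbind, curves)
  colnames(vals) <- sprintf("v%03d", 0:100)
  out <- dplyr::bind_cols(
    tibble::tibble(
      subject_id = subjects,
      side = factor(sides, levels = c("left", "right")),
      trial_id = trials,
      label = ifelse(sides == "right", 1L, -1L)
    ),
    tibble::as_tibble(vals)
  )
  class(out) <- unique(c("gait_patterns", class(out)))
  out
}

# a noiseless synthetic stance curve sampled at the 101 grid points
nominal_curve <- function(fz1 = 114, tz1 = 23, fz2 = 75, tz2 = 49,
                          fz3 = 110, tz3 = 77) {
  grf_curve(curve_params(fz1, tz1, fz2, tz2, fz3, tz3), 0:100)
}

# small paired cohort of patterns: one left + one right curve per subject,
# right side scaled by (1 + delta) on the chosen parameters
toy_pattern_cohort <- function(n_subjects, delta = c(fz1 = 0), sd_pct = 5,
                               seed = 1) {
  base <- c(fz1 = 114, tz1 = 23, fz2 = 75, tz2 = 49, fz3 = 110, tz3 = 77)
  d <- stats::setNames(rep(0, 6), names(base))
  d[names(delta)] <- delta
  withr::with_seed(seed, {
    curves <- list(); sides <- character(); subjects <- character()
    for (i in seq_len(n_subjects)) {
      p <- base * (1 + rnorm(6, 0, sd_pct / 100))
      p["tz2"] <- max(p["tz2"], p["tz1"] + 3)
      p["tz3"] <- max(p["tz3"], p["tz2"] + 3)
      p["fz2"] <- min(p["fz2"], 0.9 * min(p["fz1"], p["fz3"]))
      pr <- p * (1 + d)
      curves <- c(curves,
                  list(nominal_curve(p["fz1"], p["tz1"], p["fz2"], p["tz2"],
                                     p["fz3"], p["tz3"]),
                       nominal_curve(pr["fz1"], pr["tz1"], pr["fz2"],
                                     pr["tz2"], pr["fz3"], pr["tz3"])))
      sides <- c(sides, "left", "right")
      subjects <- c(subjects, rep(sprintf("S%02d", i), 2))
    }
    patterns_from_curves(curves, sides, subjects)
  })
}
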