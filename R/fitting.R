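#' Coefficient of determination on the linear response scale
#'
#' `1 - SSres/SStot` with `SStot` taken about the mean of the observations.
#' Can be negative when the model does worse than the mean; is 1 for a
#' perfect fit.
#'
#' @param observed,predicted Numeric vectors of equal length (at least 2).
#' @return A single number, at most 1.
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))   # 0.5
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("r_squared(): `observed` and `predicted` must have the same length",
         call. = FALSE)
  }
  if (length(observed) < 2) {
    stop("r_squared(): need at least two observations", call. = FALSE)
  }
  sstot <- sum((observed - mean(observed))^2)
  if (sstot == 0) {
    stop("r_squared(): observations are all equal; r-squared is undefined",
         call. = FALSE)
  }
  1 - sum((observed - predicted)^2) / sstot
}

#' Fit the gated power law to (monocular, combined) observations
#'
#' Nonlinear least squares for \eqn{C = a M^n} on the linear response scale,
#' initialized from ordinary least squares on the log-log transformed data
#' and refined by Levenberg-Marquardt. Standard errors are the asymptotic
#' (Jacobian-based) ones from the parameter covariance.
#'
#' @param mono Driving-channel responses, positive, length >= 3.
#' @param combined Observed combined responses, positive, same length.
#' @return An object of class `power_law_fit`: a list with elements `a`,
#'   `n`, `se_a`, `se_n`, `r2`, `n_obs` and `fitted`.
#' @examples
#' mono <- seq(5, 200, length.out = 20)
#' fit <- fit_power_law(mono, 2.2 * mono^0.84)
#' fit$a; fit$n; fit$r2
#' @export
fit_power_law <- function(mono, combined) {
  check_positive(mono, "mono")
  check_positive(combined, "combined")
  if (length(mono) != length(combined)) {
    stop("fit_power_law(): `mono` and `combined` must have the same length",
         call. = FALSE)
  }
  if (length(mono) < 3) {
    stop("fit_power_law(): need at least 3 observations", call. = FALSE)
  }
  if (diff(range(mono)) == 0) {
    stop("fit_power_law(): all `mono` values are equal; fit is singular",
         call. = FALSE)
  }
  ols <- stats::lm(log(combined) ~ log(mono))
  start <- list(a = exp(unname(stats::coef(ols)[1])),
                n = unname(stats::coef(ols)[2]))
  dat <- data.frame(mono = mono, combined = combined)
  fit <- minpack.lm::nlsLM(
    combined ~ a * mono^n, data = dat, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14)
  )
  est <- summary(fit)$coefficients
  fitted_vals <- as.numeric(stats::fitted(fit))
  structure(
    list(a = est["a", "Estimate"], n = est["n", "Estimate"],
         se_a = est["a", "Std. Error"], se_n = est["n", "Std. Error"],
         r2 = r_squared(combined, fitted_vals),
         n_obs = length(mono), fitted = fitted_vals),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit (n_obs = %d)\n", x$n_obs))
  cat(sprintf("  a = %.4g +/- %.3g\n  n = %.4g +/- %.3g\n  r2 = %.4f\n",
              x$a, x$se_a, x$n, x$se_n, x$r2))
  invisible(x)
}

#' Fit a single Minkowski exponent to (best, worst, combined) triples
#'
#' Least squares on the linear response scale for
#' \eqn{C = (B^m + W^m)^{1/m}} with one shared exponent across all
#' observations. The start value is chosen by a coarse log-spaced grid
#' search over `m` in [0.05, 50] and refined by Levenberg-Marquardt within
#' [1e-3, 500].
#'
#' @param best Better-channel responses, positive.
#' @param worst Worse-channel responses, non-negative.
#' @param combined Observed combined responses, positive.
#' @return An object of class `minkowski_fit`: a list with elements `m`,
#'   `se_m`, `r2`, `n_obs` and `fitted`.
#' @examples
#' b <- seq(10, 100, length.out = 12); w <- 0.7 * b
#' fit <- fit_minkowski_global(b, w, minkowski_combine(b, w, 2))
#' fit$m
#' @export
fit_minkowski_global <- function(best, worst, combined) {
  check_positive(best, "best")
  check_nonnegative(worst, "worst")
  check_positive(combined, "combined")
  n <- length(best)
  if (length(worst) != n || length(combined) != n) {
    stop("fit_minkowski_global(): inputs must have the same length",
         call. = FALSE)
  }
  if (n < 2) {
    stop("fit_minkowski_global(): need at least 2 observations", call. = FALSE)
  }
  hi <- pmax(best, worst)
  if (!any(combined > hi)) {
    stop(paste0("fit_minkowski_global(): no observation shows combined > best;",
                " the Minkowski exponent has no finite optimum"),
         call. = FALSE)
  }
  grid <- exp(seq(log(0.05), log(50), length.out = 60))
  ss <- vapply(grid, function(m) {
    sum((combined - minkowski_combine(best, worst, m))^2)
  }, numeric(1))
  start <- list(m = grid[which.min(ss)])
  dat <- data.frame(best = best, worst = worst, combined = combined)
  fit <- minpack.lm::nlsLM(
    combined ~ minkowski_combine(best, worst, m), data = dat, start = start,
    lower = 1e-3, upper = 500,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14)
  )
  est <- summary(fit)$coefficients
  fitted_vals <- as.numeric(stats::fitted(fit))
  structure(
    list(m = est["m", "Estimate"], se_m = est["m", "Std. Error"],
         r2 = r_squared(combined, fitted_vals),
         n_obs = n, fitted = fitted_vals),
    class = "minkowski_fit"
  )
}

#' @export
print.minkowski_fit <- function(x, ...) {
  cat(sprintf("Minkowski fit (n_obs = %d)\n  m = %.4g +/- %.3g\n  r2 = %.4f\n",
              x$n_obs, x$m, x$se_m, x$r2))
  invisible(x)
}

#' Per-observation Minkowski exponent by bracketed root finding
#'
#' Solves \eqn{C - (B^m + W^m)^{1/m} = 0} for `m` with a bracketed
#' bisection/secant/inverse-quadratic hybrid (zeroin, via [stats::uniroot()]).
#' The combined response predicted by the Minkowski rule decreases
#' monotonically in `m` from unbounded values (as `m` approaches 0) down to
#' `max(best, worst)` (the MAX limit), so the root is unique whenever it
#' exists.
#'
#' A triple has no valid exponent unless the combined response exceeds both
#' monocular responses; such triples return `status = "no_solution"` rather
#' than an error. Roots are sought in [0.05, 50]; if the bracket fails it is
#' widened to [1e-3, 500], and solutions found only in the widened bracket
#' (or not at all, as happens when the combined response barely exceeds the
#' better channel, or when the worse channel is zero) are flagged
#' `status = "extreme"`.
#'
#' @param best,worst,combined Positive response magnitudes; vectors are
#'   recycled to a common length. `best`/`worst` are ordered internally.
#' @param tol Absolute residual tolerance certifying a root (default 1e-10).
#' @return A tibble with one row per triple: `m` (NA when no finite root),
#'   `status` in `"ok"`, `"no_solution"`, `"extreme"`, and `residual`.
#' @examples
#' solve_minkowski_exponent(4, 3, 5)       # m = 2
#' solve_minkowski_exponent(1, 1, 2)       # m = 1 (additive)
#' solve_minkowski_exponent(10, 8, 9.5)    # no_solution: combined below best
#' @export
solve_minkowski_exponent <- function(best, worst, combined, tol = 1e-10) {
  check_positive(best, "best")
  check_positive(worst, "worst")
  check_positive(combined, "combined")
  n <- max(length(best), length(worst), length(combined))
  best <- rep_len(best, n)
  worst <- rep_len(worst, n)
  combined <- rep_len(combined, n)
  hi <- pmax(best, worst)
  lo <- pmin(best, worst)

  one <- function(b, w, cmb) {
    if (cmb <= b) {
      return(list(m = NA_real_, status = "no_solution", residual = NA_real_))
    }
    f <- function(m) cmb - minkowski_combine(b, w, m)
    solve_in <- function(loB, hiB) {
      flo <- f(loB); fhi <- f(hiB)
      if (is.na(flo) || is.na(fhi) || flo * fhi > 0) return(NULL)
      r <- stats::uniroot(f, c(loB, hiB), tol = 1e-12, maxiter = 1000)
      list(m = r$root, residual = f(r$root))
    }
    r <- solve_in(0.05, 50)
    if (!is.null(r) && abs(r$residual) < tol) {
      return(list(m = r$m, status = "ok", residual = r$residual))
    }
    r <- solve_in(1e-3, 500)
    if (!is.null(r) && abs(r$residual) < tol) {
      return(list(m = r$m, status = "extreme", residual = r$residual))
    }
    list(m = NA_real_, status = "extreme", residual = NA_real_)
  }

  res <- lapply(seq_len(n), function(i) one(hi[i], lo[i], combined[i]))
  tibble::tibble(
    m = vapply(res, `[[`, numeric(1), "m"),
    status = vapply(res, `[[`, character(1), "status"),
    residual = vapply(res, `[[`, numeric(1), "residual")
  )
}
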