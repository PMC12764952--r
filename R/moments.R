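#' Population summary statistics for mean estimation with an auxiliary variable
#'
#' Bundles the finite-population quantities every first-order formula in the
#' package consumes: size N, means, variances and covariance (N-1 divisor),
#' coefficients of variation, the relative covariance
#' \eqn{C_{yx} = S_{yx}/(\mu_y \mu_x) = \rho C_y C_x}, the correlation, and the
#' auxiliary median (used by the shifted-log estimator T8).
#'
#' Fields that are unknown may be left `NA`; derivable fields are completed
#' from the ones supplied (e.g. `rho` from `S_yx` and the variances, `C_y`
#' from `S2_y` and `mu_y`, `C_yx` from `rho*C_y*C_x`).
#'
#' @param N Population size (integer, >= 2), or `NA`.
#' @param mu_y,mu_x Population means of study and auxiliary variable.
#' @param S2_y,S2_x Population variances (N-1 divisor).
#' @param S_yx Population covariance (N-1 divisor).
#' @param C_y,C_x Coefficients of variation (S/mean).
#' @param C_yx Relative covariance \eqn{S_{yx}/(\mu_y\mu_x)}.
#' @param rho Correlation between y and x.
#' @param median_x Population median of x.
#' @return An object of class `population_summary` (a named list).
#' @seealso [summarize_population()], [consistency_check()]
#' @export
population_summary <- function(N = NA, mu_y = NA, mu_x = NA,
                               S2_y = NA, S2_x = NA, S_yx = NA,
                               C_y = NA, C_x = NA, C_yx = NA,
                               rho = NA, median_x = NA) {
  ps <- list(N = N, mu_y = mu_y, mu_x = mu_x, S2_y = S2_y, S2_x = S2_x,
             S_yx = S_yx, C_y = C_y, C_x = C_x, C_yx = C_yx, rho = rho,
             median_x = median_x)
  ps <- lapply(ps, as.numeric)
  # complete derivable fields without overwriting supplied ones
  if (is.na(ps$C_y) && !is.na(ps$S2_y) && !is.na(ps$mu_y) && ps$mu_y != 0)
    ps$C_y <- sqrt(ps$S2_y) / ps$mu_y
  if (is.na(ps$C_x) && !is.na(ps$S2_x) && !is.na(ps$mu_x) && ps$mu_x != 0)
    ps$C_x <- sqrt(ps$S2_x) / ps$mu_x
  if (is.na(ps$rho) && !is.na(ps$S_yx) && !is.na(ps$S2_y) && !is.na(ps$S2_x) &&
      ps$S2_y > 0 && ps$S2_x > 0)
    ps$rho <- ps$S_yx / sqrt(ps$S2_y * ps$S2_x)
  if (is.na(ps$S_yx) && !is.na(ps$rho) && !is.na(ps$S2_y) && !is.na(ps$S2_x))
    ps$S_yx <- ps$rho * sqrt(ps$S2_y * ps$S2_x)
  if (is.na(ps$C_yx)) {
    if (!is.na(ps$S_yx) && !is.na(ps$mu_y) && !is.na(ps$mu_x) &&
        ps$mu_y != 0 && ps$mu_x != 0) {
      ps$C_yx <- ps$S_yx / (ps$mu_y * ps$mu_x)
    } else if (!is.na(ps$rho) && !is.na(ps$C_y) && !is.na(ps$C_x)) {
      ps$C_yx <- ps$rho * ps$C_y * ps$C_x
    }
  }
  if (!is.na(ps$N) && ps$N < 2) stop("population size N must be >= 2")
  structure(ps, class = "population_summary")
}

#' @export
print.population_summary <- function(x, digits = 6, ...) {
  cat("Finite-population summary\n")
  v <- unlist(x)
  cat(paste0("  ", format(names(v), width = 8), " ",
             format(signif(v, digits))), sep = "\n")
  invisible(x)
}

#' Summarize a finite population
#'
#' Computes the full [population_summary()] from the paired population vectors.
#' Variances and the covariance use the N-1 divisor. When either variance is
#' zero the correlation is undefined and returned as `NA` (flagged, not an
#' error, so degenerate populations can still flow through the estimators that
#' do not need \eqn{\rho}).
#'
#' @param y Study-variable values for all N units.
#' @param x Auxiliary-variable values for all N units.
#' @return A `population_summary`.
#' @examples
#' summarize_population(c(2, 4, 6), c(1, 2, 3))
#' @export
summarize_population <- function(y, x) {
  if (length(y) != length(x)) stop("y and x must have equal length")
  if (length(y) < 2) stop("need at least 2 population units")
  if (anyNA(y) || anyNA(x)) stop("missing values in population vectors")
  N <- length(y)
  mu_y <- mean(y); mu_x <- mean(x)
  S2_y <- var(y); S2_x <- var(x)
  S_yx <- cov(y, x)
  rho <- if (S2_y > 0 && S2_x > 0) S_yx / sqrt(S2_y * S2_x) else NA_real_
  C_y <- if (mu_y != 0) sqrt(S2_y) / mu_y else NA_real_
  C_x <- if (mu_x != 0) sqrt(S2_x) / mu_x else NA_real_
  C_yx <- if (mu_y != 0 && mu_x != 0) S_yx / (mu_y * mu_x) else NA_real_
  population_summary(N = N, mu_y = mu_y, mu_x = mu_x, S2_y = S2_y,
                     S2_x = S2_x, S_yx = S_yx, C_y = C_y, C_x = C_x,
                     C_yx = C_yx, rho = rho, median_x = median(x))
}

#' SRSWOR design constants
#'
#' The sampling fraction \eqn{f = n/N} and the finite-population-correction
#' variance factor \eqn{\lambda = (1-f)/n = (N-n)/(Nn)} that scales every
#' first-order variance and MSE under SRSWOR. \eqn{\lambda = 0} iff the sample
#' is a census.
#'
#' @param n Sample size (2 <= n <= N).
#' @param N Population size.
#' @return An object of class `design_spec`: list with `n`, `N`, `f`, `lam`.
#' @examples
#' design_constants(12, 111)$lam   # 99/1332
#' @export
design_constants <- function(n, N) {
  n <- as.integer(n); N <- as.integer(N)
  if (length(n) != 1 || length(N) != 1 || is.na(n) || is.na(N))
    stop("n and N must be single integers")
  if (n < 2) stop("sample size n must be >= 2")
  if (n > N) stop("sample size n cannot exceed population size N")
  structure(list(n = n, N = N, f = n / N, lam = (N - n) / (N * n)),
            class = "design_spec")
}

#' Sample moments from paired SRSWOR data
#'
#' Means and n-1-divisor second moments of the drawn sample, including the
#' plug-in regression slope \eqn{\hat\varphi_1 = s_{yx}/s_x^2} used by the
#' difference-type regression estimator.
#'
#' @param y,x Paired sample values.
#' @return An object of class `sample_moments`: list with `n`, `ybar`, `xbar`,
#'   `s2_y`, `s2_x`, `s_yx`.
#' @export
summarize_sample <- function(y, x) {
  if (length(y) != length(x)) stop("y and x must have equal length")
  if (length(y) < 2) stop("need a sample of size >= 2")
  if (anyNA(y) || anyNA(x)) stop("missing values in sample")
  structure(list(n = length(y), ybar = mean(y), xbar = mean(x),
                 s2_y = var(y), s2_x = var(x), s_yx = cov(y, x)),
            class = "sample_moments")
}

#' Check internal consistency of a population summary
#'
#' Published summary tables are internally redundant: the relative covariance
#' must equal \eqn{\rho C_y C_x}, the covariance is bounded by the
#' Cauchy-Schwarz inequality, and \eqn{\rho} must reproduce
#' \eqn{S_{yx}/\sqrt{S_y^2 S_x^2}}. This reports every violated invariant with
#' its magnitude; an empty report means the summary is consistent at the given
#' tolerance. Checks involving `NA` fields are skipped.
#'
#' @param summary A [population_summary()].
#' @param tol Absolute tolerance for each check.
#' @return A data.frame with columns `invariant` and `magnitude` (empty when
#'   all checks pass).
#' @examples
#' ps <- population_summary(rho = 0.99, C_y = 0.621743, C_x = 0.7019,
#'                          C_yx = 0.4320)
#' consistency_check(ps, tol = 5e-5)   # 0 rows
#' @export
consistency_check <- function(summary, tol = 1e-8) {
  stopifnot(inherits(summary, "population_summary"))
  s <- summary
  bad <- list()
  add <- function(name, mag) bad[[length(bad) + 1]] <<- data.frame(
    invariant = name, magnitude = mag, stringsAsFactors = FALSE)
  if (!is.na(s$N) && s$N < 2) add("N >= 2", 2 - s$N)
  if (!is.na(s$S_yx) && !is.na(s$S2_y) && !is.na(s$S2_x)) {
    excess <- s$S_yx^2 - s$S2_y * s$S2_x
    if (excess > tol * max(1, s$S2_y * s$S2_x))
      add("S_yx^2 <= S2_y*S2_x", excess)
  }
  if (!is.na(s$rho) && !is.na(s$S_yx) && !is.na(s$S2_y) && !is.na(s$S2_x) &&
      s$S2_y > 0 && s$S2_x > 0) {
    d <- abs(s$rho - s$S_yx / sqrt(s$S2_y * s$S2_x))
    if (d > tol) add("rho = S_yx/sqrt(S2_y*S2_x)", d)
  }
  if (!is.na(s$rho) && (s$rho < -1 - tol || s$rho > 1 + tol))
    add("rho in [-1, 1]", abs(s$rho) - 1)
  if (!is.na(s$C_yx) && !is.na(s$rho) && !is.na(s$C_y) && !is.na(s$C_x)) {
    d <- abs(s$C_yx - s$rho * s$C_y * s$C_x)
    if (d > tol) add("C_yx = rho*C_y*C_x", d)
  }
  if (!is.na(s$C_y) && !is.na(s$S2_y) && !is.na(s$mu_y) && s$mu_y != 0) {
    d <- abs(s$C_y - sqrt(s$S2_y) / s$mu_y)
    if (d > tol) add("C_y = S_y/mu_y", d)
  }
  if (!is.na(s$C_x) && !is.na(s$S2_x) && !is.na(s$mu_x) && s$mu_x != 0) {
    d <- abs(s$C_x - sqrt(s$S2_x) / s$mu_x)
    if (d > tol) add("C_x = S_x/mu_x", d)
  }
  if (length(bad) == 0) {
    data.frame(invariant = character(0), magnitude = numeric(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, bad)
  }
}
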