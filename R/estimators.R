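#' Names of the supported mean estimators
#'
#' `T0` sample mean; `T1` ratio; `T2` product; `T3` exponential ratio;
#' `T4` difference-type regression; `T5` log-auxiliary ratio; `T6`, `T7`
#' additive log-auxiliary forms; `T8` shifted-log form in x only; `TP1`, `TP2`
#' the two logarithmic ratio-type estimators with Searls-type constants.
#'
#' @return Character vector of estimator names.
#' @export
estimator_names <- function() {
  c("T0", "T1", "T2", "T3", "T4", "T5", "T6", "T7", "T8", "TP1", "TP2")
}

#' Free constants required by an estimator
#'
#' @param name Estimator name.
#' @return Character vector of constant names (empty for estimators without
#'   free constants).
#' @export
required_constants <- function(name) {
  switch(match.arg(name, estimator_names()),
         T6 = "alpha", T7 = c("w1", "w2"), T8 = c("K1", "K2"),
         TP1 = c("k1", "k2"), TP2 = c("k3", "k4"),
         character(0))
}

#' Log-ratio adjustment factor of the first proposed estimator
#'
#' The scalar factor \eqn{g(\bar x) = \mu_x \log(\bar x/\mu_x)/(\bar x - \mu_x)},
#' continuously extended to 1 at \eqn{\bar x = \mu_x} (the limit of
#' \eqn{\log(1+e_1)/e_1}). Near the removable singularity the truncated series
#' \eqn{1 - d/2 + d^2/3 - d^3/4} in \eqn{d = (\bar x - \mu_x)/\mu_x} is used,
#' which is exact to well below machine precision for |d| < 1e-4.
#'
#' @param xbar Sample auxiliary mean(s), > 0. Vectorized.
#' @param mu_x Known population auxiliary mean, > 0.
#' @return Numeric vector of factors, each in (0, Inf).
#' @examples
#' tp1_adjustment(exp(1), 1)   # 1/(e - 1)
#' tp1_adjustment(50, 50)      # exactly 1
#' @export
tp1_adjustment <- function(xbar, mu_x) {
  if (any(!is.finite(xbar)) || any(xbar <= 0)) stop("xbar must be positive")
  if (!is.finite(mu_x) || mu_x <= 0) stop("mu_x must be positive")
  d <- xbar / mu_x - 1
  out <- numeric(length(d))
  small <- abs(d) < 1e-4
  out[small] <- 1 - d[small] / 2 + d[small]^2 / 3 - d[small]^3 / 4
  out[!small] <- log1p(d[!small]) / d[!small]
  out
}

#' Log-ratio adjustment factor of the second proposed estimator
#'
#' \eqn{h(\bar x) = \log(\bar x/\mu_x)\,\exp\{(\bar x-\mu_x)/(\bar x+\mu_x)\}}.
#' Vanishes at \eqn{\bar x = \mu_x} and has the sign of \eqn{\bar x - \mu_x}.
#'
#' @inheritParams tp1_adjustment
#' @return Numeric vector of factors.
#' @export
tp2_adjustment <- function(xbar, mu_x) {
  if (any(!is.finite(xbar)) || any(xbar <= 0)) stop("xbar must be positive")
  if (!is.finite(mu_x) || mu_x <= 0) stop("mu_x must be positive")
  log(xbar / mu_x) * exp((xbar - mu_x) / (xbar + mu_x))
}

# Vectorized estimator formulas shared by estimate() and the Monte-Carlo
# engine. ybar/xbar may be vectors of replicate means; phi1 likewise for T4.
# Returns list(value, degenerate) where degenerate marks replicates whose
# value was defined by the documented continuous extension (TP2 at
# xbar == mu_x returns 0 rather than aborting a replication run).
estimator_value <- function(name, ybar, xbar, mu_x,
                            constants = list(), phi1 = NULL,
                            median_x = NULL, mu_y = NULL,
                            variant = "standard") {
  name <- match.arg(name, estimator_names())
  need <- required_constants(name)
  missing_k <- setdiff(need, names(constants))
  if (length(missing_k))
    stop(sprintf("estimator %s requires constants: %s", name,
                 paste(missing_k, collapse = ", ")))
  deg <- rep(FALSE, length(ybar))
  needs_log_x <- name %in% c("T5", "T6", "T7", "TP1", "TP2")
  if (needs_log_x && any(xbar <= 0))
    stop(sprintf("estimator %s needs xbar > 0 (log form)", name))
  if (name %in% c("T1", "T2", "T3", "TP1", "TP2") && mu_x <= 0)
    stop("mu_x must be positive")
  value <- switch(name,
    T0 = ybar,
    T1 = mu_x * ybar / xbar,
    T2 = ybar * xbar / mu_x,
    T3 = ybar * exp((mu_x - xbar) / (mu_x + xbar)),
    T4 = {
      if (is.null(phi1)) stop("T4 requires the regression slope phi1")
      ybar + phi1 * (mu_x - xbar)
    },
    T5 = {
      if (identical(variant, "paper")) {
        if (is.null(mu_y)) stop("paper-literal T5 requires mu_y")
        if (any(ybar <= 0)) stop("paper-literal T5 needs ybar > 0")
        if (any(log(xbar) == 0)) stop("T5 undefined: log(xbar) = 0")
        mu_y * log(ybar) / log(xbar)
      } else {
        if (mu_x == 1) stop("T5 undefined when mu_x = 1 (log(mu_x) = 0)")
        if (any(log(xbar) == 0)) stop("T5 undefined: log(xbar) = 0")
        ybar * log(mu_x) / log(xbar)
      }
    },
    T6 = ybar + constants$alpha * log(xbar / mu_x),
    T7 = ybar * (constants$w1 + 1) + constants$w2 * log(xbar / mu_x),
    T8 = {
      if (is.null(median_x)) stop("T8 requires the auxiliary median median_x")
      if (any(xbar + median_x <= 0) || mu_x + median_x <= 0)
        stop("T8 needs xbar + median_x > 0")
      lg <- log((mu_x + median_x) / (xbar + median_x))
      constants$K1 * lg - constants$K2 * lg
    },
    TP1 = (constants$k1 * ybar + constants$k2) * tp1_adjustment(xbar, mu_x),
    TP2 = {
      h <- tp2_adjustment(xbar, mu_x)
      deg <- xbar == mu_x
      (constants$k3 * ybar + constants$k4) * h
    })
  list(value = value, degenerate = deg)
}

#' Estimate the population mean with a named estimator
#'
#' Applies one of the supported estimators to a drawn sample's moments, using
#' the known auxiliary population mean \eqn{\mu_x}. The proposed logarithmic
#' ratio-type estimators are
#' \deqn{T_{P1} = (k_1\bar y + k_2)\,\frac{\mu_x}{\bar x-\mu_x}\log(\bar x/\mu_x),
#'       \qquad
#'       T_{P2} = (k_3\bar y + k_4)\log(\bar x/\mu_x)\,
#'                e^{(\bar x-\mu_x)/(\bar x+\mu_x)}.}
#' \eqn{T_{P1}} uses the analytic limit of its factor at \eqn{\bar x=\mu_x};
#' \eqn{T_{P2}} is identically 0 there and returns 0 with a degeneracy note
#' (Monte-Carlo replication must not abort on a measure-zero event).
#'
#' @param name Estimator name, see [estimator_names()].
#' @param sample A [summarize_sample()] result (or a list with at least
#'   `ybar`, `xbar`, and for T4 `s2_x`, `s_yx`).
#' @param mu_x Known population mean of the auxiliary variable.
#' @param constants Named list of free constants
#'   (`k1`,`k2` for TP1; `k3`,`k4` for TP2; `alpha` for T6; `w1`,`w2` for T7;
#'   `K1`,`K2` for T8). For T6 the constant is filled from `summary` (optimal
#'   \eqn{\alpha = -\mu_y \rho C_y/C_x}) when omitted.
#' @param summary Optional [population_summary()]; needed for the theoretical
#'   regression slope, T6's default constant, paper-literal T5, and T8's
#'   auxiliary median.
#' @param variant `"standard"` (default) or `"paper"` where the two printed
#'   forms differ (T5; see Details).
#' @param slope For T4: `"sample"` (default, \eqn{s_{yx}/s_x^2}) or
#'   `"theoretical"` (\eqn{\beta_1 = S_{yx}/S_x^2} from `summary`).
#' @details The published T5 contains the unknown target \eqn{\mu_y}
#'   (\eqn{\mu_y\log\bar y/\log\bar x}); it is available as `variant="paper"`
#'   for diagnostic use only. The default standard variant
#'   \eqn{\bar y\log(\mu_x)/\log(\bar x)} is the unique log-ratio form whose
#'   first-order MSE matches the published closed form with
#'   \eqn{k = 1/\log\mu_x}. T8 is a function of x alone as published; its
#'   constants must come from user input or empirical tuning.
#' @return An object of class `estimate_result`: list with `name`, `value`,
#'   `constants_used`, `notes` (character vector of degeneracy flags).
#' @examples
#' s <- summarize_sample(c(8, 10, 12), c(4, 5, 6))
#' estimate("T1", s, mu_x = 10)
#' @export
estimate <- function(name, sample, mu_x, constants = list(), summary = NULL,
                     variant = c("standard", "paper"),
                     slope = c("sample", "theoretical")) {
  name <- match.arg(name, estimator_names())
  variant <- match.arg(variant)
  slope <- match.arg(slope)
  if (!is.finite(mu_x) || mu_x <= 0) stop("mu_x must be a positive number")
  phi1 <- NULL
  if (name == "T4") {
    phi1 <- if (slope == "theoretical") {
      if (is.null(summary)) stop("theoretical slope requires `summary`")
      summary$S_yx / summary$S2_x
    } else {
      if (sample$s2_x == 0) stop("T4 sample slope undefined: s_x^2 = 0")
      sample$s_yx / sample$s2_x
    }
  }
  if (name == "T6" && is.null(constants$alpha)) {
    if (is.null(summary))
      stop("estimator T6 requires constants: alpha (or a `summary` to derive it)")
    constants$alpha <- -summary$mu_y * summary$rho * summary$C_y / summary$C_x
  }
  median_x <- if (!is.null(summary)) summary$median_x else NULL
  mu_y <- if (!is.null(summary)) summary$mu_y else NULL
  ev <- estimator_value(name, sample$ybar, sample$xbar, mu_x,
                        constants = constants, phi1 = phi1,
                        median_x = median_x, mu_y = mu_y, variant = variant)
  notes <- character(0)
  if (any(ev$degenerate)) notes <- "tp2_degenerate_at_xbar_equal_mu_x"
  used <- constants
  if (name == "T4") used <- list(phi1 = phi1, slope = slope)
  if (name == "T5") used <- list(variant = variant)
  structure(list(name = name, value = ev$value, constants_used = used,
                 notes = notes),
            class = "estimate_result")
}

#' @export
print.estimate_result <- function(x, digits = 6, ...) {
  cat(sprintf("%s = %s", x$name,
              format(signif(x$value, digits))), "\n")
  if (length(x$constants_used))
    cat("  constants:",
        paste(names(x$constants_used),
              vapply(x$constants_used,
                     function(v) if (is.numeric(v)) format(signif(v[1], 4))
                     else as.character(v)[1], ""),
              sep = "=", collapse = ", "), "\n")
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
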