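#' Estimate a finite-population mean from an SRSWOR sample
#'
#' The package's main fitting interface. Given a drawn sample of the study
#' and auxiliary variables and the known auxiliary population mean
#' \eqn{\mu_x}, computes the requested point estimators of \eqn{\mu_y}
#' (classical mean, ratio/product/exponential/regression/log-auxiliary
#' competitors and the two proposed logarithmic ratio-type estimators).
#'
#' Searls-type constants for TP1/TP2 that are not supplied are resolved from
#' the population information available: if `summary` (or `N` plus the data
#' being a census) provides the needed coefficients of variation, TP1 uses
#' the series-derived optimum and TP2 the printed optimum for the design
#' implied by `n` and `N`; otherwise the neutral values
#' \eqn{(k_1,k_2)=(1,0)} and \eqn{(k_3,k_4)=(1,0)} are used and noted.
#'
#' @param formula A two-sided formula `y ~ x` naming the study and auxiliary
#'   columns in `data`.
#' @param data A data.frame containing the sampled units.
#' @param mu_x Known population mean of the auxiliary variable (> 0).
#' @param N Population size (needed for the finite-population correction when
#'   resolving optimal constants and for summaries); may be `NULL`.
#' @param estimators Estimators to compute, see [estimator_names()].
#' @param constants Named list of per-estimator constant lists.
#' @param summary Optional [population_summary()] carrying known population
#'   quantities (used for optimal constants, T6's default alpha, T8's
#'   median).
#' @param variant `"standard"` or `"paper"` for the forms that differ.
#' @param na.action How to handle missing values; rows incomplete in either
#'   variable are dropped pairwise.
#' @return An object of class `lrmean` with components `estimates`
#'   (data.frame), `sample` (a [summarize_sample()]), `mu_x`, `N`, `call`.
#'   Methods: `print`, `summary`, `coef`.
#' @examples
#' d <- data.frame(y = c(8, 10, 12, 9), x = c(4, 5, 6, 4.5))
#' fit <- lrmean(y ~ x, d, mu_x = 5.2, estimators = c("T0", "T1", "T3"))
#' coef(fit)
#' @export
lrmean <- function(formula, data, mu_x, N = NULL,
                   estimators = c("T0", "T1", "T2", "T3", "T4", "T5", "T6",
                                  "TP1", "TP2"),
                   constants = list(), summary = NULL,
                   variant = c("standard", "paper"),
                   na.action = stats::na.omit) {
  variant <- match.arg(variant)
  estimators <- match.arg(estimators, estimator_names(), several.ok = TRUE)
  mf <- stats::model.frame(formula, data, na.action = na.action)
  if (ncol(mf) != 2) stop("formula must be of the form y ~ x")
  y <- mf[[1]]; x <- mf[[2]]
  smp <- summarize_sample(y, x)
  if (!is.null(N)) {
    N <- as.integer(N)
    if (N < smp$n) stop("N cannot be smaller than the sample size")
  }
  design <- if (!is.null(N) && !is.null(summary))
    design_constants(smp$n, N) else NULL
  notes_all <- character(0)
  rows <- lapply(estimators, function(nm) {
    k <- constants[[nm]]
    if (is.null(k) && nm %in% c("TP1", "TP2")) {
      if (!is.null(summary) && !is.null(design)) {
        k <- as.list(optimal_constants_for(nm, summary, design, "series"))
      } else {
        k <- if (nm == "TP1") list(k1 = 1, k2 = 0) else list(k3 = 1, k4 = 0)
        notes_all <<- union(notes_all,
                            sprintf("%s: neutral constants (no population summary)", nm))
      }
    }
    er <- estimate(nm, smp, mu_x, constants = k %||% list(),
                   summary = summary, variant = variant)
    data.frame(estimator = nm, estimate = er$value,
               constants = if (length(er$constants_used))
                 paste(names(er$constants_used),
                       vapply(er$constants_used, format_constant, ""),
                       sep = "=", collapse = ",") else "",
               stringsAsFactors = FALSE)
  })
  structure(list(estimates = do.call(rbind, rows), sample = smp,
                 mu_x = mu_x, N = N, summary = summary, variant = variant,
                 notes = notes_all, call = match.call()),
            class = "lrmean")
}

format_constant <- function(v) {
  if (is.numeric(v)) format(signif(v[1], 4)) else as.character(v)[1]
}

#' @export
print.lrmean <- function(x, digits = 6, ...) {
  cat("Finite-population mean estimation under SRSWOR\n")
  cat(sprintf("  n = %d%s, mu_x = %s, ybar = %s, xbar = %s\n",
              x$sample$n,
              if (!is.null(x$N)) sprintf(", N = %d", x$N) else "",
              format(signif(x$mu_x, digits)),
              format(signif(x$sample$ybar, digits)),
              format(signif(x$sample$xbar, digits))))
  df <- x$estimates
  df$estimate <- signif(df$estimate, digits)
  print(df, row.names = FALSE)
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.lrmean <- function(object, ...) {
  setNames(object$estimates$estimate, object$estimates$estimator)
}

#' @export
summary.lrmean <- function(object, ...) {
  out <- object$estimates
  if (!is.null(object$summary) && !is.null(object$N)) {
    design <- design_constants(object$sample$n, object$N)
    th <- tryCatch(
      mse_table(object$summary, n = object$sample$n,
                estimators = out$estimator, mode = "series",
                design = design),
      error = function(e) NULL)
    if (!is.null(th)) {
      out$mse_series <- th$mse[match(out$estimator, th$estimator)]
      out$pre_series <- th$pre[match(out$estimator, th$estimator)]
    }
  }
  structure(list(estimates = out, sample = object$sample, mu_x = object$mu_x,
                 N = object$N, call = object$call),
            class = "summary.lrmean")
}

#' @export
print.summary.lrmean <- function(x, digits = 6, ...) {
  cat("Finite-population mean estimation under SRSWOR\n")
  cat(sprintf("  n = %d%s, ybar = %s, xbar = %s, mu_x = %s\n",
              x$sample$n,
              if (!is.null(x$N)) sprintf(", N = %d", x$N) else "",
              format(signif(x$sample$ybar, digits)),
              format(signif(x$sample$xbar, digits)),
              format(signif(x$mu_x, digits))))
  df <- x$estimates
  for (cc in intersect(c("estimate", "mse_series", "pre_series"), names(df)))
    df[[cc]] <- signif(df[[cc]], digits)
  print(df, row.names = FALSE)
  invisible(x)
}
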