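#' Specify a Monte-Carlo scenario
#'
#' Describes a synthetic bivariate finite population and the SRSWOR
#' replication experiment run on it. Defaults follow the simulation design the
#' package targets: populations of N = 1000 units with mean vector (40, 50),
#' study-auxiliary correlations chosen from \{0.92, 0.71, 0.38\}, sample sizes
#' \{50, 150, 200\}, and R = 10000 replicates.
#'
#' Marginals per family: `normal` uses `sd_y`, `sd_x` (default 1, the
#' unit-variance covariance structure of the target design); `gamma` uses
#' shapes `shape_y`, `shape_x` (default 4, positively skewed) with scales set
#' from the means; `lognormal` uses log-scale standard deviations `sdlog_y`,
#' `sdlog_x` (default 0.5, heavy-tailed) with `meanlog` set from the means.
#'
#' @param family `"normal"`, `"gamma"` or `"lognormal"`.
#' @param rho_target Target Pearson correlation in (-1, 1).
#' @param N Population size.
#' @param n_list Sample sizes to run.
#' @param R Number of SRSWOR replicates per sample size.
#' @param seed Integer seed; every random draw of the run flows from it.
#' @param mean_y,mean_x Marginal means.
#' @param sd_y,sd_x Normal-family standard deviations.
#' @param shape_y,shape_x Gamma-family shapes.
#' @param sdlog_y,sdlog_x Lognormal-family log-scale sd.
#' @param estimators Estimators to evaluate.
#' @param constants Named list of per-estimator constant lists overriding the
#'   automatic resolution.
#' @param tuning `"theoretical"` (constants computed once from the population
#'   summary; default) or `"estimated"` (recomputed per replicate from sample
#'   moments, for TP1/TP2/T6).
#' @param R_tune Replicates used by the data-driven tuning of T7/T8.
#' @param max_fail Maximum tolerated fraction of failed replicates per
#'   estimator before the run aborts.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(family = c("normal", "gamma", "lognormal"),
                          rho_target = 0.92, N = 1000,
                          n_list = c(50, 150, 200), R = 10000, seed = 1,
                          mean_y = 40, mean_x = 50,
                          sd_y = 1, sd_x = 1,
                          shape_y = 4, shape_x = 4,
                          sdlog_y = 0.5, sdlog_x = 0.5,
                          estimators = estimator_names(),
                          constants = list(),
                          tuning = c("theoretical", "estimated"),
                          R_tune = 1000, max_fail = 0.05) {
  family <- match.arg(family)
  tuning <- match.arg(tuning)
  stopifnot(rho_target > -1, rho_target < 1, N >= 2,
            all(n_list >= 2), max(n_list) <= N, R >= 2)
  estimators <- match.arg(estimators, estimator_names(), several.ok = TRUE)
  structure(list(family = family, rho_target = rho_target, N = as.integer(N),
                 n_list = as.integer(n_list), R = as.integer(R),
                 seed = as.integer(seed), mean_y = mean_y, mean_x = mean_x,
                 sd_y = sd_y, sd_x = sd_x, shape_y = shape_y,
                 shape_x = shape_x, sdlog_y = sdlog_y, sdlog_x = sdlog_x,
                 estimators = estimators, constants = constants,
                 tuning = tuning, R_tune = as.integer(R_tune),
                 max_fail = max_fail),
            class = "scenario_spec")
}

# marginal inverse-CDF transforms, x strictly positive for gamma/lognormal
marginal_quantile <- function(u, family, mean, sd, shape, sdlog) {
  switch(family,
         normal = mean + sd * qnorm(u),
         gamma = qgamma(u, shape = shape, scale = mean / shape),
         lognormal = qlnorm(u, meanlog = log(mean) - sdlog^2 / 2,
                            sdlog = sdlog))
}

#' Generate a correlated bivariate finite population
#'
#' Gaussian-copula (NORTA) construction: a latent standard-normal pair
#' \eqn{(z_1, z_2)} with latent correlation r is transformed through the
#' inverse CDF of the requested marginal family. The latent draw is made once
#' from the stream; r is then root-found so that the *realized* Pearson
#' correlation of the generated population equals `rho_target` (to ~1e-9),
#' making scenarios that differ only in correlation exactly comparable. The
#' normal family passes through the identity case of the same construction,
#' so its marginals are exactly normal.
#'
#' @param spec A [scenario_spec()].
#' @param stream An [rng_stream()].
#' @return An object of class `finite_population`: list with `y`, `x`,
#'   `summary` (a [population_summary()]), `family`, `rho_target`,
#'   `latent_r`.
#' @export
generate_population <- function(spec, stream) {
  stopifnot(inherits(spec, "scenario_spec"))
  N <- spec$N
  z1 <- with_stream(stream, rnorm(N))
  eps <- with_stream(stream, rnorm(N))
  y <- marginal_quantile(pnorm(z1), spec$family, spec$mean_y, spec$sd_y,
                         spec$shape_y, spec$sdlog_y)
  x_of <- function(r) {
    z2 <- r * z1 + sqrt(1 - r^2) * eps
    marginal_quantile(pnorm(z2), spec$family, spec$mean_x, spec$sd_x,
                      spec$shape_x, spec$sdlog_x)
  }
  fr <- function(r) cor(y, x_of(r)) - spec$rho_target
  lo <- -1 + 1e-6; hi <- 1 - 1e-6
  if (fr(lo) > 0 || fr(hi) < 0)
    stop("copula calibration failed: target correlation unreachable")
  r <- uniroot(fr, c(lo, hi), tol = 1e-12)$root
  x <- x_of(r)
  if (abs(cor(y, x) - spec$rho_target) > 0.05)
    stop(sprintf("copula calibration failed: realized rho %.4f vs target %.4f",
                 cor(y, x), spec$rho_target))
  structure(list(y = y, x = x, summary = summarize_population(y, x),
                 family = spec$family, rho_target = spec$rho_target,
                 latent_r = r),
            class = "finite_population")
}

#' @export
print.finite_population <- function(x, ...) {
  cat(sprintf("Finite population: N = %d, family = %s, realized rho = %.4f\n",
              x$summary$N, x$family, x$summary$rho))
  invisible(x)
}

#' Draw one SRSWOR sample
#'
#' @param pop A [generate_population()] result (or any list with `y`, `x`).
#' @param n Sample size, 2 <= n <= N.
#' @param stream An [rng_stream()].
#' @return List with `idx` (distinct unit indices, uniform over all
#'   \eqn{\binom{N}{n}} subsets), `y`, `x`.
#' @export
draw_srswor <- function(pop, n, stream) {
  N <- length(pop$y)
  n <- as.integer(n)
  if (n < 2 || n > N) stop("n must satisfy 2 <= n <= N")
  idx <- with_stream(stream, sample.int(N, n))
  list(idx = idx, y = pop$y[idx], x = pop$x[idx])
}

#' Enumerate all SRSWOR samples
#'
#' Exhaustive oracle for design moments on tiny populations: every size-n
#' subset exactly once, guarded against combinatorial blow-up.
#'
#' @inheritParams draw_srswor
#' @param max_samples Guard on \eqn{\binom{N}{n}}.
#' @return Integer matrix with n rows, one column per subset.
#' @export
enumerate_srswor <- function(pop, n, max_samples = 1e6) {
  N <- length(pop$y)
  if (n < 1 || n > N) stop("n must satisfy 1 <= n <= N")
  if (choose(N, n) > max_samples)
    stop(sprintf("refusing to enumerate choose(%d, %d) = %g samples",
                 N, n, choose(N, n)))
  combn(N, n)
}

#' Summaries of a vector of Monte-Carlo replicate values
#'
#' Mean, Monte-Carlo standard error \eqn{sd/\sqrt R} (R-1 divisor), the
#' normal-approximation 95% interval, and the nonparametric 95% percentile
#' interval (2.5th/97.5th empirical quantiles, inclusive linear-interpolation
#' rule, i.e. R's quantile type 7).
#'
#' @param values Replicate values (length >= 2).
#' @return List with `mean`, `mc_se`, `ci_norm`, `ci_pct`, `R`,
#'   `quantile_rule`.
#' @export
summarize_replicates <- function(values) {
  R <- length(values)
  if (R < 2) stop("need at least 2 replicate values")
  m <- mean(values)
  se <- sd(values) / sqrt(R)
  list(mean = m, mc_se = se,
       ci_norm = c(m - 1.96 * se, m + 1.96 * se),
       ci_pct = unname(quantile(values, c(0.025, 0.975), type = 7,
                                names = FALSE)),
       R = R, quantile_rule = "type7-linear-interpolation")
}

# Vectorized per-replicate estimated-mode constants (plug-in): computes the
# same optimum formula as the theoretical mode but from sample moments.
plugin_constants <- function(name, ybar, xbar, s2y, s2x, syx, mu_x, lam) {
  cy2 <- s2y / ybar^2; cx2 <- s2x / xbar^2; cyx <- syx / (ybar * xbar)
  if (name == "T6") {
    # alpha_opt = -mu_y rho C_y/C_x = -S_yx mu_x/S_x^2, plug-in version
    return(list(alpha = -syx * mu_x / s2x))
  }
  if (name == "TP1") {
    # mechanically derived 2x2 system with plug-in moments (same algebra as
    # series_mse_quadratic for TP1, vectorized over replicates)
    A1 <- 1 + lam * (cy2 + (11 / 12) * cx2 - 2 * cyx)
    B1 <- 1 + (11 / 12) * lam * cx2
    E1 <- 1 + lam * ((11 / 12) * cx2 - cyx)
    C1 <- 1 + lam * ((1 / 3) * cx2 - 0.5 * cyx)
    D1 <- 1 + (1 / 3) * lam * cx2
    det <- A1 * B1 - E1^2
    k1 <- (B1 * C1 - E1 * D1) / det
    k2 <- ybar * (A1 * D1 - E1 * C1) / det
    return(list(k1 = k1, k2 = k2))
  }
  if (name == "TP2") {
    alpha <- lam * cx2; beta <- lam * cy2
    A2 <- (alpha * (1 + beta) + alpha^2) / 64
    B2 <- (alpha + alpha^2) / 64
    E2 <- (alpha + alpha^2) / 32
    C2 <- alpha / 4
    d2 <- A2 * B2 - E2^2
    return(list(k3 = (B2 * C2 - C2 * E2) / d2,
                k4 = C2 * ybar * (A2 + E2) / d2))
  }
  stop(sprintf("no plug-in constants for %s", name))
}

#' Run the SRSWOR Monte-Carlo experiment
#'
#' Generates the scenario's finite population, resolves each estimator's
#' constants, draws R SRSWOR replicates per sample size, and reports the
#' empirical variance/MSE (deviations taken from the true population mean
#' \eqn{\mu_y}), the PRE against the classical mean, and replicate-wise PRE
#' uncertainty (Monte-Carlo SE, normal and percentile 95% intervals).
#'
#' Constants resolution in `"theoretical"` mode: TP1 takes the series-derived
#' optimum, TP2 the printed optimum (its series derivation is degenerate by
#' construction), T6 the optimal \eqn{\alpha = -\mu_y\rho C_y/C_x}, and T7/T8
#' are tuned data-driven via [empirical_tune()]; T4 recomputes its sample
#' slope each replicate. In `"estimated"` mode TP1/TP2/T6 recompute their
#' constants each replicate from sample moments. Explicit entries in
#' `spec$constants` always win.
#'
#' @param spec A [scenario_spec()].
#' @return An object of class `lrmean_sim`: list with `results` (one row per
#'   estimator and sample size), `population`, `constants`, `replicate_pre`
#'   (per-n matrices of replicate PREs), `scenario`, `seed`,
#'   `quantile_rule`.
#' @export
run_monte_carlo <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  stream <- rng_stream(spec$seed)
  pop <- generate_population(spec, stream)
  ps <- pop$summary
  mu_y <- ps$mu_y; mu_x <- ps$mu_x
  res <- list(); rep_pre <- list(); consts_used <- list()
  for (n in spec$n_list) {
    design <- design_constants(n, spec$N)
    # resolve fixed constants for this n
    kn <- list()
    for (nm in spec$estimators) {
      if (!is.null(spec$constants[[nm]])) {
        kn[[nm]] <- spec$constants[[nm]]
      } else if (nm == "T6") {
        kn[[nm]] <- list(alpha = -mu_y * ps$rho * ps$C_y / ps$C_x)
      } else if (nm == "TP1") {
        kn[[nm]] <- as.list(optimal_constants_for("TP1", ps, design, "series"))
      } else if (nm == "TP2") {
        kn[[nm]] <- as.list(optimal_constants_for("TP2", ps, design, "series"))
      } else if (nm %in% c("T7", "T8")) {
        tune <- empirical_tune(nm, pop, n, R_tune = spec$R_tune,
                               stream = child_stream(stream, 7000 + n))
        kn[[nm]] <- tune$constants
      }
    }
    consts_used[[as.character(n)]] <- kn
    # replicate sample moments
    R <- spec$R
    ybar <- xbar <- s2y <- s2x <- syx <- numeric(R)
    for (r in seq_len(R)) {
      smp <- draw_srswor(pop, n, stream)
      ybar[r] <- mean(smp$y); xbar[r] <- mean(smp$x)
      s2y[r] <- var(smp$y); s2x[r] <- var(smp$x); syx[r] <- cov(smp$y, smp$x)
    }
    phi1 <- syx / s2x
    est <- matrix(NA_real_, R, length(spec$estimators),
                  dimnames = list(NULL, spec$estimators))
    flags <- setNames(integer(length(spec$estimators)), spec$estimators)
    for (nm in spec$estimators) {
      kk <- kn[[nm]]
      if (spec$tuning == "estimated" && nm %in% c("TP1", "TP2", "T6") &&
          is.null(spec$constants[[nm]])) {
        kk <- plugin_constants(nm, ybar, xbar, s2y, s2x, syx,
                               mu_x, design$lam)
      }
      ev <- estimator_value(nm, ybar, xbar, mu_x, constants = kk %||% list(),
                            phi1 = phi1, median_x = ps$median_x,
                            mu_y = mu_y)
      est[, nm] <- ev$value
      flags[nm] <- sum(ev$degenerate)
    }
    bad_frac <- colMeans(!is.finite(est))
    if (any(bad_frac > spec$max_fail))
      stop(sprintf("estimator failure rate above %.1f%%: %s",
                   100 * spec$max_fail,
                   paste(names(bad_frac)[bad_frac > spec$max_fail],
                         collapse = ", ")))
    sq <- (est - mu_y)^2
    mse <- colMeans(sq)
    mse_se <- apply(sq, 2, sd) / sqrt(R)
    if (!"T0" %in% spec$estimators)
      stop("the replication experiment needs T0 as PRE reference")
    pre_agg <- 100 * mse["T0"] / mse
    pre_repl <- 100 * (sq[, "T0"] / sq)   # ratio first: T0 vs itself is exact
    rows <- lapply(spec$estimators, function(nm) {
      sm <- summarize_replicates(pre_repl[, nm])
      data.frame(family = spec$family, rho_target = spec$rho_target,
                 n = n, estimator = nm, mse = mse[nm], mse_se = mse_se[nm],
                 pre = pre_agg[nm], pre_mean = sm$mean, mc_se = sm$mc_se,
                 ci_lo_norm = sm$ci_norm[1], ci_hi_norm = sm$ci_norm[2],
                 ci_lo_pct = sm$ci_pct[1], ci_hi_pct = sm$ci_pct[2],
                 flags = flags[nm], stringsAsFactors = FALSE)
    })
    res[[as.character(n)]] <- do.call(rbind, rows)
    rep_pre[[as.character(n)]] <- pre_repl
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(list(results = out, population = pop, constants = consts_used,
                 replicate_pre = rep_pre, scenario = spec, seed = spec$seed,
                 R = spec$R,
                 quantile_rule = "type7-linear-interpolation"),
            class = "lrmean_sim")
}

#' @export
print.lrmean_sim <- function(x, digits = 4, ...) {
  cat(sprintf("SRSWOR Monte-Carlo: family = %s, target rho = %.2f (realized %.4f)\n",
              x$scenario$family, x$scenario$rho_target,
              x$population$summary$rho))
  cat(sprintf("N = %d, R = %d, seed = %d, tuning = %s\n",
              x$scenario$N, x$R, x$seed, x$scenario$tuning))
  df <- x$results[, c("n", "estimator", "mse", "pre", "pre_mean", "mc_se")]
  df$mse <- signif(df$mse, digits); df$pre <- signif(df$pre, digits)
  df$pre_mean <- signif(df$pre_mean, digits)
  df$mc_se <- signif(df$mc_se, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.lrmean_sim <- function(object, ...) {
  object$results
}

#' @export
plot.lrmean_sim <- function(x, n = NULL, log = TRUE, ...) {
  nn <- if (is.null(n)) names(x$replicate_pre)[1] else as.character(n)
  m <- x$replicate_pre[[nn]]
  if (is.null(m)) stop("no replicates stored for n = ", nn)
  vals <- as.data.frame(m)
  if (log) {
    boxplot(lapply(vals, function(v) log10(pmax(v, 1e-12))),
            ylab = "log10 replicate PRE", las = 2,
            main = sprintf("Replicate PRE, n = %s", nn), ...)
    abline(h = 2, lty = 2)
  } else {
    boxplot(vals, ylab = "replicate PRE", las = 2,
            main = sprintf("Replicate PRE, n = %s", nn), ...)
    abline(h = 100, lty = 2)
  }
  invisible(x)
}

#' Data-driven tuning of an estimator's free constants
#'
#' Minimises the empirical mean squared error over a fixed, pre-drawn set of
#' SRSWOR replicates (so the objective is deterministic given the stream).
#' Every tunable estimator here is linear in its constants, making the
#' objective an exact quadratic: the minimiser is obtained by least squares
#' and accepted when it lies inside the search box and the replicate design
#' is numerically full-rank; otherwise a box-constrained quasi-Newton search
#' from the origin is used and the solution is flagged as boundary when it
#' lands on the box edge (the documented outcome for TP2 and T8, whose
#' replicate designs are collinear by construction).
#'
#' @param name One of `"TP1"`, `"TP2"`, `"T7"`, `"T8"`, `"T6"`.
#' @param pop A [generate_population()] result.
#' @param n Sample size.
#' @param R_tune Number of pre-drawn replicates.
#' @param stream An [rng_stream()].
#' @param box Half-width of the search box for dimensionless constants; boxes
#'   for additive constants are scaled by \eqn{\max(1, |\mu_y|)}.
#' @return List with `constants` (named list), `mse` (achieved empirical MSE
#'   over the replicate set), `status` (`"interior"`/`"boundary"`),
#'   `boundary` (logical), `R_tune`.
#' @export
empirical_tune <- function(name, pop, n, R_tune = 1000, stream = rng_stream(1),
                           box = 10) {
  name <- match.arg(name, c("TP1", "TP2", "T7", "T8", "T6"))
  ps <- pop$summary
  mu_y <- ps$mu_y; mu_x <- ps$mu_x
  ybar <- xbar <- numeric(R_tune)
  for (r in seq_len(R_tune)) {
    smp <- draw_srswor(pop, n, stream)
    ybar[r] <- mean(smp$y); xbar[r] <- mean(smp$x)
  }
  lg <- log(xbar / mu_x)
  design <- switch(name,
    TP1 = {
      g <- tp1_adjustment(xbar, mu_x)
      list(X = cbind(k1 = ybar * g, k2 = g), off = 0,
           scales = c(1, max(1, abs(mu_y))))
    },
    TP2 = {
      h <- tp2_adjustment(xbar, mu_x)
      list(X = cbind(k3 = ybar * h, k4 = h), off = 0,
           scales = c(1, max(1, abs(mu_y))))
    },
    T7 = list(X = cbind(w1 = ybar, w2 = lg), off = ybar,
              scales = c(1, max(1, abs(mu_y)))),
    T8 = {
      l8 <- log((mu_x + ps$median_x) / (xbar + ps$median_x))
      list(X = cbind(K1 = l8, K2 = -l8), off = 0,
           scales = rep(max(1, abs(mu_y)), 2))
    },
    T6 = list(X = cbind(alpha = lg), off = ybar,
              scales = max(1, abs(mu_y))))
  X <- design$X
  off <- rep(design$off, length.out = nrow(X))
  target <- mu_y - off
  obj <- function(k) mean((drop(X %*% k) + off - mu_y)^2)
  grad <- function(k) drop(2 * crossprod(X, drop(X %*% k) - target) / nrow(X))
  lower <- -box * design$scales
  upper <- box * design$scales
  sv <- svd(X, nu = 0, nv = 0)$d
  singular <- sv[length(sv)] < 1e-8 * sv[1]
  k_ls <- if (!singular) qr.coef(qr(X), target) else NULL
  if (!singular && all(k_ls >= lower) && all(k_ls <= upper)) {
    k <- k_ls
    status <- "interior"
  } else {
    start <- if (!singular) pmin(pmax(k_ls, lower), upper) else rep(0, ncol(X))
    opt <- optim(start, obj, gr = grad, method = "L-BFGS-B",
                 lower = lower, upper = upper)
    k <- opt$par
    status <- if (any(abs(k - lower) < 1e-6 * (upper - lower)) ||
                  any(abs(k - upper) < 1e-6 * (upper - lower)))
      "boundary" else "interior"
  }
  if (!is.finite(obj(k))) stop("tuning objective is not finite")
  list(constants = as.list(setNames(as.numeric(k), colnames(X))),
       mse = obj(k), status = status, boundary = status == "boundary",
       R_tune = R_tune)
}
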