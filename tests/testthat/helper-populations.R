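# Shared builders for small finite populations and random parameter draws.

# A population_summary from the handful of quantities the first-order theory
# actually uses.
summary_from_cv <- function(N, mu_y, mu_x, C_y, C_x, rho, median_x = mu_x) {
  population_summary(N = N, mu_y = mu_y, mu_x = mu_x,
                     S2_y = (C_y * mu_y)^2, S2_x = (C_x * mu_x)^2,
                     C_y = C_y, C_x = C_x, rho = rho, median_x = median_x)
}

# Random draw within the regime the first-order theory is meant for.
random_summary <- function(max_cv = 0.5) {
  mu_y <- runif(1, 5, 90)
  mu_x <- runif(1, 5, 90)
  summary_from_cv(N = sample(100:2000, 1), mu_y = mu_y, mu_x = mu_x,
                  C_y = runif(1, 0.02, max_cv), C_x = runif(1, 0.02, max_cv),
                  rho = runif(1, -0.95, 0.95))
}

# A design with lam <= max_lam (lam = (N-n)/(Nn) <= 1/n - 1/N < 1/n).
random_design <- function(N, max_lam = 0.2) {
  n_min <- max(2L, ceiling(1 / max_lam * 0.9))
  n <- sample(n_min:max(n_min + 1L, min(N, 60L)), 1)
  design_constants(n, N)
}

# Small integer population used by the exhaustive design-moment oracle.
tiny_population <- function() {
  list(y = c(3, 7, 11, 2, 9, 5), x = c(1, 4, 8, 2, 6, 3))
}

# Enumerated SRSWOR moments of (e0, e1) on a tiny population.
enumerated_error_moments <- function(pop, n) {
  ps <- summarize_population(pop$y, pop$x)
  idx <- enumerate_srswor(pop, n)
  e0 <- apply(idx, 2, function(i) mean(pop$y[i])) / ps$mu_y - 1
  e1 <- apply(idx, 2, function(i) mean(pop$x[i])) / ps$mu_x - 1
  list(E_e0 = mean(e0), E_e1 = mean(e1), E_e0sq = mean(e0^2),
       E_e1sq = mean(e1^2), E_e0e1 = mean(e0 * e1), summary = ps)
}
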