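test_that("series expansions of the key factors have the expected coefficients", {
  e1 <- tpoly(c01 = 1)
  g <- tp_log1p_over_z(e1)                       # TP1 factor
  expect_equal(unclass(g), c(c00 = 1, c10 = 0, c01 = -0.5,
                             c20 = 0, c11 = 0, c02 = 1 / 3))
  # exponential-ratio factor exp(-e1/(2+e1)) -> 1 - e1/2 + (3/8) e1^2
  half <- tp_scale(e1, 0.5)
  t3 <- tp_exp(tp_mul(tp_scale(e1, -0.5), tp_inv1p(half)))
  expect_equal(unclass(t3), c(c00 = 1, c10 = 0, c01 = -0.5,
                              c20 = 0, c11 = 0, c02 = 3 / 8))
  # TP2 factor log(1+e1) exp(e1/(2+e1)) -> e1 + 0 e1^2
  h <- tp_mul(tp_log1p(e1), tp_exp(tp_mul(half, tp_inv1p(half))))
  expect_equal(unclass(h), c(c00 = 0, c10 = 0, c01 = 1,
                             c20 = 0, c11 = 0, c02 = 0))
})

test_that("full TP1 expansion reproduces the published degree-2 terms", {
  # (k1 ybar + k2) g expands to
  # k1 mu_y (1 + e0 - e1/2 - e0 e1/2 + e1^2/3) + k2 (1 - e1/2 + e1^2/3)
  k1 <- 0.8; k2 <- 3; mu_y <- 40
  ex <- expand_estimator("TP1", mu_y, 50, constants = list(k1 = k1, k2 = k2))
  expect_equal(unclass(ex),
               c(c00 = k1 * mu_y + k2,
                 c10 = k1 * mu_y,
                 c01 = -(k1 * mu_y + k2) / 2,
                 c20 = 0,
                 c11 = -k1 * mu_y / 2,
                 c02 = (k1 * mu_y + k2) / 3))
})

test_that("expectation follows the SRSWOR moment contract", {
  m <- error_moments_values(0.1, 1, 1, 0.5)
  expect_identical(tp_expectation(tpoly(c00 = 1), m), 1)
  expect_identical(tp_expectation(tpoly(c11 = 1), m), 0.1 * 0.5)
  expect_identical(tp_expectation(tpoly(c10 = 1, c01 = 1), m), 0)
  ps <- summary_from_cv(100, 40, 50, 1, 1, 0.5)
  d <- design_constants(10, 100)
  em <- error_moments(ps, d)
  expect_equal(em$E_e0sq, d$lam)
  expect_equal(em$E_e0e1, d$lam * 0.5)
  # census design: all second moments vanish
  em0 <- error_moments(ps, design_constants(100, 100))
  expect_identical(em0$E_e0sq, 0)
  expect_identical(em0$E_e1sq, 0)
  expect_identical(em0$E_e0e1, 0)
})

test_that("series engine reproduces classical closed forms over random draws", {
  set.seed(101)
  for (i in 1:60) {
    ps <- random_summary()
    d <- random_design(ps$N)
    lam <- d$lam; muy <- ps$mu_y; R <- ps$mu_y / ps$mu_x
    expect_equal(series_bias_mse("T0", ps, d)$mse, lam * muy^2 * ps$C_y^2,
                 tolerance = 1e-12)
    expect_equal(series_bias_mse("T1", ps, d)$mse,
                 lam * (ps$S2_y + R^2 * ps$S2_x - 2 * R * ps$S_yx),
                 tolerance = 1e-12)
    expect_equal(series_bias_mse("T3", ps, d)$mse,
                 lam * (ps$S2_y + 0.25 * R^2 * ps$S2_x - R * ps$S_yx),
                 tolerance = 1e-12)
    # regression / optimal-log estimators carry the (1 - rho^2) structure
    expect_equal(series_bias_mse("T4", ps, d)$mse,
                 lam * ps$S2_y * (1 - ps$rho^2), tolerance = 1e-12)
    expect_equal(series_bias_mse("T6", ps, d)$mse,
                 lam * muy^2 * ps$C_y^2 * (1 - ps$rho^2), tolerance = 1e-12)
  }
})

test_that("series bias of the ratio estimator matches the classical form", {
  set.seed(7)
  for (i in 1:20) {
    ps <- random_summary()
    d <- random_design(ps$N)
    R <- ps$mu_y / ps$mu_x
    expect_equal(series_bias_mse("T1", ps, d)$bias,
                 d$lam / ps$mu_x * (R * ps$S2_x - ps$S_yx), tolerance = 1e-12)
  }
})

test_that("series MSE of T4 vanishes for a perfectly linear auxiliary", {
  ps <- summary_from_cv(500, 30, 60, 0.3, 0.4, 1)
  d <- design_constants(25, 500)
  expect_equal(series_bias_mse("T4", ps, d)$mse, 0, tolerance = 1e-14)
})

test_that("published quadratic-form constants match their definitions", {
  ps <- summary_from_cv(400, 40, 50, 1, 1, 0)
  d <- list(n = 9L, N = 400L, f = 9 / 400, lam = 0.1)
  class(d) <- "design_spec"
  p1 <- theory_constants("P1", ps, d)
  expect_equal(p1$A1, 1.191667, tolerance = 1e-6)
  expect_equal(p1$B1, 1.091667, tolerance = 1e-6)
  expect_equal(p1$E1, 1.091667, tolerance = 1e-6)
  expect_equal(p1$C1, 1.033333, tolerance = 1e-6)
  expect_equal(p1$D1, 1.033333, tolerance = 1e-6)
  expect_equal(p1$Delta1, 0.109167, tolerance = 1e-5)
  p2 <- theory_constants("P2", ps, d)
  expect_equal(p2$alpha, 0.1)
  expect_equal(p2$beta, 0.1)
  expect_equal(p2$A2, 0.0018750, tolerance = 1e-12)
  expect_equal(p2$B2, 0.00171875, tolerance = 1e-12)
  expect_equal(p2$E2, 0.0034375, tolerance = 1e-12)
  expect_equal(p2$C2, 0.025)
  expect_identical(p2$E2, 2 * p2$B2)
  expect_identical(p2$D2, p2$C2)
  # census: all P1 constants collapse to 1 and Delta1 to 0
  d0 <- design_constants(400, 400)
  p10 <- theory_constants("P1", ps, d0)
  expect_identical(unlist(p10[c("A1", "B1", "C1", "D1", "E1")]),
                   c(A1 = 1, B1 = 1, C1 = 1, D1 = 1, E1 = 1))
  expect_identical(p10$Delta1, 0)
  expect_error(printed_optimal_k("P1", p10, 40), "zero")
  expect_error(printed_min_mse("P1", p10, 40), "zero")
})

test_that("printed optimum has k1 = 0 when the relative covariance vanishes", {
  ps <- summary_from_cv(400, 40, 50, 0.8, 0.6, 0)
  d <- design_constants(20, 400)
  k <- printed_optimal_k("P1", theory_constants("P1", ps, d), 40)
  expect_identical(unname(k["k1"]), 0)
})

test_that("printed P2 optimum follows its formula; sign is set by Delta2 < 0", {
  ps <- summary_from_cv(400, 40, 50, 1, 1, 0.5)
  d <- list(n = 9L, N = 400L, f = 9 / 400, lam = 0.1)
  class(d) <- "design_spec"
  p2 <- theory_constants("P2", ps, d)
  k <- printed_optimal_k("P2", p2, 40)
  expect_equal(unname(k["k3"]), p2$C2 * (p2$B2 - p2$E2) / p2$Delta2,
               tolerance = 1e-14)
  expect_lt(p2$B2 - p2$E2, 0)
  expect_lt(p2$Delta2, 0)
  expect_gt(unname(k["k3"]), 0)   # ratio of two negatives
})

test_that("printed minimum MSEs match the worked arithmetic", {
  ps <- summary_from_cv(400, 40, 50, 1, 1, 0)
  d <- list(n = 9L, N = 400L, f = 9 / 400, lam = 0.1)
  class(d) <- "design_spec"
  p1 <- theory_constants("P1", ps, d)
  expect_equal(printed_min_mse("P1", p1, 40) / 40^2, 0.0218829516539,
               tolerance = 1e-9)
  # the P2 correction term vanishes as alpha -> 0
  ps2 <- summary_from_cv(10000, 40, 50, 0.3, 1e-4, 0)
  d2 <- design_constants(5000, 10000)
  p2 <- theory_constants("P2", ps2, d2)
  expect_equal(printed_min_mse("P2", p2, 40), 1600, tolerance = 1e-4)
})

test_that("printed TP1/TP2 quadratic forms agree with series mode where they should", {
  # at (k1, k2) = (1, 0) with C_yx = 0 the printed form reduces to
  # mu_y^2 lam (C_y^2 + C_x^2/4), exactly the series value
  set.seed(11)
  for (i in 1:20) {
    mu_y <- runif(1, 5, 80)
    ps <- summary_from_cv(600, mu_y, runif(1, 5, 80),
                          runif(1, 0.05, 0.5), runif(1, 0.05, 0.5), 0)
    d <- random_design(600)
    printed <- printed_bias_mse("TP1", ps, d,
                                constants = list(k1 = 1, k2 = 0))$mse
    series <- series_bias_mse("TP1", ps, d,
                              constants = list(k1 = 1, k2 = 0))$mse
    # the printed path evaluates mu_y^2 (A1 - 2 C1 + 1): agreement is at
    # machine precision relative to the scale mu_y^2 of the cancelled terms
    expect_lt(abs(printed - mu_y^2 * d$lam * (ps$C_y^2 + ps$C_x^2 / 4)),
              1e-12 * mu_y^2)
    expect_lt(abs(printed - series), 1e-12 * mu_y^2)
  }
})

test_that("the printed-vs-derived discrepancies stay pinned", {
  ps <- summary_from_cv(400, 40, 50, 1, 1, 0.5)
  d <- list(n = 9L, N = 400L, f = 9 / 400, lam = 0.1)
  class(d) <- "design_spec"
  p1 <- theory_constants("P1", ps, d)
  kp <- printed_optimal_k("P1", p1, 40)
  kc <- solve_printed_system("P1", p1, 40)
  # printed k1 flips the sign of the D1E1 term relative to the literal
  # Cramer solution; k2 agrees
  expect_equal(unname(kp["k1"] - kc["k1"]), -2 * p1$D1 * p1$E1 / p1$Delta1,
               tolerance = 1e-10)
  expect_equal(unname(kp["k1"]), -0.02734375, tolerance = 1e-10)
  expect_equal(unname(kp["k2"]), 807.1354167, tolerance = 1e-7)
  expect_equal(unname(kc["k2"]), unname(kp["k2"]), tolerance = 1e-10)
  # the printed minimum-MSE expression matches neither evaluation of the
  # printed quadratic form: the gaps are frozen
  eq20_at_printed <- printed_bias_mse(
    "TP1", ps, d, constants = list(k1 = kp[["k1"]], k2 = kp[["k2"]]))$mse
  eq20_at_cramer <- printed_bias_mse(
    "TP1", ps, d, constants = list(k1 = kc[["k1"]], k2 = kc[["k2"]]))$mse
  eq24 <- printed_min_mse("P1", p1, 40)
  expect_equal(eq24, 34.89583333, tolerance = 1e-8)
  expect_equal(eq20_at_printed, 647988.7713, tolerance = 1e-8)
  expect_equal(eq20_at_cramer, -63472.04861, tolerance = 1e-8)
})

test_that("mechanical and printed TP1 biases differ by the documented gap", {
  # printed: (1/3) lam Cx2 (k1 muy - k2) - (k1/2) muy lam C_yx
  # series:  (k1 muy + k2 - muy) + (1/3) lam Cx2 (k1 muy + k2)
  #          - (k1/2) muy lam C_yx
  # gap = (k1 muy + k2 - muy) + (2/3) lam Cx2 k2; zero at (k1, k2) = (1, 0)
  set.seed(5)
  for (i in 1:10) {
    ps <- random_summary()
    d <- random_design(ps$N)
    k1 <- runif(1, 0.5, 1.5); k2 <- runif(1, -1, 1) * ps$mu_y
    b_series <- series_bias_mse("TP1", ps, d,
                                constants = list(k1 = k1, k2 = k2))$bias
    b_printed <- printed_bias_mse("TP1", ps, d,
                                  constants = list(k1 = k1, k2 = k2))$bias
    gap <- (k1 * ps$mu_y + k2 - ps$mu_y) + (2 / 3) * d$lam * ps$C_x^2 * k2
    expect_equal(b_series - b_printed, gap, tolerance = 1e-9)
  }
  ps <- summary_from_cv(500, 40, 50, 0.3, 0.3, 0.6)
  d <- design_constants(25, 500)
  expect_equal(series_bias_mse("TP1", ps, d,
                               constants = list(k1 = 1, k2 = 0))$bias,
               printed_bias_mse("TP1", ps, d,
                                constants = list(k1 = 1, k2 = 0))$bias,
               tolerance = 1e-12)
})

test_that("generic 2x2 solve agrees with explicit Cramer formulas", {
  set.seed(23)
  for (i in 1:50) {
    ps <- random_summary()
    d <- random_design(ps$N)
    p1 <- theory_constants("P1", ps, d)
    kc <- solve_printed_system("P1", p1, ps$mu_y)
    # literal algebraic solution of the published system
    expect_equal(unname(kc["k1"]),
                 (p1$B1 * p1$C1 + p1$D1 * p1$E1) / p1$Delta1,
                 tolerance = 1e-10)
    expect_equal(unname(kc["k2"]),
                 ps$mu_y * (p1$A1 * p1$D1 + p1$C1 * p1$E1) / p1$Delta1,
                 tolerance = 1e-10)
  }
})

test_that("derived optimum is a true minimum with vanishing gradient", {
  ps <- summary_from_cv(1000, 40, 50, 0.1, 0.1, 0.7)
  d <- design_constants(150, 1000)
  dk <- derived_optimal_k("P1", ps, d)
  expect_identical(dk$status, "ok")
  expect_lt(sqrt(sum(dk$gradient^2)), 1e-8)
  # the optimum improves on the neutral constants (1, 0)
  mse_neutral <- series_bias_mse("TP1", ps, d,
                                 constants = list(k1 = 1, k2 = 0))$mse
  expect_lt(dk$mse, mse_neutral)
  # perturbations increase the series MSE
  for (delta in list(c(0.01, 0), c(0, 0.5), c(-0.01, 0.3))) {
    kk <- dk$k + delta
    expect_gt(series_bias_mse("TP1", ps, d,
                              constants = list(k1 = kk[1], k2 = kk[2]))$mse,
              dk$mse)
  }
})

test_that("TP2 series minimisation is degenerate as documented", {
  ps <- summary_from_cv(1000, 40, 50, 0.1, 0.1, 0.7)
  d <- design_constants(150, 1000)
  dk <- derived_optimal_k("P2", ps, d)
  expect_identical(dk$status, "degenerate")
  # the objective is unbounded below along k4 = -mu_y k3: a step along that
  # direction from the returned point must not increase the MSE
  k3 <- dk$k[["k3"]] ; k4 <- dk$k[["k4"]]
  further <- series_bias_mse("TP2", ps, d,
                             constants = list(k3 = k3 * 2, k4 = -40 * k3 * 2))$mse
  base <- series_bias_mse("TP2", ps, d,
                          constants = list(k3 = k3, k4 = -40 * k3))$mse
  expect_lte(further, base)
})

test_that("series MSE is nonnegative for all estimators except the documented TP2 region", {
  set.seed(31)
  offenders <- character(0)
  for (i in 1:300) {
    ps <- random_summary(max_cv = 0.5)
    d <- random_design(ps$N)
    kk <- list(T6 = list(alpha = runif(1, -2, 2) * ps$mu_y),
               T7 = list(w1 = runif(1, -0.5, 0.5), w2 = runif(1, -2, 2) * ps$mu_y),
               T8 = list(K1 = runif(1, -2, 2) * ps$mu_y,
                         K2 = runif(1, -2, 2) * ps$mu_y),
               TP1 = list(k1 = runif(1, -2, 2), k2 = runif(1, -2, 2) * ps$mu_y),
               TP2 = list(k3 = runif(1, -2, 2), k4 = runif(1, -2, 2) * ps$mu_y))
    for (nm in c("T0", "T1", "T2", "T3", "T4", "T5", "T6", "T7", "T8",
                 "TP1", "TP2")) {
      mse <- series_bias_mse(nm, ps, d, constants = kk[[nm]] %||% list())$mse
      if (mse < 0) offenders <- c(offenders, nm)
    }
  }
  expect_true(all(offenders %in% "TP2"))
})

test_that("percent relative efficiency behaves as a ratio index", {
  expect_identical(pre(0.37, 0.37), 100)
  expect_identical(pre(2, 1), 200)
  expect_error(pre(1, 0), "positive")
  expect_error(pre(0, 1), "positive")
})

test_that("efficiency margins are consistent with direct MSE comparison", {
  ps <- summary_from_cv(1000, 40, 50, 0.15, 0.12, 0.6)
  d <- design_constants(100, 1000)
  expect_identical(efficiency_margin("T1", "T1", ps, d), 0)
  # TP1 at its derived optimum dominates the classical mean in series mode
  # within the regime ratio-type estimation is meant for (auxiliary CV not
  # far above the study CV: the family's best point at k1 mu_y + k2 = mu_y
  # has MSE <= lam mu_y^2 Cx^2 (1 - rho^2)/4 < MSE(T0) when Cx < 2 Cy)
  set.seed(17)
  for (i in 1:25) {
    mu_y <- runif(1, 5, 90); C_y <- runif(1, 0.05, 0.4)
    ps2 <- summary_from_cv(N = sample(100:2000, 1), mu_y = mu_y,
                           mu_x = runif(1, 5, 90), C_y = C_y,
                           C_x = C_y * runif(1, 0.5, 1.5),
                           rho = runif(1, -0.95, 0.95))
    if (abs(ps2$rho) < 0.05) next
    d2 <- random_design(ps2$N)
    expect_gt(efficiency_margin("TP1", "T0", ps2, d2, mode = "series"), 0)
    # sign agrees with the direct inequality
    m <- efficiency_margin("TP1", "T3", ps2, d2, mode = "series")
    mse_tp1 <- derived_optimal_k("P1", ps2, d2)$mse
    mse_t3 <- series_bias_mse("T3", ps2, d2)$mse
    expect_identical(m > 0, mse_t3 > mse_tp1)
  }
})

test_that("printed T8 closed form is refused as under-specified", {
  ps <- summary_from_cv(100, 40, 50, 0.2, 0.2, 0.5)
  d <- design_constants(10, 100)
  expect_error(printed_bias_mse("T8", ps, d), "under-specified")
})

test_that("mse_table assembles bias, MSE and PRE per estimator", {
  ps <- summary_from_cv(1000, 40, 50, 0.1, 0.1, 0.7)
  tab <- mse_table(ps, n = 150)
  expect_identical(nrow(tab), 9L)
  expect_identical(tab$pre[tab$estimator == "T0"], 100)
  expect_true(all(tab$mse > 0 | tab$estimator == "T4"))
  expect_gt(tab$pre[tab$estimator == "TP1"], 100)
})
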