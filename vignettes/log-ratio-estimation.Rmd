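---
title: "Log-ratio estimation of a finite-population mean under SRSWOR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Log-ratio estimation of a finite-population mean under SRSWOR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrmean)
```

## The estimation problem

A finite population of $N$ units carries a study variable $y$ and an
auxiliary variable $x$ whose population mean $\mu_x$ is known (a register
total, a previous census, an instrumented covariate). A sample of $n$ units
is drawn by simple random sampling without replacement (SRSWOR) and the goal
is to estimate $\mu_y$ with smaller mean squared error than the sample mean
$\bar y$ achieves, by exploiting the correlation between $y$ and $x$.

All first-order theory in the package is written in the relative sampling
errors
$$e_0 = \frac{\bar y - \mu_y}{\mu_y}, \qquad e_1 = \frac{\bar x - \mu_x}{\mu_x},$$
whose design moments under SRSWOR are
$E(e_0)=E(e_1)=0$, $E(e_0^2)=\lambda C_y^2$, $E(e_1^2)=\lambda C_x^2$,
$E(e_0e_1)=\lambda C_{yx}$, with $\lambda = (1-f)/n = (N-n)/(Nn)$ the
finite-population-correction variance factor, $C$'s the coefficients of
variation and $C_{yx}=\rho C_y C_x$ the relative covariance. The
`design_constants()`, `error_moments()` and `enumerate_srswor()` functions
expose this contract, and the test suite verifies it exactly by enumerating
all $\binom{N}{n}$ samples of tiny populations.

## The estimator family

`estimate()` and the `lrmean()` fitting interface implement the classical
mean `T0`, the ratio (`T1`), product (`T2`), exponential-ratio (`T3`),
difference-type regression (`T4`) and log-auxiliary (`T5`–`T8`) competitors,
and the two proposed logarithmic ratio-type estimators
$$T_{P1} = (k_1\bar y + k_2)\,\frac{\mu_x}{\bar x-\mu_x}\,
           \log\!\Big(\frac{\bar x}{\mu_x}\Big), \qquad
  T_{P2} = (k_3\bar y + k_4)\,\log\!\Big(\frac{\bar x}{\mu_x}\Big)\,
           \exp\!\Big(\frac{\bar x-\mu_x}{\bar x+\mu_x}\Big),$$
which carry Searls-type tuning constants. The $T_{P1}$ factor
$\log(1+e_1)/e_1$ has a removable singularity at $\bar x=\mu_x$;
`tp1_adjustment()` extends it continuously (value 1), switching to a
truncated series for $|e_1|<10^{-4}$, where the switch error is far below
machine precision. $T_{P2}$ vanishes identically at $\bar x=\mu_x$; because
a Monte-Carlo run must not abort on a measure-zero event, the value 0 is
returned with a degeneracy flag that the simulator counts and reports.

Two printed forms are implemented in a *paper-literal* variant in addition
to the standard one. The literal `T5` is $\mu_y\log\bar y/\log\bar x$, which
contains the unknown target $\mu_y$ and is therefore only useful
diagnostically; the default standard form $\bar y\log\mu_x/\log\bar x$ is
the unique log-ratio form whose first-order MSE matches the published closed
form with $k=1/\log\mu_x$. `T8` is a function of $x$ alone as published
(equal to $(K_1-K_2)\log[(\mu_x+Md)/(\bar x+Md)]$ with $Md$ the auxiliary
median); its constants come only from user input or empirical tuning, never
from its published closed form, whose constants are not all defined.

## Dual-path first-order theory

The central design decision of the package is that bias and MSE are
available through **two parallel paths**:

* `printed_bias_mse()` transcribes the published closed forms literally,
  including the quadratic forms $MSE(T_{P1};k_1,k_2)$ and
  $MSE(T_{P2};k_3,k_4)$, their constants ($A_1,\dots,E_1$;
  $A_2,\dots,E_2$ with $\alpha=\lambda C_x^2$, $\beta=\lambda C_y^2$), the
  printed optimal constants, and the printed minimum MSEs.
* `series_bias_mse()` derives the same quantities mechanically with a
  truncated bivariate Taylor engine (`tpoly`): every estimator is expanded
  to total degree 2 in $(e_0,e_1)$ by composing four primitive series
  ($\log(1+z)$, $1/(1+z)$, $e^z$, $\log(1+z)/z$) with truncated ring
  products; no estimator receives hand-tailored coefficients. The MSE is
  the expectation of the degree-2 truncation of the squared deviation,
  which keeps the squared-linear and constant-times-quadratic terms.

The two paths agree exactly (machine precision) for the classical results —
the sample-mean MSE $\lambda\mu_y^2C_y^2$, the exponential-ratio structure,
the $(1-\rho^2)$ structure of the regression and optimal-log estimators,
and the $T_{P1}$ quadratic form at $(k_1,k_2)=(1,0)$ when $C_{yx}=0$ — and
they **disagree in documented places** that the test suite pins so that no
later edit can silently "fix" them:

* the printed $C_1$ carries $-\lambda C_{yx}$ where the mechanical
  derivation gives $-\tfrac12\lambda C_{yx}$;
* the printed optimal $k_1$ has a $-D_1E_1$ term where the literal Cramer
  solution of the printed normal equations (`solve_printed_system()`) has
  $+D_1E_1$;
* the printed minimum-MSE expression equals neither evaluation of the
  printed quadratic form (the frozen gaps at a reference parameter point
  are kept as regression values);
* the printed $T_{P1}$ bias omits the constant $(k_1\mu_y+k_2-\mu_y)$ and
  flips the sign of $k_2$ in the $\lambda C_x^2$ term; the two biases
  coincide exactly at $(k_1,k_2)=(1,0)$;
* the published ratio-estimator MSE uses the ratio $D=\mu_x/\mu_y$
  linearly, which is dimensionally inconsistent; the standard variant uses
  the classical $R=\mu_y/\mu_x$ with $R^2$ on $S_x^2$, which is what the
  series engine reproduces. Both are selectable via `variant=`.

Where a printed constant is ambiguous we adopt the only reading that keeps
the algebra consistent: the products written "$C_xC_y$" in $A_1,C_1,E_1$
are read as $C_{yx}=\rho C_yC_x$ (the bias uses $C_{yx}$ explicitly), and
the undefined $D_2$ is set to $C_2$, matching the quadratic form's linear
$k_4$ term.

### Optimal constants

`derived_optimal_k()` minimises the series-mode MSE, which is an exact
quadratic in the constants. For $T_{P1}$ the quadratic part is positive
definite away from a census and the closed-form solution is returned with
status `"ok"` (its gradient vanishes to numerical precision; a census or
any $|\Delta|<10^{-12}\cdot|A\,B|$ is treated as degenerate). For $T_{P2}$
the degree-2 linearisation has no constant term — its expansion is
$(k_3\mu_y+k_4)e_1 + k_3\mu_ye_0e_1$ — so the objective is indefinite and
unbounded below along $k_4=-\mu_yk_3$; the expected status is
`"degenerate"` with a bounded box search as fallback. This is a structural
property of the estimator as printed, not a numerical accident, and it is
asserted by tests.

## The Monte-Carlo framework

`scenario_spec()` + `run_monte_carlo()` reproduce a standard synthetic
design: finite populations of $N=1000$ units with mean vector $(40, 50)$
from three marginal families — Normal (symmetric, light tails; unit
standard deviations by default), Gamma (positively skewed; shape 4 by
default), Lognormal (heavy-tailed; $\sigma_{\log}=0.5$ by default) — at
target correlations $\rho\in\{0.92, 0.71, 0.38\}$, sample sizes
$n\in\{50,150,200\}$ and $R=10{,}000$ SRSWOR replicates. The Gamma shape
and Lognormal log-scale defaults are our choice of realistic skew/tail
settings for an under-specified non-normal design; means are matched
exactly through the marginal parameterisation.

All three families are generated through one Gaussian-copula (NORTA)
construction: a latent standard-normal pair is transformed by the inverse
marginal CDF, and the latent correlation is root-found **on the realized
draw** so that the population's Pearson correlation equals the target to
~1e-9. Conditioning on the realized correlation makes scenarios that
"differ only in correlation" exactly comparable across families and seeds;
the marginals remain exactly Normal/Gamma/Lognormal either way, and the
construction fails loudly if the target is unreachable.

Replication follows the design-based convention of centering at the true
$\mu_y$: the "variance" of $T_0$ and the MSE of every competitor are
$R^{-1}\sum_r (T^{(r)}-\mu_y)^2$, so $T_0$'s variance is its MSE about
$\mu_y$. PRE is $100\,\mathrm{Var}(T_0)/MSE(T_i)$ on the aggregate, and
per-replicate PREs $100\,(T_0^{(r)}-\mu_y)^2/(T_i^{(r)}-\mu_y)^2$ feed the
uncertainty summaries: Monte-Carlo standard error $sd/\sqrt R$, a normal
95% interval, and the nonparametric 95% percentile interval using the
inclusive linear-interpolation quantile rule (R's type 7; the rule name is
recorded in the output metadata). Per-replicate PRE ratios are extremely
heavy-tailed — a replicate in which a competitor lands near $\mu_y$ by
chance produces an enormous ratio — so the aggregate PRE is the meaningful
efficiency index while the replicate summaries quantify that instability;
both are reported.

Constants are resolved once per scenario in the default `"theoretical"`
mode — $T_{P1}$ from the series-derived optimum, $T_{P2}$ from the printed
optimum (its series derivation being degenerate), $T_6$ from
$\alpha=-\mu_y\rho C_y/C_x$, and $T_7$/$T_8$ by data-driven minimisation —
or per replicate from sample moments in `"estimated"` mode. All randomness
flows through an explicit `rng_stream()` object, so a scenario's seed fully
determines every output table (asserted byte-for-byte in tests).

### Empirical tuning

`empirical_tune()` minimises the empirical MSE over a fixed pre-drawn
replicate set, so the objective is deterministic given the stream. Every
tunable estimator is *linear* in its constants, making the objective an
exact quadratic: the minimiser is computed by least squares and accepted
when the replicate design is numerically full-rank (smallest singular value
above $10^{-8}$ of the largest) and the solution lies inside the search box
($\pm 10$ for dimensionless constants, scaled by $|\mu_y|$ for additive
ones). Otherwise a box-constrained L-BFGS-B search from the origin is used
and a solution on the box edge is flagged `boundary`. $T_{P2}$'s replicate
design is nearly collinear ($\bar y h$ vs $h$), reproducing its theoretical
degeneracy empirically (boundary-flagged); $T_8$'s two columns are exactly
collinear ($\ell$, $-\ell$), so the optimiser settles on a finite point of
the flat valley whose achieved MSE can only improve on $(0,0)$.

## Problem sizes used by the checks

The shipped tests run the replication experiments at desk scale: the
MC-versus-theory comparison uses $N=1000$, $n=150$, $R=5000$ with CVs near
0.10 and $\rho\approx0.7$, where three Monte-Carlo standard errors bound
both the simulation noise and the (much smaller) degree-2 truncation error;
tuning recovery uses the same scenario with $R_{tune}=5000$; generator
calibration is checked for all nine family-correlation combinations at
$N=1000$. The acceptance script runs the full $R=10{,}000$ normal-family
scenarios at $n=150$.

## What the synthetic populations do and do not show

The generator emulates correlated bivariate finite populations with exact
target correlation, matched means, and controlled skewness/tails. It does
not emulate outlier contamination, measurement error in $x$, nonlinear
mean relationships beyond what the copula induces, clustered or stratified
structure, or an unknown $\mu_x$. Passing tests therefore demonstrate the
internal correctness of the estimators, the first-order theory and the
replication machinery — not that the proposed estimators dominate on any
particular real dataset. Two honest caveats carry over to practice:

* $T_{P1}$'s large theoretical and simulated PRE gains at small CVs are
  mostly Searls shrinkage toward $k_1\mu_y+k_2\approx\mu_y$, which
  presumes the population summary used to tune the constants is accurate;
  with plug-in constants (`tuning = "estimated"`) the gains shrink.
* $T_{P2}$ as printed is not a consistent estimator of $\mu_y$ (it
  vanishes at $\bar x=\mu_x$), and its empirical MSE is dominated by
  $\mu_y^2$; the package reports this honestly rather than repairing the
  estimator.

The dominance of the tuned $T_{P1}$ over the classical mean (positive
`efficiency_margin()`) is guaranteed in the regime ratio-type estimation is
meant for — auxiliary CV comparable to the study CV — since the family's
constrained best point already has MSE $\lambda\mu_y^2C_x^2(1-\rho^2)/4$;
with $C_x$ far above $C_y$ the margin can turn negative, and the property
tests draw from the former regime.

## Known limitations

First-order (degree-2) theory only; no higher-order corrections, no
variance estimator for a single drawn sample, SRSWOR only (no stratified or
two-phase designs), and $\mu_x$ assumed known exactly.
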