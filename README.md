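# lrmean

Design-based estimation of a finite-population mean under simple random
sampling without replacement (SRSWOR), using a known auxiliary mean.

## The problem and who it is for

Survey statisticians, quality-control engineers and environmental
monitors routinely know the population mean `μx` of an auxiliary variable
(a register, a previous census, an instrumented covariate) that is
correlated with the study variable `y`. Ratio-type estimators fold that
knowledge into the estimate of `μy` and can beat the sample mean `ȳ` by a
wide margin. This package implements the classical family — sample mean
(T0), ratio (T1), product (T2), exponential ratio (T3), difference-type
regression (T4) and log-auxiliary forms (T5–T8) — together with two
logarithmic ratio-type estimators carrying Searls-type tuning constants:

```
T_P1 = (k1·ȳ + k2) · μx·log(x̄/μx)/(x̄ − μx)
T_P2 = (k3·ȳ + k4) · log(x̄/μx) · exp((x̄ − μx)/(x̄ + μx))
```

Around the estimators it ships the full first-order toolkit: sampling-error
moments under SRSWOR (`λ = (N−n)/(Nn)` times squared CVs), bias and MSE for
every estimator through **two parallel theory paths** — a literal
transcription of the published closed forms (`printed_bias_mse()`) and an
independent truncated bivariate Taylor engine (`series_bias_mse()`, built
from primitive series compositions) — optimal-constant solvers for both
paths, percent relative efficiency (PRE), MSE-dominance margins, and a
reproducible Monte-Carlo framework (Gaussian-copula Normal/Gamma/Lognormal
finite populations with exactly realized target correlations, SRSWOR
replication, MC standard errors and percentile intervals, data-driven
tuning). The two paths disagree in documented places; the disagreements are
pinned by regression tests rather than silently repaired — see the methods
vignette (`vignettes/log-ratio-estimation.Rmd`).

## Worked example

A skewed finite population of N = 1000 units (gamma auxiliary, linear
signal plus noise, realized ρ = 0.926), a single SRSWOR sample of n = 100,
and the known auxiliary mean:

```r
library(lrmean)
set.seed(2026)
N <- 1000
x <- rgamma(N, shape = 4, scale = 12.5)
y <- 10 + 0.6 * x + rnorm(N, 0, 6)
ps  <- summarize_population(y, x)     # mu_y = 39.649, mu_x = 49.747

smp <- draw_srswor(list(y = y, x = x), 100, rng_stream(1))
fit <- lrmean(y ~ x, data.frame(y = smp$y, x = smp$x),
              mu_x = ps$mu_x, N = N, summary = ps,
              estimators = c("T0", "T1", "T3", "T4", "TP1", "TP2"))
summary(fit)
#> Finite-population mean estimation under SRSWOR
#>   n = 100, N = 1000, ybar = 38.4672, xbar = 47.3735, mu_x = 49.7469
#>  estimator estimate                constants  mse_series pre_series
#>         T0  38.4672                             2.254220  100.00000
#>         T1  40.3944                             0.510188  441.84000
#>         T3  39.4188                             0.547381  411.81800
#>         T4  39.9361 phi1=0.6189,slope=sample    0.319665  705.18100
#>        TP1  39.9305        k1=0.5634,k2=17.3    0.118215 1906.87000
#>        TP2  20.4568       k3=5.325,k4=-633.6 1924.210000    0.11715
```

Reading the output: the true mean is 39.649. The plain sample mean misses
by 1.2; every auxiliary-assisted estimator lands within 0.5 of the truth.
The `mse_series`/`pre_series` columns are the first-order theoretical MSE
and percent relative efficiency for this design (n = 100 of N = 1000): the
regression estimator is ~7x as efficient as the sample mean, and the tuned
log-ratio estimator TP1 ~19x (much of that gain is Searls shrinkage, which
presumes the population summary used for tuning is accurate — see the
vignette). TP2 with its published optimal constants is *not* a usable
estimator of the mean (its printed form vanishes at x̄ = μx); the package
reports that honestly rather than repairing it.

The same table is available directly from population quantities:

```r
mse_table(ps, n = 100)          # bias, MSE, PRE per estimator, series mode
mse_table(ps, n = 100, mode = "printed")   # literal published formulas
```

And the Monte-Carlo machinery reproduces the theory empirically:

```r
sc  <- scenario_spec(family = "gamma", rho_target = 0.92, N = 1000,
                     n_list = c(50, 150), R = 10000, seed = 1)
sim <- run_monte_carlo(sc)      # empirical MSE, PRE, MC-SE, 95% CIs
plot(sim, n = 150)              # replicate-PRE boxplots
```

A thin command-line wrapper over the same functions lives in
`inst/scripts/lrmean-cli.R` (modes `estimate`, `theory`, `simulate`,
`tune`, YAML/JSON configs).

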