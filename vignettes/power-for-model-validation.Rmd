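---
title: "Exact power and sample size for validating a regression formula"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact power and sample size for validating a regression formula}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointpwr)
```

## The model and the hypothesis

Model validation asks a different question from model selection: not *which*
model fits, but whether newly collected data are compatible with a
*previously published* regression formula. For the linear model

$$Y_i = \beta_I + X_i^T \beta_S + \varepsilon_i, \qquad
\varepsilon_i \sim N(0, \sigma^2),$$

compatibility with a postulated formula $(\beta_{I0}, \beta_{S0})$ is a
*joint* test of the full coefficient vector, because predictions depend on
intercept and slopes together. The test statistic is the
general-linear-hypothesis F,

$$F = \frac{(\hat\beta - \theta)^T (X^T X)(\hat\beta - \theta)/(p+1)}
           {\hat\sigma^2},$$

central $F(p+1,\ \nu)$ under the null with $\nu = N - p - 1$, and the test
rejects when $F$ strictly exceeds the upper-$\alpha$ critical value.

## Why random predictors change power analysis

Inference is the same whether predictors are regarded as fixed or random.
Power analysis is not. Conditional on observed predictors, the nonnull
distribution is noncentral F with

$$\Delta = \frac{N(\beta_{ID} + \beta_{SD}^T \bar X)^2
                 + \beta_{SD}^T A\, \beta_{SD}}{\sigma^2},$$

a function of the data only through the predictor mean $\bar X$ and scatter
matrix $A$ (`conditional_noncentrality()`, `power_conditional()`). But at
the planning stage the predictor values do not yet exist; $\bar X$ and $A$
are random, and a sample size chosen for one hypothetical design can be
badly calibrated on average. The unconditional power must integrate the
conditional power over the predictor distribution.

With $X_i \sim N_p(\mu_X, \Sigma_X)$ i.i.d., $\bar X \sim N_p(\mu_X,
\Sigma_X/N)$ and $A$ is Wishart with $\kappa = N - 1$ degrees of freedom,
and the noncentrality collapses to a two-variable mixture

$$\Delta = \frac{N(a + bZ)^2 + dK}{\sigma^2}, \qquad
Z \sim N(0,1),\ K \sim \chi^2(\kappa) \text{ independent},$$

with $a = \beta_{ID} + \beta_{SD}^T \mu_X$ (the mean-level discrepancy),
$d = \beta_{SD}^T \Sigma_X \beta_{SD}$ (the slope discrepancy expressed
through the predictor variance), and $b = \sqrt{d/N}$
(`mixture_representation()`). Exact power is then

$$\Psi = E_K E_Z\left[P\{F(p+1, \nu, \Delta) > F_{p+1,\nu,\alpha}\}\right],$$

covering simple regression as the $p = 1$ special case.

The popular shortcut replaces every $X_i$ by $\mu_X$, giving the single
noncentral-F power $\Psi_C$ with noncentrality $Na^2/\sigma^2$
(`power_approx()`). Its per-observation effect size
$a^2/\sigma^2$ is strictly smaller than the exact
$(a^2 + d)/\sigma^2$ whenever $d > 0$ (`asymptotic_effect_size()`), so the
approximation understates power and oversizes studies precisely when the
slopes disagree and the predictors vary — the typical validation setting.

## Numerical evaluation

The double expectation is evaluated by an analytic collapse
(`quadrature_spec("mixture_1d")`, the default). Because $Nb^2 = d$,
$N(a+bZ)^2/d = (Z + a/b)^2$ is a 1-df noncentral chi-square with
noncentrality $\lambda = Na^2/d$, independent of $K$; hence
$W = N(a+bZ)^2/d + K$ is noncentral chi-square with $N$ degrees of freedom
and noncentrality $\lambda$, and

$$\Psi = \int P\{F(p+1,\nu,\ (d/\sigma^2)\,w) > F_{crit}\}\ dF_W(w)$$

is one smooth 1-D integral, evaluated adaptively to absolute tolerance
`1e-8` (printed powers carry 4 decimals; `1e-8` leaves their rounding
unambiguous). This collapse is an implementation theorem, not part of the
derivation, so the package retains the direct transcription — Gauss–Hermite
over $Z$ crossed with adaptive integration over the $\chi^2(\kappa)$
density (`"hermite_x_chisq_2d"`) — and the test suite requires the two
schemes to agree to `1e-7` across a 108-point stress grid. A plain Monte
Carlo scheme over $(Z, K)$ (`"monte_carlo"`) is available as a third
cross-check; it reports a standard error instead of a quadrature bound.

Numerical choices worth recording:

* **Integration range.** R's noncentral chi-square *quantile* function is
  not accurate at extreme tail probabilities (its upper 1e-10 quantile can
  leave ~1e-6 of mass outside), which would silently cap accuracy. The
  integration range is instead taken from *central* chi-square quantiles at
  Poisson-mixture index bounds: with $J \sim \text{Poisson}(\lambda/2)$ and
  $W \mid J \sim \chi^2(N + 2J)$, central quantiles at the outer $J$ values
  bracket the tails conservatively (mass outside $< 10^{-19}$ at the default
  `tail_mass_cut = 1e-10`).
* **Degenerate branch.** When $d = 0$ (no slope difference, or no predictor
  variance) the mixture collapses to the constant $Na^2/\sigma^2$; power is
  a single noncentral-F probability, and the exact and approximate methods
  coincide identically.
* **Failure is loud.** If a scheme cannot certify its absolute-error
  estimate below the requested tolerance it raises a convergence error
  rather than returning a silently degraded value.
* **Strict rejection.** The rejection rule is `F > critical value`; ties
  have probability zero for continuous data.
* Powers are stored at full precision; 4-decimal rounding happens only in
  printed reports.

## Sample-size search

`min_sample_size()` returns the smallest integer $N$ with power at or above
the target. It doubles from the floor $N_0 = p + 3$ until the target is
bracketed, then bisects — result-identical to an incremental scan from a
small initial value, in $O(\log N)$ power evaluations, and the returned $N$
is certified minimal (`power(N−1) < target` whenever $N > N_0$). The floor
$p + 3$ guarantees $\nu \ge 2$ and $\kappa \ge 2$ so every mixing
distribution is proper; it is configurable. Power is compared to the target
with no epsilon slack — the `1e-8` quadrature tolerance makes 4-decimal
boundary cases deterministic. A zero relevant effect size ($\Delta^* = 0$
for the chosen method) raises a no-solution error; a target at or below
$\alpha$ returns the floor with an explicit warning record.

```{r fetal}
eff <- effect_spec(c(4.1, 0.15), c(4.198, 0.143), 0.095)
prd <- predictor_spec(24.2, 6)
min_sample_size(eff, prd, target_power = 0.80)
min_sample_size(eff, prd, target_power = 0.80, method = "approximate")
```

## What the simulation engine emulates — and what it does not

`simulate_power()` is the empirical counterpart of the analytic engine:
every replicate draws a fresh predictor sample *and* fresh responses,
applies the joint test, and counts rejections, so the rejection proportion
estimates the unconditional power. Replicates run in seed-derived RNG
substreams, making any single replicate reproducible in isolation and all
counts bit-for-bit reproducible. Study grids (`run_validation_study()`,
`validation_grid()`) follow the standard design: intercept and slope
differences both equal to $d \in \{0.3, 0.4, 0.5\}$ against the null
$(0, 1)$, $\sigma^2 = 1$, $\mu_X \in \{0, 0.5, 1\}$,
$\sigma_X^2 \in \{0.5, 1, 2\}$, $\alpha = 0.05$, nominal power 0.90,
10,000 replicates per cell — sizes chosen so each grid runs in tens of
seconds while the Monte Carlo standard error (~0.003 near power 0.9)
resolves the effects of interest.

Non-normal predictor families probe robustness of the normal-theory power
functions. Each is the unique affine map of its source distribution onto
the requested mean and variance: Exponential(1) via $\mu + \sigma(E-1)$,
Gamma(2,1) via $\mu + \sigma(G-2)/\sqrt2$, Laplace via
$\mu + \sigma L/\sqrt2$, Uniform(0,1) via $\mu + \sigma\sqrt{12}(U-1/2)$.
In these runs the skewed exponential family perturbs the achieved power
most (deviations above 0.03 at the smallest sample sizes with
$\sigma_X^2 = 2$), the symmetric families far less.

What passing these simulations does **not** show about real data: errors
are homoscedastic, independent and normal by construction; predictors are
i.i.d. with known moments and measured without error; and the candidate
departures from predictor normality are only the four families above.
A validation study whose covariates are strongly skewed, clustered, or
measured with error is outside what the simulated evidence covers.

## Design choices that were genuinely open

* The mean-substitution comparison and the simulation engine accept any
  `p`, but the non-normal families are implemented for $p = 1$ only — the
  robustness study design is univariate, and a multivariate non-normal
  copula would add assumptions the rest of the package does not use.
* Positive-definiteness of $\Sigma_X$ is enforced by attempted Cholesky
  factorization (symmetry tolerance `1e-10`): a degenerate $\Sigma_X$
  makes $d$ ill-defined as a variance.
* Coefficient vectors are intercept-first everywhere, and the intercept and
  slope *differences* are always recomputed from the two coefficient
  vectors rather than stored, so the specifications cannot drift apart.
* The CLI accepts either a variance (`--sigma2`) or a standard deviation
  (`--sigma`, squared on ingestion); the internal parameterization is the
  variance.

## Known limitations

Analytic power assumes normal predictors; for other families only the
simulation route is available. The exact method, like the approximation,
takes $(\mu_X, \Sigma_X, \sigma^2)$ as known planning inputs — uncertainty
in them is not propagated. Power for slope-only subsets or for the squared
multiple correlation is a different testing problem and is out of scope.
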