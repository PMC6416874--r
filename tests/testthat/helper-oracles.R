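# Shared fixtures and independent oracles for the test suite.
# The Monte Carlo oracles below deliberately use the closed-form simple
# regression algebra (slope = SSXY/SSX etc.) rather than any code path from
# the package, so they can adjudicate the package's analytic power functions.

fetal_effect <- function() effect_spec(c(4.1, 0.15), c(4.198, 0.143), 0.095)
fetal_predictor <- function() predictor_spec(24.2, 6)

# Study-design effect: intercept and slope differences both equal d,
# tested against null coefficients (0, 1), error variance 1.
grid_effect <- function(d) effect_spec(c(d, 1 + d), c(0, 1), 1)

# Standardized predictor draws, duplicated here independently of
# generate_predictors() so moment tests check the package against a second
# transcription of the same affine maps.
oracle_draw <- function(n, family, mu, sx2) {
  s <- sqrt(sx2)
  switch(family,
    normal      = mu + s * rnorm(n),
    exponential = mu + s * (rexp(n) - 1),
    gamma       = mu + s * (rgamma(n, shape = 2, rate = 1) - 2) / sqrt(2),
    laplace     = mu + s * (rexp(n) - rexp(n)) / sqrt(2),
    uniform     = mu + s * sqrt(12) * (runif(n) - 0.5))
}

# Vectorized Monte Carlo power of the joint test for simple regression.
# When fixed_x is supplied the design is held constant across replicates
# (conditional power); otherwise predictors are redrawn each replicate
# (unconditional power). Returns the rejection proportion.
oracle_mc_power <- function(beta, theta, s2, n, alpha, R, seed,
                            mu = NULL, sx2 = NULL, family = "normal",
                            fixed_x = NULL, chunk = 20000L) {
  set.seed(seed)
  crit <- qf(1 - alpha, 2, n - 2)
  rej <- 0L
  done <- 0L
  while (done < R) {
    r <- min(chunk, R - done)
    X <- if (is.null(fixed_x))
      matrix(oracle_draw(n * r, family, mu, sx2), n, r)
    else matrix(fixed_x, n, r)
    Y <- beta[1] + beta[2] * X + matrix(rnorm(n * r, sd = sqrt(s2)), n, r)
    sx <- colSums(X); sy <- colSums(Y)
    xb <- sx / n; yb <- sy / n
    sxx <- colSums(X^2) - n * xb^2
    sxy <- colSums(X * Y) - n * xb * yb
    syy <- colSums(Y^2) - n * yb^2
    bS <- sxy / sxx
    bI <- yb - xb * bS
    s2h <- (syy - sxy^2 / sxx) / (n - 2)
    bID <- bI - theta[1]
    bSD <- bS - theta[2]
    # quadratic form against (X^T X): N*bID^2 + 2*(sum x)*bID*bSD + (sum x^2)*bSD^2
    qf2 <- n * bID^2 + 2 * sx * bID * bSD + colSums(X^2) * bSD^2
    rej <- rej + sum(qf2 / 2 / s2h > crit)
    done <- done + r
  }
  rej / R
}

# A fixed design vector with exactly the requested mean and SSX.
fixed_design_x <- function(n, xbar, ssx) {
  z <- seq_len(n) - (n + 1) / 2
  xbar + z * sqrt(ssx / sum(z^2))
}

mc_se <- function(p, R) sqrt(p * (1 - p) / R)
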