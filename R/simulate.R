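#' Draw random predictor values
#'
#' Generates an `n x p` matrix of predictor values under the specified
#' family, standardized so the population mean and (co)variance match the
#' specification exactly. The non-normal families (simple regression only)
#' are the unique affine transforms of the source distributions matching
#' \eqn{(\mu_X, \sigma_X^2)}:
#' Exponential(1): \eqn{X = \mu + \sigma (E - 1)};
#' Gamma(2, 1): \eqn{X = \mu + \sigma (G - 2)/\sqrt 2};
#' Laplace(scale 1): \eqn{X = \mu + \sigma L/\sqrt 2};
#' Uniform(0, 1): \eqn{X = \mu + \sigma \sqrt{12}\,(U - 1/2)};
#' Normal: \eqn{X = \mu + \sigma Z}.
#'
#' @param predictor A [predictor_spec()]. Families other than normal are
#'   supported only for `p = 1`.
#' @param n Number of observations.
#' @param seed Optional integer seed; when supplied, output is a pure
#'   function of `(predictor, n, seed)`. When `NULL` the current RNG stream
#'   is consumed.
#' @return An `n x p` numeric matrix.
#' @export
generate_predictors <- function(predictor, n, seed = NULL) {
  stopifnot(inherits(predictor, "predictor_spec"))
  n <- check_count(n, "n")
  if (!is.null(seed)) set.seed(seed)
  p <- predictor$p
  if (p > 1L) {
    if (predictor$family != "normal")
      stop_input("non-normal predictor families are only supported for p = 1")
    z <- matrix(stats::rnorm(n * p), n, p)
    return(sweep(z %*% chol(predictor$covariance), 2L, predictor$mean, "+"))
  }
  mu <- predictor$mean
  s <- sqrt(predictor$covariance[1L, 1L])
  x <- switch(predictor$family,
    normal      = mu + s * stats::rnorm(n),
    exponential = mu + s * (stats::rexp(n) - 1),
    gamma       = mu + s * (stats::rgamma(n, shape = 2, rate = 1) - 2) / sqrt(2),
    # difference of two independent Exp(1) draws is standard Laplace
    laplace     = mu + s * (stats::rexp(n) - stats::rexp(n)) / sqrt(2),
    uniform     = mu + s * sqrt(12) * (stats::runif(n) - 0.5))
  matrix(x, ncol = 1L)
}

#' Draw responses from the true regression model
#'
#' Generates \eqn{Y = \beta_I + X \beta_S + \epsilon} with independent
#' \eqn{N(0, \sigma^2)} errors, using the *true* coefficients of the effect
#' specification.
#'
#' @param true_effect An [effect_spec()].
#' @param predictors An `n x p` matrix (as from [generate_predictors()]).
#' @param seed Optional integer seed.
#' @param error_sd Optional override of the error standard deviation;
#'   defaults to `sqrt(true_effect$error_variance)`. Zero is permitted here
#'   (and only here) so deterministic checks can recover the linear
#'   predictor exactly.
#' @return Numeric response vector of length `n`.
#' @export
generate_responses <- function(true_effect, predictors, seed = NULL,
                               error_sd = NULL) {
  stopifnot(inherits(true_effect, "effect_spec"))
  predictors <- as.matrix(predictors)
  if (ncol(predictors) != true_effect$p)
    stop_input("predictor matrix column count does not match the effect specification")
  if (is.null(error_sd)) error_sd <- sqrt(true_effect$error_variance)
  if (!is.numeric(error_sd) || length(error_sd) != 1L || error_sd < 0)
    stop_input("'error_sd' must be a single nonnegative number")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(predictors)
  b <- true_effect$true_coefficients
  drop(b[1L] + predictors %*% b[-1L]) + stats::rnorm(n, sd = error_sd)
}

# Core least-squares fit and joint F statistic; shared by joint_f_test()
# and the simulation loop. theta is the full null coefficient vector.
joint_f_core <- function(X, y, theta) {
  n <- nrow(X)
  p <- ncol(X) - 1L
  fit <- stats::.lm.fit(X, y)
  if (fit$rank < ncol(X))
    stop_input("design matrix is rank deficient (singular design)")
  bhat <- fit$coefficients
  sse <- sum(fit$residuals^2)
  nu <- n - p - 1L
  s2hat <- sse / nu
  if (s2hat <= 0)
    stop_input("zero residual variance: responses are an exact linear function of the predictors")
  diffv <- bhat - theta
  xtx <- crossprod(X)
  fstat <- drop(crossprod(diffv, xtx %*% diffv)) / (p + 1L) / s2hat
  list(bhat = bhat, sse = sse, s2hat = s2hat, nu = nu, fstat = fstat,
       xtx = xtx)
}

#' Joint F test of intercept and slope coefficients
#'
#' Tests whether the full coefficient vector (intercept and all slopes)
#' equals the hypothesized values, via the general-linear-hypothesis
#' statistic
#' \deqn{F = \frac{(\hat\beta - \theta)^T (X^T X)(\hat\beta - \theta)/(p+1)}
#'   {\hat\sigma^2},}
#' which under the null follows a central F with `p + 1` and `n - p - 1`
#' degrees of freedom. Rejection is strict (`F > critical value`).
#'
#' @param predictors `n x p` matrix (or vector for `p = 1`) of predictor
#'   values.
#' @param responses Numeric response vector of length `n`.
#' @param null_coefficients Hypothesized coefficient vector of length
#'   `p + 1`, intercept first.
#' @param alpha Significance level for the reject decision.
#' @return An object of class `"joint_f_test"`: coefficient and error
#'   variance estimates, the F statistic and degrees of freedom, p-value,
#'   reject indicator, the [design_summary()] of the observed predictors,
#'   and the unscaled coefficient covariance factor \eqn{(X^T X)^{-1}}.
#' @examples
#' x <- c(-1, 0, 1, 0); y <- c(-1, 1, 1, -1)
#' joint_f_test(x, y, c(0, 0))
#' @export
joint_f_test <- function(predictors, responses, null_coefficients,
                         alpha = 0.05) {
  predictors <- as.matrix(predictors)
  n <- nrow(predictors)
  p <- ncol(predictors)
  if (!is.numeric(responses) || length(responses) != n)
    stop_input("'responses' must be a numeric vector with one value per predictor row")
  if (!is.numeric(null_coefficients) || length(null_coefficients) != p + 1L)
    stop_input(sprintf("'null_coefficients' must have length p + 1 = %d", p + 1L))
  if (n < p + 2L)
    stop_input(sprintf("need n >= p + 2 = %d observations for positive residual degrees of freedom", p + 2L))
  check_scalar_prob(alpha, "alpha")
  X <- cbind(1, predictors)
  core <- joint_f_core(X, responses, null_coefficients)
  df1 <- p + 1L
  crit <- stats::qf(alpha, df1, core$nu, lower.tail = FALSE)
  xbar <- colMeans(predictors)
  scat <- crossprod(sweep(predictors, 2L, xbar))
  structure(
    list(coefficient_estimates = core$bhat,
         error_variance_estimate = core$s2hat,
         f_statistic = core$fstat,
         numerator_df = df1, denominator_df = core$nu,
         p_value = stats::pf(core$fstat, df1, core$nu, lower.tail = FALSE),
         alpha = alpha, critical_value = crit,
         reject = core$fstat > crit,
         null_coefficients = as.numeric(null_coefficients),
         design_summary = design_summary(xbar, scat, n),
         covariance_factor = solve(core$xtx)),
    class = "joint_f_test"
  )
}

#' @export
print.joint_f_test <- function(x, digits = 4, ...) {
  cat("Joint F test of intercept and slope coefficients\n")
  cat(sprintf("  F = %.*f on (%d, %d) df, p-value = %.4g\n", digits,
              x$f_statistic, x$numerator_df, x$denominator_df, x$p_value))
  cat(sprintf("  H0 coefficients: %s\n",
              paste(format(x$null_coefficients), collapse = ", ")))
  cat(sprintf("  estimates:       %s\n",
              paste(format(round(x$coefficient_estimates, digits)),
                    collapse = ", ")))
  cat(sprintf("  decision at alpha = %s: %s\n", format(x$alpha),
              if (x$reject) "reject H0" else "do not reject H0"))
  invisible(x)
}

#' Monte Carlo power of the joint test under random predictors
#'
#' Estimates the unconditional power empirically: each replicate draws a
#' fresh predictor sample from the specified distribution *and* fresh
#' responses from the true model, applies the joint F test against the null
#' coefficients, and the empirical power is the rejection proportion.
#' Regenerating the predictors every replicate is what makes this the
#' empirical counterpart of the unconditional (random-design) power.
#'
#' Each replicate runs in its own RNG substream: replicate seeds are derived
#' from the master `seed`, so any single replicate can be reproduced in
#' isolation and results are bit-for-bit reproducible.
#'
#' @param true_effect An [effect_spec()] (true coefficients generate the
#'   data; its null coefficients are ignored here).
#' @param null_coefficients Hypothesized coefficient vector for the test.
#' @param predictor A [predictor_spec()]; any supported family.
#' @param n Per-replicate sample size.
#' @param alpha Significance level.
#' @param replicates Number of Monte Carlo replicates.
#' @param seed Master integer seed.
#' @return An object of class `"simulation_result"`: `replicates`,
#'   `rejections`, `empirical_power`, `mc_standard_error`
#'   (\eqn{\sqrt{\hat p(1-\hat p)/R}}), `seed`, and `config_echo`.
#' @export
simulate_power <- function(true_effect, null_coefficients, predictor, n,
                           alpha = 0.05, replicates = 10000, seed = 1) {
  stopifnot(inherits(true_effect, "effect_spec"),
            inherits(predictor, "predictor_spec"))
  if (!is.numeric(null_coefficients) ||
      length(null_coefficients) != true_effect$p + 1L)
    stop_input("'null_coefficients' must have length p + 1")
  n <- check_count(n, "n", min = true_effect$p + 2L)
  check_scalar_prob(alpha, "alpha")
  replicates <- check_count(replicates, "replicates")
  seed <- check_count(seed, "seed", min = 0L)

  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, replicates, replace = TRUE)
  df1 <- true_effect$p + 1L
  nu <- n - true_effect$p - 1L
  crit <- stats::qf(alpha, df1, nu, lower.tail = FALSE)
  theta <- as.numeric(null_coefficients)

  rejections <- 0L
  for (k in seq_len(replicates)) {
    set.seed(rep_seeds[k])
    xmat <- generate_predictors(predictor, n)
    if (max(xmat) == min(xmat))
      stop_input("degenerate replicate: predictor sample has zero variance")
    y <- generate_responses(true_effect, xmat)
    core <- joint_f_core(cbind(1, xmat), y, theta)
    if (core$fstat > crit) rejections <- rejections + 1L
  }
  phat <- rejections / replicates
  structure(
    list(replicates = replicates, rejections = rejections,
         empirical_power = phat,
         mc_standard_error = sqrt(phat * (1 - phat) / replicates),
         seed = seed,
         config_echo = list(true_coefficients = true_effect$true_coefficients,
                            null_coefficients = theta,
                            error_variance = true_effect$error_variance,
                            predictor_mean = predictor$mean,
                            predictor_covariance = predictor$covariance,
                            family = predictor$family,
                            n = n, alpha = alpha)),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, digits = 4, ...) {
  cat("Monte Carlo power estimate\n")
  cat(sprintf("  %d rejections in %d replicates (family = %s, n = %d)\n",
              x$rejections, x$replicates, x$config_echo$family,
              x$config_echo$n))
  cat(sprintf("  empirical power = %.*f (MC SE %.4f), seed = %d\n", digits,
              x$empirical_power, x$mc_standard_error, x$seed))
  invisible(x)
}

#' Configuration grid for the validation study
#'
#' Builds the standard study grid: intercept and slope differences both
#' equal to `d`, predictor mean and variance crossed over the supplied
#' values, variance varying fastest. With the defaults this is the nine-cell
#' design at `d = 0.3`.
#'
#' @param d Common intercept/slope coefficient difference (one value).
#' @param mu_x Predictor means.
#' @param sigma2_x Predictor variances.
#' @param family Predictor family for the simulated column.
#' @return A data frame with columns `mu_x`, `sigma2_x`, `d`, `family`.
#' @export
validation_grid <- function(d = 0.3, mu_x = c(0, 0.5, 1),
                            sigma2_x = c(0.5, 1, 2), family = "normal") {
  g <- expand.grid(sigma2_x = sigma2_x, mu_x = mu_x,
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(mu_x = g$mu_x, sigma2_x = g$sigma2_x, d = d,
             family = family, stringsAsFactors = FALSE)
}

#' Run an analytic-versus-simulated power validation study
#'
#' For each grid row: builds the effect (`true = null + (d, d)` against the
#' null coefficients), finds the exact method's minimal sample size for the
#' target power, evaluates the exact and approximate analytic powers at that
#' size, and estimates the empirical power by Monte Carlo under the row's
#' predictor family. The analytic columns (`n`, `power_exact`,
#' `power_approx`) are deterministic and do not depend on `seed`.
#'
#' @param grid Data frame with columns `mu_x`, `sigma2_x`, `d`, and
#'   optionally `family` (default `"normal"`); see [validation_grid()].
#' @param target_power Nominal power for the sample-size column.
#' @param alpha Significance level.
#' @param replicates Monte Carlo replicates per cell.
#' @param seed Master seed; per-row substream seeds are derived from it.
#' @param error_variance Error variance shared by all cells.
#' @param null_coefficients Null (hypothesized) coefficient vector.
#' @param quad A [quadrature_spec()] for the exact computations.
#' @return A data frame with one row per configuration and columns `mu_x`,
#'   `sigma2_x`, `family`, `d`, `n`, `power_simulated`, `power_exact`,
#'   `error_exact`, `power_approx`, `error_approx`, where each error column
#'   is the analytic estimate minus the simulated power.
#' @export
run_validation_study <- function(grid, target_power = 0.90, alpha = 0.05,
                                 replicates = 10000, seed = 1,
                                 error_variance = 1,
                                 null_coefficients = c(0, 1),
                                 quad = quadrature_spec()) {
  if (!is.data.frame(grid) ||
      !all(c("mu_x", "sigma2_x", "d") %in% names(grid)))
    stop_input("'grid' must be a data frame with columns mu_x, sigma2_x, d")
  if (is.null(grid$family)) grid$family <- "normal"
  seed <- check_count(seed, "seed", min = 0L)
  set.seed(seed)
  row_seeds <- sample.int(.Machine$integer.max, nrow(grid), replace = TRUE)

  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    d <- grid$d[i]
    eff <- effect_spec(null_coefficients + c(d, d), null_coefficients,
                       error_variance)
    prd_normal <- predictor_spec(grid$mu_x[i], grid$sigma2_x[i])
    nres <- min_sample_size(eff, prd_normal, alpha, target_power,
                            method = "exact", quad = quad)
    p_exact <- nres$attained_power
    p_approx <- power_approx(eff, prd_normal, nres$n, alpha)$power
    prd_sim <- predictor_spec(grid$mu_x[i], grid$sigma2_x[i],
                              family = grid$family[i])
    sim <- simulate_power(eff, null_coefficients, prd_sim, nres$n, alpha,
                          replicates, row_seeds[i])
    out[[i]] <- data.frame(
      mu_x = grid$mu_x[i], sigma2_x = grid$sigma2_x[i],
      family = grid$family[i], d = d, n = nres$n,
      power_simulated = sim$empirical_power,
      power_exact = p_exact,
      error_exact = p_exact - sim$empirical_power,
      power_approx = p_approx,
      error_approx = p_approx - sim$empirical_power,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
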