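#' Effect specification for the joint intercept-slope test
#'
#' Bundles the true regression coefficients, the hypothesized (null)
#' coefficients, and the error variance of the linear model
#' \eqn{Y = \beta_I + X^T \beta_S + \epsilon}, \eqn{\epsilon \sim N(0, \sigma^2)}.
#' Coefficient vectors are intercept-first, so a model with `p` slope
#' predictors is described by vectors of length `p + 1`.
#'
#' The intercept and slope differences (true minus null) that drive every
#' noncentrality computation are never stored; they are recomputed on demand
#' by [coefficient_differences()] so the two coefficient vectors remain the
#' single source of truth.
#'
#' @param true_coefficients Numeric vector of length `p + 1`, intercept first:
#'   the coefficients assumed to hold in the population under study.
#' @param null_coefficients Numeric vector of the same length: the published
#'   or postulated coefficients being validated.
#' @param error_variance Positive scalar, the error variance \eqn{\sigma^2}
#'   (a variance, not a standard deviation).
#' @return An object of class `"effect_spec"` with elements
#'   `true_coefficients`, `null_coefficients`, `error_variance`, and `p`.
#' @examples
#' effect_spec(c(4.1, 0.15), c(4.198, 0.143), 0.095)
#' @export
effect_spec <- function(true_coefficients, null_coefficients, error_variance) {
  if (!is.numeric(true_coefficients) || !is.numeric(null_coefficients) ||
      anyNA(true_coefficients) || anyNA(null_coefficients) ||
      any(!is.finite(true_coefficients)) || any(!is.finite(null_coefficients)))
    stop_input("coefficient vectors must be finite numeric vectors")
  if (length(true_coefficients) != length(null_coefficients))
    stop_input("'true_coefficients' and 'null_coefficients' must have the same length")
  if (length(true_coefficients) < 2L)
    stop_input("coefficient vectors must have length >= 2 (intercept plus at least one slope)")
  if (!is.numeric(error_variance) || length(error_variance) != 1L ||
      !is.finite(error_variance) || error_variance <= 0)
    stop_input("'error_variance' must be a single positive number (a variance, sigma^2)")
  structure(
    list(
      true_coefficients = as.numeric(true_coefficients),
      null_coefficients = as.numeric(null_coefficients),
      error_variance = as.numeric(error_variance),
      p = length(true_coefficients) - 1L
    ),
    class = "effect_spec"
  )
}

#' Intercept and slope differences of an effect specification
#'
#' @param effect An [effect_spec()].
#' @return A list with `intercept` (scalar difference, true minus null) and
#'   `slope` (length-`p` vector of slope differences).
#' @export
coefficient_differences <- function(effect) {
  stopifnot(inherits(effect, "effect_spec"))
  d <- effect$true_coefficients - effect$null_coefficients
  list(intercept = d[1L], slope = d[-1L])
}

#' @export
print.effect_spec <- function(x, ...) {
  d <- coefficient_differences(x)
  cat("Effect specification (p =", x$p, "slope predictor(s))\n")
  cat("  true coefficients: ", paste(format(x$true_coefficients), collapse = ", "), "\n")
  cat("  null coefficients: ", paste(format(x$null_coefficients), collapse = ", "), "\n")
  cat("  differences:        intercept", format(d$intercept),
      " slope", paste(format(d$slope), collapse = ", "), "\n")
  cat("  error variance:    ", format(x$error_variance), "\n")
  invisible(x)
}

#' Predictor distribution specification
#'
#' Describes the population distribution of the predictor variables: mean
#' vector, covariance (a scalar variance when `p = 1`), and the distribution
#' family. The analytic power functions are derived under normally distributed
#' predictors and refuse any other family; the non-normal families
#' (`exponential`, `gamma`, `laplace`, `uniform`) exist only for the
#' simulation engine, which standardizes them to the requested mean and
#' variance (see [generate_predictors()]).
#'
#' @param mean Numeric vector of length `p`: predictor mean \eqn{\mu_X}.
#' @param covariance Either a positive scalar (the variance
#'   \eqn{\sigma_X^2} when `p = 1`) or a `p x p` symmetric positive-definite
#'   matrix \eqn{\Sigma_X}. Symmetry is checked to 1e-10 and definiteness by
#'   Cholesky factorization.
#' @param family Distribution family label; one of `"normal"`,
#'   `"exponential"`, `"gamma"`, `"laplace"`, `"uniform"`. Defaults to normal.
#' @return An object of class `"predictor_spec"` with elements `mean`,
#'   `covariance` (always a matrix), `family`, and `p`.
#' @examples
#' predictor_spec(24.2, 6)                    # scalar convenience, p = 1
#' predictor_spec(c(0, 0), diag(2))           # bivariate predictors
#' @export
predictor_spec <- function(mean, covariance,
                           family = c("normal", "exponential", "gamma",
                                      "laplace", "uniform")) {
  family <- match.arg(family)
  if (!is.numeric(mean) || length(mean) < 1L || anyNA(mean) ||
      any(!is.finite(mean)))
    stop_input("'mean' must be a finite numeric vector")
  p <- length(mean)
  if (is.numeric(covariance) && is.null(dim(covariance)) &&
      length(covariance) == 1L) {
    if (p != 1L)
      stop_input("scalar 'covariance' is only allowed when 'mean' has length 1")
    covariance <- matrix(covariance, 1L, 1L)
  }
  if (!is.matrix(covariance) || !is.numeric(covariance) ||
      any(!is.finite(covariance)))
    stop_input("'covariance' must be a finite numeric matrix (or a scalar when p = 1)")
  if (nrow(covariance) != p || ncol(covariance) != p)
    stop_input(sprintf("'covariance' must be %d x %d to match 'mean'", p, p))
  if (max(abs(covariance - t(covariance))) > 1e-10)
    stop_input("'covariance' must be symmetric (tolerance 1e-10)")
  ok <- tryCatch({ chol(covariance); TRUE }, error = function(e) FALSE)
  if (!ok)
    stop_input("'covariance' must be positive definite (Cholesky factorization failed)")
  structure(
    list(mean = as.numeric(mean), covariance = covariance,
         family = family, p = p),
    class = "predictor_spec"
  )
}

#' @export
print.predictor_spec <- function(x, ...) {
  cat("Predictor specification (p =", x$p, ", family =", x$family, ")\n")
  cat("  mean:      ", paste(format(x$mean), collapse = ", "), "\n")
  if (x$p == 1L) {
    cat("  variance:  ", format(x$covariance[1L, 1L]), "\n")
  } else {
    cat("  covariance:\n")
    print(x$covariance)
  }
  invisible(x)
}

#' Observed design summary for conditional power
#'
#' Summarizes a realized set of predictor values by the statistics that the
#' joint test's conditional distribution depends on: the predictor mean
#' vector, and the centered scatter (cross-product) matrix — `SSX` in simple
#' regression, \eqn{A = \sum_i (X_i - \bar X)(X_i - \bar X)^T} in general.
#'
#' @param xbar Numeric vector of length `p`: observed predictor mean.
#' @param scatter Scalar `SSX` (when `p = 1`) or `p x p` symmetric positive
#'   semi-definite scatter matrix.
#' @param n Integer sample size; must satisfy `n >= p + 2` so the residual
#'   degrees of freedom are positive.
#' @return An object of class `"design_summary"`.
#' @export
design_summary <- function(xbar, scatter, n) {
  if (!is.numeric(xbar) || length(xbar) < 1L || any(!is.finite(xbar)))
    stop_input("'xbar' must be a finite numeric vector")
  p <- length(xbar)
  if (is.numeric(scatter) && is.null(dim(scatter)) && length(scatter) == 1L) {
    if (p != 1L) stop_input("scalar 'scatter' is only allowed when p = 1")
    scatter <- matrix(scatter, 1L, 1L)
  }
  if (!is.matrix(scatter) || nrow(scatter) != p || ncol(scatter) != p ||
      any(!is.finite(scatter)))
    stop_input(sprintf("'scatter' must be a finite %d x %d matrix", p, p))
  if (max(abs(scatter - t(scatter))) > 1e-10)
    stop_input("'scatter' must be symmetric (tolerance 1e-10)")
  if (min(eigen(scatter, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop_input("'scatter' must be positive semi-definite")
  n <- check_count(n, "n", min = p + 2L)
  structure(list(xbar = as.numeric(xbar), scatter = scatter, n = n, p = p),
            class = "design_summary")
}

#' @export
print.design_summary <- function(x, ...) {
  cat("Design summary: n =", x$n, ", p =", x$p, "\n")
  cat("  xbar:   ", paste(format(x$xbar), collapse = ", "), "\n")
  if (x$p == 1L) cat("  SSX:    ", format(x$scatter[1L, 1L]), "\n")
  else { cat("  scatter matrix:\n"); print(x$scatter) }
  invisible(x)
}

#' Two-stage mixture representation of the random-design noncentrality
#'
#' Under normal predictors the noncentrality of the joint test can be written
#' \eqn{\Delta = \{N(a + bZ)^2 + dK\}/\sigma^2} with \eqn{Z \sim N(0,1)} and
#' \eqn{K \sim \chi^2(\kappa)} independent, where
#' \eqn{a = \beta_{ID} + \beta_{SD}^T \mu_X},
#' \eqn{d = \beta_{SD}^T \Sigma_X \beta_{SD}}, \eqn{b = (d/N)^{1/2}},
#' \eqn{\kappa = N - 1}, and \eqn{\nu = N - p - 1}. This function computes
#' those parameters; the exact power function integrates over `(Z, K)`.
#'
#' @param effect An [effect_spec()].
#' @param predictor A [predictor_spec()] with `family = "normal"`.
#' @param n Integer sample size, at least `p + 2`.
#' @return An object of class `"mixture_representation"`: a list with
#'   elements `a`, `b`, `d`, `kappa`, `nu`, `n`, `p`, `sigma2`.
#' @export
mixture_representation <- function(effect, predictor, n) {
  stopifnot(inherits(effect, "effect_spec"),
            inherits(predictor, "predictor_spec"))
  if (effect$p != predictor$p)
    stop_input("effect and predictor specifications disagree on the number of predictors")
  if (predictor$family != "normal")
    stop_unsupported(
      "the two-stage mixture representation is derived for normal predictors; set family = \"normal\"")
  n <- check_count(n, "n", min = effect$p + 2L)
  dd <- coefficient_differences(effect)
  a <- dd$intercept + sum(dd$slope * predictor$mean)
  d <- drop(crossprod(dd$slope, predictor$covariance %*% dd$slope))
  d <- max(d, 0)  # guard tiny negative round-off from the quadratic form
  structure(
    list(a = a, b = sqrt(d / n), d = d, kappa = n - 1L,
         nu = n - effect$p - 1L, n = n, p = effect$p,
         sigma2 = effect$error_variance),
    class = "mixture_representation"
  )
}

#' @export
print.mixture_representation <- function(x, ...) {
  cat("Mixture representation of the noncentrality (n =", x$n, ")\n")
  cat("  a =", format(x$a), " b =", format(x$b), " d =", format(x$d), "\n")
  cat("  kappa =", x$kappa, " nu =", x$nu, " sigma2 =", format(x$sigma2), "\n")
  invisible(x)
}

#' Conditional noncentrality for an observed design
#'
#' Computes the noncentrality parameter of the joint test statistic's
#' distribution conditional on the observed predictor values:
#' \deqn{\Delta = \{N(\beta_{ID} + \beta_{SD}^T \bar X)^2 +
#'   \beta_{SD}^T A \beta_{SD}\}/\sigma^2,}
#' where \eqn{A} is the centered predictor scatter matrix (`SSX` when
#' `p = 1`). Depends on the data only through `xbar` and `scatter`.
#'
#' @param effect An [effect_spec()].
#' @param design A [design_summary()].
#' @return Nonnegative scalar noncentrality.
#' @export
conditional_noncentrality <- function(effect, design) {
  stopifnot(inherits(effect, "effect_spec"), inherits(design, "design_summary"))
  if (effect$p != design$p)
    stop_input("effect and design summaries disagree on the number of predictors")
  dd <- coefficient_differences(effect)
  lin <- dd$intercept + sum(dd$slope * design$xbar)
  quad <- drop(crossprod(dd$slope, design$scatter %*% dd$slope))
  delta <- (design$n * lin^2 + quad) / effect$error_variance
  max(delta, 0)
}

#' Asymptotic effect sizes of the joint test
#'
#' The per-observation (asymptotic) noncentrality of the joint test,
#' \eqn{\Delta^*_{exact} = \{(\beta_{ID} + \beta_{SD}^T \mu_X)^2 +
#' \beta_{SD}^T \Sigma_X \beta_{SD}\}/\sigma^2}, together with the
#' mean-substitution counterpart
#' \eqn{\Delta^*_{approx} = (\beta_{ID} + \beta_{SD}^T \mu_X)^2/\sigma^2}.
#' The approximate effect size can never exceed the exact one; they agree
#' exactly when the slope differences carry no predictor variance
#' (\eqn{\beta_{SD}^T \Sigma_X \beta_{SD} = 0}).
#'
#' @inheritParams mixture_representation
#' @return Named numeric vector with components `exact` and `approximate`.
#' @export
asymptotic_effect_size <- function(effect, predictor) {
  stopifnot(inherits(effect, "effect_spec"),
            inherits(predictor, "predictor_spec"))
  if (effect$p != predictor$p)
    stop_input("effect and predictor specifications disagree on the number of predictors")
  dd <- coefficient_differences(effect)
  a <- dd$intercept + sum(dd$slope * predictor$mean)
  d <- max(drop(crossprod(dd$slope, predictor$covariance %*% dd$slope)), 0)
  c(exact = (a^2 + d) / effect$error_variance,
    approximate = a^2 / effect$error_variance)
}
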