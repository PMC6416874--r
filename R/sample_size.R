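#' Minimal sample size for a target power
#'
#' Smallest integer sample size whose power under the chosen method (exact
#' two-stage mixture or mean-substitution approximation) reaches the target.
#' The search doubles the sample size from the floor `p + 3` until the target
#' is bracketed, then bisects to the minimal integer — result-identical to an
#' incremental scan from the floor, in O(log N) power evaluations. The floor
#' guarantees at least two residual and two scatter degrees of freedom so all
#' mixing distributions are proper.
#'
#' @param effect An [effect_spec()]; the relevant effect size must be nonzero
#'   (otherwise power never exceeds `alpha` and no finite solution exists).
#' @param predictor A [predictor_spec()] with `family = "normal"`.
#' @param alpha Significance level.
#' @param target_power Target power in (0, 1), above `alpha`.
#' @param method `"exact"` or `"approximate"`.
#' @param quad A [quadrature_spec()] used by the exact method.
#' @param n_floor Smallest sample size considered (default `p + 3`).
#' @param n_max Search ceiling; exceeding it raises a no-solution error.
#' @param trace If `TRUE`, record every `(n, power)` evaluation.
#' @return An object of class `"sample_size_result"`: a list with `n`,
#'   `attained_power`, `method`, `target_power`, `alpha`, and (if requested)
#'   `search_trace`.
#' @examples
#' eff <- effect_spec(c(4.1, 0.15), c(4.198, 0.143), 0.095)
#' prd <- predictor_spec(24.2, 6)
#' min_sample_size(eff, prd, target_power = 0.80)
#' @export
min_sample_size <- function(effect, predictor, alpha = 0.05, target_power,
                            method = c("exact", "approximate"),
                            quad = quadrature_spec(),
                            n_floor = NULL, n_max = 1e6, trace = FALSE) {
  stopifnot(inherits(effect, "effect_spec"),
            inherits(predictor, "predictor_spec"))
  method <- match.arg(method)
  check_scalar_prob(alpha, "alpha")
  check_scalar_prob(target_power, "target_power")
  if (is.null(n_floor)) n_floor <- effect$p + 3L
  n_floor <- check_count(n_floor, "n_floor", min = effect$p + 2L)

  es <- asymptotic_effect_size(effect, predictor)
  relevant <- if (method == "exact") es[["exact"]] else es[["approximate"]]
  if (relevant <= 0)
    stop_no_solution(sprintf(
      "the %s method's effect size is zero: power never exceeds alpha, no finite sample size exists",
      method))

  steps <- list()
  pow <- function(n) {
    p <- if (method == "exact")
      power_exact(effect, predictor, n, alpha, quad)$power
    else
      power_approx(effect, predictor, n, alpha)$power
    if (trace) steps[[length(steps) + 1L]] <<- c(n = n, power = p)
    p
  }

  warning_record <- NULL
  if (target_power <= alpha) {
    warning_record <- sprintf(
      "target_power (%g) <= alpha (%g): any sample size suffices; returning the floor n = %d",
      target_power, alpha, n_floor)
    warning(warning_record)
    n_star <- n_floor
    attained <- pow(n_star)
  } else {
    lo <- n_floor
    p_lo <- pow(lo)
    if (p_lo >= target_power) {
      n_star <- lo
      attained <- p_lo
    } else {
      hi <- lo
      p_hi <- p_lo
      repeat {
        hi <- min(2L * hi, as.integer(n_max))
        p_hi <- pow(hi)
        if (p_hi >= target_power) break
        if (hi >= n_max)
          stop_no_solution(sprintf(
            "power is still %.4f below target at the search ceiling n = %g",
            target_power - p_hi, n_max))
      }
      # invariant: pow(lo) < target <= pow(hi)
      while (hi - lo > 1L) {
        mid <- lo + (hi - lo) %/% 2L
        p_mid <- pow(mid)
        if (p_mid >= target_power) { hi <- mid; p_hi <- p_mid }
        else lo <- mid
      }
      n_star <- hi
      attained <- p_hi
    }
  }

  structure(
    list(n = n_star, attained_power = attained, method = method,
         target_power = target_power, alpha = alpha, n_floor = n_floor,
         warning_record = warning_record,
         search_trace = if (trace) do.call(rbind, steps) else NULL),
    class = "sample_size_result"
  )
}

#' @export
print.sample_size_result <- function(x, digits = 4, ...) {
  cat(sprintf("Minimal sample size (%s method)\n", x$method))
  cat(sprintf("  target power %.2f at alpha = %s\n", x$target_power,
              format(x$alpha)))
  cat(sprintf("  n = %d  (attained power %.*f)\n", x$n, digits,
              x$attained_power))
  if (!is.null(x$warning_record)) cat("  note:", x$warning_record, "\n")
  invisible(x)
}
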