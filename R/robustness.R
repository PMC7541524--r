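#' Robustness of inference to replacement of cases
#'
#' Quantifies how much bias an estimated effect could absorb before its
#' inference is invalidated, expressed as the proportion of cases that
#' would have to be replaced with null-hypothesis cases (zero effect) to
#' pull the estimate below its significance threshold. The threshold is
#' `se * t_crit(df, alpha)` (two-sided); the fraction is
#' `max(0, 1 - threshold / |estimate|)`.
#'
#' @param estimate point estimate of the effect.
#' @param se standard error, > 0.
#' @param df degrees of freedom, >= 1. For dyadic regressions the natural
#'   case count is the number of ordered dyads in a year, minus the number
#'   of fixed coefficients.
#' @param alpha two-sided significance level, default 0.05.
#' @param n_cases number of cases the fraction is scaled to (e.g. ordered
#'   dyads per year), >= 1.
#' @return An object of class `robustness_result`: list with `estimate`,
#'   `se`, `df`, `alpha`, `threshold`, `fraction_to_invalidate`,
#'   `cases_to_invalidate`, `n_cases`, and `inference_made` (FALSE when
#'   the estimate does not clear the threshold).
#' @export
rir <- function(estimate, se, df, alpha = 0.05, n_cases = NULL) {
  if (!is.finite(se) || se <= 0) stop("se must be > 0")
  if (!is.finite(df) || df < 1) stop("df must be >= 1")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  if (!is.null(n_cases) && (!is.finite(n_cases) || n_cases < 1)) {
    stop("n_cases must be >= 1")
  }
  threshold <- se * stats::qt(1 - alpha / 2, df)
  inference_made <- abs(estimate) > threshold
  fraction <- if (inference_made) 1 - threshold / abs(estimate) else 0
  structure(list(
    estimate = estimate, se = se, df = df, alpha = alpha,
    threshold = threshold,
    fraction_to_invalidate = fraction,
    cases_to_invalidate = if (is.null(n_cases)) NA_integer_ else
      as.integer(round(fraction * n_cases)),
    n_cases = if (is.null(n_cases)) NA_integer_ else as.integer(n_cases),
    inference_made = inference_made),
    class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  if (!x$inference_made) {
    cat(sprintf(
      "<robustness_result> inference not made at alpha = %.3g (|%.4g| <= threshold %.4g)\n",
      x$alpha, x$estimate, x$threshold))
  } else {
    cat(sprintf(
      "<robustness_result> estimate %.4g (se %.4g): replace %.1f%% of cases%s to invalidate\n",
      x$estimate, x$se, 100 * x$fraction_to_invalidate,
      if (is.na(x$cases_to_invalidate)) "" else
        sprintf(" (%d of %d)", x$cases_to_invalidate, x$n_cases)))
  }
  invisible(x)
}

#' Robustness of inference from posterior draws
#'
#' Uses the posterior mean as the estimate and the time-series standard
#' error of the chain (which accounts for MCMC autocorrelation) as the
#' standard error, then delegates to [rir()].
#'
#' @param draws numeric vector of at least 50 posterior draws of one
#'   coefficient.
#' @param df,alpha,n_cases as in [rir()].
#' @return A `robustness_result`.
#' @export
rir_from_posterior <- function(draws, df, alpha = 0.05, n_cases = NULL) {
  if (length(draws) < 50) stop("need at least 50 draws")
  rir(mean(draws), time_series_se(draws), df, alpha, n_cases)
}
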