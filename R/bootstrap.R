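#' Case-resampling bootstrap confidence interval for the half-maximal
#' concentration
#'
#' Resamples the (concentration, response) points of a fitted series with
#' replacement, refits the 4PL curve to each resample, and takes the
#' percentile interval of the refitted `half_max` values. Resamples with
#' fewer than 4 distinct concentrations, refits that fail, or refits whose
#' dynamic range collapses below the flatness rule are counted as failures;
#' if more than half of the refits fail the interval is deemed unstable and
#' an error is raised.
#'
#' @param fit A converged [fit_4pl()] object with `no_inhibition = FALSE`.
#' @param n_boot Number of bootstrap resamples, >= 100 (default 1000).
#' @param alpha Two-sided miscoverage, default 0.05 (a 95% interval).
#' @param seed Integer seed; required so that intervals are reproducible.
#' @return The `fit` object with `ci`, `ci_alpha` and `n_boot` filled in.
#'   The interval is also available via [confint()].
#' @examples
#' conc <- rep(100 / 2^(0:9), each = 2)
#' set.seed(1)
#' resp <- pmax(0, 1 / (1 + (conc / 10)^2) + rnorm(length(conc), 0, 0.05))
#' fit <- bootstrap_ci(fit_4pl(conc, resp), n_boot = 200, seed = 7)
#' confint(fit)
#' @export
bootstrap_ci <- function(fit, n_boot = 1000, alpha = 0.05, seed) {
  stopifnot(inherits(fit, "fit4pl"))
  if (!is_count(n_boot, min = 100L))
    stop("'n_boot' must be an integer >= 100", call. = FALSE)
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  if (missing(seed))
    stop("'seed' is required for reproducible intervals", call. = FALSE)
  if (fit$no_inhibition || is.na(fit$half_max))
    stop("cannot bootstrap a series with no inhibition signal", call. = FALSE)
  conc <- fit$data$conc
  resp <- fit$data$response
  x <- log10(conc)
  n <- length(conc)
  flat_cut <- fit$flat_threshold * fit$control_level
  hm <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(conc[idx])) < 4L) return(NA_real_)
      z <- tryCatch(.fit4pl_core(x[idx], resp[idx],
                                 hill_bounds = fit$hill_bounds),
                    error = function(e) NULL)
      if (is.null(z) || abs(z$c1) < flat_cut) return(NA_real_)
      10^z$e
    }, numeric(1))
  })
  fail <- mean(is.na(hm))
  if (fail > 0.5)
    stop(sprintf("unstable fit: %.0f%% of bootstrap refits failed",
                 100 * fail), call. = FALSE)
  ci <- stats::quantile(hm, c(alpha / 2, 1 - alpha / 2),
                        na.rm = TRUE, names = FALSE)
  fit$ci <- as.numeric(ci)
  fit$ci_alpha <- alpha
  fit$n_boot <- as.integer(n_boot)
  fit
}
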