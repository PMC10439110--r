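#' Normalize raw plate responses to the control level
#'
#' Divides raw responses (e.g. OD600 at the assay endpoint, or ammonium)
#' by the mean response of control wells containing neither added ion nor
#' phage, so that 1 means "grows like the control" and 0 means no signal.
#'
#' @param raw Numeric vector of raw responses, >= 0.
#' @param control_mean Mean control response, > 0.
#' @return `raw / control_mean`.
#' @examples
#' normalize_responses(c(0.3, 0.6, 0), 0.6)
#' @export
normalize_responses <- function(raw, control_mean) {
  if (!is.numeric(raw) || any(!is.finite(raw)))
    stop("'raw' must be finite numeric", call. = FALSE)
  if (!is_number(control_mean) || control_mean <= 0)
    stop("degenerate control: 'control_mean' must be > 0", call. = FALSE)
  raw / control_mean
}

# Internal parameterization
# -------------------------
# With x = log10(conc), e = log10(half_max) and h = hill > 0, the curve is
#   mu(x) = c0 + c1 / (1 + 10^(h * (x - e)))
# which is linear in (c0, c1) given (e, h). The asymptote as conc -> 0 is
# c0 + c1 and as conc -> Inf is c0, so c1 > 0 is an inhibition curve and
# c1 < 0 a stimulation curve: the sign of the linear coefficient carries the
# direction of the response and a single optimisation covers both. The
# nonlinear profile over (e, h) is minimised by a coarse grid followed by
# box-constrained quasi-Newton refinement.

.fit4pl_rss <- function(par, x, resp) {
  f <- 1 / (1 + 10^(par[2L] * (x - par[1L])))
  z <- .lm.fit(cbind(1, f), resp)
  sum(z$residuals^2)
}

.fit4pl_core <- function(x, resp, hill_bounds = c(0.2, 10),
                         e_bounds = NULL) {
  if (is.null(e_bounds)) e_bounds <- c(min(x) - 1, max(x) + 1)
  e_grid <- unique(c(seq(min(x), max(x), length.out = 9L)))
  h_grid <- c(0.3, 0.5, 1, 2, 4, 8)
  best <- c(stats::median(x), 1)
  best_rss <- Inf
  for (e in e_grid) for (h in h_grid) {
    r <- .fit4pl_rss(c(e, h), x, resp)
    if (r < best_rss) { best_rss <- r; best <- c(e, h) }
  }
  o <- stats::optim(best, .fit4pl_rss, x = x, resp = resp,
                    method = "L-BFGS-B",
                    lower = c(e_bounds[1L], hill_bounds[1L]),
                    upper = c(e_bounds[2L], hill_bounds[2L]),
                    control = list(factr = 10, pgtol = 1e-14,
                                   ndeps = rep(1e-7, 2L), maxit = 300L))
  f <- 1 / (1 + 10^(o$par[2L] * (x - o$par[1L])))
  z <- .lm.fit(cbind(1, f), resp)
  list(e = o$par[1L], h = o$par[2L],
       c0 = z$coefficients[1L], c1 = z$coefficients[2L],
       rss = sum(z$residuals^2), convergence = o$convergence)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of the 4PL model
#' \deqn{y = bottom + \frac{top - bottom}{1 + (c / c_{50})^{hill}}}
#' to normalized response vs ion concentration, on a log10 concentration
#' scale. `half_max` is the IC50 when the series was measured without
#' phage (direct ion toxicity) and the EC50 when measured with phage (ion
#' requirement for lytic infection). Both response directions are handled:
#' a decreasing curve is an inhibition fit, an increasing curve a
#' stimulation fit (e.g. phage protection against metal toxicity), and the
#' better-fitting direction is kept.
#'
#' Zero-concentration wells are excluded from the regression (they are used
#' only for normalization, see [normalize_responses()]). If the fitted
#' dynamic range `|top - bottom|` is below `flat_threshold` times the
#' control level, or all responses are equal, the series is reported as
#' showing no inhibition (`no_inhibition = TRUE`, `half_max = NA`) rather
#' than an extrapolated half-maximal concentration.
#'
#' @param x Concentrations (mM) or a formula `response ~ conc`.
#' @param response Numeric responses (same length as `x`), finite, >= 0.
#' @param data Data frame for the formula method.
#' @param controls Optional normalized control responses at concentration 0
#'   (stored on the object; their mean defines the control level for the
#'   flatness rule; defaults to 1, i.e. responses already normalized).
#' @param ion,phage Optional labels carried through to downstream tables.
#' @param hill_bounds Bounds for the hill slope, default `c(0.2, 10)`.
#' @param flat_threshold Minimum dynamic range, as a fraction of the
#'   control level, below which the series is called flat (default 0.2).
#' @param ... Passed between methods.
#' @return An object of class `"fit4pl"` with components `half_max`,
#'   `hill`, `top`, `bottom`, `direction` (`"inhibition"` or
#'   `"stimulation"`), `rss`, `converged`, `no_inhibition`, `ci`
#'   (filled by [bootstrap_ci()]), and the data.
#' @seealso [bootstrap_ci()], [call_threshold()], [analyze_plate()]
#' @examples
#' conc <- rep(100 / 2^(0:9), each = 2)
#' resp <- 1 / (1 + (conc / 10)^2)
#' fit <- fit_4pl(conc, resp)
#' coef(fit)
#' @export
fit_4pl <- function(x, ...) UseMethod("fit_4pl")

#' @rdname fit_4pl
#' @export
fit_4pl.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  fit_4pl.default(mf[[2L]], mf[[1L]], ...)
}

#' @rdname fit_4pl
#' @export
fit_4pl.default <- function(x, response, controls = NULL, ion = NULL,
                            phage = NULL, hill_bounds = c(0.2, 10),
                            flat_threshold = 0.2, ...) {
  conc <- x
  if (!is.numeric(conc) || !is.numeric(response) ||
      length(conc) != length(response))
    stop("'x' (conc) and 'response' must be numeric vectors of equal length",
         call. = FALSE)
  if (any(!is.finite(response)) || any(response < 0))
    stop("responses must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and >= 0", call. = FALSE)
  keep <- conc > 0
  conc <- conc[keep]; response <- response[keep]
  if (length(unique(conc)) < 4L)
    stop("insufficient data: need >= 4 distinct nonzero concentrations",
         call. = FALSE)
  control_level <- if (!is.null(controls) && length(controls)) {
    mean(controls)
  } else 1
  cl <- match.call()
  out <- structure(
    list(half_max = NA_real_, hill = NA_real_,
         top = NA_real_, bottom = NA_real_,
         direction = NA_character_, rss = NA_real_,
         converged = FALSE, no_inhibition = FALSE,
         ci = c(NA_real_, NA_real_), ci_alpha = NA_real_, n_boot = NA_integer_,
         data = data.frame(conc = conc, response = response),
         controls = controls, control_level = control_level,
         ion = ion, phage = phage,
         flat_threshold = flat_threshold, hill_bounds = hill_bounds,
         call = cl),
    class = "fit4pl")
  if (length(unique(response)) == 1L) {
    # flat series: no dose dependence at all
    out$top <- out$bottom <- response[1L]
    out$rss <- 0
    out$converged <- TRUE
    out$no_inhibition <- TRUE
    return(out)
  }
  z <- .fit4pl_core(log10(conc), response, hill_bounds = hill_bounds)
  out$rss <- z$rss
  out$converged <- z$convergence == 0L
  out$hill <- z$h
  out$top <- max(z$c0, z$c0 + z$c1)
  out$bottom <- min(z$c0, z$c0 + z$c1)
  out$direction <- if (z$c1 >= 0) "inhibition" else "stimulation"
  if (abs(z$c1) < flat_threshold * control_level) {
    out$no_inhibition <- TRUE
    return(out)
  }
  out$half_max <- 10^z$e
  out
}

# Predicted mean response of a fitted curve at given concentrations.
fit4pl_curve <- function(object, conc) {
  if (object$no_inhibition || is.na(object$half_max)) {
    level <- if (is.na(object$top)) mean(object$data$response) else
      (object$top + object$bottom) / 2
    if (object$no_inhibition && !is.na(object$top) &&
        object$top == object$bottom) level <- object$top
    return(rep(level, length(conc)))
  }
  f <- 1 / (1 + (conc / object$half_max)^object$hill)
  if (object$direction == "inhibition") {
    object$bottom + (object$top - object$bottom) * f
  } else {
    object$top + (object$bottom - object$top) * f
  }
}

#' @export
print.fit4pl <- function(x, digits = 4, ...) {
  lab <- paste0(if (!is.null(x$ion)) paste0(x$ion, ", ") else "",
                if (!is.null(x$phage)) paste0("phage = ", x$phage) else "")
  cat("<fit4pl>", if (nzchar(lab)) paste0("[", lab, "]"), "\n")
  if (x$no_inhibition) {
    cat("  no inhibition within tested range (dynamic range below",
        format(x$flat_threshold * x$control_level, digits = digits),
        ")\n")
  } else {
    cat(sprintf("  half_max: %s mM  (%s)\n",
                format(x$half_max, digits = digits), x$direction))
    if (!any(is.na(x$ci)))
      cat(sprintf("  %g%% CI: [%s, %s] mM (%d bootstrap refits)\n",
                  100 * (1 - x$ci_alpha), format(x$ci[1L], digits = digits),
                  format(x$ci[2L], digits = digits), x$n_boot))
    cat(sprintf("  hill: %s   top: %s   bottom: %s   rss: %s\n",
                format(x$hill, digits = digits),
                format(x$top, digits = digits),
                format(x$bottom, digits = digits),
                format(x$rss, digits = digits)))
  }
  invisible(x)
}

#' @export
coef.fit4pl <- function(object, ...) {
  c(top = object$top, bottom = object$bottom,
    hill = object$hill, half_max = object$half_max)
}

#' @export
summary.fit4pl <- function(object, ...) {
  n <- nrow(object$data)
  res <- stats::residuals(object)
  structure(
    list(fit = object, n = n,
         sigma = sqrt(object$rss / max(1L, n - 4L)),
         range = range(object$data$conc)),
    class = "summary.fit4pl")
}

#' @export
print.summary.fit4pl <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("  n = %d points over %s-%s mM, residual sd = %s\n",
              x$n, format(x$range[1L], digits = 3),
              format(x$range[2L], digits = 3),
              format(x$sigma, digits = digits)))
  invisible(x)
}

#' @export
predict.fit4pl <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) {
    object$data$conc
  } else if (is.data.frame(newdata)) {
    newdata$conc
  } else {
    newdata
  }
  if (is.null(conc) || !is.numeric(conc))
    stop("'newdata' must be numeric concentrations or have a 'conc' column",
         call. = FALSE)
  fit4pl_curve(object, conc)
}

#' @export
fitted.fit4pl <- function(object, ...) fit4pl_curve(object, object$data$conc)

#' @export
residuals.fit4pl <- function(object, ...) {
  object$data$response - fitted(object)
}

#' @export
simulate.fit4pl <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- fitted(object)
  sigma <- sqrt(object$rss / max(1L, nrow(object$data) - 4L))
  gen <- function() pmax(0, mu + stats::rnorm(length(mu), 0, sigma))
  sims <- if (is.null(seed)) {
    replicate(nsim, gen(), simplify = FALSE)
  } else {
    with_seed(seed, replicate(nsim, gen(), simplify = FALSE))
  }
  out <- as.data.frame(sims, col.names = paste0("sim_", seq_len(nsim)))
  attr(out, "conc") <- object$data$conc
  out
}

#' @export
plot.fit4pl <- function(x, n_curve = 200, ...) {
  d <- x$data
  graphics::plot(d$conc, d$response, log = "x",
                 xlab = "concentration (mM)",
                 ylab = "normalized response",
                 main = paste0(x$ion %||% "dose-response",
                               if (!is.null(x$phage)) paste0(" (", x$phage, ")")),
                 ...)
  cg <- 10^seq(log10(min(d$conc)), log10(max(d$conc)), length.out = n_curve)
  graphics::lines(cg, fit4pl_curve(x, cg), col = "firebrick", lwd = 2)
  if (!x$no_inhibition)
    graphics::abline(v = x$half_max, lty = 2, col = "grey40")
  invisible(x)
}

#' @export
confint.fit4pl <- function(object, parm = "half_max", level = NULL, ...) {
  if (any(is.na(object$ci)))
    stop("no bootstrap interval stored; run bootstrap_ci() first",
         call. = FALSE)
  out <- matrix(object$ci, nrow = 1,
                dimnames = list("half_max",
                                paste0(100 * c(object$ci_alpha / 2,
                                               1 - object$ci_alpha / 2), "%")))
  out
}
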