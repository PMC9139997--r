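# Maximum-likelihood psychometric function fitting. The sigmoid is a
# logistic with lapse and guess bounds:
#   psi(x) = guess + (1 - guess - lapse) * plogis(slope * (x - location))
# For binary responses the fit maximizes the Bernoulli likelihood; for
# continuous ratings it minimizes squared error (Gaussian ML). This is a
# deterministic, bounded MLE summary of sigmoidal trends (slope and
# threshold), deliberately lighter than full Bayesian psychometric fitting.

#' Lapse-bounded logistic psychometric function
#'
#' @param x Stimulus level(s).
#' @param location Threshold (level of the sigmoid midpoint).
#' @param slope Logistic slope.
#' @param lapse,guess Upper/lower asymptote rates.
#' @return `guess + (1 - guess - lapse) * plogis(slope * (x - location))`.
#' @export
psy_fun <- function(x, location, slope, lapse, guess) {
  guess + (1 - guess - lapse) * stats::plogis(slope * (x - location))
}

#' Fit a psychometric function
#'
#' @param step_values Numeric stimulus levels (e.g. morph steps 1--5), one
#'   per response.
#' @param responses Numeric responses: either binary (0/1 choices) or
#'   continuous ratings in `[0, 1]`.
#' @param max_rate Upper bound for the lapse and guess rates.
#' @return List of class `psychometric_fit`: `location`, `slope`, `lapse`,
#'   `guess`, `logLik` (binary) or `sse` (continuous), `converged`, and
#'   `flat` (`TRUE` when the data carry no usable slope, in which case the
#'   fit is returned with a warning rather than an error).
#' @export
#' @examples
#' x <- rep(1:5, each = 20)
#' y <- psy_fun(x, 3, 1.5, 0.02, 0.02)
#' f <- fit_psychometric(x, y)
#' abs(f$slope - 1.5) < 0.05
fit_psychometric <- function(step_values, responses, max_rate = 0.35) {
  x <- as.numeric(step_values); y <- as.numeric(responses)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5L || length(unique(x)) < 2L)
    stop("need >= 5 points spanning >= 2 distinct steps", call. = FALSE)
  if (any(y < 0 | y > 1))
    stop("responses must lie in [0, 1]", call. = FALSE)
  binary <- all(y %in% c(0, 1))
  xr <- range(x); span <- diff(xr)
  eps <- 1e-9
  obj <- function(par) {
    p <- psy_fun(x, par[1], par[2], par[3], par[4])
    if (binary) {
      p <- pmin(pmax(p, eps), 1 - eps)
      -sum(y * log(p) + (1 - y) * log(1 - p))
    } else {
      sum((y - p)^2)
    }
  }
  lower <- c(xr[1] - span, -60 / max(span, eps), 0, 0)
  upper <- c(xr[2] + span, 60 / max(span, eps), max_rate, max_rate)
  starts <- expand.grid(location = stats::quantile(x, c(0.35, 0.5, 0.65)),
                        slope = c(-2, -0.5, 0.5, 2) / max(span / 4, eps),
                        lapse = 0.02, guess = 0.02)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(stats::optim(as.numeric(starts[i, ]), obj, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(maxit = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("psychometric optimization failed", call. = FALSE)
  par <- best$par
  pred_range <- diff(range(psy_fun(sort(unique(x)), par[1], par[2], par[3], par[4])))
  flat <- pred_range < 0.01 || abs(par[2]) * span < 0.05
  if (flat) warning("flat psychometric data: slope is not identified",
                    call. = FALSE)
  structure(
    c(list(location = par[1], slope = par[2], lapse = par[3], guess = par[4]),
      if (binary) list(logLik = -best$value) else list(sse = best$value),
      list(converged = best$convergence == 0, flat = flat, binary = binary)),
    class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit> location %.3f, slope %.3f, lapse %.3f, guess %.3f%s\n",
              x$location, x$slope, x$lapse, x$guess,
              if (x$flat) " [flat]" else ""))
  invisible(x)
}

#' Per-condition psychometric fits of slider responses
#'
#' Convenience wrapper that fits one psychometric function per group of a
#' response table (e.g. by sprouting condition, limb count, or odd/even
#' limb parity), on mean-rating-per-step data.
#'
#' @param responses A `response_table` from [simulate_slider()].
#' @param by Name of the grouping column (`NULL` fits all responses pooled).
#' @return Named list of `psychometric_fit` objects.
#' @export
fit_psychometric_by <- function(responses, by = NULL) {
  groups <- if (is.null(by)) list(all = responses) else
    split(responses, responses[[by]])
  lapply(groups, function(g) fit_psychometric(g$step, g$rating))
}
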