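# Statistical battery: exact one-sided binomial preference tests, one-way
# ANOVA with Tukey HSD post-hoc comparisons, one-sample t-tests, and the
# JZS Bayes factor for a t-contrast (Cauchy prior on effect size).

#' One-sided binomial preference test
#'
#' Tests whether a pooled (or per-participant) choice count exceeds chance.
#'
#' @param K Number of "preferred" responses.
#' @param N Total number of responses (> 0).
#' @param p0 Chance level (0.5 for 2-AFC).
#' @return List with `proportion` (`K/N`), `p_value` (upper-tail exact
#'   binomial probability of `K` or more successes), `K`, `N`.
#' @export
#' @examples
#' binomial_preference(4735, 5200)$proportion  # 0.91
binomial_preference <- function(K, N, p0 = 0.5) {
  if (N <= 0) stop("`N` must be > 0", call. = FALSE)
  if (K < 0 || K > N) stop("`K` must lie in 0..N", call. = FALSE)
  bt <- stats::binom.test(K, N, p = p0, alternative = "greater")
  list(proportion = K / N, p_value = bt$p.value, K = K, N = N)
}

#' One-way ANOVA
#'
#' @param values Numeric response vector (or a list of per-group vectors,
#'   in which case `groups` is ignored).
#' @param groups Factor (or coercible) of group labels, same length as
#'   `values`.
#' @return List with `F`, `df` (numerator, denominator), `p_value`, and the
#'   underlying `aov` fit.
#' @export
one_way_anova <- function(values, groups = NULL) {
  if (is.list(values) && is.null(groups)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values)
  }
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(tabulate(g) < 2L)) stop("every group needs >= 2 values", call. = FALSE)
  if (stats::var(values) == 0)
    stop("degenerate data: zero total variance", call. = FALSE)
  fit <- stats::aov(values ~ g)
  tab <- summary(fit)[[1]]
  list(F = tab[["F value"]][1],
       df = c(tab[["Df"]][1], tab[["Df"]][2]),
       p_value = tab[["Pr(>F)"]][1],
       fit = fit)
}

#' Tukey HSD post-hoc comparisons
#'
#' @inheritParams one_way_anova
#' @return Data frame with one row per group pair: `comparison`, `diff`,
#'   `lwr`, `upr`, `p_adj` (studentized-range adjusted).
#' @export
tukey_posthoc <- function(values, groups = NULL) {
  av <- one_way_anova(values, groups)
  tk <- stats::TukeyHSD(av$fit)$g
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
             row.names = NULL)
}

#' One-sample t-test
#'
#' @param values Numeric vector (length >= 2, non-degenerate).
#' @param mu0 Null-hypothesis mean.
#' @return List with `t`, `df`, `p_value` (two-sided), `mean`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("degenerate data: zero variance", call. = FALSE)
  tt <- stats::t.test(values, mu = mu0)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean = unname(tt$estimate))
}

#' JZS Bayes factor for a one-sample t-contrast
#'
#' Computes `BF10` under the Jeffreys--Zellner--Siow prior: a Cauchy prior
#' with scale `rscale` on the standardized effect size, equivalent to a
#' normal prior with variance `g * rscale^2` mixed over an inverse-gamma
#' `(1/2, 1/2)` prior on `g`. The marginal likelihood ratio is evaluated by
#' adaptive quadrature; values below 1 favor the null.
#'
#' @param t Observed t statistic.
#' @param n Sample size (>= 2); degrees of freedom are `n - 1`.
#' @param rscale Cauchy prior scale on effect size (default 0.707).
#' @return `BF10`, the probability of the data under H1 relative to H0.
#' @export
#' @examples
#' jzs_bayes_factor(0, 100) < 1
jzs_bayes_factor <- function(t, n, rscale = 0.707) {
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  nu <- n - 1
  # integrand on g: likelihood under effect variance g * rscale^2 times the
  # inverse-gamma(1/2, 1/2) prior density
  f <- function(g) {
    a <- 1 + n * g * rscale^2
    a^(-0.5) * (1 + t^2 / (a * nu))^(-(nu + 1) / 2) *
      (2 * pi)^(-0.5) * g^(-1.5) * exp(-1 / (2 * g))
  }
  num <- stats::integrate(f, 0, Inf, rel.tol = 1e-10, abs.tol = 0,
                          stop.on.error = FALSE)
  if (num$message != "OK" || !is.finite(num$value) || num$value <= 0)
    stop("JZS integration failed to converge: ", num$message, call. = FALSE)
  den <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  num$value / den
}
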