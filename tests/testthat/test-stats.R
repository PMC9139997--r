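# Statistical battery vs. brute-force oracles.

test_that("binomial preference matches the exact upper-tail sum", {
  bp <- binomial_preference(4735, 5200)
  expect_equal(bp$proportion, 4735 / 5200)
  # oracle: direct summation of the binomial pmf
  expect_equal(bp$p_value, sum(stats::dbinom(4735:5200, 5200, 0.5)),
               tolerance = 1e-12)
  half <- binomial_preference(50, 100)
  expect_gt(half$p_value, 0.5)
  expect_lt(half$p_value, 0.56)
  expect_error(binomial_preference(5, 0), "N")
  expect_error(binomial_preference(11, 10), "K")
})

test_that("one-way ANOVA matches a direct sums-of-squares decomposition", {
  set.seed(77)
  g <- rep(1:4, each = 12)
  y <- stats::rnorm(48, mean = g / 3)
  res <- one_way_anova(y, g)
  # oracle: explicit SS decomposition
  gm <- mean(y)
  means <- tapply(y, g, mean)
  ssb <- sum(tabulate(g) * (means - gm)^2)
  ssw <- sum((y - means[g])^2)
  Fo <- (ssb / 3) / (ssw / 44)
  expect_equal(res$F, Fo, tolerance = 1e-9)
  expect_equal(res$df, c(3, 44))
  expect_equal(res$p_value, stats::pf(Fo, 3, 44, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("identical groups give F = 0; two groups give squared t", {
  expect_equal(one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))$F, 0)
  set.seed(5)
  a <- stats::rnorm(10); b <- stats::rnorm(12, 0.5)
  res <- one_way_anova(list(a, b))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_error(one_way_anova(list(c(1, 1), c(1, 1))), "degenerate")
  expect_error(one_way_anova(list(c(1, 2))), "2 groups")
})

test_that("Tukey post-hoc matches the studentized-range formula", {
  set.seed(11)
  g <- rep(1:3, each = 15)
  y <- stats::rnorm(45, mean = c(0, 0.4, 0.9)[g])
  tk <- tukey_posthoc(y, g)
  expect_equal(nrow(tk), 3L)
  # oracle: manual Tukey HSD for balanced groups
  ni <- 15; k <- 3; df <- 45 - 3
  means <- tapply(y, g, mean)
  mse <- sum((y - means[g])^2) / df
  se <- sqrt(mse / ni)
  for (r in seq_len(nrow(tk))) {
    ij <- as.integer(strsplit(tk$comparison[r], "-")[[1]])
    dif <- unname(means[ij[1]] - means[ij[2]])
    expect_equal(tk$diff[r], dif, tolerance = 1e-9)
    p <- stats::ptukey(abs(dif) / se, k, df, lower.tail = FALSE)
    expect_equal(tk$p_adj[r], p, tolerance = 1e-9)
  }
})

test_that("one-sample t matches the closed form and flips with reflection", {
  set.seed(21)
  x <- stats::rnorm(30, 0.2)
  res <- one_sample_t(x, 0)
  expect_equal(res$t, mean(x) / (stats::sd(x) / sqrt(30)), tolerance = 1e-12)
  expect_equal(res$df, 29)
  refl <- one_sample_t(-x, 0)
  expect_equal(refl$t, -res$t, tolerance = 1e-12)
  expect_equal(refl$p_value, res$p_value, tolerance = 1e-12)
  expect_error(one_sample_t(rep(1, 5), 1), "degenerate")
})

test_that("JZS Bayes factor favors the null at t = 0 and grows with |t|", {
  expect_lt(jzs_bayes_factor(0, 100), 1)
  bfs <- vapply(c(0, 1, 2, 3, 5), function(t) jzs_bayes_factor(t, 50), 0)
  expect_true(all(diff(bfs) > 0))
  expect_equal(jzs_bayes_factor(-3, 50), jzs_bayes_factor(3, 50),
               tolerance = 1e-9)
})

test_that("JZS Bayes factor matches an independent quadrature oracle", {
  # oracle: trapezoidal quadrature on the bounded substitution u = g/(1+g)
  jzs_oracle <- function(t, n, rscale = 0.707) {
    nu <- n - 1
    u <- seq(1e-9, 1 - 1e-9, length.out = 200001)
    g <- u / (1 - u)
    a <- 1 + n * g * rscale^2
    fg <- a^(-0.5) * (1 + t^2 / (a * nu))^(-(nu + 1) / 2) *
      (2 * pi)^(-0.5) * g^(-1.5) * exp(-1 / (2 * g))
    integrand <- fg / (1 - u)^2
    num <- sum((integrand[-1] + integrand[-length(u)]) / 2) * diff(u[1:2])
    num / (1 + t^2 / nu)^(-(nu + 1) / 2)
  }
  for (t in c(0, 1.5, 3)) for (n in c(10, 60, 550)) {
    expect_equal(jzs_bayes_factor(t, n), jzs_oracle(t, n),
                 tolerance = 1e-6 * jzs_oracle(t, n))
  }
})

test_that("a large t with the experiment's sample size yields decisive evidence", {
  expect_gt(jzs_bayes_factor(28.47, 7700), 1e6)
  expect_lt(jzs_bayes_factor(0.1, 550), 0.1)  # strong evidence for the null
})
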