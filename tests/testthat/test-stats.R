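test_that("one-sample t matches the closed-form df = 2 tail", {
  tr <- t_one_sample(c(1, 2, 3))
  expect_equal(tr$statistic, sqrt(12), tolerance = 1e-10)
  expect_equal(tr$df, 2)
  expect_equal(tr$p_raw, 0.0741799002, tolerance = 1e-8)
  expect_equal(t_one_sample(c(1, 2, 3), alternative = "greater")$p_raw,
               0.0370899501, tolerance = 1e-8)
  sym <- t_one_sample(c(-1, 0, 1))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_raw, 1)
  expect_error(t_one_sample(c(2, 2, 2)), "degenerate")
  expect_error(t_one_sample(1), "n >= 2")
})

test_that("one-sample and Welch t agree with stats::t.test", {
  set.seed(10)
  for (i in 1:10) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1), sd = 2)
    expect_equal(t_one_sample(x, 0.2)$p_raw,
                 t.test(x, mu = 0.2)$p.value)
    expect_equal(t_one_sample(x, alternative = "less")$p_raw,
                 t.test(x, alternative = "less")$p.value)
    expect_equal(t_welch(x, y)$p_raw, t.test(x, y)$p.value)
    expect_equal(t_welch(x, y, "greater")$p_raw,
                 t.test(x, y, alternative = "greater")$p.value)
  }
})

test_that("Holm adjustment follows the step-down definition", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(0.05, 0.05)), c(0.10, 0.10))
  expect_identical(holm_adjust(numeric(0)), numeric(0))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Holm lies between unadjusted and Bonferroni", {
  set.seed(11)
  for (i in 1:30) {
    m <- sample(1:30, 1)
    p <- runif(m)
    h <- holm_adjust(p)
    expect_true(all(h >= p))
    expect_true(all(h <= pmin(1, m * p) + 1e-15))
  }
})

test_that("exact sign test reproduces binomial tail probabilities", {
  expect_equal(sign_test_exact(8, 9, "greater")$p_raw, 10 / 512)
  expect_equal(round(sign_test_exact(8, 9, "greater")$p_raw, 2), 0.02)
  expect_equal(sign_test_exact(1, 1, "greater")$p_raw, 0.5)
  expect_equal(sign_test_exact(5, 5, "greater")$p_raw, 1 / 32)
  expect_equal(sign_test_exact(0, 7, "greater")$p_raw, 1)
  # oracle: stats::binom.test on random cases, all three alternatives
  set.seed(12)
  for (i in 1:20) {
    n <- sample(1:25, 1); k <- sample(0:n, 1)
    expect_equal(sign_test_exact(k, n, "greater")$p_raw,
                 binom.test(k, n, alternative = "greater")$p.value)
    expect_equal(sign_test_exact(k, n, "less")$p_raw,
                 binom.test(k, n, alternative = "less")$p.value)
  }
  # the probability mass sums to one
  expect_equal(sum(dbinom(0:9, 9, 0.5)), 1)
})

test_that("Dunnett with one treatment reduces to the pooled two-sample t", {
  set.seed(13)
  x <- rnorm(6); y <- rnorm(6, 1)
  dt <- dunnett_test(list(trt = y), x, mc_draws = 1e5, seed = 5)[[1]]
  pooled <- t.test(y, x, var.equal = TRUE)$p.value
  expect_equal(dt$p_raw, pooled, tolerance = 1e-10)
  expect_lt(abs(dt$p_adjusted - pooled), 0.005)
})

test_that("Dunnett is null-calibrated, monotone in |t|, and seed-reproducible", {
  groups <- list(a = c(1, 2, 3, 4), b = c(2, 3, 1, 4), c = c(4, 1, 2, 3))
  ctrl <- c(3, 2, 4, 1)
  dt <- dunnett_test(groups, ctrl, mc_draws = 2e4, seed = 3)
  expect_true(all(vapply(dt, function(t) t$p_adjusted, numeric(1)) > 0.99))

  set.seed(14)
  g2 <- list(a = rnorm(4), b = rnorm(4, 1), c = rnorm(4, 3))
  d2 <- dunnett_test(g2, rnorm(4), mc_draws = 5e4, seed = 9)
  stat <- abs(vapply(d2, function(t) t$statistic, numeric(1)))
  padj <- vapply(d2, function(t) t$p_adjusted, numeric(1))
  expect_true(all(diff(padj[order(stat)]) <= 0))

  # same seed, same draws: byte-identical adjusted p-values
  d2b <- dunnett_test(g2, ctrl, mc_draws = 5e4, seed = 9)
  d2c <- dunnett_test(g2, ctrl, mc_draws = 5e4, seed = 9)
  expect_identical(vapply(d2b, function(t) t$p_adjusted, numeric(1)),
                   vapply(d2c, function(t) t$p_adjusted, numeric(1)))

  expect_error(dunnett_test(list(a = 1), c(1, 2)), ">= 2")
  expect_error(dunnett_test(list(a = c(1, 1)), c(1, 1)), "pooled variance")
})

test_that("Dunnett agrees with the multcomp reference on a balanced layout", {
  skip_if_not_installed("multcomp")
  set.seed(15)
  k <- 4; n <- 5
  dat <- data.frame(g = factor(rep(0:k, each = n)),
                    y = rnorm((k + 1) * n) + rep(c(0, 0.5, 1, 1.5, 2),
                                                 each = n))
  groups <- split(dat$y, dat$g)
  dt <- dunnett_test(groups[-1], groups[[1]], mc_draws = 2e5, seed = 21)
  fit <- multcomp::glht(stats::aov(y ~ g, dat),
                        linfct = multcomp::mcp(g = "Dunnett"))
  ref <- summary(fit)$test$pvalues
  mine <- vapply(dt, function(t) t$p_adjusted, numeric(1))
  expect_equal(unname(mine), unname(as.numeric(ref)), tolerance = 0.01)
})

test_that("Tukey HSD matches the pooled t at k = 2 and is null-calibrated", {
  set.seed(16)
  x <- rnorm(5); y <- rnorm(7, 1)
  tk <- tukey_hsd(list(a = x, b = y))[[1]]
  expect_equal(tk$p_adjusted, t.test(x, y, var.equal = TRUE)$p.value,
               tolerance = 1e-6)

  null3 <- tukey_hsd(list(a = c(1, 2, 3), b = c(2, 1, 3), c = c(3, 2, 1)))
  expect_true(all(vapply(null3, function(t) t$p_adjusted, numeric(1)) > 0.9))

  # wiring check against stats::TukeyHSD on a k = 3 unbalanced layout
  g <- list(a = rnorm(4), b = rnorm(6, 1), c = rnorm(5, 2))
  dat <- data.frame(y = unlist(g),
                    f = factor(rep(names(g), lengths(g))))
  ref <- TukeyHSD(aov(y ~ f, dat))$f[, "p adj"]
  mine <- vapply(tukey_hsd(g), function(t) t$p_adjusted, numeric(1))
  expect_equal(sort(unname(mine)), sort(unname(ref)), tolerance = 1e-6)
  expect_error(tukey_hsd(list(a = c(1, 2))), ">= 2")
})

test_that("run_family Holm-adjusts a family in place", {
  one <- run_family(list(t_one_sample(c(1, 2, 3))), "solo")
  expect_equal(one[[1]]$p_adjusted, one[[1]]$p_raw)
  expect_equal(one[[1]]$family_id, "solo")

  ties <- replicate(23, test_result("t_one_sample", "x", "two_sided", 1,
                                    p_raw = 0.001), simplify = FALSE)
  adj <- run_family(ties, "panel")
  expect_equal(vapply(adj, function(t) t$p_adjusted, numeric(1)),
               rep(0.023, 23))

  set.seed(17)
  mixed <- lapply(runif(7), function(p)
    test_result("t_one_sample", "x", "two_sided", 1, p_raw = p))
  got <- run_family(mixed, "f")
  expect_equal(vapply(got, function(t) t$p_adjusted, numeric(1)),
               holm_adjust(vapply(mixed, function(t) t$p_raw, numeric(1))))
})
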