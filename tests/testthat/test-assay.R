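test_that("single-plate estimate matches the closed-form MLE", {
  est <- estimate_population(plate_obs(d = 2, vol = 100, count = 50), 1000)
  expect_equal(est$spores_total, 50000)
  expect_false(est$censored)
})

test_that("pooled estimate equals the Poisson MLE over countable plates", {
  obs <- plate_obs(d = c(1, 2), vol = 100, count = c(100, 8))
  est <- estimate_population(obs, 1000)
  expect_equal(est$spores_total, 108 / 0.011, tolerance = 1e-12)
  # independent oracle: direct numerical maximization of the Poisson
  # likelihood in the total spore count
  f <- c(0.01, 0.001)
  nll <- function(N) -sum(dpois(c(100, 8), N * f, log = TRUE))
  expect_equal(est$spores_total, optimize(nll, c(1, 1e6))$minimum,
               tolerance = 1e-4)
})

test_that("plates above the countability ceiling are excluded", {
  obs <- plate_obs(d = c(1, 2), vol = 100, count = c(5000, 8))
  est <- estimate_population(obs, 1000)
  expect_equal(est$spores_total, 8 / 0.001)
  expect_error(
    estimate_population(plate_obs(d = 1, vol = 100, count = 5000), 1000),
    "no usable plates")
})

test_that("all-zero plates yield a censored provisional zero", {
  est <- estimate_population(plate_obs(d = c(2, 3), vol = 100,
                                       count = c(0, 0)), 1000)
  expect_true(est$censored)
  expect_equal(est$spores_total, 0)
})

test_that("over-sampling (total fraction >= 1) is tolerated with a warning", {
  obs <- plate_obs(d = c(0, 0), vol = 600, count = c(10, 12))
  expect_warning(est <- estimate_population(obs, 1000), "over-sampling")
  expect_equal(est$spores_total, 22 / 1.2)
})

test_that("estimator is scale-equivariant and collapses to the single-plate formula", {
  set.seed(42)
  for (i in 1:20) {
    d <- sample(1:5, 3, replace = TRUE)
    cnt <- sample(0:300, 3, replace = TRUE)
    base <- estimate_population(plate_obs(d = d, count = cnt), 1000,
                                count_ceiling = Inf)
    scaled <- estimate_population(plate_obs(d = d, count = 2L * cnt), 1000,
                                  count_ceiling = Inf)
    expect_equal(scaled$spores_total, 2 * base$spores_total)
  }
  one <- estimate_population(plate_obs(d = 3, vol = 50, count = 17), 500)
  expect_equal(one$spores_total, 17 / (0.1 * 1e-3))
})

test_that("pooled MLE is unbiased under the true Poisson plating model", {
  truth <- 2e5
  f <- 100 / 1000 * 10^-(2:4)   # expected counts 20, 2, 0.2 per plate
  set.seed(7)
  n_sim <- 1e4
  counts <- matrix(rpois(n_sim * length(f), rep(truth * f, n_sim)),
                   nrow = length(f))
  est <- colSums(counts) / sum(f)
  expect_gt(mean(est) / truth, 0.99)
  expect_lt(mean(est) / truth, 1.01)
  # the vectorized closed form above is exactly what estimate_population does
  est1 <- estimate_population(plate_obs(d = 2:4, count = counts[, 1]), 1000)
  expect_equal(est1$spores_total, est[1])
})

test_that("mixture subtraction conserves totals and clamps noise-driven negatives", {
  tot <- count_estimate("m1", NA, 1e6)
  minr <- count_estimate("m1", "A", 1e4)
  sp <- split_mixture_counts(tot, minr, "B")
  expect_equal(sp$majority$spores_total, 9.9e5)
  expect_equal(sp$minority$spores_total + sp$majority$spores_total,
               tot$spores_total)

  noisy <- count_estimate("m1", "A", 1.2e4)
  expect_warning(
    sp2 <- split_mixture_counts(count_estimate("m1", NA, 1e4), noisy, "B"),
    "clamped")
  expect_equal(sp2$majority$spores_total, 0)
  expect_true(sp2$majority$censored)

  cen <- count_estimate("m1", "A", 0, censored = TRUE)
  sp3 <- split_mixture_counts(tot, cen, "B")
  expect_equal(sp3$majority$spores_total, tot$spores_total)
  expect_true(sp3$minority$censored)

  expect_error(split_mixture_counts(count_estimate("m2", NA, 1), minr),
               "mismatch")
})

test_that("detection-limit imputation follows the below-limit maximum rule", {
  cen <- count_estimate("s", "A", 0, censored = TRUE)
  imp <- apply_detection_limit(cen, 10)
  expect_equal(imp$spores_total, 9)
  expect_true(imp$imputed)

  alt <- apply_detection_limit(cen, 10, policy = "dl")
  expect_equal(alt$spores_total, 10)

  ok <- apply_detection_limit(count_estimate("s", "A", 5000), 10)
  expect_equal(ok$spores_total, 5000)
  expect_false(ok$imputed)
})

test_that("sporulation efficiency uses the per-strain inoculum", {
  s_mono <- mono_sample(strain = "A")
  expect_equal(sporulation_efficiency(count_estimate("s1", "A", 2.5e6),
                                      s_mono), 1e-2)
  s_mix <- mix_sample(strain_i = "A", strain_j = "B")
  expect_equal(sporulation_efficiency(count_estimate("m1", "A", 2.5e4),
                                      s_mix), 1e-2)
  # imputed censored minority: 9 spores over a 2.5e6-cell inoculum
  imp <- apply_detection_limit(count_estimate("m1", "A", 0, censored = TRUE),
                               10)
  expect_equal(sporulation_efficiency(imp, s_mix), 3.6e-6)
  bad <- mix_sample(); bad$initial_cells_total <- 0
  expect_error(sporulation_efficiency(count_estimate("m1", "A", 10), bad),
               "zero cells")
  expect_warning(
    sporulation_efficiency(count_estimate("s1", "A", 3e8), s_mono), "> 1")
})

test_that("count_samples resolves mixtures and traces imputations", {
  plates <- rbind(
    plate_obs("mono_A", d = 2, count = 25, selective = 1L),
    plate_obs("mix_1", d = 2, count = 0, selective = 1L),
    plate_obs("mix_1", d = 2, count = 250, selective = 0L))
  samples <- rbind(mono_sample("mono_A", "A"),
                   mix_sample("mix_1", "A", "B"))
  counts <- count_samples(plates, samples)
  expect_equal(nrow(counts), 3L)
  a_mix <- counts[counts$sample_id == "mix_1" & counts$strain_id == "A", ]
  expect_true(a_mix$censored & a_mix$imputed)
  expect_equal(a_mix$spores_total, 9)
  b_mix <- counts[counts$sample_id == "mix_1" & counts$strain_id == "B", ]
  expect_equal(b_mix$spores_total, 250 / 1e-3)
  expect_match(attr(counts, "log"), "impute", all = FALSE)
})
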