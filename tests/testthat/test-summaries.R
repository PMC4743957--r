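test_that("mu_per_treatment averages plot-level kernels, in metres", {
  draws <- make_fake_draws(plots = c("A1", "A2", "H1", "H2"),
                           treatments = c(0, 0, 1, 1),
                           beta0 = c(1.0, 1.4, 1.2, 1.1),
                           beta1 = c(0.3, -0.1, -0.5, -0.3),
                           alpha = 1, n = 5, bin_width_m = 0.1)
  # hand-computed plot-averaged exponentials
  expect_equal(unique(mu_per_treatment(draws, 0, units = "bins")),
               mean(c(exp(1.0), exp(1.4))))
  expect_equal(unique(mu_per_treatment(draws, 1, units = "bins")),
               mean(c(exp(1.2 - 0.5), exp(1.1 - 0.3))))
  expect_equal(mu_per_treatment(draws, 0),
               mu_per_treatment(draws, 0, units = "bins") * 0.1)
  expect_error(mu_per_treatment(draws, 2), "no plots")
})

test_that("a zero treatment slope leaves the kernel mean unchanged", {
  draws <- make_fake_draws(plots = c("A1", "H1"), treatments = c(0, 1),
                           beta0 = c(1.3, 1.3), beta1 = c(0, 0), alpha = 1)
  expect_equal(mu_per_treatment(draws, 0), mu_per_treatment(draws, 1))
})

test_that("posterior-predictive distances follow the NB law of the draws", {
  draws <- make_fake_draws(plots = c("A1", "H1"), treatments = c(0, 1),
                           beta0 = c(log(2), log(2)), beta1 = c(0, 0),
                           alpha = 1, bin_width_m = 1)
  d <- posterior_predictive_distances(draws, 0, n_sim = 2e5, seed = 31)
  # var/mean of the NB: 1 + mu/alpha = 3
  expect_lt(abs(var(d) / mean(d) - 3), 0.1)
  expect_lt(abs(mean(d) - 2), 0.05)
  # quantiles agree with the closed-form NB within one bin
  for (q in c(0.5, 0.9, 0.99)) {
    expect_lte(abs(tail_quantile(d, q) - qnbinom(q, size = 1, mu = 2)), 1)
  }

  big <- make_fake_draws(plots = c("A1", "H1"), treatments = c(0, 1),
                         beta0 = c(log(4), log(4)), beta1 = c(0, 0),
                         alpha = 1e6, bin_width_m = 1)
  db <- posterior_predictive_distances(big, 0, n_sim = 2e5, seed = 32)
  expect_lt(abs(var(db) / mean(db) - 1), 0.05)  # Poisson limit
})

test_that("tail_quantile uses the lower tie-break convention", {
  expect_equal(tail_quantile(0:99, 0.99), 98)
  expect_equal(tail_quantile(rep(7.5, 40), 0.42), 7.5)
  expect_error(tail_quantile(1:5, 1), "domain error")
  expect_error(tail_quantile(1:5, 0), "domain error")
  expect_error(tail_quantile(numeric(0), 0.5), "empty")
})

test_that("tail_quantile is monotone in q and scale-equivariant", {
  set.seed(33)
  x <- rgamma(500, 0.7, 0.2)
  qs <- seq(0.05, 0.99, by = 0.05)
  v <- vapply(qs, function(q) tail_quantile(x, q), numeric(1))
  expect_true(all(diff(v) >= 0))
  expect_equal(vapply(qs, function(q) tail_quantile(3.7 * x, q), numeric(1)),
               3.7 * v)
})

test_that("overlap_quantile handles the symmetric and disjoint cases", {
  set.seed(34)
  x <- rnorm(2000, 5, 1)
  expect_equal(overlap_quantile(x, x), 0.5)
  expect_equal(overlap_quantile(x, x + 100), 0)
  expect_warning(ov <- overlap_quantile(x + 100, x), "reversed")
  expect_equal(ov, 0.5)
})

test_that("overlap_quantile matches a brute-force scan on fixture vectors", {
  a <- c(1.1, 1.3, 1.8, 2.0, 2.2, 2.4, 2.5, 2.7, 3.0, 3.3)
  b <- c(2.1, 2.6, 2.9, 3.1, 3.4, 3.6, 3.9, 4.2, 4.8, 5.5)
  scan_oracle <- function(a, b) {
    qs <- seq(1e-4, 0.5, by = 1e-4)
    gap <- vapply(qs, function(q)
      unname(quantile(a, 1 - q, type = 7) - quantile(b, q, type = 7)),
      numeric(1))
    qs[which.min(abs(gap))]
  }
  expect_lt(abs(overlap_quantile(a, b) - scan_oracle(a, b)), 2e-4)

  set.seed(35)
  for (shift in c(0.5, 1.5, 3)) {
    x <- rnorm(500); y <- rnorm(500) + shift
    expect_lt(abs(overlap_quantile(x, y) - scan_oracle(x, y)), 2e-4)
  }
})

test_that("kernel_summary reports a coherent headline table", {
  draws <- make_fake_draws(plots = c("A1", "H1"), treatments = c(0, 1),
                           beta0 = c(log(10), log(10)),
                           beta1 = c(log(0.75), log(0.75)), alpha = 0.55,
                           n = 200, bin_width_m = 0.1)
  ks <- kernel_summary(draws, n_sim = 5e4, n_tail_draws = 50, seed = 36)
  tab <- setNames(ks$table$value, ks$table$statistic)
  expect_equal(unname(tab["mu_absent_m"]), 1.0, tolerance = 1e-9)
  expect_equal(unname(tab["mean_diff_m"]), 0.25, tolerance = 1e-9)
  expect_equal(unname(tab["overlap"]), 0)  # point-mass posteriors are disjoint
  # right-skewed NB: the farthest-1% distance sits far above the mean
  expect_gt(tab["range_absent_m"], tab["mu_absent_m"])
  expect_gt(tab["range_absent_m"], tab["range_present_m"])
  # per-draw tail of the same fixed kernel equals the closed-form NB quantile
  expect_equal(unique(ks$tail_draws$absent),
               qnbinom(0.99, size = 0.55, mu = 10) * 0.1)
})
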