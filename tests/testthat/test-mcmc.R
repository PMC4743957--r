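test_that("log_posterior equals an independent term-by-term evaluation", {
  kd <- make_kernels(plot = c("A1", "A1", "A1", "H1", "H1"),
                     treatment = c(0, 0, 0, 1, 1),
                     y = c(0, 1, 3, 2, 0))
  spec <- model_spec()
  state <- list(beta0 = c(0.9, 1.1), beta1 = c(-0.2, -0.4),
                delta0 = 1.0, delta1 = -0.3, tau0 = 4, tau1 = 9, alpha = 1.7)
  # oracle: every density term written out, one by one
  mu_a <- exp(0.9); mu_h <- exp(1.1 - 0.4)
  oracle <-
    sum(dnbinom(c(0, 1, 3), size = 1.7, mu = mu_a, log = TRUE)) +
    sum(dnbinom(c(2, 0), size = 1.7, mu = mu_h, log = TRUE)) +
    dnorm(0.9, 1.0, 1 / 2, log = TRUE) + dnorm(1.1, 1.0, 1 / 2, log = TRUE) +
    dnorm(-0.2, -0.3, 1 / 3, log = TRUE) + dnorm(-0.4, -0.3, 1 / 3, log = TRUE) +
    dnorm(1.0, 0, 100, log = TRUE) + dnorm(-0.3, 0, 100, log = TRUE) +
    dgamma(4, 1e-4, 1e-4, log = TRUE) + dgamma(9, 1e-4, 1e-4, log = TRUE) +
    log(1e-4 / 2) - 1e-4 * abs(log(1.7))
  expect_equal(log_posterior(state, kd, spec), oracle, tolerance = 1e-10)
})

test_that("log_posterior returns -Inf outside the support, never an error", {
  kd <- make_kernels("A1", 0, c(0, 2))
  base <- list(beta0 = 0.5, beta1 = 0, delta0 = 0, delta1 = 0,
               tau0 = 1, tau1 = 1, alpha = 1)
  for (bad in list(c("alpha", -1), c("tau0", 0), c("beta0", Inf))) {
    st <- base
    st[[bad[1]]] <- as.numeric(bad[2])
    expect_identical(suppressWarnings(log_posterior(st, kd)), -Inf)
  }
})

test_that("identical seeds give identical retained draws", {
  set.seed(6)
  kd <- make_kernels(rep(c("A1", "H1"), each = 20),
                     rep(c(0, 1), each = 20),
                     c(rpois(20, 5), rpois(20, 3)))
  a <- run_mcmc(kd, chains = 2, iter = 200, burnin = 100, thin = 2, seed = 7)
  b <- run_mcmc(kd, chains = 2, iter = 200, burnin = 100, thin = 2, seed = 7)
  expect_identical(a$chains, b$chains)
})

test_that("gelman_rubin matches the split-chain formula and flags failure", {
  # well-mixed: iid normal chains
  set.seed(11)
  chains <- lapply(1:4, function(i)
    matrix(rnorm(4000), ncol = 1, dimnames = list(NULL, "x")))
  expect_lt(gelman_rubin(chains), 1.01)
  expect_gt(gelman_rubin(chains), 0.99)  # split-Rhat can dip just below 1

  # stuck chains at disjoint constants diverge
  stuck <- list(matrix(rep(0, 50), ncol = 1), matrix(rep(5, 50), ncol = 1))
  expect_gt(gelman_rubin(stuck), 10)

  # hand-sized fixture against the textbook formula (no splitting)
  c1 <- matrix(c(1, 2, 3, 4), ncol = 1); c2 <- matrix(c(2, 4, 6, 8), ncol = 1)
  n <- 4
  W <- mean(c(var(c1), var(c2)))
  B <- n * var(c(mean(c1), mean(c2)))
  expect_equal(unname(gelman_rubin(list(c1, c2), split = FALSE)),
               sqrt(((n - 1) / n * W + B / n) / W), tolerance = 1e-12)

  expect_error(gelman_rubin(list(c1)), "at least 2 chains")
})

test_that("latent-rho and marginalized samplers target the same posterior", {
  set.seed(12)
  kd <- make_kernels(rep(c("A1", "H1"), c(25, 15)),
                     rep(c(0, 1), c(25, 15)),
                     c(rnbinom(25, size = 1, mu = 5),
                       rnbinom(15, size = 1, mu = 3)))
  marg <- run_mcmc(kd, chains = 2, iter = 4000, burnin = 1000, thin = 4,
                   seed = 13, marginalize = TRUE)
  lat <- run_mcmc(kd, chains = 2, iter = 4000, burnin = 1000, thin = 4,
                  seed = 14, marginalize = FALSE)
  a1 <- log(as.matrix(marg)[, "alpha"])
  a2 <- log(as.matrix(lat)[, "alpha"])
  # same posterior up to MC error: compare locations and a thinned KS test
  expect_lt(abs(mean(a1) - mean(a2)), 3 * sd(a1) / sqrt(100))
  ks <- suppressWarnings(ks.test(a1[seq(1, length(a1), by = 20)],
                                 a2[seq(1, length(a2), by = 20)]))
  expect_gt(ks$p.value, 0.001)
  d1 <- as.matrix(marg)[, "delta0"]; d2 <- as.matrix(lat)[, "delta0"]
  expect_lt(abs(mean(d1) - mean(d2)), 3 * sd(d1) / sqrt(100))
})

test_that("control-plot slopes are exact draws from their hierarchical law", {
  # beta1 of a trt = 0 plot never touches the likelihood; standardized by the
  # current (delta1, tau1) it must be exactly standard normal
  set.seed(15)
  kd <- make_kernels(rep(c("A1", "H1"), each = 30),
                     rep(c(0, 1), each = 30),
                     c(rnbinom(30, 1, mu = 5), rnbinom(30, 1, mu = 3)))
  fit <- run_mcmc(kd, chains = 2, iter = 3000, burnin = 500, thin = 3,
                  seed = 16)
  m <- as.matrix(fit)
  z <- (m[, "beta1[A1]"] - m[, "delta1"]) * sqrt(m[, "tau1"])
  ks <- suppressWarnings(ks.test(z[seq(1, length(z), by = 10)], "pnorm"))
  expect_gt(ks$p.value, 0.001)
})

test_that("credible intervals for delta1 contract as data grow", {
  set.seed(17)
  widths <- sapply(c(120, 600), function(n_per) {
    mean(replicate(3, {
      cfg <- sim_config(delta0 = log(5), delta1 = -0.5, sigma0 = 0.1,
                        sigma1 = 0.1, alpha = 2, lambda_absent = n_per / 3,
                        lambda_present = n_per / 3)
      kd <- discretize(simulate_establishment(cfg))
      fit <- run_mcmc(kd, chains = 2, iter = 1500, burnin = 600, thin = 2)
      ci <- quantile(as.matrix(fit)[, "delta1"], c(0.025, 0.975))
      diff(ci)
    }))
  })
  expect_lt(widths[2], widths[1])
})

test_that("initialization failure is reported after retries", {
  kd <- make_kernels("A1", 0, c(0, 1))
  expect_error(suppressWarnings(
    run_mcmc(kd, chains = 1, iter = 10, burnin = 0,
             fixed = list(alpha = NaN))),
    "initialization error")
})
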