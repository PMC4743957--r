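test_that("negative log-likelihoods match closed forms", {
  # Poisson(1) at 0: -log(e^-1) = 1
  expect_equal(neg_log_likelihood(0, "poisson", 1), 1.0)
  # exponential: n(-log rate) + rate * sum(x)
  expect_equal(neg_log_likelihood(c(2, 2), "nexp", 0.5), 2 * log(2) + 2)
  # normal at its own mean
  expect_equal(neg_log_likelihood(3, "normal", c(3, 2)),
               -dnorm(0, 0, 2, log = TRUE))
  # NB at huge dispersion converges to the Poisson pmf
  y <- c(0, 1, 2, 5, 3, 3)
  expect_lt(abs(neg_log_likelihood(y, "nbinom", c(3, 1e6)) -
                neg_log_likelihood(y, "poisson", 3)), 1e-3)
})

test_that("parameters outside the family support are rejected", {
  expect_error(neg_log_likelihood(1, "poisson", -1), "domain error")
  expect_error(neg_log_likelihood(1, "nexp", 0), "domain error")
  expect_error(neg_log_likelihood(1, "nbinom", c(2, -1)), "domain error")
  expect_error(neg_log_likelihood(1, "normal", c(0, 0)), "domain error")
  expect_error(neg_log_likelihood(numeric(0), "poisson", 1), "empty")
})

test_that("closed-form MLEs are exact and the NB recovers its dispersion", {
  expect_equal(unname(fit_kernel_mle(c(1, 2, 3), "poisson")$params), 2.0)
  expect_equal(unname(fit_kernel_mle(c(1, 3), "nexp")$params), 0.5)
  nf <- fit_kernel_mle(c(1, 2, 3, 6), "normal")
  expect_equal(unname(nf$params), c(3, sqrt(mean((c(1, 2, 3, 6) - 3)^2))))

  set.seed(101)
  y <- rnbinom(1e5, size = 1, mu = 3)
  fit <- fit_kernel_mle(y, "nbinom")
  expect_lt(abs(fit$params[["alpha"]] - 1), 0.1)
  expect_equal(fit$params[["mu"]], mean(y))
})

test_that("no random perturbation beats the fitted optimum", {
  set.seed(102)
  y <- rnbinom(300, size = 0.8, mu = 6)
  for (fam in c("poisson", "nexp", "normal", "nbinom")) {
    fit <- fit_kernel_mle(y, fam)
    nll0 <- neg_log_likelihood(y, fam, unname(fit$params))
    for (r in 1:20) {
      pert <- unname(fit$params) * exp(rnorm(fit$n_params, 0, 0.05))
      expect_gte(neg_log_likelihood(y, fam, pert), nll0 - 1e-8)
    }
  }
})

test_that("aic_table satisfies the AIC identities and records failures", {
  set.seed(103)
  y <- rnbinom(400, size = 0.5, mu = 8)
  tab <- aic_table(y)
  expect_equal(tab$AIC, 2 * tab$k - 2 * tab$logLik)
  expect_true(all(diff(tab$AIC) >= 0))
  expect_equal(tab$dAIC[1], 0)
  expect_true(all(tab$dAIC >= 0))

  single <- aic_table(y, "poisson")
  expect_equal(single$dAIC, 0)

  zeros <- rep(0L, 10)  # nexp and nbinom fits are undefined, table survives
  tab0 <- aic_table(zeros)
  expect_true(is.na(tab0$AIC[tab0$family == "nexp"]))
  expect_false(is.na(tab0$AIC[tab0$family == "poisson"]))
})

test_that("the AIC winner matches an exhaustive grid-search oracle", {
  grid_oracle <- function(y) {
    # coarse but independent: profile each family on a parameter grid
    best <- Inf; who <- NA
    for (fam in list(
      list(name = "poisson", k = 1,
           grid = lapply(seq(0.2, 20, by = 0.05), function(m) m)),
      list(name = "nexp", k = 1,
           grid = lapply(seq(0.01, 2, by = 0.005), function(r) r)),
      list(name = "normal", k = 2,
           grid = {
             g <- expand.grid(m = seq(0, 20, by = 0.25),
                              s = seq(0.25, 20, by = 0.25))
             lapply(seq_len(nrow(g)), function(i) c(g$m[i], g$s[i]))
           }),
      list(name = "nbinom", k = 2,
           grid = {
             g <- expand.grid(m = seq(0.25, 20, by = 0.25),
                              a = exp(seq(-3, 6, by = 0.1)))
             lapply(seq_len(nrow(g)), function(i) c(g$m[i], g$a[i]))
           }))) {
      nll <- min(vapply(fam$grid, function(p)
        neg_log_likelihood(y, fam$name, p), numeric(1)))
      aic <- 2 * fam$k + 2 * nll
      if (aic < best - 1e-9) { best <- aic; who <- fam$name }
    }
    who
  }
  set.seed(104)
  cases <- list(rnbinom(50, size = 0.3, mu = 8),
                rpois(50, 10),
                round(rnorm(50, 10, 1.2)))
  for (y in cases) {
    tab <- aic_table(y)
    expect_equal(tab$family[1], grid_oracle(y))
  }
})

test_that("AIC between nested Poisson and NB stays small on Poisson data", {
  set.seed(105)
  y <- rpois(1e4, 3)
  tab <- aic_table(y)
  expect_true(tab$family[1] %in% c("poisson", "nbinom"))
  expect_lt(abs(tab$AIC[tab$family == "poisson"] -
                tab$AIC[tab$family == "nbinom"]), 4)
})
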