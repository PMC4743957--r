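kernel_families <- c("nbinom", "nexp", "normal", "poisson")

family_npar <- c(nbinom = 2L, nexp = 1L, normal = 2L, poisson = 1L)

#' Negative log-likelihood of a candidate kernel family
#'
#' The negative binomial and Poisson use their exact log pmf on the binned
#' integer distances; the normal and negative exponential are continuous
#' densities evaluated at the same binned values, so all four families see
#' identical data. (Mixing pmfs and unnormalized densities in one AIC
#' comparison is the conventional, if statistically awkward, procedure for
#' kernel fitting; see the methods vignette for the caveat.) The negative
#' binomial uses the mean-dispersion parameterization: mean `mu`, variance
#' `mu + mu^2/alpha`.
#'
#' @param y Non-empty vector of binned (integer) distances.
#' @param family One of `"nbinom"` (`params = c(mu, alpha)`), `"nexp"`
#'   (`params = rate`), `"normal"` (`params = c(mean, sd)`), `"poisson"`
#'   (`params = mean`).
#' @param params Numeric parameter vector for the family.
#' @return The negative log-likelihood; `Inf` for data of probability zero,
#'   never `NaN`.
#' @export
neg_log_likelihood <- function(y, family = kernel_families, params) {
  family <- match.arg(family)
  if (!length(y)) stop("empty distance vector")
  ll <- switch(family,
    poisson = {
      # mean 0 allowed: it is the boundary MLE for all-zero data
      if (length(params) != 1 || params < 0)
        stop("domain error: poisson mean must be a single non-negative value")
      sum(stats::dpois(y, params, log = TRUE))
    },
    nbinom = {
      if (length(params) != 2 || params[1] <= 0 || params[2] <= 0)
        stop("domain error: nbinom needs mu > 0 and alpha > 0")
      sum(stats::dnbinom(y, size = params[2], mu = params[1], log = TRUE))
    },
    nexp = {
      if (length(params) != 1 || params <= 0)
        stop("domain error: nexp rate must be a single positive value")
      sum(stats::dexp(y, rate = params, log = TRUE))
    },
    normal = {
      if (length(params) != 2 || params[2] <= 0)
        stop("domain error: normal needs sd > 0")
      sum(stats::dnorm(y, params[1], params[2], log = TRUE))
    }
  )
  if (is.nan(ll)) ll <- -Inf
  -ll
}

#' Maximum-likelihood fit of one candidate kernel family
#'
#' Normal, negative exponential and Poisson have closed-form MLEs (sample
#' mean/MLE sd; 1/mean; mean). The negative binomial profiles the mean at the
#' sample mean and optimizes the dispersion `alpha` on the log scale over a
#' coarse multi-start grid refined by [stats::optimize()].
#'
#' @param y Vector of at least two binned distances.
#' @param family Candidate family name.
#' @return A list of class `candidate_fit`: `family`, `params` (named),
#'   `log_lik`, `n_params`, `aic`.
#' @export
fit_kernel_mle <- function(y, family = kernel_families) {
  family <- match.arg(family)
  if (length(y) < 2) stop("need at least 2 observations to fit ", family)
  m <- mean(y)
  params <- switch(family,
    poisson = c(mean = m),
    nexp = {
      if (m == 0)
        stop("fit error (nexp): rate MLE undefined for all-zero data")
      c(rate = 1 / m)
    },
    normal = {
      s <- sqrt(mean((y - m)^2))
      if (s == 0)
        stop("fit error (normal): zero variance, sd MLE degenerate")
      c(mean = m, sd = s)
    },
    nbinom = {
      if (m == 0)
        stop("fit error (nbinom): mean zero, mu MLE degenerate")
      f <- function(la) neg_log_likelihood(y, "nbinom", c(m, exp(la)))
      grid <- seq(-7, 14, by = 1.5)          # multi-start over log alpha
      nll <- vapply(grid, f, numeric(1))
      k <- which.min(nll)
      lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
      opt <- stats::optimize(f, c(lo, hi))
      c(mu = m, alpha = exp(opt$minimum))
    }
  )
  ll <- -neg_log_likelihood(y, family, unname(params))
  k <- family_npar[[family]]
  structure(list(family = family, params = params, log_lik = ll,
                 n_params = k, aic = 2 * k - 2 * ll),
            class = "candidate_fit")
}

#' AIC comparison of the candidate establishment-kernel families
#'
#' Fits every requested family to the pooled binned distances and ranks them
#' by AIC. A family whose fit fails (e.g. the negative exponential on all-zero
#' data) is kept in the table with `NA` values rather than aborting the
#' comparison. Ties in AIC are broken in favour of fewer parameters.
#'
#' @param y Vector of binned integer distances (all plots pooled by default;
#'   subset upstream for per-treatment comparisons).
#' @param families Families to compare.
#' @return A `data.frame` with columns `family`, `params`, `logLik`, `k`,
#'   `AIC`, `dAIC`, sorted by AIC; the full `candidate_fit` objects are in
#'   attribute `fits`.
#' @export
aic_table <- function(y, families = kernel_families) {
  fits <- lapply(families, function(fam) {
    tryCatch(fit_kernel_mle(y, fam), error = function(e) {
      structure(list(family = fam, params = NULL, log_lik = NA_real_,
                     n_params = family_npar[[fam]], aic = NA_real_,
                     error = conditionMessage(e)),
                class = "candidate_fit")
    })
  })
  tab <- data.frame(
    family = vapply(fits, `[[`, character(1), "family"),
    params = vapply(fits, function(f) {
      if (is.null(f$params)) NA_character_
      else paste(sprintf("%s=%.6g", names(f$params), f$params),
                 collapse = ", ")
    }, character(1)),
    logLik = vapply(fits, `[[`, numeric(1), "log_lik"),
    k = vapply(fits, `[[`, integer(1), "n_params"),
    AIC = vapply(fits, `[[`, numeric(1), "aic"),
    stringsAsFactors = FALSE
  )
  ord <- order(tab$AIC, tab$k, tab$family, na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  tab$dAIC <- tab$AIC - min(tab$AIC, na.rm = TRUE)
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[ord]
  tab
}
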