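# In-code fixtures shared across test files.

# Minimal stem table built directly (bypasses CSV round trip).
make_stems <- function(plot, treatment, distance_m, transect = "1", ...) {
  if (length(transect) == 1) transect <- rep(transect, length(plot))
  df <- data.frame(plot = plot, treatment = as.integer(treatment),
                   transect = transect, distance_m = distance_m,
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

# Write a stem-table CSV with given columns and return its path.
write_fixture_csv <- function(df, file = tempfile(fileext = ".csv")) {
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  file
}

# Hand-built kernel_data table (what discretize() returns).
make_kernels <- function(plot, treatment, y, bin_width_m = 0.1) {
  out <- data.frame(plot = plot, treatment = as.integer(treatment),
                    y = as.integer(y), stringsAsFactors = FALSE)
  attr(out, "bin_width_m") <- bin_width_m
  class(out) <- c("kernel_data", class(out))
  out
}

# Stem table whose per-plot totals are exactly the given counts.
stems_with_totals <- function(totals_absent, totals_present) {
  plots <- c(paste0("A", seq_along(totals_absent)),
             paste0("H", seq_along(totals_present)))
  trt <- rep(c(0L, 1L), c(length(totals_absent), length(totals_present)))
  n <- c(totals_absent, totals_present)
  make_stems(plot = rep(plots, n), treatment = rep(trt, n),
             distance_m = rep(1, sum(n)))
}

# Fake posterior object for the summary-layer arithmetic tests: constant
# parameter values replicated over n draws.
make_fake_draws <- function(plots, treatments, beta0, beta1, alpha,
                            n = 100, bin_width_m = 0.1) {
  cols <- c(paste0("beta0[", plots, "]"), paste0("beta1[", plots, "]"),
            "delta0", "delta1", "tau0", "tau1", "alpha")
  row <- c(beta0, beta1, 0, 0, 1, 1, alpha)
  m <- matrix(rep(row, each = n), nrow = n, dimnames = list(NULL, cols))
  structure(list(chains = list(m),
                 plots = data.frame(plot = plots, treatment = treatments,
                                    stringsAsFactors = FALSE),
                 bin_width_m = bin_width_m,
                 settings = list(chains = 1)),
            class = "kernel_draws")
}
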