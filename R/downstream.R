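#' One-way ANOVA of plot-level population growth between treatments
#'
#' Population growth is measured as the total number of established stems per
#' plot (the size of the non-normalized establishment kernel). Plots are the
#' replicates; the treatment effect is tested by one-way ANOVA, and the
#' treatment means give the percent reduction attributable to herbivores.
#'
#' @param stems A stem table.
#' @return A list of class `growth_result`: per-plot totals, treatment means,
#'   `percent_reduction` = 100 (mean_absent - mean_present) / mean_absent,
#'   `F`, `df` (pair), `p`.
#' @export
population_growth_anova <- function(stems) {
  totals <- stats::aggregate(list(total = stems$distance_m),
                             by = list(plot = stems$plot,
                                       treatment = stems$treatment),
                             FUN = length)
  n_per <- table(factor(totals$treatment, levels = c(0, 1)))
  if (any(n_per < 2))
    stop("need at least 2 plots per treatment for the ANOVA (have ",
         paste(n_per, collapse = " and "), ")")
  fit <- stats::lm(total ~ factor(treatment), data = totals)
  av <- stats::anova(fit)
  mean_abs <- mean(totals$total[totals$treatment == 0])
  mean_pres <- mean(totals$total[totals$treatment == 1])
  structure(list(
    totals = totals,
    means = c(absent = mean_abs, present = mean_pres),
    percent_reduction = 100 * (mean_abs - mean_pres) / mean_abs,
    F = av$`F value`[1],
    df = c(av$Df[1], av$Df[2]),
    p = av$`Pr(>F)`[1]
  ), class = "growth_result")
}

#' @export
print.growth_result <- function(x, ...) {
  cat(sprintf(paste0("Population growth: %.4g vs %.4g stems/plot ",
                     "(%.1f%% reduction)\n  F(%d,%d) = %.4g, p = %.4g\n"),
              x$means["absent"], x$means["present"], x$percent_reduction,
              x$df[1], x$df[2], x$F, x$p))
  invisible(x)
}

#' Bin stem counts by surrounding cover
#'
#' Counts established stems per treatment within half-open cover bins
#' \[lo, hi) of the given width; the last bin is closed at 100 so a stem
#' surrounded by full cover is counted. Bins with no stems are kept at zero.
#'
#' @param stems A stem table with the relevant cover column filled in.
#' @param cover_type One of `"native"`, `"weedy"`, `"bare"`.
#' @param bin_width_pct Bin width in cover percentage points (default 10).
#' @return A `data.frame` with `treatment`, `bin_lo`, `bin_hi`, `midpoint`,
#'   `count`; attribute `cover_type` records the type.
#' @export
cover_bin_counts <- function(stems, cover_type = c("native", "weedy", "bare"),
                             bin_width_pct = 10) {
  cover_type <- match.arg(cover_type)
  col <- paste0("cover_", cover_type, "_pct")
  if (!col %in% names(stems))
    stop("cover column missing for type '", cover_type, "' (", col, ")")
  stopifnot(bin_width_pct > 0, bin_width_pct <= 100)
  lo <- seq(0, 100 - bin_width_pct, by = bin_width_pct)
  nbin <- length(lo)
  out <- expand.grid(bin = seq_len(nbin), treatment = c(0L, 1L))
  out$bin_lo <- lo[out$bin]
  out$bin_hi <- out$bin_lo + bin_width_pct
  out$midpoint <- out$bin_lo + bin_width_pct / 2
  cv <- stems[[col]]
  keep <- !is.na(cv)
  idx <- pmin(floor(cv[keep] / bin_width_pct), nbin - 1) + 1  # 100 -> last bin
  tab <- table(factor(stems$treatment[keep], levels = c(0, 1)),
               factor(idx, levels = seq_len(nbin)))
  out$count <- as.vector(t(tab[match(c(0, 1), rownames(tab)), ]))
  out$bin <- NULL
  attr(out, "cover_type") <- cover_type
  attr(out, "bin_width_pct") <- bin_width_pct
  out
}

#' Linear model of binned stem counts on cover, treatment and their
#' interaction
#'
#' Ordinary least squares of stem count per cover bin on the bin midpoint,
#' herbivore treatment and their product. F tests use sequential (type-I)
#' sums of squares with terms entered cover, then treatment, then the
#' interaction — the default decomposition of the analysis environment the
#' field study used. Per-treatment slopes are reported alongside.
#'
#' @param counts A [cover_bin_counts()] table.
#' @return A list of class `context_result`: the fitted `lm`, an `anova`
#'   table (`term`, `df`, `F`, `p`), and `slopes` (stems per cover percentage
#'   point, by treatment).
#' @export
cover_interaction_lm <- function(counts) {
  per_trt <- tapply(counts$count > 0, counts$treatment, sum)
  if (any(per_trt < 3))
    stop("need at least 3 non-empty cover bins per treatment")
  if (length(unique(counts$treatment)) < 2 ||
      length(unique(counts$midpoint)) < 2)
    stop("rank-deficient design: treatment and cover midpoint must both ",
         "vary; a single level is collinear with the intercept")
  counts$trt_f <- factor(counts$treatment, levels = c(0, 1))
  fit <- stats::lm(count ~ midpoint + trt_f + midpoint:trt_f, data = counts)
  if (fit$rank < 4)
    stop("rank-deficient design: cover midpoints and treatment are ",
         "collinear; check that both treatments span several cover bins")
  av <- stats::anova(fit)
  cf <- stats::coef(fit)
  structure(list(
    model = fit,
    anova = data.frame(
      term = c("cover", "treatment", "cover:treatment", "residuals"),
      df = av$Df,
      sum_sq = av$`Sum Sq`,
      F = av$`F value`,
      p = av$`Pr(>F)`,
      stringsAsFactors = FALSE),
    slopes = c(absent = unname(cf["midpoint"]),
               present = unname(cf["midpoint"] + cf["midpoint:trt_f1"])),
    cover_type = attr(counts, "cover_type")
  ), class = "context_result")
}

#' @export
print.context_result <- function(x, ...) {
  cat("Cover-context model", if (!is.null(x$cover_type))
    paste0("(", x$cover_type, " cover)"), "\n")
  print(transform(x$anova, sum_sq = signif(sum_sq, 4), F = signif(F, 4),
                  p = signif(p, 4)), row.names = FALSE)
  cat(sprintf("slopes: absent %.4g, present %.4g stems per cover %%\n",
              x$slopes["absent"], x$slopes["present"]))
  invisible(x)
}
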