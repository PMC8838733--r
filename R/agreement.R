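#' Root mean square error between paired methods
#'
#' Absolute RMSE of the estimate against the gold standard, and relative
#' RMSE as a percentage of the mean gold-standard value.
#'
#' @param gold,est Paired numeric vectors (gold standard, estimate).
#' @return Named list `rmse_abs` (gold units) and `rmse_rel_pct` (%).
#' @examples
#' rmse_paired(gold = c(100, 300), est = c(110, 290))  # 10, 5%
#' @export
rmse_paired <- function(gold, est) {
  check_pairs(gold, est, min_n = 1L)
  rmse_abs <- sqrt(mean((est - gold)^2))
  m <- mean(gold)
  if (m == 0) stop("relative RMSE undefined: mean of gold values is zero")
  list(rmse_abs = rmse_abs, rmse_rel_pct = 100 * rmse_abs / m)
}

#' Smallest real difference
#'
#' `SRD = 1.96 * sigma`, where `sigma` is the standard deviation of the
#' between-method differences: the smallest change that indicates a
#' clinically important difference. The limits of agreement are
#' `bias +/- SRD`.
#'
#' @param sd_diff Standard deviation of the paired differences (>= 0).
#' @return SRD in the same units.
#' @export
srd <- function(sd_diff) {
  if (any(sd_diff < 0)) stop("sd_diff must be non-negative")
  1.96 * sd_diff
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as `est - gold`, so a positive bias means the
#' estimating method overestimates. Limits of agreement are
#' `bias +/- 1.96 * sd`, i.e. `bias +/- SRD`. The 95% confidence interval of
#' the bias uses `t * sd / sqrt(n)`; each limit's interval uses the standard
#' approximation `SE(LoA) = sd * sqrt(3/n)`. The sample (n-1) standard
#' deviation is used throughout.
#'
#' @param gold,est Paired numeric vectors, `n >= 3`.
#' @param conf Confidence level for the intervals (default 0.95).
#' @return List of class `bland_altman`: `bias`, `sd_diff`, `srd`,
#'   `loa_lower`, `loa_upper`, `ci_bias`, `ci_loa_lower`, `ci_loa_upper`
#'   (each a length-2 vector), `n`.
#' @examples
#' ba <- bland_altman(gold = c(0, 0, 0), est = c(1, 2, 3))
#' ba$bias  # 2
#' ba$srd   # 1.96
#' @export
bland_altman <- function(gold, est, conf = 0.95) {
  check_pairs(gold, est, min_n = 3L, what = "insufficient pairs")
  d <- est - gold
  n <- length(d)
  bias <- mean(d)
  sd_d <- stats::sd(d)
  s <- srd(sd_d)
  tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  loa_l <- bias - s
  loa_u <- bias + s
  se_loa <- sd_d * sqrt(3 / n)
  structure(list(bias = bias, sd_diff = sd_d, srd = s,
                 loa_lower = loa_l, loa_upper = loa_u,
                 ci_bias = bias + c(-1, 1) * tq * sd_d / sqrt(n),
                 ci_loa_lower = loa_l + c(-1, 1) * tq * se_loa,
                 ci_loa_upper = loa_u + c(-1, 1) * tq * se_loa,
                 n = n),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d\n  bias %.4g [%.4g, %.4g]\n  LoA [%.4g, %.4g], SRD %.4g\n",
              x$n, x$bias, x$ci_bias[1], x$ci_bias[2],
              x$loa_lower, x$loa_upper, x$srd))
  invisible(x)
}

#' Proportional bias of a method comparison
#'
#' Ordinary least squares of the between-method difference `est - gold` on a
#' magnitude regressor: by default the pairwise mean `(est + gold)/2` (the
#' Bland-Altman plot abscissa), optionally the gold-standard value alone. A
#' significant slope indicates that the error grows or shrinks with the
#' measured magnitude.
#'
#' @param gold,est Paired numeric vectors, `n >= 4`.
#' @param regressor `"mean"` (default) or `"gold"`.
#' @return Named list `slope`, `se`, `p` (two-sided, t with n-2 df).
#' @export
proportional_bias <- function(gold, est, regressor = c("mean", "gold")) {
  regressor <- match.arg(regressor)
  check_pairs(gold, est, min_n = 4L)
  x <- if (regressor == "mean") (est + gold) / 2 else gold
  if (stats::var(x) == 0) stop("zero regressor variance")
  fit <- stats::lm((est - gold) ~ x)
  co <- summary(fit)$coefficients
  list(slope = unname(co["x", "Estimate"]),
       se = unname(co["x", "Std. Error"]),
       p = unname(co["x", "Pr(>|t|)"]))
}

#' Cohen's d effect size for a method comparison
#'
#' Computed as `(mean(gold) - mean(est)) / s`, so the sign is negative when
#' the estimating method overestimates. `s` is the pooled standard deviation
#' of the two samples by default; a paired variant (`mean difference / SD of
#' differences`) is available. The returned value carries a `band` attribute
#' labelling the magnitude: |d| close to 0.01, 0.2, 0.5, 0.8 is very small,
#' small, moderate, large (band edges at the midpoints 0.105, 0.35, 0.65).
#'
#' @param gold,est Paired numeric vectors, `n >= 2`.
#' @param method `"pooled"` (default) or `"paired"`.
#' @return Cohen's d (numeric scalar with attribute `band`).
#' @export
cohens_d <- function(gold, est, method = c("pooled", "paired")) {
  method <- match.arg(method)
  check_pairs(gold, est, min_n = 2L)
  n <- length(gold)
  s <- if (method == "pooled") {
    sqrt(((n - 1) * stats::var(gold) + (n - 1) * stats::var(est)) / (2 * n - 2))
  } else {
    stats::sd(gold - est)
  }
  if (s == 0) stop("zero pooled standard deviation")
  d <- (mean(gold) - mean(est)) / s
  bands <- c("very small", "small", "moderate", "large")
  band <- bands[findInterval(abs(d), c(0.105, 0.35, 0.65)) + 1L]
  structure(d, band = band)
}

#' Full agreement report for a paired-trial table
#'
#' Assembles the method-comparison table a validation study reports: one row
#' per variable and speed with bias, limits of agreement and their
#' confidence intervals, SRD, absolute and relative RMSE, proportional-bias
#' slope with standard error and p-value, Cohen's d, and n. Groups with
#' missing values are reduced to their complete pairs with a warning;
#' groups with fewer than 3 complete pairs are an error.
#'
#' @param pairs Data frame with columns `participant`, `speed_kmh`,
#'   `variable`, `gold`, `est` (one row per participant, speed, and
#'   variable; trial means).
#' @param regressor Passed to [proportional_bias()].
#' @param d_method Passed to [cohens_d()].
#' @param conf Confidence level for [bland_altman()].
#' @return Data frame of class `agreement_table`, one row per
#'   (variable, speed).
#' @export
validate_agreement <- function(pairs, regressor = c("mean", "gold"),
                               d_method = c("pooled", "paired"),
                               conf = 0.95) {
  regressor <- match.arg(regressor)
  d_method <- match.arg(d_method)
  need <- c("participant", "speed_kmh", "variable", "gold", "est")
  missing_cols <- setdiff(need, names(pairs))
  if (length(missing_cols) > 0L)
    stop(sprintf("pairs is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  groups <- unique(pairs[, c("variable", "speed_kmh")])
  groups <- groups[order(groups$variable, groups$speed_kmh), , drop = FALSE]
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- pairs$variable == groups$variable[i] &
      pairs$speed_kmh == groups$speed_kmh[i]
    g <- pairs$gold[sel]; e <- pairs$est[sel]
    ok <- stats::complete.cases(g, e)
    if (any(!ok)) {
      warning(sprintf("%s at %g km/h: excluded %d incomplete pair(s) (participants %s)",
                      groups$variable[i], groups$speed_kmh[i], sum(!ok),
                      paste(pairs$participant[sel][!ok], collapse = ", ")))
      g <- g[ok]; e <- e[ok]
    }
    ba <- bland_altman(g, e, conf)
    rm <- rmse_paired(g, e)
    pb <- proportional_bias(g, e, regressor)
    d <- cohens_d(g, e, d_method)
    data.frame(variable = groups$variable[i],
               speed_kmh = groups$speed_kmh[i],
               n = ba$n,
               gold_mean = mean(g), gold_sd = stats::sd(g),
               est_mean = mean(e), est_sd = stats::sd(e),
               bias = ba$bias, sd_diff = ba$sd_diff, srd = ba$srd,
               loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
               ci_bias_lower = ba$ci_bias[1], ci_bias_upper = ba$ci_bias[2],
               ci_loa_lower_lower = ba$ci_loa_lower[1],
               ci_loa_lower_upper = ba$ci_loa_lower[2],
               ci_loa_upper_lower = ba$ci_loa_upper[1],
               ci_loa_upper_upper = ba$ci_loa_upper[2],
               rmse_abs = rm$rmse_abs, rmse_rel_pct = rm$rmse_rel_pct,
               prop_slope = pb$slope, prop_se = pb$se, prop_p = pb$p,
               cohens_d = as.numeric(d), effect_band = attr(d, "band"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("agreement_table", "data.frame")
  out
}

check_pairs <- function(gold, est, min_n = 3L, what = NULL) {
  if (length(gold) != length(est)) stop("gold and est must have equal length")
  if (length(gold) < min_n)
    stop(what %||% sprintf("need at least %d pairs", min_n))
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
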