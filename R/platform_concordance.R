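#' Pearson correlation with significance
#'
#' Product-moment correlation of paired values with a two-sided p-value from
#' the exact t distribution on `n - 2` degrees of freedom
#' (`t = r * sqrt((n-2)/(1-r^2))`), as returned by [stats::cor.test()].
#'
#' @param x,y Paired numeric vectors, `n >= 3`, finite, non-constant.
#' @return A list with `r`, `p` and `n`.
#' @export
pearson_with_p <- function(x, y) {
  check_pairs(x, y, min_n = 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance in input")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Lin's concordance correlation coefficient
#'
#' Agreement measure penalising both loss of correlation and location/scale
#' shift between two measurement methods:
#' `CCC = 2 s_xy / (s_x^2 + s_y^2 + (mean_x - mean_y)^2)` with population
#' (1/n) moments. Significance is assessed on the Fisher z-transform of the
#' CCC with Lin's (1989) asymptotic standard error (two-sided normal test of
#' zero concordance).
#'
#' @param x,y Paired numeric vectors, `n >= 3`, finite; not both constant.
#' @return A list with `ccc`, `p` and `n`.
#' @export
lin_ccc <- function(x, y) {
  check_pairs(x, y, min_n = 3L)
  n <- length(x)
  sx2 <- mean((x - mean(x))^2)
  sy2 <- mean((y - mean(y))^2)
  if (sx2 == 0 && sy2 == 0) stop("CCC undefined: both sequences constant")
  sxy <- mean((x - mean(x)) * (y - mean(y)))
  ccc <- 2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
  p <- NA_real_
  if (sx2 > 0 && sy2 > 0 && abs(ccc) < 1) {
    r <- sxy / sqrt(sx2 * sy2)
    u <- (mean(x) - mean(y)) / (sx2 * sy2)^(1 / 4)
    z <- atanh(ccc)
    se_z <- sqrt(((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
                    2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
                    ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2))
    p <- 2 * stats::pnorm(-abs(z / se_z))
  } else if (abs(ccc) == 1) {
    p <- 0
  }
  list(ccc = ccc, p = p, n = n)
}

#' Bland-Altman limits of agreement
#'
#' Differences `d_i = x_i - y_i` are summarised by their mean and sample SD;
#' the limits of agreement are `mean +/- k * SD` (k = 1.96 by default, the
#' standard construction covering ~95% of normal differences). Pairs whose
#' difference falls outside the limits are flagged as discordant.
#'
#' @param x,y Paired numeric vectors, `n >= 3`.
#' @param labels Optional labels for the pairs (defaults to indices).
#' @param k Limit multiplier.
#' @return A list with `mean_difference`, `sd_difference`, `loa_low`,
#'   `loa_high`, `outliers` (labels), plus the per-pair `differences` and
#'   `means` for plotting.
#' @export
bland_altman <- function(x, y, labels = NULL, k = 1.96) {
  check_pairs(x, y, min_n = 3L)
  if (is.null(labels)) labels <- as.character(seq_along(x))
  stopifnot(length(labels) == length(x))
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  loa_low <- m - k * s
  loa_high <- m + k * s
  out <- labels[d < loa_low | d > loa_high]
  list(mean_difference = m, sd_difference = s,
       loa_low = loa_low, loa_high = loa_high,
       outliers = out, differences = d, means = (x + y) / 2)
}

#' Full two-platform agreement report
#'
#' Bundles [pearson_with_p()], [lin_ccc()] and [bland_altman()] for one pair
#' of genotype-level series (e.g. the P indicator computed on each
#' platform).
#'
#' @inheritParams bland_altman
#' @return A list of class `agreement_report` with elements `n`,
#'   `pearson_r`, `pearson_p`, `ccc`, `ccc_p` and `bland_altman`.
#' @export
agreement_report <- function(x, y, labels = NULL, k = 1.96) {
  pr <- pearson_with_p(x, y)
  cc <- lin_ccc(x, y)
  ba <- bland_altman(x, y, labels = labels, k = k)
  structure(list(n = pr$n, pearson_r = pr$r, pearson_p = pr$p,
                 ccc = cc$ccc, ccc_p = cc$p, bland_altman = ba),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement over %d pairs\n", x$n))
  cat(sprintf("  Pearson r = %.3f (p = %.3g)\n", x$pearson_r, x$pearson_p))
  cat(sprintf("  Lin CCC   = %.3f (p = %.3g)\n", x$ccc, x$ccc_p))
  ba <- x$bland_altman
  cat(sprintf("  Bland-Altman: mean diff %.3f, LoA [%.3f, %.3f]\n",
              ba$mean_difference, ba$loa_low, ba$loa_high))
  if (length(ba$outliers))
    cat("  outside LoA:", paste(ba$outliers, collapse = ", "), "\n")
  else cat("  no pairs outside the limits of agreement\n")
  invisible(x)
}

#' Pairwise metric correlation matrix with significance masking
#'
#' Pearson correlations between genotype-mean efficiency metrics at one P
#' level, with cells masked (set `NA`) where the two-sided p-value is at or
#' above `alpha` — matching the convention of plotting only significant
#' coefficients. No multiplicity correction is applied within the matrix.
#'
#' @param table A [metric_table()].
#' @param metrics Which metrics to correlate (at least two of
#'   `"pae"`, `"prae"`, `"pue"`).
#' @param condition P level, `"P-"` or `"P+"`.
#' @param alpha Significance mask threshold.
#' @return A list with symmetric matrices `r`, `p` and `r_masked`
#'   (unit diagonal; `r_masked` has `NA` where `p >= alpha`).
#' @export
correlation_matrix <- function(table, metrics = c("pae", "prae", "pue"),
                               condition = c("P-", "P+"), alpha = 0.05) {
  stopifnot(inherits(table, "metric_table"))
  condition <- match.arg(condition)
  metrics <- match.arg(metrics, c("pae", "prae", "pue"), several.ok = TRUE)
  if (length(metrics) < 2L) stop("need at least two metrics")
  suffix <- if (condition == "P-") "pminus" else "pplus"
  df <- tibble::as_tibble(table)
  if (nrow(df) < 3L) stop("need at least three genotypes")
  m <- length(metrics)
  r <- p <- matrix(NA_real_, m, m, dimnames = list(toupper(metrics), toupper(metrics)))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    xi <- df[[paste0(metrics[i], "_", suffix, "_mean")]]
    xj <- df[[paste0(metrics[j], "_", suffix, "_mean")]]
    pr <- pearson_with_p(xi, xj)
    r[i, j] <- r[j, i] <- pr$r
    p[i, j] <- p[j, i] <- pr$p
  }
  r_masked <- r
  r_masked[p >= alpha] <- NA_real_
  list(r = r, p = p, r_masked = r_masked, alpha = alpha, condition = condition)
}

check_pairs <- function(x, y, min_n = 3L) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < min_n) stop("need at least ", min_n, " pairs")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")
  invisible(TRUE)
}
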