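#' Two-way ANOVA with interaction for a harvest response
#'
#' Fits `response ~ genotype * p_level`. Balanced designs use the classical
#' least-squares decomposition (sequential SS coincide with the unique
#' orthogonal decomposition there); unbalanced designs fall back to Type II
#' sums of squares, which test each main effect adjusted for the other and
#' do not depend on factor order. p-values come from the F distribution.
#'
#' @param records Harvest tibble with `genotype` and `p_level` columns.
#' @param response Name of the response column (e.g. `"shoot_dw"`).
#' @return A tibble of class `anova_result` with one row per term
#'   (genotype, p_level, interaction, residual): `df`, `sumsq`, `meansq`,
#'   `statistic`, `p.value` (residual row has no F/p), and attribute
#'   `ss_type` (`"classical"` or `"II"`).
#' @export
two_way_anova <- function(records, response) {
  stopifnot(response %in% names(records))
  y <- records[[response]]
  if (any(!is.finite(y))) stop("non-finite response values")
  if (stats::sd(y) == 0)
    stop("response is constant: sums of squares are all zero and F is undefined")
  d <- data.frame(y = y,
                  genotype = factor(records$genotype),
                  p_level = factor(records$p_level))
  if (nlevels(d$genotype) < 2L || nlevels(d$p_level) < 2L)
    stop("both factors need at least two observed levels")
  counts <- table(d$genotype, d$p_level)
  if (any(counts == 0L))
    stop("empty genotype x P level cell: interaction is not estimable")
  if (!any(counts >= 2L))
    stop("need at least one cell with two or more replicates for the interaction")

  balanced <- length(unique(as.vector(counts))) == 1L
  if (balanced) {
    fit <- stats::aov(y ~ genotype * p_level, data = d)
    tab <- summary(fit)[[1L]]
    ss_type <- "classical"
  } else {
    fit <- stats::lm(y ~ genotype * p_level, data = d)
    tab <- car::Anova(fit, type = 2)
    ss_type <- "II"
  }
  rn <- trimws(rownames(tab))
  term_map <- c("genotype" = "genotype", "p_level" = "p_level",
                "genotype:p_level" = "interaction", "Residuals" = "residual")
  df_col <- grep("^Df$", names(tab))
  ss_col <- grep("Sum Sq", names(tab))
  f_col <- grep("F value", names(tab))
  p_col <- grep("Pr", names(tab))
  out <- tibble::tibble(
    term = unname(term_map[rn]),
    df = as.numeric(tab[[df_col]]),
    sumsq = as.numeric(tab[[ss_col]]),
    statistic = as.numeric(tab[[f_col]]),
    p.value = as.numeric(tab[[p_col]]))
  out$meansq <- out$sumsq / out$df
  out <- out[match(c("genotype", "p_level", "interaction", "residual"), out$term),
             c("term", "df", "sumsq", "meansq", "statistic", "p.value")]
  structure(out, ss_type = ss_type,
            class = c("anova_result", class(out)))
}

#' Distributional assumption checks for the two-way model
#'
#' Homogeneity of variance by the Levene test in its Brown-Forsythe form
#' (absolute deviations from group medians, the robust default) on the
#' genotype x P level cells, and normality by the Shapiro-Wilk test on the
#' residuals of the full two-way model.
#'
#' @inheritParams two_way_anova
#' @return A list with `levene` (`statistic`, `p`, `df`) and
#'   `shapiro_wilk` (`statistic`, `p`).
#' @export
assumption_checks <- function(records, response) {
  stopifnot(response %in% names(records))
  d <- data.frame(y = records[[response]],
                  g = interaction(factor(records$genotype),
                                  factor(records$p_level), drop = TRUE))
  if (nlevels(d$g) < 2L) stop("need at least two groups for the Levene test")
  lev <- car::leveneTest(y ~ g, data = d, center = stats::median)
  res <- stats::resid(stats::lm(y ~ g, data = d))
  if (length(res) < 3L || length(res) > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  sw <- stats::shapiro.test(res)
  list(levene = list(statistic = lev[1, "F value"], p = lev[1, "Pr(>F)"],
                     df = unname(lev[["Df"]])),
       shapiro_wilk = list(statistic = unname(sw$statistic), p = sw$p.value))
}

#' Within-genotype P+ vs P- t-tests with Bonferroni correction
#'
#' For each genotype, an equal-variance two-sided Student t-test of the
#' response between the two P levels. Raw p-values are Bonferroni-adjusted
#' by the number of genotype contrasts actually tested
#' (`p_adj = min(1, p * m)`). Genotypes with fewer than two replicates in
#' either cell are skipped with a warning.
#'
#' @inheritParams two_way_anova
#' @param alpha Significance level for the `significant` flag.
#' @return A tibble with one row per tested genotype: mean difference
#'   (high minus low level), `statistic`, `df`, `p.value`, `p.adjusted`,
#'   `significant`; attribute `n_comparisons`.
#' @export
pairwise_t_bonferroni <- function(records, response, alpha = 0.05) {
  stopifnot(response %in% names(records))
  levels_present <- unique(records$p_level)
  if (length(levels_present) != 2L) stop("exactly two P levels are required")
  high <- levels_present[[1L]]; low <- levels_present[[2L]]
  genos <- unique(records$genotype)
  rows <- list(); skipped <- character()
  for (g in genos) {
    xh <- records[[response]][records$genotype == g & records$p_level == high]
    xl <- records[[response]][records$genotype == g & records$p_level == low]
    if (length(xh) < 2L || length(xl) < 2L) {
      skipped <- c(skipped, g)
      next
    }
    pooled_var <- (sum((xh - mean(xh))^2) + sum((xl - mean(xl))^2)) /
      (length(xh) + length(xl) - 2L)
    if (pooled_var == 0) {
      # degenerate cells with zero spread: equal means are maximally
      # non-significant, unequal means maximally significant
      same <- mean(xh) == mean(xl)
      rows[[g]] <- tibble::tibble(
        genotype = g, estimate = mean(xh) - mean(xl),
        statistic = if (same) 0 else Inf,
        df = length(xh) + length(xl) - 2,
        p.value = if (same) 1 else 0)
    } else {
      tt <- stats::t.test(xh, xl, var.equal = TRUE, alternative = "two.sided")
      rows[[g]] <- tibble::tibble(
        genotype = g, estimate = unname(diff(rev(tt$estimate))),
        statistic = unname(tt$statistic), df = unname(tt$parameter),
        p.value = tt$p.value)
    }
  }
  if (length(skipped))
    warning("skipped genotype(s) with a single-replicate cell: ",
            paste(skipped, collapse = ", "))
  if (!length(rows)) stop("no genotype has two replicates in both cells")
  out <- dplyr::bind_rows(rows)
  m <- nrow(out)
  out$p.adjusted <- pmin(1, out$p.value * m)
  out$significant <- out$p.adjusted < alpha
  structure(out, n_comparisons = m, class = class(out))
}
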