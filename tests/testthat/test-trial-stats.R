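make_balanced <- function(seed = 1, g = 4, reps = 3, effect_g = 1, effect_p = 2,
                          effect_int = 0) {
  set.seed(seed)
  d <- expand.grid(genotype = paste0("g", seq_len(g)),
                   p_level = c("P+", "P-"), replicate = seq_len(reps),
                   stringsAsFactors = FALSE)
  d$shoot_dw <- rnorm(nrow(d)) +
    effect_g * as.numeric(factor(d$genotype)) +
    effect_p * (d$p_level == "P+") +
    effect_int * as.numeric(factor(d$genotype)) * (d$p_level == "P+")
  d
}

test_that("balanced two-way ANOVA matches the classical decomposition oracle", {
  d <- make_balanced(seed = 1)
  a <- two_way_anova(d, "shoot_dw")
  expect_identical(attr(a, "ss_type"), "classical")

  # oracle: textbook mean-based sums of squares, written out independently
  y <- d$shoot_dw
  gm <- mean(y)
  Am <- tapply(y, d$genotype, mean); Bm <- tapply(y, d$p_level, mean)
  cell <- tapply(y, list(d$genotype, d$p_level), mean)
  nA <- length(y) / length(Am); nB <- length(y) / length(Bm)
  ncell <- length(y) / length(cell)
  ss_a <- nA * sum((Am - gm)^2)
  ss_b <- nB * sum((Bm - gm)^2)
  ss_ab <- ncell * sum((sweep(sweep(cell, 1, Am - gm), 2, Bm - gm) - gm)^2)
  ss_e <- sum((y - cell[cbind(d$genotype, d$p_level)])^2)

  expect_equal(a$sumsq[a$term == "genotype"], ss_a, tolerance = 1e-8)
  expect_equal(a$sumsq[a$term == "p_level"], ss_b, tolerance = 1e-8)
  expect_equal(a$sumsq[a$term == "interaction"], ss_ab, tolerance = 1e-8)
  expect_equal(a$sumsq[a$term == "residual"], ss_e, tolerance = 1e-8)
  # SS decomposition is exactly additive on balanced designs
  expect_equal(sum(a$sumsq), sum((y - gm)^2), tolerance = 1e-8)
  expect_equal(sum(a$df), length(y) - 1)
  expect_true(all(is.na(a$statistic[a$term == "residual"])))
  expect_true(all(a$statistic[a$term != "residual"] >= 0))
})

test_that("unbalanced designs fall back to Type II and keep df accounting", {
  d <- make_balanced(seed = 2)[-c(1, 5), ]
  a <- two_way_anova(d, "shoot_dw")
  expect_identical(attr(a, "ss_type"), "II")
  expect_equal(sum(a$df), nrow(d) - 1)
  expect_true(all(is.finite(a$p.value[a$term != "residual"])))
})

test_that("ANOVA degenerate inputs raise explicit errors", {
  d <- make_balanced()
  dc <- d; dc$shoot_dw <- 1
  expect_error(two_way_anova(dc, "shoot_dw"), "constant")
  de <- d[!(d$genotype == "g1" & d$p_level == "P+"), ]
  expect_error(two_way_anova(de, "shoot_dw"), "empty")
  d1 <- d[d$genotype == "g1", ]
  expect_error(two_way_anova(d1, "shoot_dw"), "two observed levels")
})

test_that("interaction p-values are uniform under an interaction-free model", {
  set.seed(77)
  ps <- replicate(400, {
    d <- make_balanced(seed = sample.int(1e6, 1), g = 5, reps = 3)
    two_way_anova(d, "shoot_dw")$p.value[3]
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("assumption checks report Levene (Brown-Forsythe) and Shapiro-Wilk", {
  d <- make_balanced(seed = 3)
  ch <- assumption_checks(d, "shoot_dw")
  expect_named(ch, c("levene", "shapiro_wilk"))
  # identical groups (same triplet in every cell): absolute deviations from
  # the group medians are all zero, so W = 0
  di <- d[order(d$genotype, d$p_level), ]
  di$shoot_dw <- rep(c(1, 2, 3), nrow(di) / 3)
  expect_equal(assumption_checks(di, "shoot_dw")$levene$statistic, 0)
  # strongly skewed residuals fail normality at moderate n
  set.seed(4)
  ds <- data.frame(genotype = rep(c("a", "b"), each = 50),
                   p_level = rep(c("P+", "P-"), times = 50),
                   shoot_dw = rlnorm(100, 0, 1))
  expect_lt(assumption_checks(ds, "shoot_dw")$shapiro_wilk$p, 0.05)
})

test_that("Levene keeps its nominal type-I error under equal variances", {
  set.seed(55)
  rej <- replicate(400, {
    d <- make_balanced(seed = sample.int(1e6, 1), g = 4, reps = 5)
    assumption_checks(d, "shoot_dw")$levene$p < 0.05
  })
  expect_lt(mean(rej), 0.05 + 0.035)
})

test_that("Shapiro-Wilk detects log-normal skew at moderate n", {
  set.seed(66)
  hits <- replicate(200, stats::shapiro.test(rlnorm(100, 0, 1))$p.value < 0.05)
  expect_gte(mean(hits), 0.95)
})

test_that("Bonferroni-adjusted pairwise t-tests respect their bounds", {
  d <- make_balanced(seed = 5, g = 6, reps = 4)
  out <- pairwise_t_bonferroni(d, "shoot_dw")
  expect_true(all(out$p.adjusted >= out$p.value))
  expect_true(all(out$p.adjusted <= 1))
  expect_equal(attr(out, "n_comparisons"), 6L)

  # identical group means -> adjusted p = 1
  di <- d
  di$shoot_dw <- rep(c(1, 2, 3, 4), length.out = nrow(di))
  di$shoot_dw[di$p_level == "P-"] <- di$shoot_dw[di$p_level == "P+"]
  # force exactly equal cell values across levels per genotype
  for (g in unique(di$genotype)) {
    v <- di$shoot_dw[di$genotype == g & di$p_level == "P+"]
    di$shoot_dw[di$genotype == g & di$p_level == "P-"] <- v
  }
  outi <- pairwise_t_bonferroni(di, "shoot_dw")
  expect_true(all(outi$p.adjusted == 1))
})

test_that("a single planted effect among null genotypes is the only one flagged", {
  set.seed(8)
  d <- expand.grid(genotype = sprintf("g%02d", 1:26), p_level = c("P+", "P-"),
                   replicate = 1:6, stringsAsFactors = FALSE)
  d$shoot_dw <- rnorm(nrow(d))
  d$shoot_dw[d$genotype == "g01" & d$p_level == "P+"] <-
    d$shoot_dw[d$genotype == "g01" & d$p_level == "P+"] + 5
  out <- pairwise_t_bonferroni(d, "shoot_dw")
  expect_true(out$significant[out$genotype == "g01"])
  expect_equal(sum(out$significant), 1L)
})

test_that("single-replicate cells are skipped with a warning", {
  d <- make_balanced(seed = 6)
  d <- d[!(d$genotype == "g2" & d$p_level == "P-" & d$replicate > 1), ]
  expect_warning(out <- pairwise_t_bonferroni(d, "shoot_dw"), "g2")
  expect_false("g2" %in% out$genotype)
})

test_that("the whole pairwise procedure keeps familywise error under the null", {
  set.seed(99)
  any_fp <- replicate(300, {
    d <- expand.grid(genotype = sprintf("g%02d", 1:10), p_level = c("P+", "P-"),
                     replicate = 1:4, stringsAsFactors = FALSE)
    d$shoot_dw <- rnorm(nrow(d))
    any(pairwise_t_bonferroni(d, "shoot_dw")$significant)
  })
  expect_lt(mean(any_fp), 0.05 + 0.03)
})
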