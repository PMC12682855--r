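test_that("min-max normalization is affine with the right endpoints", {
  expect_equal(minmax_normalize(c(1, 2, 3)), c(0, 0.5, 1))
  expect_warning(out <- minmax_normalize(c(7, 7, 7)), "constant")
  expect_equal(out, c(0.5, 0.5, 0.5))
  expect_error(minmax_normalize(c(1, NA, 3)), "position 2")
  expect_error(minmax_normalize(5), "two values")
  set.seed(11)
  x <- rnorm(26)
  expect_equal(minmax_normalize(x), (x - min(x)) / (max(x) - min(x)))
})

test_that("the composite score attains its bounds at all-best and all-worst genotypes", {
  mt <- load_table3("ALSIA")
  # plant two artificial genotypes dominating / dominated in all five metrics
  best <- worst <- as.data.frame(mt)[1, ]
  best$genotype <- "BEST"; worst$genotype <- "WORST"
  for (col in c("pae_pminus_mean", "prae_pminus_mean", "pue_pminus_mean",
                "relative_efficiency", "apue")) {
    best[[col]] <- max(mt[[col]]) + 1
    worst[[col]] <- min(mt[[col]]) - 1
  }
  aug <- metric_table(rbind(as.data.frame(mt), best, worst), platform = "ALSIA")
  ind <- compute_indicator(aug, condition = "P-")
  expect_equal(ind$score[ind$genotype == "BEST"], 5)
  expect_equal(ind$score[ind$genotype == "WORST"], 0)
  expect_equal(ind$rank[ind$genotype == "BEST"], 1L)
  expect_true(all(ind$score >= 0 & ind$score <= 5))
})

test_that("indicator scores match an independently scripted normalize-and-sum oracle", {
  mt <- load_table3("ALSIA")
  ind <- compute_indicator(mt, condition = "P-")
  norm <- function(x) (x - min(x)) / (max(x) - min(x))
  oracle <- norm(mt$pae_pminus_mean) + norm(mt$prae_pminus_mean) +
    norm(mt$pue_pminus_mean) + norm(mt$relative_efficiency) + norm(mt$apue)
  expect_equal(ind$score, oracle)
  expect_equal(attr(ind, "condition"), "P-")
  expect_equal(attr(ind, "platform"), "ALSIA")
})

test_that("the indicator is invariant to positive affine rescaling of one metric", {
  mt <- load_table3("4PMI")
  ind0 <- compute_indicator(mt, condition = "P-")
  df <- as.data.frame(mt)
  df$pue_pminus_mean <- 3.7 * df$pue_pminus_mean + 11
  ind1 <- compute_indicator(metric_table(df, platform = "4PMI"), condition = "P-")
  expect_equal(ind1$score, ind0$score)
})

test_that("permuting genotype rows permutes the indicator identically", {
  mt <- load_table3("4PMI")
  set.seed(5)
  perm <- sample(nrow(mt))
  mtp <- metric_table(as.data.frame(mt)[perm, ], platform = "4PMI")
  ind <- compute_indicator(mt)
  indp <- compute_indicator(mtp)
  expect_equal(indp$score, ind$score[perm])
  expect_equal(indp$rank, ind$rank[perm])
})

test_that("rank is monotone in score with dense ties", {
  mt <- load_table3("ALSIA")
  ind <- compute_indicator(mt)
  ord <- order(-ind$score)
  expect_true(all(diff(ind$rank[ord]) >= 0))
  expect_equal(sort(unique(ind$rank)), seq_along(unique(ind$score)))
})

test_that("genotypes with missing metrics are excluded with a warning", {
  df <- as.data.frame(load_table3("ALSIA"))
  df$apue[3] <- NA
  mt <- metric_table(df, platform = "ALSIA")
  expect_warning(ind <- compute_indicator(mt), df$genotype[3])
  expect_equal(nrow(ind), 25L)
})

test_that("quadrant classes follow the threshold conventions", {
  # all identical -> everything sits on both thresholds -> ER by >=
  apue_v <- setNames(rep(2, 4), paste0("g", 1:4))
  dw_v <- setNames(rep(1, 4), paste0("g", 1:4))
  cls <- classify_quadrants(apue_v, dw_v)
  expect_true(all(cls$class == "ER"))

  # 2x2 grid: one genotype per class
  apue_v <- setNames(c(10, 10, 0, 0), paste0("g", 1:4))
  dw_v <- setNames(c(5, 1, 5, 1), paste0("g", 1:4))
  cls <- classify_quadrants(apue_v, dw_v)
  expect_equal(setNames(cls$class, cls$genotype),
               c(g1 = "ER", g2 = "NER", g3 = "ENR", g4 = "NENR"))
  expect_setequal(cls$class, c("ER", "NER", "ENR", "NENR"))
})

test_that("mismatched genotype sets are reported with the difference", {
  expect_error(
    classify_quadrants(c(a = 1, b = 2), c(a = 1, c = 2)),
    "only in apue: \\{b\\}; only in dw: \\{c\\}")
})

test_that("planted quadrant structure is recovered for well-separated effects", {
  set.seed(21)
  genos <- sprintf("g%02d", 1:12)
  truth <- rep(c("ER", "ENR", "NER", "NENR"), each = 3)
  apue_v <- setNames(ifelse(truth %in% c("ER", "NER"), 50, 5) + rnorm(12, 0, 0.5), genos)
  dw_v <- setNames(ifelse(truth %in% c("ER", "ENR"), 3, 0.5) + rnorm(12, 0, 0.05), genos)
  cls <- classify_quadrants(apue_v, dw_v)
  expect_equal(cls$class, truth)
  expect_equal(sum(table(cls$class)), 12L)
})

test_that("switching mean to median moves only between-threshold genotypes", {
  set.seed(31)
  genos <- sprintf("g%02d", 1:20)
  apue_v <- setNames(rexp(20, 1 / 30), genos)  # skewed: mean != median
  dw_v <- setNames(rexp(20, 1 / 2), genos)
  cm <- classify_quadrants(apue_v, dw_v, rule = "mean")
  cd <- classify_quadrants(apue_v, dw_v, rule = "median")
  moved <- cm$class != cd$class
  lo_a <- min(attr(cm, "apue_threshold"), attr(cd, "apue_threshold"))
  hi_a <- max(attr(cm, "apue_threshold"), attr(cd, "apue_threshold"))
  lo_d <- min(attr(cm, "dw_threshold"), attr(cd, "dw_threshold"))
  hi_d <- max(attr(cm, "dw_threshold"), attr(cd, "dw_threshold"))
  in_band <- (apue_v >= lo_a & apue_v < hi_a) | (dw_v >= lo_d & dw_v < hi_d)
  expect_true(all(in_band[moved]))
})
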