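# Shared builders for tiny, fully hand-checkable trial fixtures.

tiny_design <- function(replicates = 2L) {
  trial_design(genotypes = c("A", "B"),
               p_levels = c("P+", "P-"),
               p_applied = c("P+" = 0.05, "P-" = 0.005),
               replicates_per_cell = replicates,
               platform_label = "tiny")
}

# Two genotypes x two levels x two replicates with simple round numbers so
# every metric can be recomputed on paper (see test-efficiency-metrics.R).
tiny_harvest <- function() {
  tibble::tibble(
    genotype = rep(c("A", "A", "A", "A", "B", "B", "B", "B"), each = 1L),
    p_level = rep(c("P+", "P+", "P-", "P-"), times = 2L),
    replicate = rep(c(1L, 2L), times = 4L),
    shoot_dw = c(2.0, 2.4, 0.5, 0.7, 1.6, 1.8, 0.8, 1.0),
    root_dw = c(1.0, 1.2, 0.30, 0.34, 0.8, 1.0, 0.5, 0.5),
    plant_p_concentration = c(0.06, 0.08, 0.010, 0.012, 0.05, 0.07, 0.02, 0.02),
    p_uptake = c(0.040, 0.044, 0.0010, 0.0012, 0.030, 0.036, 0.0020, 0.0024),
    height = NA_real_, culms = NA_real_)
}

# Direct product-moment correlation, written out in full as an oracle
# independent of stats::cor / cor.test.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  r <- sxy / sqrt(sxx * syy)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# Population-moment concordance written out in full (oracle for lin_ccc).
oracle_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}
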