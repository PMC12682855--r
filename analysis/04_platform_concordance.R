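#!/usr/bin/env Rscript
# Quantify agreement between the two phenotyping platforms: metric
# correlation matrices at each P level, and Pearson / Lin CCC /
# Bland-Altman on the cross-platform P indicator.

library(pindicator)

pmi <- load_table3("4PMI")
alsia <- load_table3("ALSIA")

cat("Genotype-mean metric correlations (masked at p >= 0.05):\n")
for (cond in c("P+", "P-")) {
  for (tab in list(pmi, alsia)) {
    cm <- correlation_matrix(tab, condition = cond)
    cat(sprintf("  %-6s %s: PAE-PUE r = %+.2f%s | PAE-PRAE r = %+.2f%s\n",
                attr(tab, "platform"), cond,
                cm$r["PAE", "PUE"], ifelse(is.na(cm$r_masked["PAE", "PUE"]), " (ns)", ""),
                cm$r["PAE", "PRAE"], ifelse(is.na(cm$r_masked["PAE", "PRAE"]), " (ns)", "")))
    readr::write_csv(as.data.frame(cm$r),
                     sprintf("results/corr_%s_%s.csv", tolower(attr(tab, "platform")),
                             ifelse(cond == "P+", "pplus", "pminus")))
  }
}

i4 <- compute_indicator(pmi, condition = "P-")
ia <- compute_indicator(alsia, condition = "P-")
ar <- agreement_report(i4$score, ia$score, labels = i4$genotype)
print(ar)
writeLines(jsonlite::toJSON(
  list(n = ar$n, pearson_r = ar$pearson_r, pearson_p = ar$pearson_p,
       ccc = ar$ccc, ccc_p = ar$ccc_p,
       loa = c(ar$bland_altman$loa_low, ar$bland_altman$loa_high),
       outliers = ar$bland_altman$outliers),
  auto_unbox = TRUE, digits = 6), "results/agreement_pminus.json")

cat("\nRank-normalized variant (robust to the printed precision of the tables):\n")
i4r <- compute_indicator(pmi, condition = "P-", normalization = "rank")
iar <- compute_indicator(alsia, condition = "P-", normalization = "rank")
cat(sprintf("  Pearson r = %.3f, CCC = %.3f\n",
            pearson_with_p(i4r$score, iar$score)$r, lin_ccc(i4r$score, iar$score)$ccc))
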