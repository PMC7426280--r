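#!/usr/bin/env Rscript
# Step 5: is the difference in Berger-Parker dominance between the two
# sites larger than chance? Randomization test with 10,000 random
# partitions of the pooled individuals, overall and per stage view.

suppressPackageStartupMessages(library(gardendiv))

seed <- 1L
m <- filter_status(read_occurrences("results/occurrences.csv"))
ss <- sites(m)

rows <- list()
for (sv in c("total", "adult")) {
  x1 <- pool(m, ss[1], sv); x2 <- pool(m, ss[2], sv)
  rt <- randomization_test(x1, x2, n_partitions = 10000, seed = seed)
  rows[[sv]] <- data.frame(
    stage = sv, site_1 = ss[1], site_2 = ss[2],
    invd_1 = round(rt$index_1, 2), invd_2 = round(rt$index_2, 2),
    observed_diff = round(rt$observed_stat, 3),
    p_value = rt$p_value, n_partitions = rt$n_partitions,
    significant_5pct = rt$p_value < 0.05)
}
tab <- do.call(rbind, rows); rownames(tab) <- NULL
write.csv(tab, "results/dominance_test.csv", row.names = FALSE)

cat("Dominance randomization tests (results/dominance_test.csv):\n")
print(tab, row.names = FALSE)
cat("\nFindings:",
    sum(tab$significant_5pct), "of", nrow(tab),
    "stage views show a dominance difference significant at the 5% level.\n")
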