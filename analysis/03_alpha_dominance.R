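#!/usr/bin/env Rscript
# Step 3: alpha diversity and dominance structure. Hill series (exp H',
# inverse Simpson, inverse Berger-Parker), rarity (singletons/doubletons),
# and the minimal set of species holding at least half the individuals.

suppressPackageStartupMessages(library(gardendiv))

m <- filter_status(read_occurrences("results/occurrences.csv"))

tab <- alpha_table(m)
num <- vapply(tab, is.numeric, TRUE)
tab[num] <- lapply(tab[num], round, 2)
write.csv(tab, "results/hill_series.csv", row.names = FALSE)
cat("Hill series and rarity (results/hill_series.csv):\n")
print(tab, row.names = FALSE)

dom_rows <- list()
for (sv in c("total", "adult")) for (s in sites(m)) {
  d <- dominance(pool(m, s, sv), species_meta = m$species_meta)
  top <- d$dominant_species
  dom_rows[[paste(sv, s)]] <- data.frame(
    stage = sv, site = s, dominant = top$species, status = top$status,
    trophic = top$trophic, abundance = top$abundance,
    share_pct = top$share_pct, dominant_set_size = length(d$dominant_set))
}
dom <- do.call(rbind, dom_rows); rownames(dom) <- NULL
write.csv(dom, "results/dominance.csv", row.names = FALSE)
cat("\nDominance (results/dominance.csv):\n")
print(dom, row.names = FALSE)
cat("\nFindings: the >= 50% dominant sets hold",
    min(dom$dominant_set_size), "-", max(dom$dominant_set_size),
    "species; smaller sets mean stronger dominance.\n")
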