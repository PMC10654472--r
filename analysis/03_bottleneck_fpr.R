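#!/usr/bin/env Rscript
# Stage 3 -- how often does pure bottleneck drift fake a domestication
# signal? False-positive rates of the farmed-vs-wild Fisher test under the
# documented demography (effective size dropping to ~100 breeders for 5-10
# generations), across starting wild frequencies and generation counts.

suppressPackageStartupMessages(library(domescan))

out <- "results/bottleneck"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

grid <- expand.grid(wild_freq = c(0.1, 0.3, 0.5),
                    generations = c(0, 5, 8, 10))
rows <- lapply(seq_len(nrow(grid)), function(i) {
  r <- bottleneck_fpr(grid$wild_freq[i], farmed_n = 37, wild_n = 54,
                      nb = 100, generations = grid$generations[i],
                      replicates = 1000, seed = 500 + i)
  cbind(wild_freq = grid$wild_freq[i], generations = grid$generations[i],
        r$fpr[, c("alpha", "fpr")])
})
tab <- do.call(rbind, rows)
write.table(tab, file.path(out, "fpr_grid.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

f5 <- tab[tab$alpha == 0.05, ]
message("FPR at alpha = 0.05 (1000 replicates each):")
for (g in unique(f5$generations)) {
  message(sprintf("  G = %2d: %s", g,
                  paste(sprintf("%.1f%%", 100 * f5$fpr[f5$generations == g]),
                        collapse = " / ")))
}
message("no-drift rows stay at/below the nominal 5%; ",
        "8 generations at nb = 100 inflate the FPR several-fold -- the ",
        "reason gene-level significance is checked against this null")
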