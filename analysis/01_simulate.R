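#!/usr/bin/env Rscript
# Stage 1 -- generate the study inputs.
#
# Gene-level track: individual genotype tables for the seabream vgll3-like
# design (54 wild / 37 farmed individuals over two collection periods),
# under a drift null and under a domestication-shifted alternative.
# Chromosome-level track: one simulated Pool-Seq chromosome (20,000 SNPs,
# 4 farmed + 4 wild pools of 25 at mean depth 60) carrying a delta = 0.3
# selected region, written as readcount pileups with a truth table, a
# library manifest and a GFF3 gene annotation.

suppressPackageStartupMessages(library(domescan))

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

design <- gene_sampling_design("seabream", "vgll3")
message("gene-level design: ", sum(design$n), " individuals (",
        sum(design$n[design$origin == "wild"]), " wild, ",
        sum(design$n[design$origin == "farmed"]), " farmed)")

null_tab <- simulate_genotypes(design, wild_freq = 0.35,
                               farmed_freq = "drift", locus = "vgll3_like",
                               seed = 101)
alt_tab <- simulate_genotypes(design, wild_freq = 0.35, farmed_freq = 0.70,
                              locus = "vgll3_like", seed = 102)
write_genotypes(null_tab, file.path(out, "genotypes_drift_null.tsv"))
write_genotypes(alt_tab, file.path(out, "genotypes_shifted.tsv"))
message("wrote genotype tables: drift null and shifted (0.35 -> 0.70)")

cfg <- poolseq_config(
  chrom = "chr1", chrom_length = 2e7, n_snps = 20000,
  pools = make_pools(n_farmed = 4, n_wild = 4, n_individuals = 25,
                     n_replicates = 2),
  mean_depth = 60, depth_dispersion = 5,
  selected_region = c(8e6, 8.5e6, 0.3),
  farmed_null = "drift", seed = 103
)
sim <- simulate_poolseq(cfg)
manifest <- write_poolseq_sim(sim, file.path(out, "poolseq"),
                              dialect = "readcount")
message("wrote Pool-Seq experiment: ", nrow(sim$truth), " SNPs, ",
        nrow(manifest), " libraries, selected region ",
        "8.0-8.5 Mbp (delta = 0.3), ",
        sum(sim$truth$in_selected_region), " SNPs inside")
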