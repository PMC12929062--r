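#!/usr/bin/env Rscript
# Step 2 — ASV filtering, normalization and broad-sense heritability screen.
#
# Retains ASVs with >= 10,000 total reads detected in >= 80% of samples,
# log-transforms relative abundances, fits the plot-level variance-component
# model per ASV, and keeps ASVs with H2 > 0.15. BLUEs of the retained ASVs
# feed the GWAS/TWAS steps.

library(rhizogwas)

counts <- read_table("results/sim/asv_counts.tsv", "asv_counts")
design <- utils::read.delim("results/sim/design.tsv")

cat(sprintf("Loaded %d samples x %d ASVs\n", nrow(counts), ncol(counts)))
filtered <- filter_asv_table(counts, min_total_reads = 10000,
                             min_prevalence = 0.8)
cat(sprintf("Filter (>= 10k reads, >= 80%% prevalence): %d ASVs retained\n",
            ncol(filtered)))

abund <- normalize_asv_abundance(filtered)
screen <- h2_screen(abund, design, h2_cutoff = 0.15)

write_results(screen$h2, "results/asv_h2.tsv")
n_herit <- sum(screen$h2$H2 > 0.15)
cat(sprintf("Heritability screen: %d / %d ASVs with H2 > 0.15 (median H2 of those %.2f)\n",
            n_herit, nrow(screen$h2),
            median(screen$h2$H2[screen$h2$H2 > 0.15])))

truth <- utils::read.delim("results/sim/asv_truth.tsv")
planted <- truth$asv[truth$h2_target > 0]
recovered <- intersect(planted, screen$h2$feature[screen$h2$H2 > 0.15])
cat(sprintf("Of %d ASVs simulated as heritable, %d pass the screen\n",
            length(planted), length(recovered)))

write_results(data.frame(genotype = rownames(screen$blues), screen$blues,
                         check.names = FALSE),
              "results/asv_blues.tsv")
cat(sprintf("BLUE matrix: %d genotypes x %d heritable ASVs -> results/asv_blues.tsv\n",
            nrow(screen$blues), ncol(screen$blues)))
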