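#!/usr/bin/env Rscript
# Step 1 — generate the study-shaped synthetic dataset.
#
# A 175-genotype diversity panel with LD-blocked SNPs on 5 chromosomes, a
# replicated field trial's ASV count table (15 of 120 ASVs heritable),
# BLUE-level root expression with cis effects and one trans hub, and ionome
# traits driven by genomic/expression/microbiome kernels. Everything is
# written as plain TSV under results/sim/ so later steps exercise the same
# readers a real analysis would.

library(rhizogwas)

seed <- 7
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cat("Simulating genotype panel...\n")
G <- simulate_genotypes(n_genotypes = 175, n_markers = 1000, n_chrom = 5,
                        chrom_len = 1e7, ld_block_len = 50000, seed = seed)
geno_tab <- data.frame(marker = G$map$marker, chrom = G$map$chrom,
                       pos = G$map$pos, t(G$codes), check.names = FALSE)
write_results(geno_tab, file.path(out, "genotypes.tsv"))
cat(sprintf("  %d genotypes x %d markers, %d chromosomes\n",
            nrow(G$codes), ncol(G$codes), length(unique(G$map$chrom))))

cat("Simulating rhizosphere ASV counts (replicated field design)...\n")
asv <- simulate_asv_counts(G, n_asvs = 120, n_heritable = 15, n_causal = 1,
                           h2_target = c(0.3, 0.6), sigma_g2 = 1,
                           n_reps = 3, n_blocks = 3, seed = seed + 1)
write_results(data.frame(sample = rownames(asv$counts), asv$counts,
                         check.names = FALSE),
              file.path(out, "asv_counts.tsv"))
write_results(asv$design, file.path(out, "design.tsv"))
write_results(asv$truth, file.path(out, "asv_truth.tsv"))
cat(sprintf("  %d samples x %d ASVs; %d heritable (H2 targets %.2f-%.2f)\n",
            nrow(asv$counts), ncol(asv$counts), 15, 0.3, 0.6))

cat("Simulating root expression with a trans hub...\n")
expr <- simulate_expression(G, n_genes = 300, cis_fraction = 0.3,
                            cis_effect = 1.5, hub_n_targets = 50,
                            hub_effect = 1.2, seed = seed + 2)
write_results(data.frame(genotype = rownames(expr$expr), expr$expr,
                         check.names = FALSE),
              file.path(out, "expression.tsv"))
bed <- to_bed(expr$coords, name_col = "feature")
utils::write.table(bed, file.path(out, "genes.bed"), sep = "\t",
                   quote = FALSE, row.names = FALSE, col.names = FALSE)
write_results(expr$truth, file.path(out, "expression_truth.tsv"))
cat(sprintf("  %d genes; hub SNP %s regulates %d targets\n",
            ncol(expr$expr), expr$truth$hub_snp[1], 50))

cat("Simulating ionome traits from omics kernels...\n")
K_wgs <- vanraden_grm(G)
K_gene <- feature_kinship(expr$expr)
weights <- rbind(N = c(1.0, 0.3), P = c(0.5, 0.8), K = c(0.8, 0.0))
ion <- simulate_ionome(list(WGS = K_wgs, Gene = K_gene), weights = weights,
                       sigma_e2 = 1, trait_names = rownames(weights),
                       seed = seed + 3)
write_results(data.frame(genotype = rownames(ion$traits), ion$traits,
                         check.names = FALSE),
              file.path(out, "ionome.tsv"))
write_results(ion$truth, file.path(out, "ionome_truth.tsv"))
cat(sprintf("  %d ionome traits for %d genotypes\n",
            ncol(ion$traits), nrow(ion$traits)))
cat("Done: inputs under", out, "\n")
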