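#!/usr/bin/env Rscript
# Step 4 — eGWAS, eQTL classification and distant-eQTL hotspot detection.
#
# QQ-normalized expression traits are scanned against the marker panel with
# the same Q + K mixed model; eSNPs significant after Bonferroni-Holm
# (m = number of SNPs) are traced to eQTL intervals, classified local/distant
# by the 50-kb rule, and distant-eQTL lead positions are scanned for hotspots
# (window 100 kb, significance 0.01).

library(rhizogwas)

G <- read_genotype_matrix("results/sim/genotypes.tsv", dialect = "tsv")
G <- filter_markers(G)
K <- vanraden_grm(G)
expr <- read_table("results/sim/expression.tsv", "feature_matrix")
genes <- read_table("results/sim/genes.bed", "bed_coordinates")

Y <- apply(expr, 2, qqnorm_transform)
rownames(Y) <- rownames(expr)

spec <- study_spec("egwas")
st <- run_association_study(spec, Y, G$codes, K)
thr <- attr(adjust_pvalues(st$results[[1]]$p, "holm"), "threshold")
cat(sprintf("eGWAS over %d genes x %d SNPs; Holm first-step threshold %.3g\n",
            ncol(Y), ncol(G$codes), thr))
cat(sprintf("%d significant eSNP-eGene associations for %d eGenes\n",
            nrow(st$significant), length(unique(st$significant$response))))

events <- list()
for (gene in unique(st$significant$response)) {
  sig <- st$significant[st$significant$response == gene, ]
  q <- qtl_intervals(sig, G)
  gi <- genes[genes$feature == gene, ]
  for (r in seq_len(nrow(q))) {
    cls <- classify_eqtl(q[r, ], list(chrom = gi$chrom, start = gi$start,
                                      end = gi$end))
    events[[length(events) + 1L]] <- data.frame(
      gene = gene, chrom = q$chrom[r], start = q$start[r], end = q$end[r],
      pos = G$map$pos[match(q$lead_snp[r], G$map$marker)],
      lead_snp = q$lead_snp[r], lead_p = q$lead_p[r], class = cls)
  }
}
eqtl <- do.call(rbind, events)
write_results(eqtl, "results/eqtl.tsv")
cat(sprintf("eQTL: %d total, %d local, %d distant (%.0f%% distant)\n",
            nrow(eqtl), sum(eqtl$class == "local"),
            sum(eqtl$class == "distant"),
            100 * mean(eqtl$class == "distant")))

sizes <- tapply(G$map$pos, G$map$chrom, max)
distant <- eqtl[eqtl$class == "distant", c("gene", "chrom", "pos")]
hs <- detect_hotspots(distant, sizes, window = 100000, signif = 0.01)
write_results(hs, "results/hotspots.tsv")
cat(sprintf("Hotspot scan: %d distant-eQTL hotspot region(s)\n", nrow(hs)))

truth <- utils::read.delim("results/sim/expression_truth.tsv")
hub <- truth$hub_snp[1]
hub_pos <- G$map$pos[match(hub, G$map$marker)]
hub_chr <- G$map$chrom[match(hub, G$map$marker)]
in_hub <- any(hs$chrom == hub_chr & hs$start <= hub_pos & hs$end >= hub_pos)
cat(sprintf("Planted trans hub (%s at %s:%d) %s a detected hotspot\n",
            hub, hub_chr, hub_pos,
            if (in_hub) "falls inside" else "was MISSED by"))
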