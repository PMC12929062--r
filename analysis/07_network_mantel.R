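#!/usr/bin/env Rscript
# Step 7 — cross-omics covariation (Mantel) and the regulatory network.
#
# Mantel permutation tests relate expression (Euclidean), ionome (Euclidean)
# and microbiome (Bray-Curtis on relative abundances) distance structures;
# then GWAS QTL, TWAS genes and hotspot-resident eQTL are assembled into the
# ASV-QTL-gene-hotspot edge list.

library(rhizogwas)

expr <- read_table("results/sim/expression.tsv", "feature_matrix")
ion <- read_table("results/sim/ionome.tsv", "feature_matrix")
blues <- read_table("results/asv_blues.tsv", "feature_matrix")
genos <- intersect(rownames(expr), rownames(blues))

D_expr <- as.matrix(dist(scale(expr[genos, ])))
D_ion <- as.matrix(dist(scale(ion[genos, ])))
ab <- exp(blues[genos, ])                 # back to abundance scale
rel <- ab / rowSums(ab)
n <- length(genos)                        # Bray-Curtis on relative abundances
D_asv <- matrix(0, n, n)
for (i in seq_len(n - 1)) for (j in (i + 1):n) {
  D_asv[i, j] <- D_asv[j, i] <-
    sum(abs(rel[i, ] - rel[j, ])) / sum(rel[i, ] + rel[j, ])
}

for (pair in list(c("expression", "microbiome"), c("expression", "ionome"),
                  c("microbiome", "ionome"))) {
  Ds <- list(expression = D_expr, microbiome = D_asv, ionome = D_ion)
  m <- mantel_test(Ds[[pair[1]]], Ds[[pair[2]]], permutations = 1999, seed = 7)
  cat(sprintf("Mantel %-11s vs %-11s: r = %6.3f, p = %.4f\n",
              pair[1], pair[2], m$r, m$p))
}

gwas_qtl <- NULL
if (file.exists("results/asv_qtl.tsv")) {
  q <- utils::read.delim("results/asv_qtl.tsv")
  gwas_qtl <- data.frame(asv = q$asv,
                         qtl = sprintf("QTL_%s:%d-%d", q$chrom,
                                       as.integer(q$start), as.integer(q$end)))
}
tw <- utils::read.delim("results/twas_significant.tsv")
twas <- if (nrow(tw)) data.frame(asv = tw$response, gene = tw$feature) else NULL
eq <- utils::read.delim("results/eqtl.tsv")
hs <- utils::read.delim("results/hotspots.tsv")

net <- assemble_network(gwas_qtl = gwas_qtl, twas = twas,
                        eqtl = eq[eq$class == "distant",
                                  c("gene", "chrom", "pos")],
                        hotspots = hs, environment = "E1")
write_results(net$edges, "results/network_edges.tsv")
write_results(net$degrees, "results/network_degrees.tsv")
cat(sprintf("Network: %d edges, %d nodes; top-degree node %s (%s, degree %d)\n",
            nrow(net$edges), nrow(net$degrees), net$degrees$node[1],
            net$degrees$kind[1], net$degrees$degree[1]))
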