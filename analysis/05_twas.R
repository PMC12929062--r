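#!/usr/bin/env Rscript
# Step 5 — transcriptome-wide association of heritable ASVs.
#
# Gene expression levels act as explanatory variables for ASV BLUEs, with an
# expression-derived kinship (K = MM'/c) controlling relatedness and hidden
# confounders; per-ASV BH FDR at 5%.

library(rhizogwas)

expr <- read_table("results/sim/expression.tsv", "feature_matrix")
blues <- read_table("results/asv_blues.tsv", "feature_matrix")

K_exp <- feature_kinship(expr)
spec <- study_spec("twas")
st <- run_association_study(spec, blues, expr, K_exp)

write_results(st$significant, "results/twas_significant.tsv")
cat(sprintf("TWAS over %d ASVs x %d genes: %d significant gene-ASV pairs (FDR 5%%)\n",
            ncol(blues), ncol(expr), nrow(st$significant)))
if (nrow(st$significant)) {
  per_asv <- table(st$significant$response)
  cat(sprintf("ASVs with >= 1 associated gene: %d (max %d genes for %s)\n",
              length(per_asv), max(per_asv), names(which.max(per_asv))))
}
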