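#' Default simulation configuration
#'
#' A study-shaped default: a 175-genotype diversity panel, 3 replicates with
#' 3 blocks each, 5 chromosomes of 10 Mb carrying LD-blocked biallelic SNPs,
#' ASV counts with genotype-attributable variance in the moderate-to-high
#' heritability range, expression with cis effects and a trans hub, and ionome
#' traits driven by omics kernels. Sized to run the full pipeline end-to-end
#' in minutes.
#'
#' @return named list of configuration values.
#' @export
default_sim_config <- function() {
  list(n_genotypes = 175L, n_reps = 3L, n_blocks = 3L,
       n_chrom = 5L, chrom_len = 1e7, n_markers = 5000L,
       ld_block_len = 50000, n_founders = 4L,
       n_asvs = 300L, n_heritable_asvs = 30L, h2_range = c(0.15, 0.6),
       library_size_meanlog = log(30000), library_size_sdlog = 0.3,
       n_genes = 1000L, cis_fraction = 0.3, cis_effect = 1.0,
       hub_n_targets = 50L, hub_effect = 1.0,
       ionome_sigma_e2 = 1.0)
}

#' Simulate an LD-blocked genotype panel
#'
#' Mosaic founder model: chromosomes are tiled into blocks of `ld_block_len`
#' bp; within a block every individual inherits two of `n_founders` founder
#' haplotypes (one per gamete), so markers in a block are strongly correlated
#' while blocks are independent. Founder allele patterns are drawn so each
#' marker is polymorphic among founders; marker columns whose realized MAF
#' falls below 0.05 are redrawn, so the returned panel passes a MAF >= 0.05
#' filter by construction.
#'
#' @param n_genotypes,n_markers panel dimensions.
#' @param n_chrom,chrom_len genome layout (equal-length chromosomes).
#' @param ld_block_len LD block length in bp.
#' @param n_founders founder haplotypes per block (default 4).
#' @param seed RNG seed.
#' @return `GenotypeMatrix`.
#' @export
simulate_genotypes <- function(n_genotypes = 175, n_markers = 5000,
                               n_chrom = 5, chrom_len = 1e7,
                               ld_block_len = 50000, n_founders = 4,
                               seed = 1) {
  if (n_markers < 1) stop("config error: n_markers must be positive")
  if (ld_block_len > chrom_len) stop("config error: block length exceeds chromosome")
  set.seed(seed)
  per_chr <- diff(round(seq(0, n_markers, length.out = n_chrom + 1)))
  codes <- NULL; maps <- list()
  for (c_i in seq_len(n_chrom)) {
    m <- per_chr[c_i]
    if (m == 0L) next
    pos <- sort(sample.int(chrom_len, m))
    block <- floor((pos - 1) / ld_block_len)
    cc <- matrix(0, n_genotypes, m)
    for (b in unique(block)) {
      cols <- which(block == b)
      f1 <- sample.int(n_founders, n_genotypes, replace = TRUE)
      f2 <- sample.int(n_founders, n_genotypes, replace = TRUE)
      for (j in cols) {
        repeat {
          ones <- sample(seq_len(n_founders - 1), 1)
          hap <- sample(c(rep(1, ones), rep(0, n_founders - ones)))
          dos <- hap[f1] + hap[f2]
          f <- mean(dos) / 2
          if (min(f, 1 - f) >= 0.05) break
        }
        cc[, j] <- dos
      }
    }
    codes <- cbind(codes, cc)
    maps[[c_i]] <- data.frame(marker = sprintf("chr%d_%d", c_i, pos),
                              chrom = sprintf("chr%d", c_i), pos = pos,
                              stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, maps)
  dimnames(codes) <- list(sprintf("G%03d", seq_len(n_genotypes)), map$marker)
  new_genotype_matrix(codes, map)
}

#' Simulate a replicated field trial
#'
#' Draws plot observations
#' \eqn{y_{ijk} = \mu + g_i + r_j + b_{jk} + e_{ijk}} around supplied genetic
#' values, with independent normal replicate, block-within-replicate and
#' residual effects.
#'
#' @param genetic_values named vector, one genetic value per genotype.
#' @param n_reps,n_blocks replicates and blocks per replicate.
#' @param mu general mean.
#' @param sigma_r2,sigma_b2,sigma_e2 variance components.
#' @param environment label stored in the table.
#' @param seed RNG seed.
#' @return plot-phenotype data.frame (`genotype`, `environment`, `replicate`,
#'   `block`, `value`).
#' @export
simulate_field_trial <- function(genetic_values, n_reps = 3, n_blocks = 3,
                                 mu = 0, sigma_r2 = 0, sigma_b2 = 0,
                                 sigma_e2 = 1, environment = "E1", seed = 1) {
  set.seed(seed)
  genos <- names(genetic_values)
  if (is.null(genos)) genos <- paste0("G", seq_along(genetic_values))
  n <- length(genetic_values)
  rows <- list()
  r_eff <- stats::rnorm(n_reps, 0, sqrt(sigma_r2))
  for (j in seq_len(n_reps)) {
    b_eff <- stats::rnorm(n_blocks, 0, sqrt(sigma_b2))
    block_of <- rep(seq_len(n_blocks), length.out = n)[sample.int(n)]
    rows[[j]] <- data.frame(
      genotype = genos, environment = environment,
      replicate = paste0("R", j), block = paste0("B", block_of),
      value = mu + genetic_values + r_eff[j] + b_eff[block_of] +
        stats::rnorm(n, 0, sqrt(sigma_e2)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate ASV count tables with genotype-attributable variance
#'
#' Builds latent per-plot log-abundances in which heritable ASVs carry causal
#' SNP effects scaled to a target plot-level heritability, then draws counts
#' per sample from a multinomial over ASVs with log-normal library sizes, so
#' the table is compositional like real amplicon data.
#'
#' @param G `GenotypeMatrix`.
#' @param n_asvs total ASVs.
#' @param n_heritable how many carry genetic signal.
#' @param n_causal causal SNPs per heritable ASV.
#' @param h2_target length-2 range (or single value) of target latent-scale
#'   heritability, must lie in \[0, 1).
#' @param sigma_g2 latent genetic variance per heritable ASV.
#' @param n_reps,n_blocks field design.
#' @param library_size_meanlog,library_size_sdlog log-normal library sizes.
#' @param seed RNG seed.
#' @return list: `counts` (sample x ASV integer matrix), `design` (sample,
#'   genotype, replicate, block), `truth` (asv, causal_snps, h2_target).
#' @export
simulate_asv_counts <- function(G, n_asvs = 300, n_heritable = 30,
                                n_causal = 2, h2_target = c(0.15, 0.6),
                                sigma_g2 = 0.5, n_reps = 3, n_blocks = 3,
                                library_size_meanlog = log(30000),
                                library_size_sdlog = 0.3, seed = 1) {
  if (any(h2_target < 0) || any(h2_target >= 1))
    stop("config error: target H2 must lie in [0, 1)")
  set.seed(seed)
  codes <- G$codes
  n <- nrow(codes)
  genos <- rownames(codes)
  design <- expand.grid(genotype = genos, replicate = paste0("R", seq_len(n_reps)),
                        stringsAsFactors = FALSE)
  design$block <- paste0("B", sample(rep(seq_len(n_blocks), length.out = nrow(design))))
  design$sample <- sprintf("S%04d", seq_len(nrow(design)))
  design <- design[, c("sample", "genotype", "replicate", "block")]
  ns <- nrow(design)
  gi <- match(design$genotype, genos)

  h2s <- if (length(h2_target) == 2L) stats::runif(n_heritable, h2_target[1], h2_target[2])
         else rep(h2_target, n_heritable)
  base <- stats::rnorm(n_asvs, 0, 1.5)  # spread of mean abundances across ASVs
  latent <- matrix(rep(base, each = ns), ns, n_asvs)
  truth <- data.frame(asv = sprintf("ASV%04d", seq_len(n_asvs)),
                      causal_snps = "", h2_target = 0, stringsAsFactors = FALSE)
  for (a in seq_len(n_heritable)) {
    snps <- sample(colnames(codes), n_causal)
    beta <- stats::rnorm(n_causal)
    g <- drop(codes[, snps, drop = FALSE] %*% beta)
    g <- (g - mean(g)) / stats::sd(g) * sqrt(sigma_g2)
    h2 <- h2s[a]
    sigma_e2 <- if (h2 > 0) sigma_g2 * n_reps * (1 - h2) / h2 else 1
    latent[, a] <- latent[, a] + g[gi] + stats::rnorm(ns, 0, sqrt(sigma_e2))
    truth$causal_snps[a] <- paste(snps, collapse = ",")
    truth$h2_target[a] <- h2
  }
  # non-heritable ASVs get plot noise of comparable size
  if (n_asvs > n_heritable) {
    idx <- (n_heritable + 1):n_asvs
    latent[, idx] <- latent[, idx] + matrix(stats::rnorm(ns * length(idx), 0, 1), ns)
  }
  lib <- round(stats::rlnorm(ns, library_size_meanlog, library_size_sdlog))
  counts <- matrix(0L, ns, n_asvs,
                   dimnames = list(design$sample, truth$asv))
  for (s in seq_len(ns)) {
    pr <- exp(latent[s, ]); pr <- pr / sum(pr)
    counts[s, ] <- stats::rmultinom(1, lib[s], pr)[, 1]
  }
  list(counts = counts, design = design, truth = truth)
}

#' Simulate expression with cis eQTL and a trans hub
#'
#' Each gene is placed on the simulated map; a configurable fraction receives
#' a cis effect from its nearest SNP, and a set of hub-target genes shares a
#' trans effect from a single hub SNP (the architecture behind a distant-eQTL
#' hotspot). Values are one per genotype (BLUE-level expression).
#'
#' @param G `GenotypeMatrix`.
#' @param n_genes number of genes.
#' @param cis_fraction fraction of genes with a cis effect.
#' @param cis_effect cis effect size (per dosage unit).
#' @param hub_snp marker id of the trans hub (default: a mid-genome marker).
#' @param hub_n_targets number of hub-regulated genes.
#' @param hub_effect trans effect size.
#' @param noise_sd residual sd (default 1).
#' @param gene_len gene length in bp (default 3000).
#' @param seed RNG seed.
#' @return list: `expr` (genotype x gene matrix), `coords` (feature, chrom,
#'   start, end), `truth` (gene, cis_snp, is_hub_target, hub_snp).
#' @export
simulate_expression <- function(G, n_genes = 1000, cis_fraction = 0.3,
                                cis_effect = 1.0, hub_snp = NULL,
                                hub_n_targets = 50, hub_effect = 1.0,
                                noise_sd = 1, gene_len = 3000, seed = 1) {
  if (hub_n_targets > n_genes) stop("config error: more hub targets than genes")
  set.seed(seed)
  codes <- G$codes; map <- G$map
  n <- nrow(codes)
  if (is.null(hub_snp)) hub_snp <- map$marker[round(nrow(map) / 2)]
  if (!hub_snp %in% map$marker) stop("config error: hub SNP not on the map")
  chroms <- unique(map$chrom)
  chrom_max <- vapply(chroms, function(ch) max(map$pos[map$chrom == ch]), 1)
  gene_chrom <- sample(chroms, n_genes, replace = TRUE)
  gene_start <- vapply(gene_chrom, function(ch)
    sample.int(max(1, chrom_max[[ch]] - gene_len), 1), 1L)
  coords <- data.frame(feature = sprintf("gene%04d", seq_len(n_genes)),
                       chrom = gene_chrom, start = gene_start,
                       end = gene_start + gene_len - 1L, stringsAsFactors = FALSE)
  expr <- matrix(stats::rnorm(n * n_genes, 0, noise_sd), n, n_genes,
                 dimnames = list(rownames(codes), coords$feature))
  is_cis <- stats::runif(n_genes) < cis_fraction
  cis_snp <- rep(NA_character_, n_genes)
  for (g in which(is_cis)) {
    on_chr <- which(map$chrom == coords$chrom[g])
    nearest <- on_chr[which.min(abs(map$pos[on_chr] - coords$start[g]))]
    cis_snp[g] <- map$marker[nearest]
    expr[, g] <- expr[, g] + cis_effect * codes[, nearest]
  }
  hub_targets <- sample.int(n_genes, hub_n_targets)
  if (hub_effect != 0) {
    hub_dos <- codes[, hub_snp]
    for (g in hub_targets) expr[, g] <- expr[, g] + hub_effect * hub_dos
  }
  truth <- data.frame(gene = coords$feature, cis_snp = cis_snp,
                      is_hub_target = seq_len(n_genes) %in% hub_targets,
                      hub_snp = hub_snp, stringsAsFactors = FALSE)
  list(expr = expr, coords = coords, truth = truth)
}

#' Simulate ionome traits from omics kernels
#'
#' Traits are sums of kernel-driven genetic values plus residual noise:
#' \eqn{y = \sum_i u_i + e}, \eqn{u_i \sim N(0, V_i w_i)},
#' \eqn{e \sim N(0, \sigma_e^2 I)}. Realized variance fractions per kernel are
#' recorded as ground truth.
#'
#' @param kernels named list of `KinshipMatrix` (or matrices), equal order.
#' @param weights numeric vector (one trait) or matrix (traits x kernels) of
#'   kernel variances \eqn{w_i >= 0}.
#' @param sigma_e2 residual variance.
#' @param trait_names optional names.
#' @param exact if TRUE, each drawn component is rescaled so its realized
#'   variance equals its target exactly (fixes the realized signal-to-noise
#'   ratio instead of letting it fluctuate between draws).
#' @param seed RNG seed.
#' @return list: `traits` (genotype x trait matrix), `truth` (trait, kernel,
#'   realized_var_fraction).
#' @export
simulate_ionome <- function(kernels, weights, sigma_e2 = 1,
                            trait_names = NULL, exact = FALSE, seed = 1) {
  Ks <- lapply(kernels, function(k) if (inherits(k, "KinshipMatrix")) k$K else k)
  if (is.vector(weights)) weights <- matrix(weights, nrow = 1)
  if (any(weights < 0)) stop("config error: negative kernel weight")
  stopifnot(ncol(weights) == length(Ks))
  set.seed(seed)
  n <- nrow(Ks[[1]])
  roots <- lapply(Ks, function(K) {
    e <- eigen(K, symmetric = TRUE)
    e$vectors %*% diag(sqrt(pmax(e$values, 0)), n)
  })
  n_traits <- nrow(weights)
  if (is.null(trait_names)) trait_names <- paste0("trait", seq_len(n_traits))
  traits <- matrix(0, n, n_traits,
                   dimnames = list(rownames(Ks[[1]]), trait_names))
  truth <- list()
  for (t_i in seq_len(n_traits)) {
    parts <- matrix(0, n, length(Ks))
    for (i in seq_along(Ks)) {
      if (weights[t_i, i] > 0) {
        u <- drop(roots[[i]] %*% stats::rnorm(n))
        if (exact) u <- u / stats::sd(u)
        parts[, i] <- sqrt(weights[t_i, i]) * u
      }
    }
    e <- stats::rnorm(n)
    e <- if (exact) sqrt(sigma_e2) * e / stats::sd(e) else sqrt(sigma_e2) * e
    y <- rowSums(parts) + e
    traits[, t_i] <- y
    vtot <- stats::var(y)
    truth[[t_i]] <- data.frame(trait = trait_names[t_i],
                               kernel = names(kernels),
                               realized_var_fraction = apply(parts, 2, stats::var) / vtot,
                               stringsAsFactors = FALSE)
  }
  list(traits = traits, truth = do.call(rbind, truth))
}
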