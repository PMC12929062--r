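# Shared fixtures, built in code at test time.

# small diversity panel used across modules
small_panel <- function(n = 175, m = 400, n_chrom = 2, chrom_len = 2e6,
                        block = 10000, seed = 11) {
  simulate_genotypes(n_genotypes = n, n_markers = m, n_chrom = n_chrom,
                     chrom_len = chrom_len, ld_block_len = block, seed = seed)
}

# effectively unlinked markers: one marker per block
unlinked_panel <- function(n = 175, m = 300, seed = 11) {
  simulate_genotypes(n_genotypes = n, n_markers = m, n_chrom = 1,
                     chrom_len = m * 50000, ld_block_len = 49999, seed = seed)
}

# write a minimal biallelic VCF for io tests
write_toy_vcf <- function(path, samples, records) {
  # records: data.frame chrom, pos, id, ref, alt, gts (list of genotype strings)
  con <- file(path, "w")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  for (i in seq_len(nrow(records))) {
    writeLines(paste(c(records$chrom[i], records$pos[i], records$id[i],
                       records$ref[i], records$alt[i], ".", "PASS", ".", "GT",
                       records$gts[[i]]), collapse = "\t"), con)
  }
  close(con)
  path
}

# independent textbook step-up / step-down adjustment oracles
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- rev(cummin(rev(m * ps / seq_len(m))))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- cummax((m - seq_len(m) + 1) * ps)
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# dense restricted log-likelihood for the plot model (genotype + replicate
# random, intercept fixed), used as a grid oracle on tiny instances
plot_reml_loglik <- function(d, sg2, sr2, se2) {
  n <- nrow(d)
  Zg <- stats::model.matrix(~ 0 + factor(genotype), d)
  Zr <- stats::model.matrix(~ 0 + factor(replicate), d)
  V <- sg2 * tcrossprod(Zg) + sr2 * tcrossprod(Zr) + se2 * diag(n)
  X <- matrix(1, n, 1)
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)
  beta <- solve(XtViX, crossprod(X, Vi %*% d$value))
  r <- d$value - drop(X %*% beta)
  -0.5 * (determinant(V)$modulus[1] + determinant(XtViX)$modulus[1] +
            drop(crossprod(r, Vi %*% r)) + (n - 1) * log(2 * pi))
}

# genotype vector with a prescribed approximate correlation to a focal vector
corr_neighbor <- function(focal, rho, seed) {
  set.seed(seed)
  n <- length(focal)
  z <- scale(focal)[, 1]
  w <- rho * z + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
  # discretize back to dosage codes while keeping the correlation's sign/size
  as.numeric(cut(w, stats::quantile(w, c(0, .25, .75, 1)), labels = FALSE,
                 include.lowest = TRUE)) - 1
}
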