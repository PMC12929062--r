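#' VanRaden genomic relationship matrix
#'
#' \deqn{G = ZZ' / (2 \sum_k p_k (1 - p_k))} with Z the column-centered
#' dosage matrix (codes minus twice the allele frequency of the counted
#' allele).
#'
#' @param G a `GenotypeMatrix` or a sample x marker dosage matrix (0..2, no
#'   missing values).
#' @return `KinshipMatrix`: list with `K` (n x n), `genotype_ids`, `kind =
#'   "vanraden"`, and `scaling_constant` (the VanRaden denominator).
#' @export
vanraden_grm <- function(G) {
  codes <- if (inherits(G, "GenotypeMatrix")) G$codes else G
  stopifnot(is.matrix(codes))
  if (anyNA(codes)) stop("missing codes; impute before kinship construction")
  p <- colMeans(codes) / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < 2L) stop("need >= 2 polymorphic markers")
  codes <- codes[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(codes, 2, 2 * p)
  c0 <- 2 * sum(p * (1 - p))
  K <- tcrossprod(Z) / c0
  new_kinship(K, rownames(codes), kind = "vanraden", scaling_constant = c0)
}

#' Feature-derived kinship (expression or ASV kernel)
#'
#' \deqn{K = MM' / c} where M holds per-feature standardized values (mean 0,
#' population sd 1) and c is the mean of the diagonal of MM', so the mean
#' diagonal of K is exactly 1.
#'
#' @param M genotype x feature numeric matrix (row names = genotype ids).
#' @return `KinshipMatrix` with `kind = "feature"`.
#' @export
feature_kinship <- function(M) {
  stopifnot(is.matrix(M), nrow(M) >= 2L)
  if (anyNA(M)) stop("missing feature values")
  sdv <- apply(M, 2, function(x) sqrt(mean((x - mean(x))^2)))  # ddof 0
  drop <- sdv == 0
  if (all(drop)) stop("all features have zero variance")
  if (any(drop)) warning(sum(drop), " zero-variance feature(s) dropped")
  M <- M[, !drop, drop = FALSE]
  if (ncol(M) < 2L) stop("need >= 2 informative features")
  Ms <- scale(M, center = TRUE, scale = sdv[!drop])
  MM <- tcrossprod(Ms)
  c0 <- mean(diag(MM))
  new_kinship(MM / c0, rownames(M), kind = "feature", scaling_constant = c0)
}

new_kinship <- function(K, ids, kind, scaling_constant) {
  K <- (K + t(K)) / 2  # enforce exact symmetry against float drift
  dimnames(K) <- list(ids, ids)
  out <- list(K = K, genotype_ids = ids, kind = kind,
              scaling_constant = scaling_constant)
  class(out) <- "KinshipMatrix"
  out
}

#' @export
print.KinshipMatrix <- function(x, ...) {
  cat(sprintf("KinshipMatrix (%s): %d genotypes, mean diag %.4f, c = %.4f\n",
              x$kind, nrow(x$K), mean(diag(x$K)), x$scaling_constant))
  invisible(x)
}

#' Leading principal components of a kinship matrix
#'
#' Used as optional fixed covariates ("Q") in the Q + K association model.
#'
#' @param K `KinshipMatrix`.
#' @param n_pcs number of components (0 returns NULL).
#' @return n x n_pcs matrix of eigenvector scores, or NULL.
#' @export
kinship_pcs <- function(K, n_pcs) {
  if (n_pcs == 0L) return(NULL)
  e <- eigen(K$K, symmetric = TRUE)
  pcs <- e$vectors[, seq_len(n_pcs), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(n_pcs)], 0)), n_pcs)
  rownames(pcs) <- K$genotype_ids
  colnames(pcs) <- paste0("PC", seq_len(n_pcs))
  pcs
}
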