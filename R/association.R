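#' Marker filters for association scans
#'
#' Keeps markers with minor allele frequency at least `maf_min` and a
#' heterozygosity rate (fraction of code-1 calls) at most `het_max`.
#'
#' @param G `GenotypeMatrix`.
#' @param maf_min minimum MAF (default 0.05).
#' @param het_max maximum heterozygous fraction (default 0.95).
#' @return filtered `GenotypeMatrix`.
#' @export
filter_markers <- function(G, maf_min = 0.05, het_max = 0.95) {
  stopifnot(inherits(G, "GenotypeMatrix"))
  codes <- G$codes
  freq <- colMeans(codes) / 2
  maf <- pmin(freq, 1 - freq)
  het <- colMeans(codes == 1)
  keep <- maf >= maf_min & het <= het_max
  if (!any(keep)) stop("filter error: no markers pass MAF/heterozygosity filters")
  out <- G
  out$codes <- codes[, keep, drop = FALSE]
  out$map <- G$map[keep, , drop = FALSE]
  out$marker_ids <- out$map$marker
  out
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up FDR, Holm step-down, or Bonferroni. For Holm and
#' Bonferroni the first-step genome-wide threshold `alpha/m` is attached as
#' attribute `"threshold"` (the raw-p cutoff at which the most significant
#' test survives).
#'
#' @param p vector of raw p values in (0, 1].
#' @param method `"bh_fdr"`, `"holm"` or `"bonferroni"`.
#' @param alpha significance level used for the reported threshold
#'   (default 0.05).
#' @param m number of tests; defaults to `length(p)`. Supplying a larger `m`
#'   reproduces a correction sized to a full marker panel when only a subset
#'   of p values is in hand.
#' @return adjusted p values (capped at 1), with attribute `threshold` for
#'   holm/bonferroni.
#' @export
adjust_pvalues <- function(p, method = c("bh_fdr", "holm", "bonferroni"),
                           alpha = 0.05, m = length(p)) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p values must lie in (0, 1]")
  if (m < length(p)) stop("m cannot be smaller than length(p)")
  adj <- switch(method,
    bh_fdr = stats::p.adjust(p, method = "BH", n = m),
    holm = stats::p.adjust(p, method = "holm", n = m),
    bonferroni = stats::p.adjust(p, method = "bonferroni", n = m))
  if (method != "bh_fdr") attr(adj, "threshold") <- alpha / m
  adj
}

#' Specification of an association study
#'
#' @param mode `"gwas"`, `"egwas"` or `"twas"`.
#' @param kinship `"vanraden"` (gwas/egwas) or `"feature"` (twas). Defaults to
#'   the mode's required kind.
#' @param adjust multiple-testing method (default BH FDR for gwas/twas, Holm
#'   for egwas, matching the study design).
#' @param alpha significance level (default 0.05).
#' @param n_pcs number of kinship principal components used as fixed
#'   covariates ("Q"); default 0 (intercept only).
#' @return `StudySpec` list.
#' @export
study_spec <- function(mode = c("gwas", "egwas", "twas"), kinship = NULL,
                       adjust = NULL, alpha = 0.05, n_pcs = 0L) {
  mode <- match.arg(mode)
  required <- if (mode == "twas") "feature" else "vanraden"
  if (is.null(kinship)) kinship <- required
  if (kinship != required)
    stop("invalid study spec: mode ", mode, " requires kinship '", required, "'")
  if (is.null(adjust)) adjust <- if (mode == "egwas") "holm" else "bh_fdr"
  adjust <- match.arg(adjust, c("bh_fdr", "holm", "bonferroni"))
  structure(list(mode = mode, kinship = kinship, adjust = adjust,
                 alpha = alpha, n_pcs = as.integer(n_pcs)),
            class = "StudySpec")
}

#' Run a GWAS / eGWAS / TWAS over one or more response traits
#'
#' For each response: a REML null fit of the Q + K mixed model, a P3D Wald
#' scan over all explanatory features, and multiple-testing adjustment
#' within the response (BH FDR at 5% for GWAS/TWAS; Holm across the marker
#' panel for eGWAS).
#'
#' @param spec `StudySpec` from [study_spec()].
#' @param responses genotype x trait matrix of response values (ASV BLUEs for
#'   gwas/twas; QQ-normalized expression for egwas). Row names are genotype
#'   ids.
#' @param explanatory genotype x feature matrix: marker dosages (gwas/egwas)
#'   or standardized expression (twas). Row names are genotype ids.
#' @param kinship `KinshipMatrix` whose `kind` matches the spec.
#' @return list with `results` (one association data.frame per response,
#'   columns of [p3d_wald_scan()] plus `p_adj` and `significant`) and
#'   `significant` (combined data.frame over responses).
#' @export
run_association_study <- function(spec, responses, explanatory, kinship) {
  stopifnot(inherits(spec, "StudySpec"), inherits(kinship, "KinshipMatrix"))
  if (kinship$kind != spec$kinship)
    stop("kinship kind '", kinship$kind, "' does not match study spec")
  responses <- as.matrix(responses)
  common <- Reduce(intersect, list(rownames(responses), rownames(explanatory),
                                   kinship$genotype_ids))
  if (length(common) < 30L)
    stop("sample-size error: fewer than 30 overlapping genotypes")
  Y <- responses[common, , drop = FALSE]
  E <- as.matrix(explanatory)[common, , drop = FALSE]
  Kc <- kinship
  idx <- match(common, kinship$genotype_ids)
  Kc$K <- kinship$K[idx, idx]
  Kc$genotype_ids <- common
  if (spec$mode == "twas") E <- scale(E)  # per-sd expression effects
  X <- cbind(intercept = rep(1, length(common)), kinship_pcs(Kc, spec$n_pcs))

  rot <- eigen(Kc$K, symmetric = TRUE)  # shared across response traits
  results <- vector("list", ncol(Y))
  names(results) <- colnames(Y)
  for (j in seq_len(ncol(Y))) {
    nf <- reml_null_fit(Y[, j], X, Kc, rotation = rot)
    res <- p3d_wald_scan(nf, E)
    res$p_adj <- as.numeric(adjust_pvalues(res$p, method = spec$adjust,
                                           alpha = spec$alpha))
    res$significant <- res$p_adj < spec$alpha
    res$response <- colnames(Y)[j]
    results[[j]] <- res
  }
  sig <- do.call(rbind, lapply(results, function(r) r[r$significant, , drop = FALSE]))
  rownames(sig) <- NULL
  list(results = results, significant = sig, genotypes = common)
}
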