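#' Filter an ASV count table for robust features
#'
#' Retains ASVs with a total read count of at least `min_total_reads` and
#' detected (nonzero) in at least `ceiling(min_prevalence * n_samples)`
#' samples. The sample set is unchanged.
#'
#' @param counts sample x ASV matrix of non-negative integer counts.
#' @param min_total_reads minimum column sum (default 10000).
#' @param min_prevalence minimum detection fraction across samples
#'   (default 0.8).
#' @return the filtered count matrix.
#' @export
filter_asv_table <- function(counts, min_total_reads = 10000,
                             min_prevalence = 0.8) {
  stopifnot(is.matrix(counts))
  if (min_prevalence < 0 || min_prevalence > 1)
    stop("min_prevalence must be in [0, 1]")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  n <- nrow(counts)
  keep <- colSums(counts) >= min_total_reads &
    colSums(counts > 0) >= ceiling(min_prevalence * n)
  counts[, keep, drop = FALSE]
}

#' Log relative-abundance normalization
#'
#' Converts counts to per-sample relative abundances and log-transforms with a
#' pseudocount, reducing compositional bias and approximating normality.
#'
#' @param counts filtered sample x ASV count matrix.
#' @param pseudocount added to the relative abundance before the log
#'   (default 1e-6).
#' @return sample x ASV matrix of log(p + pseudocount) values.
#' @export
normalize_asv_abundance <- function(counts, pseudocount = 1e-6) {
  stopifnot(is.matrix(counts))
  rs <- rowSums(counts)
  if (any(rs == 0)) stop("sample(s) with zero total reads: ",
                         paste(rownames(counts)[rs == 0], collapse = ", "))
  log(counts / rs + pseudocount)
}

#' Fit the plot-level variance-component model for one environment
#'
#' Fits, by REML, the randomized-trial model
#' \deqn{y_{ijk} = \mu + g_i + r_j + b_{jk} + e_{ijk}}
#' with genotype (g), replicate (r) and block-within-replicate (b) all random,
#' for observations from a single environment.
#'
#' @param trait data.frame with columns `genotype`, `environment`,
#'   `replicate`, `block`, `value`.
#' @param environment environment to subset to; `NULL` requires `trait` to be
#'   single-environment already.
#' @return `VarianceComponents`: list with `sigma_g2`, `sigma_r2`, `sigma_b2`,
#'   `sigma_e2`, `mu`, `n_reps`, and the `lme4` fit in `$fit`.
#' @export
fit_plot_lmm <- function(trait, environment = NULL) {
  d <- .subset_env(trait, environment)
  if (length(unique(d$genotype)) < 2L) stop("need >= 2 genotypes")
  if (nrow(d) < 4L) stop("singular design: too few observations")
  d$genotype <- factor(d$genotype)
  d$replicate <- factor(d$replicate)
  d$rep_block <- interaction(d$replicate, d$block, drop = TRUE)
  form <- value ~ 1 + (1 | genotype) + (1 | replicate)
  if (nlevels(d$rep_block) > nlevels(d$replicate)) {
    form <- value ~ 1 + (1 | genotype) + (1 | replicate) + (1 | rep_block)
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = d, REML = TRUE,
               control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                           check.nobs.vs.nRE = "ignore",
                                           calc.derivs = FALSE))
  ))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v else 0
  }
  out <- list(sigma_g2 = getv("genotype"),
              sigma_r2 = getv("replicate"),
              sigma_b2 = getv("rep_block"),
              sigma_e2 = getv("Residual"),
              mu = unname(lme4::fixef(fit)[1]),
              n_reps = length(unique(d$replicate)),
              fit = fit)
  class(out) <- "VarianceComponents"
  out
}

.subset_env <- function(trait, environment) {
  stopifnot(all(c("genotype", "replicate", "block", "value") %in% names(trait)))
  if (!is.null(environment)) {
    trait <- trait[trait$environment == environment, , drop = FALSE]
  } else if ("environment" %in% names(trait) &&
             length(unique(trait$environment)) > 1L) {
    stop("multiple environments present; pass `environment`")
  }
  trait <- trait[is.finite(trait$value), , drop = FALSE]
  if (nrow(trait) == 0L) stop("no observations after filtering")
  trait
}

#' Broad-sense heritability on an entry-mean basis
#'
#' \deqn{H^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2 / R)}
#' where R is the number of replications.
#'
#' @param vc a `VarianceComponents` object or a list with `sigma_g2`,
#'   `sigma_e2`, `n_reps`.
#' @param n_reps overrides `vc$n_reps` when given.
#' @return H2 in \[0, 1\].
#' @export
estimate_h2 <- function(vc, n_reps = NULL) {
  R <- if (is.null(n_reps)) vc$n_reps else n_reps
  if (is.null(R) || R <= 0) stop("number of replications must be positive")
  denom <- vc$sigma_g2 + vc$sigma_e2 / R
  if (denom <= 0) return(0)
  vc$sigma_g2 / denom
}

#' Best linear unbiased estimates of genotype means
#'
#' Refits the plot model with the general mean and genotype effects fixed and
#' replicate / block-within-replicate random, and returns per-genotype BLUEs
#' (mean + genotype contrast).
#'
#' @inheritParams fit_plot_lmm
#' @return named numeric vector of BLUEs, one per genotype with observations.
#' @export
compute_blues <- function(trait, environment = NULL) {
  d <- .subset_env(trait, environment)
  d$genotype <- factor(d$genotype)
  d$replicate <- factor(d$replicate)
  d$rep_block <- interaction(d$replicate, d$block, drop = TRUE)
  rand <- if (nlevels(d$rep_block) > nlevels(d$replicate)) {
    value ~ 0 + genotype + (1 | replicate) + (1 | rep_block)
  } else {
    value ~ 0 + genotype + (1 | replicate)
  }
  if (nlevels(d$replicate) < 2L) {
    # no replicate structure: BLUE reduces to the genotype mean
    blues <- tapply(d$value, d$genotype, mean)
    return(stats::setNames(as.numeric(blues), names(blues)))
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(rand, data = d, REML = TRUE,
               control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                           check.nobs.vs.nRE = "ignore",
                                           calc.derivs = FALSE))
  ))
  b <- lme4::fixef(fit)
  names(b) <- sub("^genotype", "", names(b))
  b[levels(d$genotype)]
}

#' Rank-based inverse-normal (QQ-normal) transform
#'
#' Maps values to normal scores via Blom's offset, \eqn{\Phi^{-1}((r - 3/8) /
#' (n + 1/4))}; tied observations receive the average normal score over their
#' rank span so the transform is well defined on discrete data.
#'
#' @param values numeric vector, length >= 2, not all equal.
#' @return numeric vector of normal scores (mean approximately 0).
#' @export
qqnorm_transform <- function(values) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 values")
  if (anyNA(values)) stop("missing values not allowed")
  if (max(values) == min(values)) stop("constant vector cannot be transformed")
  # average the Blom scores of the integer ranks spanned by each tie group
  score <- stats::qnorm((seq_len(n) - 3 / 8) / (n + 1 / 4))
  r <- rank(values, ties.method = "min")
  cnt <- table(r)
  avg <- vapply(as.integer(names(cnt)), function(lo) {
    mean(score[lo:(lo + cnt[[as.character(lo)]] - 1L)])
  }, numeric(1))
  unname(avg[match(r, as.integer(names(cnt)))])
}

#' Heritability screen over an ASV abundance table
#'
#' Runs the full per-feature screen for one environment: variance-component
#' fit, broad-sense heritability, and BLUEs for features passing the H2
#' cutoff.
#'
#' @param abund sample x feature matrix of normalized abundances; row names
#'   are sample ids matching `design$sample`.
#' @param design data.frame with columns `sample`, `genotype`, `replicate`,
#'   `block` describing each row of `abund`.
#' @param h2_cutoff retain features with H2 strictly greater (default 0.15).
#' @return list with `h2` (data.frame feature, H2, sigma_g2, sigma_e2) and
#'   `blues` (genotype x retained-feature matrix).
#' @export
h2_screen <- function(abund, design, h2_cutoff = 0.15) {
  stopifnot(identical(rownames(abund), design$sample))
  feats <- colnames(abund)
  h2 <- numeric(length(feats)); sg <- h2; se <- h2
  for (i in seq_along(feats)) {
    d <- data.frame(genotype = design$genotype, replicate = design$replicate,
                    block = design$block, value = abund[, i])
    vc <- fit_plot_lmm(d)
    h2[i] <- estimate_h2(vc); sg[i] <- vc$sigma_g2; se[i] <- vc$sigma_e2
  }
  keep <- which(h2 > h2_cutoff)
  blues <- NULL
  if (length(keep)) {
    genos <- sort(unique(design$genotype))
    blues <- matrix(NA_real_, length(genos), length(keep),
                    dimnames = list(genos, feats[keep]))
    for (j in seq_along(keep)) {
      d <- data.frame(genotype = design$genotype, replicate = design$replicate,
                      block = design$block, value = abund[, keep[j]])
      b <- compute_blues(d)
      blues[names(b), j] <- b
    }
  }
  list(h2 = data.frame(feature = feats, H2 = h2, sigma_g2 = sg, sigma_e2 = se,
                       stringsAsFactors = FALSE),
       blues = blues)
}
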