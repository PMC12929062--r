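#' Enumerate multi-omics prediction scenarios
#'
#' All non-empty subsets of the supplied omics layers, ordered by subset size
#' then lexicographically; a scenario's name is the sorted concatenation of
#' its members. Four layers give the 15 ionome scenarios; three give the 7 ASV
#' scenarios.
#'
#' @param layers character vector of 1-4 unique kernel names, e.g.
#'   `c("WGS", "RNA", "Gene", "ASV")`.
#' @return data.frame with `name` and list-column `members`.
#' @export
enumerate_scenarios <- function(layers) {
  if (anyDuplicated(layers)) stop("duplicate layer name")
  if (length(layers) < 1L || length(layers) > 4L)
    stop("between 1 and 4 layers supported")
  subsets <- list()
  for (size in seq_along(layers)) {
    cmb <- utils::combn(sort(layers), size, simplify = FALSE)
    subsets <- c(subsets, cmb[order(vapply(cmb, paste, "", collapse = "_"))])
  }
  data.frame(name = vapply(subsets, paste, "", collapse = "_"),
             members = I(subsets), stringsAsFactors = FALSE)
}

#' Seeded fold assignment for one cross-validation repeat
#'
#' Deterministic counter scheme: repeat `rep_i` under base seed `seed` always
#' yields the same partition, and every genotype lands in exactly one fold.
#'
#' @param n number of genotypes.
#' @param folds number of folds.
#' @param seed base seed.
#' @param rep_i repeat counter (>= 1).
#' @return integer vector of fold labels in `1:folds`, length `n`.
#' @export
cv_folds <- function(n, folds, seed, rep_i = 1L) {
  set.seed((seed * 1009L + rep_i) %% 2147483647L)
  fold_of <- integer(n)
  fold_of[sample.int(n)] <- rep(seq_len(folds), length.out = n)
  fold_of
}

#' Repeated cross-validated kernel prediction
#'
#' Five-fold cross-validation of the multi-kernel mixed model, repeated with
#' reshuffled folds. Per repeat, genotypes are partitioned into folds
#' (each genotype in exactly one fold); per fold the model is fitted on the
#' training genotypes and the held-out genotypes are predicted through the
#' BLUP cross-covariance; the repeat's accuracy is the Pearson correlation
#' between observed and pooled predicted values. Fold shuffles are derived
#' from `seed` by a per-repeat counter so results are reproducible.
#'
#' @param y named trait vector (BLUEs), aligned with the kernels.
#' @param kernels named list of `KinshipMatrix` covering all genotypes.
#' @param scenario character vector of kernel names to use (a row of
#'   [enumerate_scenarios()]'s `members`), or NULL for all.
#' @param folds number of CV folds (default 5).
#' @param repeats number of repeats (default 100).
#' @param seed base RNG seed.
#' @param method variance estimation passed to [fit_multikernel()].
#' @return `CVResult`: list with `scenario`, `mean_r`, `sd_r`, `r` (length
#'   `repeats`).
#' @export
kernel_cv_predict <- function(y, kernels, scenario = NULL, folds = 5,
                              repeats = 100, seed = 1, method = "reml") {
  if (stats::var(y) == 0) stop("constant trait: accuracy undefined")
  if (!is.null(scenario)) kernels <- kernels[scenario]
  stopifnot(length(kernels) >= 1L, !anyNA(names(kernels)))
  n <- length(y)
  if (n < 5 * folds) stop("need at least ", 5 * folds, " genotypes")
  Ks <- lapply(kernels, function(k) if (inherits(k, "KinshipMatrix")) k$K else k)
  r <- numeric(repeats)
  for (rep_i in seq_len(repeats)) {
    fold_of <- cv_folds(n, folds, seed, rep_i)
    pred <- rep(NA_real_, n)
    for (f in seq_len(folds)) {
      test <- which(fold_of == f)
      train <- which(fold_of != f)
      Ktr <- lapply(Ks, function(K) K[train, train, drop = FALSE])
      fit <- fit_multikernel(y[train], Ktr, method = method)
      pred[test] <- predict_multikernel(fit, Ks, train, test)
    }
    r[rep_i] <- stats::cor(y, pred)
  }
  out <- list(scenario = paste(sort(names(kernels)), collapse = "_"),
              mean_r = mean(r), sd_r = stats::sd(r), r = r,
              folds = folds, repeats = repeats)
  class(out) <- "CVResult"
  out
}

#' @export
print.CVResult <- function(x, ...) {
  cat(sprintf("CV prediction [%s]: mean r = %.3f (sd %.3f) over %d x %d-fold\n",
              x$scenario, x$mean_r, x$sd_r, x$repeats, x$folds))
  invisible(x)
}

#' Cross-validated accuracy for every scenario
#'
#' @inheritParams kernel_cv_predict
#' @param layers layer names to enumerate (default: names of `kernels`).
#' @return data.frame with one row per scenario: `scenario`, `n_layers`,
#'   `mean_r`, `sd_r`.
#' @export
scenario_cv_table <- function(y, kernels, layers = names(kernels), folds = 5,
                              repeats = 100, seed = 1, method = "reml") {
  sc <- enumerate_scenarios(layers)
  rows <- lapply(sc$members, function(mem) {
    cv <- kernel_cv_predict(y, kernels, scenario = mem, folds = folds,
                            repeats = repeats, seed = seed, method = method)
    data.frame(scenario = cv$scenario, n_layers = length(mem),
               mean_r = cv$mean_r, sd_r = cv$sd_r, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
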