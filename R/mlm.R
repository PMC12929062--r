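#' REML null fit of the kinship mixed model
#'
#' Fits \eqn{y = X\beta + g + e}, \eqn{g \sim N(0, K\sigma_g^2)},
#' \eqn{e \sim N(0, I\sigma_e^2)} by restricted maximum likelihood. The
#' kinship is eigendecomposed once and the restricted likelihood is profiled
#' over the variance ratio \eqn{\lambda = \sigma_g^2/\sigma_e^2} on a log grid
#' spanning \[1e-5, 1e5\], then refined by one-dimensional optimization
#' (EMMA-style rotation). The rotation is cached for the subsequent scan.
#'
#' @param y trait vector (finite, length n).
#' @param X fixed-covariate matrix including the intercept; `NULL` gives
#'   intercept only.
#' @param K `KinshipMatrix` or bare n x n matrix.
#' @param rotation optional precomputed `eigen(K)` (list with `values`,
#'   `vectors`); lets many traits share one decomposition.
#' @return `MLMNullFit`: list with `sigma_g2`, `sigma_e2`, `lambda`, `beta`,
#'   `loglik`, and the cached rotation (`U`, `d`, `ystar`, `Xstar`).
#' @export
reml_null_fit <- function(y, X = NULL, K, rotation = NULL) {
  n <- length(y)
  stopifnot(all(is.finite(y)))
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("design error: X is rank deficient")
  p <- ncol(X)
  eig <- if (is.null(rotation)) {
    Kmat <- if (inherits(K, "KinshipMatrix")) K$K else K
    stopifnot(nrow(Kmat) == n)
    eigen(Kmat, symmetric = TRUE)
  } else rotation
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  ystar <- drop(crossprod(U, y))
  Xstar <- crossprod(U, X)

  negll <- function(log_lambda) -.reml_loglik(exp(log_lambda), ystar, Xstar, d)
  grid <- seq(log(1e-5), log(1e5), length.out = 41)
  vals <- vapply(grid, negll, numeric(1))
  i0 <- which.min(vals)
  lo <- grid[max(1L, i0 - 1L)]; hi <- grid[min(length(grid), i0 + 1L)]
  opt <- stats::optimize(negll, lower = lo, upper = hi)
  lambda <- exp(opt$minimum)
  # respect the boundary if the grid end beats the interior optimum
  if (vals[i0] < opt$objective) lambda <- exp(grid[i0])

  fit0 <- .gls_at_lambda(lambda, ystar, Xstar, d)
  sigma_e2 <- max(fit0$rss / (n - p), 1e-8 * stats::var(y))
  out <- list(sigma_g2 = lambda * sigma_e2, sigma_e2 = sigma_e2,
              lambda = lambda, beta = fit0$beta,
              loglik = .reml_loglik(lambda, ystar, Xstar, d),
              U = U, d = d, ystar = ystar, Xstar = Xstar,
              y = y, X = X, n = n, p = p)
  class(out) <- "MLMNullFit"
  out
}

# restricted log-likelihood at variance ratio lambda (scale profiled out)
.reml_loglik <- function(lambda, ystar, Xstar, d) {
  n <- length(ystar); p <- ncol(Xstar)
  w <- 1 / (lambda * d + 1)
  fit <- .gls_at_lambda(lambda, ystar, Xstar, d)
  sigma_e2 <- max(fit$rss / (n - p), 1e-300)  # guard the noise-free limit
  XtWX <- crossprod(Xstar, Xstar * w)
  -0.5 * ((n - p) * log(2 * pi * sigma_e2) + (n - p) +
            sum(log(lambda * d + 1)) + determinant(XtWX)$modulus[1] -
            determinant(crossprod(Xstar))$modulus[1])
}

.gls_at_lambda <- function(lambda, ystar, Xstar, d) {
  w <- 1 / (lambda * d + 1)
  XtWX <- crossprod(Xstar, Xstar * w)
  beta <- solve(XtWX, crossprod(Xstar, ystar * w))
  resid <- ystar - drop(Xstar %*% beta)
  list(beta = drop(beta), rss = sum(w * resid^2), w = w)
}

#' P3D Wald scan over explanatory features
#'
#' Tests each column of `features` as the candidate term in
#' \eqn{y = X\beta + m a + g + e}, holding the variance ratio at the null-fit
#' estimate ("population parameters previously determined"). Under the fixed
#' covariance structure the per-feature generalized-least-squares estimate
#' \eqn{\hat a} and its variance give the Wald statistic
#' \eqn{W = \hat a^2/\mathrm{var}(\hat a)}, referred to \eqn{\chi^2_1}. The
#' residual scale is re-estimated per feature from the augmented-model
#' weighted residuals (df = n - p - 1), so with an identity kinship the scan
#' reduces exactly to ordinary least squares.
#'
#' With `method = "exact"` the variance ratio is re-estimated by REML for
#' every feature (slow; validation mode).
#'
#' @param nullfit `MLMNullFit` from [reml_null_fit()] on the same y/X/K.
#' @param features n x m matrix, one explanatory vector per column.
#' @param method `"p3d"` (default) or `"exact"`.
#' @return data.frame: `feature`, `effect`, `se`, `wald`, `p`, `constant`.
#' @export
p3d_wald_scan <- function(nullfit, features, method = c("p3d", "exact")) {
  method <- match.arg(method)
  stopifnot(inherits(nullfit, "MLMNullFit"))
  features <- as.matrix(features)
  stopifnot(nrow(features) == nullfit$n)
  n <- nullfit$n; p <- nullfit$p
  ids <- colnames(features)
  if (is.null(ids)) ids <- paste0("f", seq_len(ncol(features)))

  if (method == "exact") {
    res <- lapply(seq_len(ncol(features)), function(j) {
      m <- features[, j]
      if (stats::var(m) == 0) return(c(0, NA, 0, 1, 1))
      Xa <- cbind(nullfit$X, m)
      fit <- reml_null_fit(nullfit$y, Xa, .K_from_rotation(nullfit))
      g <- .gls_at_lambda(fit$lambda, fit$ystar, fit$Xstar, fit$d)
      XtWX <- crossprod(fit$Xstar, fit$Xstar * g$w)
      s2 <- g$rss / (n - p - 1)
      va <- s2 * solve(XtWX)[p + 1, p + 1]
      a <- g$beta[p + 1]
      W <- a^2 / va
      c(a, sqrt(va), W, stats::pchisq(W, 1, lower.tail = FALSE), 0)
    })
    out <- do.call(rbind, res)
  } else {
    w <- 1 / (nullfit$lambda * nullfit$d + 1)
    sw <- sqrt(w)
    yt <- nullfit$ystar * sw
    Xt <- nullfit$Xstar * sw
    Mt <- crossprod(nullfit$U, features) * sw
    XtX_inv <- solve(crossprod(Xt))
    ry <- yt - Xt %*% (XtX_inv %*% crossprod(Xt, yt))
    RM <- Mt - Xt %*% (XtX_inv %*% crossprod(Xt, Mt))
    num <- drop(crossprod(RM, ry))
    den <- colSums(RM^2)
    rss0 <- sum(ry^2)
    const <- den <= 1e-12 * rss0 / n | apply(features, 2, stats::var) == 0
    den[const] <- NA
    a <- num / den
    rss1 <- pmax(rss0 - num^2 / den, 0)
    s2 <- rss1 / (n - p - 1)
    va <- s2 / den
    W <- a^2 / va
    pval <- stats::pchisq(W, 1, lower.tail = FALSE)
    a[const] <- 0; W[const] <- 0; pval[const] <- 1; va[const] <- NA
    out <- cbind(a, sqrt(va), W, pval, as.numeric(const))
  }
  data.frame(feature = ids, effect = out[, 1], se = out[, 2], wald = out[, 3],
             p = out[, 4], constant = as.logical(out[, 5]),
             stringsAsFactors = FALSE)
}

.K_from_rotation <- function(nullfit) {
  nullfit$U %*% (nullfit$d * t(nullfit$U))
}

#' Multi-kernel variance-component fit
#'
#' Fits \eqn{y = 1_n\mu + \sum_i u_i + e} with \eqn{u_i \sim N(0, V_i
#' \sigma_i^2)} for 1-4 similarity kernels, by restricted maximum likelihood
#' (default) or by Gibbs sampling with scaled-inverse-chi-squared priors.
#' A single kernel reduces to the eigen-rotated null fit.
#'
#' @param y trait vector.
#' @param kernels list of `KinshipMatrix` (or bare matrices) sharing genotype
#'   order with `y`.
#' @param method `"reml"` or `"gibbs"`.
#' @param n_iter,burn_in Gibbs chain length and burn-in (defaults 5000/1000).
#' @param seed seed for the Gibbs sampler.
#' @return list with `mu`, `sigma2` (per-kernel), `sigma_e2`, `alpha`
#'   (\eqn{V^{-1}(y - \mu)}, for BLUP cross-covariance prediction) and
#'   `method`.
#' @export
fit_multikernel <- function(y, kernels, method = c("reml", "gibbs"),
                            n_iter = 5000, burn_in = 1000, seed = 1) {
  method <- match.arg(method)
  if (length(kernels) < 1L) stop("need at least one kernel")
  if (length(kernels) > 4L) stop("at most four kernels supported")
  Ks <- lapply(kernels, function(k) if (inherits(k, "KinshipMatrix")) k$K else k)
  n <- length(y)
  if (any(vapply(Ks, nrow, 1L) != n)) stop("kernel dimensions do not match y")
  k <- length(Ks)

  if (method == "gibbs") {
    est <- .gibbs_varcomp(y, Ks, n_iter, burn_in, seed)
    sigma2 <- est$sigma2; sigma_e2 <- est$sigma_e2
  } else if (k == 1L) {
    nf <- reml_null_fit(y, NULL, Ks[[1]])
    sigma2 <- nf$sigma_g2; sigma_e2 <- nf$sigma_e2
  } else {
    vy <- stats::var(y)
    negll <- function(theta) {
      s2 <- exp(theta)
      V <- diag(s2[k + 1], n)
      for (i in seq_len(k)) V <- V + s2[i] * Ks[[i]]
      ch <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      logdetV <- 2 * sum(log(diag(ch)))
      Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
      Vi_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
      xvx <- sum(Vi_1)
      mu <- sum(Vi_y) / xvx
      r <- y - mu
      Vi_r <- Vi_y - mu * Vi_1
      0.5 * (logdetV + log(xvx) + sum(r * Vi_r))
    }
    theta0 <- log(rep(vy / (k + 1), k + 1))
    opt <- stats::optim(theta0, negll, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
    s2 <- exp(opt$par)
    sigma2 <- s2[seq_len(k)]
    sigma_e2 <- max(s2[k + 1], 1e-8 * vy)
  }

  V <- diag(sigma_e2, n)
  for (i in seq_len(k)) V <- V + sigma2[i] * Ks[[i]]
  ch <- chol(V)
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  mu <- sum(Vi_y) / sum(Vi_1)
  alpha <- Vi_y - mu * Vi_1  # = V^{-1} (y - 1 mu)
  list(mu = mu, sigma2 = sigma2, sigma_e2 = sigma_e2, alpha = alpha,
       method = method, n = n)
}

# Gibbs sampler over the spectral parameterization u_i = E_i sqrt(d_i) z_i
.gibbs_varcomp <- function(y, Ks, n_iter, burn_in, seed) {
  set.seed(seed)
  n <- length(y); k <- length(Ks)
  B <- lapply(Ks, function(K) {
    e <- eigen(K, symmetric = TRUE)
    keep <- e$values > 1e-8 * max(e$values)
    e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]), sum(keep))
  })
  vy <- stats::var(y)
  df0 <- 5
  S0 <- vy * 0.5 / k * (df0 + 2)   # prior mode at an even split of half the variance
  S0e <- vy * 0.5 * (df0 + 2)
  z <- lapply(B, function(b) rep(0, ncol(b)))
  sigma2 <- rep(vy / (2 * k), k); sigma_e2 <- vy / 2
  mu <- mean(y)
  acc_s2 <- rep(0, k); acc_se <- 0; kept <- 0L
  BtB <- lapply(B, crossprod)
  for (it in seq_len(n_iter)) {
    u <- Reduce(`+`, Map(function(b, zz) drop(b %*% zz), B, z))
    mu <- stats::rnorm(1, mean(y - u), sqrt(sigma_e2 / n))
    for (i in seq_len(k)) {
      others <- if (k > 1L) Reduce(`+`, Map(function(b, zz) drop(b %*% zz),
                                            B[-i], z[-i])) else 0
      r <- y - mu - others
      C <- BtB[[i]] / sigma_e2 + diag(1 / sigma2[i], ncol(B[[i]]))
      ch <- chol(C)
      m <- backsolve(ch, forwardsolve(t(ch), crossprod(B[[i]], r) / sigma_e2))
      z[[i]] <- drop(m + backsolve(ch, stats::rnorm(ncol(B[[i]]))))
      ssq <- sum(z[[i]]^2)
      sigma2[i] <- (ssq + S0) / stats::rchisq(1, ncol(B[[i]]) + df0)
    }
    u <- Reduce(`+`, Map(function(b, zz) drop(b %*% zz), B, z))
    e <- y - mu - u
    sigma_e2 <- (sum(e^2) + S0e) / stats::rchisq(1, n + df0)
    if (it > burn_in) {
      acc_s2 <- acc_s2 + sigma2; acc_se <- acc_se + sigma_e2; kept <- kept + 1L
    }
  }
  list(sigma2 = acc_s2 / kept, sigma_e2 = acc_se / kept)
}

#' BLUP prediction for held-out genotypes
#'
#' Predicts test-set trait values from a training-set multi-kernel fit via the
#' cross-covariance \eqn{\hat y_{test} = \hat\mu + \sum_i \hat\sigma_i^2
#' V_i[test, train] V_{train}^{-1} (y_{train} - \hat\mu)}.
#'
#' @param fit result of [fit_multikernel()] on the training subset.
#' @param kernels the same kernels on all genotypes (full matrices).
#' @param train,test integer indices into the full genotype set.
#' @return numeric vector of predictions, one per test genotype.
#' @export
predict_multikernel <- function(fit, kernels, train, test) {
  Ks <- lapply(kernels, function(k) if (inherits(k, "KinshipMatrix")) k$K else k)
  stopifnot(length(fit$alpha) == length(train))
  pred <- rep(fit$mu, length(test))
  for (i in seq_along(Ks)) {
    pred <- pred + fit$sigma2[i] *
      drop(Ks[[i]][test, train, drop = FALSE] %*% fit$alpha)
  }
  pred
}
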