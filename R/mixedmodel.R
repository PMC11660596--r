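# Variance-component machinery for the single-kinship mixed model
#   y = X b + g + e,  g ~ N(0, sigma_g^2 K),  e ~ N(0, sigma_e^2 I).
# The likelihood is profiled over delta = sigma_e^2 / sigma_g^2 using one
# eigendecomposition of K (the EMMA device): with K = U D U', rotating by U'
# diagonalises V = sigma_g^2 (K + delta I), so each candidate delta costs
# O(n q^2). delta is scanned on a log grid and refined with Brent's method.

eigen_kinship <- function(k) {
  e <- eigen((unclass(k) + t(unclass(k))) / 2, symmetric = TRUE)
  e$values <- pmax(e$values, 0)
  e
}

# profile log-likelihood in log(delta); REML or ML
profile_ll <- function(log_delta, yt, xt, d, n, q, reml = TRUE) {
  delta <- exp(log_delta)
  w <- 1 / (d + delta)
  xtw <- xt * w
  xtwx <- crossprod(xt, xtw)
  beta <- tryCatch(solve(xtwx, crossprod(xtw, yt)),
                   error = function(e) NULL)
  if (is.null(beta)) return(-Inf)
  r <- yt - xt %*% beta
  rss <- sum(w * r^2)
  if (rss <= 0) return(-Inf)
  if (reml) {
    df <- n - q
    -0.5 * (df * log(2 * pi * rss / df) + df + sum(log(d + delta)) +
              determinant(xtwx, logarithm = TRUE)$modulus)
  } else {
    -0.5 * (n * log(2 * pi * rss / n) + n + sum(log(d + delta)))
  }
}

# core fit: eig may be precomputed eigen_kinship(K)
mm_fit <- function(y, x, k = NULL, eig = NULL, reml = TRUE,
                   grid = seq(log(1e-6), log(1e6), length.out = 61),
                   tol = 1e-8) {
  n <- length(y)
  x <- as.matrix(x)
  q <- qr(x)$rank
  if (q < ncol(x)) stop("fixed-effect design not full column rank")
  if (stats::var(y) < 1e-12) stop("phenotype has zero variance")
  if (n <= q + 1L) stop("too few observations for the design")
  if (is.null(eig)) eig <- eigen_kinship(k)
  yt <- crossprod(eig$vectors, y)
  xt <- crossprod(eig$vectors, x)
  ll <- vapply(grid, profile_ll, numeric(1), yt = yt, xt = xt,
               d = eig$values, n = n, q = ncol(x), reml = reml)
  if (all(!is.finite(ll))) stop("REML/ML profile likelihood degenerate")
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(profile_ll, c(lo, hi), maximum = TRUE, tol = tol,
                         yt = yt, xt = xt, d = eig$values, n = n,
                         q = ncol(x), reml = reml)
  delta <- exp(opt$maximum)
  w <- 1 / (eig$values + delta)
  xtw <- xt * w
  xtwx <- crossprod(xt, xtw)
  beta <- solve(xtwx, crossprod(xtw, yt))
  r <- yt - xt %*% beta
  rss <- sum(w * r^2)
  sigma_g2 <- rss / if (reml) (n - ncol(x)) else n
  list(sigma_g2 = sigma_g2, sigma_e2 = sigma_g2 * delta, delta = delta,
       loglik = opt$objective, beta = drop(beta), eig = eig,
       yt = drop(yt), xt = xt, n = n, q = ncol(x), reml = reml)
}

#' REML variance components for the null mixed model
#'
#' Fits `y = Q a + g + e` with `g ~ N(0, sigma_g^2 K)` by restricted maximum
#' likelihood, profiling over `delta = sigma_e^2 / sigma_g^2` via one
#' eigendecomposition of the kinship matrix. The returned object carries the
#' rotation needed for fast per-marker generalized-least-squares tests
#' ([marker_scan()]).
#'
#' @param y numeric trait vector.
#' @param Q covariate design matrix (intercept + sex/batch dummies), full
#'   column rank, rows aligned with `y` and `kinship`.
#' @param kinship N x N `kinship` matrix.
#' @param reml fit by REML (default) or full ML.
#' @return object of class `mlm_fit` with `sigma_g2`, `sigma_e2`, `delta`,
#'   `loglik`, `beta`, and cached rotation components.
#' @export
reml_fit <- function(y, Q, kinship, reml = TRUE) {
  fit <- mm_fit(y, Q, k = kinship, reml = reml)
  class(fit) <- "mlm_fit"
  fit
}

#' @export
print.mlm_fit <- function(x, ...) {
  cat("mixed-model fit (", if (x$reml) "REML" else "ML", "): sigma_g2 = ",
      signif(x$sigma_g2, 4), ", sigma_e2 = ", signif(x$sigma_e2, 4),
      ", logLik = ", signif(x$loglik, 6), "\n", sep = "")
  invisible(x)
}
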