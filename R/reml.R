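# Restricted maximum likelihood for the single-G mixed model
#   y = X b + u + e,  u ~ MVN(0, sigma_a2 G),  e ~ MVN(0, sigma_e2 I)
# profiled over delta = sigma_e2 / sigma_a2 through one spectral
# decomposition of G: with G = U diag(lambda) U', V = sigma_a2 (G + delta I)
# becomes diagonal in the rotated basis, so each likelihood evaluation is
# O(n) after the O(n^3) decomposition is paid once (EMMA-style).

reml_eigen <- function(G) {
  eg <- eigen(G, symmetric = TRUE)
  if (min(eg$values) < -1e-6) {
    warn("GRM has eigenvalues below -1e-6; clamping to 0.")
  }
  eg$values <- pmax(eg$values, 0)
  eg
}

# Restricted log-likelihood at a given delta, with sigma_a2 profiled out.
# ys, Xs are the rotated response and fixed-effect design (U'y, U'X).
reml_ll_delta <- function(delta, ys, Xs, lambda, logdet_xtx) {
  n <- length(ys)
  q <- ncol(Xs)
  d <- lambda + delta
  w <- 1 / d
  A <- crossprod(Xs, Xs * w)
  b <- crossprod(Xs, ys * w)
  beta <- solve(A, b)
  r <- ys - Xs %*% beta
  rss <- sum(r^2 * w)
  sigma_a2 <- rss / (n - q)
  ll <- -0.5 * ((n - q) * log(2 * pi * sigma_a2) + sum(log(d)) +
                  determinant(A, logarithm = TRUE)$modulus - logdet_xtx +
                  (n - q))
  list(ll = as.numeric(ll), sigma_a2 = sigma_a2, beta = beta)
}

#' Profile the restricted likelihood over a grid of variance ratios
#'
#' Evaluates the restricted log-likelihood of the mixed model at each value
#' of `delta = sigma_e2 / sigma_a2`.  Useful for visualising the likelihood
#' surface and as a grid-search check of [reml_fit()].
#'
#' @param y Numeric phenotype vector (typically the `resid` column of
#'   [residualize()]).
#' @param G A [compute_grm()] matrix (or its precomputed eigendecomposition).
#' @param deltas Numeric vector of variance ratios (> 0).
#' @param X Fixed-effect design matrix; default a column of ones.
#' @return Tibble with `delta`, `loglik`, `h2` (`= 1 / (1 + delta)`).
#' @export
reml_profile <- function(y, G, deltas, X = NULL) {
  n <- length(y)
  if (!all(is.finite(y))) stop_invalid("`y` must be finite.")
  eg <- if (is.list(G) && !is.null(G$vectors)) G else reml_eigen(G)
  X <- X %||% matrix(1, n, 1L)
  ys <- crossprod(eg$vectors, y)
  Xs <- crossprod(eg$vectors, X)
  logdet_xtx <- as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)
  ll <- vapply(deltas, function(d) {
    reml_ll_delta(d, ys, Xs, eg$values, logdet_xtx)$ll
  }, numeric(1))
  tibble(delta = deltas, loglik = ll, h2 = 1 / (1 + deltas))
}

#' REML variance components and genomic heritability
#'
#' Estimates the additive and residual variance of the polygenic model by
#' restricted maximum likelihood.  The variance ratio is located on a
#' 64-point logarithmic grid over `[1e-5, 1e5]` and refined by bounded
#' scalar optimisation around the best grid point, which is robust to the
#' mildly multimodal profiles that small GRMs can produce.  The
#' decomposition of `G` is computed once and is reused by [lmm_scan()].
#'
#' @inheritParams reml_profile
#' @return Object of class `reml_fit`: list with `sigma_a2`, `sigma_e2`,
#'   `delta`, `h2`, `loglik`, `boundary` (logical: optimum at the search
#'   bound), `n`, and the reusable `eigen` of `G`.
#' @export
reml_fit <- function(y, G, X = NULL) {
  n <- length(y)
  if (n < 10) stop_invalid("REML needs at least 10 observations.")
  if (!all(is.finite(y))) stop_invalid("`y` must be finite.")
  eg <- if (is.list(G) && !is.null(G$vectors)) G else reml_eigen(G)
  X <- X %||% matrix(1, n, 1L)
  ys <- crossprod(eg$vectors, y)
  Xs <- crossprod(eg$vectors, X)
  logdet_xtx <- as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)
  f <- function(d) reml_ll_delta(d, ys, Xs, eg$values, logdet_xtx)$ll

  grid <- 10^seq(-5, 5, length.out = 64L)
  ll_grid <- vapply(grid, f, numeric(1))
  i <- which.max(ll_grid)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- optimize(f, interval = c(lo, hi), maximum = TRUE, tol = 1e-10)
  delta <- opt$maximum
  ll <- opt$objective
  if (ll < ll_grid[i]) {   # keep the grid point if refinement lost ground
    delta <- grid[i]
    ll <- ll_grid[i]
  }
  boundary <- i %in% c(1L, length(grid))
  at <- reml_ll_delta(delta, ys, Xs, eg$values, logdet_xtx)
  structure(list(sigma_a2 = at$sigma_a2,
                 sigma_e2 = at$sigma_a2 * delta,
                 delta = delta,
                 h2 = 1 / (1 + delta),
                 loglik = ll,
                 boundary = boundary,
                 n = n,
                 eigen = eg),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf(
    "<reml_fit> n=%d  sigma_a2=%.4g  sigma_e2=%.4g  h2=%.3f  logLik=%.3f%s\n",
    x$n, x$sigma_a2, x$sigma_e2, x$h2, x$loglik,
    if (x$boundary) "  [boundary]" else ""))
  invisible(x)
}

#' @export
tidy.reml_fit <- function(x, ...) {
  tibble(term = c("sigma_a2", "sigma_e2", "delta", "h2"),
         estimate = c(x$sigma_a2, x$sigma_e2, x$delta, x$h2))
}

#' @export
glance.reml_fit <- function(x, ...) {
  tibble(sigma_a2 = x$sigma_a2, sigma_e2 = x$sigma_e2, h2 = x$h2,
         logLik = x$loglik, n = x$n, boundary = x$boundary)
}
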