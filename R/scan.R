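#' Mixed-model single-SNP association scan
#'
#' Tests every variant with the model `y = x b + u + e`,
#' `u ~ MVN(0, sigma_a2 G)`, `e ~ MVN(0, sigma_e2 I)`, where `x` counts
#' minor-allele copies (0/1/2).  With `vc_mode = "null_reuse"` (default) the
#' variance components are estimated once under the null and reused for all
#' variants, the fast approximation popularised by EMMAX; `"per_snp"` refits
#' the variance ratio for every variant (exact, slower).  Either way the
#' per-variant test is generalised least squares in the rotated eigenbasis:
#' `beta = (x' V^-1 x)^-1 x' V^-1 y` with `V = sigma_a2 G + sigma_e2 I`, the
#' standard error from the GLS information matrix, and a two-sided Wald
#' p-value on one degree of freedom.
#'
#' @param y Numeric phenotype vector (residualized, see [residualize()]).
#' @param geno A [geno_matrix()] aligned to `y`.
#' @param G Optional [compute_grm()] result (computed from `geno` when
#'   omitted).
#' @param vc Optional [reml_fit()] under the null (computed when omitted).
#' @param vc_mode `"null_reuse"` or `"per_snp"`.
#' @param trait,population Optional labels copied onto every row.
#' @return Tibble of class `assoc_scan`, one row per tested variant:
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `maf`, `n`, `beta`,
#'   `se`, `p` (plus `trait` / `population` when given).  Monomorphic
#'   variants are skipped with a warning.
#' @export
lmm_scan <- function(y, geno, G = NULL, vc = NULL,
                     vc_mode = c("null_reuse", "per_snp"),
                     trait = NULL, population = NULL) {
  vc_mode <- match.arg(vc_mode)
  stopifnot(inherits(geno, "geno_matrix"))
  n <- length(y)
  if (n != nrow(geno$dosage)) stop_invalid("`y` and `geno` are not aligned.")
  if (!all(is.finite(y))) stop_invalid("`y` must be finite.")
  G <- G %||% compute_grm(geno)
  vc <- vc %||% reml_fit(y, G)
  eg <- vc$eigen %||% reml_eigen(G)

  x <- geno$dosage
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2L]]
  }
  poly <- apply(x, 2L, function(v) var(v) > 0)
  if (any(!poly)) {
    warn(sprintf("Skipping %d monomorphic variant(s).", sum(!poly)))
  }
  info <- geno$info[poly, , drop = FALSE]
  x <- x[, poly, drop = FALSE]
  m <- ncol(x)
  U <- eg$vectors
  ys <- as.numeric(crossprod(U, y))
  os <- as.numeric(crossprod(U, rep(1, n)))
  Xs <- crossprod(U, x)

  if (vc_mode == "null_reuse") {
    w <- 1 / (vc$sigma_a2 * eg$values + vc$sigma_e2)
    c11 <- sum(w * os^2)
    b1 <- sum(w * os * ys)
    c12 <- colSums(Xs * (w * os))
    c22 <- colSums(Xs^2 * w)
    b2 <- colSums(Xs * (w * ys))
    det <- c11 * c22 - c12^2
    beta <- (c11 * b2 - c12 * b1) / det
    se <- sqrt(c11 / det)
  } else {
    beta <- se <- numeric(m)
    for (j in seq_len(m)) {
      Xj <- cbind(os, Xs[, j])
      Xraw <- cbind(1, x[, j])
      ld <- as.numeric(determinant(crossprod(Xraw), logarithm = TRUE)$modulus)
      fj <- function(d) reml_ll_delta(d, ys, Xj, eg$values, ld)$ll
      grid <- 10^seq(-5, 5, length.out = 64L)
      llg <- vapply(grid, fj, numeric(1))
      i <- which.max(llg)
      opt <- optimize(fj, c(grid[max(i - 1L, 1L)], grid[min(i + 1L, 64L)]),
                      maximum = TRUE, tol = 1e-10)
      at <- reml_ll_delta(opt$maximum, ys, Xj, eg$values, ld)
      w <- 1 / (eg$values + opt$maximum)
      A <- crossprod(Xj, Xj * w)
      cov2 <- at$sigma_a2 * solve(A)[2L, 2L]
      beta[j] <- at$beta[2L]
      se[j] <- sqrt(cov2)
    }
  }
  chi2 <- (beta / se)^2
  out <- dplyr::bind_cols(
    info[, c("chrom", "pos", "effect_allele", "other_allele", "maf")],
    tibble(n = n, beta = beta, se = se,
           p = pchisq(chi2, df = 1, lower.tail = FALSE))
  )
  if (!is.null(trait)) out$trait <- trait
  if (!is.null(population)) out$population <- population
  class(out) <- c("assoc_scan", class(out))
  out
}

#' Variance explained by a variant: residual-variance estimator
#'
#' `(V_reduce - V_full) / V_reduce`, where `V_reduce` and `V_full` are the
#' residual variances of the ordinary linear model without and with the
#' variant's dosage.
#'
#' @param y Numeric phenotype vector with positive variance.
#' @param x Dosage vector aligned to `y`.
#' @return Proportion in `[0, 1]` (0 when `x` is constant).
#' @export
variance_explained_residual <- function(y, x) {
  if (length(y) != length(x)) stop_invalid("`y` and `x` differ in length.")
  if (!all(is.finite(y)) || var(y) == 0) {
    stop_invalid("`y` must be finite with positive variance.")
  }
  v_reduce <- sum((y - mean(y))^2)
  if (var(x) == 0) return(0)
  fit <- lm(y ~ x)
  v_full <- sum(residuals(fit)^2)
  (v_reduce - v_full) / v_reduce
}

#' Variance explained by a variant: allele-frequency closed form
#'
#' `2 p (1 - p) a^2 / sigma_p2` for allele frequency `p`, additive allelic
#' effect `a`, and phenotypic variance `sigma_p2`.
#'
#' @param p Allele frequency in `(0, 1)`.
#' @param a Additive allelic effect (trait units per copy).
#' @param sigma_p2 Phenotypic variance (> 0).
#' @return The proportion of phenotypic variance.
#' @export
variance_explained_formula <- function(p, a, sigma_p2) {
  if (any(p <= 0 | p >= 1)) stop_invalid("`p` must lie in (0, 1).")
  if (any(sigma_p2 <= 0)) stop_invalid("`sigma_p2` must be positive.")
  2 * p * (1 - p) * a^2 / sigma_p2
}
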