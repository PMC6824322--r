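#' Genotype dosage container
#'
#' Bundles an `n x m` dosage matrix coded as copies of the minor (effect)
#' allele with per-variant metadata and sample ids.  All association
#' functions in the package consume this container.
#'
#' @param dosage Numeric `n x m` matrix with entries in `{0, 1, 2}` or `NA`.
#' @param info Tibble with one row per variant: `chrom`, `pos`, `ref`, `alt`,
#'   `effect_allele`, `other_allele`, `maf`, `call_rate`.
#' @param samples Character vector of sample ids (length `n`).
#' @return Object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, info, samples) {
  if (nrow(info) != ncol(dosage) || length(samples) != nrow(dosage)) {
    stop_invalid("Shapes of `dosage`, `info` and `samples` disagree.")
  }
  rownames(dosage) <- samples
  structure(list(dosage = dosage, info = as_tibble(info), samples = samples),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d variants (MAF %.3f-%.3f)\n",
              length(x$samples), nrow(x$info),
              min(x$info$maf), max(x$info$maf)))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

variant_stats <- function(dosage) {
  call_rate <- colMeans(!is.na(dosage))
  p_alt <- colMeans(dosage, na.rm = TRUE) / 2
  p_alt[is.nan(p_alt)] <- 0
  list(call_rate = call_rate, p_alt = p_alt)
}

#' Convert a phased population to minor-allele dosages
#'
#' Sums the two chromosome rows of every individual and flips coding at sites
#' where the alternate allele is the major one, so dosages always count
#' copies of the minor allele (the effect allele of the association model).
#'
#' @param pop A `phased_pop`.
#' @return A [geno_matrix()].
#' @export
as_geno_matrix <- function(pop) {
  stopifnot(inherits(pop, "phased_pop"))
  h <- pop$haplotypes
  n_hap <- nrow(h)
  alt <- h[seq(1L, n_hap, 2L), , drop = FALSE] +
    h[seq(2L, n_hap, 2L), , drop = FALSE]
  p_alt <- colMeans(alt) / 2
  flip <- p_alt > 0.5
  dosage <- alt
  dosage[, flip] <- 2L - alt[, flip, drop = FALSE]
  m <- ncol(dosage)
  info <- tibble(
    chrom = rep(pop$chrom, m),
    pos = pop$positions,
    ref = rep("A", m),
    alt = rep("G", m),
    effect_allele = ifelse(flip, "A", "G"),
    other_allele = ifelse(flip, "G", "A"),
    maf = pmin(p_alt, 1 - p_alt),
    call_rate = rep(1, m)
  )
  geno_matrix(dosage, info, pop$samples$id)
}

#' Quality-control filter on variants and individuals
#'
#' Applies the standard chip-data quality rules: individuals are removed
#' first (call rate must exceed `min_ind_call`), variant statistics are then
#' recomputed on the remaining individuals, and variants are kept when their
#' call rate exceeds `min_snp_call` and their minor-allele frequency exceeds
#' `min_maf`.  All comparisons are strict (`>`), matching the usual "call
#' rate greater than 90%, MAF higher than 5%" phrasing; a threshold of 0
#' disables that filter entirely.
#'
#' @param geno A [geno_matrix()].
#' @param min_snp_call,min_ind_call,min_maf Proportion thresholds in `[0, 1]`.
#' @return A filtered [geno_matrix()] with recomputed `maf` and `call_rate`.
#' @export
qc_filter <- function(geno, min_snp_call = 0.9, min_ind_call = 0.9,
                      min_maf = 0.05) {
  stopifnot(inherits(geno, "geno_matrix"))
  for (t in c(min_snp_call, min_ind_call, min_maf)) {
    check_scalar_number(t, "threshold", 0, 1)
  }
  pass <- function(x, thr) if (thr > 0) x > thr else rep(TRUE, length(x))

  ind_call <- rowMeans(!is.na(geno$dosage))
  keep_ind <- pass(ind_call, min_ind_call)
  dosage <- geno$dosage[keep_ind, , drop = FALSE]

  st <- variant_stats(dosage)
  maf <- pmin(st$p_alt, 1 - st$p_alt)
  keep_snp <- pass(st$call_rate, min_snp_call) & pass(maf, min_maf)
  if (!any(keep_snp)) {
    abort(sprintf(
      "QC removed all %d variants (%d failed call rate > %s, %d failed MAF > %s).",
      ncol(dosage), sum(!pass(st$call_rate, min_snp_call)),
      format(min_snp_call), sum(!pass(maf, min_maf)), format(min_maf)),
      class = "crosspop_empty")
  }
  info <- geno$info[keep_snp, , drop = FALSE]
  info$maf <- maf[keep_snp]
  info$call_rate <- st$call_rate[keep_snp]
  geno_matrix(dosage[, keep_snp, drop = FALSE], info,
              geno$samples[keep_ind])
}

#' Residualize a phenotype on categorical fixed effects
#'
#' Removes sex and slaughter-batch (or any categorical covariates) from the
#' raw trait by ordinary least squares and returns the input table with a
#' `resid` column: the phenotype corrected for fixed effects that all
#' downstream mixed-model functions expect.  A rank-deficient (confounded)
#' design is handled by the pivoting least-squares fit, with a warning.
#'
#' @param data Data frame with the trait and covariate columns.
#' @param trait Name of the trait column (string).
#' @param covariates Character vector of covariate column names.
#' @return `data` with an added `resid` column, orthogonal to the covariate
#'   design.
#' @export
residualize <- function(data, trait = "trait", covariates = c("sex", "batch")) {
  missing_cols <- setdiff(c(trait, covariates), names(data))
  if (length(missing_cols)) {
    stop_invalid(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  y <- data[[trait]]
  if (!all(is.finite(y))) stop_invalid("Trait values must be finite.")
  df <- data.frame(.y = y, lapply(data[covariates], as.factor))
  usable <- covariates[vapply(df[covariates], nlevels, integer(1)) >= 2L]
  fml <- if (length(usable)) {
    stats::as.formula(paste(".y ~", paste(usable, collapse = " + ")))
  } else {
    .y ~ 1
  }
  fit <- lm(fml, data = df)
  if (anyNA(coef(fit))) {
    warn("Confounded covariate design; residualizing with a pivoted (pseudoinverse) fit.")
  }
  dplyr::mutate(as_tibble(data), resid = unname(residuals(fit)))
}

#' Genomic relationship matrix (centered and scaled)
#'
#' Computes `G = (1/m) * sum_k (x_k - 2 p_k)(x_k - 2 p_k)' / (2 p_k (1 - p_k))`
#' over all polymorphic markers, with missing dosages mean-imputed per
#' marker: the centered-scaled GRM used by the standard mixed-model GWAS
#' software.
#'
#' @param geno A [geno_matrix()].
#' @return An `n x n` symmetric matrix of class `grm` with attribute
#'   `n_markers`.
#' @export
compute_grm <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  x <- geno$dosage
  # per-marker mean imputation
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2L]]
  }
  p <- colMeans(x) / 2
  poly <- p > 0 & p < 1 & apply(x, 2L, var) > 0
  if (!any(poly)) stop_invalid("No polymorphic markers; cannot compute a GRM.")
  x <- x[, poly, drop = FALSE]
  p <- p[poly]
  z <- sweep(x, 2L, 2 * p)
  z <- sweep(z, 2L, sqrt(2 * p * (1 - p)), "/")
  g <- tcrossprod(z) / ncol(z)
  dimnames(g) <- list(geno$samples, geno$samples)
  structure(g, class = c("grm", "matrix", "array"), n_markers = ncol(z))
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d x %d from %d markers; mean diagonal %.3f\n",
              nrow(x), ncol(x), attr(x, "n_markers"), mean(diag(x))))
  invisible(x)
}
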