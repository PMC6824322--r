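# Independent oracles and small fixture builders used across the suite.

# Dense generalised least squares with known covariance V:
# beta = (X'V^-1 X)^-1 X'V^-1 y; scale-free SEs use V as given,
# scale-estimated SEs multiply by sigma2_hat = r'V^-1 r / (n - p).
dense_gls <- function(y, X, V, estimate_scale = FALSE) {
  Vi <- solve(V)
  A <- t(X) %*% Vi %*% X
  beta <- solve(A, t(X) %*% Vi %*% y)
  covb <- solve(A)
  if (estimate_scale) {
    r <- y - X %*% beta
    sigma2 <- as.numeric(t(r) %*% Vi %*% r) / (length(y) - ncol(X))
    covb <- sigma2 * covb
  }
  list(beta = as.numeric(beta), se = unname(sqrt(diag(covb))))
}

# Random symmetric positive semi-definite matrix with unit-scale diagonal.
random_psd <- function(n) {
  a <- matrix(rnorm(n * n), n)
  g <- tcrossprod(a) / n
  g / mean(diag(g))
}

# Quadratic point-in-interval membership (1-based inclusive intervals).
overlap_oracle <- function(pos, starts, ends) {
  vapply(pos, function(p) any(p >= starts & p <= ends), logical(1))
}

# A small population whose genotypes are drawn directly (no panel), for
# matrix-level unit tests.
toy_geno <- function(n, m, seed = 1, maf = NULL) {
  set.seed(seed)
  p <- maf %||% runif(m, 0.1, 0.5)
  dosage <- sapply(p, function(q) rbinom(n, 2, q))
  flip <- colMeans(dosage) / 2 > 0.5
  dosage[, flip] <- 2 - dosage[, flip]
  info <- tibble::tibble(
    chrom = "1", pos = seq_len(m) * 100L, ref = "A", alt = "G",
    effect_allele = "G", other_allele = "A",
    maf = pmin(colMeans(dosage) / 2, 1 - colMeans(dosage) / 2),
    call_rate = 1)
  geno_matrix(dosage, info, sprintf("ind%03d", seq_len(n)))
}

`%||%` <- rlang::`%||%`

hap_strings_test <- function(mat) apply(mat, 1L, paste0, collapse = "")

# Three-population fixture with a planted haplotype whose core segment is
# shared exactly while the flanks differ per population, so the expected
# shared segment is known by construction.
shared_core_fixture <- function(seed, n_ind = 80, core = 5:9, width = 13) {
  set.seed(seed)
  panel <- simulate_panel(60, 60, recomb_rate = 0.05, mutation_density = 1,
                          seed = seed)
  win_idx <- 20:(20 + width - 1)
  start <- panel$positions[win_idx[1]]
  end <- panel$positions[win_idx[width]]
  core_str <- paste0(rbinom(width, 1, 0.5)[core], collapse = "")
  flanks <- list(c("00", "11"), c("11", "00"), c("01", "10"))
  pops <- list()
  strings <- character(3)
  for (i in 1:3) {
    nm <- paste0("P", i)
    pop <- sample_population(panel, nm, n_ind, drift = 25, seed = seed + i)
    pre <- strsplit(flanks[[i]][1], "")[[1]]
    post <- strsplit(flanks[[i]][2], "")[[1]]
    s <- rep("0", width)
    s[core] <- strsplit(core_str, "")[[1]]
    s[(min(core) - 2):(min(core) - 1)] <- pre
    s[(max(core) + 1):(max(core) + 2)] <- post
    # randomize the remaining outer sites per population
    outer_idx <- setdiff(seq_len(width),
                         c(core, (min(core) - 2):(min(core) - 1),
                           (max(core) + 1):(max(core) + 2)))
    s[outer_idx] <- as.character((i + outer_idx) %% 2)
    strings[i] <- paste0(s, collapse = "")
    planted <- plant_causal_haplotype(
      setNames(list(pop), nm), start, end, strings[i],
      frequency = setNames(0.3, nm), seed = seed + 10 + i)
    pops[[nm]] <- planted$pops[[nm]]
  }
  list(pops = pops, positions = panel$positions[win_idx],
       core_idx = core, strings = strings,
       expected_start = panel$positions[win_idx[min(core)]],
       expected_end = panel$positions[win_idx[max(core)]])
}
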