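make_pop <- function(hap_mat, positions, name = "P", chrom = "1",
                     samples = NULL) {
  n <- nrow(hap_mat) / 2
  structure(list(
    haplotypes = hap_mat, positions = positions, chrom = chrom, name = name,
    samples = samples %||% tibble::tibble(id = sprintf("%s_%03d", name, 1:n),
                                          sex = "S1", batch = "B1")),
    class = "phased_pop")
}

test_that("window extraction centres on the lead and truncates at ends", {
  panel <- simulate_panel(300, 60, seed = 61)
  pop <- sample_population(panel, "W", 100, drift = 20, seed = 62)

  hs <- extract_window(pop, pop$positions[100], k = 20)
  expect_length(hs$positions, 41L)
  expect_identical(hs$positions, pop$positions[80:120])
  expect_equal(hs$positions[21], hs$lead_pos)

  # lead 5 SNPs from the chromosome start: 6 + 20 positions remain
  expect_warning(hs2 <- extract_window(pop, pop$positions[6], k = 20),
                 "truncated")
  expect_length(hs2$positions, 26L)

  expect_error(extract_window(pop, max(pop$positions) + 1, k = 20),
               class = "crosspop_key")

  # frequencies sum to one; diplotype ids are consistent
  expect_equal(sum(hs$haplotypes$freq), 1)
  expect_true(all(hs$diplotypes %in% hs$haplotypes$haplotype))

  # a population with one haplotype yields a single frequency-1 entry
  one <- make_pop(matrix(rep(c(0L, 1L, 0L), each = 20), 20, 3, byrow = FALSE),
                  positions = c(10L, 20L, 30L))
  h1 <- extract_window(one, 20L, k = 1)
  expect_equal(nrow(h1$haplotypes), 1L)
  expect_equal(h1$haplotypes$freq, 1)
})

test_that("incidence matrices pool rare haplotypes and conserve diplotypes", {
  # 10 individuals; haplotype frequencies 0.5 / 0.3 / 0.15 / 0.05
  strings <- c(rep("000", 10), rep("011", 6), rep("110", 3), "101")
  hap <- do.call(rbind, strsplit(strings, "")) |> apply(2, as.integer)
  pop <- make_pop(hap, c(1L, 2L, 3L), name = "I")
  hs <- extract_window(pop, 2L, k = 1)
  inc <- build_incidence(hs, min_freq = 0.05)
  # strict >: the 0.05 haplotype is pooled
  expect_equal(ncol(inc$H), 4L)
  expect_true("rare" %in% colnames(inc$H))
  expect_equal(nrow(inc$haplotypes), 3L)
  expect_equal(unname(rowSums(inc$H)), rep(2, 10))

  # single-haplotype population: one constant column of 2
  mono <- make_pop(matrix(0L, 20, 3), c(1L, 2L, 3L), name = "M")
  im <- build_incidence(extract_window(mono, 2L, k = 1))
  expect_equal(ncol(im$H), 1L)
  expect_true(all(im$H == 2L))
})

test_that("whitened haplotype effects equal dense GLS against the reference", {
  set.seed(70)
  n <- 40
  # three haplotypes with known frequencies
  strings <- sample(c("0000", "0110", "1011"), 2 * n, replace = TRUE,
                    prob = c(0.5, 0.3, 0.2))
  hap <- do.call(rbind, strsplit(strings, "")) |> apply(2, as.integer)
  pop <- make_pop(hap, c(5L, 10L, 15L, 20L), name = "G")
  hs <- extract_window(pop, 10L, k = 1)
  inc <- build_incidence(hs, min_freq = 0.05)

  G <- random_psd(n)
  vc <- list(sigma_a2 = 0.8, sigma_e2 = 0.6)
  V <- vc$sigma_a2 * G + vc$sigma_e2 * diag(n)
  y <- as.numeric(chol(V) %*% rnorm(n)) + inc$H[, 2] * 0.5

  eff <- estimate_haplotype_effects(y, inc, vc, G)
  ref <- colnames(inc$H)[1]
  X <- cbind(1, inc$H[, setdiff(colnames(inc$H), ref), drop = FALSE])
  o <- dense_gls(y, X, V, estimate_scale = TRUE)
  est <- eff[!eff$reference, ]
  expect_equal(est$beta, o$beta[-1], tolerance = 1e-8)
  expect_equal(est$se, o$se[-1], tolerance = 1e-8)
  expect_equal(eff$beta[eff$reference], 0)

  # sigma_a2 = 0: reduces to ordinary least squares on haplotype counts
  vc0 <- list(sigma_a2 = 0, sigma_e2 = 0.6)
  eff0 <- estimate_haplotype_effects(y, inc, vc0, G)
  ols <- lm(y ~ X - 1)
  sm <- summary(ols)$coefficients
  expect_equal(eff0$beta[!eff0$reference], unname(sm[-1, 1]),
               tolerance = 1e-8)
  expect_equal(eff0$se[!eff0$reference], unname(sm[-1, 2]), tolerance = 1e-8)

  # invariant to haplotype column ordering
  perm <- inc
  keep_ref <- colnames(inc$H)[1]
  others <- setdiff(colnames(inc$H), keep_ref)
  perm$H <- inc$H[, c(keep_ref, rev(others))]
  eff_perm <- estimate_haplotype_effects(y, perm, vc, G)
  merged <- dplyr::inner_join(est, eff_perm[!eff_perm$reference, ],
                              by = "haplotype")
  expect_equal(merged$beta.x, merged$beta.y, tolerance = 1e-10)
})

test_that("the whitening transform makes mixed-model residuals white", {
  set.seed(71)
  n <- 60
  G <- random_psd(n)
  vc <- list(sigma_a2 = 1.2, sigma_e2 = 0.7)
  V <- vc$sigma_a2 * G + vc$sigma_e2 * diag(n)
  eg <- eigen(V, symmetric = TRUE)
  w_inv <- eg$vectors %*% diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
  # W^-1 V W^-T = I
  expect_equal(w_inv %*% V %*% t(w_inv), diag(n), tolerance = 1e-6)
  # empirical covariance of whitened draws approaches the identity
  cv <- chol(V)
  draws <- sapply(1:500, function(i) w_inv %*% (t(cv) %*% rnorm(n)))
  emp <- tcrossprod(draws) / 500
  expect_lt(mean(abs(emp - diag(n))), 0.1)
  expect_lt(abs(mean(diag(emp)) - 1), 0.2)
})

test_that("shared segments are found exactly by run enumeration", {
  pos <- seq(100L, 1000L, by = 100L)
  # identical haplotypes: whole window
  full <- shared_segment(c("0110011010", "0110011010"), pos)
  expect_equal(full$start_bp, 100)
  expect_equal(full$end_bp, 1000)

  # constructed agreement at positions 4..7
  a <- "0110011010"
  b <- "1010011001"
  c_ <- "0000011111"
  # positions 4..7 agree (alleles 0,0,1,1 in all three)
  seg <- shared_segment(c(a, b, c_), pos)
  expect_equal(seg$start_bp, 400)
  expect_equal(seg$end_bp, 700)
  expect_equal(seg$n_snps, 4L)

  # enumeration oracle over all runs for random cases
  set.seed(72)
  for (i in 1:20) {
    strs <- replicate(3, paste0(rbinom(10, 1, 0.5), collapse = ""))
    got <- shared_segment(strs, pos)
    mat <- do.call(rbind, strsplit(strs, ""))
    agree <- apply(mat, 2, function(cc) all(cc == cc[1]))
    runs <- rle(agree)
    if (!any(runs$values)) {
      expect_equal(nrow(got), 0L)
    } else {
      best_len <- max(runs$lengths[runs$values])
      expect_equal(got$n_snps, best_len)
      idx_start <- match(got$start_bp, pos)
      expect_true(all(agree[idx_start:(idx_start + best_len - 1)]))
      # maximality: no extension agrees
      if (idx_start > 1) expect_false(agree[idx_start - 1])
      if (idx_start + best_len <= length(pos)) {
        expect_false(agree[idx_start + best_len])
      }
    }
  }

  # total disagreement
  expect_equal(nrow(shared_segment(c("0000", "1111"), pos[1:4])), 0L)
  expect_error(shared_segment(character(), pos), class = "crosspop_invalid")
})

test_that("sharing classification separates shared, specific and absent", {
  freqs <- tibble::tribble(
    ~population, ~haplotype, ~freq,
    "A", "h1", 0.30, "B", "h1", 0.00, "C", "h1", 0.005,
    "A", "h2", 0.20, "B", "h2", 0.25, "C", "h2", 0.0,
    "A", "h3", 0.03, "B", "h3", 0.03, "C", "h3", 0.03,
    "A", "h4", 0.30, "B", "h4", 0.03, "C", "h4", 0.0)
  out <- classify_sharing(freqs, presence_freq = 0.05, absence_freq = 0.01)
  st <- setNames(out$status, out$haplotype)
  expect_equal(unname(st["h1"]), "specific")
  expect_equal(unname(st["h2"]), "shared")
  expect_equal(unname(st["h3"]), "absent")
  # present once but not rare everywhere else: neither specific nor shared
  expect_equal(unname(st["h4"]), "absent")
  expect_error(classify_sharing(freqs, 0.01, 0.05),
               class = "crosspop_invalid")
})
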