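test_that("panel simulation honours its degenerate limits and determinism", {
  # no mutation: every site monomorphic
  p0 <- simulate_panel(50, 10, recomb_rate = 0.1, mutation_density = 0,
                       seed = 1)
  expect_true(all(p0$haplotypes == 0L))

  # no recombination: every pool haplotype copies one of the founders; with
  # 4 founders there are at most 4 distinct strings
  p1 <- simulate_panel(200, 4, recomb_rate = 0, mutation_density = 1, seed = 2)
  expect_lte(length(unique(hap_strings_test(p1$haplotypes))), 4L)

  # determinism
  a <- simulate_panel(1000, 100, seed = 1)
  b <- simulate_panel(1000, 100, seed = 1)
  expect_identical(a, b)
  expect_true(all(diff(a$positions) > 0))
  expect_true(any(colMeans(a$haplotypes) %% 1 != 0 |
                    (colMeans(a$haplotypes) > 0 & colMeans(a$haplotypes) < 1)))

  expect_error(simulate_panel(0, 10), class = "crosspop_invalid")
  expect_error(simulate_panel(10, 1), class = "crosspop_invalid")
})

test_that("population sampling drifts, differs across seeds, and is reproducible", {
  panel <- simulate_panel(300, 80, seed = 3)

  # single founder: all individuals identical homozygotes
  mono <- sample_population(panel, "M", 20, drift = 1, seed = 4)
  dosage <- as_geno_matrix(mono)$dosage
  expect_true(all(dosage %in% c(0, 2)))
  expect_true(all(apply(dosage, 2, function(v) length(unique(v))) == 1))

  p1 <- sample_population(panel, "A", 300, drift = 30, seed = 7)
  p2 <- sample_population(panel, "A", 300, drift = 30, seed = 8)
  maf1 <- as_geno_matrix(p1)$info$maf
  maf2 <- as_geno_matrix(p2)$info$maf
  expect_true(any(maf1 != maf2))

  expect_identical(sample_population(panel, "A", 50, drift = 10, seed = 9),
                   sample_population(panel, "A", 50, drift = 10, seed = 9))

  expect_error(sample_population(list(), "A", 10), class = "crosspop_invalid")
})

test_that("causal haplotype planting reaches its target frequencies", {
  panel <- simulate_panel(120, 80, seed = 11)
  mk <- function(nm, seed) sample_population(panel, nm, 150, drift = 25,
                                             seed = seed)
  pops <- list(A = mk("A", 1), B = mk("B", 2), C = mk("C", 3))
  w <- panel$positions[c(50, 56)]
  s <- distinct_window_string(panel, w[1], w[2])

  # null planting leaves populations untouched
  null <- plant_causal_haplotype(pops, w[1], w[2], s,
                                 frequency = c(A = 0, B = 0, C = 0), seed = 5)
  expect_identical(null$pops, pops)
  expect_true(all(vapply(null$truth$carriers,
                         function(d) sum(d$copies), numeric(1)) == 0))

  # plant in A only: absent elsewhere
  pa <- plant_causal_haplotype(pops, w[1], w[2], s,
                               frequency = c(A = 0.25), seed = 6)
  expect_equal(unname(pa$truth$realized_frequency["A"]), 0.25,
               tolerance = 0.05)
  expect_lt(unname(pa$truth$realized_frequency["B"]), 0.01)
  expect_lt(unname(pa$truth$realized_frequency["C"]), 0.01)

  # plant in A and B at 0.3: both carry the identical substring
  pab <- plant_causal_haplotype(pops, w[1], w[2], s,
                                frequency = c(A = 0.3, B = 0.3), seed = 7)
  for (nm in c("A", "B")) {
    idx <- which(pab$pops[[nm]]$positions >= w[1] &
                   pab$pops[[nm]]$positions <= w[2])
    carried <- hap_strings_test(pab$pops[[nm]]$haplotypes[, idx])
    expect_equal(mean(carried == s), 0.3, tolerance = 0.05)
  }

  expect_error(plant_causal_haplotype(pops, max(panel$positions) + 10,
                                      max(panel$positions) + 20, "11",
                                      frequency = c(A = 0.1)),
               class = "crosspop_range")
})

test_that("planted frequency recovery holds across seeds", {
  panel <- simulate_panel(100, 60, seed = 21)
  w <- panel$positions[c(40, 44)]
  s <- distinct_window_string(panel, w[1], w[2])
  for (seed in 1:20) {
    pop <- sample_population(panel, "A", 300, drift = 30, seed = seed)
    pl <- plant_causal_haplotype(list(A = pop), w[1], w[2], s,
                                 frequency = c(A = 0.2), seed = seed + 100)
    expect_lte(abs(pl$truth$realized_frequency[["A"]] - 0.2), 0.05)
  }
})

test_that("phenotype simulation decomposes variance as designed", {
  panel <- simulate_panel(150, 80, seed = 31)
  pop <- sample_population(panel, "A", 200, drift = 40, seed = 32)

  # degenerate limits
  pl <- plant_causal_haplotype(list(A = pop), panel$positions[70],
                               panel$positions[74],
                               distinct_window_string(panel,
                                                      panel$positions[70],
                                                      panel$positions[74]),
                               frequency = c(A = 0.3), effect = 1,
                               h2 = 0.3, seed = 33)
  flat <- simulate_phenotypes(pl$pops$A, pl$truth, h2 = 0, sigma_e2 = 0,
                              fixed_effects = FALSE, seed = 34)
  expect_equal(flat$trait, flat$copies)   # y == carrier copy count exactly

  zero <- plant_causal_haplotype(list(A = pop), panel$positions[70],
                                 panel$positions[74], pl$truth$hap_string,
                                 frequency = c(A = 0), effect = 0, seed = 35)
  const <- simulate_phenotypes(zero$pops$A, zero$truth, h2 = 0, sigma_e2 = 0,
                               fixed_effects = FALSE, seed = 36)
  expect_true(all(const$trait == const$trait[1]))

  expect_error(simulate_phenotypes(pop, NULL, h2 = 0.5, sigma_e2 = -1),
               class = "crosspop_invalid")

  # empirical var(u) / (var(u) + var(e)) approaches the h2 target
  pop5 <- sample_population(panel, "B", 500, drift = 40, seed = 37)
  geno <- as_geno_matrix(pop5)
  grm <- compute_grm(geno)
  h2_hat <- replicate(8, {
    ph <- simulate_phenotypes(pop5, NULL, h2 = 0.5, sigma_e2 = 1,
                              fixed_effects = FALSE, grm = grm,
                              seed = sample.int(1e6, 1))
    fit <- reml_fit(ph$trait - mean(ph$trait), grm)
    fit$h2
  })
  expect_lte(abs(mean(h2_hat) - 0.5), 0.1)
})

test_that("fixtures round-trip through VCF, TSV and truth files", {
  panel <- simulate_panel(80, 40, seed = 41)
  pop <- sample_population(panel, "RT", 30, drift = 15, seed = 42)
  pl <- plant_causal_haplotype(list(RT = pop), panel$positions[30],
                               panel$positions[34],
                               distinct_window_string(panel,
                                                      panel$positions[30],
                                                      panel$positions[34]),
                               frequency = c(RT = 0.2), effect = -0.5,
                               seed = 43)
  ph <- simulate_phenotypes(pl$pops$RT, pl$truth, seed = 44)
  dir <- withr::local_tempdir()
  paths <- write_fixture(pl$pops$RT, ph, pl$truth, dir)

  # VCF header contract
  lines <- readLines(paths[["vcf"]])
  expect_match(lines[1], "VCFv4.2")
  expect_true(any(grepl("^##contig=<ID=1,", lines)))
  header <- strsplit(grep("^#CHROM", lines, value = TRUE), "\t")[[1]]
  expect_length(header, 9 + 30)

  back <- read_phased_vcf(paths[["vcf"]], samples = ph[, c("id", "sex", "batch")])
  expect_identical(back$haplotypes, pl$pops$RT$haplotypes)
  expect_identical(back$positions, pl$pops$RT$positions)

  ph_back <- read_phenotypes(paths[["pheno"]])
  expect_equal(ph_back$trait, ph$trait, tolerance = 1e-10)
  expect_identical(ph_back$id, ph$id)

  truth_back <- read_truth(paths[["truth"]])
  expect_equal(truth_back$hap_string, pl$truth$hap_string)
  expect_equal(truth_back$realized_frequency, pl$truth$realized_frequency)
  expect_equal(truth_back$carriers$RT$copies, pl$truth$carriers$RT$copies)
  expect_equal(truth_back$start_bp, pl$truth$start_bp)
})
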