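#' Simulate an ancestral haplotype panel
#'
#' Builds a pool of phased binary haplotypes that later serves as the common
#' ancestral gene pool from which the individual study populations are drawn.
#' Sites are made segregating independently with probability
#' `mutation_density`; the derived-allele frequency of a segregating site is
#' drawn from a U-shaped Beta(0.4, 0.4) so that the panel carries a realistic
#' minor-allele-frequency spectrum with an excess of rare variants.  Local
#' linkage disequilibrium arises from a few rounds of random-mating
#' recombination within the pool (per-site crossover probability
#' `recomb_rate`).
#'
#' @param l_sites Number of variant sites (columns of the panel).
#' @param n_pool Number of haplotypes kept in the pool.
#' @param recomb_rate Per-site crossover probability between consecutive
#'   sites, in `[0, 1]`.  `0` keeps every pool haplotype an exact copy of one
#'   founder.
#' @param mutation_density Fraction of sites that segregate in the founders,
#'   in `[0, 1]`.  `0` yields a fully monomorphic panel.
#' @param seed Integer seed; identical seeds give bit-identical panels.
#' @param chrom Chromosome label written into all downstream output.
#' @param n_founders Number of distinct deep-ancestry haplotypes the pool is
#'   recombined from (capped at `n_pool`).  A limited founder set is what
#'   makes window haplotypes recur at appreciable frequencies, as in real
#'   livestock populations.
#'
#' @return An object of class `ancestral_panel`: a list with `haplotypes`
#'   (`n_pool` x `l_sites` 0/1 matrix), `positions` (strictly increasing
#'   1-based bp), `chrom`, and `recomb_rate`.
#' @export
simulate_panel <- function(l_sites, n_pool, recomb_rate = 0.01,
                           mutation_density = 0.9, seed = NULL,
                           chrom = "1", n_founders = 30L) {
  check_scalar_number(l_sites, "l_sites", lower = 1)
  check_scalar_number(n_pool, "n_pool", lower = 2)
  check_scalar_number(recomb_rate, "recomb_rate", 0, 1)
  check_scalar_number(mutation_density, "mutation_density", 0, 1)
  check_scalar_number(n_founders, "n_founders", lower = 2)
  l_sites <- as.integer(l_sites)
  n_pool <- as.integer(n_pool)
  n_founders <- min(as.integer(n_founders), n_pool)

  with_seed(seed, {
    positions <- cumsum(sample.int(4000L, l_sites, replace = TRUE))
    segregating <- runif(l_sites) < mutation_density
    founders <- matrix(0L, nrow = n_founders, ncol = l_sites)
    if (any(segregating)) {
      q <- stats::rbeta(sum(segregating), 0.4, 0.4)
      founders[, segregating] <- vapply(q, function(p) rbinom(n_founders, 1L, p),
                                        integer(n_founders))
    }
    # guarantee at least one segregating site when mutation was requested
    if (mutation_density > 0 &&
        all(colSums(founders) %in% c(0L, n_founders))) {
      founders[, 1L] <- rep_len(c(0L, 1L), n_founders)
    }
    hap <- founders[rep_len(seq_len(n_founders), n_pool), , drop = FALSE]
    # random-mating rounds within the pool generate local LD blocks
    if (recomb_rate > 0) {
      for (gen in 1:3) {
        parents <- matrix(sample.int(n_pool, 2L * n_pool, replace = TRUE),
                          ncol = 2L)
        hap <- t(vapply(seq_len(n_pool), function(i) {
          recombine_pair(hap[parents[i, 1L], ], hap[parents[i, 2L], ],
                         recomb_rate)
        }, integer(l_sites)))
      }
    }
    structure(list(haplotypes = hap, positions = positions,
                   chrom = as.character(chrom), recomb_rate = recomb_rate),
              class = "ancestral_panel")
  })
}

#' @export
print.ancestral_panel <- function(x, ...) {
  seg <- sum(colSums(x$haplotypes) %% nrow(x$haplotypes) != 0)
  cat(sprintf("<ancestral_panel> %d haplotypes x %d sites (%d segregating), chrom %s\n",
              nrow(x$haplotypes), ncol(x$haplotypes), seg, x$chrom))
  invisible(x)
}

#' Draw one population from an ancestral panel through a drift bottleneck
#'
#' `drift` founder haplotypes are sampled from the panel; every individual
#' chromosome is then produced by recombining two random founders at the
#' panel's crossover rate.  Small `drift` values produce strong differentiation
#' from the panel (and between populations), large values keep the population
#' close to the ancestral frequencies, so a single parameter controls both
#' drift and background relatedness.
#'
#' @param panel An `ancestral_panel`.
#' @param name Population label (used in sample ids and all reports).
#' @param n_individuals Number of diploid individuals (`>= 2`).
#' @param drift Bottleneck size: number of founder haplotypes (`>= 1`).
#'   `1` makes every individual an identical homozygote.
#' @param n_sex,n_batch Numbers of sex and slaughter-batch levels assigned
#'   uniformly at random to individuals (defaults 2 and 3).
#' @param seed Integer seed for reproducibility.
#'
#' @return An object of class `phased_pop`: list with `haplotypes`
#'   (`2 * n_individuals` x L 0/1 matrix; individual i owns rows 2i-1 and 2i),
#'   `positions`, `chrom`, `name`, and a `samples` tibble
#'   (`id`, `sex`, `batch`).
#' @export
sample_population <- function(panel, name, n_individuals, drift = 30,
                              n_sex = 2, n_batch = 3, seed = NULL) {
  if (!inherits(panel, "ancestral_panel") || ncol(panel$haplotypes) == 0) {
    stop_invalid("`panel` must be a non-empty `ancestral_panel`.")
  }
  check_scalar_number(n_individuals, "n_individuals", lower = 2)
  check_scalar_number(drift, "drift", lower = 1)
  n_individuals <- as.integer(n_individuals)
  drift <- as.integer(drift)

  with_seed(seed, {
    n_pool <- nrow(panel$haplotypes)
    founders <- panel$haplotypes[
      sample.int(n_pool, drift, replace = drift > n_pool), , drop = FALSE]
    l <- ncol(founders)
    n_hap <- 2L * n_individuals
    pick <- matrix(sample.int(drift, 2L * n_hap, replace = TRUE), ncol = 2L)
    hap <- t(vapply(seq_len(n_hap), function(i) {
      recombine_pair(founders[pick[i, 1L], ], founders[pick[i, 2L], ],
                     panel$recomb_rate)
    }, integer(l)))
    samples <- tibble(
      id = sprintf("%s_%04d", name, seq_len(n_individuals)),
      sex = paste0("S", sample.int(n_sex, n_individuals, replace = TRUE)),
      batch = paste0("B", sample.int(n_batch, n_individuals, replace = TRUE))
    )
    structure(list(haplotypes = hap, positions = panel$positions,
                   chrom = panel$chrom, name = name, samples = samples),
              class = "phased_pop")
  })
}

#' @export
print.phased_pop <- function(x, ...) {
  cat(sprintf("<phased_pop> '%s': %d individuals x %d sites, chrom %s\n",
              x$name, nrow(x$samples), ncol(x$haplotypes), x$chrom))
  invisible(x)
}

n_ind <- function(pop) nrow(pop$samples)

window_index <- function(positions, start_bp, end_bp) {
  idx <- which(positions >= start_bp & positions <= end_bp)
  if (length(idx) == 0) {
    abort("Causal window contains no panel positions.", class = "crosspop_range")
  }
  idx
}

#' Pick a window haplotype string absent from a panel
#'
#' Returns an allele string over the window that no panel haplotype carries,
#' so that planting it leaves non-target populations free of the segment.
#' The string is built by complementing the window alleles of the most common
#' panel haplotype; if that string happens to exist in the panel, single sites
#' are flipped until it is unique.
#'
#' @param panel An `ancestral_panel`.
#' @param start_bp,end_bp Window bounds in bp (1-based inclusive).
#' @return Character scalar of 0/1 alleles over the window sites.
#' @export
distinct_window_string <- function(panel, start_bp, end_bp) {
  idx <- window_index(panel$positions, start_bp, end_bp)
  sub <- panel$haplotypes[, idx, drop = FALSE]
  existing <- unique(hap_strings(sub))
  major <- as.integer(round(colMeans(sub)))
  cand <- 1L - major
  flip <- 0L
  while (paste0(cand, collapse = "") %in% existing && flip < length(cand)) {
    flip <- flip + 1L
    cand[flip] <- 1L - cand[flip]
  }
  paste0(cand, collapse = "")
}

#' Plant a causal haplotype segment into one or more populations
#'
#' Overwrites the window alleles of randomly chosen chromosomes with
#' `hap_string` until the carrier-haplotype frequency in each targeted
#' population reaches its requested value.  Populations with target 0 are
#' left untouched.  The returned truth record carries everything needed to
#' simulate phenotypes and audit recovery: the window, the allele string,
#' per-population per-copy effects, the polygenic heritability target, and
#' the exact per-individual carrier copy counts.
#'
#' @param pops Named list of `phased_pop` objects sharing the same positions.
#' @param start_bp,end_bp Causal window in bp (1-based inclusive); must
#'   contain at least one site.
#' @param hap_string Allele string (0/1 characters) over the window sites.
#' @param frequency Named numeric vector of target carrier frequencies per
#'   population (names matching `names(pops)`; missing names mean 0).
#' @param effect Per-copy trait effect of the planted haplotype; scalar or
#'   named per-population vector (trait units).
#' @param h2 Polygenic (narrow-sense) heritability target of the genomic
#'   background, in `[0, 1)`; default 0.46, a typical genomic heritability
#'   for muscle fatty-acid composition traits.
#' @param sigma_e2 Residual variance (trait units squared).
#' @param seed Integer seed.
#'
#' @return A list with `pops` (modified populations) and `truth` (class
#'   `truth_record`).
#' @export
plant_causal_haplotype <- function(pops, start_bp, end_bp, hap_string,
                                   frequency, effect = 0, h2 = 0.46,
                                   sigma_e2 = 1, seed = NULL) {
  if (!is.list(pops) || is.null(names(pops)) ||
      !all(vapply(pops, inherits, logical(1), "phased_pop"))) {
    stop_invalid("`pops` must be a named list of `phased_pop` objects.")
  }
  check_scalar_number(h2, "h2", 0, 1 - 1e-12)
  check_scalar_number(sigma_e2, "sigma_e2", lower = 0)
  idx <- window_index(pops[[1]]$positions, start_bp, end_bp)
  alleles <- as.integer(strsplit(hap_string, "")[[1]])
  if (length(alleles) != length(idx) || !all(alleles %in% c(0L, 1L))) {
    stop_invalid("`hap_string` must be a 0/1 string over the window sites.")
  }
  freq <- setNames(rep(0, length(pops)), names(pops))
  freq[names(frequency)] <- frequency
  if (any(freq < 0 | freq > 1)) stop_invalid("Target frequencies must lie in [0, 1].")
  eff <- if (length(effect) == 1L && is.null(names(effect))) {
    setNames(rep(effect, length(pops)), names(pops))
  } else {
    out <- setNames(rep(0, length(pops)), names(pops))
    out[names(effect)] <- effect
    out
  }

  with_seed(seed, {
    carriers <- list()
    for (pn in names(pops)) {
      pop <- pops[[pn]]
      n_hap <- nrow(pop$haplotypes)
      target_k <- as.integer(round(freq[[pn]] * n_hap))
      is_carrier <- function() {
        rowSums(pop$haplotypes[, idx, drop = FALSE] !=
                  matrix(alleles, n_hap, length(idx), byrow = TRUE)) == 0
      }
      if (freq[[pn]] > 0) {
        carrier <- is_carrier()
        attempts <- 0L
        max_attempts <- 10L * n_hap
        while (sum(carrier) < target_k) {
          attempts <- attempts + 1L
          if (attempts > max_attempts) {
            abort(sprintf("Could not reach target frequency %.2f in '%s' after %d attempts.",
                          freq[[pn]], pn, max_attempts),
                  class = "crosspop_invalid")
          }
          j <- sample.int(n_hap, 1L)
          if (carrier[j]) next
          pop$haplotypes[j, idx] <- alleles
          carrier[j] <- TRUE
        }
        pops[[pn]] <- pop
      }
      carrier <- is_carrier()
      copies <- carrier[seq(1L, n_hap, by = 2L)] + carrier[seq(2L, n_hap, by = 2L)]
      carriers[[pn]] <- tibble(id = pop$samples$id, copies = as.integer(copies))
    }
    truth <- structure(list(
      chrom = pops[[1]]$chrom,
      start_bp = pops[[1]]$positions[idx[1]],
      end_bp = pops[[1]]$positions[idx[length(idx)]],
      hap_string = paste0(alleles, collapse = ""),
      effect = eff,
      h2 = setNames(rep(h2, length(pops)), names(pops)),
      sigma_e2 = sigma_e2,
      target_frequency = freq,
      realized_frequency = vapply(names(pops), function(pn) {
        mean(carriers[[pn]]$copies) / 2
      }, numeric(1)),
      shared = freq > 0,
      carriers = carriers
    ), class = "truth_record")
    list(pops = pops, truth = truth)
  })
}

#' Simulate phenotypes with a polygenic background and planted effects
#'
#' Generates `y = mu + sex + batch + copies * a + u + e` for one population:
#' `u ~ MVN(0, sigma_a2 * G)` with `G` the realized genomic relationship
#' matrix of the population and `sigma_a2` set from the truth record's
#' heritability target (`sigma_a2 = h2 / (1 - h2) * sigma_e2`), and
#' `e ~ N(0, sigma_e2)` iid.  Sex and batch act as fixed offsets of
#' 0 for the reference level and `+1 * sigma_e` for every other level, large
#' enough to matter but not to dominate, so that the residualization step of
#' the association pipeline is genuinely exercised.
#'
#' @param pop A `phased_pop`.
#' @param truth A `truth_record` from [plant_causal_haplotype()], or `NULL`
#'   for a purely polygenic trait (then `h2` and `sigma_e2` must be given).
#' @param h2,sigma_e2 Overrides of the truth record's values.
#' @param fixed_effects Logical; `FALSE` switches the sex/batch offsets off.
#' @param mu Trait intercept.
#' @param grm Optional precomputed [compute_grm()] result for this population.
#' @param seed Integer seed.
#'
#' @return The population's `samples` tibble with an added numeric `trait`
#'   column (and the carrier `copies` used, for auditing).
#' @export
simulate_phenotypes <- function(pop, truth = NULL, h2 = NULL, sigma_e2 = NULL,
                                fixed_effects = TRUE, mu = 0, grm = NULL,
                                seed = NULL) {
  h2 <- h2 %||% (if (!is.null(truth)) unname(truth$h2[pop$name]) else NULL)
  sigma_e2 <- sigma_e2 %||% (if (!is.null(truth)) truth$sigma_e2 else NULL)
  if (is.null(h2) || is.null(sigma_e2)) {
    stop_invalid("`h2` and `sigma_e2` must be supplied when `truth` is NULL.")
  }
  check_scalar_number(h2, "h2", 0, 1 - 1e-12)
  check_scalar_number(sigma_e2, "sigma_e2", lower = 0)
  n <- n_ind(pop)
  sigma_a2 <- h2 / (1 - h2) * sigma_e2
  copies <- rep(0L, n)
  a <- 0
  if (!is.null(truth)) {
    car <- truth$carriers[[pop$name]]
    if (!is.null(car)) copies <- car$copies[match(pop$samples$id, car$id)]
    a <- unname(truth$effect[pop$name])
    if (is.na(a)) a <- 0
  }

  with_seed(seed, {
    u <- rep(0, n)
    if (sigma_a2 > 0) {
      if (is.null(grm)) grm <- compute_grm(as_geno_matrix(pop))
      eg <- eigen(unclass(grm), symmetric = TRUE)
      lam <- pmax(eg$values, 0)
      u <- as.numeric(eg$vectors %*% (sqrt(sigma_a2 * lam) * rnorm(n)))
    }
    e <- rnorm(n, 0, sqrt(sigma_e2))
    sig_e <- sqrt(sigma_e2)
    fx <- rep(0, n)
    if (isTRUE(fixed_effects)) {
      sex_lv <- sort(unique(pop$samples$sex))
      batch_lv <- sort(unique(pop$samples$batch))
      fx <- sig_e * ((pop$samples$sex != sex_lv[1]) +
                       (pop$samples$batch != batch_lv[1]))
    }
    dplyr::mutate(pop$samples,
                  copies = copies,
                  trait = mu + fx + copies * a + u + e)
  })
}
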