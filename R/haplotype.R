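#' Extract window haplotypes around a lead variant
#'
#' Collects the phased haplotypes over a window of `2k + 1` SNPs centered on
#' the lead variant (`k` on each side; the window is truncated with a
#' warning at chromosome ends).  Distinct allele strings are enumerated,
#' labelled `Hap1, Hap2, ...` in decreasing frequency order, and every
#' individual's diplotype (its pair of haplotype ids) is recorded.
#'
#' @param pop A `phased_pop`.
#' @param lead_pos Position (bp) of the lead variant; must exist in the
#'   population's variant set.
#' @param k Number of flanking SNPs on each side (default 20, i.e. 41-SNP
#'   windows).
#' @return Object of class `hap_set`: list with `chrom`, `positions`,
#'   `lead_pos`, `population`, `haplotypes` (tibble `haplotype`, `string`,
#'   `count`, `freq`), and `diplotypes` (`n x 2` character matrix of
#'   haplotype ids).
#' @export
extract_window <- function(pop, lead_pos, k = 20) {
  stopifnot(inherits(pop, "phased_pop"))
  check_scalar_number(k, "k", lower = 0)
  i <- match(lead_pos, pop$positions)
  if (is.na(i)) {
    abort(sprintf("Lead position %s absent from population '%s'.",
                  format(lead_pos), pop$name), class = "crosspop_key")
  }
  l <- length(pop$positions)
  idx <- max(1L, i - k):min(l, i + k)
  if (length(idx) < 2L * k + 1L) {
    warn(sprintf("Window truncated at chromosome end: %d of %d positions.",
                 length(idx), 2L * k + 1L))
  }
  strings <- hap_strings(pop$haplotypes[, idx, drop = FALSE])
  tab <- sort(table(strings), decreasing = TRUE)
  haps <- tibble(
    haplotype = paste0("Hap", seq_along(tab)),
    string = names(tab),
    count = as.integer(tab),
    freq = as.integer(tab) / length(strings)
  )
  ids <- haps$haplotype[match(strings, haps$string)]
  n <- n_ind(pop)
  diplo <- cbind(ids[seq(1L, 2L * n, 2L)], ids[seq(2L, 2L * n, 2L)])
  rownames(diplo) <- pop$samples$id
  structure(list(chrom = pop$chrom, positions = pop$positions[idx],
                 lead_pos = lead_pos, population = pop$name,
                 haplotypes = haps, diplotypes = diplo),
            class = "hap_set")
}

#' @export
print.hap_set <- function(x, ...) {
  cat(sprintf("<hap_set> '%s': %d positions around %s, %d distinct haplotypes\n",
              x$population, length(x$positions), format(x$lead_pos),
              nrow(x$haplotypes)))
  invisible(x)
}

#' Build the haplotype incidence (copy-count) matrix
#'
#' Haplotypes with frequency strictly above `min_freq` receive their own
#' column; all remaining haplotypes are pooled into a single `rare` column so
#' that every individual's row still sums to 2 and no carrier is discarded.
#'
#' @param hset A [extract_window()] result.
#' @param min_freq Frequency threshold (strict `>`), default 0.05.
#' @return Object of class `hap_incidence`: list with `H` (`n x p` integer
#'   matrix), `haplotypes` (tibble for retained columns), `rare_pooled`
#'   (ids pooled into `rare`, possibly empty), `population`.
#' @export
build_incidence <- function(hset, min_freq = 0.05) {
  stopifnot(inherits(hset, "hap_set"))
  check_scalar_number(min_freq, "min_freq", 0, 0.5)
  keep <- hset$haplotypes$freq > min_freq
  if (!any(keep)) {
    stop_invalid("No haplotype exceeds `min_freq`; nothing to model.")
  }
  ids <- hset$haplotypes$haplotype[keep]
  pooled <- hset$haplotypes$haplotype[!keep]
  cols <- c(ids, if (length(pooled)) "rare")
  n <- nrow(hset$diplotypes)
  H <- matrix(0L, n, length(cols), dimnames = list(rownames(hset$diplotypes), cols))
  for (j in 1:2) {
    hit <- hset$diplotypes[, j]
    hit[hit %in% pooled] <- "rare"
    H[cbind(seq_len(n), match(hit, cols))] <-
      H[cbind(seq_len(n), match(hit, cols))] + 1L
  }
  structure(list(H = H, haplotypes = hset$haplotypes[keep, , drop = FALSE],
                 rare_pooled = pooled, population = hset$population),
            class = "hap_incidence")
}

#' Estimate haplotype effects by whitened least squares
#'
#' Fits `y = H b + u + e` with `u ~ MVN(0, sigma_a2 G)` by transforming the
#' model with the inverse square root of `V = sigma_a2 G + sigma_e2 I`
#' (computed through the eigendecomposition of `V`): after whitening, the
#' residuals are iid and the haplotype effects are estimated by ordinary
#' least squares.  Because the rows of `H` sum to 2, the model with an
#' intercept is identified by dropping the most frequent haplotype as the
#' reference; effects are reported per copy, as deviations from the
#' reference (whose effect is fixed at 0).
#'
#' @param y Numeric phenotype vector (residualized).
#' @param incidence A [build_incidence()] result aligned to `y`.
#' @param vc A [reml_fit()] (supplies `sigma_a2`, `sigma_e2`).
#' @param G The [compute_grm()] matrix used for `vc` (or its
#'   eigendecomposition).
#' @return Tibble of class `hap_effects`: `population`, `haplotype`, `freq`,
#'   `beta`, `se`, `statistic`, `p` (reference row: `beta` 0, `se`/`p` `NA`;
#'   t-test with `n - ncol(design)` degrees of freedom).
#' @export
estimate_haplotype_effects <- function(y, incidence, vc, G) {
  stopifnot(inherits(incidence, "hap_incidence"))
  H <- incidence$H
  n <- length(y)
  if (nrow(H) != n) stop_invalid("`y` and `incidence` are not aligned.")
  eg <- if (is.list(G) && !is.null(G$vectors)) G else reml_eigen(G)
  d <- vc$sigma_a2 * eg$values + vc$sigma_e2
  if (min(d) <= 0) stop_invalid("V = sigma_a2 G + sigma_e2 I is not positive definite.")
  winv <- function(v) eg$vectors %*% ((1 / sqrt(d)) * crossprod(eg$vectors, v))

  ref <- colnames(H)[1L]   # most frequent haplotype
  X <- cbind(`(Intercept)` = 1, H[, setdiff(colnames(H), ref), drop = FALSE])
  Xt <- apply(X, 2L, winv)
  yt <- as.numeric(winv(y))

  qrX <- qr(Xt)
  if (qrX$rank < ncol(Xt)) {
    dropped <- colnames(Xt)[qrX$pivot[(qrX$rank + 1L):ncol(Xt)]]
    warn(paste0("Dropping collinear haplotype column(s): ",
                paste(dropped, collapse = ", ")))
    Xt <- Xt[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    X <- X[, colnames(Xt), drop = FALSE]
    qrX <- qr(Xt)
  }
  beta <- qr.coef(qrX, yt)
  res <- yt - Xt %*% beta
  df <- n - ncol(Xt)
  sigma2 <- sum(res^2) / df
  xtx_inv <- solve(crossprod(Xt))
  se <- sqrt(sigma2 * diag(xtx_inv))
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df = df)

  hap_cols <- setdiff(colnames(Xt), "(Intercept)")
  freq_of <- function(id) {
    if (id == "rare") {
      1 - sum(incidence$haplotypes$freq)
    } else {
      incidence$haplotypes$freq[match(id, incidence$haplotypes$haplotype)]
    }
  }
  j <- match(hap_cols, colnames(Xt))
  out <- dplyr::bind_rows(
    tibble(population = incidence$population, haplotype = ref,
           freq = freq_of(ref), beta = 0, se = NA_real_,
           statistic = NA_real_, p = NA_real_, reference = TRUE),
    tibble(population = incidence$population, haplotype = hap_cols,
           freq = vapply(hap_cols, freq_of, numeric(1)),
           beta = unname(beta[j]), se = unname(se[j]),
           statistic = unname(tval[j]), p = unname(pval[j]),
           reference = FALSE)
  )
  class(out) <- c("hap_effects", class(out))
  out
}

#' Longest shared segment among selected haplotypes
#'
#' Finds the longest run of consecutive window positions at which all
#' supplied haplotype strings (typically the trait-decreasing haplotypes of
#' several populations, over a common position list) carry identical
#' alleles, and reports it as a 1-based inclusive bp interval.  Ties are
#' broken by the leftmost run.
#'
#' @param strings Character vector of allele strings (equal length, one per
#'   selected haplotype; at least one).
#' @param positions Bp positions of the window sites (length = string width).
#' @param chrom Optional chromosome label for the report.
#' @return One-row tibble (`chrom`, `start_bp`, `end_bp`, `n_snps`,
#'   `length_bp`), or a zero-row tibble when no position agrees.
#' @export
shared_segment <- function(strings, positions, chrom = NA_character_) {
  if (length(strings) == 0) stop_invalid("`strings` must not be empty.")
  widths <- unique(nchar(strings))
  if (length(widths) != 1L || widths != length(positions)) {
    stop_invalid("All strings must match the length of `positions`.")
  }
  mat <- do.call(rbind, strsplit(strings, ""))
  agree <- apply(mat, 2L, function(col) all(col == col[1L]))
  empty <- tibble(chrom = character(), start_bp = numeric(),
                  end_bp = numeric(), n_snps = integer(),
                  length_bp = numeric())
  if (!any(agree)) return(empty)
  r <- rle(agree)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  true_runs <- which(r$values)
  best <- true_runs[which.max(r$lengths[true_runs])]   # leftmost on ties
  s <- starts[best]; e <- ends[best]
  tibble(chrom = chrom, start_bp = positions[s], end_bp = positions[e],
         n_snps = e - s + 1L, length_bp = positions[e] - positions[s] + 1)
}

#' Classify haplotype sharing across populations
#'
#' A haplotype is `specific` when its frequency reaches `presence_freq` in
#' exactly one population and stays below `absence_freq` everywhere else,
#' `shared` when it reaches `presence_freq` in two or more populations, and
#' `absent` otherwise.
#'
#' @param freqs Tibble with columns `population`, `haplotype` (or any id
#'   column named `haplotype`), `freq`; one row per population-haplotype.
#' @param presence_freq,absence_freq Frequency thresholds with
#'   `presence_freq > absence_freq`.
#' @return Tibble `haplotype`, `status`, `n_present`, `populations_present`.
#' @export
classify_sharing <- function(freqs, presence_freq = 0.05, absence_freq = 0.01) {
  if (presence_freq <= absence_freq) {
    stop_invalid("`presence_freq` must exceed `absence_freq`.")
  }
  as_tibble(freqs) |>
    dplyr::group_by(.data$haplotype) |>
    dplyr::summarise(
      n_present = sum(.data$freq >= presence_freq),
      n_low = sum(.data$freq < absence_freq),
      n_pops = dplyr::n(),
      populations_present = paste(
        .data$population[.data$freq >= presence_freq], collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::mutate(status = dplyr::case_when(
      .data$n_present >= 2 ~ "shared",
      .data$n_present == 1 & .data$n_low == .data$n_pops - 1 ~ "specific",
      TRUE ~ "absent"
    )) |>
    dplyr::select("haplotype", "status", "n_present", "populations_present")
}
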