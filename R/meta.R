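# Sample-size weighted z-score meta-analysis across populations, in the
# style of METAL's "samplesize" scheme: per-population signed z-scores
# z_i = sign(beta_i) * qnorm(1 - p_i / 2) are combined as
# Z = sum(sqrt(N_i) z_i) / sqrt(sum(N_i)), p = 2 * (1 - Phi(|Z|)).

AMBIGUOUS_PAIRS <- c("A/T", "T/A", "C/G", "G/C")

#' Harmonize per-population association records to shared effect alleles
#'
#' Variants are keyed by `chrom:pos`.  The effect/other allele pair of the
#' first population carrying a variant defines the reference orientation;
#' records whose alleles are swapped relative to it have their effect
#' direction negated, records with incompatible alleles are excluded and
#' flagged, and strand-ambiguous pairs (A/T, C/G) are kept but flagged.
#'
#' @param scans Named list of association tibbles ([lmm_scan()] output; the
#'   names label the populations).
#' @param min_p Floor applied to p-values before conversion to z (underflow
#'   guard); floored records carry the `p_clamped` flag.
#' @return Long tibble of class `aligned_assoc`: `chrom`, `pos`,
#'   `population`, `z`, `n`, `direction`, `effect_allele`, `excluded`,
#'   `flag`.
#' @export
align_alleles <- function(scans, min_p = 1e-300) {
  if (is.null(names(scans)) || any(names(scans) == "")) {
    stop_invalid("`scans` must be a named list (one name per population).")
  }
  long <- purrr::imap(scans, function(s, nm) {
    dplyr::mutate(as_tibble(s), population = nm)
  }) |> dplyr::bind_rows()
  long$key <- paste0(long$chrom, ":", long$pos)

  ref <- long |>
    dplyr::distinct(.data$key, .keep_all = TRUE) |>
    dplyr::select("key", ref_ea = "effect_allele", ref_oa = "other_allele")

  long |>
    dplyr::left_join(ref, by = "key") |>
    dplyr::mutate(
      swapped = .data$effect_allele == .data$ref_oa &
        .data$other_allele == .data$ref_ea,
      matched = (.data$effect_allele == .data$ref_ea &
                   .data$other_allele == .data$ref_oa) | .data$swapped,
      ambiguous = paste0(.data$effect_allele, "/", .data$other_allele) %in%
        AMBIGUOUS_PAIRS,
      p_clamped = .data$p < min_p,
      p_use = pmax(.data$p, min_p),
      direction = ifelse(.data$swapped, -sign(.data$beta), sign(.data$beta)),
      z = .data$direction * qnorm(.data$p_use / 2, lower.tail = FALSE),
      excluded = !.data$matched,
      flag = dplyr::case_when(
        !.data$matched ~ "allele_mismatch",
        .data$ambiguous & .data$p_clamped ~ "strand_ambiguous;p_clamped",
        .data$ambiguous ~ "strand_ambiguous",
        .data$p_clamped ~ "p_clamped",
        TRUE ~ ""
      ),
      effect_allele = .data$ref_ea,
      other_allele = .data$ref_oa
    ) |>
    dplyr::select("chrom", "pos", "population", "z", "n", "direction",
                  "effect_allele", "other_allele", "excluded", "flag") |>
    structure(class = c("aligned_assoc", class(tibble())))
}

#' Combine aligned records into meta-analysis statistics
#'
#' @param aligned An `aligned_assoc` tibble from [align_alleles()]
#'   (excluded records are dropped here).
#' @param populations Population order for the direction string; defaults to
#'   the order of appearance.
#' @param min_populations Keep variants present in at least this many
#'   populations (default 1).
#' @return Tibble of class `meta_scan`: `chrom`, `pos`, `effect_allele`,
#'   `Z`, `p`, `n_total`, `n_pops`, `direction` (one `+`/`-`/`?` character
#'   per population).
#' @export
meta_z <- function(aligned, populations = NULL, min_populations = 1) {
  aligned <- dplyr::filter(as_tibble(aligned), !.data$excluded)
  if (nrow(aligned) == 0) {
    return(tibble(chrom = character(), pos = numeric(),
                  effect_allele = character(), Z = numeric(), p = numeric(),
                  n_total = numeric(), n_pops = integer(),
                  direction = character()))
  }
  populations <- populations %||% unique(aligned$population)
  dir_string <- function(pop, dir) {
    s <- rep("?", length(populations))
    s[match(pop, populations)] <- ifelse(dir >= 0, "+", "-")
    paste0(s, collapse = "")
  }
  out <- aligned |>
    dplyr::group_by(.data$chrom, .data$pos, .data$effect_allele) |>
    dplyr::summarise(
      Z = sum(sqrt(.data$n) * .data$z) / sqrt(sum(.data$n)),
      n_total = sum(.data$n),
      n_pops = dplyr::n(),
      direction = dir_string(.data$population, .data$z),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_pops >= min_populations) |>
    dplyr::mutate(p = pmax(2 * pnorm(abs(.data$Z), lower.tail = FALSE),
                           1e-300)) |>
    dplyr::select("chrom", "pos", "effect_allele", "Z", "p", "n_total",
                  "n_pops", "direction") |>
    dplyr::arrange(.data$chrom, .data$pos)
  class(out) <- c("meta_scan", class(out))
  out
}

#' Meta-analyse per-population scans and call meta leads
#'
#' Convenience wrapper: harmonizes alleles, combines z-scores, calls lead
#' variants on the meta p-values with the genome-wide threshold, and reports
#' for each meta lead the best single-population `-log10 p` at the same
#' variant, the quantity used to judge whether meta-analysis enhanced the
#' signal.
#'
#' @inheritParams align_alleles
#' @param threshold Lead-calling threshold on the meta p-value.
#' @param min_populations Passed to [meta_z()].
#' @return List of class `meta_result` with `meta` (the [meta_z()] tibble)
#'   and `leads` (meta leads with `best_single_log10p` and
#'   `meta_log10p` columns).
#' @export
meta_scan <- function(scans, threshold = 5e-8, min_populations = 1) {
  aligned <- align_alleles(scans)
  meta <- meta_z(aligned, populations = names(scans),
                 min_populations = min_populations)
  leads <- call_lead_snps(meta, threshold = threshold)
  if (nrow(leads) > 0) {
    best <- purrr::imap(scans, function(s, nm) {
      tibble(chrom = s$chrom, pos = s$pos, p_single = s$p)
    }) |>
      dplyr::bind_rows() |>
      dplyr::group_by(.data$chrom, .data$pos) |>
      dplyr::summarise(best_single_log10p = max(-log10(.data$p_single)),
                       .groups = "drop")
    leads <- leads |>
      dplyr::left_join(best, by = c("chrom", "pos")) |>
      dplyr::mutate(meta_log10p = -log10(.data$p))
  }
  structure(list(meta = meta, leads = leads), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result> %d variants combined, %d meta lead(s)\n",
              nrow(x$meta), nrow(x$leads)))
  invisible(x)
}
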