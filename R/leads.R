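#' Call lead variants per chromosome
#'
#' A lead variant is the most significant variant on a chromosome (for a
#' trait) among those passing the genome-wide threshold; ties on p-value are
#' broken by the smaller position.  The conventional empirical threshold is
#' `5e-8`.
#'
#' @param records Association tibble with at least `chrom`, `pos`, `p`
#'   (optionally `trait`, `population`; leads are called within trait when a
#'   `trait` column is present).
#' @param threshold Genome-wide significance threshold on `p` (strict `<`).
#' @param trait,population Optional labels attached to the result when the
#'   input lacks those columns.
#' @return Tibble of lead variants (possibly empty), one per chromosome
#'   (and trait).
#' @export
call_lead_snps <- function(records, threshold = 5e-8, trait = NULL,
                           population = NULL) {
  check_scalar_number(threshold, "threshold", 0, 1)
  records <- as_tibble(records)
  if (!is.null(trait) && !("trait" %in% names(records))) records$trait <- trait
  if (!is.null(population) && !("population" %in% names(records))) {
    records$population <- population
  }
  keys <- intersect(c("trait", "chrom"), names(records))
  out <- records |>
    dplyr::filter(.data$p < threshold) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::arrange(.data$p, .data$pos, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  out
}

#' Merge nearby lead variants into sentinel variants
#'
#' Lead variants for correlated traits often stack within a narrow region;
#' leads on the same chromosome lying within `window_bp` of each other
#' (single linkage: a chain of sub-window gaps joins one cluster) are merged,
#' and the member with the strongest association (largest `-log10 p`,
#' position as tie-break) represents the cluster as its sentinel.
#'
#' @param leads Lead tibble from [call_lead_snps()] (any traits mixed).
#' @param window_bp Clustering distance in bp (default 1 Mb).
#' @return Tibble of sentinel variants with `cluster_size`, `cluster_start`,
#'   `cluster_end` columns.
#' @export
sentinel_merge <- function(leads, window_bp = 1e6) {
  check_scalar_number(window_bp, "window_bp", lower = 1)
  leads <- as_tibble(leads)
  if (nrow(leads) == 0) {
    return(dplyr::mutate(leads, cluster_size = integer(),
                         cluster_start = numeric(), cluster_end = numeric()))
  }
  leads |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$pos, .by_group = TRUE) |>
    dplyr::mutate(.cluster = cumsum(c(1, diff(.data$pos) > window_bp))) |>
    dplyr::group_by(.data$chrom, .data$.cluster) |>
    dplyr::mutate(cluster_size = dplyr::n(),
                  cluster_start = min(.data$pos),
                  cluster_end = max(.data$pos)) |>
    dplyr::arrange(.data$p, .data$pos, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select(-".cluster") |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Classify leads against a reference scan
#'
#' Compares each lead to the nearest same-chromosome (and same-trait, when a
#' `trait` column is present in both tables) lead of a reference analysis,
#' e.g. a chip-based scan: `novel` when no reference lead lies within
#' `novel_dist_bp` (strictly more than 1 Mb away, or none at all),
#' `enhanced` when a reference lead is nearby but the association strength
#' gained at least `enhanced_gain` units of `-log10 p`, otherwise `known`.
#'
#' @param leads Lead tibble (`chrom`, `pos`, `p`, optional `trait`).
#' @param reference_leads Reference lead tibble with the same columns.
#' @param novel_dist_bp Distance beyond which a lead is novel (default 1 Mb).
#' @param enhanced_gain Minimum `-log10 p` gain for `enhanced` (default 2).
#' @return `leads` with added `class` (`novel`/`enhanced`/`known`),
#'   `ref_pos`, `ref_p`, `ref_dist_bp`, `gain_log10p` columns.
#' @export
classify_vs_reference <- function(leads, reference_leads,
                                  novel_dist_bp = 1e6, enhanced_gain = 2) {
  leads <- as_tibble(leads)
  reference_leads <- as_tibble(reference_leads)
  by_trait <- "trait" %in% names(leads) && "trait" %in% names(reference_leads)
  classify_one <- function(chrom, pos, p, trait_val) {
    ref <- reference_leads[reference_leads$chrom == chrom, , drop = FALSE]
    if (by_trait) ref <- ref[ref$trait == trait_val, , drop = FALSE]
    if (nrow(ref) == 0) {
      return(tibble(class = "novel", ref_pos = NA_real_, ref_p = NA_real_,
                    ref_dist_bp = NA_real_, gain_log10p = NA_real_))
    }
    d <- abs(ref$pos - pos)
    j <- which.min(d)
    gain <- -log10(p) + log10(ref$p[j])
    cls <- if (d[j] > novel_dist_bp) "novel"
           else if (gain >= enhanced_gain) "enhanced"
           else "known"
    tibble(class = cls, ref_pos = ref$pos[j], ref_p = ref$p[j],
           ref_dist_bp = d[j], gain_log10p = gain)
  }
  extra <- purrr::pmap(
    list(leads$chrom, leads$pos, leads$p,
         if (by_trait) leads$trait else rep(NA, nrow(leads))),
    classify_one)
  dplyr::bind_cols(leads, dplyr::bind_rows(extra))
}
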