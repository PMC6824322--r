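# Regulatory-peak overlap of lead variants.  BED input follows the 0-based
# half-open convention and is converted to 1-based inclusive intervals on
# read; interval merging and point queries go through IRanges.

#' Read a BED file of regulatory peaks
#'
#' Parses a 3+ column BED file (column 4, when present, labels the mark,
#' e.g. `H3K27ac` / `H3K4me3`), converts the 0-based half-open intervals to
#' 1-based inclusive coordinates, and merges overlapping or abutting
#' intervals of the same mark.
#'
#' @param path BED file path.
#' @return Tibble of class `peak_set`: `chrom`, `start`, `end` (1-based
#'   inclusive), `mark`.
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("BED file not found: '%s'.", path), class = "crosspop_io")
  }
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  if (length(rows) == 0) {
    return(structure(tibble(chrom = character(), start = integer(),
                            end = integer(), mark = character()),
                     class = c("peak_set", class(tibble()))))
  }
  fields <- strsplit(lines[rows], "\t|[ ]+")
  parsed <- purrr::map2(fields, rows, function(f, ln) {
    if (length(f) < 3) {
      abort(sprintf("Malformed BED line %d: fewer than 3 fields.", ln),
            class = "crosspop_parse")
    }
    start0 <- suppressWarnings(as.numeric(f[2]))
    end0 <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start0) || is.na(end0) || start0 >= end0 || start0 < 0) {
      abort(sprintf("Malformed BED line %d: invalid interval '%s'-'%s'.",
                    ln, f[2], f[3]), class = "crosspop_parse")
    }
    tibble(chrom = f[1], start = as.integer(start0) + 1L,
           end = as.integer(end0),
           mark = if (length(f) >= 4) f[4] else "peak")
  })
  peaks <- dplyr::bind_rows(parsed)
  merged <- peaks |>
    dplyr::group_by(.data$chrom, .data$mark) |>
    dplyr::group_modify(function(d, key) {
      red <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
      tibble(start = IRanges::start(red), end = IRanges::end(red))
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chrom, .data$mark, .data$start) |>
    dplyr::select("chrom", "start", "end", "mark")
  structure(merged, class = c("peak_set", class(tibble())))
}

peaks_granges <- function(peaks, marks = NULL) {
  if (!is.null(marks)) peaks <- peaks[peaks$mark %in% marks, , drop = FALSE]
  GenomicRanges::GRanges(peaks$chrom, IRanges::IRanges(peaks$start, peaks$end),
                         mark = peaks$mark)
}

variants_granges <- function(variants) {
  variants <- as_tibble(variants)
  if (!all(c("chrom", "pos") %in% names(variants))) {
    stop_invalid("`variants` needs `chrom` and `pos` columns.")
  }
  GenomicRanges::GRanges(variants$chrom,
                         IRanges::IRanges(variants$pos, variants$pos))
}

#' Proportion of variants falling inside peaks
#'
#' A variant inside intervals of several marks counts once; interval ends
#' are inclusive after the BED conversion.
#'
#' @param variants Tibble with `chrom` and `pos` columns (non-empty).
#' @param peaks A [read_peaks()] tibble.
#' @param marks Optional subset of mark labels to consider.
#' @return One-row tibble: `n_overlap`, `n_total`, `proportion`.
#' @export
overlap_proportion <- function(variants, peaks, marks = NULL) {
  variants <- dplyr::distinct(as_tibble(variants), .data$chrom, .data$pos)
  if (nrow(variants) == 0) stop_invalid("`variants` must not be empty.")
  gr_p <- peaks_granges(peaks, marks)
  hit <- if (length(gr_p) == 0) {
    rep(FALSE, nrow(variants))
  } else {
    IRanges::overlapsAny(variants_granges(variants), gr_p)
  }
  tibble(n_overlap = sum(hit), n_total = nrow(variants),
         proportion = mean(hit))
}

#' Fold enrichment of lead variants in regulatory peaks
#'
#' Compares the fraction of lead variants inside peaks with the fraction of
#' a background variant set (typically all tested SNPs):
#' `fold = lead proportion / background proportion`, reported overall
#' (`mark = "combined"`, variants deduplicated across marks) and per mark.
#'
#' @param lead_variants,background_variants Tibbles with `chrom`, `pos`
#'   (both non-empty).
#' @param peaks A [read_peaks()] tibble.
#' @param marks Optional subset of marks (default: all marks present).
#' @return Tibble of class `enrichment_result`: `mark`, `lead_overlap`,
#'   `lead_total`, `lead_prop`, `bg_overlap`, `bg_total`, `bg_prop`,
#'   `fold`, `fold_undefined`.
#' @export
fold_enrichment <- function(lead_variants, background_variants, peaks,
                            marks = NULL) {
  marks <- marks %||% unique(peaks$mark)
  one <- function(mark_sel, label) {
    lp <- overlap_proportion(lead_variants, peaks, mark_sel)
    bp <- overlap_proportion(background_variants, peaks, mark_sel)
    undef <- bp$proportion == 0
    tibble(mark = label,
           lead_overlap = lp$n_overlap, lead_total = lp$n_total,
           lead_prop = lp$proportion,
           bg_overlap = bp$n_overlap, bg_total = bp$n_total,
           bg_prop = bp$proportion,
           fold = if (undef) NA_real_ else lp$proportion / bp$proportion,
           fold_undefined = undef)
  }
  out <- dplyr::bind_rows(
    one(marks, "combined"),
    purrr::map(marks, function(m) one(m, m)) |> dplyr::bind_rows()
  )
  structure(out, class = c("enrichment_result", class(out)))
}

#' Genes near lead variants
#'
#' Reads gene features from a GFF3 annotation and reports, for each
#' variant, the genes whose span lies within `max_dist` bp (distance 0 when
#' the variant falls inside the span), sorted by distance.
#'
#' @param variants Tibble with `chrom`, `pos`.
#' @param gff Path to a GFF3 file, or a pre-parsed tibble with `chrom`,
#'   `start`, `end`, `gene` columns.
#' @param max_dist Maximum distance in bp (default 500 kb, inclusive).
#' @return Tibble `chrom`, `pos`, `gene`, `gene_start`, `gene_end`,
#'   `distance`, sorted by variant then distance.  Variants with no gene in
#'   range are omitted; a missing-gene annotation yields an empty result
#'   with a warning.
#' @export
nearest_genes <- function(variants, gff, max_dist = 5e5) {
  variants <- as_tibble(variants)
  genes <- if (is.character(gff)) read_gff_genes(gff) else as_tibble(gff)
  empty <- tibble(chrom = character(), pos = numeric(), gene = character(),
                  gene_start = numeric(), gene_end = numeric(),
                  distance = numeric())
  if (nrow(genes) == 0) {
    warn("No gene features found in the annotation.")
    return(empty)
  }
  out <- purrr::pmap(list(variants$chrom, variants$pos), function(ch, pos) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0) return(NULL)
    d <- ifelse(pos < g$start, g$start - pos,
                ifelse(pos > g$end, pos - g$end, 0))
    sel <- d <= max_dist
    if (!any(sel)) return(NULL)
    tibble(chrom = ch, pos = pos, gene = g$gene[sel],
           gene_start = g$start[sel], gene_end = g$end[sel],
           distance = d[sel]) |>
      dplyr::arrange(.data$distance)
  }) |>
    dplyr::bind_rows()
  if (ncol(out) == 0) empty else out
}

read_gff_genes <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("GFF3 file not found: '%s'.", path), class = "crosspop_io")
  }
  g <- ape::read.gff(path)
  g <- g[g$type == "gene", , drop = FALSE]
  name <- stringr::str_match(g$attributes, "Name=([^;]+)")[, 2]
  id <- stringr::str_match(g$attributes, "ID=([^;]+)")[, 2]
  tibble(chrom = as.character(g$seqid), start = g$start, end = g$end,
         gene = dplyr::coalesce(name, id, paste0("gene", seq_len(nrow(g)))))
}
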