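# Fixture serialization: phased VCF 4.2, phenotype TSV, truth records as
# structured key-value text (YAML).  Reading goes through vcfR so the files
# interoperate with standard tooling.

#' Write a simulated population to standard file formats
#'
#' Emits a phased VCF 4.2 (pipe-separated GT), a phenotype TSV with header
#' `id<TAB>trait<TAB>sex<TAB>batch`, and, when given, the truth record as
#' YAML.  Reading the files back ([read_phased_vcf()], [read_phenotypes()],
#' [read_truth()]) reproduces the matrices exactly.
#'
#' @param pop A `phased_pop`.
#' @param phenotypes Tibble from [simulate_phenotypes()] (or `NULL`).
#' @param truth A `truth_record` (or `NULL`).
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of written paths (`vcf`, `pheno`, `truth`).
#' @export
write_fixture <- function(pop, phenotypes = NULL, truth = NULL, out_dir) {
  stopifnot(inherits(pop, "phased_pop"))
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    abort(sprintf("Cannot create output directory '%s'.", out_dir),
          class = "crosspop_io")
  }
  paths <- c(vcf = file.path(out_dir, paste0(pop$name, ".vcf")))
  write_phased_vcf(pop, paths[["vcf"]])
  if (!is.null(phenotypes)) {
    paths[["pheno"]] <- file.path(out_dir, paste0(pop$name, "_pheno.tsv"))
    utils::write.table(
      phenotypes[, c("id", "trait", "sex", "batch")],
      paths[["pheno"]], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(truth)) {
    paths[["truth"]] <- file.path(out_dir, "truth.yml")
    write_truth(truth, paths[["truth"]])
  }
  paths
}

#' Write a phased population as VCF 4.2
#'
#' @param pop A `phased_pop`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(pop, path) {
  h <- pop$haplotypes
  n <- n_ind(pop)
  gt <- matrix(paste0(h[seq(1L, 2L * n, 2L), , drop = FALSE], "|",
                      h[seq(2L, 2L * n, 2L), , drop = FALSE]),
               nrow = n)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=crosspop %s", as.character(utils::packageVersion("crosspop"))),
    sprintf("##contig=<ID=%s,length=%d>", pop$chrom, max(pop$positions) + 1L),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", pop$samples$id), collapse = "\t")
  )
  body <- paste(pop$chrom, pop$positions,
                paste0(pop$chrom, ":", pop$positions),
                "A", "G", ".", "PASS", ".", "GT",
                apply(gt, 2L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a phased VCF into a population object
#'
#' Uses vcfR to parse the file; genotypes must be phased (`|` separator) and
#' biallelic.
#'
#' @param path VCF path.
#' @param name Population label; defaults to the file stem.
#' @param samples Optional covariate tibble (`id`, `sex`, `batch`) to attach;
#'   otherwise placeholder levels are used.
#' @return A `phased_pop`.
#' @export
read_phased_vcf <- function(path, name = NULL, samples = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("VCF not found: '%s'.", path), class = "crosspop_io")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(grepl("/", gt, fixed = TRUE))) {
    abort("Unphased genotypes found ('/'); phase the VCF before analysis.",
          class = "crosspop_invalid")
  }
  ids <- colnames(gt)
  n <- length(ids)
  l <- nrow(gt)
  a1 <- matrix(as.integer(substr(gt, 1L, 1L)), nrow = l)
  a2 <- matrix(as.integer(substr(gt, 3L, 3L)), nrow = l)
  hap <- matrix(0L, nrow = 2L * n, ncol = l)
  hap[seq(1L, 2L * n, 2L), ] <- t(a1)
  hap[seq(2L, 2L * n, 2L), ] <- t(a2)
  name <- name %||% sub("\\.vcf(\\.gz)?$", "", basename(path))
  if (is.null(samples)) {
    samples <- tibble(id = ids, sex = "S1", batch = "B1")
  }
  structure(list(haplotypes = hap,
                 positions = as.integer(vcfR::getPOS(v)),
                 chrom = as.character(vcfR::getCHROM(v)[1]),
                 name = name,
                 samples = samples[match(ids, samples$id), , drop = FALSE]),
            class = "phased_pop")
}

#' Read a phenotype TSV (`id`, `trait`, `sex`, `batch`)
#'
#' @param path TSV path.
#' @return Tibble with the four columns.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Phenotype file not found: '%s'.", path), class = "crosspop_io")
  }
  out <- as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                     colClasses = c("character", "numeric",
                                                    "character", "character")))
  need <- c("id", "trait", "sex", "batch")
  if (!all(need %in% names(out))) {
    stop_invalid("Phenotype TSV must have columns id, trait, sex, batch.")
  }
  out
}

#' Serialize / deserialize a truth record
#'
#' @param truth A `truth_record`.
#' @param path File path (YAML text).
#' @return `path` (write) or the `truth_record` (read).
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "truth_record"))
  x <- unclass(truth)
  x$effect <- as.list(x$effect)
  x$h2 <- as.list(x$h2)
  x$target_frequency <- as.list(x$target_frequency)
  x$realized_frequency <- as.list(x$realized_frequency)
  x$shared <- as.list(x$shared)
  x$carriers <- lapply(x$carriers, function(d) {
    list(id = as.list(d$id), copies = as.list(d$copies))
  })
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- yaml::read_yaml(path)
  to_num <- function(v) unlist(v)
  x$effect <- to_num(x$effect)
  x$h2 <- to_num(x$h2)
  x$target_frequency <- to_num(x$target_frequency)
  x$realized_frequency <- to_num(x$realized_frequency)
  x$shared <- unlist(x$shared)
  x$carriers <- lapply(x$carriers, function(d) {
    tibble(id = unlist(d$id), copies = as.integer(unlist(d$copies)))
  })
  x$start_bp <- as.integer(x$start_bp)
  x$end_bp <- as.integer(x$end_bp)
  structure(x, class = "truth_record")
}
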