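#' Pipeline run configuration
#'
#' Collects all stage switches, paths, thresholds and seeds of the
#' end-to-end analysis into one validated list.  Defaults follow the usual
#' conventions of multi-population trait-mapping studies: genome-wide
#' significance `5e-8`, sentinel merging and novelty distance of 1 Mb,
#' 2-unit `-log10 p` gain for "enhanced", 41-SNP haplotype windows, a 0.05
#' haplotype frequency floor, and candidate genes within 500 kb.  The
#' simulated design mirrors a six-population study of unequal sizes with a
#' polygenic heritability of 0.46, one causal haplotype shared by three
#' populations and one private to a fifth.
#'
#' @param out_dir Run directory for all artifacts.
#' @param seed Integer seed (mandatory; drives every stochastic stage).
#' @param stages Character subset of
#'   `c("simulate", "gwas", "meta", "haplo", "enrich")`.
#' @param ... Overrides of any default listed below.
#' @return Object of class `run_config` (a named list).
#' @export
run_config <- function(out_dir, seed, stages = c("simulate", "gwas", "meta",
                                                 "haplo", "enrich"), ...) {
  check_scalar_number(seed, "seed")
  stages <- match.arg(stages, several.ok = TRUE)
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed), stages = stages,
    # thresholds
    significance = 5e-8, sentinel_window_bp = 1e6, novel_dist_bp = 1e6,
    enhanced_gain = 2, flank_k = 20L, min_hap_freq = 0.05,
    gene_dist_bp = 5e5, hap_alpha = 0.01,
    min_snp_call = 0.9, min_ind_call = 0.9, min_maf = 0.05,
    vc_mode = "null_reuse", min_populations = 1L,
    # simulated study design
    pop_names = c("PopA", "PopB", "PopC", "PopD", "PopE", "PopF"),
    pop_sizes = c(591L, 296L, 608L, 305L, 331L, 315L),
    l_sites = 1500L, n_pool = 150L, drift = 40L,
    recomb_rate = 0.003, mutation_density = 0.9,
    h2 = 0.46, sigma_e2 = 1,
    shared_center_frac = 0.3, private_center_frac = 0.7,
    window_halfwidth_sites = 3L,
    shared_pops = c("PopA", "PopB", "PopC"), private_pop = "PopE",
    shared_freq = 0.3, private_freq = 0.3,
    shared_effect = -0.9, private_effect = 1.2,
    # external inputs (used when `simulate` is not among the stages)
    vcf_paths = NULL, pheno_paths = NULL,
    peaks_bed = NULL, genes_gff = NULL, reference_leads = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop_invalid(paste0("Unknown config field(s): ",
                        paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  for (f in c("significance", "sentinel_window_bp", "novel_dist_bp",
              "enhanced_gain", "flank_k", "min_hap_freq", "gene_dist_bp")) {
    if (cfg[[f]] <= 0) stop_invalid(sprintf("`%s` must be positive.", f))
  }
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration
#'
#' Round-trips the configuration through flat YAML so a run can be archived
#' and replayed.
#'
#' @param config A [run_config()].
#' @param path YAML path.
#' @return `path` (write) / the `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, c(cfg[c("out_dir", "seed", "stages")],
                        cfg[setdiff(names(cfg), c("out_dir", "seed", "stages"))]))
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

read_tsv_ <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                              colClasses = NA, stringsAsFactors = FALSE,
                              check.names = FALSE,
                              comment.char = ""))
}

log_stage <- function(stage, msg) {
  inform(sprintf("[%s] %s", stage, msg))
}

#' Run the full multi-population analysis pipeline
#'
#' Executes the selected stages in order: `simulate` (build the
#' multi-population fixture with planted causal haplotypes and write VCF /
#' phenotype / truth / synthetic annotation files), `gwas` (per-population
#' QC, residualization, REML and mixed-model scan), `meta` (allele
#' harmonisation and sample-size weighted z-score combination with meta
#' lead calling), `haplo` (41-SNP window haplotype effects at the top lead,
#' shared-segment detection, sharing classification and a neighbor-joining
#' tree), and `enrich` (peak-overlap fold enrichment of sentinel variants
#' and candidate genes within 500 kb).  Every artifact lands in
#' `config$out_dir` together with a manifest (package version, seed, config
#' and its hash).  Re-running with the same configuration reproduces the
#' association tables bit-identically.
#'
#' @param config A [run_config()].
#' @return The run directory path, invisibly; artifacts on disk.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  state <- list()

  if ("simulate" %in% stages) {
    state <- stage_simulate(config)
  } else if (any(c("gwas", "meta", "haplo", "enrich") %in% stages)) {
    state <- load_external_inputs(config)
  }
  if ("gwas" %in% stages) state <- stage_gwas(config, state)
  if ("meta" %in% stages) state <- stage_meta(config, state)
  if ("haplo" %in% stages) state <- stage_haplo(config, state)
  if ("enrich" %in% stages) state <- stage_enrich(config, state)

  manifest <- list(
    package = "crosspop",
    version = as.character(utils::packageVersion("crosspop")),
    r_version = as.character(getRversion()),
    created = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    stages = stages,
    config_hash = rlang::hash(unclass(config)),
    config = unclass(config)
  )
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yml"),
                   precision = 15L)
  invisible(config$out_dir)
}

stage_simulate <- function(config) {
  log_stage("simulate", sprintf("panel of %d sites, %d populations",
                                config$l_sites, length(config$pop_names)))
  panel <- simulate_panel(config$l_sites, config$n_pool, config$recomb_rate,
                          config$mutation_density, seed = config$seed)
  pops <- purrr::imap(setNames(config$pop_sizes, config$pop_names),
                      function(nsize, nm) {
    sample_population(panel, nm, nsize, drift = config$drift,
                      seed = config$seed + 101L * match(nm, config$pop_names))
  })

  hw <- config$window_halfwidth_sites
  site_window <- function(frac) {
    c0 <- max(hw + 1L, min(config$l_sites - hw,
                           as.integer(round(frac * config$l_sites))))
    panel$positions[c(c0 - hw, c0 + hw)]
  }
  sw <- site_window(config$shared_center_frac)
  pw <- site_window(config$private_center_frac)
  shared_str <- distinct_window_string(panel, sw[1], sw[2])
  planted <- plant_causal_haplotype(
    pops, sw[1], sw[2], shared_str,
    frequency = setNames(rep(config$shared_freq, length(config$shared_pops)),
                         config$shared_pops),
    effect = config$shared_effect, h2 = config$h2,
    sigma_e2 = config$sigma_e2, seed = config$seed + 7L)
  pops <- planted$pops
  truth_shared <- planted$truth
  private_str <- distinct_window_string(panel, pw[1], pw[2])
  planted2 <- plant_causal_haplotype(
    pops, pw[1], pw[2], private_str,
    frequency = setNames(config$private_freq, config$private_pop),
    effect = config$private_effect, h2 = config$h2,
    sigma_e2 = config$sigma_e2, seed = config$seed + 13L)
  pops <- planted2$pops
  truth_private <- planted2$truth

  data_dir <- file.path(config$out_dir, "data")
  genos <- grms <- phenos <- list()
  for (nm in names(pops)) {
    geno <- as_geno_matrix(pops[[nm]])
    grm <- compute_grm(geno)
    ph1 <- simulate_phenotypes(pops[[nm]], truth_shared, grm = grm,
                               seed = config$seed + 23L + match(nm, names(pops)))
    # add the private causal contribution on top of the shared simulation
    car <- truth_private$carriers[[nm]]
    copies2 <- car$copies[match(pops[[nm]]$samples$id, car$id)]
    a2 <- unname(truth_private$effect[nm]); if (is.na(a2)) a2 <- 0
    ph <- dplyr::mutate(ph1, trait = .data$trait + copies2 * a2)
    write_fixture(pops[[nm]], ph, out_dir = data_dir)
    genos[[nm]] <- geno; grms[[nm]] <- grm; phenos[[nm]] <- ph
  }
  write_truth(truth_shared, file.path(data_dir, "truth_shared.yml"))
  write_truth(truth_private, file.path(data_dir, "truth_private.yml"))
  write_synthetic_annotation(config, panel, truth_shared, truth_private)
  log_stage("simulate", sprintf("planted shared %d-%d and private %d-%d",
                                truth_shared$start_bp, truth_shared$end_bp,
                                truth_private$start_bp, truth_private$end_bp))
  list(pops = pops, genos = genos, grms = grms, phenos = phenos,
       truths = list(shared = truth_shared, private = truth_private))
}

# Peaks covering the planted windows plus seeded random background peaks,
# and a small gene annotation; both clearly labelled synthetic.
write_synthetic_annotation <- function(config, panel, truth_shared,
                                       truth_private) {
  data_dir <- file.path(config$out_dir, "data")
  span <- max(panel$positions)
  with_seed(config$seed + 31L, {
    starts <- sort(sample.int(span, 20L))
    widths <- sample(200:800, 20L, replace = TRUE)
    bed <- tibble(
      chrom = panel$chrom,
      start0 = c(truth_shared$start_bp - 1L, truth_private$start_bp - 1L,
                 starts - 1L),
      end = c(truth_shared$end_bp, truth_private$end_bp, starts + widths),
      mark = c("H3K27ac", "H3K4me3",
               sample(c("H3K27ac", "H3K4me3"), 20L, replace = TRUE, c(0.8, 0.2)))
    )
    writeLines(paste(bed$chrom, bed$start0, bed$end, bed$mark, sep = "\t"),
               file.path(data_dir, "synthetic_peaks.bed"))
    gstart <- c(truth_shared$end_bp + 150L, truth_private$end_bp + 150L,
                sort(sample.int(span, 8L)))
    gend <- gstart + sample(500:2000, length(gstart), replace = TRUE)
    gff <- c("##gff-version 3",
             sprintf("%s\tcrosspop\tgene\t%d\t%d\t.\t+\t.\tID=gene%02d;Name=SYNG%02d",
                     panel$chrom, gstart, gend, seq_along(gstart),
                     seq_along(gstart)))
    writeLines(gff, file.path(data_dir, "synthetic_genes.gff3"))
  })
  invisible(NULL)
}

load_external_inputs <- function(config) {
  if (is.null(config$vcf_paths) || is.null(config$pheno_paths)) {
    stop_invalid("Without the `simulate` stage, `vcf_paths` and `pheno_paths` must be set.")
  }
  pops <- genos <- grms <- phenos <- list()
  for (nm in names(config$vcf_paths)) {
    ppath <- config$pheno_paths[[nm]]
    if (!file.exists(ppath)) {
      abort(sprintf("Phenotype file not found: '%s'.", ppath),
            class = "crosspop_io")
    }
    ph <- read_phenotypes(ppath)
    pop <- read_phased_vcf(config$vcf_paths[[nm]], name = nm,
                           samples = ph[, c("id", "sex", "batch")])
    pops[[nm]] <- pop
    genos[[nm]] <- as_geno_matrix(pop)
    grms[[nm]] <- compute_grm(genos[[nm]])
    phenos[[nm]] <- ph
  }
  list(pops = pops, genos = genos, grms = grms, phenos = phenos)
}

stage_gwas <- function(config, state) {
  scans <- leads <- vcs <- resids <- list()
  for (nm in names(state$genos)) {
    log_stage("gwas", nm)
    geno <- qc_filter(state$genos[[nm]], config$min_snp_call,
                      config$min_ind_call, config$min_maf)
    ph <- residualize(state$phenos[[nm]])
    y <- ph$resid
    grm <- compute_grm(geno)
    vc <- reml_fit(y, grm)
    scan <- lmm_scan(y, geno, G = grm, vc = vc, vc_mode = config$vc_mode,
                     trait = "trait", population = nm)
    ld <- call_lead_snps(scan, threshold = config$significance)
    if (nrow(ld) > 0) {
      ld$var_explained <- vapply(seq_len(nrow(ld)), function(i) {
        j <- which(geno$info$pos == ld$pos[i] & geno$info$chrom == ld$chrom[i])
        variance_explained_residual(y, geno$dosage[, j[1]])
      }, numeric(1))
    }
    write_tsv(scan, file.path(config$out_dir, sprintf("assoc_%s.tsv", nm)))
    scans[[nm]] <- scan; leads[[nm]] <- ld; vcs[[nm]] <- vc
    resids[[nm]] <- y
    state$grms[[nm]] <- grm
    state$genos_qc[[nm]] <- geno
  }
  all_leads <- dplyr::bind_rows(leads)
  if (!is.null(config$reference_leads)) {
    ref <- if (is.character(config$reference_leads)) {
      read_tsv_(config$reference_leads)
    } else as_tibble(config$reference_leads)
    all_leads <- classify_vs_reference(all_leads, ref,
                                       config$novel_dist_bp,
                                       config$enhanced_gain)
  }
  write_tsv(all_leads, file.path(config$out_dir, "leads.tsv"))
  sentinels <- sentinel_merge(all_leads, config$sentinel_window_bp)
  write_tsv(sentinels, file.path(config$out_dir, "sentinels.tsv"))
  vc_tab <- purrr::imap(vcs, function(v, nm) {
    dplyr::mutate(glance(v), population = nm)
  }) |> dplyr::bind_rows()
  write_tsv(vc_tab, file.path(config$out_dir, "variance_components.tsv"))
  c(state, list(scans = scans, leads = all_leads, sentinels = sentinels,
                vcs = vcs, resids = resids))
}

stage_meta <- function(config, state) {
  if (is.null(state$scans)) stop_invalid("`meta` requires the `gwas` stage outputs.")
  log_stage("meta", sprintf("%d populations", length(state$scans)))
  mr <- meta_scan(state$scans, threshold = config$significance,
                  min_populations = config$min_populations)
  write_tsv(mr$meta, file.path(config$out_dir, "meta.tsv"))
  write_tsv(mr$leads, file.path(config$out_dir, "meta_leads.tsv"))
  c(state, list(meta = mr))
}

stage_haplo <- function(config, state) {
  if (is.null(state$scans)) stop_invalid("`haplo` requires the `gwas` stage outputs.")
  focal <- if (!is.null(state$meta) && nrow(state$meta$leads) > 0) {
    state$meta$leads
  } else if (nrow(state$leads %||% tibble()) > 0) {
    state$leads
  } else {
    log_stage("haplo", "no lead variants; skipping")
    return(state)
  }
  focal <- dplyr::arrange(focal, .data$p)[1, ]
  log_stage("haplo", sprintf("window at %s:%s", focal$chrom, focal$pos))

  effects <- list(); freqs <- list(); windows <- list()
  for (nm in names(state$pops)) {
    pop <- state$pops[[nm]]
    if (!(focal$pos %in% pop$positions)) next
    hset <- extract_window(pop, focal$pos, k = config$flank_k)
    inc <- tryCatch(build_incidence(hset, min_freq = config$min_hap_freq),
                    crosspop_invalid = function(e) NULL)
    if (is.null(inc)) {
      warn(sprintf("No haplotype above the frequency floor in '%s'; skipped.", nm))
      next
    }
    eff <- estimate_haplotype_effects(state$resids[[nm]], inc,
                                      state$vcs[[nm]], state$grms[[nm]])
    eff <- dplyr::left_join(eff, hset$haplotypes[, c("haplotype", "string")],
                            by = "haplotype")
    effects[[nm]] <- eff
    freqs[[nm]] <- dplyr::mutate(hset$haplotypes, population = nm)
    windows[[nm]] <- hset
  }
  eff_all <- dplyr::bind_rows(effects)
  write_tsv(dplyr::select(eff_all, -"string"),
            file.path(config$out_dir, "haplotype_effects.tsv"))

  # haplotypes significant at hap_alpha with a common effect sign feed the
  # shared-segment search
  sig <- dplyr::filter(eff_all, !is.na(.data$p), .data$p < config$hap_alpha,
                       !is.na(.data$string))
  seg <- tibble(chrom = character(), start_bp = numeric(),
                end_bp = numeric(), n_snps = integer(), length_bp = numeric())
  if (nrow(sig) > 0) {
    dominant_sign <- sign(sig$beta[which.min(sig$p)])
    sel <- dplyr::filter(sig, sign(.data$beta) == dominant_sign)
    if (nrow(sel) > 0) {
      seg <- shared_segment(sel$string, windows[[1]]$positions,
                            chrom = focal$chrom)
    }
  }
  write_tsv(seg, file.path(config$out_dir, "shared_segment.tsv"))

  freq_tab <- dplyr::bind_rows(freqs) |>
    dplyr::select("population", "haplotype", "string", "freq")
  # sharing is a property of the allele string, compared across populations
  by_string <- freq_tab |>
    dplyr::rename(hap_label = "haplotype") |>
    dplyr::rename(haplotype = "string")
  sharing <- classify_sharing(by_string, presence_freq = config$min_hap_freq)
  write_tsv(sharing, file.path(config$out_dir, "haplotype_sharing.tsv"))

  major <- dplyr::filter(freq_tab, .data$freq > config$min_hap_freq)
  if (nrow(major) >= 2) {
    D <- hamming_distance_matrix(major$string,
                                 paste0(major$population, "-", major$haplotype))
    tree <- neighbor_joining(D)
    writeLines(tree$newick, file.path(config$out_dir, "haplotypes.nwk"))
  }
  c(state, list(hap_effects = eff_all, shared_seg = seg, sharing = sharing))
}

stage_enrich <- function(config, state) {
  if (is.null(state$scans)) stop_invalid("`enrich` requires the `gwas` stage outputs.")
  bed <- config$peaks_bed %||%
    file.path(config$out_dir, "data", "synthetic_peaks.bed")
  gff <- config$genes_gff %||%
    file.path(config$out_dir, "data", "synthetic_genes.gff3")
  leads <- dplyr::bind_rows(
    state$sentinels %||% tibble(),
    if (!is.null(state$meta)) state$meta$leads else tibble()
  ) |> dplyr::distinct(.data$chrom, .data$pos, .keep_all = TRUE)
  if (nrow(leads) == 0) {
    log_stage("enrich", "no lead variants; skipping")
    return(state)
  }
  background <- dplyr::bind_rows(state$scans) |>
    dplyr::distinct(.data$chrom, .data$pos)
  peaks <- read_peaks(bed)
  enr <- fold_enrichment(leads, background, peaks)
  write_tsv(enr, file.path(config$out_dir, "enrichment.tsv"))
  genes <- nearest_genes(leads, gff, max_dist = config$gene_dist_bp)
  write_tsv(genes, file.path(config$out_dir, "candidate_genes.tsv"))
  log_stage("enrich", sprintf("combined fold = %.2f", enr$fold[1]))
  c(state, list(enrichment = enr, genes = genes))
}

#' Summarize a completed pipeline run
#'
#' Builds one row per sentinel (and meta lead) from the artifacts in a run
#' directory: position, trait, population (`META` for meta-analysis leads),
#' p-value, minor-allele frequency, variance explained, classification
#' against the reference scan when one was supplied, and nearby candidate
#' genes.  An incomplete run yields the rows that can be built, with a
#' warning.
#'
#' @param run_dir Directory written by [run_full_pipeline()].
#' @return A tibble, empty (with the documented columns) when the run found
#'   no leads.
#' @export
summarize_run <- function(run_dir) {
  empty <- tibble(variant = character(), trait = character(),
                  population = character(), p = numeric(), maf = numeric(),
                  var_explained = numeric(), class = character(),
                  candidate_genes = character())
  f_sent <- file.path(run_dir, "sentinels.tsv")
  f_meta <- file.path(run_dir, "meta_leads.tsv")
  f_genes <- file.path(run_dir, "candidate_genes.tsv")
  if (!file.exists(f_sent)) {
    warn("Run is incomplete: no sentinels.tsv; returning what exists.")
    return(empty)
  }
  sent <- read_tsv_(f_sent)
  rows <- list()
  if (nrow(sent) > 0) {
    rows$single <- tibble(
      chrom = as.character(sent$chrom), pos = sent$pos,
      trait = if ("trait" %in% names(sent)) sent$trait else NA_character_,
      population = sent$population,
      p = sent$p, maf = sent$maf,
      var_explained = if ("var_explained" %in% names(sent))
        sent$var_explained else NA_real_,
      class = if ("class" %in% names(sent)) sent$class else NA_character_
    )
  }
  if (file.exists(f_meta)) {
    meta <- read_tsv_(f_meta)
    if (nrow(meta) > 0) {
      rows$meta <- tibble(
        chrom = as.character(meta$chrom), pos = meta$pos,
        trait = "trait", population = "META", p = meta$p,
        maf = NA_real_, var_explained = NA_real_, class = NA_character_)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (is.null(out) || nrow(out) == 0) return(empty)
  genes <- if (file.exists(f_genes)) read_tsv_(f_genes) else NULL
  gene_str <- function(ch, pos) {
    if (is.null(genes) || nrow(genes) == 0) return(NA_character_)
    g <- genes[genes$chrom == ch & genes$pos == pos, , drop = FALSE]
    if (nrow(g) == 0) NA_character_ else paste(g$gene, collapse = ",")
  }
  out |>
    dplyr::mutate(variant = paste0(.data$chrom, ":", .data$pos),
                  candidate_genes = purrr::map2_chr(.data$chrom, .data$pos,
                                                    gene_str)) |>
    dplyr::select("variant", "trait", "population", "p", "maf",
                  "var_explained", "class", "candidate_genes")
}
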