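write_bed <- function(lines) {
  path <- withr::local_tempfile(fileext = ".bed",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("BED peaks are converted to 1-based inclusive and merged per mark", {
  p <- read_peaks(write_bed("chr1\t100\t200\tH3K27ac"))
  expect_equal(p$start, 101L)
  expect_equal(p$end, 200L)

  # abutting intervals of one mark merge; different marks stay apart
  p2 <- read_peaks(write_bed(c("chr1\t100\t200\tH3K27ac",
                               "chr1\t200\t300\tH3K27ac",
                               "chr1\t400\t500\tH3K4me3")))
  k27 <- p2[p2$mark == "H3K27ac", ]
  expect_equal(nrow(k27), 1L)
  expect_equal(c(k27$start, k27$end), c(101L, 300L))
  expect_equal(nrow(p2), 2L)

  expect_equal(nrow(read_peaks(write_bed(character()))), 0L)
  expect_error(read_peaks(write_bed("chr1\t100")), class = "crosspop_parse")
  expect_error(read_peaks(write_bed(c("chr1\t100\t200", "chr1\t500\t400"))),
               class = "crosspop_parse")
})

test_that("overlap proportions match the quadratic point-in-interval oracle", {
  v_in <- tibble::tibble(chrom = "chr1", pos = c(101L, 150L, 200L))
  peaks <- read_peaks(write_bed("chr1\t100\t200\tH3K27ac"))
  expect_equal(overlap_proportion(v_in, peaks)$proportion, 1)
  v_out <- tibble::tibble(chrom = "chr1", pos = c(50L, 250L))
  expect_equal(overlap_proportion(v_out, peaks)$proportion, 0)
  # boundary: position 100 (0-based start) is outside, 101 is inside
  expect_equal(overlap_proportion(tibble::tibble(chrom = "chr1", pos = 100L),
                                  peaks)$proportion, 0)
  expect_error(overlap_proportion(v_in[0, ], peaks),
               class = "crosspop_invalid")

  set.seed(90)
  starts <- sort(sample.int(99000, 200))
  ends <- starts + 1L + sample.int(400, 200, replace = TRUE)
  bed <- write_bed(sprintf("chr2\t%d\t%d\tmark", starts, ends))
  pk <- read_peaks(bed)
  pos <- sample.int(1e5, 1000)
  got <- overlap_proportion(tibble::tibble(chrom = "chr2", pos = pos), pk)
  want <- overlap_oracle(pos, starts + 1, ends)
  expect_equal(got$n_overlap, sum(want))
  expect_equal(got$proportion, mean(want))

  # splitting an interval into abutting pieces does not change overlaps
  mids <- starts + pmax(1L, (ends - starts) %/% 2L)
  split_bed <- write_bed(c(
    sprintf("chr2\t%d\t%d\tmark", starts, mids),
    sprintf("chr2\t%d\t%d\tmark", mids, ends)))
  pk_split <- read_peaks(split_bed)
  got_split <- overlap_proportion(tibble::tibble(chrom = "chr2", pos = pos),
                                  pk_split)
  expect_equal(got_split$proportion, got$proportion)
})

test_that("fold enrichment follows the ratio of overlap proportions", {
  # constructed counts: 10 of 50 leads vs 20 of 500 background -> fold 5
  peaks <- read_peaks(write_bed("chr1\t1000\t2000\tH3K27ac"))
  leads <- tibble::tibble(chrom = "chr1",
                          pos = c(seq(1001L, by = 10L, length.out = 10),
                                  seq(100000L, by = 10L, length.out = 40)))
  background <- tibble::tibble(chrom = "chr1",
                               pos = c(seq(1201L, by = 10L, length.out = 20),
                                       seq(200000L, by = 10L, length.out = 480)))
  fe <- fold_enrichment(leads, background, peaks)
  comb <- fe[fe$mark == "combined", ]
  expect_equal(comb$lead_prop, 0.2)
  expect_equal(comb$bg_prop, 0.04)
  expect_equal(comb$fold, 5)

  # lead set equal to background: fold 1
  fe1 <- fold_enrichment(background, background, peaks)
  expect_equal(fe1$fold[fe1$mark == "combined"], 1)

  # zero background overlap: undefined fold, flagged
  far <- tibble::tibble(chrom = "chr1", pos = seq(5e6, by = 10, length.out = 10))
  fe0 <- fold_enrichment(leads, far, peaks)
  expect_true(fe0$fold_undefined[fe0$mark == "combined"])
  expect_true(is.na(fe0$fold[fe0$mark == "combined"]))

  # per-mark breakdown: a variant inside peaks of two marks counts once
  pk2 <- read_peaks(write_bed(c("chr1\t1000\t2000\tH3K27ac",
                                "chr1\t1000\t2000\tH3K4me3")))
  v <- tibble::tibble(chrom = "chr1", pos = c(1500L, 99999L))
  fe2 <- fold_enrichment(v, v, pk2)
  expect_equal(fe2$lead_overlap[fe2$mark == "combined"], 1L)
  expect_equal(nrow(fe2), 3L)
})

test_that("nearby genes are reported within the distance bound, sorted", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1000\t2000\t.\t+\t.\tID=g1;Name=ALPHA",
    "chr1\tsrc\tgene\t600000\t601000\t.\t-\t.\tID=g2;Name=BETA",
    "chr1\tsrc\tgene\t5000000\t5001000\t.\t+\t.\tID=g3;Name=GAMMA",
    "chr1\tsrc\texon\t1000\t1100\t.\t+\t.\tID=e1"), gff)

  # variant inside a gene: distance 0, listed first
  v <- tibble::tibble(chrom = "chr1", pos = 1500L)
  g <- nearest_genes(v, gff, max_dist = 5e5)
  expect_equal(g$gene[1], "ALPHA")
  expect_equal(g$distance[1], 0)

  # boundary: gene ending exactly 500,000 bp away is included; 500,001 is not
  v2 <- tibble::tibble(chrom = "chr1", pos = 601000L + 500000L)
  expect_true("BETA" %in% nearest_genes(v2, gff, max_dist = 5e5)$gene)
  v3 <- tibble::tibble(chrom = "chr1", pos = 601000L + 500001L)
  expect_false("BETA" %in% nearest_genes(v3, gff, max_dist = 5e5)$gene)

  # brute-force distance oracle on a constructed annotation
  genes <- tibble::tibble(chrom = "chr1",
                          start = c(100, 5000, 20000, 50000, 90000),
                          end = c(200, 6000, 21000, 51000, 91000),
                          gene = paste0("g", 1:5))
  set.seed(91)
  for (pos in sample.int(1e5, 20)) {
    got <- nearest_genes(tibble::tibble(chrom = "chr1", pos = pos), genes,
                         max_dist = 1e4)
    d <- ifelse(pos < genes$start, genes$start - pos,
                ifelse(pos > genes$end, pos - genes$end, 0))
    want <- genes$gene[d <= 1e4][order(d[d <= 1e4])]
    expect_equal(got$gene, want)
  }
})
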