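test_that("parse_locus handles dot notation, commas, and degenerate spans", {
  r <- parse_locus("chr05:9901255.9916669")
  expect_equal(r$chrom, "chr05")
  expect_equal(r$start, 9901255)
  expect_equal(r$end, 9916669)
  expect_equal(r$span_bp, 15414)

  r2 <- parse_locus("chr03:46,329605.46336003")
  expect_equal(r2$start, 46329605)
  expect_equal(r2$span_bp, 6398)

  expect_equal(parse_locus("chr1:100.100")$span_bp, 0)

  expect_error(parse_locus("chr1-100.200"), "malformed")
  expect_error(parse_locus("chr1:200.100"), "exceeds")
})

test_that("format_locus round-trips modulo commas and whitespace", {
  for (s in c("chr05:9901255.9916669", "chr1:100.100", "scaffold_2:5.9")) {
    expect_equal(format_locus(parse_locus(s)), s)
  }
  expect_equal(format_locus(parse_locus("chr03:46,329605.46336003")),
               "chr03:46329605.46336003")
})

test_that("packaged gene models reproduce the printed exon bookkeeping", {
  gm <- load_gene_models()
  gwd <- gm$GWD1
  dmr <- gm$`DMR6-1`

  expect_equal(nrow(gwd$exons), 33)
  expect_equal(gwd$region$span_bp, 15414)
  ex24 <- gwd$exons[gwd$exons$exon_rank == 24, ]
  expect_equal(c(ex24$start, ex24$end), c(9911740, 9911953))

  expect_equal(nrow(dmr$exons), 4)
  expect_equal(dmr$region$span_bp, 6398)
  # minus-strand gene: exon 1 has the highest coordinates
  ex1 <- dmr$exons[dmr$exons$exon_rank == 1, ]
  expect_equal(c(ex1$start, ex1$end), c(46335699, 46335896))

  # introns exist: the locus span exceeds the summed exon lengths
  expect_gt(gwd$region$span_bp - sum(gwd$exons$width), 0)
  expect_gt(dmr$region$span_bp - sum(dmr$exons$width), 0)
})

test_that("build_gene_model validates its exon list", {
  reg <- genomic_region("chr1", 100, 1000)
  expect_error(build_gene_model("g", reg, data.frame(start = numeric(),
                                                     end = numeric())),
               "empty")
  expect_error(
    build_gene_model("g", reg, data.frame(start = c(150, 200),
                                          end = c(250, 300))),
    "overlaps")
  expect_error(
    build_gene_model("g", reg, data.frame(start = 50, end = 80)),
    "outside")
  m <- build_gene_model("g", reg, c("200.300", "400.500"), strand = "-")
  expect_equal(m$exons$exon_rank, c(2, 1))
})

test_that("gene models export to GRanges/GFF3", {
  gm <- load_gene_models()$`DMR6-1`
  gr <- gene_model_granges(gm)
  expect_equal(length(gr), 5L)  # gene + 4 exons
  expect_equal(as.character(GenomicRanges::strand(gr)[1]), "-")
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gene_model_gff3(gm, path)
  expect_true(any(grepl("\texon\t", readLines(path))))
})

test_that("call_variants is empty for identical haplotypes and collapses gap runs", {
  seqs <- rep(strrep("ACGT", 25), 4)
  as <- allele_set("r", seqs, strrep("ACGT", 25))
  expect_equal(nrow(call_variants(as)), 0L)

  # one haplotype gapped at columns 40-42: a single 3 bp deletion record
  h <- seqs
  substr(h[2], 40, 42) <- "---"
  v <- call_variants(allele_set("r", h, strrep("ACGT", 25)))
  expect_equal(nrow(v), 1L)
  expect_equal(v$kind, "deletion")
  expect_equal(v$position, 40)
  expect_equal(v$length, 3)
  expect_equal(v$allele_id, "allele2")
})

test_that("call_variants records SNP columns with per-allele states", {
  ref <- strrep("A", 30)
  h <- c(ref, ref, ref, ref)
  substr(h[1], 5, 5) <- "G"
  substr(h[3], 5, 5) <- "T"   # same column, different haplotype: one record
  substr(h[2], 12, 12) <- "C"
  v <- call_variants(allele_set("r", h, ref))
  expect_equal(nrow(v), 2L)
  snp5 <- v[v$position == 5, ]
  expect_equal(snp5$kind, "SNP")
  expect_equal(snp5$allele_states, "G,A,T,A")
  # insertions relative to the reference are their own per-haplotype events
  ref_g <- paste0(strrep("A", 10), "--", strrep("A", 10))
  h2 <- c(paste0(strrep("A", 10), "GG", strrep("A", 10)),
          paste0(strrep("A", 10), "--", strrep("A", 10)))
  v2 <- call_variants(allele_set("r", h2, ref_g, ploidy = 2))
  expect_equal(v2$kind, "insertion")
  expect_equal(c(v2$position, v2$length), c(11, 2))
})

test_that("call_variants recovers generator truth exactly and ignores haplotype order", {
  for (seed in c(11, 202, 3003)) {
    cfg <- simulation_config(seed = seed, snp_rate = 0.02, indel_rate = 0.004)
    sim <- simulate_haplotypes(cfg)
    called <- call_variants(sim$alleles)
    expect_identical(variant_key(called), variant_key(sim$truth))

    # reordering haplotypes must not change the number of records
    perm <- rev(seq_len(sim$alleles$ploidy))
    reordered <- allele_set(sim$alleles$region_id,
                            sim$alleles$haplotypes[perm],
                            sim$alleles$reference)
    expect_equal(nrow(call_variants(reordered)), nrow(called))
  }
})

test_that("allele FASTA round-trips through Biostrings", {
  cfg <- simulation_config(seed = 77)
  sim <- simulate_haplotypes(cfg)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_allele_fasta(sim$alleles, path)
  back <- read_allele_fasta(path)
  expect_equal(back$haplotypes, sim$alleles$haplotypes)
  expect_equal(back$reference, sim$alleles$reference)
  expect_equal(back$region_id, sim$alleles$region_id)
})

test_that("prevalence_fold mirrors the fold-change arithmetic", {
  p <- prevalence_fold(list(snp_count = 14, indel_count = 0),
                       region_len = 1000, reference_rate = 0.005)
  expect_equal(p$snp_rate, 0.014)
  expect_equal(p$fold_vs_reference, 2.8)

  expect_equal(prevalence_fold(list(snp_count = 5), 1000, 0.005)$fold_vs_reference, 1)
  expect_equal(prevalence_fold(list(snp_count = 0), 1000, 0.005)$fold_vs_reference, 0)
  expect_identical(prevalence_fold(list(snp_count = 3), 1000, 0)$fold_vs_reference, Inf)
  expect_error(prevalence_fold(list(snp_count = 3), 0, 0.005), "region_len")
})
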