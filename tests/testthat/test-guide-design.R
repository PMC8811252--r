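test_that("scan_pam_sites handles constructed and degenerate sequences", {
  s <- scan_pam_sites("ACGTACGTACGTACGTACGTAGG", strand_mode = "plus")
  expect_equal(nrow(s), 1L)
  expect_equal(s$protospacer, "ACGTACGTACGTACGTACGT")
  expect_equal(s$pam, "AGG")
  expect_equal(s$proto_start, 1)

  expect_equal(nrow(scan_pam_sites(strrep("A", 500))), 0L)
  expect_equal(nrow(scan_pam_sites("ACGTACGTACGTACGTACGTGG")), 0L)  # 22 nt
  expect_error(scan_pam_sites("ACG-TT"), "gapless")
})

test_that("scan_pam_sites equals a brute-force scan on random sequences", {
  set.seed(401)
  lens <- c(rep(60, 800), rep(200, 195), rep(500, 5))
  for (n in lens) {
    seq <- random_dna(n)
    got <- scan_pam_sites(seq)
    want <- oracle_pam_scan(seq)
    expect_identical(site_key(got), site_key(want))
  }
  # every reported protospacer/PAM is consistent with the sequence
  seq <- random_dna(300)
  got <- scan_pam_sites(seq)
  for (i in seq_len(nrow(got))) {
    sub <- substr(seq, min(got$proto_start[i], got$pam_start[i]),
                  max(got$pam_end[i], got$proto_end[i]))
    if (got$strand[i] == "-") sub <- revcomp(sub)
    expect_equal(sub, paste0(got$protospacer[i], got$pam[i]))
    expect_match(got$pam[i], "^.GG$")
    expect_equal(nchar(got$protospacer[i]), 20L)
  }
})

test_that("cut positions follow the blunt-cut convention on both strands", {
  plus <- tibble::tibble(strand = "+", pam_start = 121, pam_end = 123)
  expect_equal(cut_site(plus), 117)
  minus <- tibble::tibble(strand = "-", pam_start = 78, pam_end = 80)
  expect_equal(cut_site(minus), 83)
  expect_equal(dual_cut_deletion_size(117, 217), 100)

  # scanned sites carry the same convention
  s <- scan_pam_sites("ACGTACGTACGTACGTACGTAGG", strand_mode = "plus")
  expect_equal(s$cut_position, cut_site(s))
  expect_equal(s$cut_position, 17)
})

test_that("allele-consensus flags match a brute-force overlap check and are monotone", {
  seq <- {set.seed(77); random_dna(400)}
  sites <- scan_pam_sites(seq)

  no_var <- tibble::tibble(position = numeric(), kind = character(),
                           length = numeric())
  f0 <- filter_allele_consensus(sites, no_var)
  expect_true(all(f0$allele_consensus))
  expect_false(any(f0$variant_in_seed))

  # SNP on a PAM base: consensus lost and the seed flag raised
  one <- sites[1, ]
  pam_var <- tibble::tibble(position = one$pam_end, kind = "SNP", length = 1)
  f1 <- filter_allele_consensus(one, pam_var)
  expect_false(f1$allele_consensus)
  expect_true(f1$variant_in_seed)

  set.seed(88)
  vars <- tibble::tibble(position = sort(sample(400, 20)),
                         kind = sample(c("SNP", "deletion"), 20, TRUE),
                         length = sample(1:3, 20, TRUE))
  f <- filter_allele_consensus(sites, vars)
  blocked <- variant_positions(vars)
  for (i in seq_len(nrow(f))) {
    fp <- min(f$proto_start[i], f$pam_start[i]):max(f$proto_end[i], f$pam_end[i])
    expect_equal(f$allele_consensus[i], !any(blocked %in% fp))
    expect_setequal(f$overlapping_variants[[i]], intersect(blocked, fp))
  }

  # monotone: adding variants can only clear flags, never set them
  more <- rbind(vars, tibble::tibble(position = c(10, 111, 333),
                                     kind = "SNP", length = 1))
  f2 <- filter_allele_consensus(sites, more)
  expect_true(all(f$allele_consensus | !f2$allele_consensus))
})

test_that("design_primers emits only pairs that pass an exhaustive checker", {
  set.seed(55)
  ref <- random_dna(600)
  clean <- allele_set("r", rep(ref, 4), ref)
  no_var <- call_variants(clean)
  pp <- design_primers(clean, no_var, cut_sites = 300,
                       amplicon_range = c(150, 500))
  expect_gt(nrow(pp), 0L)
  expect_false(is.unsorted(pp$amplicon_size_ref))
  for (i in seq_len(nrow(pp))) {
    expect_true(oracle_check_pair(pp[i, ], clean, no_var, 300, c(150, 500)))
  }

  # with real inter-allelic variation the checker must still pass
  cfg <- simulation_config(seed = 91, snp_rate = 0.02)
  sim <- simulate_haplotypes(cfg)
  v <- call_variants(sim$alleles)
  cuts <- c(280, 330)
  pv <- design_primers(sim$alleles, v, cut_sites = cuts,
                       amplicon_range = c(120, 450))
  for (i in seq_len(nrow(pv))) {
    expect_true(oracle_check_pair(pv[i, ], sim$alleles, v, cuts, c(120, 450)))
  }
})

test_that("design_primers reports the failing constraint when infeasible", {
  ref <- strrep("ACGT", 100)
  al <- allele_set("x", rep(ref, 2), ref, ploidy = 2)
  # variants tiling every 10 bp across the whole forward flank
  vars <- tibble::tibble(position = seq(1, 200, by = 10), kind = "SNP",
                         length = 1)
  pp <- design_primers(al, vars, cut_sites = 205, amplicon_range = c(50, 390))
  expect_equal(nrow(pp), 0L)
  rep <- attr(pp, "failure_report")
  expect_equal(rep$reason, "no variant-free forward footprint")
  expect_equal(rep$n_forward_feasible, 0L)

  # feasible footprints but no amplicon inside the size window
  pp2 <- design_primers(al, tibble::tibble(position = numeric(),
                                           kind = character(),
                                           length = numeric()),
                        cut_sites = 200, amplicon_range = c(401, 450))
  expect_equal(nrow(pp2), 0L)
  expect_equal(attr(pp2, "failure_report")$reason,
               "no pair within amplicon size window")
})

test_that("per-allele amplicon sizes track indels between the primers", {
  ref <- {set.seed(9); random_dna(300)}
  h <- rep(ref, 4)
  substr(h[3], 150, 152) <- "---"  # 3 bp deletion in one allele
  al <- allele_set("r", h, ref)
  v <- call_variants(al)
  pp <- design_primers(al, v, cut_sites = c(140, 160),
                       amplicon_range = c(80, 280))
  expect_gt(nrow(pp), 0L)
  sizes <- pp$amplicon_size_per_allele[[1]]
  expect_equal(unname(sizes["allele3"]), pp$amplicon_size_ref[1] - 3)
  expect_equal(unname(sizes["allele1"]), pp$amplicon_size_ref[1])
})

test_that("rank tables are validated on load", {
  rk <- load_guide_ranks()
  expect_s3_class(rk, "rank_table")
  expect_equal(nrow(rk), 16L)
  expect_equal(sort(table(rk$group), decreasing = TRUE)[[1]], 6L)
  expect_equal(length(unique(rk$group)), 4L)
  expect_setequal(attr(rk, "methods"), c("chopchop", "ssc", "crisprater"))

  one <- data.frame(guide_id = "g1", group = "A", ssc = 1, in_vivo = 1)
  expect_s3_class(load_rank_table(one), "rank_table")

  dup <- rbind(one, one)
  expect_error(load_rank_table(dup), "duplicated")

  bad <- data.frame(guide_id = c("a", "b"), group = "A",
                    ssc = c(1, 3), in_vivo = c(1, 2))
  expect_error(load_rank_table(bad), "not a valid ranking")

  expect_error(load_rank_table(one[, -3]), "method column")
})
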