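# Independent brute-force oracles used only by the tests.

# position-by-position N20-NGG scan, deliberately naive
oracle_pam_scan <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  rows <- list()
  if (n >= 23L) {
    for (s in 1:(n - 22L)) {
      if (ch[s + 21L] == "G" && ch[s + 22L] == "G") {
        rows[[length(rows) + 1L]] <-
          data.frame(strand = "+", proto_start = s, pam_start = s + 20L)
      }
      if (ch[s] == "C" && ch[s + 1L] == "C") {
        rows[[length(rows) + 1L]] <-
          data.frame(strand = "-", proto_start = s + 3L, pam_start = s)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(strand = character(), proto_start = integer(),
                      pam_start = integer())
  }
  out[order(out$proto_start, out$strand), , drop = FALSE]
}

site_key <- function(df) {
  paste(df$strand, df$proto_start, df$pam_start, sep = ":")
}

# exhaustive feasibility check of one reported primer pair
oracle_check_pair <- function(pair, alleles, variants, cut_sites,
                              amplicon_range, primer_len_range = c(18, 25)) {
  blocked <- variant_positions(variants)
  refch <- strsplit(alleles$reference, "")[[1]]
  fw <- pair$fwd_start:pair$fwd_end
  rv <- pair$rev_start:pair$rev_end
  size <- sum(refch[pair$fwd_start:pair$rev_end] != "-")
  !any(fw %in% blocked) && !any(rv %in% blocked) &&
    !any(refch[fw] == "-") && !any(refch[rv] == "-") &&
    length(fw) >= primer_len_range[1] && length(fw) <= primer_len_range[2] &&
    length(rv) >= primer_len_range[1] && length(rv) <= primer_len_range[2] &&
    max(fw) < min(cut_sites) && min(rv) > max(cut_sites) &&
    size >= amplicon_range[1] && size <= amplicon_range[2]
}

# exact two-sided permutation test on the difference of means
oracle_perm_t_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  obs <- abs(mean(a) - mean(b))
  idx <- utils::combn(length(pooled), n)
  diffs <- apply(idx, 2L, function(ix) {
    abs(mean(pooled[ix]) - mean(pooled[-ix]))
  })
  mean(diffs >= obs - 1e-12)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# event set comparison helper: injected truth vs called records
variant_key <- function(df) {
  sort(paste(df$position, df$kind, df$length,
             ifelse(is.na(df$allele_id), ".", df$allele_id), sep = ":"))
}
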