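#' Construct an allele set (aligned haplotypes plus reference)
#'
#' An allele set holds the full allelic sequence of one target region: one
#' aligned sequence per haplotype (ploidy-many, typically 4 in cultivated
#' potato) plus the reference sequence, all of equal alignment length.  The
#' gap character `-` is allowed; `N` is treated as a no-call.
#'
#' @param region_id Region label.
#' @param haplotypes Character vector of aligned haplotype sequences.  Names
#'   are kept; unnamed inputs are labelled `allele1..alleleP`.
#' @param reference Aligned reference sequence (same length).
#' @param ploidy Expected number of haplotypes (default `length(haplotypes)`).
#' @return An `allele_set` list: `region_id`, `ploidy`, `haplotypes`
#'   (named character vector), `reference`, `alignment_length`.
#' @export
allele_set <- function(region_id, haplotypes, reference,
                       ploidy = length(haplotypes)) {
  haplotypes <- toupper(as.character(haplotypes))
  reference <- toupper(as.character(reference))
  if (length(reference) != 1L) stop("`reference` must be a single sequence")
  if (length(haplotypes) != ploidy) {
    stop("expected ", ploidy, " haplotypes, got ", length(haplotypes))
  }
  widths <- nchar(c(haplotypes, reference))
  if (length(unique(widths)) != 1L) {
    stop("aligned sequences must all have equal length; got lengths ",
         paste(widths, collapse = ", "))
  }
  all_chars <- unique(strsplit(paste0(c(haplotypes, reference), collapse = ""),
                               "")[[1]])
  bad <- setdiff(all_chars, c("A", "C", "G", "T", "N", "-"))
  if (length(bad)) {
    stop("disallowed characters in alignment: ",
         paste(bad, collapse = ", "))
  }
  if (is.null(names(haplotypes))) {
    names(haplotypes) <- paste0("allele", seq_along(haplotypes))
  }
  structure(
    list(region_id = as.character(region_id), ploidy = as.integer(ploidy),
         haplotypes = haplotypes, reference = reference,
         alignment_length = widths[1]),
    class = "allele_set"
  )
}

#' @export
print.allele_set <- function(x, ...) {
  cat("<allele_set> ", x$region_id, ": ", x$ploidy,
      " haplotypes + reference, alignment length ", x$alignment_length,
      "\n", sep = "")
  invisible(x)
}

#' Read an allele set from FASTA
#'
#' Record IDs follow the convention `"<region>|allele<k>"` for haplotypes and
#' `"<region>|ref"` for the reference; the gap character `-` is permitted.
#'
#' @param path FASTA file.
#' @return An `allele_set`.
#' @seealso [write_allele_fasta()]
#' @export
read_allele_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  parts <- strsplit(ids, "|", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("FASTA record IDs must look like \"<region>|allele<k>\" or ",
         "\"<region>|ref\": ", path)
  }
  region <- unique(vapply(parts, `[`, "", 1L))
  if (length(region) != 1L) {
    stop("FASTA mixes multiple regions: ", paste(region, collapse = ", "))
  }
  role <- vapply(parts, `[`, "", 2L)
  is_ref <- role == "ref"
  if (sum(is_ref) != 1L) stop("FASTA must contain exactly one \"|ref\" record")
  haps <- as.character(seqs[!is_ref])
  names(haps) <- role[!is_ref]
  allele_set(region, haps, as.character(seqs[is_ref])[1])
}

#' Write an allele set to FASTA
#'
#' @param alleles An `allele_set`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_allele_fasta <- function(alleles, path) {
  stopifnot(inherits(alleles, "allele_set"))
  seqs <- Biostrings::DNAStringSet(c(alleles$haplotypes,
                                     ref = alleles$reference))
  names(seqs) <- paste0(alleles$region_id, "|", names(seqs))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Call inter-allelic variants from an aligned allele set
#'
#' Compares every haplotype against the reference, column by column.
#' Substitution columns (where at least one haplotype carries a different
#' base) yield one `SNP` record per alignment column, carrying the full
#' per-allele state string.  Gap runs are collapsed: a contiguous run of `-`
#' in one haplotype against reference bases is a single `deletion` record of
#' that run length, and a run of haplotype bases against reference gaps is a
#' single `insertion` record.  The same columns gapped in different
#' haplotypes count as distinct events (one record per haplotype).  `N` is a
#' no-call and never produces a record.
#'
#' @param alleles An `allele_set`.
#' @return A `variant_table`: a tibble with columns `position` (1-based
#'   alignment column of the event start), `kind` (`"SNP"`, `"insertion"`,
#'   `"deletion"`), `length` (bp; 1 for SNPs), `ref_state`, `allele_id`
#'   (haplotype carrying an indel; `NA` for SNP records) and `allele_states`
#'   (comma-separated per-haplotype states for SNP records).
#' @export
call_variants <- function(alleles) {
  stopifnot(inherits(alleles, "allele_set"))
  ref <- strsplit(alleles$reference, "")[[1]]
  hap_mat <- do.call(rbind, strsplit(unname(alleles$haplotypes), ""))
  rownames(hap_mat) <- names(alleles$haplotypes)
  n_col <- length(ref)
  recs <- list()

  # SNPs: one record per column where >=1 haplotype base differs from a
  # reference base (gaps and N excluded from the comparison)
  ref_base <- ref != "-"
  differs <- sweep(hap_mat, 2, ref, FUN = "!=") &
    hap_mat != "-" & hap_mat != "N"
  snp_cols <- which(ref_base & ref != "N" & colSums(differs) > 0)
  if (length(snp_cols)) {
    recs[[length(recs) + 1L]] <- tibble::tibble(
      position = as.numeric(snp_cols),
      kind = "SNP",
      length = 1,
      ref_state = ref[snp_cols],
      allele_id = NA_character_,
      allele_states = apply(hap_mat[, snp_cols, drop = FALSE], 2,
                            paste, collapse = ",")
    )
  }

  run_records <- function(mask, kind, hap_name, hap_chars) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (!length(keep)) return(NULL)
    tibble::tibble(
      position = as.numeric(starts[keep]),
      kind = kind,
      length = as.numeric(r$lengths[keep]),
      ref_state = vapply(keep, function(i) {
        paste(ref[starts[i]:ends[i]], collapse = "")
      }, ""),
      allele_id = hap_name,
      allele_states = vapply(keep, function(i) {
        paste(hap_chars[starts[i]:ends[i]], collapse = "")
      }, "")
    )
  }

  for (h in rownames(hap_mat)) {
    hc <- hap_mat[h, ]
    del_mask <- hc == "-" & ref_base
    ins_mask <- hc != "-" & hc != "N" & !ref_base
    recs[[length(recs) + 1L]] <- run_records(del_mask, "deletion", h, hc)
    recs[[length(recs) + 1L]] <- run_records(ins_mask, "insertion", h, hc)
  }

  out <- do.call(rbind, recs[!vapply(recs, is.null, TRUE)])
  if (is.null(out)) {
    out <- tibble::tibble(position = numeric(), kind = character(),
                          length = numeric(), ref_state = character(),
                          allele_id = character(), allele_states = character())
  }
  out <- out[order(out$position, out$kind, out$allele_id), ]
  class(out) <- c("variant_table", class(out))
  attr(out, "region_id") <- alleles$region_id
  attr(out, "alignment_length") <- n_col
  out
}

#' Alignment columns covered by any variant
#'
#' SNPs cover their own column; indels cover `position .. position+length-1`.
#' Used to block guide and primer footprints.
#'
#' @param variants A `variant_table`.
#' @return Sorted unique integer vector of alignment columns.
#' @export
variant_positions <- function(variants) {
  if (nrow(variants) == 0L) return(integer())
  cols <- unlist(mapply(function(p, l) seq(p, p + l - 1),
                        variants$position, variants$length,
                        SIMPLIFY = FALSE))
  sort(unique(as.integer(cols)))
}

#' Export a variant table as a simplified VCF-like TSV
#'
#' Columns `CHROM`, `POS`, `KIND`, `REF`, `ALT`, `ALLELE` — a documented,
#' simplified dialect (alignment coordinates, per-haplotype ALT states),
#' not a spec-compliant VCF.
#'
#' @param variants A `variant_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_variant_tsv <- function(variants, path) {
  df <- data.frame(
    CHROM = attr(variants, "region_id") %||% ".",
    POS = variants$position,
    KIND = variants$kind,
    REF = variants$ref_state,
    ALT = variants$allele_states,
    ALLELE = ifelse(is.na(variants$allele_id), ".", variants$allele_id)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Polymorphism prevalence relative to a reference genome rate
#'
#' Summarizes a target region's SNP density and expresses it as a fold change
#' over a supplied reference SNP rate (e.g. the heterozygous diploid RH
#' genome's rate, which is an input parameter since that genome is not
#' shipped).  Tetraploid elite cultivars typically show a 1.3-2.8 fold
#' elevated SNP prevalence over a diploid reference.
#'
#' @param variants A `variant_table`, or a list with `snp_count` and
#'   `indel_count`.
#' @param region_len Region length in bp (> 0).
#' @param reference_rate Reference SNP rate in SNPs per bp (>= 0).
#' @return A `prevalence_stats` list: `snp_count`, `indel_count`,
#'   `region_len`, `snp_rate`, `fold_vs_reference` (`Inf` only when the
#'   reference rate is 0 and SNPs are present; 0/0 is reported as 0).
#' @export
prevalence_fold <- function(variants, region_len, reference_rate) {
  if (!is.numeric(region_len) || region_len <= 0) {
    stop("`region_len` must be > 0")
  }
  if (reference_rate < 0) stop("`reference_rate` must be >= 0")
  if (inherits(variants, "variant_table") || is.data.frame(variants)) {
    snp_count <- sum(variants$kind == "SNP")
    indel_count <- sum(variants$kind != "SNP")
  } else {
    snp_count <- variants$snp_count
    indel_count <- variants$indel_count %||% 0
  }
  snp_rate <- snp_count / region_len
  fold <- if (reference_rate == 0) {
    if (snp_rate > 0) Inf else 0
  } else {
    snp_rate / reference_rate
  }
  structure(
    list(snp_count = snp_count, indel_count = indel_count,
         region_len = region_len, snp_rate = snp_rate,
         fold_vs_reference = fold),
    class = "prevalence_stats"
  )
}

#' @export
print.prevalence_stats <- function(x, ...) {
  cat("<prevalence_stats> ", x$snp_count, " SNPs + ", x$indel_count,
      " indels over ", x$region_len, " bp (",
      signif(x$snp_rate, 3), " SNPs/bp; ",
      signif(x$fold_vs_reference, 3), "x reference)\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
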