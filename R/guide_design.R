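#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA sequences (ACGTN-).
#' @return Reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(toupper(s), "")[[1]]), collapse = ""))
  }, "", USE.NAMES = FALSE)
}

#' Scan a sequence for SpCas9 protospacer sites (N20-NGG)
#'
#' Enumerates every position where a 20-nt protospacer lies immediately 5' of
#' an NGG PAM, on the plus strand, the minus strand, or both.  Minus-strand
#' sites are reported in plus-strand coordinates (a minus-strand PAM is a
#' `CCN` on the plus strand, with the protospacer to its right).  The scan is
#' exhaustive: it equals a brute-force check of every position.
#'
#' @section Cut-site convention:
#' SpCas9 cuts bluntly 3 bp 5' of the PAM, i.e. between protospacer positions
#' 17 and 18.  `cut_position` reports the plus-strand coordinate of the base
#' immediately left of the cut boundary: for a plus-strand site whose PAM
#' starts at coordinate q the cut position is `q - 4`; for a minus-strand
#' site whose PAM occupies `p..p+2` it is `p + 5`.
#'
#' @param sequence A single gapless DNA string (length >= 23 for any hit).
#' @param strand_mode `"both"` (default), `"plus"` or `"minus"`.
#' @return A `guide_sites` tibble: `guide_id`, `protospacer` (20 nt, read 5'
#'   to 3' on the site's own strand), `pam` (3 nt, NGG), `strand`,
#'   `proto_start`, `proto_end`, `pam_start`, `pam_end` (all plus-strand
#'   coordinates), `cut_position`.  Sequences shorter than 23 nt give an
#'   empty table, not an error.
#' @export
scan_pam_sites <- function(sequence, strand_mode = c("both", "plus", "minus")) {
  strand_mode <- match.arg(strand_mode)
  seq <- toupper(as.character(sequence)[1])
  if (grepl("-", seq, fixed = TRUE)) {
    stop("`sequence` must be gapless; degap the reference before scanning")
  }
  n <- nchar(seq)
  empty <- tibble::tibble(
    guide_id = character(), protospacer = character(), pam = character(),
    strand = character(), proto_start = numeric(), proto_end = numeric(),
    pam_start = numeric(), pam_end = numeric(), cut_position = numeric()
  )
  if (n < 23L) return(structure(empty, class = c("guide_sites", class(empty))))
  chars <- strsplit(seq, "")[[1]]
  rows <- list()
  if (strand_mode %in% c("both", "plus")) {
    # PAM start q in 21..(n-2); require G at q+1 and q+2
    q <- 21:(n - 2)
    hit <- q[chars[q + 1] == "G" & chars[q + 2] == "G"]
    if (length(hit)) {
      rows[[1]] <- tibble::tibble(
        protospacer = substring(seq, hit - 20, hit - 1),
        pam = substring(seq, hit, hit + 2),
        strand = "+",
        proto_start = as.numeric(hit - 20), proto_end = as.numeric(hit - 1),
        pam_start = as.numeric(hit), pam_end = as.numeric(hit + 2),
        cut_position = as.numeric(hit - 4)
      )
    }
  }
  if (strand_mode %in% c("both", "minus")) {
    # plus-strand CCN at p..p+2, protospacer at p+3..p+22
    p <- 1:(n - 22)
    hit <- p[chars[p] == "C" & chars[p + 1] == "C"]
    if (length(hit)) {
      rows[[2]] <- tibble::tibble(
        protospacer = revcomp(substring(seq, hit + 3, hit + 22)),
        pam = revcomp(substring(seq, hit, hit + 2)),
        strand = "-",
        proto_start = as.numeric(hit + 3), proto_end = as.numeric(hit + 22),
        pam_start = as.numeric(hit), pam_end = as.numeric(hit + 2),
        cut_position = as.numeric(hit + 5)
      )
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) out <- empty[, -1]
  out <- out[order(out$proto_start, out$strand), ]
  out <- tibble::add_column(
    out, guide_id = sprintf("site_%04d", seq_len(nrow(out))), .before = 1
  )
  structure(out, class = c("guide_sites", class(out)))
}

#' Blunt cut coordinate of a guide site
#'
#' Recomputes the SpCas9 cut boundary (3 bp 5' of the PAM; see
#' [scan_pam_sites()] for the coordinate convention) from PAM coordinates and
#' strand.
#'
#' @param sites A `guide_sites` tibble (or any data frame with `pam_start`,
#'   `pam_end`, `strand`).
#' @return Numeric vector of cut positions, one per site.
#' @export
cut_site <- function(sites) {
  ifelse(sites$strand == "+", sites$pam_start - 4, sites$pam_start + 5)
}

#' Expected dual-cut deletion size for a pair of guides
#'
#' Two simultaneously cutting RNPs excise the fragment between their blunt
#' cut boundaries; the resulting amplicon is shorter by the boundary distance.
#'
#' @param cut1,cut2 Cut positions (see [cut_site()]).
#' @return Absolute distance in bp.
#' @export
dual_cut_deletion_size <- function(cut1, cut2) {
  abs(cut2 - cut1)
}

#' Flag guide sites overlapping inter-allelic variants
#'
#' A gRNA can only cut every allele if its protospacer + PAM footprint is
#' identical across haplotypes; any inter-allelic variant inside the
#' footprint clears the `allele_consensus` flag.  Variants falling in the
#' PAM-proximal seed (the PAM plus the last `seed_len` protospacer
#' nucleotides, where mismatches are least tolerated) additionally set
#' `variant_in_seed`.
#'
#' @param sites A `guide_sites` tibble (coordinates must be in the same
#'   system as `variants`, i.e. alignment columns).
#' @param variants A `variant_table`.
#' @param seed_len Seed length in nt (default 12, a common SpCas9 heuristic).
#' @return `sites` with added columns `allele_consensus` (logical),
#'   `variant_in_seed` (logical) and `overlapping_variants` (list of variant
#'   positions).
#' @export
filter_allele_consensus <- function(sites, variants, seed_len = 12) {
  blocked <- variant_positions(variants)
  fp_start <- pmin(sites$proto_start, sites$pam_start)
  fp_end <- pmax(sites$proto_end, sites$pam_end)
  seed_start <- ifelse(sites$strand == "+",
                       sites$proto_end - seed_len + 1, sites$pam_start)
  seed_end <- ifelse(sites$strand == "+",
                     sites$pam_end, sites$proto_start + seed_len - 1)
  ov <- lapply(seq_len(nrow(sites)), function(i) {
    blocked[blocked >= fp_start[i] & blocked <= fp_end[i]]
  })
  sites$allele_consensus <- lengths(ov) == 0L
  sites$variant_in_seed <- vapply(seq_len(nrow(sites)), function(i) {
    any(blocked >= seed_start[i] & blocked <= seed_end[i])
  }, TRUE)
  sites$overlapping_variants <- ov
  sites
}

#' Design polymorphism-avoiding diagnostic IDAA primer pairs
#'
#' Places a forward/reverse primer pair flanking the given cut sites such
#' that both primer footprints are free of inter-allelic variants in all
#' haplotypes (so the FAM-labelled amplicon forms on every allele) and the
#' reference amplicon length falls in `amplicon_range`.  Feasibility is
#' footprint variant-exclusion plus length windows only; no thermodynamic
#' model is applied (melting behaviour is left to the bench).
#'
#' All coordinates are alignment columns of `alleles`.  Per-allele amplicon
#' sizes are the gap-free lengths of each haplotype between the primer
#' outer ends; they differ across alleles when an allele carries an indel
#' between the primers.
#'
#' @param alleles An `allele_set`.
#' @param variants A `variant_table` for the same alignment (typically
#'   `call_variants(alleles)`).
#' @param cut_sites Numeric vector of cut positions the amplicon must span.
#' @param amplicon_range Length-2 numeric `(min_bp, max_bp)` window for the
#'   reference amplicon size.
#' @param primer_len_range Length-2 integer range of primer lengths
#'   (default `c(18, 25)`).
#' @param max_pairs Maximum number of pairs to return (default 20).
#' @param fam Which primer carries the FAM label (`"forward"` or
#'   `"reverse"`).
#' @return A `primer_pairs` tibble sorted by reference amplicon size:
#'   `forward`, `reverse` (primer sequences, reverse primer given 5'-3' on
#'   the minus strand), `fwd_start`, `fwd_end`, `rev_start`, `rev_end`
#'   (alignment columns), `fam_label`, `amplicon_size_ref`,
#'   `amplicon_size_per_allele` (list column, one size per haplotype) and
#'   `spans_cut_sites` (list column).  When no pair is feasible the table is
#'   empty and carries a machine-readable `failure_report` attribute naming
#'   the binding constraint that failed (`reason`, plus feasible footprint
#'   counts).
#' @export
design_primers <- function(alleles, variants, cut_sites,
                           amplicon_range = c(150, 500),
                           primer_len_range = c(18, 25),
                           max_pairs = 20, fam = c("forward", "reverse")) {
  stopifnot(inherits(alleles, "allele_set"))
  fam <- match.arg(fam)
  if (length(cut_sites) < 1L) stop("at least one cut site is required")
  if (amplicon_range[1] >= amplicon_range[2]) {
    stop("`amplicon_range` must satisfy min < max")
  }
  L <- alleles$alignment_length
  ref <- strsplit(alleles$reference, "")[[1]]
  blocked <- logical(L)
  blocked[variant_positions(variants)] <- TRUE
  blocked[ref == "-"] <- TRUE  # insertion columns never enter a footprint
  cb <- cumsum(blocked)
  clean_window <- function(s, e) cb[e] - c(0, cb)[s] == 0

  nongap <- cumsum(ref != "-")
  amp_size <- function(s, e) nongap[e] - c(0, nongap)[s]

  mincut <- floor(min(cut_sites))
  maxcut <- ceiling(max(cut_sites))
  lens <- seq(primer_len_range[1], primer_len_range[2])

  enum_feasible <- function(starts, len) {
    ok <- starts[clean_window(starts, starts + len - 1)]
    if (!length(ok)) return(NULL)
    data.frame(start = ok, end = ok + len - 1)
  }
  fwd <- do.call(rbind, lapply(lens, function(l) {
    s_max <- mincut - l  # footprint strictly 5' of the first cut boundary
    if (s_max < 1) return(NULL)
    enum_feasible(seq_len(s_max), l)
  }))
  rev_ <- do.call(rbind, lapply(lens, function(l) {
    s_min <- maxcut + 1
    if (s_min + l - 1 > L) return(NULL)
    enum_feasible(seq(s_min, L - l + 1), l)
  }))

  empty <- tibble::tibble(
    forward = character(), reverse = character(),
    fwd_start = numeric(), fwd_end = numeric(),
    rev_start = numeric(), rev_end = numeric(),
    fam_label = character(), amplicon_size_ref = numeric(),
    amplicon_size_per_allele = list(), spans_cut_sites = list()
  )
  fail <- function(reason) {
    attr(empty, "failure_report") <- list(
      reason = reason,
      n_forward_feasible = if (is.null(fwd)) 0L else nrow(fwd),
      n_reverse_feasible = if (is.null(rev_)) 0L else nrow(rev_)
    )
    structure(empty, class = c("primer_pairs", class(empty)))
  }
  if (is.null(fwd)) return(fail("no variant-free forward footprint"))
  if (is.null(rev_)) return(fail("no variant-free reverse footprint"))

  # per-allele gap-free length helper
  hap_nongap <- lapply(alleles$haplotypes, function(h) {
    cumsum(strsplit(h, "")[[1]] != "-")
  })

  rev_ <- rev_[order(rev_$end), ]
  pairs <- list()
  # smallest amplicons first: forwards closest to the cut region
  for (i in order(fwd$start, decreasing = TRUE)) {
    fs <- fwd$start[i]
    sz <- amp_size(fs, rev_$end)
    sel <- which(sz >= amplicon_range[1] & sz <= amplicon_range[2])
    if (!length(sel)) next
    j <- sel[1]  # shortest feasible amplicon for this forward
    pairs[[length(pairs) + 1L]] <- tibble::tibble(
      forward = paste(ref[fs:fwd$end[i]], collapse = ""),
      reverse = revcomp(paste(ref[rev_$start[j]:rev_$end[j]], collapse = "")),
      fwd_start = fs, fwd_end = fwd$end[i],
      rev_start = rev_$start[j], rev_end = rev_$end[j],
      fam_label = fam,
      amplicon_size_ref = sz[j],
      amplicon_size_per_allele = list(vapply(hap_nongap, function(cs) {
        cs[rev_$end[j]] - c(0, cs)[fs]
      }, 0)),
      spans_cut_sites = list(cut_sites)
    )
    if (length(pairs) >= max_pairs) break
  }
  if (!length(pairs)) return(fail("no pair within amplicon size window"))
  out <- do.call(rbind, pairs)
  out <- out[order(out$amplicon_size_ref), ]
  structure(out, class = c("primer_pairs", class(out)))
}

#' Load and validate an in-silico vs in-vivo guide rank table
#'
#' The table has one row per gRNA with a grouping column (target region), one
#' rank column per in-silico prediction method and the observed in-vivo rank
#' (1 = best).  Within a group every rank must be an integer between 1 and
#' the group size; ties (repeated ranks, as prediction servers sometimes
#' emit) are allowed, values outside `1..n` are not.
#'
#' @param x Path to a TSV, or a data frame.  Required columns: `guide_id`,
#'   `group`, `in_vivo`, plus at least one method column.
#' @return A `rank_table` data frame with a `methods` attribute naming the
#'   in-silico method columns.
#' @seealso [rank_concordance()], [load_guide_ranks()] for the packaged
#'   potato GWD1/DMR6-1 benchmark.
#' @export
load_rank_table <- function(x) {
  df <- if (is.character(x)) {
    utils::read.delim(x, stringsAsFactors = FALSE)
  } else {
    as.data.frame(x)
  }
  required <- c("guide_id", "group", "in_vivo")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("rank table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  methods <- setdiff(names(df), required)
  if (!length(methods)) stop("rank table needs at least one in-silico method column")
  dup <- df$guide_id[duplicated(df$guide_id)]
  if (length(dup)) stop("duplicated guide_id: ", paste(unique(dup), collapse = ", "))
  for (g in unique(df$group)) {
    sub <- df[df$group == g, ]
    n <- nrow(sub)
    for (col in c(methods, "in_vivo")) {
      r <- sub[[col]]
      if (any(is.na(r)) || any(r != round(r)) || any(r < 1) || any(r > n)) {
        stop("column `", col, "` in group `", g,
             "` is not a valid ranking of 1..", n)
      }
    }
  }
  structure(df, methods = methods, class = c("rank_table", "data.frame"))
}
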