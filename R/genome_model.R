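#' Parse a dot-notation locus string
#'
#' Genomic loci are written here as `"<chrom>:<start>.<end>"`, the notation
#' used in potato gene-structure listings (e.g. `"chr05:9901255.9916669"`).
#' Thousands separators (commas) inside coordinates and stray whitespace are
#' tolerated and stripped.
#'
#' @section Span convention:
#' `span_bp` is defined as `end - start` (not `end - start + 1`).  This is the
#' bookkeeping under which the GWD1 locus above spans 15,414 bp and the DMR6-1
#' locus `"chr03:46,329605.46336003"` spans 6,398 bp, and it is used
#' consistently for every region in the package.
#'
#' @param locus A single locus string.
#' @return A `genomic_region` object: a list with elements `chrom`, `start`,
#'   `end` (1-based, inclusive) and `span_bp = end - start`.
#' @examples
#' parse_locus("chr05:9901255.9916669")$span_bp  # 15414
#' @seealso [format_locus()], [genomic_region()]
#' @export
parse_locus <- function(locus) {
  if (!is.character(locus) || length(locus) != 1L || is.na(locus)) {
    stop("`locus` must be a single character string")
  }
  s <- gsub("[[:space:]]", "", locus)
  m <- regmatches(s, regexec("^([^:]+):([0-9,]+)\\.([0-9,]+)$", s))[[1]]
  if (length(m) != 4L) {
    stop("malformed locus string: '", locus,
         "' (expected \"<chrom>:<start>.<end>\")")
  }
  start <- suppressWarnings(as.numeric(gsub(",", "", m[3])))
  end <- suppressWarnings(as.numeric(gsub(",", "", m[4])))
  if (is.na(start)) stop("malformed start coordinate in '", locus, "': ", m[3])
  if (is.na(end)) stop("malformed end coordinate in '", locus, "': ", m[4])
  if (end < start) {
    stop("locus '", locus, "': start ", format(start, scientific = FALSE),
         " exceeds end ", format(end, scientific = FALSE))
  }
  genomic_region(m[2], start, end)
}

#' Construct a genomic region
#'
#' @param chrom Chromosome label (non-empty string).
#' @param start,end 1-based inclusive coordinates, `end >= start`.
#' @return A `genomic_region` list with `chrom`, `start`, `end`, `span_bp`.
#' @export
genomic_region <- function(chrom, start, end) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(chrom) != 1L || is.na(chrom) || !nzchar(chrom)) {
    stop("`chrom` must be a non-empty string")
  }
  if (is.na(start) || is.na(end)) stop("coordinates must be numeric")
  if (end < start) stop("`end` (", end, ") must be >= `start` (", start, ")")
  structure(
    list(chrom = chrom, start = start, end = end, span_bp = end - start),
    class = "genomic_region"
  )
}

#' Format a genomic region back to dot notation
#'
#' Inverse of [parse_locus()] modulo commas and whitespace.
#'
#' @param region A `genomic_region`.
#' @return A locus string `"<chrom>:<start>.<end>"`.
#' @export
format_locus <- function(region) {
  stopifnot(inherits(region, "genomic_region"))
  paste0(region$chrom, ":",
         format(region$start, scientific = FALSE, trim = TRUE), ".",
         format(region$end, scientific = FALSE, trim = TRUE))
}

#' @export
print.genomic_region <- function(x, ...) {
  cat("<genomic_region> ", format_locus(x),
      " (span ", format(x$span_bp, big.mark = ","), " bp)\n", sep = "")
  invisible(x)
}

#' Build a validated gene model from an exon interval list
#'
#' Exons may be supplied in any order (minus-strand genes are conventionally
#' listed 5' to 3', i.e. in descending coordinate); they are stored sorted by
#' start coordinate, with `exon_rank` numbering following the strand.
#'
#' @param gene_id Gene identifier.
#' @param region A `genomic_region` containing all exons.
#' @param exons Either a data frame with columns `start` and `end`, or a
#'   character vector of `"start.end"` pairs as printed in gene-structure
#'   listings.
#' @param strand `"+"` or `"-"`.
#' @return A `gene_model` list: `gene_id`, `region`, `strand`, and an `exons`
#'   tibble (`exon_rank`, `start`, `end`, `width`).
#' @export
build_gene_model <- function(gene_id, region, exons, strand = "+") {
  stopifnot(inherits(region, "genomic_region"))
  if (!strand %in% c("+", "-")) stop("`strand` must be \"+\" or \"-\"")
  if (is.character(exons)) {
    exons <- parse_exon_list(exons)
  }
  exons <- as.data.frame(exons)
  if (!all(c("start", "end") %in% names(exons))) {
    stop("`exons` must have columns `start` and `end`")
  }
  if (nrow(exons) == 0L) stop("exon list is empty")
  st <- as.numeric(exons$start)
  en <- as.numeric(exons$end)
  bad <- which(en < st)
  if (length(bad)) stop("exon ", bad[1], ": end precedes start")
  out_of_region <- which(st < region$start | en > region$end)
  if (length(out_of_region)) {
    stop("exon ", out_of_region[1], " (", st[out_of_region[1]], "-",
         en[out_of_region[1]], ") lies outside region ", format_locus(region))
  }
  ord <- order(st)
  st <- st[ord]
  en <- en[ord]
  if (nrow(exons) > 1L) {
    overlap <- which(st[-1] <= en[-length(en)])
    if (length(overlap)) {
      stop("exon ", overlap[1] + 1L, " overlaps exon ", overlap[1],
           " after coordinate sorting")
    }
  }
  rank <- if (strand == "+") seq_along(st) else rev(seq_along(st))
  structure(
    list(
      gene_id = as.character(gene_id),
      region = region,
      strand = strand,
      exons = tibble::tibble(exon_rank = rank, start = st, end = en,
                             width = en - st + 1)
    ),
    class = "gene_model"
  )
}

#' Parse a printed exon interval list
#'
#' @param pairs Character vector of `"start.end"` strings (commas allowed).
#' @return A data frame with columns `start`, `end`.
#' @export
parse_exon_list <- function(pairs) {
  pairs <- gsub("[[:space:]]", "", pairs)
  m <- regmatches(pairs, regexec("^([0-9,]+)\\.([0-9,]+)$", pairs))
  bad <- which(lengths(m) != 3L)
  if (length(bad)) stop("malformed exon interval: '", pairs[bad[1]], "'")
  data.frame(
    start = as.numeric(gsub(",", "", vapply(m, `[`, "", 2L))),
    end = as.numeric(gsub(",", "", vapply(m, `[`, "", 3L)))
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$gene_id, " (", x$strand, ") ", format_locus(x$region),
      "\n  ", nrow(x$exons), " exons, ",
      format(sum(x$exons$width), big.mark = ","), " exonic bp of a ",
      format(x$region$span_bp, big.mark = ","), " bp locus\n", sep = "")
  invisible(x)
}

#' Convert a gene model to a GRanges object
#'
#' @param model A `gene_model`.
#' @return A [GenomicRanges::GRanges] with one range per exon plus a gene-level
#'   range; metadata columns `type`, `ID` and `Parent` follow GFF3 usage.
#' @export
gene_model_granges <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  ex <- model$exons
  gr <- GenomicRanges::GRanges(
    seqnames = model$region$chrom,
    ranges = IRanges::IRanges(
      start = c(model$region$start, ex$start),
      end = c(model$region$end, ex$end)
    ),
    strand = model$strand
  )
  gr$type <- c("gene", rep("exon", nrow(ex)))
  gr$ID <- c(model$gene_id,
             paste0(model$gene_id, ".exon", ex$exon_rank))
  gr$Parent <- c(NA_character_, rep(model$gene_id, nrow(ex)))
  gr
}

#' Export a gene model as GFF3
#'
#' @param model A `gene_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_model_gff3 <- function(model, path) {
  rtracklayer::export(gene_model_granges(model), path, format = "GFF3")
  invisible(path)
}

#' Read exon intervals from a two-column TSV
#'
#' @param path TSV with columns `start` and `end` (additional columns,
#'   e.g. `gene_id`, are preserved).
#' @return A data frame.
#' @export
read_exon_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("start", "end") %in% names(df))) {
    stop("exon TSV must have columns `start` and `end`: ", path)
  }
  df
}
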