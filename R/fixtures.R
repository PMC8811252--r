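#' Path to a packaged data file
#'
#' @param file File name under the package's `extdata` directory; empty to
#'   list the directory.
#' @return Absolute path.
#' @export
polyedit_extdata <- function(file = "") {
  path <- system.file("extdata", file, package = "polyedit", mustWork = FALSE)
  if (!nzchar(path)) stop("no packaged file called '", file, "'")
  path
}

#' Packaged gRNA table for the potato GWD1 / DMR6-1 benchmark
#'
#' The 16 published SpCas9 gRNAs targeting the 5' and 3' ends of the potato
#' glucan water dikinase 1 (GWD1, cultivar Saturna) and downy mildew
#' resistant 6-1 (DMR6-1, cultivar Wotan) genes: 4 + 6 guides for GWD1 and
#' 3 + 3 for DMR6-1.
#'
#' @return A tibble: `guide_id`, `gene`, `region`, `protospacer` (20 nt).
#' @export
load_guide_table <- function() {
  tibble::as_tibble(utils::read.delim(polyedit_extdata("guides.tsv"),
                                      stringsAsFactors = FALSE))
}

#' Packaged diagnostic IDAA primer table
#'
#' The published FAM-labelled diagnostic PCR designs for the four target
#' regions, including the FAM-tail (nested) design used for the DMR6-1
#' exon-2 amplicon.
#'
#' @return A tibble: `region`, `primer_id`, `role`, `fam`, `sequence`.
#' @export
load_primer_table <- function() {
  tibble::as_tibble(utils::read.delim(polyedit_extdata("primers.tsv"),
                                      stringsAsFactors = FALSE))
}

#' Packaged in-silico versus in-vivo guide rank benchmark
#'
#' Published rankings of the 16 GWD1/DMR6-1 gRNAs by three in-silico
#' prediction servers (CHOPCHOP, SSC, CRISPRater) alongside the in-vivo
#' rank from single-RNP protoplast transformations (1 = best), grouped by
#' target region.
#'
#' @return A validated `rank_table` (see [load_rank_table()]).
#' @export
load_guide_ranks <- function() {
  load_rank_table(polyedit_extdata("guide_ranks.tsv"))
}

#' Packaged gene models for GWD1 and DMR6-1
#'
#' Printed exon coordinate lists of the two benchmark genes on the potato
#' DM reference: GWD1 (33 exons on chromosome 5) and DMR6-1 (4 exons, minus
#' strand, chromosome 3).
#'
#' @return A named list of [build_gene_model()] objects.
#' @export
load_gene_models <- function() {
  meta <- utils::read.delim(polyedit_extdata("gene_models.tsv"),
                            stringsAsFactors = FALSE)
  exons <- read_exon_tsv(polyedit_extdata("exons.tsv"))
  out <- lapply(seq_len(nrow(meta)), function(i) {
    build_gene_model(
      gene_id = meta$gene_id[i],
      region = parse_locus(meta$locus[i]),
      exons = exons[exons$gene_id == meta$gene_id[i], c("start", "end")],
      strand = meta$strand[i]
    )
  })
  names(out) <- meta$gene_id
  out
}
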