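#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [demo_pipeline_config()].
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("pipeline config must set `seed`")
  if (!is.null(cfg$guides)) cfg$guides <- unlist(cfg$guides)
  cfg
}

#' Write a pipeline configuration to YAML
#'
#' The guide-efficiency map is stored as a YAML mapping so guide names
#' survive the round trip.
#'
#' @param config A config list.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  if (!is.null(config$guides)) config$guides <- as.list(config$guides)
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Demonstration pipeline configuration
#'
#' A small, fully seeded two-guide experiment: one simulated tetraploid
#' target region, two RNPs quantified individually and as a twin-RNP
#' multiplex, with an end-to-end report.
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param n_cells Cells per simulated transformation.
#' @return A config list for [run_pipeline()].
#' @export
demo_pipeline_config <- function(seed = 1, n_cells = 10000) {
  list(
    seed = seed,
    ploidy = 4,
    region_len = 600,
    snp_rate = 0.01,
    indel_rate = 0.002,
    n_cells = n_cells,
    guides = c(gX = 0.3, gY = 0.15),
    interaction_gamma = 0,
    amplicon_range = c(150, 500),
    synergy_threshold = 0.02,
    reference_snp_rate = 0.005,
    # peak thresholds relative to the trace maximum: set well below the
    # smallest minor-allele bin worth reporting (~1% molar fraction) while
    # staying >5x above the default simulated noise
    min_height_frac = 0.005,
    min_area_frac = 0.002
  )
}

# map positions on the gapless reference to alignment columns
ref_to_alignment <- function(alleles) {
  which(strsplit(alleles$reference, "")[[1]] != "-")
}

#' Run the full simulate-design-quantify-stats pipeline
#'
#' Executes the stages in order against one seeded synthetic experiment:
#' (1) simulate aligned tetraploid haplotypes and call inter-allelic
#' variants; (2) scan the reference for PAM sites, flag allele consensus,
#' pick one cut site per configured guide and design a
#' polymorphism-avoiding diagnostic primer pair; (3) simulate single-RNP
#' editing outcomes and traces for each guide and quantify them; (4)
#' simulate the twin-RNP multiplex, quantify it, screen for the dual-cut
#' deletion and compute synergy and full-allelic screening estimates.
#' Intermediate files (FASTA, variant TSV, trace CSVs) and a JSON report
#' are written under `out_dir`; on a stage failure, partial outputs are
#' moved under a `failed/` prefix and the error names the stage.
#'
#' Every stochastic stage derives its RNG state from the single config seed
#' via fixed per-stage offsets, so a rerun with the same config reproduces
#' the report byte for byte.
#'
#' @param config A config list (see [demo_pipeline_config()] /
#'   [read_pipeline_config()]).
#' @param out_dir Output directory (created if needed).
#' @return The report, invisibly (also written to `out_dir/report.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  cfg_hash <- rlang::hash(config)
  note <- function(stage, msg) {
    line <- sprintf("[%s] seed=%d config=%s %s", stage, config$seed,
                    cfg_hash, msg)
    log_lines <<- c(log_lines, line)
  }
  current_stage <- "init"
  run_stage <- function(name, expr) {
    current_stage <<- name
    tryCatch(expr, error = function(e) {
      failed <- file.path(out_dir, "failed")
      dir.create(failed, showWarnings = FALSE)
      produced <- setdiff(list.files(out_dir, full.names = TRUE), failed)
      file.rename(produced, file.path(failed, basename(produced)))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  guides <- config$guides
  if (length(guides) != 2L || is.null(names(guides))) {
    stop("`config$guides` must be a named vector of two per-allele efficiencies")
  }

  # -- stage 1: simulate target region, call variants ----------------------
  sim <- run_stage("simulate", {
    base_cfg <- simulation_config(
      seed = config$seed, ploidy = config$ploidy,
      region_len = config$region_len, snp_rate = config$snp_rate,
      indel_rate = config$indel_rate, n_cells = config$n_cells,
      guide_efficiencies = guides,
      interaction_gamma = config$interaction_gamma %||% 0
    )
    hap <- simulate_haplotypes(base_cfg)
    write_allele_fasta(hap$alleles, file.path(out_dir, "alleles.fasta"))
    variants <- call_variants(hap$alleles)
    write_variant_tsv(variants, file.path(out_dir, "variants.tsv"))
    note("simulate", sprintf("%d variants over %d alignment columns",
                             nrow(variants), hap$alleles$alignment_length))
    list(cfg = base_cfg, alleles = hap$alleles, truth = hap$truth,
         variants = variants)
  })

  # -- stage 2: guide placement + diagnostic primers -----------------------
  design <- run_stage("design", {
    ref_gapless <- gsub("-", "", sim$alleles$reference, fixed = TRUE)
    sites <- scan_pam_sites(ref_gapless)
    if (nrow(sites) < 2L) stop("fewer than two PAM sites in the region")
    col_map <- ref_to_alignment(sim$alleles)
    sites_aln <- sites
    for (col in c("proto_start", "proto_end", "pam_start", "pam_end",
                  "cut_position")) {
      sites_aln[[col]] <- col_map[sites[[col]]]
    }
    sites_aln <- filter_allele_consensus(sites_aln, sim$variants)
    consensus <- sites_aln[sites_aln$allele_consensus, ]
    if (nrow(consensus) < 2L) stop("fewer than two allele-consensus sites")
    L <- nchar(ref_gapless)
    pick <- function(target) which.min(abs(consensus$cut_position - target))
    i1 <- pick(col_map[round(L / 3)])
    i2 <- pick(col_map[round(2 * L / 3)])
    if (i1 == i2) i2 <- if (i1 < nrow(consensus)) i1 + 1L else i1 - 1L
    chosen <- consensus[sort(c(i1, i2)), ]
    chosen$guide_id <- names(guides)
    cuts_aln <- chosen$cut_position
    # deletion size in amplicon bp = gapless reference distance between cuts
    dual_del <- diff(range(match(cuts_aln, col_map)))
    primers <- design_primers(sim$alleles, sim$variants, cut_sites = cuts_aln,
                              amplicon_range = config$amplicon_range %||%
                                c(150, 500))
    if (nrow(primers) == 0L) {
      stop("no feasible diagnostic primer pair: ",
           attr(primers, "failure_report")$reason)
    }
    pair <- primers[1, ]
    note("design", sprintf(
      "%d PAM sites (%d consensus); guides at cuts %d/%d; amplicon %d bp",
      nrow(sites), nrow(consensus), cuts_aln[1], cuts_aln[2],
      pair$amplicon_size_ref))
    list(sites = sites_aln, chosen = chosen, dual_del = dual_del,
         pair = pair, wt_size = pair$amplicon_size_ref)
  })

  # -- stage 3: single-RNP quantification ----------------------------------
  singles <- run_stage("quantify", {
    lapply(seq_along(guides), function(i) {
      g <- names(guides)[i]
      cfg_g <- simulation_config(
        seed = config$seed + 100L * i, ploidy = config$ploidy,
        region_len = config$region_len, n_cells = config$n_cells,
        guide_efficiencies = guides[i],
        spectra = sim$cfg$spectra[g],
        wt_size = design$wt_size
      )
      out <- simulate_editing_outcomes(cfg_g)
      trace <- simulate_trace(out$truth$spectrum, cfg_g)
      write_trace_csv(trace, file.path(out_dir, paste0("trace_", g, ".csv")))
      res <- quantify_trace(trace, expected_wt_size = design$wt_size,
                            min_height_frac = config$min_height_frac %||% 0.005,
                            min_area_frac = config$min_area_frac %||% 0.002)
      note("quantify", sprintf("%s: estimated %.3f (true %.3f)", g,
                               res$efficiency, out$truth$pooled_efficiency))
      list(guide = g, true_efficiency = out$truth$pooled_efficiency,
           estimated_efficiency = res$efficiency,
           true_full_allelic = out$truth$full_allelic_fraction)
    })
  })

  # -- stage 4: multiplex + statistics -------------------------------------
  stats_out <- run_stage("stats", {
    cfg_m <- simulation_config(
      seed = config$seed + 999L, ploidy = config$ploidy,
      region_len = config$region_len, n_cells = config$n_cells,
      guide_efficiencies = guides, spectra = sim$cfg$spectra,
      interaction_gamma = config$interaction_gamma %||% 0,
      dual_cut_distance = design$dual_del, wt_size = design$wt_size
    )
    out_m <- simulate_editing_outcomes(cfg_m)
    trace_m <- simulate_trace(out_m$truth$spectrum, cfg_m)
    write_trace_csv(trace_m, file.path(out_dir, "trace_multiplex.csv"))
    res_m <- quantify_trace(trace_m, expected_wt_size = design$wt_size,
                            expected_deletion = design$dual_del,
                            min_height_frac = config$min_height_frac %||% 0.005,
                            min_area_frac = config$min_area_frac %||% 0.002)
    e_est <- vapply(singles, `[[`, 0, "estimated_efficiency")
    syn <- synergy(e_est[1], e_est[2], res_m$efficiency,
                   threshold = config$synergy_threshold %||% 0.02,
                   guide_ids = names(guides))
    pf <- per_allele_to_full(e_est, config$ploidy)
    fa <- full_allelic(pf)
    note("stats", sprintf("multiplex observed %.3f vs theoretical %.3f (%s)",
                          syn$observed_total, syn$theoretical,
                          syn$classification))
    list(multiplex = syn, multiplex_true = out_m$truth$pooled_efficiency,
         dual_cut = res_m$dual_cut,
         dual_cut_true = spectrum_fraction(out_m$truth$spectrum,
                                           -design$dual_del),
         full_allelic = fa)
  })

  prev <- prevalence_fold(sim$variants, config$region_len,
                          config$reference_snp_rate %||% 0.005)
  report <- list(
    schema_version = "1.0",
    tool_version = as.character(utils::packageVersion("polyedit")),
    seed = config$seed,
    config_hash = cfg_hash,
    config = config,
    region = list(
      region_id = sim$alleles$region_id,
      alignment_length = sim$alleles$alignment_length,
      n_snps = prev$snp_count,
      n_indels = prev$indel_count,
      snp_rate = prev$snp_rate,
      fold_vs_reference = prev$fold_vs_reference
    ),
    design = list(
      guide_cut_positions = design$chosen$cut_position,
      dual_cut_deletion_bp = design$dual_del,
      amplicon_size_ref = design$pair$amplicon_size_ref,
      amplicon_size_per_allele = design$pair$amplicon_size_per_allele[[1]],
      forward = design$pair$forward,
      reverse = design$pair$reverse
    ),
    guides = lapply(singles, function(s) {
      list(guide = s$guide,
           estimated_efficiency_pct = round(100 * s$estimated_efficiency, 1),
           true_efficiency_pct = round(100 * s$true_efficiency, 1))
    }),
    multiplex = list(
      observed_total_pct = round(100 * stats_out$multiplex$observed_total, 1),
      theoretical_pct = round(100 * stats_out$multiplex$theoretical, 1),
      synergy_pct = round(100 * stats_out$multiplex$synergy, 1),
      classification = stats_out$multiplex$classification,
      dual_cut_present = stats_out$dual_cut$present,
      dual_cut_fraction = stats_out$dual_cut$fraction
    ),
    full_allelic = list(
      per_guide_full_rate = stats_out$full_allelic$per_gene_full_rate,
      p_all = stats_out$full_allelic$p_all,
      plants_per_hit = stats_out$full_allelic$plants_per_hit
    ),
    log = log_lines
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(report)
}

#' Validate pipeline input files without running stages
#'
#' Checks the schema of every supplied input and reports all violations,
#' not just the first.
#'
#' @param manifest Named list of file paths; recognized names are
#'   `alleles_fasta`, `traces` (character vector), `rank_table`,
#'   `exons_tsv`.
#' @return A tibble (`input`, `path`, `status`, `message`) with one row per
#'   check; `status` is `"ok"` or `"violation"`.
#' @export
validate_inputs <- function(manifest) {
  rows <- list()
  add <- function(input, path, status, message = "") {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      input = input, path = path, status = status, message = message)
  }
  check <- function(input, path, reader) {
    if (!file.exists(path)) {
      add(input, path, "violation", "file does not exist")
      return()
    }
    tryCatch({
      reader(path)
      add(input, path, "ok")
    }, error = function(e) {
      add(input, path, "violation", conditionMessage(e))
    })
  }
  if (!is.null(manifest$alleles_fasta)) {
    check("alleles_fasta", manifest$alleles_fasta, read_allele_fasta)
  }
  for (tr in manifest$traces %||% character()) {
    check("trace", tr, read_trace_csv)
  }
  if (!is.null(manifest$rank_table)) {
    check("rank_table", manifest$rank_table, load_rank_table)
  }
  if (!is.null(manifest$exons_tsv)) {
    check("exons_tsv", manifest$exons_tsv, read_exon_tsv)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- tibble::tibble(input = character(), path = character(),
                          status = character(), message = character())
  }
  out
}
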