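#' Simulation configuration for the synthetic-data generator
#'
#' One config object drives all three generators ([simulate_haplotypes()],
#' [simulate_editing_outcomes()], [simulate_trace()]) so that a single seed
#' reproduces a whole synthetic experiment.  Defaults emulate a tetraploid
#' potato protoplast editing experiment: 4 haplotypes, a ~600 bp target
#' region with elevated inter-allelic SNP density, per-allele Bernoulli
#' cutting with guide-specific indel spectra dominated by one characteristic
#' indel, and capillary traces with sub-bp peak width and modest noise.
#'
#' @param seed Integer seed; every generator derives its RNG state from it
#'   (plus a fixed per-operation offset, so the generators are independent
#'   but jointly reproducible).
#' @param ploidy Haplotypes per cell (default 4).
#' @param region_len Target-region length in bp (default 600).
#' @param snp_rate Per-bp per-haplotype SNP probability (default 0.01).
#' @param indel_rate Per-bp per-haplotype indel probability (default 0.002).
#' @param indel_len_geom_p Geometric length parameter for indel lengths
#'   (default 0.5; lengths capped at 8 bp).
#' @param n_cells Cells per simulated transformation (default 10000).
#' @param guide_efficiencies Named vector of per-allele editing
#'   probabilities, one or two guides (default `c(g1 = 0.3)`).
#' @param spectra Named list of per-guide edit-outcome spectra (tibbles with
#'   `delta`, `weight`, nonzero deltas); `NULL` uses
#'   [default_guide_spectra()].
#' @param interaction_gamma Multiplicative perturbation of the joint-cut
#'   probability for twin-RNP simulations: `P(both cut) = e1*e2*(1+gamma)`,
#'   clipped into the Frechet bounds (default 0 = independence).
#' @param dual_cut_distance Deletion size (bp) for alleles cut by both
#'   guides (required for two-guide simulations).
#' @param wt_size Wild-type amplicon size in bp (default 321).
#' @param trace_noise_sd I.i.d. Gaussian trace noise, RFU (default 2).
#' @param peak_sigma_bp Gaussian peak width (sd) in bp (default 0.15, a
#'   full width at half maximum of ~0.35 bp — capillary electrophoresis
#'   baseline-resolves single-bp size differences).
#' @param trace_total_area Total integrated signal of a trace (default 1000).
#' @param grid_bp Trace sampling grid (default 0.1 bp).
#' @param baseline_intercept,baseline_slope Optional sloped baseline added
#'   to traces (default 0).
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(seed, ploidy = 4, region_len = 600,
                              snp_rate = 0.01, indel_rate = 0.002,
                              indel_len_geom_p = 0.5, n_cells = 10000,
                              guide_efficiencies = c(g1 = 0.3),
                              spectra = NULL, interaction_gamma = 0,
                              dual_cut_distance = NULL, wt_size = 321,
                              trace_noise_sd = 2, peak_sigma_bp = 0.15,
                              trace_total_area = 1000, grid_bp = 0.1,
                              baseline_intercept = 0, baseline_slope = 0) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  rates <- c(snp_rate, indel_rate, indel_len_geom_p, guide_efficiencies)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (n_cells < 1) stop("`n_cells` must be >= 1")
  if (peak_sigma_bp <= 0) stop("`peak_sigma_bp` must be > 0")
  if (ploidy < 1) stop("`ploidy` must be >= 1")
  if (is.null(names(guide_efficiencies))) {
    names(guide_efficiencies) <- paste0("g", seq_along(guide_efficiencies))
  }
  if (is.null(spectra)) {
    spectra <- default_guide_spectra(names(guide_efficiencies))
  }
  structure(
    list(seed = as.integer(seed), ploidy = as.integer(ploidy),
         region_len = as.integer(region_len), snp_rate = snp_rate,
         indel_rate = indel_rate, indel_len_geom_p = indel_len_geom_p,
         n_cells = as.integer(n_cells),
         guide_efficiencies = guide_efficiencies, spectra = spectra,
         interaction_gamma = interaction_gamma,
         dual_cut_distance = dual_cut_distance, wt_size = wt_size,
         trace_noise_sd = trace_noise_sd, peak_sigma_bp = peak_sigma_bp,
         trace_total_area = trace_total_area, grid_bp = grid_bp,
         baseline_intercept = baseline_intercept,
         baseline_slope = baseline_slope),
    class = "sim_config"
  )
}

# derive a sub-seed; keeps the generators decoupled but reproducible
sub_seed <- function(config, offset) {
  as.integer((as.numeric(config$seed) + offset) %% .Machine$integer.max)
}

#' Default guide-specific indel spectra
#'
#' Each guide gets a categorical edit-outcome distribution over small indels
#' `{-3, -1, +1, -2}` with one dominant characteristic indel (weights 0.85 /
#' 0.10 / 0.05), rotating the dominant class across guides — emulating the
#' observation that individual gRNAs confer reproducible, guide-specific
#' indel patterns (e.g. one guide favouring a 3 bp deletion, another 1 bp
#' indels).  These are configuration, not hard-coded biology: supply your
#' own via `simulation_config(spectra = ...)`.
#'
#' @param guide_ids Character vector of guide names.
#' @return Named list of tibbles (`delta`, `weight`).
#' @export
default_guide_spectra <- function(guide_ids) {
  pool <- list(c(-3, -1, +1), c(-1, +1, -2), c(+1, -1, -3), c(-2, -3, -1))
  out <- lapply(seq_along(guide_ids), function(i) {
    tibble::tibble(delta = pool[[(i - 1L) %% 4L + 1L]],
                   weight = c(0.85, 0.10, 0.05))
  })
  names(out) <- guide_ids
  out
}

#' Simulate aligned tetraploid haplotypes with known variants
#'
#' Draws a uniform-random reference and injects SNPs, deletions and
#' insertions into the haplotypes at the configured per-bp rates.  Event
#' sites are placed with a minimum mutual separation (longest indel + 2 bp)
#' and away from the region edges, so the returned gapped alignment is
#' unambiguous and [call_variants()] can recover the injected truth exactly.
#' Rates summing above 0.3 are refused (the alignment assumption breaks
#' down at that divergence).
#'
#' @param config A `sim_config`.
#' @return A list: `alleles` (an [allele_set()]) and `truth` (a tibble with
#'   the injected events in [call_variants()] record convention: `position`
#'   = alignment column, `kind`, `length`, `allele_id` — `NA` for SNP
#'   records — plus `carrier`, the haplotype the event was injected into).
#' @export
simulate_haplotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config, 11))
  if (config$snp_rate + config$indel_rate > 0.3) {
    stop("snp_rate + indel_rate > 0.3: divergence too high for an ",
         "unambiguous alignment")
  }
  L <- config$region_len
  P <- config$ploidy
  bases <- c("A", "C", "G", "T")
  ref0 <- sample(bases, L, replace = TRUE)

  # indel events need mutual spacing (longest indel + 2 bp) so gap runs never
  # merge or share an insertion junction; SNPs only need to avoid indel spans
  n_ind <- stats::rbinom(1L, L * P, config$indel_rate)
  ind_len <- if (n_ind) {
    pmin(stats::rgeom(n_ind, config$indel_len_geom_p) + 1L, 8L)
  } else integer()
  max_len <- max(c(ind_len, 1L))
  min_gap <- max_len + 2L
  ind_pos <- integer(0)
  for (p in sample(seq(3L, L - max_len - 3L))) {
    if (length(ind_pos) == n_ind) break
    if (!length(ind_pos) || all(abs(ind_pos - p) > min_gap)) {
      ind_pos <- c(ind_pos, p)
    }
  }
  if (length(ind_pos) < n_ind) {
    stop("could not place ", n_ind, " spaced indels in ", L,
         " bp; lower the rates or enlarge the region")
  }
  hap_names <- paste0("allele", seq_len(P))
  ind_hap <- sample(seq_len(P), n_ind, replace = TRUE)
  ind_kind <- sample(c("deletion", "insertion"), n_ind, replace = TRUE)

  blocked <- unique(unlist(mapply(function(p, l) (p - 1L):(p + l),
                                  ind_pos, ind_len, SIMPLIFY = FALSE)))
  free <- setdiff(seq(2L, L - 1L), blocked)
  snp_pos <- integer(0)
  snp_hap <- integer(0)
  for (h in seq_len(P)) {
    k <- min(stats::rbinom(1L, L, config$snp_rate), length(free))
    ph <- sample(free, k)
    snp_pos <- c(snp_pos, ph)
    snp_hap <- c(snp_hap, rep(h, k))
  }
  n_snp <- length(snp_pos)
  snp_alt <- vapply(snp_pos, function(p) sample(setdiff(bases, ref0[p]), 1L), "")

  # alignment layout: each insertion opens `len` gap columns after its site
  ins_after <- integer(L)
  is_ins <- ind_kind == "insertion"
  ins_after[ind_pos[is_ins]] <- ind_len[is_ins]
  col_end <- cumsum(1L + ins_after)
  col_of <- col_end - ins_after  # alignment column of each reference base
  A <- L + sum(ins_after)

  ref_aln <- rep("-", A)
  ref_aln[col_of] <- ref0
  hap_mat <- matrix(rep(ref_aln, P), nrow = P, byrow = TRUE,
                    dimnames = list(hap_names, NULL))
  for (i in seq_len(n_snp)) {
    hap_mat[snp_hap[i], col_of[snp_pos[i]]] <- snp_alt[i]
  }
  for (i in seq_len(n_ind)) {
    p <- ind_pos[i]
    l <- ind_len[i]
    if (ind_kind[i] == "deletion") {
      hap_mat[ind_hap[i], col_of[p:(p + l - 1L)]] <- "-"
    } else {
      hap_mat[ind_hap[i], col_of[p] + seq_len(l)] <-
        sample(bases, l, replace = TRUE)
    }
  }

  # truth in call_variants record convention: SNP columns are single records
  # even when several haplotypes share them; indels are per-haplotype events
  snp_truth <- if (n_snp) {
    carriers <- split(hap_names[snp_hap], snp_pos)
    cols <- as.integer(names(carriers))
    tibble::tibble(
      position = as.numeric(col_of[cols]), kind = "SNP", length = 1,
      allele_id = NA_character_,
      carrier = vapply(carriers, paste, "", collapse = ","))
  } else NULL
  ind_truth <- if (n_ind) {
    tibble::tibble(
      position = as.numeric(ifelse(ind_kind == "deletion", col_of[ind_pos],
                                   col_of[ind_pos] + 1)),
      kind = ind_kind, length = as.numeric(ind_len),
      allele_id = hap_names[ind_hap], carrier = hap_names[ind_hap])
  } else NULL
  truth <- rbind(snp_truth, ind_truth)
  if (is.null(truth)) {
    truth <- tibble::tibble(position = numeric(), kind = character(),
                            length = numeric(), allele_id = character(),
                            carrier = character())
  }
  truth <- truth[order(truth$position, truth$kind), ]

  alleles <- allele_set(
    region_id = paste0("sim", config$seed),
    haplotypes = apply(hap_mat, 1L, paste, collapse = ""),
    reference = paste(ref_aln, collapse = "")
  )
  list(alleles = alleles, truth = truth)
}

sample_spectrum_delta <- function(spectrum, k) {
  if (any(spectrum$delta == 0)) stop("edit-outcome spectra must exclude delta = 0")
  if (k == 0L) return(numeric())
  spectrum$delta[sample.int(nrow(spectrum), k, replace = TRUE,
                            prob = spectrum$weight)]
}

#' Simulate per-cell, per-allele editing outcomes
#'
#' Each allele of each cell is cut by guide g with probability `e_g`.  With
#' two active guides the joint-cut probability is `e1*e2*(1+gamma)` (clipped
#' into its feasible range, with a warning when clipping occurs); alleles
#' cut by both guides lose the inter-cut fragment
#' (`delta = -dual_cut_distance`), alleles cut by a single guide draw their
#' size change from that guide's spectrum, uncut alleles keep `delta = 0`.
#'
#' @param config A `sim_config` with 1 or 2 entries in
#'   `guide_efficiencies` (two-guide runs require `dual_cut_distance`).
#' @return A list: `outcomes` (tibble `cell`, `allele`, `delta`, plus one
#'   logical cut column per guide) and `truth` (list with
#'   `pooled_efficiency` — the edited-amplicon molar fraction,
#'   `full_allelic_fraction`, and `spectrum`, the realized
#'   [indel_spectrum()]).
#' @export
simulate_editing_outcomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config, 23))
  e <- config$guide_efficiencies
  if (!length(e) || length(e) > 2L) stop("1 or 2 active guides are supported")
  n <- config$n_cells * config$ploidy
  delta <- numeric(n)
  if (length(e) == 1L) {
    cut1 <- stats::runif(n) < e[1]
    delta[cut1] <- sample_spectrum_delta(config$spectra[[names(e)[1]]],
                                         sum(cut1))
    cuts <- tibble::tibble(cut1)
    names(cuts) <- paste0("cut_", names(e)[1])
  } else {
    if (is.null(config$dual_cut_distance)) {
      stop("two-guide simulations require `dual_cut_distance`")
    }
    p11_raw <- e[1] * e[2] * (1 + config$interaction_gamma)
    lo <- max(0, e[1] + e[2] - 1)
    hi <- min(e[1], e[2])
    p11 <- min(max(p11_raw, lo), hi)
    if (abs(p11 - p11_raw) > 1e-12) {
      warning("interaction_gamma pushes the joint-cut probability out of ",
              "range; clipped to ", signif(p11, 4))
    }
    u <- stats::runif(n)
    both <- u < p11
    only1 <- !both & u < e[1]
    only2 <- !both & !only1 & u < e[1] + e[2] - p11
    delta[both] <- -config$dual_cut_distance
    delta[only1] <- sample_spectrum_delta(config$spectra[[names(e)[1]]],
                                          sum(only1))
    delta[only2] <- sample_spectrum_delta(config$spectra[[names(e)[2]]],
                                          sum(only2))
    cuts <- tibble::tibble(both | only1, both | only2)
    names(cuts) <- paste0("cut_", names(e))
  }
  outcomes <- tibble::tibble(
    cell = rep(seq_len(config$n_cells), each = config$ploidy),
    allele = rep(seq_len(config$ploidy), times = config$n_cells)
  )
  outcomes$delta <- delta
  outcomes <- cbind(outcomes, cuts)
  edited <- delta != 0
  full_allelic_fraction <- mean(
    rowSums(matrix(edited, ncol = config$ploidy, byrow = TRUE)) ==
      config$ploidy)
  tab <- table(delta)
  truth <- list(
    pooled_efficiency = mean(edited),
    full_allelic_fraction = full_allelic_fraction,
    spectrum = indel_spectrum(as.numeric(names(tab)), as.numeric(tab),
                              wt_size = config$wt_size)
  )
  list(outcomes = tibble::as_tibble(outcomes), truth = truth)
}

#' Simulate a size-calibrated fragment-analysis trace
#'
#' Renders an indel spectrum as a chromatogram: one Gaussian per distinct
#' amplicon size with area proportional to molar fraction (no
#' length-dependent fluorescence correction, matching the quantification
#' module's molar assumption), on a 0.1 bp grid, plus i.i.d. Gaussian noise
#' and an optional sloped baseline.
#'
#' @param spectrum An [indel_spectrum()], or any tibble with `delta` and
#'   `fraction`.
#' @param config A `sim_config` (supplies peak width, noise, grid, total
#'   area, baseline).
#' @param wt_size Wild-type amplicon size (default `config$wt_size`; must
#'   exceed the largest deletion).
#' @return A trace tibble (`size_bp`, `signal`) with the
#'   `expected_wt_size` attribute set.
#' @export
simulate_trace <- function(spectrum, config, wt_size = config$wt_size) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config, 37))
  if (wt_size <= -min(spectrum$delta)) {
    stop("`wt_size` must exceed the largest deletion in the spectrum")
  }
  sizes <- wt_size + spectrum$delta
  grid <- seq(min(sizes) - 8, max(sizes) + 8, by = config$grid_bp)
  signal <- numeric(length(grid))
  for (k in seq_along(sizes)) {
    signal <- signal + spectrum$fraction[k] * config$trace_total_area *
      stats::dnorm(grid, mean = sizes[k], sd = config$peak_sigma_bp)
  }
  signal <- signal + config$baseline_intercept +
    config$baseline_slope * (grid - grid[1]) +
    stats::rnorm(length(grid), 0, config$trace_noise_sd)
  out <- tibble::tibble(size_bp = grid, signal = signal)
  attr(out, "expected_wt_size") <- wt_size
  out
}
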