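#' Theoretical combined editing of two independent RNPs
#'
#' Under independence, the probability that an allele escapes both RNPs is
#' `(1 - e1)(1 - e2)`, so the combined editing fraction is
#' `1 - (1 - e1)(1 - e2) = e1 + e2 - e1*e2`.  This never falls below the
#' better single efficiency (no masking) and is symmetric in its arguments.
#'
#' @param e1,e2 Single-RNP editing fractions in `[0, 1]` (vectorized).
#' @return Combined editing fraction.
#' @export
theoretical_combined <- function(e1, e2) {
  if (any(e1 < 0 | e1 > 1 | e2 < 0 | e2 > 1, na.rm = TRUE)) {
    stop("efficiencies must lie in [0, 1]")
  }
  1 - (1 - e1) * (1 - e2)
}

#' Twin-RNP synergy relative to the independence expectation
#'
#' Compares the observed total editing of a two-RNP transformation with the
#' expectation under independent action ([theoretical_combined()]); the
#' deviation is the synergy.  Classification uses an absolute threshold
#' (default 0.02): `positive` when observed exceeds theoretical by more than
#' the threshold, `negative` when it falls short by more, otherwise `none`.
#' The plain sum `e1 + e2` is available as an alternative estimator
#' (`estimator = "sum"`) but exceeds 1 for large efficiencies and is not the
#' default.
#'
#' @param e1,e2 Single-RNP efficiencies in `[0, 1]`.
#' @param observed_total Observed combined editing fraction in `[0, 1]`.
#' @param threshold Classification threshold (absolute fraction, default
#'   0.02).
#' @param guide_ids Optional length-2 guide labels.
#' @param estimator `"independence"` (default) or `"sum"`.
#' @return A `multiplex_result` list: `guide_ids`, `e1`, `e2`,
#'   `observed_total`, `theoretical`, `synergy` (observed - theoretical),
#'   `classification`.
#' @export
synergy <- function(e1, e2, observed_total, threshold = 0.02,
                    guide_ids = c(NA_character_, NA_character_),
                    estimator = c("independence", "sum")) {
  estimator <- match.arg(estimator)
  if (any(c(e1, e2, observed_total) < 0) || any(c(e1, e2, observed_total) > 1)) {
    stop("all fractions must lie in [0, 1]")
  }
  theo <- if (estimator == "independence") {
    theoretical_combined(e1, e2)
  } else {
    e1 + e2
  }
  syn <- observed_total - theo
  cls <- if (syn > threshold) "positive" else if (syn < -threshold) "negative" else "none"
  structure(
    list(guide_ids = guide_ids, e1 = e1, e2 = e2,
         observed_total = observed_total, theoretical = theo,
         synergy = syn, classification = cls, estimator = estimator),
    class = "multiplex_result"
  )
}

#' @export
print.multiplex_result <- function(x, ...) {
  ids <- if (all(is.na(x$guide_ids))) "" else
    paste0(" ", paste(x$guide_ids, collapse = " + "))
  cat(sprintf(
    "<multiplex_result>%s observed %.1f%% vs theoretical %.1f%% -> synergy %+.1f%% (%s)\n",
    ids, 100 * x$observed_total, 100 * x$theoretical, 100 * x$synergy,
    x$classification))
  invisible(x)
}

#' Full-allelic knockout probability across genes
#'
#' With per-gene full-allelic editing rates (the fraction of cells in which
#' every allele copy of that gene is edited), and independence across genes,
#' the probability that one regenerated plant carries full knockouts of all
#' genes is the product of the rates; the expected screening effort is its
#' reciprocal.  Two genes at 10% each give 1 hit per 100 plants; three give
#' 1 per 1,000.
#'
#' @param per_gene_full_rate Numeric vector of per-gene full-allelic rates
#'   in `[0, 1]`.
#' @return A `full_allelic_model` list: `n_genes`, `per_gene_full_rate`,
#'   `p_all` (product), `plants_per_hit` (exact reciprocal; `Inf` when any
#'   rate is 0) and `plants_per_hit_rounded`.
#' @export
full_allelic <- function(per_gene_full_rate) {
  r <- as.numeric(per_gene_full_rate)
  if (!length(r)) stop("at least one per-gene rate is required")
  if (any(r < 0 | r > 1)) stop("rates must lie in [0, 1]")
  p_all <- prod(r)
  pph <- if (p_all == 0) Inf else 1 / p_all
  structure(
    list(n_genes = length(r), per_gene_full_rate = r, p_all = p_all,
         plants_per_hit = pph,
         plants_per_hit_rounded = if (is.finite(pph)) round(pph) else Inf),
    class = "full_allelic_model"
  )
}

#' @export
print.full_allelic_model <- function(x, ...) {
  cat(sprintf(
    "<full_allelic_model> %d gene(s), p(all) = %.4g -> 1 hit per %s plants\n",
    x$n_genes, x$p_all,
    if (is.finite(x$plants_per_hit)) format(x$plants_per_hit_rounded,
                                            big.mark = ",") else "Inf"))
  invisible(x)
}

#' Per-allele editing rate to full-allelic rate
#'
#' Assuming alleles within a cell are cut independently with the same
#' per-allele probability, the fraction of cells with all `ploidy` copies
#' edited is `p_allele ^ ploidy` (0.0625 for 50% per-allele editing in a
#' tetraploid).
#'
#' @param p_allele Per-allele editing probability in `[0, 1]` (vectorized).
#' @param ploidy Number of allele copies (>= 1).
#' @return Full-allelic cell fraction.
#' @export
per_allele_to_full <- function(p_allele, ploidy) {
  if (any(p_allele < 0 | p_allele > 1)) stop("`p_allele` must lie in [0, 1]")
  if (any(ploidy < 1)) stop("`ploidy` must be >= 1")
  p_allele^ploidy
}

#' Compare mean editing efficiency between two target regions
#'
#' Two-sided t test on per-gRNA (or per-replicate) mean efficiencies of two
#' regions, e.g. the 5' versus the 3' end of a gene.  The pooled-variance
#' Student form is the default; Welch is available.  Identical zero-variance
#' inputs are degenerate and reported with `t = 0`, `p = 1` and a flag.
#'
#' @param effs_a,effs_b Numeric vectors of efficiencies (length >= 2 each).
#' @param test `"student"` (pooled variance, default) or `"welch"`.
#' @return A `region_comparison` list: `mean_a`, `mean_b`, `mean_ratio`
#'   (`mean_a / mean_b`), `t_stat`, `df`, `p_value`, `test`, `flags`.
#' @export
compare_regions <- function(effs_a, effs_b, test = c("student", "welch")) {
  test <- match.arg(test)
  if (length(effs_a) < 2L || length(effs_b) < 2L) {
    stop("each group needs at least 2 values")
  }
  flags <- character()
  if (stats::sd(c(effs_a, effs_b)) == 0) {
    flags <- "degenerate_zero_variance"
    t_stat <- 0
    df <- length(effs_a) + length(effs_b) - 2
    p <- 1
  } else {
    tt <- stats::t.test(effs_a, effs_b, var.equal = (test == "student"))
    t_stat <- unname(tt$statistic)
    df <- unname(tt$parameter)
    p <- tt$p.value
  }
  structure(
    list(mean_a = mean(effs_a), mean_b = mean(effs_b),
         mean_ratio = mean(effs_a) / mean(effs_b),
         t_stat = t_stat, df = df, p_value = p, test = test, flags = flags),
    class = "region_comparison"
  )
}

#' @export
print.region_comparison <- function(x, ...) {
  cat(sprintf(
    "<region_comparison> mean ratio %.2f (%.3f vs %.3f), %s t = %.2f, p = %.3g\n",
    x$mean_ratio, x$mean_a, x$mean_b, x$test, x$t_stat, x$p_value))
  invisible(x)
}

# all permutations of 1..n (n <= 7), one row per permutation
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

spearman_perm_p <- function(pred, obs, n_perm = 2000) {
  rho <- suppressWarnings(stats::cor(pred, obs, method = "spearman"))
  if (is.na(rho)) return(c(rho = NA_real_, p = NA_real_))
  n <- length(obs)
  perms <- if (n <= 7L) all_perms(n) else NULL
  rhos <- if (!is.null(perms)) {
    apply(perms, 1L, function(ix) {
      suppressWarnings(stats::cor(pred, obs[ix], method = "spearman"))
    })
  } else {
    vapply(seq_len(n_perm), function(i) {
      suppressWarnings(stats::cor(pred, sample(obs), method = "spearman"))
    }, 0)
  }
  rhos <- rhos[!is.na(rhos)]
  p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  c(rho = rho, p = p)
}

#' In-silico versus in-vivo rank concordance
#'
#' For one in-silico prediction method, counts the gRNAs whose predicted
#' rank equals the in-vivo rank (exact matches) and computes Spearman's rho
#' (average-rank tie handling) per target-region group and pooled over all
#' rows.  P-values are two-sided permutation p-values — exact enumeration of
#' all within-group permutations for groups of up to 7 guides, where
#' asymptotic formulas are unreliable.
#'
#' @param table A `rank_table` (see [load_rank_table()]).
#' @param method Name of the in-silico method column.
#' @param n_perm Monte-Carlo permutations for groups larger than 7.
#' @return A `rank_concordance` list: `method`, `matches`, `n`,
#'   `pooled_rho`, and a `groups` tibble (`group`, `n`, `matches`, `rho`,
#'   `p_perm`).
#' @export
rank_concordance <- function(table, method, n_perm = 2000) {
  if (!inherits(table, "rank_table")) table <- load_rank_table(table)
  if (!method %in% attr(table, "methods")) {
    stop("method column `", method, "` not present; available: ",
         paste(attr(table, "methods"), collapse = ", "))
  }
  pred <- table[[method]]
  obs <- table$in_vivo
  groups <- lapply(unique(table$group), function(g) {
    sel <- table$group == g
    rp <- spearman_perm_p(pred[sel], obs[sel], n_perm)
    tibble::tibble(group = g, n = sum(sel),
                   matches = sum(pred[sel] == obs[sel]),
                   rho = unname(rp["rho"]), p_perm = unname(rp["p"]))
  })
  groups <- do.call(rbind, groups)
  structure(
    list(method = method,
         matches = sum(pred == obs),
         n = nrow(table),
         pooled_rho = suppressWarnings(
           stats::cor(pred, obs, method = "spearman")),
         groups = groups),
    class = "rank_concordance"
  )
}

#' @export
print.rank_concordance <- function(x, ...) {
  cat(sprintf(
    "<rank_concordance> %s: %d of %d ranks match in vivo (pooled rho %.2f)\n",
    x$method, x$matches, x$n, x$pooled_rho))
  print(x$groups)
  invisible(x)
}
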