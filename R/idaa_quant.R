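#' Read a size-calibrated fragment trace from CSV
#'
#' Traces arrive size-calibrated: two columns `size_bp` (strictly
#' increasing) and `signal` (relative fluorescence units).  Raw capillary
#' ladder calibration and binary ABIF parsing are out of scope.
#'
#' @param path CSV file with header `size_bp,signal`.
#' @param sample_id Optional sample label stored as an attribute.
#' @param expected_wt_size Optional expected wild-type amplicon size (bp),
#'   stored as an attribute.
#' @return A tibble with columns `size_bp`, `signal`.
#' @export
read_trace_csv <- function(path, sample_id = NULL, expected_wt_size = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("size_bp", "signal") %in% names(df))) {
    stop("trace CSV must have columns `size_bp` and `signal`: ", path)
  }
  validate_trace(df)
  out <- tibble::as_tibble(df[, c("size_bp", "signal")])
  attr(out, "sample_id") <- sample_id
  attr(out, "expected_wt_size") <- expected_wt_size
  out
}

#' Write a fragment trace to CSV
#'
#' @param trace A trace tibble (`size_bp`, `signal`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace[, c("size_bp", "signal")], path, row.names = FALSE)
  invisible(path)
}

validate_trace <- function(trace) {
  if (nrow(trace) >= 2L && any(diff(trace$size_bp) <= 0)) {
    stop("trace `size_bp` must be strictly increasing")
  }
  invisible(trace)
}

rolling_extreme <- function(x, halfwidth, fun) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    fun(x[max(1L, i - halfwidth):min(n, i + halfwidth)])
  }, 0)
}

#' Baseline-correct a fragment trace
#'
#' Estimates the baseline as the rolling minimum of the signal followed by a
#' rolling maximum over the same window (a morphological opening — the
#' rolling minimum alone undershoots near peak flanks), subtracts it, and
#' clips the result at zero.  The opening removes every feature narrower
#' than the window while following offsets and slow baseline drift exactly,
#' so the operation is idempotent: applying it to an already-corrected
#' trace changes nothing (to machine precision) as long as peaks are
#' narrower than the window.
#'
#' @param trace A trace tibble (>= 10 points).
#' @param window_bp Baseline window width in bp (default 20; must exceed the
#'   widest expected peak).
#' @return The corrected trace (attributes preserved).
#' @export
baseline_correct <- function(trace, window_bp = 20) {
  validate_trace(trace)
  if (nrow(trace) < 10L) stop("trace has fewer than 10 points")
  step <- stats::median(diff(trace$size_bp))
  halfwidth <- max(1L, as.integer(round(window_bp / 2 / step)))
  baseline <- rolling_extreme(rolling_extreme(trace$signal, halfwidth, min),
                              halfwidth, max)
  out <- trace
  out$signal <- pmax(trace$signal - baseline, 0)
  out
}

#' Detect amplicon peaks in a baseline-corrected trace
#'
#' Local maxima above `min_height_frac` of the trace maximum are candidate
#' apexes.  Unresolved shoulders — adjacent candidates whose intervening
#' valley stays above `merge_shoulder_frac` of the smaller apex, the
#' signature of capillary stutter within the instrument's resolution — are
#' merged into the larger peak.  Apexes are refined by 3-point parabolic
#' interpolation.  Areas are trapezoidal integrals between flanking minima,
#' truncated where the signal falls below 0.5% of the apex; peaks narrower
#' than `min_fwhm_bp` at half maximum (grid-scale noise spikes) or holding
#' less than `min_area_frac` of the total detected area are discarded.
#'
#' @param trace A baseline-corrected trace tibble.
#' @param min_height_frac Minimum apex height as a fraction of the trace
#'   maximum (default 0.02).
#' @param min_area_frac Minimum peak area as a fraction of total detected
#'   area (default 0.01).
#' @param min_height Absolute minimum apex height in RFU (default 20, an
#'   instrument-style noise floor several times the typical baseline noise;
#'   keeps noise-only traces from yielding peaks, since the fractional
#'   threshold is relative to whatever the trace maximum is).
#' @param merge_shoulder_frac Valley-to-apex ratio above which two candidate
#'   apexes are considered one unresolved peak (default 0.75).
#' @param min_fwhm_bp Minimum full width at half maximum in bp (default 0.2).
#' @return A `peaks` tibble sorted by size: `apex_size`, `height`, `area`,
#'   `width` (FWHM, bp).  Empty, with attribute `flags =
#'   "no_peaks_above_threshold"`, when nothing clears the height threshold.
#' @export
detect_peaks <- function(trace, min_height_frac = 0.02, min_area_frac = 0.01,
                         min_height = 20, merge_shoulder_frac = 0.75,
                         min_fwhm_bp = 0.2) {
  validate_trace(trace)
  x <- trace$size_bp
  y <- trace$signal
  n <- length(y)
  empty <- tibble::tibble(apex_size = numeric(), height = numeric(),
                          area = numeric(), width = numeric())
  if (n < 3L || max(y) <= 0) {
    attr(empty, "flags") <- "no_peaks_above_threshold"
    return(empty)
  }
  thr <- max(min_height_frac * max(y), min_height)
  apex <- which(y[-c(1, n)] >= y[-c(n - 1, n)] & y[-c(1, n)] > y[-c(1, 2)]) + 1L
  apex <- apex[y[apex] >= thr]
  if (!length(apex)) {
    attr(empty, "flags") <- "no_peaks_above_threshold"
    return(empty)
  }

  # merge unresolved shoulders into their larger neighbour
  repeat {
    if (length(apex) < 2L) break
    valley <- vapply(seq_len(length(apex) - 1L), function(i) {
      min(y[apex[i]:apex[i + 1L]])
    }, 0)
    ratio <- valley / pmin(y[apex[-length(apex)]], y[apex[-1]])
    i <- which.max(ratio)
    if (ratio[i] <= merge_shoulder_frac) break
    drop <- if (y[apex[i]] < y[apex[i + 1L]]) i else i + 1L
    apex <- apex[-drop]
  }

  # integration bounds: flanking minima, truncated where the signal falls to
  # 0.5% of the apex or to the residual noise floor (trace median), and never
  # further than 3 bp from the apex; the integrand is the signal above that
  # floor, so stretches of corrected baseline noise do not accrue into areas
  k <- length(apex)
  sep <- vapply(seq_len(max(k - 1L, 0L)), function(i) {
    apex[i] + which.min(y[apex[i]:apex[i + 1L]]) - 1L
  }, 0L)
  lo <- c(1L, sep)
  hi <- c(sep, n)
  floor_frac <- 0.005
  noise_floor <- stats::median(y)
  step <- if (n > 1L) stats::median(diff(x)) else 1
  cap <- max(1L, as.integer(round(3 / step)))
  bounds <- lapply(seq_len(k), function(i) {
    a <- apex[i]
    fl <- max(floor_frac * y[a], noise_floor)
    l <- a
    while (l > max(lo[i], a - cap) && y[l - 1L] > fl) l <- l - 1L
    r <- a
    while (r < min(hi[i], a + cap) && y[r + 1L] > fl) r <- r + 1L
    # one point past the floor crossing so the tail trapezoid is kept
    c(max(lo[i], l - 1L), min(hi[i], r + 1L))
  })
  area <- vapply(seq_len(k), function(i) {
    idx <- bounds[[i]][1]:bounds[[i]][2]
    if (length(idx) < 2L) return(0)
    pracma::trapz(x[idx], pmax(y[idx] - noise_floor, 0))
  }, 0)

  # FWHM and parabolic apex refinement
  fwhm <- vapply(seq_len(k), function(i) {
    a <- apex[i]
    half <- y[a] / 2
    l <- a
    while (l > bounds[[i]][1] && y[l] > half) l <- l - 1L
    r <- a
    while (r < bounds[[i]][2] && y[r] > half) r <- r + 1L
    x[r] - x[l]
  }, 0)
  apex_size <- vapply(seq_len(k), function(i) {
    a <- apex[i]
    if (a <= 1L || a >= n) return(x[a])
    y1 <- y[a - 1L]; y2 <- y[a]; y3 <- y[a + 1L]
    denom <- y1 - 2 * y2 + y3
    if (denom == 0) return(x[a])
    x[a] + 0.5 * (y1 - y3) / denom * (x[a + 1L] - x[a])
  }, 0)

  out <- tibble::tibble(apex_size = apex_size, height = y[apex],
                        area = area, width = fwhm)
  out <- out[out$width >= min_fwhm_bp & out$area > 0, ]
  if (nrow(out)) {
    out <- out[out$area >= min_area_frac * sum(out$area), ]
  }
  if (!nrow(out)) attr(out, "flags") <- "no_peaks_above_threshold"
  out[order(out$apex_size), ]
}

#' Construct / validate an indel spectrum
#'
#' An indel spectrum maps the signed amplicon size change `delta` (bp; 0 =
#' wild type) to molar fraction, anchored at the wild-type amplicon size.
#' Fractions are normalized to sum to one and a `delta = 0` entry is always
#' present (possibly 0).
#'
#' @param delta Integer size changes (bp).
#' @param fraction Non-negative weights (normalized internally).
#' @param wt_size Wild-type amplicon size in bp.
#' @return An `indel_spectrum` tibble (`delta`, `fraction`) with attribute
#'   `wt_size`.
#' @export
indel_spectrum <- function(delta, fraction, wt_size = NA_real_) {
  if (length(delta) != length(fraction)) stop("lengths differ")
  if (any(fraction < 0)) stop("fractions must be >= 0")
  if (any(delta != round(delta))) stop("`delta` must be integer bp")
  tot <- sum(fraction)
  if (tot <= 0) stop("spectrum has zero total weight")
  agg <- tapply(fraction / tot, delta, sum)
  delta <- as.numeric(names(agg))
  fraction <- as.numeric(agg)
  if (!any(delta == 0)) {
    delta <- c(delta, 0)
    fraction <- c(fraction, 0)
  }
  ord <- order(delta)
  out <- tibble::tibble(delta = delta[ord], fraction = fraction[ord])
  attr(out, "wt_size") <- wt_size
  class(out) <- c("indel_spectrum", class(out))
  out
}

#' Molar fraction of a spectrum bin
#'
#' @param spectrum An `indel_spectrum`.
#' @param delta Size-change bin (bp).
#' @return The fraction (0 if the bin is absent).
#' @export
spectrum_fraction <- function(spectrum, delta) {
  i <- match(delta, spectrum$delta)
  ifelse(is.na(i), 0, spectrum$fraction[i])
}

#' Bin called peaks into an indel spectrum
#'
#' The wild-type peak is the called peak whose apex lies within
#' `size_tolerance` of `expected_wt_size` (nearest apex wins; an exact tie
#' goes to the larger area).  Every peak is then binned to the nearest
#' integer size change relative to the wild-type apex (or to
#' `expected_wt_size` when no wild-type peak is present), and fractions are
#' peak areas over total area.
#'
#' @param peaks A `peaks` tibble from [detect_peaks()].
#' @param expected_wt_size Expected wild-type amplicon size (bp).
#' @param size_tolerance Wild-type matching tolerance in bp (default 0.5).
#' @param allow_empty If `TRUE`, an empty peak table is interpreted as an
#'   unedited sample (spectrum `{0: 1}` flagged `"no_peaks_assumed_wt"`)
#'   rather than an error.
#' @return An `indel_spectrum`; attribute `flags` carries quality warnings
#'   (`"no_wt_peak"` when all signal is in indel peaks).
#' @export
assign_spectrum <- function(peaks, expected_wt_size, size_tolerance = 0.5,
                            allow_empty = FALSE) {
  flags <- character()
  if (nrow(peaks) == 0L) {
    if (!allow_empty) {
      stop("no peaks to assign; pass `allow_empty = TRUE` to interpret an ",
           "empty trace as unedited")
    }
    sp <- indel_spectrum(0, 1, wt_size = expected_wt_size)
    attr(sp, "flags") <- "no_peaks_assumed_wt"
    return(sp)
  }
  dist <- abs(peaks$apex_size - expected_wt_size)
  cand <- which(dist <= size_tolerance)
  if (length(cand)) {
    best <- cand[order(dist[cand], -peaks$area[cand])][1]
    anchor <- peaks$apex_size[best]
  } else {
    anchor <- expected_wt_size
    flags <- c(flags, "no_wt_peak")
  }
  delta <- round(peaks$apex_size - anchor)
  sp <- indel_spectrum(delta, peaks$area, wt_size = expected_wt_size)
  if (length(flags)) attr(sp, "flags") <- flags
  sp
}

#' Pooled editing efficiency from an indel spectrum
#'
#' Editing efficiency of "all alleles in the cell pool" is defined
#' operationally as the non-wild-type molar fraction of amplicons:
#' `efficiency = 1 - fraction(delta = 0)`.
#'
#' @param spectrum An `indel_spectrum`.
#' @param sample_id Optional sample label.
#' @return An `editing_result` list: `sample_id`, `efficiency` (in
#'   `[0, 1]`), `spectrum`, `n_peaks` (spectrum bins with non-zero
#'   fraction), `flags`.
#' @export
editing_efficiency <- function(spectrum, sample_id = NA_character_) {
  stopifnot(inherits(spectrum, "indel_spectrum"))
  eff <- 1 - spectrum_fraction(spectrum, 0)
  structure(
    list(sample_id = sample_id,
         efficiency = min(max(eff, 0), 1),
         spectrum = spectrum,
         n_peaks = sum(spectrum$fraction > 0),
         flags = attr(spectrum, "flags") %||% character()),
    class = "editing_result"
  )
}

#' @export
print.editing_result <- function(x, ...) {
  cat("<editing_result>", if (!is.na(x$sample_id)) x$sample_id else "",
      sprintf(" efficiency %.1f%% over %d peak(s)\n",
              100 * x$efficiency, x$n_peaks))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Detect a dual-cut deletion in an indel spectrum
#'
#' Two simultaneously delivered RNPs excise the intervening fragment,
#' producing amplicons shorter by (approximately) the cut-to-cut distance.
#' The deletion is called present when any spectrum bin falls within
#' `tolerance` bp of `-expected_deletion`.
#'
#' @param spectrum An `indel_spectrum`.
#' @param expected_deletion Expected deletion size in bp (> 0).
#' @param tolerance Matching window half-width in bp (default 2).
#' @return A list: `present` (logical), `fraction` (summed molar fraction of
#'   matching bins).
#' @export
detect_dual_cut_deletion <- function(spectrum, expected_deletion,
                                     tolerance = 2) {
  if (expected_deletion <= 0) stop("`expected_deletion` must be > 0")
  sel <- spectrum$delta <= -(expected_deletion - tolerance) &
    spectrum$delta >= -(expected_deletion + tolerance)
  frac <- sum(spectrum$fraction[sel])
  list(present = frac > 0, fraction = frac)
}

#' Quantify a trace end to end
#'
#' Convenience wrapper: baseline correction, peak detection, spectrum
#' assignment and efficiency in one call.
#'
#' @param trace A raw trace tibble.
#' @param expected_wt_size Expected wild-type amplicon size (bp; defaults to
#'   the trace's `expected_wt_size` attribute).
#' @param size_tolerance Wild-type matching tolerance (bp).
#' @param expected_deletion Optional dual-cut deletion size to screen for.
#' @param ... Passed to [detect_peaks()].
#' @return An `editing_result`; when `expected_deletion` is given, the
#'   result additionally carries a `dual_cut` element.
#' @export
quantify_trace <- function(trace, expected_wt_size = NULL,
                           size_tolerance = 0.5, expected_deletion = NULL,
                           ...) {
  expected_wt_size <- expected_wt_size %||% attr(trace, "expected_wt_size")
  if (is.null(expected_wt_size)) stop("`expected_wt_size` is required")
  corrected <- baseline_correct(trace)
  peaks <- detect_peaks(corrected, ...)
  sp <- assign_spectrum(peaks, expected_wt_size,
                        size_tolerance = size_tolerance, allow_empty = TRUE)
  res <- editing_efficiency(sp, sample_id = attr(trace, "sample_id") %||%
                              NA_character_)
  res$n_peaks <- nrow(peaks)
  if (!is.null(expected_deletion)) {
    res$dual_cut <- detect_dual_cut_deletion(sp, expected_deletion)
  }
  res
}

#' Write an indel spectrum as TSV
#'
#' @param spectrum An `indel_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  utils::write.table(as.data.frame(spectrum), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
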