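noiseless_cfg <- function(seed = 3) {
  simulation_config(seed = seed, trace_noise_sd = 0)
}

test_that("baseline correction removes offsets, fixes zero, and is idempotent", {
  cfg <- noiseless_cfg()
  sp <- indel_spectrum(c(0, -3), c(0.6, 0.4), wt_size = 321)
  clean <- simulate_trace(sp, cfg)

  offset <- clean
  offset$signal <- offset$signal + 100
  a_clean <- sum(detect_peaks(baseline_correct(clean))$area)
  a_off <- sum(detect_peaks(baseline_correct(offset))$area)
  expect_lt(abs(a_off - a_clean) / a_clean, 0.01)

  zero <- tibble::tibble(size_bp = seq(100, 110, 0.1), signal = 0)
  expect_equal(baseline_correct(zero)$signal, zero$signal)

  # single Gaussian on a zero baseline is unchanged within tolerance
  single <- simulate_trace(indel_spectrum(0, 1, wt_size = 321), cfg)
  corr <- baseline_correct(single)
  expect_lt(max(abs(corr$signal - pmax(single$signal, 0))) / max(single$signal),
            0.01)

  # idempotence, including under noise
  noisy <- simulate_trace(sp, simulation_config(seed = 5))
  b1 <- baseline_correct(noisy)
  b2 <- baseline_correct(b1)
  expect_lt(max(abs(b2$signal - b1$signal)) / max(b1$signal), 1e-6)

  expect_error(baseline_correct(tibble::tibble(size_bp = 1:5, signal = 0)),
               "fewer than 10")
})

test_that("detect_peaks recovers areas of known Gaussian mixtures", {
  cfg <- noiseless_cfg()
  one <- detect_peaks(baseline_correct(
    simulate_trace(indel_spectrum(0, 1, wt_size = 321), cfg)))
  expect_equal(nrow(one), 1L)
  expect_lt(abs(one$area - cfg$trace_total_area) / cfg$trace_total_area, 0.01)
  expect_lt(abs(one$apex_size - 321), 0.05)

  two <- detect_peaks(baseline_correct(
    simulate_trace(indel_spectrum(c(0, -5), c(0.7, 0.3), wt_size = 321), cfg)))
  expect_equal(nrow(two), 2L)
  fr <- two$area / sum(two$area)
  expect_lt(max(abs(sort(fr) - c(0.3, 0.7))), 0.02)

  # pure noise below threshold: no peaks, warning flag set
  set.seed(12)
  noise <- tibble::tibble(size_bp = seq(300, 340, 0.1),
                          signal = abs(rnorm(401, 0, 2)))
  pk <- detect_peaks(baseline_correct(noise))
  expect_equal(nrow(pk), 0L)
  expect_equal(attr(pk, "flags"), "no_peaks_above_threshold")
})

test_that("assign_spectrum bins peaks against the wild-type anchor", {
  pk <- tibble::tibble(apex_size = c(321, 318), height = c(4, 6),
                       area = c(40, 60), width = 0.4)
  sp <- assign_spectrum(pk, expected_wt_size = 321)
  expect_equal(spectrum_fraction(sp, 0), 0.4)
  expect_equal(spectrum_fraction(sp, -3), 0.6)

  single <- assign_spectrum(pk[1, ], 321)
  expect_equal(single$delta, 0)
  expect_equal(single$fraction, 1)

  # no wild-type candidate: anchored at the expected size, WT fraction 0
  sp2 <- assign_spectrum(pk[2, ], 321)
  expect_equal(spectrum_fraction(sp2, 0), 0)
  expect_equal(spectrum_fraction(sp2, -3), 1)
  expect_equal(attr(sp2, "flags"), "no_wt_peak")

  empty <- pk[0, ]
  expect_error(assign_spectrum(empty, 321), "no peaks")
  sp3 <- assign_spectrum(empty, 321, allow_empty = TRUE)
  expect_equal(spectrum_fraction(sp3, 0), 1)

  # tie-break within tolerance: nearest apex wins, larger area on exact tie
  tie <- tibble::tibble(apex_size = c(320.7, 321.3), height = c(1, 2),
                        area = c(10, 30), width = 0.4)
  expect_equal(spectrum_fraction(assign_spectrum(tie, 321), 0), 0.75)
})

test_that("spectrum fractions always normalize and editing efficiency follows", {
  expect_equal(editing_efficiency(indel_spectrum(0, 1))$efficiency, 0)
  expect_equal(
    editing_efficiency(indel_spectrum(c(0, -1), c(0, 1)))$efficiency, 1)
  expect_equal(
    editing_efficiency(indel_spectrum(c(0, -3), c(0.7, 0.3)))$efficiency, 0.3)

  set.seed(31)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    sp <- indel_spectrum(sample(-30:30, k), runif(k))
    expect_equal(sum(sp$fraction), 1, tolerance = 1e-9)
    expect_true(any(sp$delta == 0))
  }
})

test_that("multiplex spectra with a large deletion are recovered from the trace", {
  cfg <- simulation_config(seed = 21)
  truth <- indel_spectrum(c(0, -1, 1, -100), c(0.5, 0.2, 0.1, 0.2),
                          wt_size = 321)
  trace <- simulate_trace(truth, cfg)
  res <- quantify_trace(trace, expected_wt_size = 321)
  for (d in truth$delta) {
    expect_lt(abs(spectrum_fraction(res$spectrum, d) -
                    spectrum_fraction(truth, d)), 0.02)
  }
})

test_that("dual-cut deletion detection applies its tolerance window", {
  sp <- indel_spectrum(c(0, -97, -1), c(0.6, 0.25, 0.15))
  hit <- detect_dual_cut_deletion(sp, expected_deletion = 98)
  expect_true(hit$present)
  expect_equal(hit$fraction, 0.25)

  none <- detect_dual_cut_deletion(indel_spectrum(0, 1), 98)
  expect_false(none$present)
  expect_equal(none$fraction, 0)

  edge <- detect_dual_cut_deletion(indel_spectrum(c(-3, 0), c(0.3, 0.7)), 3)
  expect_true(edge$present)
  expect_equal(edge$fraction, 0.3)

  expect_error(detect_dual_cut_deletion(sp, 0), "expected_deletion")
})

test_that("efficiency is gain-invariant and monotone in the true edited fraction", {
  cfg <- simulation_config(seed = 14)
  sp <- indel_spectrum(c(0, -3, -1), c(0.6, 0.3, 0.1), wt_size = 321)
  trace <- simulate_trace(sp, cfg)
  e1 <- quantify_trace(trace, 321)$efficiency
  gained <- trace
  gained$signal <- gained$signal * 7.3
  expect_equal(quantify_trace(gained, 321)$efficiency, e1, tolerance = 1e-12)

  est <- vapply(c(0.1, 0.25, 0.4, 0.6, 0.8), function(e) {
    cfg <- simulation_config(seed = 60, guide_efficiencies = c(g1 = e))
    out <- simulate_editing_outcomes(cfg)
    quantify_trace(simulate_trace(out$truth$spectrum, cfg), 321)$efficiency
  }, 0)
  expect_false(is.unsorted(est))
})

test_that("trace CSV io validates monotone sizes", {
  cfg <- noiseless_cfg()
  trace <- simulate_trace(indel_spectrum(0, 1, wt_size = 321), cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(trace, path)
  back <- read_trace_csv(path, expected_wt_size = 321)
  expect_equal(back$signal, trace$signal, tolerance = 1e-6)

  bad <- trace[c(2, 1, 3:10), ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(bad, path2)
  expect_error(read_trace_csv(path2), "strictly increasing")
})
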