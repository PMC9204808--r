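# EIC extraction, peak detection, shape scoring, untargeted features,
# blank subtraction.

noise_free_run <- function(formula = "C6H7N", apex_rt = 2, sigma = 0.05,
                           apex = 1e6, run_length = 4, ms1_cycle = 2,
                           seed = 1) {
  generate_run(
    synthetic_config(run_length = run_length, ms1_cycle = ms1_cycle,
                     seed = seed, mass_jitter_ppm = 0,
                     noise_peaks_per_scan = 0),
    spike_spec("x", formula, apex_rt = apex_rt, sigma = sigma,
               apex_intensity = apex)
  )
}

test_that("EIC extraction finds planted peaks and behaves at the edges", {
  gen <- noise_free_run("C4H4ClNOS", apex_rt = 2)
  mz <- adduct_mz("C4H4ClNOS")
  eic <- extract_eic(gen$run, mz, 5)
  expect_equal(nrow(eic), sum(gen$run$scans$ms_level == 1))
  expect_lte(abs(eic$rt[which.max(eic$intensity)] - 2), 2 / 60)
  # absent mass: all-zero trace (with a warning when out of observed range)
  far <- suppressWarnings(extract_eic(gen$run, 700, 5))
  expect_true(all(far$intensity == 0))
  # widening the tolerance never loses signal
  wide <- extract_eic(gen$run, mz, 10)
  expect_true(all(wide$intensity >= eic$intensity))
})

test_that("peak detection recovers a Gaussian with its analytic area", {
  gen <- noise_free_run(apex_rt = 2, sigma = 0.05, apex = 1e6)
  eic <- extract_eic(gen$run, adduct_mz("C6H7N"), 5)
  pks <- detect_peaks(eic, min_height = 1000, min_snr = 3)
  expect_equal(nrow(pks), 1)
  analytic <- 1e6 * 0.05 * sqrt(2 * pi)
  expect_equal(pks$area, analytic, tolerance = 0.02)
  expect_equal(pks$apex_rt, 2, tolerance = 2 / 60)
  expect_gte(pks$shape, 0.99)
  # flat traces yield nothing
  flat <- eic
  flat$intensity <- 0
  expect_equal(nrow(detect_peaks(flat, 1000, 3)), 0)
})

test_that("two separated Gaussians give two features with correct apexes", {
  cfg <- synthetic_config(run_length = 6, seed = 2, mass_jitter_ppm = 0,
                          noise_peaks_per_scan = 0)
  spikes <- dplyr::bind_rows(
    spike_spec("a", "C6H7N", apex_rt = 2, apex_intensity = 1e6),
    spike_spec("b", "C6H7N", apex_rt = 4, apex_intensity = 5e5)
  )
  gen <- generate_run(cfg, spikes)
  eic <- extract_eic(gen$run, adduct_mz("C6H7N"), 5)
  pks <- detect_peaks(eic, 1000, 3)
  expect_equal(nrow(pks), 2)
  expect_equal(sort(pks$apex_rt), c(2, 4), tolerance = 2 / 60)
})

test_that("the shape score separates Gaussians from noise bumps", {
  rt <- seq(0, 1, by = 1 / 30)
  clean <- 1000 * exp(-(rt - 0.5)^2 / (2 * 0.05^2))
  expect_gte(gaussian_shape_score(rt, clean), 0.99)
  set.seed(7)
  scores <- replicate(20, {
    bump <- abs(stats::rnorm(length(rt), 200, 150))
    gaussian_shape_score(rt, bump)
  })
  expect_lt(stats::median(scores), 0.5)
  expect_true(all(scores >= 0 & scores <= 1))
  expect_warning(s <- gaussian_shape_score(c(1, 2, 3), c(1, 5, 1)),
                 "fewer than 4")
  expect_equal(s, 0)
})

test_that("untargeted detection finds exactly the planted traces", {
  cfg <- synthetic_config(run_length = 5, seed = 3, mass_jitter_ppm = 0,
                          noise_peaks_per_scan = 0)
  spikes <- dplyr::bind_rows(
    spike_spec("a", "C6H7N", apex_rt = 1.5, apex_intensity = 1e6),
    spike_spec("b", "C16H33NO3", apex_rt = 3.5, apex_intensity = 1e6)
  )
  gen <- generate_run(cfg, spikes)
  feats <- detect_features(gen$run, min_height = 1000, min_snr = 3)
  # expected: every isotopologue trace whose apex clears the height cut
  expected <- 0
  for (f in c("C6H7N", "C16H33NO3")) {
    pat <- simulate_isotope_pattern(f, "[M+H]+", min_rel = 0.5)
    expected <- expected + sum(1e6 * pat$abundance / 100 >= 1000)
  }
  expect_equal(nrow(feats), expected)
  for (tr in gen$truth$mz) {
    expect_true(any(abs(feats$mz - tr) / tr * 1e6 < 5))
  }
  # an empty run yields an empty table
  empty <- generate_run(synthetic_config(run_length = 1, seed = 1,
                                         noise_peaks_per_scan = 0), NULL)
  expect_equal(nrow(detect_features(empty$run)), 0)
})

test_that("peak area is stable under MS1 cycle-time halving", {
  a1 <- noise_free_run(ms1_cycle = 2, seed = 5)
  a2 <- noise_free_run(ms1_cycle = 1, seed = 5)
  area <- function(gen) {
    eic <- extract_eic(gen$run, adduct_mz("C6H7N"), 5)
    detect_peaks(eic, 1000, 3)$area[1]
  }
  expect_equal(area(a1), area(a2), tolerance = 0.01)
})

test_that("planted features are fully recovered under ppm jitter", {
  cfg <- synthetic_config(run_length = 6, seed = 10, mass_jitter_ppm = 2,
                          noise_peaks_per_scan = 10)
  spikes <- dplyr::bind_rows(
    spike_spec("a", "C6H7N", apex_rt = 1.5, apex_intensity = 5e5),
    spike_spec("b", "C7H5NOS", apex_rt = 3, apex_intensity = 5e5),
    spike_spec("c", "C16H33NO3", apex_rt = 4.5, apex_intensity = 5e5)
  )
  gen <- generate_run(cfg, spikes)
  feats <- detect_features(gen$run, min_height = 1000, min_snr = 3,
                           tol_ppm = 5)
  for (i in seq_len(nrow(gen$truth))) {
    hit <- abs(feats$mz - gen$truth$mz[i]) / gen$truth$mz[i] * 1e6 < 5 &
      abs(feats$apex_rt - gen$truth$apex_rt[i]) <= 0.1
    expect_true(any(hit), info = gen$truth$compound[i])
  }
})

test_that("blank subtraction removes exactly the blank-matched features", {
  gen <- noise_free_run("C7H5NOS", apex_rt = 2)
  feats <- detect_features(gen$run)
  # blank identical to sample: everything dies
  expect_equal(nrow(subtract_blank(feats, feats)), 0)
  # empty blank: identity
  expect_identical(subtract_blank(feats, feats[0, ]), feats)
  # contaminant in blank removed, analyte retained
  cfg <- synthetic_config(run_length = 4, seed = 4, mass_jitter_ppm = 0,
                          noise_peaks_per_scan = 0)
  both <- generate_run(cfg, dplyr::bind_rows(
    spike_spec("analyte", "C16H33NO3", apex_rt = 1.5,
               apex_intensity = 1e6),
    spike_spec("contaminant", "C7H5NOS", apex_rt = 2.5,
               apex_intensity = 1e6)
  ))
  blank <- generate_blank(cfg, spike_spec("contaminant", "C7H5NOS",
                                          apex_rt = 2.5,
                                          apex_intensity = 8e5))
  sf <- detect_features(both$run)
  bf <- detect_features(blank)
  kept <- subtract_blank(sf, bf)
  target <- adduct_mz("C16H33NO3")
  contam <- adduct_mz("C7H5NOS")
  expect_true(any(abs(kept$mz - target) / target * 1e6 < 5))
  expect_false(any(abs(kept$mz - contam) / contam * 1e6 < 5))
})
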