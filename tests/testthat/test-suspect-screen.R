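# Suspect screening, isotope verification, ddMS2 fragment matching,
# Schymanski levels, standard confirmation.

test_that("planted suspects are screened with small mass errors", {
  fx <- make_screen_fixture()
  rec <- screen_suspects(fx$run, fx$blank, fx$db)
  expect_setequal(unique(rec$suspect),
                  c("methylchloroisothiazolinone", "lauramide DEA"))
  expect_true(all(abs(rec$mass_error_ppm) <= 5))
  expect_true(all(rec$level == 5L))
  expect_true(all(rec$adduct == "[M+H]+"))
  expect_error(screen_suspects(fx$run, fx$blank, fx$db[0, ]), "empty")
})

test_that("a compound present only in the blank is not reported", {
  cfg <- synthetic_config(run_length = 4, seed = 21, mass_jitter_ppm = 1,
                          noise_peaks_per_scan = 5)
  sp <- spike_spec("1-methylpyrrolidin-2-one", "C5H9NO", apex_rt = 2,
                   apex_intensity = 1e6)
  run <- generate_run(cfg, NULL)$run
  blank <- generate_blank(cfg, sp)
  db <- read_suspect_db(system.file("extdata", "suspect_db.csv",
                                    package = "ppscreen"))
  rec <- screen_suspects(run, blank, db)
  expect_false("1-methylpyrrolidin-2-one" %in% rec$suspect)
  # and the mirror case: in the sample, not in the blank -> reported
  run2 <- generate_run(cfg, sp)$run
  blank2 <- generate_blank(synthetic_config(run_length = 4, seed = 22,
                                            noise_peaks_per_scan = 5))
  rec2 <- screen_suspects(run2, blank2, db)
  expect_true("1-methylpyrrolidin-2-one" %in% rec2$suspect)
})

test_that("tightening the tolerance below the jitter loses detections", {
  fx <- make_screen_fixture(jitter = 3)
  wide <- screen_suspects(fx$run, fx$blank, fx$db, tol_ppm = 5)
  narrow <- screen_suspects(fx$run, fx$blank, fx$db, tol_ppm = 0.1)
  expect_lt(nrow(narrow), nrow(wide))
})

test_that("isotope patterns verify true chlorine compounds and refute fakes", {
  fx <- make_screen_fixture(noise = 0)
  rec <- screen_suspects(fx$run, fx$blank, fx$db)
  rec <- verify_isotope_pattern(fx$run, rec)
  mci <- rec[rec$suspect == "methylchloroisothiazolinone", ]
  expect_true(all(mci$isotope_verified))
  expect_false(any(mci$isotope_refuted))
  # negative control: a Cl-free isobar (C3H4NO2PS, 1.2 ppm away) planted
  # instead of the chlorinated compound -> no M+2, suspect refuted
  cfg <- synthetic_config(run_length = 4, seed = 31, mass_jitter_ppm = 0.5,
                          noise_peaks_per_scan = 0)
  fake <- generate_run(cfg, spike_spec("isobar", "C3H4NO2PS", apex_rt = 2,
                                       apex_intensity = 1e6))
  rec2 <- screen_suspects(fake$run, NULL, fx$db)
  mci2 <- rec2[rec2$suspect == "methylchloroisothiazolinone", ]
  expect_gte(nrow(mci2), 1)
  mci2 <- verify_isotope_pattern(fake$run, mci2)
  expect_true(all(mci2$isotope_refuted))
  expect_equal(nrow(assign_level(mci2)), 0)
})

test_that("with a 100% intensity tolerance verification is presence-only", {
  fx <- make_screen_fixture(noise = 0)
  rec <- screen_suspects(fx$run, fx$blank, fx$db)
  strict <- verify_isotope_pattern(fx$run, rec, intensity_tol = 30)
  loose <- verify_isotope_pattern(fx$run, rec, intensity_tol = 1e6)
  expect_true(all(loose$isotope_verified >= strict$isotope_verified))
})

test_that("ddMS2 fragments are matched and the two-fragment rule enforced", {
  fx <- make_screen_fixture()
  rec <- screen_suspects(fx$run, fx$blank, fx$db)
  rec <- verify_isotope_pattern(fx$run, rec)
  rec <- match_fragments(fx$run, rec)
  dea <- rec[rec$suspect == "lauramide DEA", ]
  expect_true(all(dea$ms2_available))
  expect_true(all(dea$fragments_matched >= 2))
  expect_true(all(abs(dea$fragment_matches[[1]]$ppm_error) < 6))
  out <- assign_level(rec)
  # two fragments + verified isotope pattern = level 2
  expect_equal(out$level[out$suspect == "lauramide DEA"], 2L)
  # no record at level <= 3 without two matched fragments
  lvl3 <- out[out$level <= 3, ]
  expect_true(all(lvl3$fragments_matched >= 2))
})

test_that("a suspect whose fragments all fail to match is rejected", {
  # plant butyl glycol's exact mass but with unrelated fragments, the way
  # an isomeric interferent would fragment
  cfg <- synthetic_config(run_length = 4, seed = 41, mass_jitter_ppm = 1,
                          noise_peaks_per_scan = 0)
  imposter <- spike_spec("imposter", "C6H14O2", apex_rt = 2,
                         apex_intensity = 1e6,
                         fragments = tibble::tibble(
                           formula = c("C3H7O", "C2H5O"),
                           rel_intensity = c(1, 0.5)))
  gen <- generate_run(cfg, imposter)
  db <- read_suspect_db(system.file("extdata", "suspect_db.csv",
                                    package = "ppscreen"))
  rec <- screen_suspects(gen$run, NULL, db)
  bg <- rec[rec$suspect == "butyl glycol", ]
  expect_equal(nrow(bg), 1)
  bg <- match_fragments(gen$run, bg)
  expect_true(bg$ms2_available)
  expect_equal(bg$fragments_matched, 0L)
  expect_true(bg$rejected)
  expect_equal(bg$level, 5L)        # never promoted past exact-mass-only
  expect_equal(nrow(assign_level(bg)), 0)
})

test_that("records with no nearby MS2 event are marked unavailable", {
  cfg <- synthetic_config(run_length = 4, seed = 42, top_n = 0,
                          mass_jitter_ppm = 1, noise_peaks_per_scan = 0)
  gen <- generate_run(cfg, spike_spec("lauramide DEA", "C16H33NO3",
                                      apex_rt = 2, apex_intensity = 1e6))
  db <- read_suspect_db(system.file("extdata", "suspect_db.csv",
                                    package = "ppscreen"))
  rec <- match_fragments(gen$run, screen_suspects(gen$run, NULL, db))
  expect_false(any(rec$ms2_available))
  expect_true(all(is.na(rec$fragments_matched)))
})

test_that("the level rule table is monotone in evidence", {
  base <- screen_suspects(make_screen_fixture(noise = 0)$run, NULL,
                          read_suspect_db(system.file(
                            "extdata", "suspect_db.csv",
                            package = "ppscreen")))[1, ]
  with_evidence <- function(iso, frags, std) {
    r <- base
    r$isotope_verified <- iso
    r$fragments_matched <- frags
    r$rt_standard_delta <- std
    assign_level(r)$level
  }
  expect_equal(with_evidence(NA, NA_integer_, NA_real_), 5L)
  expect_equal(with_evidence(TRUE, NA_integer_, NA_real_), 4L)
  expect_equal(with_evidence(FALSE, 2L, NA_real_), 3L)
  expect_equal(with_evidence(TRUE, 2L, NA_real_), 2L)
  expect_equal(with_evidence(TRUE, 2L, 0.02), 1L)
  expect_equal(with_evidence(FALSE, 1L, NA_real_), 5L)  # two-fragment rule
  # adding evidence never increases the level number
  expect_lte(with_evidence(TRUE, 2L, NA_real_),
             with_evidence(FALSE, 2L, NA_real_))
  expect_lte(with_evidence(TRUE, 2L, 0.02),
             with_evidence(TRUE, 2L, NA_real_))
})

test_that("standard confirmation upgrades only close retention matches", {
  fx <- make_screen_fixture(noise = 0)
  rec <- screen_suspects(fx$run, fx$blank, fx$db)
  rec <- verify_isotope_pattern(fx$run, rec)
  rec <- match_fragments(fx$run, rec)
  dea <- rec[rec$suspect == "lauramide DEA", ][1, ]
  # standard elutes 0.02 min away: confirmed at level 1
  std_cfg <- synthetic_config(run_length = 10, seed = 51,
                              mass_jitter_ppm = 0.5,
                              noise_peaks_per_scan = 0)
  std <- generate_run(std_cfg, spike_spec("lauramide DEA", "C16H33NO3",
                                          apex_rt = dea$apex_rt + 0.02,
                                          apex_intensity = 1e6))$run
  conf <- confirm_with_standard(dea, std)
  expect_lt(conf$rt_standard_delta, 0.1)
  expect_equal(conf$level, 1L)
  # standard eluting 0.15 min away: no upgrade
  far <- generate_run(std_cfg, spike_spec("lauramide DEA", "C16H33NO3",
                                          apex_rt = dea$apex_rt + 0.15,
                                          apex_intensity = 1e6))$run
  conf2 <- confirm_with_standard(dea, far)
  expect_gt(conf2$rt_standard_delta, 0.1)
  expect_gt(conf2$level, 1L)
  # analyte absent from the standard run: an error
  empty_std <- generate_blank(synthetic_config(run_length = 10, seed = 52,
                                               noise_peaks_per_scan = 0))
  expect_error(confirm_with_standard(dea, empty_std), "not found")
})

test_that("screening has perfect recall and precision on clean data", {
  db <- read_suspect_db(system.file("extdata", "suspect_db.csv",
                                    package = "ppscreen"))
  planted <- c("methylchloroisothiazolinone", "lauramide DEA", "aniline",
               "1,2-benzisothiazol-3(2H)-one", "1-methylpyrrolidin-2-one")
  spikes <- purrr::imap(planted, function(nm, i) {
    spike_spec(nm, db$formula[db$name == nm], apex_rt = 1 + i,
               apex_intensity = 1e6)
  }) |> purrr::list_rbind()
  cfg <- synthetic_config(run_length = 8, seed = 61, mass_jitter_ppm = 0,
                          noise_peaks_per_scan = 0)
  gen <- generate_run(cfg, spikes)
  pos_db <- db[vapply(db$adducts, function(a) "[M+H]+" %in% a,
                      logical(1)), ]
  rec <- screen_suspects(gen$run, NULL, pos_db)
  rec_h <- rec[rec$adduct == "[M+H]+", ]
  expect_setequal(unique(rec_h$suspect), planted)   # recall & precision 1
})
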