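# Exact-mass chemistry core.

test_that("formula parsing reads Hill strings and round-trips", {
  expect_mapequal(as.list(parse_formula("C4H4ClNOS")),
                  list(C = 4L, H = 4L, Cl = 1L, N = 1L, O = 1L, S = 1L))
  expect_mapequal(as.list(parse_formula("H2O")), list(H = 2L, O = 1L))
  expect_mapequal(as.list(parse_formula("C21H42O4")),
                  list(C = 21L, H = 42L, O = 4L))
  # repeated element symbols accumulate
  expect_equal(parse_formula("CH3CH3")[["C"]], 2L)
  for (f in c("C4H4ClNOS", "H2O", "C21H42O4", "C16H33NO3")) {
    expect_mapequal(as.list(parse_formula(formula_string(parse_formula(f)))),
                    as.list(parse_formula(f)))
  }
  expect_error(parse_formula("C4Xx2"), "unknown element")
  expect_error(parse_formula("C4H4/Cl"), "malformed|unparseable")
})

test_that("monoisotopic masses sum lightest-isotope atomic masses", {
  # frozen from independent sums of IUPAC atomic masses
  expect_equal(monoisotopic_mass("H2O"), 18.0105646, tolerance = 1e-6)
  expect_equal(monoisotopic_mass(""), 0)
  expect_equal(monoisotopic_mass("C4H4ClNOS"), 148.9702126,
               tolerance = 1e-6)
})

test_that("adduct and fragment-cation m/z reproduce the printed anchors", {
  # ten five-decimal m/z anchors of known co-formulant ions
  expect_equal(adduct_mz("C4H4ClNOS", "[M+H]+"), 149.97749,
               tolerance = 1e-4)
  expect_equal(adduct_mz("C16H33NO3", "[M+H]+"), 288.25332,
               tolerance = 1e-4)
  expect_equal(fragment_cation_mz("C14H28NO"), 226.21654, tolerance = 1e-4)
  expect_equal(fragment_cation_mz("C4H12NO2"), 106.08626, tolerance = 1e-4)
  expect_equal(fragment_cation_mz("C21H41O3"), 341.30502, tolerance = 1e-4)
  expect_equal(fragment_cation_mz("C18H37O2"), 285.27881, tolerance = 1e-4)
  expect_equal(fragment_cation_mz("C18H35O"), 267.26824, tolerance = 1e-4)
  expect_equal(fragment_cation_mz("C18H33"), 249.25768, tolerance = 1e-4)
  expect_equal(fragment_cation_mz("C12H21"), 165.16378, tolerance = 1e-4)
  expect_equal(fragment_cation_mz("C6H13"), 85.10118, tolerance = 1e-4)
})

test_that("adduct arithmetic is internally consistent", {
  for (f in c("C16H33NO3", "C7H5NOS", "C6H7N")) {
    expect_equal(adduct_mz(f, "[M+H]+", digits = NULL) -
                   adduct_mz(f, "[M-H]-", digits = NULL),
                 2 * 1.00727646, tolerance = 1e-9)
    # proton-mass convention nets out the electron: MH+ cation atoms
    mh <- parse_formula(f)
    mh["H"] <- mh["H"] + 1L
    expect_equal(fragment_cation_mz(mh), adduct_mz(f, "[M+H]+"),
                 tolerance = 2e-5)
  }
  expect_error(adduct_mz("H2O", "[M+2H]2+"), "unsupported adduct")
})

test_that("ppm errors follow the rounded-theoretical convention", {
  theo <- adduct_mz("C4H4ClNOS", "[M+H]+")
  expect_equal(round(ppm_error(149.97716, theo), 2), -2.20)
  # against the unrounded theoretical mass the error is a shade smaller
  unrounded <- monoisotopic_mass("C4H4ClNOS") + 1.00727646
  expect_equal(round(ppm_error(149.97716, unrounded, "unrounded"), 2),
               -2.19)
  expect_equal(ppm_error(100, 100), 0)
  expect_error(ppm_error(100, 0), "positive")
  # algebraic identity ppm(a,b) = -ppm(b,a) * a/b
  set.seed(1)
  a <- runif(20, 50, 750)
  b <- a * (1 + runif(20, -1e-5, 1e-5))
  expect_equal(ppm_error(a, b, "unrounded"),
               -ppm_error(b, a, "unrounded") * a / b, tolerance = 1e-12)
})

test_that("simulated isotope patterns are valid and match expectations", {
  p <- simulate_isotope_pattern("C4H4ClNOS", "[M+H]+", min_rel = 5)
  expect_true(all(diff(p$mz) > 0))
  expect_equal(sum(p$abundance == 100), 1)
  expect_true(all(p$abundance > 0 & p$abundance <= 100))
  # chlorine + sulfur M+2 signature: ~32% (37Cl) + ~4.4% (34S)
  m2 <- p$abundance[which.min(abs(p$mz - (p$mz[1] + 1.996)))]
  expect_gte(m2, 33)
  expect_lte(m2, 39)
  # single carbon: M+1 is the 13C/12C abundance ratio
  pc <- simulate_isotope_pattern("C", "[M+H]+", min_rel = 0.1)
  m1 <- pc$abundance[which.min(abs(pc$mz - (pc$mz[1] + 1.0034)))]
  expect_equal(m1, 0.0107 / 0.9893 * 100, tolerance = 0.05)
  # no Cl/Br/S and modest C,O count: M+2 below 2%
  for (f in c("C12H25NO", "C7H16O3", "C5H9NO")) {
    pf <- simulate_isotope_pattern(f, "[M+H]+", min_rel = 0.01)
    m2f <- pf$abundance[abs(pf$mz - (pf$mz[1] + 2)) < 0.5]
    expect_lt(max(c(m2f, 0)), 2)
  }
})

test_that("fast isotope patterns agree with brute-force expansion", {
  cases <- list(
    list(f = "C4H4ClNOS", ion = c(C = 4L, H = 5L, Cl = 1L, N = 1L,
                                  O = 1L, S = 1L)),
    list(f = "C7H5NOS", ion = c(C = 7L, H = 6L, N = 1L, O = 1L, S = 1L)),
    list(f = "C6H7N", ion = c(C = 6L, H = 8L, N = 1L))
  )
  for (cs in cases) {
    fast <- simulate_isotope_pattern(cs$f, "[M+H]+", min_rel = 0.5)
    slow <- oracle_isotope_pattern(cs$ion, charge = 1, min_rel = 0.01)
    for (k in seq_len(nrow(fast))) {
      j <- which.min(abs(slow$mz - fast$mz[k]))
      expect_lt(abs(slow$mz[j] - fast$mz[k]), 0.01)
      expect_lt(abs(slow$abundance[j] - fast$abundance[k]), 0.5)
    }
  }
})

test_that("formula enumeration is exhaustive, filtered and sorted", {
  hits <- enumerate_formulas(149.97749, "[M+H]+", 5,
                             default_element_bounds(chlorine = TRUE))
  expect_true("C4H4ClNOS" %in% hits$formula)
  expect_true(all(abs(hits$ppm_error) <= 5))
  expect_true(all(diff(abs(hits$ppm_error)) >= -1e-12))
  expect_true(all(hits$rdbe >= 0))
  # monotone in tolerance
  h2 <- enumerate_formulas(149.97749, "[M+H]+", 2,
                           default_element_bounds(chlorine = TRUE))
  expect_true(all(h2$formula %in% hits$formula))
  # zero tolerance: exact-only (empty here)
  h0 <- enumerate_formulas(149.97749, "[M+H]+", 1e-6,
                           default_element_bounds(chlorine = TRUE))
  expect_lte(nrow(h0), 1)
  expect_error(enumerate_formulas(100, "[M+H]+", 5, list()), "empty")
})

test_that("formula enumeration matches a naive nested-loop oracle", {
  bounds <- list(C = c(0, 10), H = c(0, 24), N = c(0, 2), O = c(0, 5),
                 S = c(0, 2))
  for (mz in c(119.10666, 150.05495, 94.06513)) {
    mine <- sort(enumerate_formulas(mz, "[M+H]+", 5, bounds)$formula)
    oracle <- oracle_enumerate(mz, 1.00727646, 5, bounds)
    expect_equal(mine, oracle, info = paste("mz", mz))
  }
})
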