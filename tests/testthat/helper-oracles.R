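# Independent oracles and shared fixtures for the test suite.
# These deliberately re-derive quantities by brute force, not by calling
# the package's fast implementations.

# isotope data as a plain list, read straight from the packaged CSV
oracle_isotopes <- function() {
  tab <- read.csv(system.file("extdata", "isotope_table.csv",
                              package = "ppscreen"))
  split(tab[, c("mass", "abundance")], tab$element)
}

# brute-force isotopologue expansion: enumerate every way of assigning
# isotopes to atoms (as multinomial compositions per element), then merge
# peaks within merge_tol Da. counts is a named integer vector of the ION's
# atoms; charge +1/-1 removes/adds one electron mass.
oracle_isotope_pattern <- function(counts, charge = 1, min_rel = 0.01,
                                   merge_tol = 0.01) {
  iso <- oracle_isotopes()
  per_element <- lapply(names(counts), function(el) {
    n <- counts[[el]]
    d <- iso[[el]]
    k <- nrow(d)
    # compositions of n atoms into k isotopes
    comps <- compositions(n, k)
    mass <- as.numeric(comps %*% d$mass)
    p <- d$abundance / sum(d$abundance)
    logp <- apply(comps, 1, function(cc) {
      lgamma(n + 1) - sum(lgamma(cc + 1)) + sum(cc * log(p))
    })
    data.frame(mass = mass, prob = exp(logp))
  })
  combo <- Reduce(function(a, b) {
    out <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
    data.frame(mass = a$mass[out$i] + b$mass[out$j],
               prob = a$prob[out$i] * b$prob[out$j])
  }, per_element)
  combo$mass <- combo$mass - sign(charge) * 0.00054858
  combo <- combo[order(combo$mass), ]
  grp <- cumsum(c(TRUE, diff(combo$mass) > merge_tol))
  mass <- tapply(combo$mass * combo$prob, grp, sum) /
    tapply(combo$prob, grp, sum)
  prob <- tapply(combo$prob, grp, sum)
  ab <- prob / max(prob) * 100
  keep <- ab >= min_rel
  data.frame(mz = as.numeric(mass[keep]), abundance = as.numeric(ab[keep]))
}

# all compositions of n into k non-negative parts
compositions <- function(n, k) {
  if (k == 1) return(matrix(n, ncol = 1))
  out <- list()
  for (i in 0:n) {
    rest <- compositions(n - i, k - 1)
    out[[length(out) + 1]] <- cbind(i, rest)
  }
  do.call(rbind, out)
}

# naive nested-loop formula enumeration over small CHNO(S) bounds
oracle_enumerate <- function(mz, shift, tol_ppm, bounds) {
  masses <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
              O = 15.9949146221, S = 31.9720706900, P = 30.9737615100,
              Cl = 34.9688527100)
  target <- mz - shift
  half <- mz * tol_ppm * 1e-6
  grid <- expand.grid(lapply(bounds, function(b) b[1]:b[2]))
  hits <- character(0)
  for (r in seq_len(nrow(grid))) {
    cc <- unlist(grid[r, , drop = TRUE])
    m <- sum(cc * masses[names(cc)])
    if (abs(m - target) > half) next
    cc <- cc[cc > 0]
    if (length(cc) == 0) next
    # same sanity filters as the implementation under test
    val <- c(C = 4, N = 3, P = 3, O = 2, S = 2, H = 1, Cl = 1)
    rdbe <- 1 + sum(cc * (val[names(cc)] - 2)) / 2
    if (rdbe < 0) next
    if (!is.na(cc["C"]) && cc["C"] > 0) {
      nh <- if (is.na(cc["H"])) 0 else cc["H"]
      if (nh / cc["C"] < 0.1 || nh / cc["C"] > 4) next
    }
    hits <- c(hits, ppscreen::formula_string(cc))
  }
  sort(unique(hits))
}

# shared small fixture: a short run with two identifiable suspects
make_screen_fixture <- function(seed = 11, jitter = 1, noise = 10,
                                run_length = 10) {
  cfg <- synthetic_config(run_length = run_length, seed = seed,
                          mass_jitter_ppm = jitter,
                          noise_peaks_per_scan = noise)
  spikes <- dplyr::bind_rows(
    spike_spec("methylchloroisothiazolinone", "C4H4ClNOS",
               apex_rt = 7.65, apex_intensity = 5e5),
    spike_spec("lauramide DEA", "C16H33NO3", apex_rt = 4.2,
               apex_intensity = 2e6,
               fragments = tibble::tibble(
                 formula = c("C14H28NO", "C4H12NO2"),
                 rel_intensity = c(1, 0.6)))
  )
  gen <- generate_run(cfg, spikes)
  blank <- generate_blank(synthetic_config(run_length = run_length,
                                           seed = seed + 1000,
                                           noise_peaks_per_scan = noise))
  list(run = gen$run, truth = gen$truth, blank = blank,
       db = read_suspect_db(system.file("extdata", "suspect_db.csv",
                                        package = "ppscreen")))
}
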