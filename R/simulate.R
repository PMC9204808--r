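# Synthetic LC-HRMS run generator: Gaussian chromatographic peaks of spiked
# co-formulants with isotopologues, ppm-scale mass jitter, noise centroids,
# and top-N data-dependent MS2 triggering, with a ground-truth table.

#' Describe a spiked compound
#'
#' One row of a spike table consumed by [generate_run()]. A spike is a
#' compound eluting as a Gaussian peak; its adduct ions (with relative
#' response) and full isotopologue pattern are planted in every MS1 scan,
#' and its fragment list is emitted when a ddMS2 event fires on one of its
#' precursors.
#'
#' @param name Compound name (appears in the ground-truth table).
#' @param formula Neutral elemental formula string.
#' @param adducts Named numeric vector of relative adduct responses, e.g.
#'   `c("[M+H]+" = 1, "[M+Na]+" = 0.4)`.
#' @param apex_rt Elution apex in minutes.
#' @param sigma Gaussian peak width (standard deviation) in minutes.
#' @param apex_intensity Apex intensity of the base isotopologue of the
#'   most abundant adduct, in counts.
#' @param fragments Optional tibble with columns `formula` (fragment cation
#'   formula) and `rel_intensity` (relative to the MS2 base peak, in (0,1]).
#' @return A one-row tibble with list-columns; rows from repeated calls are
#'   combined with `dplyr::bind_rows()`.
#' @export
spike_spec <- function(name, formula, adducts = c("[M+H]+" = 1),
                       apex_rt, sigma = 0.05, apex_intensity = 1e6,
                       fragments = NULL) {
  stopifnot(sigma > 0, apex_intensity > 0, apex_rt >= 0,
            length(adducts) >= 1, !is.null(names(adducts)))
  parse_formula(formula)  # validates
  if (!is.null(fragments)) {
    fragments <- as_tibble(fragments)
    stopifnot(all(c("formula", "rel_intensity") %in% names(fragments)))
  }
  tibble(name = name, formula = formula, adducts = list(adducts),
         apex_rt = apex_rt, sigma = sigma, apex_intensity = apex_intensity,
         fragments = list(fragments))
}

#' Expand a homolog series into individual spikes
#'
#' Polyethoxylate surfactants (alkyl ethoxylates and related polymers) are
#' mixtures of oligomers differing by a repeat unit (ethylene oxide,
#' C2H4O). All members co-elute as one chromatographic peak and show a
#' characteristic bell-shaped m/z ladder in the apex spectrum. This helper
#' builds one spike per oligomer with abundances following a discretized
#' Gaussian over the repeat count n.
#'
#' @param name_prefix Series label; members are named `"<prefix>-<n>"`.
#' @param core_formula Formula of the n = 0 member (e.g. `"C16H34O"` for
#'   the ceteth series: cetyl alcohol).
#' @param repeat_unit Repeat-unit formula (default ethylene oxide,
#'   `"C2H4O"`, exact mass 44.02621 Da).
#' @param n_min,n_max Repeat-count range (inclusive).
#' @param profile_center,profile_sd Center and width of the Gaussian
#'   abundance profile over n; defaults to the middle of the range and a
#'   quarter of its span.
#' @inheritParams spike_spec
#' @return A tibble of spikes, one row per oligomer.
#' @export
homolog_series_spikes <- function(name_prefix, core_formula,
                                  repeat_unit = "C2H4O",
                                  n_min, n_max, apex_rt, sigma = 0.05,
                                  apex_intensity = 1e6,
                                  adducts = c("[M+H]+" = 1),
                                  profile_center = (n_min + n_max) / 2,
                                  profile_sd = max((n_max - n_min) / 4, 1)) {
  stopifnot(n_min >= 0, n_max >= n_min)
  core <- parse_formula(core_formula)
  unit <- parse_formula(repeat_unit)
  ns <- seq(n_min, n_max)
  w <- exp(-(ns - profile_center)^2 / (2 * profile_sd^2))
  w <- w / max(w)
  purrr::map2(ns, w, function(n, wi) {
    f <- core
    if (n > 0) f <- formula_add(f, unit, mult = n)
    spike_spec(paste0(name_prefix, "-", n), formula_string(f),
               adducts = adducts, apex_rt = apex_rt, sigma = sigma,
               apex_intensity = apex_intensity * wi)
  }) |> list_rbind()
}

#' Synthetic acquisition configuration
#'
#' Defaults mirror a 30-min full-scan + top-5 ddMS2 Orbitrap method:
#' MS1 over m/z 50-750, a 2-s MS1 cycle (at least 15 points across a
#' 0.5-min-wide peak), a 5.0 Da isolation window (half-width 2.5), loop
#' count 5, and 10 s dynamic exclusion.
#'
#' @param run_length Run length in minutes.
#' @param ms1_cycle MS1 cycle time in seconds.
#' @param mz_range Acquisition m/z range, `c(low, high)`.
#' @param mass_jitter_ppm Standard deviation of multiplicative m/z jitter,
#'   in ppm; every planted centroid gets `mz * (1 + rnorm(0, sd))`.
#' @param noise_peaks_per_scan Poisson mean of random noise centroids per
#'   MS1 scan.
#' @param noise_intensity_meanlog,noise_intensity_sdlog Log-normal
#'   parameters of noise-centroid intensities.
#' @param top_n ddMS2 loop count: precursors fragmented per MS1 cycle.
#' @param ms2_intensity_floor Minimum precursor intensity to trigger ddMS2.
#' @param dynamic_exclusion Seconds a fragmented precursor is excluded from
#'   re-selection.
#' @param isolation_half_width Half of the isolation window, Da.
#' @param collision_energy Nominal ddMS2 collision energy (eV), stored in
#'   scan metadata.
#' @param polarity `"+"` or `"-"`.
#' @param seed Integer seed fixing all randomness of the generator.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(run_length = 30, ms1_cycle = 2,
                             mz_range = c(50, 750), mass_jitter_ppm = 1,
                             noise_peaks_per_scan = 20,
                             noise_intensity_meanlog = log(500),
                             noise_intensity_sdlog = 1,
                             top_n = 5, ms2_intensity_floor = 1e4,
                             dynamic_exclusion = 10,
                             isolation_half_width = 2.5,
                             collision_energy = 30,
                             polarity = "+", seed = 1L) {
  stopifnot(run_length > 0, ms1_cycle > 0, mass_jitter_ppm >= 0,
            noise_peaks_per_scan >= 0, top_n >= 0)
  structure(
    list(run_length = run_length, ms1_cycle = ms1_cycle, mz_range = mz_range,
         mass_jitter_ppm = mass_jitter_ppm,
         noise_peaks_per_scan = noise_peaks_per_scan,
         noise_intensity_meanlog = noise_intensity_meanlog,
         noise_intensity_sdlog = noise_intensity_sdlog,
         top_n = top_n, ms2_intensity_floor = ms2_intensity_floor,
         dynamic_exclusion = dynamic_exclusion,
         isolation_half_width = isolation_half_width,
         collision_energy = collision_energy, polarity = polarity,
         seed = seed),
    class = "synthetic_config"
  )
}

jitter_mz <- function(mz, sd_ppm) {
  if (sd_ppm == 0) return(mz)
  mz * (1 + rnorm(length(mz), 0, sd_ppm * 1e-6))
}

#' Generate a synthetic LC-HRMS run with ground truth
#'
#' Plants each spike as a Gaussian elution profile sampled at the MS1
#' cycle, with the full isotopologue pattern of every adduct, ppm-scale
#' mass jitter, and random noise centroids. ddMS2 events fire on the top-N
#' most intense precursors of each MS1 scan above the intensity floor,
#' subject to dynamic exclusion, and emit the matching spike's fragment
#' list (with jitter). Deterministic under the config seed.
#'
#' @param config A [synthetic_config()].
#' @param spikes Spike table from [spike_spec()] /
#'   [homolog_series_spikes()] rows, or `NULL` for a noise-only run.
#' @param run_id,role,dilution_factor Passed to [ms_run()].
#' @return A list with elements `run` (an [ms_run()]) and `truth` (a tibble
#'   listing every planted adduct trace: compound, adduct, theoretical m/z,
#'   apex rt, apex intensity and true Gaussian area in counts x min).
#' @export
generate_run <- function(config, spikes, run_id = "synthetic",
                         role = "sample", dilution_factor = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  rt <- seq(0, config$run_length, by = config$ms1_cycle / 60)
  n_ms1 <- length(rt)
  peak_rows <- list()
  truth_rows <- list()
  # spike -> precursor lookup for ddMS2 content
  precursor_map <- list()

  if (!is.null(spikes) && nrow(spikes) > 0) {
    for (i in seq_len(nrow(spikes))) {
      sp <- spikes[i, ]
      adducts <- sp$adducts[[1]]
      if (sp$apex_rt < 0 || sp$apex_rt > config$run_length) {
        stop("spike '", sp$name, "' elutes outside the run", call. = FALSE)
      }
      for (a in names(adducts)) {
        pat <- simulate_isotope_pattern(sp$formula, a, min_rel = 0.5)
        base_mz <- adduct_mz(sp$formula, a)
        if (base_mz < config$mz_range[1] || base_mz > config$mz_range[2]) {
          stop("spike '", sp$name, "' adduct ", a,
               " falls outside the acquisition m/z range", call. = FALSE)
        }
        apex <- sp$apex_intensity * adducts[[a]]
        prof <- apex * exp(-(rt - sp$apex_rt)^2 / (2 * sp$sigma^2))
        keep_scan <- which(prof >= 1)
        if (length(keep_scan) > 0) {
          grid <- expand.grid(si = keep_scan, pi = seq_len(nrow(pat)))
          ints <- prof[grid$si] * pat$abundance[grid$pi] / 100
          ok <- ints >= 1
          peak_rows[[length(peak_rows) + 1]] <- tibble(
            scan = grid$si[ok],
            mz = jitter_mz(pat$mz[grid$pi[ok]], config$mass_jitter_ppm),
            intensity = ints[ok]
          )
        }
        truth_rows[[length(truth_rows) + 1]] <- tibble(
          compound = sp$name, adduct = a, formula = sp$formula,
          mz = base_mz, apex_rt = sp$apex_rt,
          apex_intensity = apex,
          true_area = apex * sp$sigma * sqrt(2 * pi)
        )
        precursor_map[[length(precursor_map) + 1]] <- tibble(
          mz = base_mz, spike = i
        )
      }
    }
  }

  # noise centroids
  if (config$noise_peaks_per_scan > 0) {
    n_noise <- stats::rpois(n_ms1, config$noise_peaks_per_scan)
    tot <- sum(n_noise)
    if (tot > 0) {
      peak_rows[[length(peak_rows) + 1]] <- tibble(
        scan = rep(seq_len(n_ms1), n_noise),
        mz = stats::runif(tot, config$mz_range[1], config$mz_range[2]),
        intensity = stats::rlnorm(tot, config$noise_intensity_meanlog,
                                  config$noise_intensity_sdlog)
      )
    }
  }

  ms1_peaks <- if (length(peak_rows)) list_rbind(peak_rows) else
    tibble(scan = integer(), mz = numeric(), intensity = numeric())
  scans <- tibble(scan = seq_len(n_ms1), rt = rt, ms_level = 1L,
                  polarity = config$polarity,
                  precursor_mz = NA_real_, isolation_half_width = NA_real_,
                  collision_energy = NA_real_)

  # top-N ddMS2 with dynamic exclusion
  pmap_tbl <- if (length(precursor_map)) list_rbind(precursor_map) else NULL
  ms2_scans <- list()
  ms2_peaks <- list()
  excl <- tibble(mz = numeric(), until = numeric())
  next_scan <- n_ms1
  if (config$top_n > 0 && nrow(ms1_peaks) > 0) {
    split_peaks <- split(ms1_peaks, ms1_peaks$scan)
    for (si in seq_len(n_ms1)) {
      pk <- split_peaks[[as.character(si)]]
      if (is.null(pk)) next
      pk <- pk[pk$intensity >= config$ms2_intensity_floor, ]
      if (nrow(pk) == 0) next
      excl <- excl[excl$until > rt[si], ]
      pk <- arrange(pk, dplyr::desc(.data$intensity))
      fired <- 0
      for (j in seq_len(nrow(pk))) {
        if (fired >= config$top_n) break
        prec <- pk$mz[j]
        if (nrow(excl) > 0 && any(abs(excl$mz - prec) < 0.01)) next
        fired <- fired + 1
        excl <- bind_rows(excl,
                          tibble(mz = prec,
                                 until = rt[si] +
                                   config$dynamic_exclusion / 60))
        next_scan <- next_scan + 1
        ev_rt <- rt[si] + fired * (config$ms1_cycle / 60) /
          (config$top_n + 1)
        ms2_scans[[length(ms2_scans) + 1]] <- tibble(
          scan = next_scan, rt = ev_rt, ms_level = 2L,
          polarity = config$polarity, precursor_mz = prec,
          isolation_half_width = config$isolation_half_width,
          collision_energy = config$collision_energy
        )
        # fragment content from the spike whose precursor is isolated
        frag <- NULL
        if (!is.null(pmap_tbl)) {
          d <- abs(pmap_tbl$mz - prec)
          if (min(d) <= config$isolation_half_width) {
            spk <- spikes[pmap_tbl$spike[which.min(d)], ]
            frag <- spk$fragments[[1]]
          }
        }
        if (!is.null(frag) && nrow(frag) > 0) {
          fmz <- vapply(frag$formula, fragment_cation_mz, numeric(1),
                        USE.NAMES = FALSE)
          ms2_peaks[[length(ms2_peaks) + 1]] <- tibble(
            scan = next_scan,
            mz = jitter_mz(fmz, config$mass_jitter_ppm),
            intensity = pk$intensity[j] * 0.5 * frag$rel_intensity
          )
        }
      }
    }
  }

  scans <- bind_rows(scans, if (length(ms2_scans)) list_rbind(ms2_scans))
  peaks <- bind_rows(ms1_peaks, if (length(ms2_peaks)) list_rbind(ms2_peaks))
  run <- ms_run(scans, peaks, run_id = run_id, role = role,
                dilution_factor = dilution_factor,
                metadata = list(config = unclass(config)))
  truth <- if (length(truth_rows)) list_rbind(truth_rows) else
    tibble(compound = character(), adduct = character(),
           formula = character(), mz = numeric(), apex_rt = numeric(),
           apex_intensity = numeric(), true_area = numeric())
  list(run = run, truth = truth)
}

#' Generate a blank run
#'
#' Noise-only run under the same acquisition configuration, optionally
#' carrying contaminant spikes (compounds that must later be removed by
#' blank subtraction).
#'
#' @inheritParams generate_run
#' @param contaminants Optional spike table of contaminants present in the
#'   blank.
#' @return An [ms_run()] with role `"blank"`.
#' @export
generate_blank <- function(config, contaminants = NULL, run_id = "blank") {
  generate_run(config, contaminants, run_id = run_id, role = "blank")$run
}

#' Generate a calibration / standard-addition response table
#'
#' Linear detector response with multiplicative log-free Gaussian noise:
#' `response = slope * level * (1 + delta)`, `delta ~ N(0, cv)`. The true
#' slope is carried in the table for recovery tests.
#'
#' @param compound Compound label.
#' @param levels Concentration levels (>= 2 distinct, all >= 0), e.g.
#'   1-600 ug/L.
#' @param slope True response per concentration unit.
#' @param noise_cv Relative noise, percent.
#' @param intercept Constant response offset (for standard-addition tables
#'   this is the response of the unspiked extract).
#' @param seed Optional integer seed.
#' @return A tibble with columns `compound`, `level`, `response`,
#'   `true_slope`, `true_intercept`.
#' @export
generate_calibration_series <- function(compound, levels, slope,
                                        noise_cv = 0, intercept = 0,
                                        seed = NULL) {
  if (any(levels < 0)) stop("negative concentration level", call. = FALSE)
  if (length(unique(levels)) < 2) {
    stop("need at least 2 distinct levels", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  mu <- intercept + slope * levels
  delta <- if (noise_cv > 0) rnorm(length(levels), 0, noise_cv / 100) else 0
  tibble(compound = compound, level = levels,
         response = mu * (1 + delta),
         true_slope = slope, true_intercept = intercept)
}
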