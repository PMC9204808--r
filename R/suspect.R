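# Suspect screening: database matching by characteristic ions, isotope
# pattern verification, ddMS2 fragment matching, Schymanski confidence
# levels, and confirmation against analytical standards.

#' Read a suspect database
#'
#' CSV schema: `name`, `formula`, `adducts` (semicolon-separated adduct
#' names), `fragment_formulas` (semicolon-separated fragment-cation
#' formulas, may be empty), `banned_eu`, `banned_spain` (logical), `rfd`
#' (oral reference dose, mg/kg/day, may be empty).
#'
#' @param path Path to the CSV file.
#' @return A tibble with list-columns `adducts` (character vectors) and
#'   `fragments` (tibbles of `formula`, `mz`).
#' @export
read_suspect_db <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("name", "formula", "adducts")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("suspect database lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"fragment_formulas" %in% names(raw)) {
    raw$fragment_formulas <- NA_character_
  }
  if (!"banned_eu" %in% names(raw)) raw$banned_eu <- FALSE
  if (!"banned_spain" %in% names(raw)) raw$banned_spain <- FALSE
  if (!"rfd" %in% names(raw)) raw$rfd <- NA_real_
  split_semis <- function(x) {
    if (is.na(x) || x == "") character(0) else
      trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  }
  out <- raw |>
    mutate(
      adducts = purrr::map(.data$adducts, split_semis),
      fragments = purrr::map(.data$fragment_formulas, function(x) {
        fs <- split_semis(x)
        tibble(formula = fs,
               mz = vapply(fs, fragment_cation_mz, numeric(1),
                           USE.NAMES = FALSE))
      }),
      banned_eu = as.logical(.data$banned_eu),
      banned_spain = as.logical(.data$banned_spain),
      rfd = as.numeric(.data$rfd)
    )
  if (any(vapply(out$adducts, length, integer(1)) == 0)) {
    stop("every suspect entry needs at least one allowed adduct",
         call. = FALSE)
  }
  out |> select(-"fragment_formulas")
}

# intensity-weighted observed m/z near a target across a peak's rt span
observed_mz <- function(run, mz, tol_ppm, rt_left, rt_right) {
  cent <- ms1_centroids(run)
  half <- mz * tol_ppm * 1e-6
  hits <- cent[abs(cent$mz - mz) <= half &
                 cent$rt >= rt_left & cent$rt <= rt_right, ]
  if (nrow(hits) == 0) return(NA_real_)
  stats::weighted.mean(hits$mz, hits$intensity)
}

#' Screen a run against a suspect database
#'
#' For every database entry and allowed adduct, extracts the EIC at the
#' theoretical m/z, detects chromatographic peaks, drops features that
#' match a blank peak (within 0.1 min) or fail the peak-shape score, and
#' emits identification records at Schymanski level 5 (exact mass only) --
#' the evidence upgrades (isotope pattern, ddMS2 fragments, standards) come
#' from the downstream verification operations.
#'
#' @param run Sample [ms_run()].
#' @param blank Blank [ms_run()] or `NULL`.
#' @param db Suspect database from [read_suspect_db()].
#' @param tol_ppm Mass tolerance, ppm (default 5).
#' @param min_shape Minimum Gaussian shape score in [0, 1].
#' @param min_height,min_snr Peak thresholds (see [detect_peaks()]).
#' @param rt_tol Blank-match rt tolerance, minutes.
#' @return A tibble of identification records (one row per suspect x
#'   adduct x retained feature), carrying the suspect's fragment list for
#'   [match_fragments()].
#' @export
screen_suspects <- function(run, blank, db, tol_ppm = 5, min_shape = 0.8,
                            min_height = 1000, min_snr = 3, rt_tol = 0.1) {
  if (is.null(db) || nrow(db) == 0) {
    stop("empty suspect database", call. = FALSE)
  }
  rows <- list()
  for (i in seq_len(nrow(db))) {
    entry <- db[i, ]
    for (a in entry$adducts[[1]]) {
      a <- normalize_adduct(a)
      theo <- adduct_mz(entry$formula, a)
      eic <- suppressWarnings(extract_eic(run, theo, tol_ppm))
      pks <- detect_peaks(eic, min_height, min_snr)
      if (nrow(pks) == 0) next
      pks <- pks[pks$shape >= min_shape, ]
      if (nrow(pks) == 0) next
      if (!is.null(blank)) {
        beic <- suppressWarnings(extract_eic(blank, theo, tol_ppm))
        bpks <- detect_peaks(beic, min_height, min_snr)
        if (nrow(bpks) > 0) {
          pks <- pks[!map_lgl(pks$apex_rt, function(r) {
            any(abs(bpks$apex_rt - r) <= rt_tol)
          }), ]
        }
      }
      if (nrow(pks) == 0) next
      for (k in seq_len(nrow(pks))) {
        obs <- observed_mz(run, theo, tol_ppm, pks$rt_left[k],
                           pks$rt_right[k])
        rows[[length(rows) + 1]] <- tibble(
          suspect = entry$name, formula = entry$formula, adduct = a,
          mz_theoretical = theo, mz_observed = obs,
          mass_error_ppm = ppm_error(obs, theo),
          apex_rt = pks$apex_rt[k], area = pks$area[k],
          height = pks$height[k], snr = pks$snr[k], shape = pks$shape[k],
          rt_left = pks$rt_left[k], rt_right = pks$rt_right[k],
          isotope_verified = NA, isotope_refuted = FALSE,
          ms2_available = NA, fragments_matched = NA_integer_,
          fragments_total = nrow(entry$fragments[[1]]),
          fragment_matches = list(tibble(formula = character(),
                                         mz = numeric(),
                                         ppm_error = numeric())),
          fragments = entry$fragments,
          banned_eu = entry$banned_eu, banned_spain = entry$banned_spain,
          rfd = entry$rfd,
          rejected = FALSE, level = 5L,
          rt_standard_delta = NA_real_, run_id = run$run_id
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(suspect = character(), formula = character(),
                  adduct = character(), mz_theoretical = numeric(),
                  mz_observed = numeric(), mass_error_ppm = numeric(),
                  apex_rt = numeric(), area = numeric(), height = numeric(),
                  snr = numeric(), shape = numeric(), rt_left = numeric(),
                  rt_right = numeric(), isotope_verified = logical(),
                  isotope_refuted = logical(), ms2_available = logical(),
                  fragments_matched = integer(),
                  fragments_total = integer(), fragment_matches = list(),
                  fragments = list(), banned_eu = logical(),
                  banned_spain = logical(), rfd = numeric(),
                  rejected = logical(), level = integer(),
                  rt_standard_delta = numeric(), run_id = character()))
  }
  list_rbind(rows)
}

# averaged spectrum over the n MS1 scans nearest an rt
apex_spectrum <- function(run, rt, n_scans = 3) {
  ms1 <- run$scans[run$scans$ms_level == 1, c("scan", "rt")]
  ms1 <- ms1[order(abs(ms1$rt - rt)), ]
  sel <- head(ms1$scan, n_scans)
  pk <- run$peaks[run$peaks$scan %in% sel, c("mz", "intensity")]
  attr(pk, "n_scans") <- length(sel)
  pk
}

#' Verify the isotope pattern of identification records
#'
#' Compares the averaged apex spectrum (the 3 MS1 scans nearest the apex)
#' with the simulated isotopologue pattern of the matched adduct. A record
#' is verified iff every predicted isotopologue at or above `min_rel`
#' percent is found within `tol_ppm` and its relative abundance agrees
#' within `intensity_tol` percent (relative). A predicted M+2 partner (the
#' Cl/S signature) that is absent -- or far weaker than predicted, beyond
#' the intensity tolerance, as when an isobar's 34S peak poses as 37Cl --
#' marks the record isotope-refuted.
#'
#' @param run Sample [ms_run()].
#' @param records Records from [screen_suspects()].
#' @param intensity_tol Relative abundance tolerance, percent (default 30).
#' @param tol_ppm Mass tolerance for isotopologue lookup.
#' @param min_rel Minimum predicted relative abundance (percent) for an
#'   isotopologue to be required; chosen so carbon-only M+1 peaks are not
#'   mandatory at low S/N.
#' @return The records with `isotope_verified` / `isotope_refuted` set.
#' @export
verify_isotope_pattern <- function(run, records, intensity_tol = 30,
                                   tol_ppm = 5, min_rel = 5) {
  if (nrow(records) == 0) return(records)
  for (i in seq_len(nrow(records))) {
    pat <- simulate_isotope_pattern(records$formula[i], records$adduct[i],
                                    min_rel = min(min_rel, 1))
    pat <- pat[pat$abundance >= min_rel, ]
    spec <- apex_spectrum(run, records$apex_rt[i])
    base_mz <- pat$mz[which.max(pat$abundance)]
    obs_at <- function(mz) {
      half <- mz * tol_ppm * 1e-6
      sum(spec$intensity[abs(spec$mz - mz) <= half])
    }
    base_int <- obs_at(base_mz)
    verified <- base_int > 0
    refuted <- FALSE
    for (k in seq_len(nrow(pat))) {
      oi <- obs_at(pat$mz[k])
      m2_type <- pat$mz[k] - base_mz > 1.5
      if (oi <= 0) {
        verified <- FALSE
        if (m2_type) refuted <- TRUE
        next
      }
      if (base_int > 0) {
        rel <- oi / base_int * 100
        if (abs(rel - pat$abundance[k]) / pat$abundance[k] * 100 >
            intensity_tol) {
          verified <- FALSE
          # an M+2 far weaker than the halogen/sulfur prediction means the
          # heteroatom cannot be there (e.g. a 34S peak posing as 37Cl)
          if (m2_type && rel < pat$abundance[k] * (1 - intensity_tol / 100)) {
            refuted <- TRUE
          }
        }
      }
    }
    records$isotope_verified[i] <- verified
    records$isotope_refuted[i] <- refuted
  }
  records
}

#' Match ddMS2 fragments for identification records
#'
#' Gathers MS2 events whose precursor matches each record (within half the
#' isolation window and 0.2 min of the apex) and counts the theoretical
#' fragments of the suspect found among the fragment centroids within
#' `tol_ppm`. At least two matched fragments are required for a proper
#' putative identification (SANTE guidance); a record whose suspect has
#' fragments listed but none matching is flagged rejected. Records with no
#' nearby MS2 event are marked `ms2_available = FALSE` and left untouched.
#'
#' @param run Sample [ms_run()].
#' @param records Records from [screen_suspects()].
#' @param tol_ppm Fragment mass tolerance, ppm.
#' @param mz_tol,rt_tol Precursor match tolerances (see
#'   [ms2_events_near()]).
#' @return Records with `fragments_matched`, `fragment_matches`,
#'   `ms2_available` and `rejected` updated.
#' @export
match_fragments <- function(run, records, tol_ppm = 5, mz_tol = 2.5,
                            rt_tol = 0.2) {
  if (nrow(records) == 0) return(records)
  for (i in seq_len(nrow(records))) {
    events <- ms2_events_near(run, records$mz_theoretical[i],
                              records$apex_rt[i], mz_tol, rt_tol)
    if (nrow(events) == 0) {
      records$ms2_available[i] <- FALSE
      next
    }
    records$ms2_available[i] <- TRUE
    frag <- records$fragments[[i]]
    if (nrow(frag) == 0) {
      records$fragments_matched[i] <- 0L
      next
    }
    all_pk <- list_rbind(events$peaks)
    matches <- purrr::map(seq_len(nrow(frag)), function(k) {
      half <- frag$mz[k] * tol_ppm * 1e-6
      hits <- all_pk[abs(all_pk$mz - frag$mz[k]) <= half, ]
      if (nrow(hits) == 0) return(NULL)
      best <- hits$mz[which.max(hits$intensity)]
      tibble(formula = frag$formula[k], mz = frag$mz[k],
             ppm_error = ppm_error(best, frag$mz[k]))
    })
    matches <- list_rbind(purrr::compact(matches))
    n <- if (is.null(matches) || nrow(matches) == 0) 0L else nrow(matches)
    records$fragments_matched[i] <- n
    if (n > 0) records$fragment_matches[[i]] <- matches
    if (n == 0) records$rejected[i] <- TRUE
  }
  records
}

#' Assign Schymanski confidence levels
#'
#' Codifies the evidence-to-level mapping: level 5 = exact mass only;
#' 4 = isotope-verified (supports a unique formula); 3 = at least two
#' matched ddMS2 fragments; 2 = two fragments and a verified isotope
#' pattern; 1 = confirmed against an analytical standard (rt shift
#' < 0.1 min plus the two-fragment rule). Records refuted by their isotope
#' pattern or by fully mismatching fragments are excluded from the output.
#'
#' @param records Records carrying accumulated evidence.
#' @return Records with `level` set, refuted/rejected rows removed.
#' @export
assign_level <- function(records) {
  if (nrow(records) == 0) return(records)
  records$level <- map_int(seq_len(nrow(records)), function(i) {
    frag2 <- !is.na(records$fragments_matched[i]) &&
      records$fragments_matched[i] >= 2
    iso <- isTRUE(records$isotope_verified[i])
    std <- !is.na(records$rt_standard_delta[i]) &&
      records$rt_standard_delta[i] < 0.1
    if (std && frag2) return(1L)
    if (frag2 && iso) return(2L)
    if (frag2) return(3L)
    if (iso) return(4L)
    5L
  })
  records[!records$rejected & !records$isotope_refuted, ]
}

#' Confirm identification records against a standard run
#'
#' Screens the record's suspect in an analytical-standard run, computes
#' the retention-time shift, and upgrades the record to level 1 iff the
#' shift is below 0.1 min and the two-fragment rule holds.
#'
#' @param records Records (after [match_fragments()]).
#' @param standard_run [ms_run()] of the injected analytical standard.
#' @param tol_ppm Mass tolerance, ppm.
#' @param min_height,min_snr Peak thresholds for the standard run.
#' @return Records with `rt_standard_delta` set and levels re-assigned.
#' @export
confirm_with_standard <- function(records, standard_run, tol_ppm = 5,
                                  min_height = 1000, min_snr = 3) {
  if (nrow(records) == 0) return(records)
  for (i in seq_len(nrow(records))) {
    eic <- suppressWarnings(extract_eic(standard_run,
                                        records$mz_theoretical[i], tol_ppm))
    pks <- detect_peaks(eic, min_height, min_snr)
    if (nrow(pks) == 0) {
      stop("analyte '", records$suspect[i],
           "' not found in the standard run", call. = FALSE)
    }
    best <- pks[which.max(pks$area), ]
    records$rt_standard_delta[i] <- abs(records$apex_rt[i] - best$apex_rt)
  }
  assign_level(records)
}
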