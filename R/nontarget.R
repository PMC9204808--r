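# Unknown analysis: Compound-Discoverer-style feature filtering, homolog
# (ethoxylate) series detection, and candidate proposal from a local table.

#' Exact mass of the ethylene oxide repeat unit
#'
#' Polyethoxylate m/z ladders are spaced by one C2H4O subunit. The exact
#' monoisotopic mass of C2H4O is 44.02621 Da, the default ladder spacing
#' used by [detect_homolog_series()].
#'
#' @return Mass in Da.
#' @export
ethoxylate_repeat_unit <- function() monoisotopic_mass("C2H4O")

#' Apply the unknown-analysis filters
#'
#' Reproduces the filter cascade applied to untargeted features: blank
#' subtraction ("no peak area in any blank"), minimum peak area in the
#' sample (default 1e6 counts), and annotation with all CHNOPS molecular
#' formula candidates within the mass tolerance; features with no
#' candidate formula are dropped.
#'
#' @param features Feature tibble from [detect_features()] on the sample.
#' @param blank_features Feature tibble from the blank run (may be empty).
#' @param element_bounds Bounds for [enumerate_formulas()]; the default is
#'   C, H, N, O, P, S only.
#' @param min_area Minimum sample peak area (counts x min equivalents of
#'   the vendor's 1e6-count rule).
#' @param tol_ppm Mass tolerance, ppm.
#' @param adduct Adduct assumed when enumerating formulas.
#' @return The retained features with a `candidates` list-column (tibbles
#'   from [enumerate_formulas()]) and an `n_candidates` column.
#' @export
apply_unknown_filters <- function(features, blank_features = NULL,
                                  element_bounds = default_element_bounds(),
                                  min_area = 1e6, tol_ppm = 5,
                                  adduct = "[M+H]+") {
  if (!is.null(blank_features)) {
    features <- subtract_blank(features, blank_features)
  }
  features <- features[features$area >= min_area, ]
  if (nrow(features) == 0) {
    features$candidates <- list()
    features$n_candidates <- integer(0)
    return(features)
  }
  features$candidates <- purrr::map(features$mz, function(m) {
    enumerate_formulas(m, adduct = adduct, tol_ppm = tol_ppm,
                       bounds = element_bounds)
  })
  features$n_candidates <- map_int(features$candidates, nrow)
  features[features$n_candidates > 0, ]
}

# averaged, lightly merged apex spectrum used for ladder search
merged_apex_spectrum <- function(run, rt, n_scans = 3, merge_tol = 0.005) {
  spec <- apex_spectrum(run, rt, n_scans)
  if (nrow(spec) == 0) return(spec)
  spec <- arrange(spec, .data$mz)
  grp <- cumsum(c(TRUE, diff(spec$mz) > merge_tol))
  spec |>
    mutate(grp = grp) |>
    group_by(.data$grp) |>
    summarise(mz = stats::weighted.mean(.data$mz, .data$intensity),
              intensity = sum(.data$intensity)) |>
    ungroup() |>
    select("mz", "intensity")
}

#' Detect a homolog series through a feature
#'
#' Within the averaged apex spectrum of the feature, greedily extends an
#' m/z ladder upward and downward in steps of the repeat-unit mass (each
#' rung matched within `tol_ppm`; when two centroids qualify, the more
#' intense wins). Members must co-elute with the seed feature: the apex of
#' each member's own EIC must lie within `coelution_tol` minutes of the
#' feature apex, since ethoxylate oligomer mixtures produce a single
#' chromatographic peak. Maximal ladders with at least `min_members`
#' members are reported.
#'
#' @param run An [ms_run()].
#' @param feature One-row feature tibble (needs `mz` and `apex_rt`).
#' @param repeat_unit Ladder spacing in Da; default the exact C2H4O mass
#'   44.02621 (use 14.01565 for CH2 homologs).
#' @param tol_ppm Rung match tolerance, ppm.
#' @param min_members Minimum ladder length.
#' @param min_intensity Minimum centroid intensity for a rung.
#' @param coelution_tol Apex rt agreement between members, minutes.
#' @return A tibble with zero or one row: `repeat_unit`, `n_members`,
#'   `mz_min`, `mz_max`, `apex_rt`, and a `members` list-column (tibble of
#'   `mz`, `intensity`, `n` offset from the seed).
#' @export
detect_homolog_series <- function(run, feature,
                                  repeat_unit = ethoxylate_repeat_unit(),
                                  tol_ppm = 5, min_members = 3,
                                  min_intensity = 1000,
                                  coelution_tol = 0.05) {
  stopifnot(nrow(feature) == 1, min_members >= 2)
  spec <- merged_apex_spectrum(run, feature$apex_rt)
  empty <- tibble(repeat_unit = numeric(), n_members = integer(),
                  mz_min = numeric(), mz_max = numeric(),
                  apex_rt = numeric(), members = list())
  if (nrow(spec) == 0) return(empty)
  spec <- spec[spec$intensity >= min_intensity, ]
  if (nrow(spec) == 0) return(empty)

  coelutes <- function(mz) {
    eic <- suppressWarnings(extract_eic(run, mz, tol_ppm))
    win <- eic[abs(eic$rt - feature$apex_rt) <= 0.3, ]
    if (nrow(win) == 0 || max(win$intensity) <= 0) return(FALSE)
    abs(win$rt[which.max(win$intensity)] - feature$apex_rt) <=
      coelution_tol
  }
  find_rung <- function(target) {
    half <- target * tol_ppm * 1e-6
    hits <- spec[abs(spec$mz - target) <= half, ]
    if (nrow(hits) == 0) return(NULL)
    hits[which.max(hits$intensity), ]
  }

  seed <- find_rung(feature$mz)
  if (is.null(seed)) return(empty)
  members <- tibble(mz = seed$mz, intensity = seed$intensity, n = 0L)
  for (dir in c(1, -1)) {
    cur <- seed$mz
    step <- 0L
    repeat {
      step <- step + dir
      rung <- find_rung(cur + dir * repeat_unit)
      if (is.null(rung)) break
      if (!coelutes(rung$mz)) break
      members <- bind_rows(members,
                           tibble(mz = rung$mz, intensity = rung$intensity,
                                  n = step))
      cur <- rung$mz
    }
  }
  members <- arrange(members, .data$mz)
  if (nrow(members) < min_members) return(empty)
  tibble(repeat_unit = repeat_unit, n_members = nrow(members),
         mz_min = min(members$mz), mz_max = max(members$mz),
         apex_rt = feature$apex_rt, members = list(members))
}

#' Read a local candidate table
#'
#' A plain-text stand-in for online compound libraries: columns `formula`,
#' `name`, `rank` (e.g. a citation-count rank; 1 = most cited).
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_candidate_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(c("formula", "name", "rank"), names(tab))
  if (length(missing) > 0) {
    stop("candidate table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab
}

#' Propose named candidates for filtered features
#'
#' Joins each feature's enumerated molecular formulas against a local
#' candidate table and returns the named candidates ranked by the table's
#' rank field. Features whose formulas match nothing yield no rows
#' (unnamed compounds are ruled out).
#'
#' @param features Output of [apply_unknown_filters()] (needs `mz` and the
#'   `candidates` list-column).
#' @param candidate_table Tibble from [read_candidate_table()].
#' @return A tibble with one row per (feature, named candidate):
#'   `feature_mz`, `apex_rt`, `formula`, `ppm_error`, `name`, `rank`.
#' @export
propose_candidates <- function(features, candidate_table) {
  if (!all(c("formula", "name", "rank") %in% names(candidate_table))) {
    stop("malformed candidate table", call. = FALSE)
  }
  if (nrow(features) == 0) {
    return(tibble(feature_mz = numeric(), apex_rt = numeric(),
                  formula = character(), ppm_error = numeric(),
                  name = character(), rank = numeric()))
  }
  out <- purrr::map(seq_len(nrow(features)), function(i) {
    cand <- features$candidates[[i]]
    hits <- dplyr::inner_join(cand, candidate_table, by = "formula")
    if (nrow(hits) == 0) return(NULL)
    tibble(feature_mz = features$mz[i], apex_rt = features$apex_rt[i],
           formula = hits$formula, ppm_error = hits$ppm_error,
           name = hits$name, rank = hits$rank) |>
      arrange(.data$rank)
  }) |>
    purrr::compact()
  if (length(out) == 0) {
    return(tibble(feature_mz = numeric(), apex_rt = numeric(),
                  formula = character(), ppm_error = numeric(),
                  name = character(), rank = numeric()))
  }
  list_rbind(out)
}
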