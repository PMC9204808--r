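# Centroided LC-MS run container and mzML input/output (via mzR/proteowizard).

#' Construct an LC-MS run object
#'
#' `ms_run` is the package's in-memory model of one centroided LC-MS run:
#' a scan table (one row per spectrum) plus a long centroid table (one row
#' per m/z, intensity pair). Retention times are minutes throughout.
#'
#' @param scans Tibble with columns `scan` (integer id), `rt` (minutes),
#'   `ms_level` (1 or 2), `polarity` (`"+"` or `"-"`), and for MS2 rows
#'   `precursor_mz`, `isolation_half_width`, `collision_energy`.
#' @param peaks Tibble with columns `scan`, `mz`, `intensity`; centroids of
#'   each scan. Sorted by (scan, mz) on construction.
#' @param run_id Character label for the run.
#' @param role One of `"sample"`, `"blank"`, `"solvent-standard"`,
#'   `"spiked-sample"`.
#' @param dilution_factor Dilution applied to the formulation before
#'   injection (>= 1); carried through to quantitation.
#' @param metadata Free-form named list.
#' @return An object of class `ms_run`.
#' @export
ms_run <- function(scans, peaks, run_id = "run", role = "sample",
                   dilution_factor = 1, metadata = list()) {
  role <- match.arg(role,
                    c("sample", "blank", "solvent-standard", "spiked-sample"))
  stopifnot(dilution_factor >= 1)
  scans <- as_tibble(scans)
  peaks <- as_tibble(peaks)
  for (col in c("precursor_mz", "isolation_half_width", "collision_energy")) {
    if (!col %in% names(scans)) scans[[col]] <- NA_real_
  }
  if (!"polarity" %in% names(scans)) scans$polarity <- "+"
  scans <- arrange(scans, .data$rt, .data$scan)
  if (any(scans$ms_level == 2 & is.na(scans$precursor_mz))) {
    stop("MS2 scans must carry a precursor m/z", call. = FALSE)
  }
  # canonical chronological scan ids, so peak order is reproducible
  if (nrow(scans) > 0) {
    remap <- setNames(seq_len(nrow(scans)), scans$scan)
    scans$scan <- seq_len(nrow(scans))
    if (nrow(peaks) > 0) {
      peaks$scan <- unname(remap[as.character(peaks$scan)])
    }
  }
  if (nrow(peaks) > 0) {
    if (any(is.na(peaks$scan))) {
      stop("peaks reference unknown scan ids", call. = FALSE)
    }
    if (any(peaks$intensity <= 0)) {
      stop("centroid intensities must be positive", call. = FALSE)
    }
    peaks <- arrange(peaks, .data$scan, .data$mz)
  }
  structure(
    list(scans = scans, peaks = peaks, run_id = run_id, role = role,
         dilution_factor = dilution_factor, metadata = metadata),
    class = "ms_run"
  )
}

#' @export
print.ms_run <- function(x, ...) {
  n1 <- sum(x$scans$ms_level == 1)
  n2 <- sum(x$scans$ms_level == 2)
  cat("<ms_run> ", x$run_id, " (", x$role, ")\n", sep = "")
  cat("  ", n1, " MS1 scans, ", n2, " ddMS2 events, ",
      nrow(x$peaks), " centroids\n", sep = "")
  if (nrow(x$scans) > 0) {
    cat("  rt range: ", round(min(x$scans$rt), 2), "-",
        round(max(x$scans$rt), 2), " min\n", sep = "")
  }
  cat("  dilution factor: ", x$dilution_factor, "\n", sep = "")
  invisible(x)
}

# centroids of MS1 scans joined with scan rt
ms1_centroids <- function(run) {
  ms1 <- run$scans[run$scans$ms_level == 1, c("scan", "rt")]
  dplyr::inner_join(run$peaks, ms1, by = "scan")
}

#' Read a centroided mzML file
#'
#' Loads an mzML file into an [ms_run()]. MS level, precursor metadata and
#' polarity are preserved; retention times are converted to minutes.
#' Profile-mode spectra are rejected (profile-to-centroid conversion is out
#' of scope).
#'
#' @param path Path to an mzML file.
#' @param role,dilution_factor,run_id Passed to [ms_run()]; `run_id`
#'   defaults to the file name.
#' @return An `ms_run`.
#' @export
read_run <- function(path, role = "sample", dilution_factor = 1,
                     run_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  handle <- mzR::openMSfile(path)
  on.exit(suppressWarnings(mzR::close(handle)), add = TRUE)
  hdr <- mzR::header(handle)
  if (nrow(hdr) == 0) {
    warning("mzML file contains no spectra: ", path)
    return(ms_run(
      scans = tibble(scan = integer(), rt = numeric(), ms_level = integer(),
                     polarity = character()),
      peaks = tibble(scan = integer(), mz = numeric(), intensity = numeric()),
      run_id = run_id %||% basename(path), role = role,
      dilution_factor = dilution_factor
    ))
  }
  if (any(!is.na(hdr$centroided) & !hdr$centroided)) {
    stop("profile-mode spectra found in ", path,
         "; only centroided data are supported", call. = FALSE)
  }
  if (any(is.na(hdr$retentionTime))) {
    stop("spectra without retention time in ", path, call. = FALSE)
  }
  pk <- mzR::peaks(handle)
  if (is.matrix(pk)) pk <- list(pk)
  scans <- tibble(
    scan = seq_len(nrow(hdr)),
    rt = hdr$retentionTime / 60,
    ms_level = as.integer(hdr$msLevel),
    polarity = dplyr::case_when(hdr$polarity == 1 ~ "+",
                                hdr$polarity == 0 ~ "-",
                                TRUE ~ NA_character_),
    precursor_mz = ifelse(hdr$msLevel >= 2, hdr$precursorMZ, NA_real_),
    isolation_half_width = ifelse(hdr$msLevel >= 2,
                                  hdr$isolationWindowLowerOffset, NA_real_),
    collision_energy = ifelse(hdr$msLevel >= 2, hdr$collisionEnergy,
                              NA_real_)
  )
  peaks <- purrr::imap(pk, function(m, i) {
    if (nrow(m) == 0) return(NULL)
    tibble(scan = i, mz = unname(m[, 1]), intensity = unname(m[, 2]))
  }) |> list_rbind()
  if (nrow(peaks) == 0) {
    peaks <- tibble(scan = integer(), mz = numeric(), intensity = numeric())
  }
  ms_run(scans, peaks, run_id = run_id %||% basename(path), role = role,
         dilution_factor = dilution_factor)
}

#' Write a run to mzML
#'
#' Writes a standards-conformant centroided mzML file; retention times are
#' stored in seconds as the format requires. `read_run(write_run(run))`
#' preserves every (rt, m/z, intensity) to float precision.
#'
#' @param run An [ms_run()].
#' @param path Output path (".mzML").
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  stopifnot(inherits(run, "ms_run"))
  sc <- run$scans
  n <- nrow(sc)
  if (n == 0) stop("cannot write an empty run to mzML", call. = FALSE)
  pk <- purrr::map(sc$scan, function(s) {
    m <- run$peaks[run$peaks$scan == s, c("mz", "intensity")]
    matrix(c(m$mz, m$intensity), ncol = 2,
           dimnames = list(NULL, c("mz", "intensity")))
  })
  counts <- vapply(pk, nrow, integer(1))
  bp <- function(m, col) if (nrow(m) == 0) 0 else m[which.max(m[, 2]), col]
  hdr <- data.frame(
    seqNum = seq_len(n),
    acquisitionNum = seq_len(n),
    msLevel = as.integer(sc$ms_level),
    polarity = ifelse(is.na(sc$polarity), -1L,
                      ifelse(sc$polarity == "+", 1L, 0L)),
    peaksCount = counts,
    totIonCurrent = vapply(pk, function(m) sum(m[, 2]), numeric(1)),
    retentionTime = sc$rt * 60,
    basePeakMZ = vapply(pk, bp, numeric(1), col = 1),
    basePeakIntensity = vapply(pk, bp, numeric(1), col = 2),
    collisionEnergy = ifelse(is.na(sc$collision_energy), 0,
                             sc$collision_energy),
    ionisationEnergy = 0,
    lowMZ = vapply(pk, function(m) if (nrow(m)) min(m[, 1]) else 0,
                   numeric(1)),
    highMZ = vapply(pk, function(m) if (nrow(m)) max(m[, 1]) else 0,
                    numeric(1)),
    precursorScanNum = 0L,
    precursorMZ = ifelse(is.na(sc$precursor_mz), NA_real_, sc$precursor_mz),
    precursorCharge = ifelse(sc$ms_level >= 2, 1L, NA_integer_),
    precursorIntensity = ifelse(sc$ms_level >= 2, 0, NA_real_),
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0,
    filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = ifelse(is.na(sc$precursor_mz), NA_real_,
                                     sc$precursor_mz),
    isolationWindowLowerOffset = ifelse(is.na(sc$isolation_half_width),
                                        NA_real_, sc$isolation_half_width),
    isolationWindowUpperOffset = ifelse(is.na(sc$isolation_half_width),
                                        NA_real_, sc$isolation_half_width),
    scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE
  )
  mzR::writeMSData(object = pk, file = path, header = hdr)
  invisible(path)
}

#' Tabular serialization of a run
#'
#' One row per centroid with its scan metadata; empty scans appear as a
#' single row with `NA` m/z. Useful for plain-text fixtures.
#'
#' @param run An [ms_run()].
#' @return A tibble.
#' @export
run_to_table <- function(run) {
  sc <- run$scans
  joined <- left_join(sc, run$peaks, by = "scan")
  joined[, c("scan", "rt", "ms_level", "polarity", "precursor_mz",
             "isolation_half_width", "collision_energy", "mz", "intensity")]
}

#' @param table A tibble as produced by [run_to_table()].
#' @param ... Passed to [ms_run()] (`run_id`, `role`, `dilution_factor`).
#' @rdname run_to_table
#' @export
run_from_table <- function(table, ...) {
  scans <- distinct(table, .data$scan, .data$rt, .data$ms_level,
                    .data$polarity, .data$precursor_mz,
                    .data$isolation_half_width, .data$collision_energy)
  peaks <- table |>
    filter(!is.na(.data$mz)) |>
    select("scan", "mz", "intensity")
  ms_run(scans, peaks, ...)
}

#' ddMS2 events near a precursor
#'
#' Returns all MS2 scans whose precursor m/z lies within `mz_tol` Da and
#' whose retention time lies within `rt_tol` minutes of the query, ordered
#' by rt. The default `mz_tol` of 2.5 Da is half the instrument's 5.0 Da
#' isolation window.
#'
#' @param run An [ms_run()].
#' @param mz,rt Query precursor m/z (Da) and retention time (minutes).
#' @param mz_tol,rt_tol Match half-windows (Da, minutes); both must be
#'   >= 0.
#' @return A tibble with one row per matching MS2 scan (`scan`, `rt`,
#'   `precursor_mz`, `collision_energy`) and a `peaks` list-column of
#'   fragment centroids.
#' @export
ms2_events_near <- function(run, mz, rt, mz_tol = 2.5, rt_tol = 0.2) {
  stopifnot(mz_tol >= 0, rt_tol >= 0)
  query_mz <- mz
  query_rt <- rt
  sc <- run$scans |>
    filter(.data$ms_level == 2,
           abs(.data$precursor_mz - query_mz) <= mz_tol,
           abs(.data$rt - query_rt) <= rt_tol) |>
    arrange(.data$rt)
  sc$peaks <- purrr::map(sc$scan, function(s) {
    run$peaks[run$peaks$scan == s, c("mz", "intensity")]
  })
  sc[, c("scan", "rt", "precursor_mz", "collision_energy", "peaks")]
}
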