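# End-to-end orchestration of the suspect, unknown and quantitation arms.
# Each stage logs record counts so the filter funnel is auditable.

#' Pipeline configuration
#'
#' Bundles inputs and tunables for the pipeline runners. Runs and tables
#' may be given either as file paths (mzML / CSV, loaded on demand) or as
#' in-memory objects.
#'
#' @param sample,blank,standard [ms_run()] objects or mzML paths (blank
#'   and standard optional).
#' @param db Suspect database tibble or CSV path.
#' @param candidate_table Candidate table tibble or CSV path (unknown arm).
#' @param tol_ppm Mass tolerance, ppm.
#' @param rt_tol Retention-time match tolerance, minutes.
#' @param intensity_tol Isotope-pattern relative intensity tolerance,
#'   percent.
#' @param min_height,min_snr Peak detection thresholds.
#' @param min_shape Minimum Gaussian peak-shape score.
#' @param min_area Minimum sample peak area for the unknown filters.
#' @param element_bounds Bounds for formula enumeration.
#' @param repeat_unit Homolog ladder spacing, Da.
#' @param dilution_factor Formulation dilution before injection.
#' @param solid_mass_per_volume g/mL for solid formulations, else `NULL`.
#' @param verbose Log per-stage record counts via `message()`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sample, blank = NULL, standard = NULL,
                            db = NULL, candidate_table = NULL,
                            tol_ppm = 5, rt_tol = 0.1, intensity_tol = 30,
                            min_height = 1000, min_snr = 3,
                            min_shape = 0.8, min_area = 1e6,
                            element_bounds = default_element_bounds(),
                            repeat_unit = ethoxylate_repeat_unit(),
                            dilution_factor = 1,
                            solid_mass_per_volume = NULL,
                            verbose = FALSE) {
  stopifnot(tol_ppm > 0, rt_tol > 0, intensity_tol > 0)
  structure(
    list(sample = sample, blank = blank, standard = standard, db = db,
         candidate_table = candidate_table, tol_ppm = tol_ppm,
         rt_tol = rt_tol, intensity_tol = intensity_tol,
         min_height = min_height, min_snr = min_snr,
         min_shape = min_shape, min_area = min_area,
         element_bounds = element_bounds, repeat_unit = repeat_unit,
         dilution_factor = dilution_factor,
         solid_mass_per_volume = solid_mass_per_volume,
         verbose = verbose),
    class = "pipeline_config"
  )
}

resolve_run <- function(x, role = "sample") {
  if (is.null(x)) return(NULL)
  if (inherits(x, "ms_run")) x else read_run(x, role = role)
}

resolve_db <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) read_suspect_db(x) else x
}

log_stage <- function(config, stage, n) {
  if (isTRUE(config$verbose)) {
    message(sprintf("[%s] %d record(s)", stage, n))
  }
}

#' Run the suspect-screening arm end-to-end
#'
#' Reads the runs, screens the suspect database, verifies isotope
#' patterns, matches ddMS2 fragments, assigns Schymanski levels, and (if a
#' standard run is configured) attempts standard confirmation for each
#' surviving record. Deterministic given its inputs.
#'
#' @param config A [pipeline_config()] with at least `sample` and `db`.
#' @return The identification-record tibble.
#' @export
run_suspect_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  db <- resolve_db(config$db)
  if (is.null(db) || nrow(db) == 0) {
    stop("empty suspect database", call. = FALSE)
  }
  sample <- resolve_run(config$sample)
  blank <- resolve_run(config$blank, role = "blank")
  records <- screen_suspects(sample, blank, db,
                             tol_ppm = config$tol_ppm,
                             min_shape = config$min_shape,
                             min_height = config$min_height,
                             min_snr = config$min_snr,
                             rt_tol = config$rt_tol)
  log_stage(config, "screen_suspects", nrow(records))
  records <- verify_isotope_pattern(sample, records,
                                    intensity_tol = config$intensity_tol,
                                    tol_ppm = config$tol_ppm)
  records <- match_fragments(sample, records, tol_ppm = config$tol_ppm)
  log_stage(config, "match_fragments",
            sum(records$fragments_matched >= 2, na.rm = TRUE))
  records <- assign_level(records)
  log_stage(config, "assign_level", nrow(records))
  standard <- resolve_run(config$standard, role = "solvent-standard")
  if (!is.null(standard) && nrow(records) > 0) {
    confirmed <- purrr::map(seq_len(nrow(records)), function(i) {
      tryCatch(confirm_with_standard(records[i, ], standard,
                                     tol_ppm = config$tol_ppm,
                                     min_height = config$min_height,
                                     min_snr = config$min_snr),
               error = function(e) records[i, ])
    })
    records <- list_rbind(confirmed)
    log_stage(config, "confirm_with_standard",
              sum(records$level == 1, na.rm = TRUE))
  }
  records
}

#' Run the unknown-analysis arm end-to-end
#'
#' Untargeted feature detection on sample and blank, blank subtraction,
#' the area / formula filters, homolog-series detection seeded on each
#' retained feature, and named-candidate proposal against the local
#' candidate table.
#'
#' @param config A [pipeline_config()].
#' @return A list with `features` (filtered, candidate-annotated),
#'   `series` (homolog series tibble) and `candidates` (named candidates).
#' @export
run_unknown_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  sample <- resolve_run(config$sample)
  blank <- resolve_run(config$blank, role = "blank")
  feats <- detect_features(sample, min_height = config$min_height,
                           min_snr = config$min_snr,
                           tol_ppm = config$tol_ppm)
  log_stage(config, "detect_features", nrow(feats))
  bfeats <- if (is.null(blank)) feats[0, ] else
    detect_features(blank, min_height = config$min_height,
                    min_snr = config$min_snr, tol_ppm = config$tol_ppm)
  filtered <- apply_unknown_filters(feats, bfeats,
                                    element_bounds = config$element_bounds,
                                    min_area = config$min_area,
                                    tol_ppm = config$tol_ppm)
  log_stage(config, "apply_unknown_filters", nrow(filtered))
  series <- purrr::map(seq_len(nrow(filtered)), function(i) {
    detect_homolog_series(sample, filtered[i, ],
                          repeat_unit = config$repeat_unit,
                          tol_ppm = config$tol_ppm,
                          min_intensity = config$min_height)
  })
  empty_series <- tibble(repeat_unit = numeric(), n_members = integer(),
                         mz_min = numeric(), mz_max = numeric(),
                         apex_rt = numeric(), members = list())
  series <- if (length(series)) list_rbind(series) else empty_series
  if (nrow(series) > 0) {
    series <- distinct(series, .data$mz_min, .data$mz_max, .data$n_members,
                       .keep_all = TRUE)
  }
  log_stage(config, "detect_homolog_series", nrow(series))
  cand <- if (is.null(config$candidate_table)) {
    propose_candidates(filtered[0, ],
                       tibble(formula = character(), name = character(),
                              rank = numeric()))
  } else {
    tab <- if (is.character(config$candidate_table)) {
      read_candidate_table(config$candidate_table)
    } else {
      config$candidate_table
    }
    propose_candidates(filtered, tab)
  }
  log_stage(config, "propose_candidates", nrow(cand))
  list(features = filtered, series = series, candidates = cand)
}

#' Run the quantitation, validation and risk arm
#'
#' For each analyte: fits the solvent and standard-addition curves,
#' computes the matrix effect from their slopes, interday RSD from the
#' replicate responses, the method LOQ, quantifies the sample response on
#' the solvent curve (the no-matrix-effect convention), and flags banned
#' compounds against the 0.1 % w/w threshold.
#'
#' @param config A [pipeline_config()] (uses `dilution_factor`,
#'   `solid_mass_per_volume`, `db`).
#' @param response_tables A list with elements `solvent` and
#'   `standard_addition` (tibbles: `compound`, `level`, `response`,
#'   optional `snr`), `replicates` (tibble: `compound`, `response`) and
#'   `samples` (tibble: `compound`, `response`, optional `rt_shift`).
#' @return A list with `validation` (one row per analyte), `quantitation`
#'   (concentrations in formulation units) and `risk` (flags, when a
#'   database is configured).
#' @export
run_quant <- function(config, response_tables) {
  stopifnot(inherits(config, "pipeline_config"))
  rt_tabs <- response_tables
  stopifnot(!is.null(rt_tabs$solvent), !is.null(rt_tabs$samples))
  analytes <- unique(rt_tabs$samples$compound)
  val_rows <- list()
  quant_rows <- list()
  for (cmp in analytes) {
    solv_d <- rt_tabs$solvent[rt_tabs$solvent$compound == cmp, ]
    if (nrow(solv_d) == 0) {
      stop("no solvent calibration for analyte '", cmp, "'", call. = FALSE)
    }
    solv <- fit_calibration(solv_d, "solvent", compound = cmp)
    me <- NA_real_
    if (!is.null(rt_tabs$standard_addition)) {
      sa_d <- rt_tabs$standard_addition[
        rt_tabs$standard_addition$compound == cmp, ]
      if (nrow(sa_d) > 0) {
        sa <- fit_calibration(sa_d, "standard-addition", compound = cmp)
        me <- matrix_effect(sa$slope, solv$slope)
      }
    }
    rsd <- NA_real_
    if (!is.null(rt_tabs$replicates)) {
      reps <- rt_tabs$replicates$response[
        rt_tabs$replicates$compound == cmp]
      if (length(reps) >= 3) rsd <- interday_rsd(reps)
    }
    loq <- estimate_loq(solv, config$dilution_factor,
                        config$solid_mass_per_volume)
    srow <- rt_tabs$samples[rt_tabs$samples$compound == cmp, ][1, ]
    rt_shift <- if ("rt_shift" %in% names(srow)) srow$rt_shift else 0
    val_rows[[cmp]] <- validation_report(cmp, me, rsd, solv$r_squared,
                                         loq, rt_shift)
    q <- quantify_sample(srow$response, solv, config$dilution_factor,
                         config$solid_mass_per_volume, loq = loq)
    q$compound <- cmp
    quant_rows[[cmp]] <- q
  }
  validation <- list_rbind(val_rows)
  quantitation <- list_rbind(quant_rows)
  log_stage(config, "run_quant", nrow(quantitation))
  risk <- NULL
  db <- resolve_db(config$db)
  if (!is.null(db)) {
    risk <- flag_banned(
      quantitation[!quantitation$below_loq,
                   c("compound", "concentration", "units")],
      db
    )
  }
  list(validation = validation, quantitation = quantitation, risk = risk)
}
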