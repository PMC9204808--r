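# Risk screening: banned co-formulants against the 0.1 % w/w threshold,
# and oral-reference-dose fold comparisons.

# convert a quantified concentration to percent w/w
percent_ww <- function(concentration, units, density = 1) {
  switch(units,
    "g/L" = concentration / (1000 * density) * 100,
    "ug/g" = concentration / 1e6 * 100,
    "mg/g" = concentration / 1e3 * 100,
    stop("cannot convert units '", units, "' to % w/w", call. = FALSE)
  )
}

#' Flag banned co-formulants against the 0.1 % w/w threshold
#'
#' Banned co-formulants are tolerated as unintentional impurities below
#' 0.1 percent w/w. Quantified concentrations are converted to percent
#' w/w (for liquids a density of 1 g/mL is assumed unless supplied -- the
#' assumption is recorded in the output) and each banned, quantified
#' compound gets a flag row.
#'
#' @param quant_results Tibble with columns `compound`, `concentration`,
#'   `units` (`"g/L"`, `"ug/g"` or `"mg/g"`).
#' @param db Suspect database from [read_suspect_db()] (supplies
#'   `banned_eu`, `banned_spain`, `rfd`).
#' @param density Formulation density in g/mL for g/L-to-w/w conversion.
#' @param threshold_pct Threshold in percent w/w (default 0.1).
#' @return A tibble with one row per quantified compound: `compound`,
#'   `concentration`, `units`, `percent_ww`, `banned_eu`, `banned_spain`,
#'   `rfd`, `exceeds_threshold`, `density_assumed`.
#' @export
flag_banned <- function(quant_results, db, density = 1,
                        threshold_pct = 0.1) {
  stopifnot(all(c("compound", "concentration", "units") %in%
                  names(quant_results)))
  joined <- left_join(
    quant_results,
    db[, c("name", "banned_eu", "banned_spain", "rfd")],
    by = c(compound = "name")
  )
  joined$banned_eu[is.na(joined$banned_eu)] <- FALSE
  joined$banned_spain[is.na(joined$banned_spain)] <- FALSE
  joined$percent_ww <- map_dbl(seq_len(nrow(joined)), function(i) {
    percent_ww(joined$concentration[i], joined$units[i], density)
  })
  joined$exceeds_threshold <- joined$percent_ww >= threshold_pct &
    (joined$banned_eu | joined$banned_spain)
  joined$density_assumed <- joined$units == "g/L"
  joined[, c("compound", "concentration", "units", "percent_ww",
             "banned_eu", "banned_spain", "rfd", "exceeds_threshold",
             "density_assumed")]
}

#' Fold comparison of oral reference doses
#'
#' How many times larger one compound's RfD is than another's:
#' `rfd_reference / rfd_other`, rounded half-up to an integer for
#' reporting; the unrounded ratio is retained.
#'
#' @param rfd_reference,rfd_other Oral reference doses in mg/kg/day, both
#'   positive.
#' @return One-row tibble: `fold` (integer) and `fold_unrounded`.
#' @examples
#' rfd_fold(0.5, 0.017) # 29-fold
#' @export
rfd_fold <- function(rfd_reference, rfd_other) {
  if (rfd_reference <= 0 || rfd_other <= 0) {
    stop("reference doses must be positive", call. = FALSE)
  }
  ratio <- rfd_reference / rfd_other
  tibble(fold = as.integer(floor(ratio + 0.5)), fold_unrounded = ratio)
}
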