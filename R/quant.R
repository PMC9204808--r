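# Calibration fitting, standard-addition quantitation, SANTE-style
# validation metrics, and back-calculation to formulation concentrations.

#' Fit a calibration curve
#'
#' Ordinary (unweighted) least squares of response on concentration level.
#' For standard-addition curves the levels are the spiked increments and
#' the intercept is the response of the unspiked extract.
#'
#' @param data Tibble with columns `level` (concentration, e.g. ug/L) and
#'   `response` (peak area); an optional `snr` column (per-level
#'   signal-to-noise) is used by [estimate_loq()].
#' @param kind `"solvent"` or `"standard-addition"`.
#' @param compound Optional compound label.
#' @return An object of class `calibration`: the fitted model plus
#'   `slope`, `intercept`, `r_squared`, `kind`, `data`.
#' @examples
#' fit_calibration(tibble::tibble(level = 1:5, response = 2 * (1:5)))
#' @export
fit_calibration <- function(data, kind = c("solvent", "standard-addition"),
                            compound = NULL) {
  kind <- match.arg(kind)
  stopifnot(all(c("level", "response") %in% names(data)))
  if (length(unique(data$level)) < 2) {
    stop("all calibration levels are identical", call. = FALSE)
  }
  if (nrow(data) == 2) {
    warning("two-point calibration: R^2 = 1 is degenerate")
  }
  fit <- lm(response ~ level, data = data)
  slope <- unname(coef(fit)[2])
  if (slope < 0) warning("negative calibration slope")
  structure(
    list(model = fit, data = as_tibble(data), kind = kind,
         compound = compound,
         slope = slope, intercept = unname(coef(fit)[1]),
         r_squared = suppressWarnings(summary(fit)$r.squared)),
    class = "calibration"
  )
}

#' @export
print.calibration <- function(x, ...) {
  cat("<calibration> ", x$kind,
      if (!is.null(x$compound)) paste0(" (", x$compound, ")"), "\n",
      sep = "")
  cat(sprintf("  slope %.6g, intercept %.6g, R^2 %.6f, %d levels\n",
              x$slope, x$intercept, x$r_squared, nrow(x$data)))
  invisible(x)
}

#' Tidy a calibration fit
#'
#' @param x A `calibration` object.
#' @param ... Ignored.
#' @return Coefficient table in broom convention.
#' @export
tidy.calibration <- function(x, ...) {
  s <- suppressWarnings(summary(x$model)$coefficients)
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' One-row summary of a calibration fit
#'
#' @param x A `calibration` object.
#' @param ... Ignored.
#' @return Tibble with `kind`, `slope`, `intercept`, `r.squared`,
#'   `n_levels`.
#' @export
glance.calibration <- function(x, ...) {
  tibble(kind = x$kind, slope = x$slope, intercept = x$intercept,
         r.squared = x$r_squared, n_levels = nrow(x$data))
}

#' Plot a calibration curve
#'
#' @param object A `calibration` object.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.calibration <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$level, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept) +
    ggplot2::labs(x = "concentration level", y = "response",
                  title = sprintf("%s calibration, R^2 = %.4f",
                                  object$kind, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Standard-addition quantitation
#'
#' The concentration of the analyte in the injected extract is the
#' magnitude of the x-intercept of the standard-addition line:
#' `intercept / slope`.
#'
#' @param curve A `calibration` of kind `"standard-addition"` with
#'   positive slope.
#' @return Concentration in the extract, in the units of the levels.
#' @export
standard_addition_quant <- function(curve) {
  stopifnot(inherits(curve, "calibration"))
  if (curve$kind != "standard-addition") {
    stop("curve is not a standard-addition curve", call. = FALSE)
  }
  if (curve$slope <= 0) {
    stop("standard-addition slope must be positive", call. = FALSE)
  }
  abs(curve$intercept / curve$slope)
}

#' Matrix effect
#'
#' Percent change of the calibration slope in matrix relative to solvent:
#' `(matrix_slope / solvent_slope - 1) * 100`. |ME| < 20 percent is
#' treated as negligible.
#'
#' @param matrix_slope,solvent_slope Slopes of the matrix-matched (or
#'   standard-addition) and solvent curves; `solvent_slope` must be
#'   non-zero.
#' @return Signed percent.
#' @export
matrix_effect <- function(matrix_slope, solvent_slope) {
  if (solvent_slope == 0) stop("zero solvent slope", call. = FALSE)
  (matrix_slope / solvent_slope - 1) * 100
}

#' Interday precision (relative standard deviation)
#'
#' `100 * sd / mean` over replicate responses measured on different days.
#'
#' @param responses Numeric vector of >= 3 replicate responses with
#'   non-zero mean.
#' @return RSD in percent.
#' @export
interday_rsd <- function(responses) {
  if (length(responses) < 3) {
    stop("need at least 3 replicates", call. = FALSE)
  }
  m <- mean(responses)
  if (m == 0) stop("mean response is zero", call. = FALSE)
  100 * sd(responses) / m
}

# convert an extract concentration (ug/L) to formulation units
to_formulation_units <- function(extract_conc, dilution_factor,
                                 solid_mass_per_volume = NULL) {
  # undo the dilution: ug/L in the formulation-equivalent liquid
  conc <- extract_conc * dilution_factor
  if (is.null(solid_mass_per_volume)) {
    list(value = conc * 1e-6, units = "g/L")
  } else {
    # solid dissolved at solid_mass_per_volume g/mL before dilution
    list(value = conc / (1000 * solid_mass_per_volume), units = "ug/g")
  }
}

#' Estimate the method limit of quantification
#'
#' The LOQ is operationalized as the lowest calibration level whose
#' back-calculated concentration is accurate within `max_bias` percent and
#' whose signal-to-noise ratio is at least `min_snr`, scaled by the
#' dilution factor to formulation units (g/L for liquid formulations,
#' ug/g for solids dissolved at a known mass per volume).
#'
#' @param curve A `calibration` whose data may carry an `snr` column; when
#'   absent, S/N per level is approximated as response over the residual
#'   standard deviation of the fit.
#' @param dilution_factor Dilution of the formulation (>= 1).
#' @param solid_mass_per_volume For solid formulations, the stock
#'   dissolution in g/mL (e.g. 1 for 2 g dissolved in 2 mL); `NULL` for
#'   liquids.
#' @param max_bias Maximum back-calculated bias, percent.
#' @param min_snr Minimum signal-to-noise at the LOQ level.
#' @return One-row tibble: `extract_loq` (level units), `method_loq`,
#'   `units`.
#' @export
estimate_loq <- function(curve, dilution_factor,
                         solid_mass_per_volume = NULL,
                         max_bias = 20, min_snr = 10) {
  stopifnot(inherits(curve, "calibration"), dilution_factor >= 1)
  d <- curve$data
  d <- d[d$level > 0, ]
  back <- (d$response - curve$intercept) / curve$slope
  bias <- abs(back - d$level) / d$level * 100
  snr <- if ("snr" %in% names(d)) {
    d$snr
  } else {
    sigma <- suppressWarnings(summary(curve$model)$sigma)
    if (sigma > 0) d$response / sigma else rep(Inf, nrow(d))
  }
  ok <- bias <= max_bias & snr >= min_snr
  if (!any(ok)) {
    stop("no calibration level meets the LOQ criteria", call. = FALSE)
  }
  lvl <- min(d$level[ok])
  conv <- to_formulation_units(lvl, dilution_factor, solid_mass_per_volume)
  tibble(extract_loq = lvl, method_loq = conv$value, units = conv$units)
}

#' Quantify a sample response against a calibration curve
#'
#' Extract concentration `(response - intercept) / slope`, then
#' back-calculation to the formulation: times the dilution factor for
#' liquids (reported in g/L), divided additionally by the stock mass per
#' volume for solids (reported in ug/g). Responses below the LOQ are
#' reported as below-LOQ; responses outside 0.5x-1.5x of the calibrated
#' response range are flagged as extrapolated.
#'
#' @param response Measured peak area of the analyte in the extract.
#' @param curve A `calibration` (solvent curve when there is no matrix
#'   effect).
#' @param dilution_factor Dilution of the formulation (>= 1).
#' @param solid_mass_per_volume See [estimate_loq()].
#' @param loq Optional LOQ row from [estimate_loq()]; when given, extract
#'   concentrations below `extract_loq` are censored.
#' @return One-row tibble: `response`, `extract_conc` (level units),
#'   `concentration`, `units`, `below_loq`, `extrapolated`, and `label`
#'   (formatted value or `"<LOQ"`).
#' @export
quantify_sample <- function(response, curve, dilution_factor = 1,
                            solid_mass_per_volume = NULL, loq = NULL) {
  stopifnot(inherits(curve, "calibration"))
  extract <- (response - curve$intercept) / curve$slope
  rng <- range(curve$data$response)
  extrapolated <- response < 0.5 * rng[1] || response > 1.5 * rng[2]
  below <- !is.null(loq) && extract < loq$extract_loq
  conv <- to_formulation_units(extract, dilution_factor,
                               solid_mass_per_volume)
  tibble(
    response = response, extract_conc = extract,
    concentration = if (below) NA_real_ else conv$value,
    units = conv$units, below_loq = below, extrapolated = extrapolated,
    label = if (below) "<LOQ" else format(signif(conv$value, 4))
  )
}

#' Assemble a validation report
#'
#' Collects the SANTE-style validation metrics for one analyte and applies
#' the pass criteria: |matrix effect| < 20 percent, interday RSD at most
#' `rsd_max`, linearity R^2 at least `r2_min`, and retention-time shift
#' below 0.1 min.
#'
#' @param compound Analyte label.
#' @param matrix_effect_pct Matrix effect, percent.
#' @param interday_rsd_pct Interday RSD, percent.
#' @param r_squared Calibration linearity.
#' @param loq One-row tibble from [estimate_loq()].
#' @param rt_shift_min Retention-time shift vs the standard, minutes.
#' @param rsd_max,r2_min Pass thresholds for RSD and R^2.
#' @return One-row tibble with the metrics, per-criterion pass flags and
#'   an overall `pass`.
#' @export
validation_report <- function(compound, matrix_effect_pct, interday_rsd_pct,
                              r_squared, loq, rt_shift_min,
                              rsd_max = 20, r2_min = 0.99) {
  loq_value <- loq$method_loq
  loq_units <- loq$units
  tibble(
    compound = compound,
    matrix_effect = matrix_effect_pct,
    interday_rsd = interday_rsd_pct,
    r_squared = r_squared,
    loq = loq_value, loq_units = loq_units,
    rt_shift = rt_shift_min,
    pass_me = abs(matrix_effect_pct) < 20,
    pass_rsd = interday_rsd_pct <= rsd_max,
    pass_r2 = r_squared >= r2_min,
    pass_rt = rt_shift_min < 0.1
  ) |>
    mutate(pass = .data$pass_me & .data$pass_rsd & .data$pass_r2 &
             .data$pass_rt)
}
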