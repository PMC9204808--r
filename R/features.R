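# EIC extraction, chromatographic peak detection with S/N and shape QC,
# untargeted feature finding, and blank subtraction.

#' Extract an ion chromatogram
#'
#' Per MS1 scan, the summed intensity of all centroids within `tol_ppm` of
#' the target m/z (0 where no centroid matches), so the trace has exactly
#' one point per MS1 scan.
#'
#' @param run An [ms_run()].
#' @param mz Target m/z (Da).
#' @param tol_ppm Mass tolerance in ppm (> 0); the paper-style default is
#'   5 ppm.
#' @return A tibble of class `eic` with columns `scan`, `rt`, `intensity`
#'   and attributes `target_mz`, `tol_ppm`, `run_id`.
#' @export
extract_eic <- function(run, mz, tol_ppm = 5) {
  stopifnot(inherits(run, "ms_run"), tol_ppm > 0)
  cent <- ms1_centroids(run)
  if (nrow(cent) > 0) {
    rng <- range(cent$mz)
    if (mz < rng[1] - 1 || mz > rng[2] + 1) {
      warning("target m/z ", round(mz, 4),
              " lies outside the run's observed m/z range")
    }
  }
  half <- mz * tol_ppm * 1e-6
  ms1 <- run$scans[run$scans$ms_level == 1, c("scan", "rt")]
  hits <- cent |>
    filter(abs(.data$mz - !!mz) <= half) |>
    group_by(.data$scan) |>
    summarise(intensity = sum(.data$intensity)) |>
    ungroup()
  out <- left_join(ms1, hits, by = "scan")
  out$intensity[is.na(out$intensity)] <- 0
  out <- as_tibble(out)
  attr(out, "target_mz") <- mz
  attr(out, "tol_ppm") <- tol_ppm
  attr(out, "run_id") <- run$run_id
  class(out) <- c("eic", class(out))
  out
}

# indices of local maxima and their spans bounded by surrounding minima
peak_spans <- function(y) {
  n <- length(y)
  if (n < 3) return(list())
  apexes <- which(y[-c(1, n)] > pmax(y[-c(n - 1, n)], 0) &
                    y[-c(1, n)] >= y[-c(1, 2)]) + 1
  apexes <- apexes[y[apexes] > 0]
  spans <- list()
  for (a in apexes) {
    l <- a
    while (l > 1 && y[l - 1] < y[l] && y[l - 1] > 0) l <- l - 1
    if (l > 1 && y[l - 1] == 0) l <- max(l - 1, 1)
    r <- a
    while (r < n && y[r + 1] < y[r] && y[r + 1] > 0) r <- r + 1
    if (r < n && y[r + 1] == 0) r <- min(r + 1, n)
    spans[[length(spans) + 1]] <- c(left = l, apex = a, right = r)
  }
  # drop duplicate spans from plateau apexes
  unique(spans)
}

#' Gaussian peak-shape score
#'
#' Coefficient of determination of a least-squares Gaussian fit over the
#' peak span, clamped to [0, 1]. Used to operationalize the "acceptable
#' peak shape" criterion of suspect screening.
#'
#' @param rt,intensity Points of the peak span (>= 4 points; otherwise
#'   score 0 with a warning).
#' @return A score in [0, 1].
#' @export
gaussian_shape_score <- function(rt, intensity) {
  if (length(rt) < 4) {
    warning("peak span has fewer than 4 points; shape score set to 0")
    return(0)
  }
  apex <- which.max(intensity)
  start <- list(A = intensity[apex], mu = rt[apex],
                s = max(diff(range(rt)) / 4, 1e-4))
  fit <- tryCatch(
    minpack.lm::nlsLM(intensity ~ A * exp(-(rt - mu)^2 / (2 * s^2)),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(0)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((intensity - mean(intensity))^2)
  if (ss_tot <= 0) return(0)
  max(0, min(1, 1 - ss_res / ss_tot))
}

#' Detect chromatographic peaks in an EIC
#'
#' Local-maximum peaks with boundaries at surrounding minima. Area is
#' computed by the trapezoid rule over the span (counts x min); S/N is
#' peak height divided by a robust noise estimate, 1.4826 x the median
#' absolute deviation of the off-peak signal. Peaks failing the height or
#' S/N thresholds are dropped.
#'
#' @param eic An [extract_eic()] trace.
#' @param min_height Minimum apex intensity (counts); paper-style default
#'   1000.
#' @param min_snr Minimum signal-to-noise ratio; paper-style default 3.
#' @return A tibble of features: `mz`, `apex_rt`, `height`, `area`, `snr`,
#'   `shape`, `rt_left`, `rt_right`, `n_points`, `run_id`.
#' @export
detect_peaks <- function(eic, min_height = 1000, min_snr = 3) {
  stopifnot(min_height > 0, min_snr > 0)
  y <- eic$intensity
  rt <- eic$rt
  spans <- peak_spans(y)
  empty <- tibble(mz = numeric(), apex_rt = numeric(), height = numeric(),
                  area = numeric(), snr = numeric(), shape = numeric(),
                  rt_left = numeric(), rt_right = numeric(),
                  n_points = integer(), run_id = character())
  if (length(spans) == 0) return(empty)
  in_peak <- rep(FALSE, length(y))
  for (s in spans) in_peak[s["left"]:s["right"]] <- TRUE
  off <- y[!in_peak]
  noise <- if (length(off) >= 4) stats::mad(off, constant = 1.4826) else 0
  rows <- purrr::map(spans, function(s) {
    idx <- s["left"]:s["right"]
    height <- y[s["apex"]]
    if (height < min_height) return(NULL)
    snr <- if (noise > 0) height / noise else Inf
    if (snr < min_snr) return(NULL)
    area <- sum(diff(rt[idx]) * (head(y[idx], -1) + tail(y[idx], -1)) / 2)
    shape <- suppressWarnings(gaussian_shape_score(rt[idx], y[idx]))
    tibble(mz = attr(eic, "target_mz") %||% NA_real_,
           apex_rt = rt[s["apex"]], height = height, area = area,
           snr = unname(snr), shape = shape,
           rt_left = rt[s["left"]], rt_right = rt[s["right"]],
           n_points = length(idx),
           run_id = attr(eic, "run_id") %||% NA_character_)
  })
  out <- list_rbind(purrr::compact(rows))
  if (nrow(out) == 0) empty else out
}

#' Untargeted feature detection
#'
#' Groups MS1 centroids into mass traces (single-linkage in m/z with a
#' `tol_ppm` gap tolerance, requiring at least `min_scans` consecutive
#' scans), runs [detect_peaks()] on each trace, reports the
#' intensity-weighted mean m/z across the peak span, and removes duplicate
#' features (within 5 ppm and 0.1 min, keeping the higher area).
#'
#' @param run An [ms_run()].
#' @inheritParams detect_peaks
#' @param tol_ppm Trace gap tolerance in ppm.
#' @param min_scans Minimum number of consecutive MS1 scans in a trace.
#' @return A feature tibble as in [detect_peaks()].
#' @export
detect_features <- function(run, min_height = 1000, min_snr = 3,
                            tol_ppm = 5, min_scans = 5) {
  cent <- ms1_centroids(run)
  empty <- detect_peaks(structure(tibble(scan = integer(), rt = numeric(),
                                         intensity = numeric()),
                                  class = c("eic", "tbl_df", "tbl", "data.frame")),
                        min_height, min_snr)
  if (nrow(cent) == 0) return(empty)
  ms1 <- run$scans[run$scans$ms_level == 1, c("scan", "rt")]
  ms1$ms1_index <- seq_len(nrow(ms1))
  cent <- left_join(cent, ms1[, c("scan", "ms1_index")], by = "scan")
  cent <- arrange(cent, .data$mz)
  gap <- c(FALSE, diff(cent$mz) / head(cent$mz, -1) * 1e6 > tol_ppm)
  cent$trace <- cumsum(gap)
  results <- list()
  for (tr in split(cent, cent$trace)) {
    idx <- sort(unique(tr$ms1_index))
    # longest stretch of consecutive MS1 scans covered by the trace
    best <- 0
    cur <- 1
    for (k in seq_along(idx)[-1]) {
      cur <- if (idx[k] - idx[k - 1] == 1) cur + 1 else 1
      best <- max(best, cur)
    }
    if (length(idx) == 1) best <- 1
    if (best < min_scans) next
    trace_eic <- tr |>
      group_by(.data$ms1_index) |>
      summarise(intensity = sum(.data$intensity)) |>
      ungroup()
    y <- rep(0, nrow(ms1))
    y[trace_eic$ms1_index] <- trace_eic$intensity
    eic <- tibble(scan = ms1$scan, rt = ms1$rt, intensity = y)
    attr(eic, "target_mz") <- stats::weighted.mean(tr$mz, tr$intensity)
    attr(eic, "run_id") <- run$run_id
    class(eic) <- c("eic", class(eic))
    pks <- detect_peaks(eic, min_height, min_snr)
    if (nrow(pks) == 0) next
    # refine m/z per peak: weighted mean over the span only
    pks$mz <- map_dbl(seq_len(nrow(pks)), function(k) {
      in_span <- ms1$rt[tr$ms1_index] >= pks$rt_left[k] &
        ms1$rt[tr$ms1_index] <= pks$rt_right[k]
      if (any(in_span)) {
        stats::weighted.mean(tr$mz[in_span], tr$intensity[in_span])
      } else {
        attr(eic, "target_mz")
      }
    })
    results[[length(results) + 1]] <- pks
  }
  if (length(results) == 0) return(empty)
  feats <- list_rbind(results) |> arrange(.data$mz)
  dedupe_features(feats, mz_tol_ppm = 5, rt_tol = 0.1)
}

# remove duplicate features within tolerances, keeping the higher area
dedupe_features <- function(feats, mz_tol_ppm = 5, rt_tol = 0.1) {
  feats <- arrange(feats, dplyr::desc(.data$area))
  keep <- rep(TRUE, nrow(feats))
  for (i in seq_len(nrow(feats))) {
    if (!keep[i]) next
    if (i < nrow(feats)) {
      j <- (i + 1):nrow(feats)
      dup <- keep[j] &
        abs(feats$mz[j] - feats$mz[i]) / feats$mz[i] * 1e6 <= mz_tol_ppm &
        abs(feats$apex_rt[j] - feats$apex_rt[i]) <= rt_tol
      keep[j][dup] <- FALSE
    }
  }
  arrange(feats[keep, ], .data$mz)
}

#' Blank subtraction
#'
#' Removes every feature that matches a blank feature within both the m/z
#' and rt tolerances ("no peak area in any blank").
#'
#' @param features,blank_features Feature tibbles from [detect_features()]
#'   or [detect_peaks()].
#' @param mz_tol_ppm,rt_tol Match tolerances (ppm, minutes), both > 0.
#' @return The retained features.
#' @export
subtract_blank <- function(features, blank_features, mz_tol_ppm = 5,
                           rt_tol = 0.1) {
  stopifnot(mz_tol_ppm > 0, rt_tol > 0)
  if (nrow(features) == 0 || nrow(blank_features) == 0) return(features)
  hit <- map_lgl(seq_len(nrow(features)), function(i) {
    any(abs(blank_features$mz - features$mz[i]) /
          features$mz[i] * 1e6 <= mz_tol_ppm &
          abs(blank_features$apex_rt - features$apex_rt[i]) <= rt_tol)
  })
  features[!hit, ]
}

#' Plot an extracted ion chromatogram
#'
#' @param object An `eic` from [extract_eic()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.eic <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rt, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "retention time (min)", y = "intensity (counts)",
      title = sprintf("EIC m/z %.5f (+/- %g ppm)",
                      attr(object, "target_mz"), attr(object, "tol_ppm"))
    ) +
    ggplot2::theme_minimal()
}
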