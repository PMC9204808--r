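# Exact-mass chemistry core: formula algebra, adduct and fragment m/z,
# ppm errors, isotope patterns, accurate-mass formula enumeration.

#' Physical constants used throughout the package
#'
#' Monoisotopic mass arithmetic uses the CODATA proton and electron masses.
#' Atomic masses and isotope abundances come from the IUPAC table shipped
#' with the package (see [isotope_table()]).
#'
#' @name constants
#' @keywords internal
NULL

PROTON_MASS   <- 1.00727646
ELECTRON_MASS <- 0.00054858

#' Isotope table
#'
#' Returns the packaged IUPAC isotope table: one row per stable isotope with
#' its exact mass (Da) and natural abundance (fraction). The table is read
#' once from `inst/extdata/isotope_table.csv` and cached.
#'
#' @return A tibble with columns `element`, `mass_number`, `mass`,
#'   `abundance`.
#' @export
isotope_table <- function() {
  if (is.null(the$isotopes)) {
    path <- system.file("extdata", "isotope_table.csv", package = "ppscreen")
    tab <- readr::read_csv(path, show_col_types = FALSE)
    the$isotopes <- tab
    # lightest isotope per element = monoisotopic mass
    mono <- tab |>
      group_by(.data$element) |>
      summarise(mass = .data$mass[which.min(.data$mass_number)]) |>
      ungroup()
    the$mono <- setNames(mono$mass, mono$element)
  }
  the$isotopes
}

mono_masses <- function() {
  isotope_table()
  the$mono
}

#' Adduct registry
#'
#' The electrospray adducts the pipeline searches. Each adduct is defined by
#' its charge, its exact mass shift relative to the neutral molecule M, and
#' the atoms it adds to (positive count) or removes from (negative count)
#' the molecule, which is what the isotope-pattern simulator needs.
#'
#' `[M+H]+` adds a proton (+1.00727646 Da); `[M-H]-` removes one;
#' `[M+Na]+` adds a sodium atom and removes an electron (+22.98922070 Da).
#' Additional singly charged adducts can be registered with
#' `register_adduct()`.
#'
#' @return A tibble with columns `name`, `charge`, `mass_shift`,
#'   `delta_element`, `delta_count`.
#' @export
adduct_registry <- function() {
  if (is.null(the$adducts)) {
    the$adducts <- tibble(
      name = c("[M+H]+", "[M-H]-", "[M+Na]+"),
      charge = c(1L, -1L, 1L),
      mass_shift = c(PROTON_MASS, -PROTON_MASS,
                     22.98976928 - ELECTRON_MASS),
      delta_element = c("H", "H", "Na"),
      delta_count = c(1L, -1L, 1L)
    )
  }
  the$adducts
}

#' @param name Adduct label, e.g. `"[M+NH4]+"`.
#' @param charge Signed unit charge (+1 or -1).
#' @param mass_shift Exact mass shift in Da relative to neutral M.
#' @param delta_element,delta_count Atoms gained (positive) or lost
#'   (negative) by the molecule, used for isotope-pattern simulation.
#' @rdname adduct_registry
#' @export
register_adduct <- function(name, charge, mass_shift,
                            delta_element = NA_character_,
                            delta_count = 0L) {
  stopifnot(abs(charge) == 1)
  reg <- adduct_registry()
  the$adducts <- bind_rows(
    reg[reg$name != name, ],
    tibble(name = name, charge = as.integer(charge),
           mass_shift = mass_shift, delta_element = delta_element,
           delta_count = as.integer(delta_count))
  )
  invisible(the$adducts)
}

normalize_adduct <- function(name) {
  # tolerate the unicode minus sign that appears in printed adduct labels
  gsub("−", "-", name)
}

adduct_spec <- function(name) {
  name <- normalize_adduct(name)
  reg <- adduct_registry()
  hit <- reg[reg$name == name, ]
  if (nrow(hit) == 0) {
    stop("unsupported adduct: '", name, "' (known: ",
         paste(reg$name, collapse = ", "), ")", call. = FALSE)
  }
  hit
}

#' Parse an elemental formula
#'
#' Parses a Hill-style formula string ("C4H4ClNOS", "H2O") into a named
#' integer count vector, the unit of all mass arithmetic in the package.
#' Multi-letter element symbols and multi-digit counts are supported;
#' a missing count means 1.
#'
#' @param text Formula string, or an already-parsed named count vector
#'   (returned unchanged after validation).
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C4H4ClNOS")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  known <- unique(isotope_table()$element)
  if (is.numeric(text) && !is.null(names(text))) {
    bad <- setdiff(names(text), known)
    if (length(bad) > 0) {
      stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (any(text < 0)) stop("negative element count", call. = FALSE)
    counts <- as.integer(text)
    names(counts) <- names(text)
    return(counts[counts > 0])
  }
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text) || text == "") {
    return(setNames(integer(0), character(0)))
  }
  matches <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, gregexpr("([A-Z][a-z]?)([0-9]*)", text))[[1]]
  if (sum(attr(matches, "match.length")) != nchar(text)) {
    consumed <- paste(tokens, collapse = "")
    offending <- substr(text, 1, nchar(text))
    stop("malformed formula '", offending, "': unparseable characters near '",
         sub(consumed, "", text, fixed = TRUE), "'", call. = FALSE)
  }
  els <- sub("[0-9]*$", "", tokens)
  cnt <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", tokens)))
  cnt[is.na(cnt)] <- 1L
  bad <- setdiff(els, known)
  if (length(bad) > 0) {
    stop("unknown element symbol(s) in '", text, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  counts <- tapply(cnt, els, sum)
  counts <- setNames(as.integer(counts), names(counts))
  counts[counts > 0]
}

#' Serialize a formula count map to Hill notation
#'
#' @param counts Named count vector as returned by [parse_formula()].
#' @return A single string: C first, then H, then remaining elements
#'   alphabetically; count 1 is omitted.
#' @export
formula_string <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) return("")
  els <- names(counts)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(ord, ifelse(counts[ord] == 1, "", counts[ord]), collapse = "")
}

# formula algebra: add/subtract atom count maps
formula_add <- function(a, b, mult = 1L) {
  els <- union(names(a), names(b))
  out <- setNames(integer(length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + mult * b
  if (any(out < 0)) stop("formula subtraction yields negative count",
                         call. = FALSE)
  out[out > 0]
}

#' Monoisotopic mass of a formula
#'
#' Sum over elements of count times lightest-isotope mass.
#'
#' @param f Formula string or named count vector.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O")
#' @export
monoisotopic_mass <- function(f) {
  counts <- parse_formula(f)
  if (length(counts) == 0) return(0)
  sum(counts * mono_masses()[names(counts)])
}

#' Theoretical adduct m/z
#'
#' m/z of the singly charged adduct ion of neutral molecule M, reported to
#' five decimals (the precision at which Orbitrap software prints masses).
#'
#' @param f Neutral formula (string or count vector).
#' @param adduct One of `"[M+H]+"`, `"[M-H]-"`, `"[M+Na]+"` or a registered
#'   adduct name.
#' @param digits Decimal places for the reported m/z (`NULL` to skip
#'   rounding).
#' @return m/z in Da.
#' @examples
#' adduct_mz("C4H4ClNOS", "[M+H]+") # 149.97749
#' @export
adduct_mz <- function(f, adduct = "[M+H]+", digits = 5) {
  spec <- adduct_spec(adduct)
  mz <- monoisotopic_mass(f) + spec$mass_shift
  if (!is.null(digits)) mz <- round(mz, digits)
  mz
}

#' Theoretical m/z of an even-electron fragment cation
#'
#' ddMS2 fragment ions of protonated molecules are even-electron cations:
#' the m/z is the atomic monoisotopic sum of the intact cation minus one
#' electron mass.
#'
#' @param cation Formula of the cation's atoms (string or count vector).
#' @param digits Decimal places for the reported m/z.
#' @return m/z in Da.
#' @examples
#' fragment_cation_mz("C14H28NO") # 226.21654
#' @export
fragment_cation_mz <- function(cation, digits = 5) {
  mz <- monoisotopic_mass(cation) - ELECTRON_MASS
  if (!is.null(digits)) mz <- round(mz, digits)
  mz
}

#' Signed ppm mass error
#'
#' `(observed - theoretical) / theoretical * 1e6`. By default the
#' theoretical mass is first rounded to five decimals, matching how mass
#' errors are computed against printed five-decimal theoretical values;
#' set `theoretical_rounding = "unrounded"` to use the value as given.
#'
#' @param observed,theoretical m/z values in Da; `theoretical` must be
#'   positive.
#' @param theoretical_rounding `"rounded"` (default; theoretical rounded to
#'   5 decimals first) or `"unrounded"`.
#' @return Signed error in ppm.
#' @examples
#' ppm_error(149.97716, adduct_mz("C4H4ClNOS")) # -2.20 ppm
#' @export
ppm_error <- function(observed, theoretical,
                      theoretical_rounding = c("rounded", "unrounded")) {
  theoretical_rounding <- match.arg(theoretical_rounding)
  if (any(theoretical <= 0)) {
    stop("theoretical m/z must be positive", call. = FALSE)
  }
  if (theoretical_rounding == "rounded") {
    theoretical <- round(theoretical, 5)
  }
  (observed - theoretical) / theoretical * 1e6
}

# single-element isotope distribution as (mass, prob) matrix
element_dist <- function(el) {
  tab <- isotope_table()
  sub <- tab[tab$element == el, ]
  cbind(mass = sub$mass, p = sub$abundance / sum(sub$abundance))
}

# convolve two (mass, p) distributions, merging near-identical masses
conv_dist <- function(a, b, prune = 1e-9) {
  mass <- outer(a[, 1], b[, 1], `+`)
  p <- outer(a[, 2], b[, 2], `*`)
  d <- cbind(mass = as.vector(mass), p = as.vector(p))
  d <- d[d[, 2] >= prune, , drop = FALSE]
  merge_dist(d, tol = 1e-4)
}

merge_dist <- function(d, tol) {
  d <- d[order(d[, 1]), , drop = FALSE]
  if (nrow(d) <= 1) return(d)
  grp <- cumsum(c(TRUE, diff(d[, 1]) > tol))
  mass <- tapply(d[, 1] * d[, 2], grp, sum) / tapply(d[, 2], grp, sum)
  p <- tapply(d[, 2], grp, sum)
  cbind(mass = as.numeric(mass), p = as.numeric(p))
}

# distribution of n atoms of one element, by binary exponentiation
element_power <- function(el, n) {
  base <- element_dist(el)
  out <- NULL
  while (n > 0) {
    if (n %% 2 == 1) out <- if (is.null(out)) base else conv_dist(out, base)
    n <- n %/% 2
    if (n > 0) base <- conv_dist(base, base)
  }
  if (is.null(out)) cbind(mass = 0, p = 1) else out
}

#' Simulate the isotope pattern of an adduct ion
#'
#' Computes the aggregated isotopologue pattern of the ion formed from
#' formula `f` and the given adduct, by exact convolution of per-element
#' isotope distributions. Isotopologue peaks closer than `merge_tol` Da are
#' merged (an Orbitrap at R = 70,000 cannot resolve finer spacings at these
#' masses), the pattern is normalized to base peak 100, and peaks below
#' `min_rel` are pruned.
#'
#' @param f Neutral formula (string or count vector).
#' @param adduct Adduct name; its atoms are added to/removed from `f`
#'   before simulation.
#' @param min_rel Prune threshold, percent of base peak (0 < min_rel < 100).
#' @param merge_tol Peak-merge tolerance in Da.
#' @return A tibble of class `isotope_pattern` with columns `mz` and
#'   `abundance` (percent of base peak), m/z increasing.
#' @examples
#' simulate_isotope_pattern("C4H4ClNOS", "[M+H]+", min_rel = 5)
#' @export
simulate_isotope_pattern <- function(f, adduct = "[M+H]+", min_rel = 1,
                                     merge_tol = 0.01) {
  stopifnot(min_rel > 0, min_rel < 100)
  spec <- adduct_spec(adduct)
  counts <- parse_formula(f)
  if (!is.na(spec$delta_element)) {
    counts <- formula_add(counts,
                          setNames(spec$delta_count, spec$delta_element))
  }
  d <- cbind(mass = 0, p = 1)
  for (el in names(counts)) {
    d <- conv_dist(d, element_power(el, counts[[el]]))
  }
  # singly charged: subtract (positive) or add (negative mode) one electron
  d[, 1] <- d[, 1] - sign(spec$charge) * ELECTRON_MASS
  d <- merge_dist(d, tol = merge_tol)
  ab <- d[, 2] / max(d[, 2]) * 100
  keep <- ab >= min_rel
  out <- tibble(mz = d[keep, 1], abundance = ab[keep]) |> arrange(.data$mz)
  class(out) <- c("isotope_pattern", class(out))
  out
}

#' Default element bounds for formula enumeration
#'
#' CHNOPS bounds wide enough for co-formulants up to m/z 750; chlorine and
#' sodium are opt-in.
#'
#' @param chlorine,sodium Include Cl / Na in the search space?
#' @return Named list of `c(min, max)` count ranges.
#' @export
default_element_bounds <- function(chlorine = FALSE, sodium = FALSE) {
  b <- list(C = c(0, 50), H = c(0, 100), N = c(0, 10), O = c(0, 25),
            P = c(0, 6), S = c(0, 6))
  if (chlorine) b$Cl <- c(0, 6)
  if (sodium) b$Na <- c(0, 2)
  b
}

# ring-plus-double-bond equivalents under standard valences
rdbe_of <- function(counts) {
  val <- c(C = 4, Si = 4, N = 3, P = 3, O = 2, S = 2,
           H = 1, F = 1, Cl = 1, Br = 1, I = 1, Na = 1, K = 1)
  1 + sum(counts * (val[names(counts)] - 2)) / 2
}

#' Enumerate molecular formulas matching an accurate mass
#'
#' Exhaustively lists element-count combinations whose adduct m/z lies
#' within `tol_ppm` of the query, subject to per-element count bounds,
#' non-negative ring-plus-double-bond equivalents (RDBE), and
#' 0.1 <= H/C <= 4 when carbon is present. Results are sorted by absolute
#' ppm error.
#'
#' @param mz Query m/z in Da.
#' @param adduct Adduct assumed for the ion.
#' @param tol_ppm Mass tolerance in ppm (>= 0; 0 keeps exact hits only).
#' @param bounds Named list of `c(min, max)` per element; see
#'   [default_element_bounds()].
#' @return A tibble with columns `formula`, `exact_mz`, `ppm_error`,
#'   `rdbe`, sorted by `abs(ppm_error)`.
#' @examples
#' enumerate_formulas(149.97749, "[M+H]+", 5,
#'                    default_element_bounds(chlorine = TRUE))
#' @export
enumerate_formulas <- function(mz, adduct = "[M+H]+", tol_ppm = 5,
                               bounds = default_element_bounds()) {
  if (length(bounds) == 0) stop("empty element bounds", call. = FALSE)
  stopifnot(tol_ppm >= 0, mz > 0)
  spec <- adduct_spec(adduct)
  target <- mz - spec$mass_shift          # neutral monoisotopic mass window
  half <- mz * tol_ppm * 1e-6
  lo <- target - half
  hi <- target + half
  masses <- mono_masses()
  els <- setdiff(names(bounds), "H")
  els <- els[order(masses[els], decreasing = TRUE)]  # heavy first: prune early
  h_bounds <- bounds$H %||% c(0, 0)
  h_mass <- masses[["H"]]
  results <- list()

  recurse <- function(i, counts, mass_so_far) {
    if (mass_so_far > hi + 1e-9) return()
    if (i > length(els)) {
      # solve for hydrogen count in the remaining mass window
      rem_lo <- lo - mass_so_far
      rem_hi <- hi - mass_so_far
      h_min <- max(h_bounds[1], ceiling(rem_lo / h_mass - 1e-9))
      h_max <- min(h_bounds[2], floor(rem_hi / h_mass + 1e-9))
      if (h_max < h_min) return()
      for (h in h_min:h_max) {
        cand <- counts
        if (h > 0) cand[["H"]] <- h
        cand <- unlist(cand)
        if (length(cand) == 0) next
        cand <- setNames(as.integer(cand), names(cand))
        if (rdbe_of(cand) < 0) next
        nc <- if ("C" %in% names(cand)) cand[["C"]] else 0L
        if (nc > 0) {
          nh <- if ("H" %in% names(cand)) cand[["H"]] else 0L
          ratio <- nh / nc
          if (ratio < 0.1 || ratio > 4) next
        }
        m <- sum(cand * masses[names(cand)])
        results[[length(results) + 1]] <<- list(counts = cand, mass = m)
      }
      return()
    }
    el <- els[i]
    b <- bounds[[el]]
    for (k in b[1]:b[2]) {
      m2 <- mass_so_far + k * masses[[el]]
      if (m2 > hi + 1e-9) break
      cnt2 <- counts
      if (k > 0) cnt2[[el]] <- k
      recurse(i + 1, cnt2, m2)
    }
  }
  recurse(1, list(), 0)

  if (length(results) == 0) {
    return(tibble(formula = character(), exact_mz = numeric(),
                  ppm_error = numeric(), rdbe = numeric()))
  }
  out <- tibble(
    formula = map_chr_(results, function(r) formula_string(r$counts)),
    exact_mz = map_dbl(results, function(r) r$mass + spec$mass_shift),
    rdbe = map_dbl(results, function(r) rdbe_of(r$counts))
  )
  out$ppm_error <- (mz - out$exact_mz) / out$exact_mz * 1e6
  out |>
    distinct(.data$formula, .keep_all = TRUE) |>
    arrange(abs(.data$ppm_error)) |>
    select("formula", "exact_mz", "ppm_error", "rdbe")
}

map_chr_ <- function(x, f) vapply(x, f, character(1))

#' Plot an isotope pattern
#'
#' Stick plot of a simulated (or measured) isotope pattern.
#'
#' @param object An `isotope_pattern` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.isotope_pattern <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mz, xend = .data$mz,
                                       y = 0, yend = .data$abundance)) +
    ggplot2::geom_segment(linewidth = 1) +
    ggplot2::labs(x = "m/z", y = "relative abundance (%)") +
    ggplot2::theme_minimal()
}
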