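---
title: "Screening and quantifying co-formulants in plant protection products"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and quantifying co-formulants in plant protection products}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppscreen)
library(dplyr)
```

## The problem

Marketed plant protection products (PPPs) are mostly *co-formulants*:
surfactants, solvents, preservatives and dispersants that accompany the
declared active substance but rarely appear on the label. Some of them
(certain alkylphenol ethoxylates, aniline, 1-methylpyrrolidin-2-one) are
banned in the EU or in Spain except as unintentional impurities below
0.1 % w/w. ppscreen implements a hybrid identification strategy for
LC-HRMS data of diluted formulations:

1. **Suspect screening** — search every compound of a curated database by
   its characteristic ions ([M+H]+, [M−H]−, and [M+Na]+ where the entry
   allows it), keep peaks with |mass error| ≤ 5 ppm, an acceptable
   Gaussian peak shape, and no counterpart in the blank; then upgrade the
   identification with isotope-pattern and ddMS2 fragment evidence.
2. **Unknown (non-target) analysis** — untargeted feature detection,
   blank subtraction, a minimum-area filter, exhaustive CHNOPS molecular
   formula generation, homolog-series (polyethoxylate) detection, and
   name proposal against a local candidate table.
3. **Quantitation and risk screening** — solvent and standard-addition
   calibration, SANTE-style validation metrics (matrix effect, interday
   RSD, linearity, LOQ, retention-time stability), back-calculation to
   formulation units through the dilution factor, and flagging of banned
   compounds against the 0.1 % w/w threshold with oral-reference-dose
   (RfD) fold comparisons.

Because formulation samples cannot be redistributed, the package ships a
**synthetic-data generator** that plants compounds with known ground
truth into simulated runs, so every stage of the pipeline is testable
end to end.

## Exact-mass conventions

All mass arithmetic is built on a packaged IUPAC isotope table and two
CODATA constants: the proton mass 1.00727646 Da and the electron mass
0.00054858 Da. Adduct m/z values are

$$ m/z_{[M+H]^+} = M + 1.00727646, \qquad
   m/z_{[M-H]^-} = M - 1.00727646, \qquad
   m/z_{[M+Na]^+} = M + m_{\mathrm{Na}} - m_e , $$

with $M$ the monoisotopic (lightest-isotope) mass of the neutral
formula. ddMS2 fragment ions of protonated molecules are even-electron
cations, so their m/z is the atomic sum of the cation minus one electron
mass. All m/z are reported to five decimals, the precision at which
Orbitrap software prints them.

```{r anchors}
adduct_mz("C4H4ClNOS", "[M+H]+")     # protonated methylchloroisothiazolinone
fragment_cation_mz("C14H28NO")       # lauramide DEA acyl fragment
```

Mass errors are signed ppm differences. Because published theoretical
masses are rounded to five decimals, `ppm_error()` rounds the
theoretical value to five decimals by default before comparing — this
reproduces reported two-decimal ppm errors exactly (an unrounded mode is
also available; the two differ by ~0.01 ppm):

```{r ppm}
ppm_error(149.97716, adduct_mz("C4H4ClNOS"))
```

## Isotope patterns and formula generation

`simulate_isotope_pattern()` convolves per-element isotope distributions
exactly (binary exponentiation of single-atom distributions), merges
isotopologues closer than 0.01 Da — an Orbitrap at R = 70,000 cannot
resolve finer spacings in this mass range — normalizes to base peak 100,
and prunes below a relative threshold. For a chlorinated, sulfur-bearing
ion such as protonated methylchloroisothiazolinone the M+2 cluster
(³⁷Cl ≈ 32 % plus ³⁴S ≈ 4.4 %) sits near 37 % of the base peak, the
diagnostic signature used by the verification step.

`enumerate_formulas()` searches element-count space (C, H, N, O, P, S by
default; Cl and Na opt-in) for formulas whose adduct m/z lies within
tolerance, with two sanity filters: ring-plus-double-bond equivalents
≥ 0 and H/C between 0.1 and 4 when carbon is present. The element-type
restriction mirrors vendor-software practice; the RDBE and H/C filters
are our declared additions, chosen to discard chemically impossible
candidates without touching plausible ones.

## Feature detection

EICs carry one point per MS1 scan (summed intensity within a ppm
window; the default 5 ppm matches the identification mass-error
criterion). Peak detection takes local maxima with boundaries at the
surrounding minima; the area is trapezoidal; the peak-shape score is the
R² of a least-squares Gaussian fit over the span, clamped to [0, 1]
(an exact Gaussian scores ≥ 0.99, a noise bump typically < 0.5). The
S/N estimator is peak height over 1.4826 × the median absolute
deviation of the off-peak signal: vendor software does not disclose its
estimator, so ours is declared rather than inferred. Untargeted feature
detection groups centroids into mass traces by single-linkage in m/z
with a 5 ppm gap tolerance and requires at least five consecutive
scans; duplicate features (within 5 ppm and 0.1 min) keep the higher
area.

## Evidence and confidence levels

The identification confidence scale (Schymanski levels 5…1) is invoked
by practitioners without a formal rule table, so the package codifies
one and documents it:

| level | evidence |
|-------|----------|
| 5 | exact mass only |
| 4 | isotope pattern verified |
| 3 | ≥ 2 ddMS2 fragments matched (SANTE two-fragment rule) |
| 2 | ≥ 2 fragments **and** isotope pattern |
| 1 | standard confirmation: rt shift < 0.1 min plus the fragment rule |

Isotope verification requires every predicted isotopologue at ≥ 5 %
relative abundance to be present within 5 ppm with relative abundance
agreeing within 30 % (relative). The 5 % floor means carbon-only M+1
peaks are not mandatory at low S/N. A predicted Cl/S M+2 that is absent
— or far weaker than predicted beyond the tolerance, as when an
isobar's ³⁴S peak poses as ³⁷Cl (every CHNOPS isobar of a chlorinated
ion within 5 ppm contains sulfur, so "absent" alone is not decisive) —
*refutes* the record, and refuted or fully fragment-mismatched records
are excluded from the report rather than demoted.

## The synthetic generator

`generate_run()` emulates a 30-min full-scan (m/z 50–750) plus top-5
ddMS2 acquisition: each spiked compound elutes as a pure Gaussian
(tailing is out of scope), carries its full isotopologue pattern, and
every centroid receives multiplicative mass jitter at the ppm scale.
The MS1 cycle default of 2 s gives ≥ 15 points across a 0.5-min-wide
peak. ddMS2 events fire on the top-5 precursors per cycle above an
intensity floor, with a 10-s dynamic exclusion (a free choice,
documented in the config) and a 5.0 Da isolation window; the matching
spike's fragment list is emitted with jitter. Polyethoxylate series are
expanded by `homolog_series_spikes()` with a discretized-Gaussian
abundance profile over the repeat count, emulating the bell-shaped
ladders of real alkyl ethoxylates, whose oligomers co-elute as a single
chromatographic peak.

What the generator does **not** emulate: electrospray response
differences between compounds, retention-time prediction from
structure, peak tailing, co-eluting isomers, and matrix-dependent ion
suppression. Passing tests therefore demonstrate the correctness of the
data treatment, not instrument-level performance on real formulations.

## Homolog series

`detect_homolog_series()` extends an m/z ladder from a seed feature in
steps of the repeat-unit mass within the averaged apex spectrum. The
default spacing is 44.02621 Da, the exact monoisotopic mass of
C₂H₄O — printed ethoxylate spacings sometimes differ in the last
decimals, and rather than guess intent the repeat unit is a parameter
with the exact mass as default (14.01565 for CH₂ homologs). When two
centroids fit a rung the more intense wins. Members must co-elute:
each member's own EIC apex within 0.05 min of the seed apex — our
operationalization of the single-chromatographic-peak behavior of
ethoxylate mixtures.

## Quantitation, validation, risk

Calibration is unweighted OLS (no weighting scheme is claimed by the
methods this emulates). Standard-addition concentration is the
x-intercept magnitude `intercept/slope`. Matrix effect is the percent
slope ratio minus 100; |ME| < 20 % counts as negligible. The LOQ
estimator is declared: the lowest calibration level with S/N ≥ 10 and
back-calculated accuracy within 20 %, scaled by the dilution factor
(e.g. 1 µg/L × 10⁴ = 0.01 g/L) and, for solids, by the stock
dissolution (1 g/mL for 2 g dissolved in 2 mL). The linearity
acceptance threshold defaults to R² ≥ 0.99 — deliberately not
hard-coding any observed study value as a gate. Banned compounds are
flagged at 0.1 % w/w; g/L concentrations convert to % w/w assuming a
density of 1 g/mL unless supplied, and the output records that
assumption. RfD folds are reported rounded half-up with the unrounded
ratio retained.

## A complete suspect-screening run

```{r pipeline}
db <- read_suspect_db(system.file("extdata", "suspect_db.csv",
                                  package = "ppscreen"))
spikes <- bind_rows(
  spike_spec("methylchloroisothiazolinone", "C4H4ClNOS",
             apex_rt = 7.65, apex_intensity = 5e5),
  spike_spec("lauramide DEA", "C16H33NO3", apex_rt = 4.2,
             apex_intensity = 2e6,
             fragments = tibble::tibble(
               formula = c("C14H28NO", "C4H12NO2"),
               rel_intensity = c(1, 0.6))))
gen   <- generate_run(synthetic_config(run_length = 10, seed = 1), spikes)
blank <- generate_blank(synthetic_config(run_length = 10, seed = 2))

report <- pipeline_config(sample = gen$run, blank = blank, db = db) |>
  run_suspect_pipeline()
select(report, suspect, mass_error_ppm, isotope_verified,
       fragments_matched, level)
```

The chlorinated preservative is verified by its isotope pattern but has
no fragments in its database entry (level 4); lauramide DEA matches
both diagnostic fragments and its pattern (level 2). A configured
standard run would upgrade matching records to level 1.

## Numerical choices and degenerate inputs

* m/z reported to 5 decimals; ppm errors computed against the rounded
  theoretical by default (both modes exposed).
* Isotopologue merging at 0.01 Da; convolution pruning at 10⁻⁹
  probability.
* Peak spans shorter than 4 points get shape score 0 with a warning;
  all-zero traces yield no peaks; an off-peak MAD of zero yields
  S/N = ∞ (noise-free synthetic data).
* Two-point calibrations warn (R² = 1 is degenerate); identical levels
  and negative standard-addition slopes are errors.
* Responses outside 0.5–1.5 × the calibrated range are flagged as
  extrapolated; extract concentrations below the LOQ are censored as
  `"<LOQ"`.
* Every stochastic component is driven by one explicit seed; a fixed
  seed reproduces a run byte for byte.

## Problem sizes in the test suite

The suite exercises full 30-min runs (900 MS1 scans) for the
recall/precision property with ten planted suspects, and shorter 2–10
min windows elsewhere; standard-addition recovery uses 200 seeded
simulations at 3 % CV with 7 addition levels. These sizes were chosen
so that each property is measured on data comfortably larger than its
estimator's support while keeping the default check fast.

## Known limitations

* Single-run design: no retention-time alignment across runs.
* Centroid data only; profile spectra are rejected, not converted.
* |z| = 1 only; multiply charged species are out of scope.
* No in-silico fragmentation: theoretical fragments are database
  entries, and the candidate table is a local stand-in for online
  compound libraries.
* Quantitation assumes linear response over the calibrated range.
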