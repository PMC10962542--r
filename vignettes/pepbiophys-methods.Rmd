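---
title: "Models and methods behind pepbiophys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pepbiophys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepbiophys)
```

`pepbiophys` implements the quantitative workflow used to characterize
constrained helical peptide inhibitors of a protein–protein interaction:
variant design, fluorescence-anisotropy (FA) binding and competition
fitting, circular-dichroism (CD) helicity estimation, and NMR
secondary-chemical-shift profiling. This vignette explains the models, the
choices that were genuinely open, and what the simulators do and do not
establish.

## Peptide model and variant design

Peptides are ordered residue lists (one-letter codes plus `pS` for
phosphoserine, counted as a single residue throughout) with parent-protein
numbering, 1-based and inclusive at both ends, so that a peptide named
after residues 73–94 spans exactly those positions. Terminal chemistry is
explicit (`acetyl` / `FAM-Ahx` / `free` at the N-terminus; `amide` / `free`
at the C-terminus) because it enters two distinct counts:

* `n_residues` — the normalisation of mean residue ellipticity;
* `n_amide` — backbone amide bonds, `(r − 1)` inter-residue bonds plus one
  per blocked terminus, hence `r + 1` for an acetyl/amide peptide. This is
  the `n` of the helicity formula. Keeping the two counts separate is
  essential: conflating them shifts every helicity estimate by roughly one
  percentage point for a 20-mer, which is the size of the effect the assay
  is meant to resolve. The 17-residue phosphoserine variant discriminates
  the conventions: only `n_amide = 18` reproduces its reported 16 %.

`enumerate_cys_pair_variants()` scans a helical region for (i, i+4) pairs
(spacing is a parameter; 4 ≈ one helical turn places both side chains on
the same face) and filters out hot-spot positions and pre-existing
cysteines. The hot-spot set is always caller-supplied, never inferred: the
exclusion list actually used in any given campaign is a scientific choice,
and hard-coding one would bake an assumption into a combinatorial
operation. For the 29-mer parent scanned over residues 76–89 with hot-spots
{77, 88} the scan yields 8 candidate pairs; published campaigns sometimes
report fewer after synthesis-feasibility triage, which is out of scope
here.

Constraint states share one sequence: `red` (free thiols) and `ox`
(disulfide) change no chemistry bookkeeping, while `mal`
(dibromomaleimide-bridged) adds one maleimide chromophore
(ε = 1700 M⁻¹cm⁻¹) to the Trp-based extinction coefficient
(ε = 5600 M⁻¹cm⁻¹ per Trp). The maleimide term is treated as additive at
the concentration-determination wavelength.

## Fluorescence anisotropy

Channel algebra: total intensity `I = 2PG + S`; anisotropy
`r = (S − GP)/(S + 2GP)`. The package uses this standard form because its
denominator is exactly the total intensity — the two definitions are a
consistent pair — and it guarantees `r ∈ (−0.5, 1]` for any non-negative
channels.

**Direct titrations** use the tight-binding (Morrison-type) quadratic: with
tracer total `[FL]`, protein total `x` and dissociation constant `K_d`, the
tracer bound fraction is the exact root of the one-site mass balance, which
the code evaluates in the cancellation-free form
`L_b = 2x / (b + √(b² − 4x[FL]))`, `b = x + [FL] + K_d`, so the `[FL] → 0`
limit recovers the hyperbolic isotherm `x/(x + K_d)` to machine precision.
Observed anisotropy is the intensity-weighted mix of free and bound states
with intensity-change factor λ; λ defaults to a fixed value of 1 (no
quantum-yield change on binding, the common case for fluorescein tracers)
and can be floated via `float_lambda = TRUE`.

**Competition curves** are fitted with a four-parameter logistic. Written
with `r_max` as the zero-competitor asymptote and `r_min` as the
full-displacement floor, the model is
`y = r_max + (r_min − r_max)/(1 + (x/x₀)^p)` and `IC50 = x₀`. Internally
the fit is direction-agnostic — asymptotes `A₀` (x→0) and `A∞` (x→∞) with
`p > 0` — and the labels `r_max = max(A₀, A∞)`, `r_min = min(A₀, A∞)` are
assigned afterwards. This is deliberate: a logistic with signed exponent
and a displacement curve read in opposite directions are the same model,
and resolving the orientation from the data avoids a silent sign
convention. When a competitor cannot fully displace the tracer the floor is
poorly determined, so `restrain_rmin = TRUE` fixes the full-displacement
asymptote at a value obtained from fully displacing competitors (default
−0.03).

Numerical choices, in one place:

* bounded Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) with a
  deterministic 3-point multi-start: edge means seed the asymptotes, the
  log-interpolated half-crossing seeds `x₀`/`K_d` (±half a decade), `p`
  starts at 1. Bounds are data-driven (e.g. `x₀ ∈ [min(x)/10³,
  max(x)·10³]`), which makes the fit equivariant under rescaling of the
  concentration axis.
* fits act on per-concentration replicate means, unweighted by default
  (inverse-variance weighting is an option); replicate SD is reported
  per concentration.
* `IC50_sd` comes from refitting each replicate series separately and
  taking the SD of the fitted midpoints when at least two full replicate
  series exist; otherwise the asymptotic fit SE is used.
* bound fractions computed from anisotropy are clamped to [0, 1] with a
  5 %-of-window overshoot tolerance; larger overshoots warn.
* degenerate inputs fail loudly: fewer points than parameters, flat curves
  (non-convergence or an `ic50_beyond_max_x` / `low_dynamic_range` flag),
  non-monotone displacement beyond a 15 %-of-range tolerance
  (`non_monotonic` flag).

Potency differences convert to free energy as
`ΔΔG = −RT ln(IC50_new/IC50_ref)` (R = 8.314 J mol⁻¹ K⁻¹, T defaulting to
298.15 K, the room-temperature equilibration of the assay), positive for an
improvement.

## Circular dichroism

`MRE = (θ_λ − θ₀)·M_w/(n_res·l·c)` with pathlength in **mm** and
concentration in **mg/mL**; this unit convention absorbs the usual factor
of 10 and is applied exactly as written. Blank subtraction is mandatory —
an explicit zero blank must be supplied if none was recorded — because a
silently skipped blank is a classic source of irreproducible MRE values.
The 222 nm value is taken at the nearest grid point (spectra are collected
on 1 nm grids); no smoothing is applied by default. Percent helicity uses
`(MRE₂₂₂ − MRE_coil)·100 / (−42500(1 − 3/n))` with the temperature-dependent
coil baseline `MRE_coil = 640 − 45T` (415 at 5 °C) and `n = n_amide`.
Estimates are reported unrounded with a nearest-integer companion for
table comparison.

## NMR secondary shifts

`Δδ = δ_obs − δ_RC` per residue and nucleus. The packaged random-coil table
is an approximate transcription of widely used disordered-peptide
compilations and is deliberately replaceable (`random_coil_table(path)`);
every numerical guarantee in the test suite uses a synthetic table instead,
so nothing depends on the shipped literature values. A maleimide-linked
cysteine (`C-mal`) has no established coil reference; it resolves to the
plain Cys entry, its out-of-trend values are reported rather than masked,
and `exclude_cmal = TRUE` removes it from segment calling only. No
neighbour or temperature corrections are applied by default.

Helical segments are maximal runs of at least `min_run = 4`
index-consecutive residues with `Δδ(Cα) > 0.1` ppm (or `Δδ(Hα) < −0.1` in
Hα mode). Both thresholds are this package's operational defaults — the
run-based reading of helical propensity is qualitative in origin — and are
exposed as parameters. Strength bands on Δδ(Cα): `< 0.1` coil-like,
`0.1–2.0` weak (transient peptide helicity), `≥ 2.0` strong (heavily
stabilised helices).

## Simulators: what they emulate, and what passing tests show

The generators reproduce the statistical structure each analysis stage
assumes, under the default study conditions: 50 nM tracer, 15 μM protein,
triplicate reads with i.i.d. Gaussian anisotropy noise of SD 0.003, and 12
log-spaced concentrations spanning 0.01–100× the curve midpoint. Noise is
applied to anisotropy rather than to the raw channels because the analysis
fits anisotropy means; a channel-level path exists through the plate-file
writer, which re-encodes anisotropy into P/S pairs and exercises the full
reader algebra. All generators are pure functions of (parameters, seed) and
restore the caller's RNG state.

The competitive-equilibrium simulator is the package's independent
thermodynamic oracle: it solves the two-ligand one-site mass balance to
machine precision (bracketed root plus Newton polish; relative mass-balance
error < 10⁻¹⁰ by test), records the bisection-found half-displacement
concentration as ground truth, and reduces exactly to the Morrison
quadratic at zero competitor. The logistic IC50 fitted to noiseless
equilibrium curves agrees with the half-displacement concentration to well
under 5 % in the assay's regime.

CD spectra are helicity-weighted mixtures of smooth, stylised helix and
coil basis shapes. Only their 222 nm values are contractually meaningful
(pinned so the helicity formula inverts exactly); band shapes elsewhere are
plausible but not calibrated, and maleimide exciton features, photobleaching
and instrument drift are not modelled. Consequently, passing round-trip
tests demonstrates the *arithmetic* of the pipeline — not that real spectra
of partially helical peptides will be this well-behaved.

## Problem sizes and tolerances

The test suite uses: noiseless round-trips at 10⁻⁶ relative tolerance; 200
seeded stochastic competition experiments (median IC50 recovery error
~2 %, asserted < 10 %); 1000 random secondary-shift profiles checked
against an exhaustive run-scanner; 40 randomized design-scan cases against
a brute-force pair enumerator; and the full 13-peptide characterization
panel reproduced row by row. These sizes give stable statistics while
keeping the default run near twenty seconds.

## Known limitations

* The logistic IC50 is an operational potency measure; no Cheng–Prusoff or
  exact-competition back-calculation of competitor K_d is attempted.
* G-factor calibration, FRET/quenching corrections and global multi-curve
  fitting are out of scope.
* CD helicity rests on the two-state 222 nm estimator; turn-like or
  exciton-distorted spectra (as constrained peptides can show) violate its
  assumptions, which is precisely why the NMR stage exists alongside it.
* The shipped coil-shift table is a convenience default, not a curated
  reference.
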