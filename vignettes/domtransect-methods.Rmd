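---
title: "Methods: molecular and optical DOM transect profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: molecular and optical DOM transect profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domtransect)
```

This vignette is the package's own account of its models and numerical
choices: what each stage computes, which parameters matter and why their
defaults are what they are, what the synthetic transect does and does not
emulate, and where the method's genuine limits lie.

## Formula assignment

A negative-mode FTICR spectrum of a DOM extract is a list of centroided
peaks (m/z, intensity, S/N). The assignment model treats every analyte as
an even-electron [M−H]⁻ ion: the neutral monoisotopic mass is the
observed m/z plus one proton mass (1.007276467 Da), and the neutral
formula must have an integer, non-negative double-bond equivalent
DBE = C + 1 − (H − N)/2 (phosphorus is fixed at zero), which forces H − N
even. All masses come from a single isotope table (¹²C = 12 exactly; ¹H,
¹⁴N, ¹⁶O, ³²S at their CODATA values), so the generator, the calibrator
and the assigner share one mass scale.

*Filtering.* Peaks must exceed S/N 6 **strictly** and lie inside the
200–800 Da acquisition window. The threshold is a property of the
instrument's noise estimate, not a tunable of this package.

*Charge.* The charge of each ion is read from the spacing to its ¹³C
isotopologue: a satellite at +1.0033548/z Da (matching tolerance 2 mDa)
fixes z. Ions without a detectable satellite inherit the
intensity-weighted majority charge and carry a `defaulted` flag. Only
z = 1 ions proceed to assignment. This is a deliberately reduced form of
full total-mass-difference charge deconvolution; DOM ESI spectra are
overwhelmingly singly charged, so the satellite test plus a majority
default recovers > 95 % of charges in the synthetic benchmark.

*Internal recalibration.* DOM spectra are self-calibrating: the abundant
CHO backbone forms CH₂-homologous series (adding CH₂ leaves O and H − 2C
invariant) spanning the whole window. The calibrator coarse-assigns the
most intense peaks CHO-only at 3 ppm, keeps unambiguous hits in series of
three or more members, fits the ppm error as a linear function of m/z by
least squares with two trimming passes (3 × MAD) to shed
misidentified calibrants, and applies the correction to every peak.
Because the fitted family nests the zero correction, the calibrant
residual RMS can never exceed the pre-correction RMS. A linear model in
m/z is sufficient for offset-plus-drift error structures; with fewer than
five calibrants the calibration is refused rather than extrapolated.

*Candidate search.* The production search enumerates the full constraint
box once — every CHNOS formula with O/C ≤ 1, H/C ≤ 2, C ≤ 120, H ≤ 200,
0 < O ≤ 60, N ≤ 2, S ≤ 1, DBE ≥ 0 and neutral mass up to the window edge
plus margin (~284,000 formulae) — sorts it by mass, and resolves each
peak by binary search. The test suite holds this path against an
independent per-mass arithmetic enumerator on hundreds of random masses;
the two agree exactly.

*Ambiguity.* When several candidates fall inside the tolerance window the
resolver prefers (1) fewest heteroatoms N + S, then (2) smallest absolute
mass error; a remaining tie is declared ambiguous and the peak is
excluded from downstream statistics. The heteroatom-minimal rule reflects
the CHO dominance of DOM. It has a hard physical consequence: C₂₁ and
H₁₂O₁₃S differ by only 0.138 mDa, i.e. less than 0.25 ppm above
~550 Da, so a highly oxygenated sulfur formula (O ≥ 14) always loses to
a pure-CHO isobar inside a 0.5 ppm window. Resolving that pair truly
requires isotope fine structure, which is out of scope; the round-trip
guarantees below therefore apply to the sub-box excluding {S = 1,
O ≥ 14}.

*Tolerance.* The default matching window is 0.5 ppm, the accuracy level
the internal calibration reliably reaches; it is configurable. Note the
window also bounds attainable recovery: with σ ppm of per-peak mass noise
a fraction 2Φ(−0.5/σ) of true formulae fall outside their own window
(1.2 % at σ = 0.2 ppm, 9.5 % at σ = 0.3 ppm). Assignments are almost
never *wrong* at these settings (> 99 % exact among assigned); they are
occasionally *missing*.

## Molecular profiles

Formula identity everywhere is the neutral CHNOS tuple; isomers are
indistinct, consistent with a stoichiometry-level analysis. Compound
classes are the conventional Van Krevelen regions with their printed
left-closed/right-open boundaries:

| class | O/C | H/C | note |
|---|---|---|---|
| aliphatics | (0, 0.65) | [1.6, 2.2) | |
| N-saturated | [0.1, 0.65) | [1, 2.2) | requires N ≥ 1 |
| low-oxidized lignins | [0.1, 0.5) | [0.7, 1.6) | |
| oxidized lignins | [0.5, 1) | [0.7, 1.6) | |
| condensed tannins | (0, 0.5) | [0.3, 0.7) | |
| hydrolysable tannins | [0.5, 1) | [0.3, 0.7) | |
| carbohydrates | [0.65, 1) | [1.3, 2.2) | |

Two design choices deserve note. First, the regions genuinely overlap:
the N-saturated box overlaps the aliphatic and lignin boxes for
N-containing formulae, and the carbohydrate box overlaps the oxidized
lignins at H/C 1.3–1.6. Classification therefore evaluates the
N-saturated rule first for N ≥ 1 formulae (the class is *defined* by the
presence of N) and then the N-free regions in the order printed above, so
oxidized lignins win their overlap with carbohydrates. Second, everything
that matches no region is an explicit eighth label, `unclassified`, so
the densities D_k = Σ I(class) / Σ I(all) always sum to one — a
seven-class report simply omits the (typically ≈ 0) remainder, which is
why published seven-class density tables can sum to slightly less than
one.

"Number-averaged" descriptors are unweighted arithmetic means over
formulae (that is what a number average is); an intensity-weighted
variant sits behind a flag for sensitivity analysis. Common formulae are
the exact intersection of the per-station formula sets; "unique" formulae
are those occurring in at most two stations (configurable).

## Optics

Absorption follows a_λ = 2.303 A_λ / L (Napierian coefficient from
decadic optical density, L in metres). Spectral slopes are fitted by
ordinary least squares of ln a_λ on λ — the log-linear fit is exact on
noiseless exponentials and statistically adequate at the ≤ 1 % noise of a
bench spectrophotometer; a nonlinear refit is available behind a flag.
Sr = S(275–295)/S(350–400) is exactly 1 for any single exponential,
which the tests exploit as a closed-form oracle.

The trilinear EEM model X[i,j,k] ≈ Σ_r A[i,r] B[j,r] C[k,r] is fitted by
hierarchical alternating least squares with nonnegativity on all three
modes. Numerical choices: scatter cells (first- and second-order Rayleigh
bands, ±10 nm) are masked as missing and re-imputed from the current
model each sweep (EM), which keeps the observed-entry loss monotone;
initialisation is uniform-random with 10 multistarts by default, keeping
the lowest-error solution; convergence is a relative loss change below
1e-8 or 2,500 sweeps; emission/excitation loadings are normalised to unit
Euclidean norm with the scale absorbed into the sample scores; components
are reported in ascending order of emission maximum, so C1 is the bluest
(protein-like) component; inter-component congruence above 0.98 flags a
degenerate solution.

The component number is chosen by growing the model while (a) the
R² gain over n − 1 exceeds 0.5 percentage points and (b) a split-half
test — independent fits on the two sample halves — agrees in its
loadings with per-component congruence above 0.95, returning the largest
accepted n. A literal "smallest n with large gain" rule would always
return the range floor (the first component always explains the most
variance), so the elbow-plus-stability form is used; on three-fluorophore
data with ≤ 5 % noise it selects three components, and the fourth is
rejected both by gain and by split-half instability.

## Correlation mapping

Spearman's rank correlation (average-rank ties) is computed between every
common formula's sum-normalized intensity and every hydrochemistry
parameter across stations. p-values use the t approximation
t = ρ√((n−2)/(1−ρ²)) for n ≥ 10 and the exact permutation null
(all n! rank permutations, cached per n) below that; the transect n of
17–18 sits comfortably in the t regime, and the null calibration test
confirms a 3–7 % rejection rate at α = 0.05. No multiple-testing
correction is applied — the screening criterion is the raw p < 0.05
count per parameter (strictly > 200 significant correlations), followed
by strict |r| > 0.7 highlighting in the Van Krevelen overlay — mirroring
standard practice for this analysis; a Benjamini–Hochberg option exists
via `p.adjust` on the returned map if a user wants it. Stations can be
excluded by configuration (e.g. a floodplain-lake outlier); the common
set is computed after exclusion.

## The synthetic transect

The generator exists so that every stage above can be scored against
known truth. It emulates:

* an 18-station transect ordered south → north with a regime step at the
  confluence station (index 9 of 18), class mixture weights calibrated to
  the printed range of a lowland-river study — hydrolysable tannins
  0.198 → 0.445, low-oxidized lignins 0.277 → 0.114, peptides/amino-
  sugars 0.06 → ~0 (a trace 0.0004 north, 0.000 at reporting precision,
  so the shared core remains present everywhere);
* a 1,600-formula shared core present at every station plus 50 planted
  singleton formulae per southern station; heteroatom families at
  CHO ≈ 0.85, CHON ≈ 0.08, CHOS ≈ 0.06 by count, with sulfur drawn in
  the low-oxidation region (O ≤ 12, C ≤ 26) where sub-ppm CHNOS
  assignment is unambiguous — see the isotope-fine-structure limit above;
* per-formula log-normal intensities (σ_log = 1) with station jitter
  (σ_log = 0.15), rescaled so each station's class intensity shares equal
  its regime weights;
* peak lists with a +1.5 ppm systematic offset and 0.3 ppm total Gaussian
  mass noise, of which 85 % of the variance is species-reproducible
  across stations (drawn deterministically from the formula itself) and
  the rest per-run shot noise — mirroring the smooth, instrument-stable
  residual error of a calibrated FTICR, and the reason common-formula
  sets survive assignment at realistic sizes; ¹³C satellites at 1.08 %
  per carbon; 200 sub-threshold noise peaks; 2 % doubly charged
  contaminants;
* single-exponential absorption spectra (a steeper UV term in the south
  raises Sr there); EEMs synthesized from three Gaussian fluorophores
  (ex/em 280/350, 320/420, 350/470 nm) whose protein-like score drops
  north of the confluence; additive EEM noise scaled to the clean-signal
  RMS;
* hydrochemistry generated as monotone functions of the realized
  hydrolysable-tannin density — C_org stepping 0.2 → 1.1 mM, a254,
  CO2 rising, pH, alkalinity, HCO₃⁻ falling, all |r| > 0.7 with each
  other — while temperature, salinity and Si carry no trend.

What it does **not** emulate: ionization-efficiency differences between
compound classes, isotope fine structure, instrument transients or
space-charge dynamics, inner-filter effects in fluorescence, and any
within-regime spatial autocorrelation beyond the step-plus-jitter model.
Passing tests therefore demonstrate the correctness and calibration of
the *computations* under realistic statistical structure, not the
instrumental fidelity of a forward model.

## Problem sizes and determinism

The test suite runs the full default transect (18 stations, ~3,600 peaks
per station) once, 50 seeded trilinear fits at 5 % noise, a 1,000-sample
Spearman null, 1,000 random partition ensembles and a 200-mass
search-oracle sweep; these sizes were chosen as the smallest that
exercise each claim at its stated confidence. Every source of randomness
takes an explicit seed, and every generator is bit-identical under a
fixed seed; reports embed a configuration hash so that reruns are
byte-comparable.

## Known limitations

* CHOS formulae with O ≥ 14 cannot be assigned correctly at 0.5 ppm by
  any rule that prefers fewer heteroatoms (0.138 mDa isobar with C₂₁);
  they require isotope fine structure.
* The recovery of *generated* formulae is bounded by the noise-escape
  probability 2Φ(−tol/σ); at σ = 0.3 ppm roughly one peak in ten falls
  outside its own 0.5 ppm window and is honestly reported as unassigned.
* The split-half component test needs enough samples per half (≥ 6); on
  very small EEM stacks the selection falls back to the range floor with
  a warning rather than inventing stability.
* Charge determination trusts the ¹³C satellite; for very low-intensity
  ions whose satellites sink below the noise floor it defaults to the
  majority charge.
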