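# domtransect

Molecular and optical profiling of dissolved organic matter (DOM) along
river transects.

Ultrahigh-resolution (FTICR) mass spectrometry resolves a riverine DOM
extract into thousands of exact-mass peaks, each attributable to one CHNOS
elemental formula. Projected onto Van Krevelen coordinates (H/C vs O/C),
these formulae fall into stoichiometric compound classes — aliphatics,
peptides/amino-sugars, lignins, tannins, carbohydrates — whose
intensity-weighted population densities trace the sources and
transformation state of the organic matter. Optical spectroscopy adds
concentration-independent descriptors of the same material: exponential
absorption slopes and their ratio Sr, fluorescence intensity ratios, and a
trilinear (PARAFAC) decomposition of excitation–emission matrices (EEMs)
into fluorophore components. `domtransect` implements this entire analysis
chain for station transects, together with a ground-truthed synthetic
transect generator so that every stage is verifiable end to end.

The package is aimed at biogeochemists and analytical chemists working
with FTICR-MS peak lists and CDOM optics who want a scripted, testable
version of the standard DOM workflow.

## What it computes

**Formula assignment.** Peaks with S/N > 6 inside the 200–800 Da window
are charge-annotated from their 13C isotopologue spacing
(Δm = 1.0033548/z), internally recalibrated against CH2-homologous CHO
series bootstrapped from the spectrum itself (linear ppm-error model,
residual RMS well under 0.5 ppm), and matched at 0.5 ppm to neutral CHNOS
formulae under the standard DOM constraints

    O/C ≤ 1, H/C ≤ 2, C ≤ 120, H ≤ 200, 0 < O ≤ 60, N ≤ 2, S ≤ 1,

with DBE = C + 1 − (H − N − P)/2 required to be a non-negative integer for
even-electron [M−H]⁻ ions. Ambiguous peaks are resolved
heteroatom-minimal, then error-minimal, or excluded.

**Molecular profiles.** Compound classes by the conventional Van Krevelen
boundaries; class densities D_k = Σ I_i (class) / Σ I_j (all);
count-based CHO/CHON/CHOS shares; number-averaged M, O/C, H/C, DBE;
common (all-station) and near-unique (≤ 2 stations) formula subspaces.

**Optics.** a_λ = 2.303 A_λ / L; slopes of ln a_λ over 275–295 and
350–400 nm and their ratio Sr; F350/Fmax (ex 280 nm) and F550/F375
(ex 350 nm); nonnegative trilinear EEM decomposition by multistart HALS
with scatter masked as missing, split-half validated component-number
selection, and the component score ratios C2/C1, C2/(C1+C2),
C2/(C1+C2+C3), C1/(C2+C3).

**Correlation mapping.** Spearman rank correlation of the sum-normalized
intensities of every common formula against the station hydrochemistry
(temperature, salinity, pH, alkalinity, HCO3⁻, CO2, Si, C_org, a254);
parameters kept when they carry > 200 significant (p < 0.05)
correlations; Van Krevelen overlays highlighting r > 0.7 / r < −0.7; and
the hydrochemistry inter-correlation matrix.

## Worked example

```r
library(domtransect)

sim <- simulate_transect(transect_design(seed = 1))   # 18 stations, south -> north
bundle <- run_pipeline(sim, pipeline_config(seed = 1))
```

The run log prints, per station (values from this run):

```
S01: 3197 peaks post-filter | cal RMS 0.275 ppm | 1540 assigned | 1621 unassigned | 0 ambiguous
...
common formulae: 1036
selected parameters (> 200 significant): a254, alkalinity, c_org, co2, hco3, ph
```

meaning: ~3,200 peaks survive the S/N filter, internal calibration leaves
a sub-0.3 ppm residual, ~1,500 peaks receive unambiguous formulae (the
unassigned are mostly 13C satellites and planted noise peaks), 1,036
formulae occur at every station, and six mutually correlated
hydrochemistry parameters each show > 200 significant correlations with
the molecular profile. Downstream tables show the transect signature the
generator plants: the hydrolysable-tannin density rises from ≈ 0.20 to
≈ 0.44 across the confluence while the amino-sugar density falls from
0.06 to ≈ 0, C_org steps from ≈ 0.2 to ≈ 1.1 mM, and the protein-like
fluorescence contrast C1/(C2+C3) drops from ≈ 1.1 to ≈ 0.15.

The numbered scripts under `analysis/` run the same chain stage by stage
(simulate → assign → profile → optics → correlate), reading and writing
delimited text under `results/`.

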