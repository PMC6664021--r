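---
title: "Methods: UAV multispectral plot phenotyping for bioethanol trait ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: UAV multispectral plot phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uavpheno)
```

## The problem

Breeding cereals for straw-based bioethanol requires phenotyping two
traits across hundreds of field plots: total biomass dry weight
(kg/m&sup2;) and saccharification sugar release (ul glucose per mg
straw), combined into a theoretical ethanol yield per hectare. Wet-lab
assays for these traits take days per trial; aerial multispectral
imaging offers a non-destructive proxy. This package implements, as a
fully testable pipeline, the image-analysis and statistics chain of such
a phenotyping system: per-plot vegetation segmentation on six-band
orthomosaics, seven vegetation indices, multi-temporal aggregation,
ethanol-yield conversion, and accession ranking via linear models.
Because no raw UAV imagery of this kind is publicly deposited, the
package ships a synthetic-data generator that reproduces the design,
temporal and statistical structure of a reference trial (66 cereal
accessions of barley, bread wheat, durum wheat and triticale in 3
randomized complete blocks of 78 plots; 7 flights between 94 and 175
days after sowing, DAS), so every downstream stage can be validated
against known ground truth.

## The pipeline stages

### Trial design

`generateTrialDesign()` lays out `nBlocks` stacked blocks of
`plotsPerBlock` rectangular plot positions and assigns each accession to
exactly one position per block by a seeded permutation (an RCBD).
Positions beyond `nAccessions` are carried as *empty plots*: they appear
in the layout and in plot-table exports but are excluded from all
analysis. The per-block composition of the reference trial is not fully
recoverable (78 positions versus 66 accessions, two of them duplicated),
so the generator exposes `plotsPerBlock` directly instead of guessing an
exact arrangement.

Coordinates are local planar metres with the origin at the raster
top-left, x east, y south; pixels are row-major and polygon membership
uses the pixel-centre-inside rule with a half-open far edge, so adjacent
rectangles can never claim the same pixel. The default desk-scale
geometry (0.6 m x 0.45 m plots, 0.3 m/0.5 m spacings, 0.01 m/pixel)
renders a full 7-date, 234-plot series in well under a minute; the
reference 5.41 mm GSD is supported via the `gsd` argument but not the
default.

### Ground-truth phenotypes and phenology

`generatePhenotypes()` draws a per-accession biomass and sugar-release
effect from truncated-at-zero normals around species means
(`speciesParams()`: biomass 0.67/0.83/0.71/0.52 kg/m&sup2; and sugar
1.16/0.98/0.98/0.94 ul/mg for bread wheat, durum, barley, triticale),
shares it across blocks, and adds block-level noise. The between-accession
standard deviations (0.18 kg/m&sup2;, 0.12 ul/mg) were chosen once so
that simulated trials span the ranges reported for comparable field
experiments (biomass roughly 0.26-1.40 kg/m&sup2;, sugar roughly
0.77-1.36 ul/mg); block noise (0.05/0.04) is small relative to the
accession effects, as expected in a well-managed irrigated trial.
Theoretical ethanol yield is computed from the two traits exactly (see
below), never drawn independently.

`generatePhenology()` assigns each accession an anthesis window: start
uniform on 110-160 DAS (the reported extremes of comparable trials),
length uniform on 10-20 days, end capped at 175 DAS.

### Synthetic reflectance imagery

`renderOrthomosaic()` builds one six-band raster per flight date (bands
450, 530, 670, 700, 740, 780 nm, float32 reflectance). Each sown plot
receives a canopy map in which every pixel is vegetation with marginal
probability equal to the canopy cover at that date; spatial clumping is
produced by thresholding a Gaussian-smoothed random field
(`clumpSigma = 4` px), and patches below `minObjectSize = 4` px are
removed from the truth because a plant occupies several pixels at the
default GSD. Remaining pixels are soil. Gaussian pixel noise
(`noiseSd = 0.01` reflectance units) is added per band and the result is
clipped to [0, 1].

The optical model has three deliberate, simple components:

* **Canopy cover** rises logistically over DAS to a plateau
  `0.50 + 0.45 w`, where `w` is the plot biomass scaled to a fixed
  reference range (0.2-1.4 kg/m&sup2;). Cover is a pure, monotone
  function of the plot's own biomass — the scaling uses the clamped
  biomass value rather than a rank statistic so that one plot's cover
  never depends on the other plots.
* **Greenness** `g` rises logistically, plateaus at
  `0.50 + 0.25 s + 0.15 w` (`s` = sugar release scaled to
  0.7-1.4 ul/mg), and after the accession's anthesis end decays
  exponentially (30-day e-folding) toward a floor of 35 % of the
  plateau: straw from a vigorous green canopy retains relatively higher
  residual greenness. The vegetation spectrum is the linear mix
  `(1 - g) * senescent + g * green` of two fixed endmembers.
* **NIR structural vigor**: the two NIR bands of the mixed spectrum are
  scaled by `0.65 + 0.35 w`. Near-infrared scattering grows with canopy
  structure largely independently of pigments, which is what makes
  NIR-based indices the better biomass proxies and visible-based indices
  the better greenness/sugar proxies — the contrast this whole approach
  relies on.

The endmember spectra are synthetic calibration constants, not measured
spectra. They were calibrated once, during design, so that the seven
indices reproduce the qualitative seasonal shapes the generator is meant
to emulate: NIR-based indices (NDVI, GNDVI, MCARI, MSR) trace a
bell-shaped curve peaking at an interior date near anthesis, while
visible-based indices (ExG, VIgreen, TCI) stay comparatively flat and
rise markedly at the last date as senescent straw brightens. The
senescent endmember is brighter and relatively green-shifted
(G > R1 > B), which produces that late visible-index rise; this is a
modeling choice, not a measured property.

What the generator does **not** emulate: radiative-transfer canopy
optics, BRDF and illumination effects, shadows, weeds, inter-plot
canopy overlap, geometric or photogrammetric distortion, and
registration error. Passing tests therefore demonstrate correctness of
the analysis chain on data with the right statistical and temporal
structure — they do not certify performance on real imagery, where
segmentation accuracy and index-trait correlations will be lower.

### Vegetation segmentation (per-plot Otsu with object cleanup)

For every plot and date, `classifyPlotVegetation()` computes a per-pixel
greenness feature inside the plot polygon — Excess Green by default,
NDVI selectable — and splits it with `otsuThreshold()`: the histogram
(256 equal-width bins over the observed per-plot range) edge that
maximizes the between-class variance `w0 w1 (mu0 - mu1)^2` of the two
classes it induces. Class means are computed from the raw values, not
bin midpoints, and ties between equally good cuts break toward the
lower threshold, so the operation is fully deterministic. The class with
the higher mean feature value is labelled vegetation (greenness
features increase with vegetation — a documented assumption).

Object-based behaviour is approximated by connected-component labelling
of the vegetation mask with a minimum object size of 4 pixels; the
multiresolution segmentation of commercial OBIA software is not
reproducible from published information, and pixel classification plus
component filtering gives the same plot-level statistics on this
imagery. Three guards map degenerate plots to an all-background,
low-cover-flagged mask rather than a biased estimate: a feature sample
with fewer than two distinct values; a between-class mean separation
below `minSeparation = 0.08` (about twice the separation Otsu finds
when splitting pure soil noise, and well below the soil-vegetation
separation of roughly 0.13); and a vegetation fraction below
`minFraction = 0.005`. Low-cover plots propagate missing values
downstream, never zeros.

`extractPlotSpectra()` then averages each band over vegetation pixels
only, excluding NaN pixels from numerator and count. Whether the
original system averaged vegetation objects or all plot pixels is
ambiguous; vegetation-only means are used here, as the classification
step would otherwise be pointless.

### Vegetation indices

`computeVIs()` evaluates, from the six band means B, G, R1 (670 nm), R2
(700 nm), NIR1 (740 nm), NIR2 (780 nm):

| index | formula | region |
|---|---|---|
| ExG | `2G - R1 - B` | visible |
| VIgreen | `(G - R1)/(G + R1)` | visible |
| TCI | `1.2(R2 - G) - 1.5(R1 - G) sqrt(R2/R1)` | visible + red edge |
| NDVI | `(NIR1 - R2)/(NIR1 + R2)` | NIR |
| GNDVI | `(NIR2 - G)/(NIR2 + G)` | NIR |
| MCARI | `((NIR1 - R2) - 0.2(NIR1 - G)) (NIR1/R2)` | NIR |
| MSR | `(NIR1/R2 - 1)/(sqrt(NIR1/R2) + 1)` | NIR |

Two conventions deserve note. MCARI is computed with the 740/700/530 nm
bands exactly as written, although the original MCARI formulation uses
700/670/550 nm — the band set of the six-filter camera modelled here is
kept deliberately. TCI is implemented in its triangular-chlorophyll form
with the `sqrt(R2/R1)` factor. The band-symbol mapping (R1 = red,
R2 = red edge, NIR1/NIR2 = 740/780 nm) is the only assignment consistent
with all seven formulas and the camera's filter set.

Indices are computed on plot-mean reflectances (mean-then-index);
per-pixel evaluation exists only as the segmentation feature. Ratio
indices yield missing values (never infinities) when a required band is
non-positive; the remaining indices are still computed.

### Temporal scenarios

Three aggregations per plot and index: **TS-1**, the raw value of one
flight date; **TS-2**, the unweighted mean over flights inside the
accession's anthesis window, inclusive at both ends (inclusivity is not
stated in the source protocols; inclusive was chosen and documented);
**TS-3**, the unweighted mean over all available flights, ignoring
missing values. Accession-level anthesis dates are used because
phenology is recorded per accession. If no flight falls inside a window
the two flights bracketing the window midpoint are averaged and the row
is flagged `fallback`, so analysts can exclude it — with the default
flight calendar this arises only for short windows inside the 18-day
gap between the 143- and 161-DAS flights.

### Theoretical ethanol yield

`theoreticalEthanolYield()` computes
`E = S x 0.511 x (W x 10000) / 1000` with S in ul/mg and W in
kg/m&sup2; (0.511 is the stoichiometric glucose-to-ethanol factor of
the NREL standard; 10000 converts to kg/ha). The result is reported on
the m&sup3;/ha scale on which species and accession yields are
conventionally tabulated for this formula; the formula's own unit label
would read L/ha — an inconsistency in the source equation that the
package documents rather than resolves, computing the formula verbatim.
The conversion factor is an overridable parameter for sensitivity
analyses.

### Association and ranking

`fitLinear()` is ordinary least squares at plot level (not accession
level — the reference analyses use all plots), with R&sup2; the squared
Pearson correlation, RMSE the root mean squared residual, and a raw
two-sided t-test on the slope; a constant response is defined to have
R&sup2; = 0. `scanModels()` fits the full grid of 7 indices x (7 single
dates + TS-2 + TS-3) x 3 phenotypes and attaches the conventional
category — low (R&sup2; < 0.50), moderate (0.50 &le; R&sup2; < 0.60),
high (R&sup2; &ge; 0.60), boundaries mapping upward. No multiple-testing
correction is applied across the 189-model grid, matching the reference
practice; p-values are reported raw and should be read accordingly.

`speciesAnova()` runs one-way ANOVA with Tukey HSD at alpha = 0.05
(the post-hoc test is a package choice; only "ANOVA" is specified in
the reference) and assigns compact letter displays by insert-and-absorb,
with "a" on the highest mean. `rankAccessions()` applies a chosen model
to plot-level index values, averages predictions per accession across
blocks, sorts descending (ties broken lexicographically by accession
ID), and reports the plot-level prediction RMSE plus the Spearman
correlation against observed accession means.

### Orchestration

`runPipeline()` chains all stages under one validated `runConfig()`.
A single master seed is expanded arithmetically into per-stage
substreams (design, phenotypes, phenology, one per rendered date), so
any stage is independently reproducible and reruns are byte-identical.
Plot-level CSVs are the inter-stage contract: any stage can be run
standalone on externally produced tables, so real UAV exports could be
swapped in at the plot-table boundary. A thin command-line wrapper with
per-stage subcommands ships in `inst/scripts/uavpheno-cli.R`.

## Numerical choices and problem sizes

Reflectance is stored at float32 precision (snapped at object
construction) to match the on-disk GeoTIFF sample format, making raster
write/read round-trips bitwise exact. Rasters are written as
single-strip uncompressed float32 GeoTIFFs with pixel-scale/tiepoint
tags and a JSON metadata block (geotransform, wavelengths, DAS) in the
ImageDescription tag, by a writer internal to the package; reading goes
through libtiff. GeoJSON carries plot polygons; CSV (comma, UTF-8, "."
decimal, empty fields for missing) is the canonical table dialect.

The test suite exercises small trials (6-8 accessions, 2 blocks) for
unit properties and one full-scale default run (66 accessions x 3
blocks x 78 plots, 7 dates, 0.01 m GSD) for the end-to-end seasonal
shape and ranking checks; parameter-recovery checks use 500 simulated
regressions at the reference size of 234 plots. These sizes keep a
complete run in tens of seconds while preserving the reference design's
cardinalities.

## Known limitations

The generator's single greenness scalar plus NIR vigor factor is a
two-degree-of-freedom caricature of canopy optics; index-trait
correlations on synthetic scenes are accordingly cleaner than any field
result, especially on early dates. Segmentation assumes vegetation is
the brighter class in the chosen feature and will mislabel plots where
that fails (e.g. algae-crusted soil). TS-2 assumes accession-level
phenology; plot-level anthesis records, if available, would need a
trivial extension. The ANOVA letters use unadjusted Tukey HSD on a
possibly unbalanced design (empty plots), which is standard but
approximate under strong imbalance.
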