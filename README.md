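# uavpheno

High-throughput phenotyping of cereal field trials from six-band aerial
orthomosaics, aimed at breeders screening wheat, barley and triticale
accessions for straw-based bioethanol potential. The package covers the
full analysis chain — and, because raw UAV imagery of this kind is not
publicly deposited, a synthetic-data generator with known ground truth
that makes every stage testable end to end:

1. **Simulate** a randomized complete block trial (66 accessions x 3
   blocks x 78 plots by default), ground-truth biomass `W` (kg/m²) and
   saccharification sugar release `S` (ul glucose/mg straw), accession
   phenology, and a six-band reflectance orthomosaic per flight date
   (450/530/670/700/740/780 nm; 7 dates, 94–175 days after sowing).
2. **Segment** the vegetation fraction of every plot on every date by
   per-plot Otsu thresholding of a greenness feature (ExG or NDVI) with
   connected-component cleanup, and extract vegetation-only band means.
3. **Index**: compute ExG, VIgreen, TCI (visible) and NDVI, GNDVI,
   MCARI, MSR (NIR-based) from the band means.
4. **Aggregate** each index per plot over three temporal scenarios:
   one flight date (TS-1), the accession's anthesis window (TS-2), the
   full season (TS-3).
5. **Convert** ground truth to theoretical ethanol yield
   (m³/ha):

   `E = S [ul/mg] x 0.511 x (W x 10000) [kg/ha] / 1000`

   with 0.511 the stoichiometric glucose→ethanol factor (NREL
   standard).
6. **Associate and rank**: scan simple linear models of every index x
   scenario against `W`, `S` and `E` (slope, intercept, R², RMSE, raw
   slope t-test; categories low R² < 0.50 ≤ moderate < 0.60 ≤ high),
   compare species by one-way ANOVA with Tukey compact-letter displays,
   and rank accessions by model-predicted ethanol yield.

## Worked example

```r
library(uavpheno)

## Eq.-style worked example: barley species means
theoreticalEthanolYield(1.16, 0.71)
#> [1] 4.208596        # 4.21 m3/ha at two decimals

## A small end-to-end run: 8 accessions x 3 blocks, 7 flight dates
cfg <- runConfig(seed = 1, nAccessions = 8, nBlocks = 3, plotsPerBlock = 9,
                 geometry = trialGeometry(plotsPerRow = 3))
man <- runPipeline(cfg, "runs/demo")
str(man$rankModel)
#> List of 8
#>  $ vi       : chr "NDVI"
#>  $ scenario : chr "TS3"
#>  $ phenotype: chr "ethanolYield"
#>  $ r2       : num 0.715
#>  $ rmse     : num 0.367
#>  $ category : chr "high"
#>  $ plotRmse : num 0.367
#>  $ spearman : num 0.762
```

The manifest says the configured ranking model (full-season mean NDVI
against theoretical ethanol yield) reached R² = 0.715 ("high") with a
plot-level prediction RMSE of 0.367 m³/ha, and that the predicted
accession ranking correlates with the true one at Spearman rho = 0.762
on this small trial. The run directory contains every stage output as
CSV/GeoJSON; the model grid, for instance:

```r
mods <- readPlotTable("runs/demo/models.csv")
top <- mods[mods$scenario == "TS3" & mods$phenotype == "ethanolYield", ]
head(top[order(-top$r2), c("vi", "slope", "intercept", "r2", "rmse", "category")], 3)
#>        vi slope intercept    r2  rmse category
#> 186 MCARI  13.3     1.194 0.735 0.355     high
#> 183 GNDVI  15.5     0.974 0.735 0.355     high
#> 180  NDVI  15.2     0.434 0.715 0.367     high

head(readPlotTable("runs/demo/ranking.csv"), 3)
#>   rank accessionId predicted observed nPlots
#> 1    1         TP5      4.36     4.19      3
#> 2    2          BW      3.44     3.36      3
#> 3    3        Anza      3.40     3.47      3
```

NIR-based indices top the ethanol and biomass models and visible-based
indices the sugar models, mirroring the spectral contrast the approach
exploits (NIR scattering tracks canopy structure, visible greenness
tracks pigments and sugars).

A thin CLI over the same functions ships in
`inst/scripts/uavpheno-cli.R` (`simulate`, `segment`, `indices`,
`aggregate`, `ethanol`, `associate`, `rank`, `run-all`); the plot-level
CSVs are the inter-stage contract, so real UAV exports can replace the
simulator at the plot-table boundary.

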