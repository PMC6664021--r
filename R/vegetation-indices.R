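#' Seven vegetation indices from six-band reflectance
#'
#' Computes, from the band means B (450 nm), G (530 nm), R1 (670 nm),
#' R2 (700 nm), NIR1 (740 nm) and NIR2 (780 nm):
#'
#' * `ExG   = 2 G - R1 - B` (Excess Green)
#' * `VIgreen = (G - R1) / (G + R1)`
#' * `TCI   = 1.2 (R2 - G) - 1.5 (R1 - G) sqrt(R2 / R1)`
#'   (Triangular Chlorophyll Index)
#' * `NDVI  = (NIR1 - R2) / (NIR1 + R2)`
#' * `GNDVI = (NIR2 - G) / (NIR2 + G)`
#' * `MCARI = ((NIR1 - R2) - 0.2 (NIR1 - G)) * (NIR1 / R2)`
#' * `MSR   = (NIR1/R2 - 1) / (sqrt(NIR1/R2) + 1)` (Modified Simple Ratio)
#'
#' ExG, VIgreen and TCI use only visible bands (450-700 nm); NDVI, GNDVI,
#' MCARI and MSR incorporate a NIR band (>= 740 nm). For the ratio indices
#' a non-positive required band yields a missing value (never infinity);
#' the remaining indices are still computed. Missing band means propagate
#' to missing index values.
#'
#' MCARI is computed with the 740/700/530 nm band set as written above
#' (rather than the 700/670/550 nm set of the original formulation), and
#' TCI with the square-root red-edge/red ratio term; both choices follow
#' the band set of the six-filter camera this pipeline models.
#'
#' @param bands data.frame (or one-row list) with numeric columns `B`,
#'   `G`, `R1`, `R2`, `NIR1`, `NIR2`; extra columns are carried through.
#' @return `bands` with the seven index columns appended (vectorized over
#'   rows).
#' @examples
#' computeVIs(data.frame(B = .05, G = .1, R1 = .08, R2 = .1,
#'                       NIR1 = .6, NIR2 = .62))
#' @export
computeVIs <- function(bands) {
  b <- as.data.frame(bands)
  miss <- setdiff(BAND_NAMES, names(b))
  if (length(miss))
    stop("missing band columns: ", paste(miss, collapse = ", "))
  B <- b$B; G <- b$G; R1 <- b$R1; R2 <- b$R2
  NIR1 <- b$NIR1; NIR2 <- b$NIR2
  safe <- function(x, ok) ifelse(ok & is.finite(x), x, NA_real_)

  b$ExG <- 2 * G - R1 - B
  b$VIgreen <- safe((G - R1) / (G + R1), G > 0 & R1 > 0)
  b$TCI <- safe(1.2 * (R2 - G) - 1.5 * (R1 - G) * sqrt(R2 / R1),
                R1 > 0 & R2 > 0)
  b$NDVI <- safe((NIR1 - R2) / (NIR1 + R2), NIR1 > 0 & R2 > 0)
  b$GNDVI <- safe((NIR2 - G) / (NIR2 + G), NIR2 > 0 & G > 0)
  b$MCARI <- safe(((NIR1 - R2) - 0.2 * (NIR1 - G)) * (NIR1 / R2),
                  NIR1 > 0 & R2 > 0)
  b$MSR <- safe((NIR1 / R2 - 1) / (sqrt(NIR1 / R2) + 1),
                NIR1 > 0 & R2 > 0)
  b
}
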