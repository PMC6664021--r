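#' Canopy reflectance model for synthetic orthomosaics
#'
#' Parameterizes the synthetic imagery: soil, peak-green vegetation and
#' senescent-vegetation endmember spectra over the six bands (450, 530,
#' 670, 700, 740, 780 nm); a logistic canopy-cover rise over days after
#' sowing, scaled by the plot's biomass; a greenness scalar that rises
#' logistically, increases with the plot's sugar release and biomass, and
#' decays exponentially after anthesis end (senescence); per-pixel Gaussian
#' noise; and the spatial clumping of canopy within a plot.
#'
#' The vegetation spectrum of a plot at greenness g is the per-band linear
#' mix (1 - g) * senescent + g * green; its two NIR bands are then scaled
#' by a structural vigor factor `nirVigorBase + nirVigorGain * w`
#' increasing with the plot's biomass (near-infrared scattering grows with
#' canopy structure, largely independently of pigments). The endmember
#' values are synthetic calibration constants chosen so that NIR-based
#' indices trace a bell-shaped seasonal curve peaking near anthesis while
#' visible-based indices stay comparatively flat and rise after senescence
#' onset; they are not measured spectra and are fully overridable.
#'
#' @param soil,greenVeg,senescentVeg numeric(6) reflectance per band.
#' @param noiseSd per-pixel i.i.d. Gaussian noise sd (reflectance units).
#' @param coverBase,coverGain canopy-cover plateau is
#'   `coverBase + coverGain * w` with w the biomass scaled to `biomassRange`.
#' @param coverMidpoint,coverRate logistic midpoint (DAS) and rate (days)
#'   of the cover rise.
#' @param greenBase,greenSugarGain,greenBiomassGain greenness plateau is
#'   `greenBase + greenSugarGain * s + greenBiomassGain * w` (clamped to 1)
#'   with s the sugar release scaled to `sugarRange`.
#' @param greenupMidpoint,greenupRate logistic midpoint/rate of green-up.
#' @param senescenceScale e-folding time (days) of greenness decay after
#'   anthesis end.
#' @param greenFloor fraction of the greenness plateau retained after full
#'   senescence: straw from a vigorous, green canopy keeps a relatively
#'   higher residual greenness than straw from a weak one.
#' @param nirVigorBase,nirVigorGain NIR-band scaling is
#'   `nirVigorBase + nirVigorGain * w`; the sum must stay within \[0, 1\]
#'   after multiplication with the NIR endmembers.
#' @param biomassRange,sugarRange reference ranges used to scale biomass
#'   (kg/m2) and sugar release (ul/mg) to \[0, 1\].
#' @param clumpSigma Gaussian smoothing sd (pixels) of the random field
#'   that places canopy patches; each pixel is vegetation with marginal
#'   probability equal to the canopy cover.
#' @param minObjectSize canopy patches smaller than this (pixels) are
#'   removed from the ground truth (a plant occupies several pixels).
#' @return list of model parameters (class `ReflectanceModel`).
#' @export
reflectanceModel <- function(
    soil = c(B = 0.22, G = 0.22, R1 = 0.28, R2 = 0.27,
             NIR1 = 0.28, NIR2 = 0.29),
    greenVeg = c(B = 0.04, G = 0.10, R1 = 0.095, R2 = 0.08,
                 NIR1 = 0.48, NIR2 = 0.50),
    senescentVeg = c(B = 0.16, G = 0.40, R1 = 0.30, R2 = 0.36,
                     NIR1 = 0.38, NIR2 = 0.40),
    noiseSd = 0.01,
    coverBase = 0.50, coverGain = 0.45,
    coverMidpoint = 95, coverRate = 8,
    greenBase = 0.50, greenSugarGain = 0.25, greenBiomassGain = 0.15,
    greenupMidpoint = 105, greenupRate = 6,
    senescenceScale = 30, greenFloor = 0.35,
    nirVigorBase = 0.65, nirVigorGain = 0.35,
    biomassRange = c(0.2, 1.4), sugarRange = c(0.7, 1.4),
    clumpSigma = 4, minObjectSize = 4L) {
  for (sp in list(soil, greenVeg, senescentVeg))
    stopifnot(length(sp) == 6L, all(sp >= 0), all(sp <= 1))
  stopifnot(noiseSd >= 0, coverBase >= 0, coverBase + coverGain <= 1,
            coverRate > 0, greenupRate > 0, senescenceScale > 0,
            clumpSigma > 0, minObjectSize >= 1L,
            greenFloor >= 0, greenFloor <= 1)
  m <- list(soil = soil, greenVeg = greenVeg, senescentVeg = senescentVeg,
            noiseSd = noiseSd, coverBase = coverBase, coverGain = coverGain,
            coverMidpoint = coverMidpoint, coverRate = coverRate,
            greenBase = greenBase, greenSugarGain = greenSugarGain,
            greenBiomassGain = greenBiomassGain,
            greenupMidpoint = greenupMidpoint, greenupRate = greenupRate,
            senescenceScale = senescenceScale, greenFloor = greenFloor,
            nirVigorBase = nirVigorBase, nirVigorGain = nirVigorGain,
            biomassRange = biomassRange, sugarRange = sugarRange,
            clumpSigma = clumpSigma, minObjectSize = as.integer(minObjectSize))
  class(m) <- "ReflectanceModel"
  m
}

rescaleTo01 <- function(x, range) clamp01((x - range[1L]) / diff(range))

#' Canopy cover of a plot at a date
#'
#' Logistic rise over DAS with a plateau increasing in the plot's biomass;
#' monotone non-decreasing in biomass at every date.
#'
#' @param model a [reflectanceModel()].
#' @param das date, days after sowing.
#' @param biomass plot biomass, kg/m2.
#' @return cover in \[0, 1\].
#' @export
canopyCover <- function(model, das, biomass) {
  w <- rescaleTo01(biomass, model$biomassRange)
  cmax <- model$coverBase + model$coverGain * w
  clamp01(cmax * stats::plogis((das - model$coverMidpoint) / model$coverRate))
}

#' Greenness scalar of a plot at a date
#'
#' Logistic green-up to a plateau increasing in sugar release and biomass,
#' then exponential decay after the accession's anthesis end (senescence).
#'
#' @inheritParams canopyCover
#' @param sugarRelease plot sugar release, ul/mg.
#' @param anthesisEnd accession anthesis end, DAS.
#' @return greenness in \[0, 1\].
#' @export
greennessAt <- function(model, das, biomass, sugarRelease, anthesisEnd) {
  w <- rescaleTo01(biomass, model$biomassRange)
  s <- rescaleTo01(sugarRelease, model$sugarRange)
  gmax <- clamp01(model$greenBase + model$greenSugarGain * s +
                    model$greenBiomassGain * w)
  rise <- stats::plogis((das - model$greenupMidpoint) / model$greenupRate)
  sen <- ifelse(das > anthesisEnd,
                exp(-(das - anthesisEnd) / model$senescenceScale), 1)
  sen <- model$greenFloor + (1 - model$greenFloor) * sen
  clamp01(gmax * rise * sen)
}

#' Vegetation endmember spectrum at a given greenness and biomass
#'
#' Linear mix of the senescent and green endmembers at greenness `green`,
#' with the two NIR bands scaled by the biomass-dependent structural vigor
#' factor; clipped to \[0, 1\].
#'
#' @inheritParams canopyCover
#' @param green greenness scalar in \[0, 1\].
#' @return numeric(6) reflectance spectrum.
#' @export
vegetationSpectrum <- function(model, green, biomass) {
  spec <- (1 - green) * model$senescentVeg + green * model$greenVeg
  w <- rescaleTo01(biomass, model$biomassRange)
  spec[5:6] <- spec[5:6] * (model$nirVigorBase + model$nirVigorGain * w)
  clamp01(spec)
}

## Spatially clumped canopy map: threshold a Gaussian-smoothed random field
## at the cover quantile so each pixel is vegetation with marginal
## probability `cover`, then drop patches below the minimum object size.
canopyMap <- function(nr, nc, cover, clumpSigma, minObjectSize) {
  if (cover <= 0) return(matrix(FALSE, nr, nc))
  if (cover >= 1 - 1e-12) return(matrix(TRUE, nr, nc))
  field <- matrix(rnorm(nr * nc), nr, nc)
  field <- EBImage::gblur(field, sigma = clumpSigma)
  veg <- field > quantile(field, 1 - cover, names = FALSE)
  dropSmallObjects(veg, minObjectSize)
}

## Remove connected components smaller than minSize pixels.
dropSmallObjects <- function(mask, minSize) {
  if (minSize <= 1L || !any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minSize)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

## Pixel window of a rectangle under the pixel-centre-inside rule
## (half-open on the far edge so adjacent rectangles never share pixels).
pixelWindow <- function(x0, x1, y0, y1, origin, gsd, nr, nc) {
  centersIn <- function(a0, a1, o, n) {
    idx <- seq_len(n)
    ctr <- o + (idx - 0.5) * gsd
    idx[ctr >= a0 & ctr < a1]
  }
  list(rows = centersIn(y0, y1, origin[2L], nr),
       cols = centersIn(x0, x1, origin[1L], nc))
}

#' Render a synthetic six-band orthomosaic for one flight date
#'
#' Fills the trial extent with soil, draws each sown plot's canopy map
#' (pixels are vegetation with probability equal to the canopy cover at
#' that date, spatially clumped into plant-sized patches), colours
#' vegetation pixels with the plot's greenness-mixed spectrum, adds i.i.d.
#' Gaussian noise per pixel and band, and clips to \[0, 1\]. Per-plot
#' ground truth (canopy map, cover, greenness) is attached to the returned
#' raster's `truth` slot for validation against segmentation output.
#'
#' @param design a [TrialDesign-class].
#' @param phenotypes output of [generatePhenotypes()].
#' @param phenology output of [generatePhenology()].
#' @param das flight date, days after sowing (90-180).
#' @param model a [reflectanceModel()].
#' @param gsd ground sampling distance, metres per pixel (> 0).
#' @param seed integer seed; rendering for a date is reproducible from it.
#' @return a [MultiSpectralRaster-class].
#' @export
renderOrthomosaic <- function(design, phenotypes, phenology, das,
                              model = reflectanceModel(), gsd = 0.01, seed) {
  stopifnot(is(design, "TrialDesign"), inherits(model, "ReflectanceModel"))
  seed <- checkSeed(seed)
  if (gsd <= 0) stop("gsd must be positive")
  das <- as.integer(das)
  if (das < 90L || das > 180L)
    stop("das must lie within 90-180 days after sowing")
  p <- designPlots(design)
  g <- design@geometry
  width <- max(p$x1) + g$margin
  height <- max(p$y1) + g$margin
  nc <- ceiling(width / gsd)
  nr <- ceiling(height / gsd)
  origin <- c(0, 0)

  set.seed(substreamSeed(seed, "render", das))
  arr <- array(rep(model$soil, each = nr * nc), dim = c(nr, nc, 6L))

  sown <- p[!p$empty, , drop = FALSE]
  iPh <- match(sown$plotId, phenotypes$plotId)
  if (anyNA(iPh))
    stop("phenotypes missing for plots: ",
         paste(sown$plotId[is.na(iPh)], collapse = ", "))
  iAn <- match(sown$accessionId, phenology$accessionId)
  if (anyNA(iAn))
    stop("phenology missing for accessions: ",
         paste(unique(sown$accessionId[is.na(iAn)]), collapse = ", "))

  truth <- vector("list", nrow(sown))
  names(truth) <- sown$plotId
  for (k in seq_len(nrow(sown))) {
    win <- pixelWindow(sown$x0[k], sown$x1[k], sown$y0[k], sown$y1[k],
                       origin, gsd, nr, nc)
    if (!length(win$rows) || !length(win$cols)) next
    W <- phenotypes$biomass[iPh[k]]
    S <- phenotypes$sugarRelease[iPh[k]]
    cover <- canopyCover(model, das, W)
    green <- greennessAt(model, das, W, S, phenology$anthesisEnd[iAn[k]])
    veg <- canopyMap(length(win$rows), length(win$cols), cover,
                     model$clumpSigma, model$minObjectSize)
    spec <- vegetationSpectrum(model, green, W)
    for (b in seq_len(6L)) {
      sub <- arr[win$rows, win$cols, b]
      sub[veg] <- spec[b]
      arr[win$rows, win$cols, b] <- sub
    }
    truth[[k]] <- list(window = win, vegetation = veg,
                       cover = cover, greenness = green)
  }
  if (model$noiseSd > 0)
    arr <- arr + rnorm(length(arr), sd = model$noiseSd)
  arr <- clamp01(arr)
  msRaster(arr, das = das, pixelSize = gsd, origin = origin, truth = truth)
}

#' Construct a MultiSpectralRaster
#'
#' Pixel values are snapped to float32 precision (the on-disk sample
#' format) so that write/read round-trips are bitwise exact.
#'
#' @param data rows x cols x 6 reflectance array in \[0, 1\].
#' @param das acquisition date (DAS); NA if untagged.
#' @param pixelSize metres per pixel.
#' @param origin numeric(2) top-left corner, metres.
#' @param wavelengths band centres, nm.
#' @param truth optional per-plot ground-truth list.
#' @return a [MultiSpectralRaster-class].
#' @export
msRaster <- function(data, das = NA_integer_, pixelSize = 0.01,
                     origin = c(0, 0), wavelengths = BAND_WAVELENGTHS,
                     truth = list()) {
  new("MultiSpectralRaster", data = float32Snap(data),
      wavelengths = as.numeric(wavelengths),
      origin = as.numeric(origin), pixelSize = as.numeric(pixelSize),
      das = as.integer(das), truth = truth)
}
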