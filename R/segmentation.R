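#' Otsu threshold of a one-dimensional feature sample
#'
#' Bins the finite values into `nBins` equal-width bins over their range
#' and returns the inner bin edge that maximizes the between-class
#' variance w0 w1 (mu0 - mu1)^2 of the two classes the edge induces on the
#' sample (class means are taken over the raw values, not bin midpoints).
#' Ties between equally good cuts are broken toward the lower threshold.
#' Deterministic for fixed input and bin count.
#'
#' @param values numeric vector with at least two distinct finite values.
#' @param nBins number of histogram bins (>= 2).
#' @return the threshold (a bin edge); values >= threshold fall in the
#'   upper class.
#' @export
otsuThreshold <- function(values, nBins = 256L) {
  v <- values[is.finite(values)]
  if (length(unique(v)) < 2L)
    stop("degenerate input: need at least two distinct finite values",
         call. = FALSE)
  nBins <- as.integer(nBins)
  stopifnot(nBins >= 2L)
  edges <- seq(min(v), max(v), length.out = nBins + 1L)
  bin <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  cnt <- tabulate(bin, nBins)
  sm <- vapply(split(v, factor(bin, levels = seq_len(nBins))), sum, 0)
  n <- length(v); total <- sum(v)
  cumN <- cumsum(cnt)[-nBins]       # counts below each inner edge
  cumS <- cumsum(sm)[-nBins]
  w0 <- cumN / n
  w1 <- 1 - w0
  mu0 <- ifelse(cumN > 0, cumS / cumN, 0)
  mu1 <- ifelse(cumN < n, (total - cumS) / (n - cumN), 0)
  bc <- w0 * w1 * (mu0 - mu1)^2
  edges[which.max(bc) + 1L]         # which.max takes the first (lowest) tie
}

## Per-pixel segmentation feature over a band array window.
pixelFeature <- function(bands, feature = c("exg", "ndvi")) {
  feature <- match.arg(feature)
  if (feature == "exg")
    2 * bands[, , 2L] - bands[, , 3L] - bands[, , 1L]
  else
    (bands[, , 5L] - bands[, , 4L]) / (bands[, , 5L] + bands[, , 4L])
}

#' Classify the vegetation fraction of one trial plot
#'
#' Computes a per-pixel greenness feature (ExG by default, NDVI
#' selectable) inside the plot's pixel window, splits it with
#' [otsuThreshold()], labels the class with the higher mean feature value
#' as vegetation, groups vegetation pixels into connected components and
#' drops objects below `minObject` pixels (object-based cleanup). The plot
#' is flagged low-cover, with an all-background mask, when the feature is
#' degenerate (all values identical), when the between-class mean
#' separation falls below `minSeparation`, or when the vegetation fraction
#' falls below `minFraction`.
#'
#' @param raster a [MultiSpectralRaster-class].
#' @param plot one row of [designPlots()] (or any list with `plotId`,
#'   `x0`, `x1`, `y0`, `y1`).
#' @param feature `"exg"` or `"ndvi"`.
#' @param nBins histogram bins for the threshold.
#' @param minFraction vegetation-fraction floor.
#' @param minObject minimum connected-object size, pixels.
#' @param minSeparation between-class mean-separation floor (feature
#'   units); guards against splitting pure soil noise.
#' @return a [VegetationMask-class].
#' @export
classifyPlotVegetation <- function(raster, plot, feature = c("exg", "ndvi"),
                                   nBins = 256L, minFraction = 0.005,
                                   minObject = 4L, minSeparation = 0.08) {
  stopifnot(is(raster, "MultiSpectralRaster"))
  feature <- match.arg(feature)
  d <- dim(raster@data)
  win <- pixelWindow(plot$x0, plot$x1, plot$y0, plot$y1,
                     raster@origin, raster@pixelSize, d[1L], d[2L])
  if (!length(win$rows) || !length(win$cols))
    stop("plot ", plot$plotId, " does not intersect the raster",
         call. = FALSE)
  bands <- raster@data[win$rows, win$cols, , drop = FALSE]
  feat <- pixelFeature(bands, feature)
  valid <- is.finite(feat)
  lowMask <- function(thr = NA_real_) new("VegetationMask",
    plotId = as.character(plot$plotId), das = raster@das,
    mask = matrix(FALSE, length(win$rows), length(win$cols)),
    threshold = thr, fraction = 0, lowCover = TRUE, window = win)
  vals <- feat[valid]
  if (length(unique(vals)) < 2L) return(lowMask())
  thr <- otsuThreshold(vals, nBins)
  hi <- vals >= thr
  if (!any(hi) || all(hi)) return(lowMask(thr))
  sep <- abs(mean(vals[hi]) - mean(vals[!hi]))
  if (sep < minSeparation) return(lowMask(thr))
  mask <- feat >= thr & valid     # higher-mean class = vegetation
  mask <- dropSmallObjects(mask, minObject)
  fraction <- sum(mask) / sum(valid)
  if (fraction < minFraction) return(lowMask(thr))
  new("VegetationMask", plotId = as.character(plot$plotId),
      das = raster@das, mask = mask, threshold = thr,
      fraction = fraction, lowCover = FALSE, window = win)
}

#' Extract vegetation-only band means for one plot
#'
#' Arithmetic per-band mean over the vegetation pixels of the mask; NaN
#' pixels are excluded from both numerator and count. With zero vegetation
#' pixels the band means are missing (propagated, never zero-filled).
#'
#' @param raster a [MultiSpectralRaster-class].
#' @param mask a [VegetationMask-class] aligned to the raster.
#' @return one-row data.frame: `plotId`, `das`, the six band means
#'   (`B`, `G`, `R1`, `R2`, `NIR1`, `NIR2`), `vegFraction`, `nPixels`
#'   (vegetation pixels contributing), `lowCover`.
#' @export
extractPlotSpectra <- function(raster, mask) {
  stopifnot(is(raster, "MultiSpectralRaster"), is(mask, "VegetationMask"))
  win <- mask@window
  m <- mask@mask
  means <- rep(NA_real_, 6L)
  nPix <- 0L
  if (any(m)) {
    for (b in seq_len(6L)) {
      px <- raster@data[win$rows, win$cols, b][m]
      px <- px[is.finite(px)]
      if (length(px)) means[b] <- mean(px)
    }
    px1 <- raster@data[win$rows, win$cols, 1L][m]
    nPix <- sum(is.finite(px1))
  }
  out <- data.frame(plotId = mask@plotId, das = mask@das,
                    t(setNames(means, BAND_NAMES)),
                    vegFraction = mask@fraction, nPixels = nPix,
                    lowCover = mask@lowCover, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Segment every plot of a design on one raster
#'
#' Runs [classifyPlotVegetation()] and [extractPlotSpectra()] over all
#' sown plots (plots are independent; processing order does not affect any
#' output). Empty plot positions and plots falling outside the raster are
#' emitted with missing spectral fields.
#'
#' @inheritParams classifyPlotVegetation
#' @param design a [TrialDesign-class].
#' @param ... passed to [classifyPlotVegetation()].
#' @return data.frame with one row per plot position of the design.
#' @export
segmentPlots <- function(raster, design, feature = c("exg", "ndvi"), ...) {
  stopifnot(is(design, "TrialDesign"))
  feature <- match.arg(feature)
  p <- designPlots(design)
  rows <- lapply(seq_len(nrow(p)), function(i) {
    na <- data.frame(plotId = p$plotId[i], das = raster@das,
                     t(setNames(rep(NA_real_, 6L), BAND_NAMES)),
                     vegFraction = NA_real_, nPixels = 0L, lowCover = NA,
                     stringsAsFactors = FALSE)
    if (p$empty[i]) return(na)
    msk <- tryCatch(
      classifyPlotVegetation(raster, p[i, ], feature = feature, ...),
      error = function(e) NULL)
    if (is.null(msk)) return(na)    # outside the raster: missing fields
    extractPlotSpectra(raster, msk)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
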