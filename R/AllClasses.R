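#' TrialDesign: a replicated field-trial layout
#'
#' Holds the plot polygons and metadata of a randomized complete block
#' design (RCBD): one row per plot position, with the accession sown there
#' (or an empty marker), its species, block, row and order in the row, and
#' the plot rectangle in planar metres. Coordinates are local: origin at the
#' raster top-left, x increasing east, y increasing south.
#'
#' @slot plots data.frame with columns `plotId`, `accessionId`, `species`,
#'   `block`, `row`, `orderInRow`, `x0`, `y0`, `x1`, `y1`, `empty`.
#' @slot geometry list of layout parameters (see [trialGeometry()]).
#'
#' @seealso [generateTrialDesign()]
#' @export
setClass("TrialDesign",
  representation(plots = "data.frame", geometry = "list"))

setValidity("TrialDesign", function(object) {
  p <- object@plots
  need <- c("plotId", "accessionId", "species", "block", "row",
            "orderInRow", "x0", "y0", "x1", "y1", "empty")
  if (!all(need %in% names(p)))
    return(paste("plots is missing columns:",
                 paste(setdiff(need, names(p)), collapse = ", ")))
  if (anyDuplicated(p$plotId))
    return("plotId values must be unique")
  occ <- p[!p$empty, ]
  tab <- table(occ$accessionId, occ$block)
  if (nrow(tab) && any(tab != 1L))
    return("every accession must appear exactly once per block")
  if (any(p$x1 <= p$x0) || any(p$y1 <= p$y0))
    return("plot rectangles must have positive extent")
  ## axis-aligned rectangles must not overlap
  if (nrow(p) > 1L) {
    o <- order(p$y0, p$x0)
    q <- p[o, ]
    for (i in seq_len(nrow(q) - 1L)) {
      j <- i + 1L
      while (j <= nrow(q) && q$y0[j] < q$y1[i]) {
        if (q$x0[j] < q$x1[i] && q$x1[j] > q$x0[i] &&
            q$y0[j] < q$y1[i] && q$y1[j] > q$y0[i])
          return("plot polygons overlap")
        j <- j + 1L
      }
    }
  }
  TRUE
})

#' MultiSpectralRaster: one six-band reflectance orthomosaic
#'
#' A single flight-date image: a rows x cols x 6 array of surface
#' reflectance in \[0, 1\] (stored at float32 precision, matching the
#' on-disk sample format), with a planar geotransform (top-left origin and
#' square pixel size in metres), the band centre wavelengths in nm, and the
#' acquisition date in days after sowing (DAS). NaN pixels are allowed and
#' are treated as masked by all downstream statistics.
#'
#' @slot data numeric array, rows x cols x 6.
#' @slot wavelengths numeric(6), strictly increasing, nm.
#' @slot origin numeric(2), x/y of the top-left corner in metres.
#' @slot pixelSize numeric(1), metres per pixel (> 0).
#' @slot das integer(1), days after sowing (NA if untagged).
#' @slot truth list; optional per-plot synthetic ground truth attached by
#'   [renderOrthomosaic()] (never serialized).
#'
#' @export
setClass("MultiSpectralRaster",
  representation(data = "array", wavelengths = "numeric", origin = "numeric",
                 pixelSize = "numeric", das = "integer", truth = "list"))

setValidity("MultiSpectralRaster", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L || d[3L] != 6L)
    return(sprintf("raster must have 6 bands, got %s",
                   if (length(d) == 3L) d[3L] else "a non-3D array"))
  if (length(object@wavelengths) != 6L ||
      any(diff(object@wavelengths) <= 0))
    return("wavelengths must be 6 strictly increasing values")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    return("pixelSize must be a single positive number")
  fin <- object@data[is.finite(object@data)]
  if (length(fin) && (min(fin) < 0 || max(fin) > 1))
    return("finite reflectance values must lie in [0, 1]")
  TRUE
})

#' VegetationMask: per-plot vegetation classification for one date
#'
#' Boolean pixel mask over one plot's pixel window (TRUE = vegetation),
#' together with the Otsu threshold used, the vegetation fraction among
#' valid pixels, and a low-cover flag set when the between-class separation
#' or the vegetation fraction fell below its floor (the mask is then all
#' background).
#'
#' @slot plotId character(1).
#' @slot das integer(1).
#' @slot mask logical matrix (plot pixel window).
#' @slot threshold numeric(1); NA when thresholding was degenerate.
#' @slot fraction numeric(1) in \[0, 1\].
#' @slot lowCover logical(1).
#' @slot window list with integer vectors `rows` and `cols` (raster indices).
#'
#' @export
setClass("VegetationMask",
  representation(plotId = "character", das = "integer", mask = "matrix",
                 threshold = "numeric", fraction = "numeric",
                 lowCover = "logical", window = "list"))

setValidity("VegetationMask", function(object) {
  w <- object@window
  if (!all(c("rows", "cols") %in% names(w)))
    return("window must have 'rows' and 'cols'")
  if (!identical(dim(object@mask),
                 c(length(w$rows), length(w$cols))))
    return("mask shape must equal the plot pixel window")
  if (!is.na(object@fraction) &&
      (object@fraction < 0 || object@fraction > 1))
    return("fraction must lie in [0, 1]")
  TRUE
})

setMethod("show", "TrialDesign", function(object) {
  p <- object@plots
  cat(sprintf(
    "TrialDesign: %d plot positions (%d sown, %d empty), %d blocks, %d accessions\n",
    nrow(p), sum(!p$empty), sum(p$empty), length(unique(p$block)),
    length(unique(p$accessionId[!p$empty]))))
  cat(sprintf("  extent: %.2f x %.2f m\n", max(p$x1), max(p$y1)))
})

setMethod("show", "MultiSpectralRaster", function(object) {
  d <- dim(object@data)
  cat(sprintf("MultiSpectralRaster: %d x %d px, 6 bands (%s nm), %.4g m/px, DAS %s\n",
              d[1L], d[2L], paste(object@wavelengths, collapse = "/"),
              object@pixelSize,
              ifelse(is.na(object@das), "untagged", object@das)))
})

setMethod("show", "VegetationMask", function(object) {
  cat(sprintf("VegetationMask: plot %s, DAS %s, fraction %.3f%s\n",
              object@plotId, object@das, object@fraction,
              if (object@lowCover) " (low cover)" else ""))
})
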