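## Raster, vector and table I/O.
##
## Rasters are written as single-strip uncompressed GeoTIFFs with six
## interleaved float32 samples per pixel. The geotransform goes into the
## standard ModelPixelScale / ModelTiepoint tags and, together with the
## band wavelengths and the DAS acquisition tag, into a JSON document in
## the ImageDescription tag; reading goes through tiff::readTIFF, which
## understands IEEE-float samples and returns the description.

tiffEntry <- function(con, tag, type, count, value) {
  writeBin(as.integer(tag), con, size = 2L, endian = "little")
  writeBin(as.integer(type), con, size = 2L, endian = "little")
  writeBin(as.integer(count), con, size = 4L, endian = "little")
  writeBin(as.integer(value), con, size = 4L, endian = "little")
}

#' Write a six-band raster as a float32 GeoTIFF
#'
#' Lossless for the in-memory data model: pixel values are stored as IEEE
#' float32 (the precision at which [MultiSpectralRaster-class] holds them),
#' so `readRaster(writeRaster(x))` reproduces the array bitwise. The
#' geotransform, band wavelengths and DAS tag are stored both in GeoTIFF
#' tags (pixel scale, tiepoint) and as JSON in the ImageDescription tag.
#'
#' @param raster a [MultiSpectralRaster-class].
#' @param path output file path (.tif).
#' @return `path`, invisibly.
#' @export
writeRaster <- function(raster, path) {
  stopifnot(is(raster, "MultiSpectralRaster"))
  d <- dim(raster@data)
  nr <- d[1L]; nc <- d[2L]
  ## interleave samples: pixel-major, band-minor, row-major pixels
  px <- aperm(raster@data, c(3L, 2L, 1L))
  meta <- jsonlite::toJSON(list(
    das = raster@das, wavelengths_nm = raster@wavelengths,
    origin_m = raster@origin, pixel_size_m = raster@pixelSize,
    units = "reflectance"), auto_unbox = TRUE, digits = NA, na = "null")
  desc <- c(charToRaw(as.character(meta)), as.raw(0L))
  descLen <- length(desc)                  # count includes one terminator
  if (descLen %% 2L) desc <- c(desc, as.raw(0L))  # alignment pad, uncounted

  dataOff <- 8L
  dataLen <- nr * nc * 6L * 4L
  descOff <- dataOff + dataLen
  bpsOff <- descOff + length(desc)        # 6 shorts
  sfOff <- bpsOff + 12L                   # 6 shorts
  exsOff <- sfOff + 12L                   # 5 shorts + pad
  scaleOff <- exsOff + 12L                # 3 doubles
  tieOff <- scaleOff + 24L                # 6 doubles
  ifdOff <- tieOff + 48L

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(as.integer(ifdOff), con, size = 4L, endian = "little")
  writeBin(as.double(px), con, size = 4L, endian = "little")
  writeBin(desc, con)
  writeBin(rep(32L, 6L), con, size = 2L, endian = "little")
  writeBin(rep(3L, 6L), con, size = 2L, endian = "little")   # IEEE float
  writeBin(c(rep(0L, 5L), 0L), con, size = 2L, endian = "little")
  writeBin(c(raster@pixelSize, raster@pixelSize, 0), con,
           size = 8L, endian = "little")
  writeBin(c(0, 0, 0, raster@origin[1L], raster@origin[2L], 0), con,
           size = 8L, endian = "little")

  writeBin(14L, con, size = 2L, endian = "little")  # entry count
  tiffEntry(con, 256, 3, 1, nc)                      # ImageWidth
  tiffEntry(con, 257, 3, 1, nr)                      # ImageLength
  tiffEntry(con, 258, 3, 6, bpsOff)                  # BitsPerSample
  tiffEntry(con, 259, 3, 1, 1)                       # no compression
  tiffEntry(con, 262, 3, 1, 1)                       # min-is-black
  tiffEntry(con, 270, 2, descLen, descOff)           # ImageDescription
  tiffEntry(con, 273, 4, 1, dataOff)                 # StripOffsets
  tiffEntry(con, 277, 3, 1, 6)                       # SamplesPerPixel
  tiffEntry(con, 278, 3, 1, nr)                      # RowsPerStrip
  tiffEntry(con, 279, 4, 1, dataLen)                 # StripByteCounts
  tiffEntry(con, 338, 3, 5, exsOff)                  # ExtraSamples (5 bands)
  tiffEntry(con, 339, 3, 6, sfOff)                   # SampleFormat
  tiffEntry(con, 33550, 12, 3, scaleOff)             # ModelPixelScale
  tiffEntry(con, 33922, 12, 6, tieOff)               # ModelTiepoint
  writeBin(0L, con, size = 4L, endian = "little")    # next IFD
  invisible(path)
}

#' Read a six-band raster
#'
#' Rejects files whose sample count differs from six (naming the count).
#' A missing DAS tag raises a warning and leaves the date NA; downstream
#' temporal aggregation then requires it to be set. Reading never rescales:
#' reflectance stays in \[0, 1\] and NaN pixels are preserved as masked.
#'
#' @param path a GeoTIFF written by [writeRaster()] (any float TIFF with
#'   six samples per pixel is accepted; metadata defaults are applied when
#'   the JSON description is absent).
#' @return a [MultiSpectralRaster-class].
#' @export
readRaster <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tiff::readTIFF(path, info = TRUE, convert = FALSE)
  d <- dim(img)
  nbands <- if (length(d) == 3L) d[3L] else 1L
  if (nbands != 6L)
    stop(sprintf("raster has %d band(s); 6 are required", nbands))
  meta <- attr(img, "description")
  parsed <- NULL
  if (!is.null(meta))
    parsed <- tryCatch(jsonlite::fromJSON(meta), error = function(e) NULL)
  if (is.null(parsed) || is.null(parsed$das) || is.na(parsed$das)) {
    warning("raster has no DAS acquisition tag; set it before temporal aggregation")
    das <- NA_integer_
  } else das <- as.integer(parsed$das)
  msRaster(unclass(img), das = das,
           pixelSize = parsed$pixel_size_m %||% 1,
           origin = parsed$origin_m %||% c(0, 0),
           wavelengths = parsed$wavelengths_nm %||% BAND_WAVELENGTHS)
}

#' Write plot polygons as GeoJSON
#'
#' One Polygon feature per plot position with properties `plot_id`,
#' `accession_id`, `species`, `block`, `row`, `order_in_row`, `empty`.
#' Coordinates are local planar metres (top-left origin).
#'
#' @param design a [TrialDesign-class].
#' @param path output file (.geojson).
#' @return `path`, invisibly.
#' @export
writePlotPolygons <- function(design, path) {
  p <- designPlots(design)
  feats <- lapply(seq_len(nrow(p)), function(i) {
    ring <- list(c(p$x0[i], p$y0[i]), c(p$x1[i], p$y0[i]),
                 c(p$x1[i], p$y1[i]), c(p$x0[i], p$y1[i]),
                 c(p$x0[i], p$y0[i]))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = list(plot_id = p$plotId[i],
                           accession_id = p$accessionId[i],
                           species = p$species[i], block = p$block[i],
                           row = p$row[i], order_in_row = p$orderInRow[i],
                           empty = p$empty[i]))
  })
  json <- jsonlite::toJSON(list(type = "FeatureCollection", features = feats),
                           auto_unbox = TRUE, digits = I(17), na = "null",
                           null = "null")
  writeLines(as.character(json), path)
  invisible(path)
}

#' Read plot polygons from GeoJSON
#'
#' Expects axis-aligned rectangular Polygon features with the properties
#' written by [writePlotPolygons()]. Duplicate plot IDs are rejected.
#'
#' @param path a GeoJSON file.
#' @return a [TrialDesign-class] (geometry slot holds only the bounding
#'   extent; layout parameters are not recoverable from polygons).
#' @export
readPlotPolygons <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection")
  rows <- lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1L]]
    xs <- vapply(ring, function(v) as.numeric(v[[1L]]), 0)
    ys <- vapply(ring, function(v) as.numeric(v[[2L]]), 0)
    pr <- f$properties
    data.frame(plotId = pr$plot_id,
               accessionId = pr$accession_id %||% NA_character_,
               species = pr$species %||% NA_character_,
               block = as.integer(pr$block), row = as.integer(pr$row),
               orderInRow = as.integer(pr$order_in_row),
               x0 = min(xs), y0 = min(ys), x1 = max(xs), y1 = max(ys),
               empty = isTRUE(pr$empty), stringsAsFactors = FALSE)
  })
  plots <- do.call(rbind, rows)
  if (anyDuplicated(plots$plotId))
    stop("duplicate plot_id in ", path, ": ",
         paste(unique(plots$plotId[duplicated(plots$plotId)]),
               collapse = ", "))
  new("TrialDesign", plots = plots,
      geometry = list(margin = min(c(plots$x0, plots$y0))))
}

#' Read/write the tabular pipeline contracts as CSV
#'
#' Comma-separated, UTF-8, header row, "." decimal; missing values are
#' empty fields. `writePlotTable()` writes the per plot x date export
#' (central coordinates, position metadata, band means, vegetation
#' fraction and index values); the phenotype and phenology tables use the
#' column names of [generatePhenotypes()] and [generatePhenology()].
#'
#' @param x data.frame to write.
#' @param path CSV file path.
#' @return the data.frame (readers) or `path` invisibly (writers).
#' @name tableIO
NULL

#' @rdname tableIO
#' @export
writePlotTable <- function(x, path) {
  write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname tableIO
#' @export
readPlotTable <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Build the per-date plot export table
#'
#' One row per plot position (empty plots included, with missing spectral
#' fields) carrying the plot's central coordinates, its position in the
#' design (block, row, order in row), the vegetation-pixel band means and
#' the vegetation fraction from segmentation, and the seven index values.
#'
#' @param design a [TrialDesign-class].
#' @param spectra per-plot spectral records from [segmentPlots()] (already
#'   including VI columns if [computeVIs()] was applied).
#' @return data.frame, one row per plot of the design.
#' @export
buildPlotTable <- function(design, spectra) {
  p <- designPlots(design)
  base <- data.frame(plotId = p$plotId, accessionId = p$accessionId,
                     species = p$species, block = p$block, row = p$row,
                     orderInRow = p$orderInRow,
                     centerX = (p$x0 + p$x1) / 2, centerY = (p$y0 + p$y1) / 2,
                     empty = p$empty, stringsAsFactors = FALSE)
  merge(base, spectra[, setdiff(names(spectra),
                                c("accessionId", "species", "block")),
                      drop = FALSE],
        by = "plotId", all.x = TRUE, sort = FALSE)
}
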