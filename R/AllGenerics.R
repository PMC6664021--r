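#' Accessors for the core classes
#'
#' `designPlots()` returns the plot table of a [TrialDesign-class];
#' `rasterData()` the pixel array of a [MultiSpectralRaster-class];
#' `rasterDate()` its acquisition date (DAS); `bandWavelengths()` its band
#' centres in nm; `maskPixels()` the logical matrix of a
#' [VegetationMask-class]; `vegetationFraction()` its vegetation fraction.
#'
#' @param x the object.
#' @return See the per-accessor description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("designPlots", function(x) standardGeneric("designPlots"))
#' @rdname accessors
#' @export
setMethod("designPlots", "TrialDesign", function(x) x@plots)

#' @rdname accessors
#' @export
setGeneric("rasterData", function(x) standardGeneric("rasterData"))
#' @rdname accessors
#' @export
setMethod("rasterData", "MultiSpectralRaster", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("rasterDate", function(x) standardGeneric("rasterDate"))
#' @rdname accessors
#' @export
setMethod("rasterDate", "MultiSpectralRaster", function(x) x@das)

#' @rdname accessors
#' @export
setGeneric("bandWavelengths", function(x) standardGeneric("bandWavelengths"))
#' @rdname accessors
#' @export
setMethod("bandWavelengths", "MultiSpectralRaster", function(x) x@wavelengths)

#' @rdname accessors
#' @export
setGeneric("maskPixels", function(x) standardGeneric("maskPixels"))
#' @rdname accessors
#' @export
setMethod("maskPixels", "VegetationMask", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("vegetationFraction",
           function(x) standardGeneric("vegetationFraction"))
#' @rdname accessors
#' @export
setMethod("vegetationFraction", "VegetationMask", function(x) x@fraction)
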