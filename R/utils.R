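## Internal helpers shared across modules.

#' @importFrom methods new validObject is
#' @importFrom stats rnorm runif qnorm pnorm quantile cor lm coef residuals
#'   aov TukeyHSD setNames
#' @importFrom utils read.csv write.csv packageVersion
NULL

BAND_NAMES <- c("B", "G", "R1", "R2", "NIR1", "NIR2")
BAND_WAVELENGTHS <- c(450, 530, 670, 700, 740, 780)
VI_NAMES <- c("ExG", "VIgreen", "TCI", "NDVI", "GNDVI", "MCARI", "MSR")
FLIGHT_DATES <- c(94L, 104L, 119L, 130L, 143L, 161L, 175L)

## Deterministic substream seeds: one master seed fans out to independent
## stage seeds so design / phenotypes / phenology / per-date rendering are
## individually reproducible. Arithmetic in double to dodge 32-bit overflow.
substreamSeed <- function(seed, stage, index = 0L) {
  offsets <- c(design = 11, phenotypes = 23, phenology = 37,
               render = 101, field = 53, pipeline = 7)
  if (!stage %in% names(offsets))
    stop("unknown substream stage: ", stage)
  v <- (as.double(seed) %% 2147483629) * 48271 +
    offsets[[stage]] * 2654435 + as.double(index) * 9973
  as.integer(v %% 2147483629)
}

checkSeed <- function(seed) {
  if (missing(seed) || is.null(seed) || !is.numeric(seed) ||
      length(seed) != 1L || is.na(seed))
    stop("an explicit integer 'seed' is required")
  as.integer(seed)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

## Snap doubles to the nearest IEEE single-precision value. Reflectance is
## stored at float32 precision (the on-disk raster sample format), so
## write-then-read round-trips are bitwise exact.
float32Snap <- function(x) {
  d <- dim(x)
  y <- readBin(writeBin(as.double(x), raw(), size = 4L),
               "double", n = length(x), size = 4L)
  dim(y) <- d
  y
}

## Tiny FNV-1a hash over a character scalar; used only to fingerprint run
## configurations in manifests.
fnv1a <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (as.double(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
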