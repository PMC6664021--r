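## Shared fixtures: small desk-scale trials built in code at test time.

smallGeometry <- function() trialGeometry(plotsPerRow = 3L, margin = 0.5)

smallDesign <- function(seed = 11, nAccessions = 6L, nBlocks = 2L,
                        plotsPerBlock = 8L) {
  generateTrialDesign(nAccessions, nBlocks, plotsPerBlock,
                      geometry = smallGeometry(), seed = seed)
}

## A complete small scene: design, phenotypes, phenology and a renderer.
smallScene <- function(seed = 11, model = reflectanceModel(), ...) {
  design <- smallDesign(seed = seed, ...)
  phen <- generatePhenotypes(design, seed = seed)
  phl <- generatePhenology(design, seed = seed)
  list(design = design, phen = phen, phl = phl, model = model,
       render = function(das, gsd = 0.01, m = model)
         renderOrthomosaic(design, phen, phl, das, model = m,
                           gsd = gsd, seed = seed))
}

sownPlots <- function(design) {
  p <- designPlots(design)
  p[!p$empty, , drop = FALSE]
}

## Brute-force Otsu oracle: explicit loop over every inner bin edge,
## classifying the raw values and computing w0 w1 (mu0 - mu1)^2 directly.
otsuOracle <- function(v, nBins) {
  edges <- seq(min(v), max(v), length.out = nBins + 1L)
  inner <- edges[-c(1L, nBins + 1L)]
  best <- -Inf
  bestEdge <- NA_real_
  bin <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  for (k in seq_along(inner)) {
    lo <- v[bin <= k]
    hi <- v[bin > k]
    if (!length(lo) || !length(hi)) bc <- 0
    else {
      w0 <- length(lo) / length(v)
      bc <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    }
    if (bc > best) {              # strict improvement: ties keep lower edge
      best <- bc
      bestEdge <- inner[k]
    }
  }
  bestEdge
}
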