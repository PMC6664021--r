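#' Species-level phenotype distribution parameters
#'
#' Per-species means of total biomass dry weight (kg/m2) and enzymatic
#' sugar release (ul glucose per mg straw) for the four cereal species of
#' the plant-material fixture, with between-accession standard deviations
#' chosen so that simulated trials span the ranges observed in comparable
#' field experiments (biomass roughly 0.26-1.40 kg/m2, sugar roughly
#' 0.77-1.36 ul/mg).
#'
#' @param meanW,meanS named per-species means (kg/m2, ul/mg).
#' @param sdW,sdS between-accession standard deviations (recycled across
#'   species if scalar).
#' @return data.frame with columns `species`, `meanW`, `sdW`, `meanS`, `sdS`.
#' @export
speciesParams <- function(meanW = c("T. aestivum" = 0.67, "T. durum" = 0.83,
                                    "H. vulgare" = 0.71,
                                    "x Triticosecale" = 0.52),
                          sdW = 0.18,
                          meanS = c("T. aestivum" = 0.98, "T. durum" = 0.98,
                                    "H. vulgare" = 1.16,
                                    "x Triticosecale" = 0.94),
                          sdS = 0.12) {
  stopifnot(identical(names(meanW), names(meanS)))
  if (any(sdW < 0) || any(sdS < 0))
    stop("standard deviations must be non-negative")
  data.frame(species = names(meanW), meanW = unname(meanW),
             sdW = rep_len(unname(sdW), length(meanW)),
             meanS = unname(meanS),
             sdS = rep_len(unname(sdS), length(meanS)),
             stringsAsFactors = FALSE)
}

## truncated-at-zero normal draw; exact via inverse CDF, degenerate sd -> mean
rtnorm0 <- function(n, mean, sd) {
  out <- numeric(n)
  pos <- sd > 0
  if (any(pos)) {
    lo <- pnorm(0, mean[pos], sd[pos])
    out[pos] <- qnorm(runif(sum(pos), lo, 1), mean[pos], sd[pos])
  }
  out[!pos] <- pmax(mean[!pos], 0)
  out
}

#' Generate ground-truth plot phenotypes
#'
#' Draws, per accession, a biomass and a sugar-release effect from
#' truncated-at-zero normals with the species mean/sd, shares that effect
#' across the accession's plots in all blocks, adds independent block-level
#' noise per plot, and computes theoretical ethanol yield from biomass and
#' sugar release exactly via [theoreticalEthanolYield()].
#'
#' @param design a [TrialDesign-class].
#' @param params species parameters from [speciesParams()].
#' @param seed integer seed; accession effects are reproducible from it.
#' @param blockSdW,blockSdS plot-level (block) noise sd for biomass and
#'   sugar release.
#' @return data.frame with one row per sown plot: `plotId`, `accessionId`,
#'   `species`, `block`, `biomass` (kg/m2), `sugarRelease` (ul/mg),
#'   `ethanolYield` (m3/ha).
#' @export
generatePhenotypes <- function(design, params = speciesParams(), seed,
                               blockSdW = 0.05, blockSdS = 0.04) {
  stopifnot(is(design, "TrialDesign"))
  seed <- checkSeed(seed)
  if (any(params$sdW < 0) || any(params$sdS < 0) ||
      blockSdW < 0 || blockSdS < 0)
    stop("standard deviations must be non-negative")
  p <- designPlots(design)
  p <- p[!p$empty, , drop = FALSE]
  accs <- unique(p[, c("accessionId", "species")])
  miss <- setdiff(accs$species, params$species)
  if (length(miss))
    stop("no species parameters for: ", paste(miss, collapse = ", "))
  i <- match(accs$species, params$species)

  set.seed(substreamSeed(seed, "phenotypes"))
  accs$W <- rtnorm0(nrow(accs), params$meanW[i], params$sdW[i])
  accs$S <- rtnorm0(nrow(accs), params$meanS[i], params$sdS[i])
  j <- match(p$accessionId, accs$accessionId)
  W <- rtnorm0(nrow(p), accs$W[j], rep(blockSdW, nrow(p)))
  S <- rtnorm0(nrow(p), accs$S[j], rep(blockSdS, nrow(p)))
  data.frame(plotId = p$plotId, accessionId = p$accessionId,
             species = p$species, block = p$block,
             biomass = W, sugarRelease = S,
             ethanolYield = theoreticalEthanolYield(S, W),
             stringsAsFactors = FALSE)
}

#' Generate accession-level anthesis phenology
#'
#' Anthesis (flowering) start dates are drawn uniformly on integer days
#' after sowing (DAS) within `startRange`, and window lengths uniformly
#' within `windowRange`; the end date is capped at 175 DAS. One record per
#' accession, reproducible from the seed.
#'
#' @param design a [TrialDesign-class].
#' @param seed integer seed.
#' @param startRange inclusive integer bounds for anthesis start, DAS.
#' @param windowRange inclusive integer bounds for window length, days.
#' @return data.frame with columns `accessionId`, `anthesisStart`,
#'   `anthesisEnd`.
#' @export
generatePhenology <- function(design, seed, startRange = c(110L, 160L),
                              windowRange = c(10L, 20L)) {
  stopifnot(is(design, "TrialDesign"),
            length(startRange) == 2L, length(windowRange) == 2L,
            startRange[1L] <= startRange[2L],
            windowRange[1L] <= windowRange[2L], windowRange[1L] >= 1L)
  seed <- checkSeed(seed)
  p <- designPlots(design)
  accs <- unique(p$accessionId[!p$empty])
  set.seed(substreamSeed(seed, "phenology"))
  runifInt <- function(n, lo, hi)
    lo + floor(runif(n) * (hi - lo + 1L)) # inclusive integer uniform
  start <- pmin(runifInt(length(accs), startRange[1L], startRange[2L]),
                startRange[2L])
  len <- pmin(runifInt(length(accs), windowRange[1L], windowRange[2L]),
              windowRange[2L])
  data.frame(accessionId = accs,
             anthesisStart = as.integer(start),
             anthesisEnd = as.integer(pmin(start + len, 175L)),
             stringsAsFactors = FALSE)
}
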