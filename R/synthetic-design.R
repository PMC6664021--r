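#' Layout geometry for a trial design
#'
#' Desk-scale defaults: 0.6 m x 0.45 m plots with 0.3 m inter-plot and
#' 0.5 m inter-row spacing, 8 plots per row, and a 1 m soil margin around
#' the trial, so that a full multi-date series renders in seconds at the
#' default ground sampling distance of 0.01 m/pixel.
#'
#' @param plotWidth,plotHeight plot rectangle size in metres.
#' @param interPlot,interRow gap between plots within a row / between rows,
#'   metres.
#' @param plotsPerRow plots laid out left-to-right per row.
#' @param margin soil margin around the whole trial, metres.
#' @return list of geometry parameters.
#' @export
trialGeometry <- function(plotWidth = 0.6, plotHeight = 0.45,
                          interPlot = 0.3, interRow = 0.5,
                          plotsPerRow = 8L, margin = 1.0) {
  stopifnot(plotWidth > 0, plotHeight > 0, interPlot >= 0, interRow >= 0,
            plotsPerRow >= 1L, margin >= 0)
  list(plotWidth = plotWidth, plotHeight = plotHeight,
       interPlot = interPlot, interRow = interRow,
       plotsPerRow = as.integer(plotsPerRow), margin = margin)
}

#' Plant-material table
#'
#' The fixture table of accessions used in the reference field experiment:
#' species, short ID, accession name and germplasm accession number. Two
#' accessions (Cayuga and Caledonia) appear under two IDs, so the table has
#' 68 entries for 66 unique accession names.
#'
#' @param unique if TRUE, keep the first entry per accession name.
#' @return data.frame with columns `species`, `id`, `accession_name`,
#'   `accession_number`.
#' @export
plantMaterial <- function(unique = FALSE) {
  path <- system.file("extdata", "plant_material.csv", package = "uavpheno",
                      mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (unique)
    tab <- tab[!duplicated(tab$accession_name), , drop = FALSE]
  tab
}

defaultAccessions <- function(nAccessions) {
  mat <- plantMaterial(unique = TRUE)
  if (nAccessions <= nrow(mat)) {
    data.frame(accessionId = mat$id[seq_len(nAccessions)],
               species = mat$species[seq_len(nAccessions)],
               stringsAsFactors = FALSE)
  } else {
    species <- rep(unique(mat$species), length.out = nAccessions)
    data.frame(accessionId = sprintf("ACC%03d", seq_len(nAccessions)),
               species = species, stringsAsFactors = FALSE)
  }
}

#' Generate a randomized complete block trial design
#'
#' Lays out `nBlocks` stacked blocks of `plotsPerBlock` plot positions
#' (rows of `plotsPerRow` plots each) and assigns each accession to exactly
#' one position per block by a seeded random permutation. Positions left
#' over when `nAccessions < plotsPerBlock` are marked empty; empty plots
#' are carried in the layout (and in plot-table exports) but excluded from
#' analysis.
#'
#' @param nAccessions number of accessions; must not exceed `plotsPerBlock`.
#' @param nBlocks number of replicate blocks.
#' @param plotsPerBlock plot positions per block.
#' @param geometry layout parameters from [trialGeometry()].
#' @param seed integer seed; the assignment is reproducible from it.
#' @param accessions optional data.frame with columns `accessionId` and
#'   `species`; defaults to the plant-material fixture (recycled synthetic
#'   IDs beyond 66 accessions).
#' @return a [TrialDesign-class].
#' @examples
#' des <- generateTrialDesign(66, 3, 78, seed = 1)
#' nrow(designPlots(des))  # 234 plot positions
#' @export
generateTrialDesign <- function(nAccessions, nBlocks = 3L,
                                plotsPerBlock = 78L,
                                geometry = trialGeometry(), seed,
                                accessions = NULL) {
  seed <- checkSeed(seed)
  nAccessions <- as.integer(nAccessions)
  nBlocks <- as.integer(nBlocks)
  plotsPerBlock <- as.integer(plotsPerBlock)
  stopifnot(nAccessions >= 1L, nBlocks >= 1L, plotsPerBlock >= 1L)
  if (nAccessions > plotsPerBlock)
    stop(sprintf(
      "nAccessions (%d) exceeds plotsPerBlock (%d): every accession must fit once per block",
      nAccessions, plotsPerBlock))
  acc <- accessions %||% defaultAccessions(nAccessions)
  stopifnot(nrow(acc) >= nAccessions)
  acc <- acc[seq_len(nAccessions), , drop = FALSE]

  g <- geometry
  rowsPerBlock <- ceiling(plotsPerBlock / g$plotsPerRow)
  set.seed(substreamSeed(seed, "design"))
  out <- vector("list", nBlocks)
  for (b in seq_len(nBlocks)) {
    pos <- sample.int(plotsPerBlock)          # seeded permutation
    assigned <- rep(NA_character_, plotsPerBlock)
    spp <- rep(NA_character_, plotsPerBlock)
    assigned[pos[seq_len(nAccessions)]] <- acc$accessionId
    spp[pos[seq_len(nAccessions)]] <- acc$species
    idx <- seq_len(plotsPerBlock)
    rowInBlock <- ((idx - 1L) %/% g$plotsPerRow) + 1L
    orderInRow <- ((idx - 1L) %% g$plotsPerRow) + 1L
    globalRow <- (b - 1L) * rowsPerBlock + rowInBlock
    x0 <- g$margin + (orderInRow - 1L) * (g$plotWidth + g$interPlot)
    y0 <- g$margin + (globalRow - 1L) * (g$plotHeight + g$interRow)
    out[[b]] <- data.frame(
      plotId = sprintf("B%d-P%02d", b, idx),
      accessionId = assigned, species = spp,
      block = b, row = rowInBlock, orderInRow = orderInRow,
      x0 = x0, y0 = y0, x1 = x0 + g$plotWidth, y1 = y0 + g$plotHeight,
      empty = is.na(assigned), stringsAsFactors = FALSE)
  }
  plots <- do.call(rbind, out)
  rownames(plots) <- NULL
  new("TrialDesign", plots = plots, geometry = g)
}
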