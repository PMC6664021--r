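#' Configuration of an end-to-end pipeline run
#'
#' Validates and freezes every knob of a simulate-to-rank run: the seed
#' (mandatory; every stage derives its own substream from it), the flight
#' dates, the trial design, the reflectance model, the segmentation
#' settings and the model-selection target.
#'
#' @param seed integer master seed (mandatory).
#' @param dates flight dates in DAS, strictly increasing.
#' @param nAccessions,nBlocks,plotsPerBlock design size.
#' @param geometry layout from [trialGeometry()].
#' @param species parameters from [speciesParams()].
#' @param model reflectance model from [reflectanceModel()].
#' @param gsd ground sampling distance, m/pixel.
#' @param feature segmentation feature, `"exg"` or `"ndvi"`.
#' @param nBins,minObject,minFraction,minSeparation segmentation settings
#'   (see [classifyPlotVegetation()]).
#' @param rankVi index used for the final ranking model.
#' @param rankScenario temporal scenario of the ranking model
#'   (`"TS1@<date>"`, `"TS2"` or `"TS3"`).
#' @param rankPhenotype phenotype the ranking predicts.
#' @param writeRasters write each date's orthomosaic as GeoTIFF (off by
#'   default; the plot-level CSVs are the inter-stage contract).
#' @return validated config list (class `RunConfig`).
#' @export
runConfig <- function(seed,
                      dates = FLIGHT_DATES,
                      nAccessions = 66L, nBlocks = 3L, plotsPerBlock = 78L,
                      geometry = trialGeometry(),
                      species = speciesParams(),
                      model = reflectanceModel(),
                      gsd = 0.01,
                      feature = c("exg", "ndvi"),
                      nBins = 256L, minObject = 4L, minFraction = 0.005,
                      minSeparation = 0.08,
                      rankVi = "NDVI", rankScenario = "TS3",
                      rankPhenotype = "ethanolYield",
                      writeRasters = FALSE) {
  seed <- checkSeed(seed)
  feature <- match.arg(feature)
  if (any(diff(dates) <= 0)) stop("flight dates must be strictly increasing")
  if (!rankVi %in% VI_NAMES)
    stop("unknown index '", rankVi, "'; known: ",
         paste(VI_NAMES, collapse = ", "))
  if (!rankScenario %in% c("TS2", "TS3") &&
      !grepl("^TS1@\\d+$", rankScenario))
    stop("rankScenario must be 'TS2', 'TS3' or 'TS1@<date>'")
  if (!rankPhenotype %in% c("biomass", "sugarRelease", "ethanolYield"))
    stop("unknown phenotype '", rankPhenotype, "'")
  stopifnot(gsd > 0, inherits(model, "ReflectanceModel"))
  cfg <- list(seed = seed, dates = as.integer(dates),
              nAccessions = as.integer(nAccessions),
              nBlocks = as.integer(nBlocks),
              plotsPerBlock = as.integer(plotsPerBlock),
              geometry = geometry, species = species, model = model,
              gsd = gsd, feature = feature, nBins = as.integer(nBins),
              minObject = as.integer(minObject), minFraction = minFraction,
              minSeparation = minSeparation, rankVi = rankVi,
              rankScenario = rankScenario, rankPhenotype = rankPhenotype,
              writeRasters = writeRasters)
  class(cfg) <- "RunConfig"
  cfg
}

stageCall <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full pipeline: simulate, segment, index, aggregate, model, rank
#'
#' Executes every stage under the given configuration and writes the
#' stage outputs (design GeoJSON + CSV, phenotypes, phenology, the long
#' plot x date table with band means and indices, the three scenario
#' tables, the model grid and the accession ranking) under `outDir`, plus
#' a manifest recording the package version, seed, config fingerprint and
#' per-stage row counts. Reruns with an identical config produce
#' byte-identical CSVs.
#'
#' @param config a [runConfig()].
#' @param outDir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config, outDir) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(outDir, f)

  design <- stageCall("design", generateTrialDesign(
    config$nAccessions, config$nBlocks, config$plotsPerBlock,
    geometry = config$geometry, seed = config$seed))
  phen <- stageCall("phenotypes", generatePhenotypes(
    design, params = config$species, seed = config$seed))
  phenology <- stageCall("phenology", generatePhenology(
    design, seed = config$seed))

  writePlotPolygons(design, pth("plots.geojson"))
  writePlotTable(designPlots(design), pth("design.csv"))
  writePlotTable(phen, pth("phenotypes.csv"))
  writePlotTable(phenology, pth("phenology.csv"))

  tables <- vector("list", length(config$dates))
  for (i in seq_along(config$dates)) {
    d <- config$dates[i]
    ras <- stageCall(sprintf("render@%d", d), renderOrthomosaic(
      design, phen, phenology, d, model = config$model,
      gsd = config$gsd, seed = config$seed))
    if (isTRUE(config$writeRasters))
      writeRaster(ras, pth(sprintf("ortho_das%03d.tif", d)))
    spec <- stageCall(sprintf("segment@%d", d), segmentPlots(
      ras, design, feature = config$feature, nBins = config$nBins,
      minFraction = config$minFraction, minObject = config$minObject,
      minSeparation = config$minSeparation))
    tables[[i]] <- stageCall(sprintf("indices@%d", d),
                             buildPlotTable(design, computeVIs(spec)))
  }
  plotTable <- do.call(rbind, tables)
  writePlotTable(plotTable, pth("plot_table.csv"))

  scen <- stageCall("aggregate", {
    out <- lapply(config$dates, function(d) ts1(plotTable, d))
    names(out) <- sprintf("TS1@%d", config$dates)
    out$TS2 <- ts2(plotTable, phenology, design)
    out$TS3 <- ts3(plotTable)
    out
  })
  for (nm in c("TS2", "TS3"))
    writePlotTable(scen[[nm]], pth(sprintf("scenario_%s.csv", tolower(nm))))

  models <- stageCall("associate", scanModels(
    plotTable, phen, phenology, design))
  writePlotTable(models, pth("models.csv"))

  ranking <- stageCall("rank", {
    m <- models[models$vi == config$rankVi &
                  models$scenario == config$rankScenario &
                  models$phenotype == config$rankPhenotype, , drop = FALSE]
    if (!nrow(m))
      stop("no fitted model for ", config$rankVi, " / ",
           config$rankScenario, " / ", config$rankPhenotype)
    rankAccessions(m[1L, ], scen[[config$rankScenario]], design,
                   observed = phen, viColumn = config$rankVi,
                   phenotypeColumn = config$rankPhenotype)
  })
  writePlotTable(ranking$table, pth("ranking.csv"))

  manifest <- list(
    package = "uavpheno",
    version = as.character(packageVersion("uavpheno")),
    seed = config$seed,
    configHash = fnv1a(paste(deparse(config), collapse = "")),
    dates = config$dates,
    rows = list(designPlots = nrow(designPlots(design)),
                phenotypes = nrow(phen), phenology = nrow(phenology),
                plotTable = nrow(plotTable), models = nrow(models),
                ranking = nrow(ranking$table)),
    rankModel = list(vi = config$rankVi, scenario = config$rankScenario,
                     phenotype = config$rankPhenotype,
                     r2 = ranking$model$r2, rmse = ranking$model$rmse,
                     category = ranking$category,
                     plotRmse = ranking$rmse, spearman = ranking$spearman))
  writeLines(as.character(jsonlite::toJSON(
    manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)),
    pth("manifest.json"))
  invisible(manifest)
}
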