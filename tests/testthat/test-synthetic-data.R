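test_that("trial design has RCBD structure and the reference cardinality", {
  des <- generateTrialDesign(66, 3, 78, seed = 1)
  p <- designPlots(des)
  expect_equal(nrow(p), 234L)
  expect_equal(sum(!p$empty), 66L * 3L)
  occ <- p[!p$empty, ]
  expect_true(all(table(occ$accessionId, occ$block) == 1L))
  expect_true(validObject(des))

  single <- generateTrialDesign(1, 1, 1, seed = 0)
  expect_equal(nrow(designPlots(single)), 1L)
  expect_false(designPlots(single)$empty)

  des2 <- generateTrialDesign(2, 2, 3, seed = 7)
  p2 <- designPlots(des2)
  expect_equal(sum(p2$empty), 2L)
  expect_true(all(table(p2$accessionId[!p2$empty], p2$block[!p2$empty]) == 1L))
})

test_that("over-full designs are rejected naming both values", {
  expect_error(generateTrialDesign(10, 2, 5, seed = 1),
               "nAccessions \\(10\\).*plotsPerBlock \\(5\\)")
  expect_error(generateTrialDesign(3, 1, 3), "seed")
})

test_that("design regeneration with the same seed is identical", {
  a <- generateTrialDesign(12, 3, 15, seed = 99)
  b <- generateTrialDesign(12, 3, 15, seed = 99)
  expect_identical(designPlots(a), designPlots(b))
  c <- generateTrialDesign(12, 3, 15, seed = 100)
  expect_false(identical(designPlots(a), designPlots(c)))
})

test_that("degenerate-sd phenotypes reproduce the species worked example", {
  des <- generateTrialDesign(66, 3, 78, seed = 1)
  phen <- generatePhenotypes(des, params = speciesParams(sdW = 0, sdS = 0),
                             seed = 1, blockSdW = 0, blockSdS = 0)
  hv <- phen[phen$species == "H. vulgare", ]
  expect_true(all(hv$biomass == 0.71))
  expect_true(all(hv$sugarRelease == 1.16))
  expect_true(all(round(hv$ethanolYield, 2) == 4.21))
})

test_that("zero biomass yields zero ethanol and Eq round-trips exactly", {
  des <- smallDesign()
  zero <- speciesParams(meanW = setNames(rep(0, 4), speciesParams()$species),
                        sdW = 0)
  phen0 <- generatePhenotypes(des, params = zero, seed = 3,
                              blockSdW = 0)
  expect_true(all(phen0$ethanolYield == 0))

  phen <- generatePhenotypes(des, seed = 5)
  expect_equal(phen$ethanolYield,
               theoreticalEthanolYield(phen$sugarRelease, phen$biomass),
               tolerance = 1e-9)
})

test_that("phenotype generation is deterministic and validates sd", {
  des <- smallDesign()
  expect_identical(generatePhenotypes(des, seed = 8),
                   generatePhenotypes(des, seed = 8))
  expect_error(generatePhenotypes(des, params = speciesParams(sdW = -1),
                                  seed = 1), "non-negative")
})

test_that("phenology respects its ranges and window bounds", {
  des <- generateTrialDesign(60, 1, 60, seed = 2)
  phl <- generatePhenology(des, seed = 2)
  expect_true(all(phl$anthesisStart >= 110 & phl$anthesisStart <= 160))
  expect_true(all(phl$anthesisEnd > phl$anthesisStart))
  expect_true(all(phl$anthesisEnd <= 175))
  win <- phl$anthesisEnd - phl$anthesisStart
  expect_true(all(win >= 10 | phl$anthesisEnd == 175))

  deg <- generatePhenology(des, seed = 2, windowRange = c(10, 10))
  expect_true(all(pmin(deg$anthesisStart + 10, 175) == deg$anthesisEnd))

  ## two seeds: different draws, same marginal bounds (empirical over many)
  many <- generateTrialDesign(78, 1, 78, seed = 3)
  a <- generatePhenology(many, seed = 10)
  b <- generatePhenology(many, seed = 11)
  expect_false(identical(a$anthesisStart, b$anthesisStart))
  expect_true(all(c(a$anthesisStart, b$anthesisStart) %in% 110:160))
})

test_that("noise-free full-cover rendering reproduces the spectrum exactly", {
  sc <- smallScene(model = reflectanceModel(noiseSd = 0, coverBase = 1,
                                            coverGain = 0,
                                            coverMidpoint = -300))
  ras <- sc$render(130)
  expect_equal(dim(rasterData(ras))[3], 6L)
  rng <- range(rasterData(ras))
  expect_true(rng[1] >= 0 && rng[2] <= 1)
  p <- sownPlots(sc$design)[1, ]
  tr <- ras@truth[[p$plotId]]
  expect_true(all(tr$vegetation))
  i <- match(p$plotId, sc$phen$plotId)
  spec <- vegetationSpectrum(sc$model, tr$greenness, sc$phen$biomass[i])
  for (b in 1:6) {
    px <- rasterData(ras)[tr$window$rows, tr$window$cols, b]
    expect_true(all(px == px[1]))              # perfectly uniform
    expect_equal(px[1], unname(spec[b]), tolerance = 1e-6)
  }
})

test_that("rendering validates its inputs", {
  sc <- smallScene()
  expect_error(renderOrthomosaic(sc$design, sc$phen, sc$phl, 130,
                                 gsd = 0, seed = 1), "gsd")
  expect_error(renderOrthomosaic(sc$design, sc$phen, sc$phl, 200, seed = 1),
               "90-180")
})

test_that("canopy cover is monotone in the biomass parameter", {
  sc <- smallScene()
  pid <- sownPlots(sc$design)$plotId[1]
  phenHi <- sc$phen
  i <- match(pid, phenHi$plotId)
  phenHi$biomass[i] <- phenHi$biomass[i] + 0.5
  for (das in c(94, 130, 175)) {
    lo <- renderOrthomosaic(sc$design, sc$phen, sc$phl, das, seed = 11)
    hi <- renderOrthomosaic(sc$design, phenHi, sc$phl, das, seed = 11)
    expect_gte(hi@truth[[pid]]$cover, lo@truth[[pid]]$cover)
  }
})

test_that("zero-cover plots are indistinguishable from margin soil", {
  sc <- smallScene(model = reflectanceModel(coverBase = 0, coverGain = 0))
  ras <- sc$render(130)
  p <- sownPlots(sc$design)[1, ]
  tr <- ras@truth[[p$plotId]]
  expect_false(any(tr$vegetation))
  plotPx <- rasterData(ras)[tr$window$rows, tr$window$cols, 5]
  marginPx <- rasterData(ras)[1:20, 1:20, 5]
  ## two-sample location test at alpha = 0.01: no detectable difference
  expect_gt(t.test(as.numeric(plotPx), as.numeric(marginPx))$p.value, 0.01)
})

test_that("per-plot NDVI over the season peaks at an interior date", {
  sc <- smallScene(seed = 21)
  ndvi <- sapply(c(94, 104, 119, 130, 143, 161, 175), function(d) {
    ras <- sc$render(d)
    spec <- computeVIs(segmentPlots(ras, sc$design))
    mean(spec$NDVI, na.rm = TRUE)
  })
  peak <- which.max(ndvi)
  expect_gt(peak, 1)
  expect_lt(peak, 7)
})
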