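test_that("Otsu matches exhaustive between-class variance search", {
  set.seed(401)
  for (i in 1:200) {
    nBins <- sample(4:32, 1)
    n <- sample(20:200, 1)
    v <- switch(sample(3, 1),
                runif(n),
                c(rnorm(n %/% 2, 0.2, 0.05), rnorm(n - n %/% 2, 0.7, 0.1)),
                rbeta(n, 0.5, 0.5))
    if (length(unique(v)) < 2) next
    expect_identical(otsuThreshold(v, nBins), otsuOracle(v, nBins))
  }
})

test_that("Otsu separates a perfectly bimodal sample", {
  v <- c(rep(0.1, 50), rep(0.9, 50))
  thr <- otsuThreshold(v, 256)
  expect_gt(thr, 0.1)
  expect_lt(thr, 0.9)
})

test_that("Otsu rejects degenerate input", {
  expect_error(otsuThreshold(rep(0.5, 100)), "degenerate")
  expect_error(otsuThreshold(c(1, NA, NaN)), "degenerate")
})

test_that("noise-free segmentation recovers the ground truth exactly", {
  sc <- smallScene(model = reflectanceModel(noiseSd = 0))
  ras <- sc$render(130)
  for (i in seq_len(nrow(sownPlots(sc$design)))) {
    p <- sownPlots(sc$design)[i, ]
    msk <- classifyPlotVegetation(ras, p)
    expect_identical(maskPixels(msk), ras@truth[[p$plotId]]$vegetation)
    expect_equal(vegetationFraction(msk),
                 mean(ras@truth[[p$plotId]]$vegetation))
  }
})

test_that("default-noise segmentation accuracy is at least 0.95", {
  sc <- smallScene(seed = 31)
  for (das in c(104, 143, 175)) {
    ras <- sc$render(das)
    acc <- sapply(seq_len(nrow(sownPlots(sc$design))), function(i) {
      p <- sownPlots(sc$design)[i, ]
      msk <- classifyPlotVegetation(ras, p)
      mean(maskPixels(msk) == ras@truth[[p$plotId]]$vegetation)
    })
    expect_gte(min(acc), 0.95)
  }
})

test_that("all-soil plots are flagged low-cover with zero fraction", {
  sc <- smallScene(model = reflectanceModel(coverBase = 0, coverGain = 0))
  ras <- sc$render(130)
  p <- sownPlots(sc$design)[1, ]
  msk <- classifyPlotVegetation(ras, p)
  expect_true(msk@lowCover)
  expect_equal(vegetationFraction(msk), 0)
  expect_false(any(maskPixels(msk)))
})

test_that("plots outside the raster raise an empty-plot error", {
  sc <- smallScene()
  ras <- sc$render(130)
  ghost <- list(plotId = "ghost", x0 = 100, x1 = 101, y0 = 100, y1 = 101)
  expect_error(classifyPlotVegetation(ras, ghost), "does not intersect")
})

test_that("spectral extraction equals masked-mean oracles", {
  ## uniform vegetation spectrum, full mask: means equal the spectrum bitwise
  spec <- c(0.05, 0.1, 0.08, 0.12, 0.5, 0.55)
  arr <- array(rep(spec, each = 100), c(10, 10, 6))
  ras <- msRaster(arr, das = 100L)
  full <- new("VegetationMask", plotId = "p", das = 100L,
              mask = matrix(TRUE, 10, 10), threshold = 0.5, fraction = 1,
              lowCover = FALSE, window = list(rows = 1:10, cols = 1:10))
  rec <- extractPlotSpectra(ras, full)
  expect_equal(as.numeric(rec[1, c("B", "G", "R1", "R2", "NIR1", "NIR2")]),
               as.numeric(rasterData(ras)[1, 1, ]), tolerance = 1e-12)

  ## checkerboard over two spectra: means equal the vegetation spectrum only
  soil <- c(0.2, 0.22, 0.25, 0.26, 0.27, 0.28)
  chk <- outer(1:10, 1:10, function(i, j) (i + j) %% 2 == 0)
  arr2 <- arr
  for (b in 1:6) { s <- arr2[, , b]; s[!chk] <- soil[b]; arr2[, , b] <- s }
  ras2 <- msRaster(arr2, das = 100L)
  m2 <- new("VegetationMask", plotId = "p", das = 100L, mask = chk,
            threshold = 0.5, fraction = 0.5, lowCover = FALSE,
            window = list(rows = 1:10, cols = 1:10))
  rec2 <- extractPlotSpectra(ras2, m2)
  expect_equal(as.numeric(rec2[1, c("B", "G", "R1", "R2", "NIR1", "NIR2")]),
               as.numeric(rasterData(ras2)[1, 1, ]), tolerance = 1e-12)

  ## NaN pixels: means equal a brute-force masked loop
  arr3 <- array(runif(600), c(10, 10, 6))
  arr3[2, 4, ] <- NaN   # a pixel inside the checkerboard mask
  ras3 <- msRaster(arr3, das = 100L)
  rec3 <- extractPlotSpectra(ras3, m2)
  for (b in 1:6) {
    acc <- c()
    for (i in 1:10) for (j in 1:10)
      if (chk[i, j] && is.finite(rasterData(ras3)[i, j, b]))
        acc <- c(acc, rasterData(ras3)[i, j, b])
    expect_equal(rec3[[c("B", "G", "R1", "R2", "NIR1", "NIR2")[b]]], mean(acc))
  }
  expect_equal(rec3$nPixels, sum(chk) - 1L)

  ## zero vegetation pixels: missing means, not zeros
  none <- new("VegetationMask", plotId = "p", das = 100L,
              mask = matrix(FALSE, 10, 10), threshold = NA_real_,
              fraction = 0, lowCover = TRUE,
              window = list(rows = 1:10, cols = 1:10))
  rec4 <- extractPlotSpectra(ras3, none)
  expect_true(all(is.na(rec4[1, c("B", "G", "R1", "R2", "NIR1", "NIR2")])))
})

test_that("segmentation is idempotent and order-independent", {
  sc <- smallScene(seed = 41)
  ras <- sc$render(143)
  a <- segmentPlots(ras, sc$design)
  b <- segmentPlots(ras, sc$design)
  expect_identical(a, b)
  ## permuted plot order yields the same per-plot records
  des2 <- sc$design
  des2@plots <- des2@plots[rev(seq_len(nrow(des2@plots))), ]
  c2 <- segmentPlots(ras, des2)
  c2 <- c2[match(a$plotId, c2$plotId), ]
  rownames(c2) <- NULL
  expect_equal(c2, a)
})

test_that("vegetation fraction is monotone in the cover parameter", {
  sc <- smallScene(seed = 51)
  fr <- sapply(c(0.3, 0.5, 0.7), function(cb) {
    m <- reflectanceModel(coverBase = cb, coverGain = 0.2)
    ras <- renderOrthomosaic(sc$design, sc$phen, sc$phl, 143,
                             model = m, seed = 51)
    mean(segmentPlots(ras, sc$design)$vegFraction, na.rm = TRUE)
  })
  expect_true(all(diff(fr) > 0))
})
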