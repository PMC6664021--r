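test_that("exact linear data recover slope, intercept, R2 = 1, RMSE = 0", {
  x <- c(1, 2, 3, 4, 5)
  fit <- fitLinear(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r2, 1)
  expect_equal(fit$rmse, 0, tolerance = 1e-12)
})

test_that("a constant response gives R2 = 0", {
  fit <- fitLinear(1:10, rep(3, 10))
  expect_equal(fit$r2, 0)
  expect_equal(fit$category, "low")
})

test_that("a 5-point toy set matches the normal-equations closed form", {
  x <- c(0.2, 0.5, 0.9, 1.4, 2.0)
  y <- c(1.1, 0.8, 1.9, 2.4, 2.2)
  n <- length(x)
  slope <- (n * sum(x * y) - sum(x) * sum(y)) /
    (n * sum(x^2) - sum(x)^2)
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  fit <- fitLinear(x, y)
  expect_equal(fit$slope, slope, tolerance = 1e-10)
  expect_equal(fit$intercept, intercept, tolerance = 1e-10)
  expect_equal(fit$r2, cor(x, y)^2, tolerance = 1e-10)
  expect_equal(fit$rmse, sqrt(mean(res^2)), tolerance = 1e-10)
})

test_that("degenerate regressions are rejected", {
  expect_error(fitLinear(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fitLinear(rep(1, 5), 1:5), "zero variance")
  expect_error(fitLinear(c(1, 2, NA, NA, NA), c(1, 2, 3, 4, 5)),
               "at least 3")
})

test_that("the correlation categories split exactly at 0.50 and 0.60", {
  expect_identical(correlationCategory(c(0.499, 0.50, 0.599, 0.60, 0.9)),
                   c("low", "moderate", "moderate", "high", "high"))
})

test_that("the model grid has the expected cardinality and skips dead columns", {
  set.seed(12)
  plots <- sprintf("p%d", 1:20)
  rec <- do.call(rbind, lapply(c(104, 143), function(d)
    data.frame(plotId = plots, das = d, NDVI = runif(20),
               ExG = NA_real_, stringsAsFactors = FALSE)))
  phen <- data.frame(plotId = plots, biomass = runif(20),
                     stringsAsFactors = FALSE)
  expect_message(
    out <- scanModels(rec, phen, scenarios = c("TS1", "TS3"),
                      phenotypeVars = "biomass"),
    "skipping ExG")
  ## NDVI only, under TS1@104, TS1@143 and TS3: 3 models
  expect_equal(nrow(out), 3L)
  expect_setequal(out$scenario, c("TS1@104", "TS1@143", "TS3"))
})

test_that("a planted NIR signal makes a NIR index the top biomass model", {
  set.seed(88)
  plots <- sprintf("p%d", 1:60)
  biomass <- runif(60, 0.3, 1.3)
  rec <- do.call(rbind, lapply(c(104, 143), function(d)
    data.frame(plotId = plots, das = d,
               NDVI = 0.2 + 0.4 * biomass + rnorm(60, sd = 0.02),
               GNDVI = 0.2 + 0.35 * biomass + rnorm(60, sd = 0.02),
               ExG = runif(60, 0.1, 0.3),      # no biomass signal
               VIgreen = runif(60, 0, 0.2),
               stringsAsFactors = FALSE)))
  phen <- data.frame(plotId = plots, biomass = biomass,
                     stringsAsFactors = FALSE)
  out <- scanModels(rec, phen, scenarios = "TS3", phenotypeVars = "biomass")
  top <- out$vi[which.max(out$r2)]
  expect_true(top %in% c("NDVI", "GNDVI", "MCARI", "MSR"))
})

test_that("well-separated species earn distinct Tukey letters", {
  set.seed(21)
  values <- c(rnorm(12, 10, 0.3), rnorm(12, 5, 0.3))
  species <- rep(c("A", "B"), each = 12)
  out <- speciesAnova(values, species)
  expect_identical(out$means$letters, c("a", "b"))
  expect_identical(out$means$species, c("A", "B"))  # highest mean first

  same <- speciesAnova(rnorm(24, 5, 0.3), species)
  expect_identical(same$means$letters, c("a", "a"))
})

test_that("four species with reference-like means group as in the table", {
  ## species means of theoretical ethanol yield; tight within-species sd
  set.seed(31)
  mu <- c("T. aestivum" = 3.49, "T. durum" = 4.14, "H. vulgare" = 4.21,
          "x Triticosecale" = 2.54)
  species <- rep(names(mu), each = 30)
  values <- rnorm(length(species), mu[species], 0.45)
  out <- speciesAnova(values, species)
  lets <- setNames(out$means$letters, out$means$species)
  ## the lowest-mean species stands alone in the last letter class
  expect_false(grepl(lets[["x Triticosecale"]],
                     paste(lets[setdiff(names(lets), "x Triticosecale")],
                           collapse = "")))
  ## the two top species share a letter; the letters match multcomp's CLD
  expect_true(any(strsplit(lets[["H. vulgare"]], "")[[1]] %in%
                    strsplit(lets[["T. durum"]], "")[[1]]))
  df <- data.frame(v = values, sp = factor(species))
  glht <- multcomp::glht(stats::aov(v ~ sp, df),
                         linfct = multcomp::mcp(sp = "Tukey"))
  cld <- multcomp::cld(glht, level = 0.05, decreasing = TRUE)$mcletters$Letters
  for (a in names(mu)) for (b in names(mu)) {
    shareOurs <- any(strsplit(lets[[a]], "")[[1]] %in%
                       strsplit(lets[[b]], "")[[1]])
    shareCld <- any(strsplit(cld[[a]], "")[[1]] %in%
                      strsplit(cld[[b]], "")[[1]])
    expect_identical(shareOurs, shareCld)
  }
})

test_that("species with fewer than two plots are excluded with a warning", {
  values <- c(rnorm(10, 5), rnorm(10, 8), 3)
  species <- c(rep("A", 10), rep("B", 10), "C")
  expect_warning(out <- speciesAnova(values, species), "C")
  expect_setequal(out$means$species, c("A", "B"))
})

test_that("slope confidence intervals attain near-nominal coverage", {
  set.seed(55)
  slope <- 3; intercept <- 1
  hits <- replicate(500, {
    x <- runif(60, 0, 1)
    y <- intercept + slope * x + rnorm(60, sd = 0.5)
    fit <- fitLinear(x, y)
    ci <- fit$slope + c(-1, 1) * qt(0.975, fit$n - 2) * fit$slopeSe
    ci[1] <= slope && slope <= ci[2]
  })
  expect_gt(mean(hits), 0.92)
  expect_lt(mean(hits), 0.98)
})

test_that("a perfect model ranks accessions exactly as observed", {
  des <- smallDesign(seed = 61)
  phen <- generatePhenotypes(des, seed = 61)
  vi <- data.frame(plotId = phen$plotId,
                   NDVI = 0.1 + 0.05 * phen$ethanolYield)
  fit <- fitLinear(vi$NDVI, phen$ethanolYield)
  rk <- rankAccessions(fit, vi, des, observed = phen, viColumn = "NDVI")
  expect_equal(rk$model$r2, 1)
  ## table is sorted by predicted; observed must be decreasing too
  expect_false(is.unsorted(rev(rk$table$observed)))
  expect_identical(rk$table$rank, seq_len(nrow(rk$table)))
  expect_lt(rk$rmse, 1e-8)
  expect_equal(rk$spearman, 1)
})

test_that("rank ties break lexicographically and singletons rank alone", {
  des <- new("TrialDesign", plots = data.frame(
    plotId = c("p1", "p2"), accessionId = c("accB", "accA"),
    species = "H. vulgare", block = 1L, row = 1L, orderInRow = 1:2,
    x0 = c(0, 1), y0 = 0, x1 = c(0.5, 1.5), y1 = 0.5, empty = FALSE,
    stringsAsFactors = FALSE), geometry = list())
  fit <- data.frame(slope = 1, intercept = 0, r2 = 0.7, rmse = 0.1,
                    n = 4, slopeSe = 0.1, p = 0.01, significant = TRUE,
                    category = "high", stringsAsFactors = FALSE)
  vi <- data.frame(plotId = c("p1", "p2"), NDVI = c(0.5, 0.5))
  rk <- rankAccessions(fit, vi, des, viColumn = "NDVI")
  expect_identical(rk$table$accessionId, c("accA", "accB"))  # tie: lexical

  one <- rankAccessions(fit, vi[1, ], des, viColumn = "NDVI")
  expect_equal(nrow(one$table), 1L)
})
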