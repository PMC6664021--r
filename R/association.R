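#' Category of a coefficient of determination
#'
#' Correlations are classed as low (R2 < 0.50), moderate
#' (0.50 <= R2 < 0.60) or high (R2 >= 0.60); the boundary values map to
#' moderate and high respectively.
#'
#' @param r2 numeric vector of R2 values.
#' @return character vector in {"low", "moderate", "high"}.
#' @export
correlationCategory <- function(r2) {
  ifelse(r2 >= 0.60, "high", ifelse(r2 >= 0.50, "moderate", "low"))
}

#' Simple linear regression of a phenotype on an index
#'
#' Ordinary least squares with pairwise deletion of missing values. R2 is
#' the squared Pearson correlation (0 when the response has zero
#' variance), RMSE the root mean squared residual, and the slope p-value a
#' two-sided t-test.
#'
#' @param x index values per plot.
#' @param y phenotype values per plot.
#' @return one-row data.frame: `slope`, `intercept`, `r2`, `rmse`, `n`,
#'   `slopeSe`, `p`, `significant` (p < 0.05), `category`.
#' @export
fitLinear <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired finite observations, got ", n)
  if (stats::var(x) == 0) stop("zero variance in x: slope undefined")
  fit <- lm(y ~ x)
  cf <- coef(fit)
  r2 <- if (stats::var(y) == 0) 0 else cor(x, y)^2
  res <- residuals(fit)
  se <- sqrt(sum(res^2) / (n - 2L) / sum((x - mean(x))^2))
  tval <- cf[[2L]] / se
  p <- if (stats::var(y) == 0) 1 else 2 * stats::pt(-abs(tval), df = n - 2L)
  data.frame(slope = cf[[2L]], intercept = cf[[1L]], r2 = r2,
             rmse = sqrt(mean(res^2)), n = n, slopeSe = se, p = p,
             significant = p < 0.05, category = correlationCategory(r2),
             stringsAsFactors = FALSE)
}

#' Scan the full index x scenario x phenotype model grid
#'
#' Fits [fitLinear()] for every index under every requested temporal
#' scenario (each single date, the anthesis window, the full season)
#' against every phenotype column, attaching the slope significance and
#' the low/moderate/high category. Index columns that are entirely
#' missing, or constant, are excluded with a message. No multiple-testing
#' correction is applied across the grid; p-values are reported raw.
#'
#' @param records long plot table (one row per plot x date, index columns
#'   present; see [computeVIs()]).
#' @param phenotypes phenotype table from [generatePhenotypes()].
#' @param phenology accession phenology (needed for the TS2 scenario).
#' @param design a [TrialDesign-class].
#' @param scenarios subset of `c("TS1", "TS2", "TS3")`.
#' @param phenotypeVars phenotype columns to model.
#' @return data.frame, one row per fitted model: `vi`, `scenario`,
#'   `phenotype` plus the [fitLinear()] columns.
#' @export
scanModels <- function(records, phenotypes, phenology = NULL, design = NULL,
                       scenarios = c("TS1", "TS2", "TS3"),
                       phenotypeVars = c("biomass", "sugarRelease",
                                         "ethanolYield")) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  tabs <- list()
  if ("TS1" %in% scenarios)
    for (d in sort(unique(records$das)))
      tabs[[sprintf("TS1@%d", d)]] <- ts1(records, d)
  if ("TS2" %in% scenarios) {
    if (is.null(phenology) || is.null(design))
      stop("TS2 requires phenology and design")
    tabs[["TS2"]] <- ts2(records, phenology, design)
  }
  if ("TS3" %in% scenarios) tabs[["TS3"]] <- ts3(records)

  vis <- viColumns(records)
  out <- list()
  for (sc in names(tabs)) {
    tab <- tabs[[sc]]
    i <- match(tab$plotId, phenotypes$plotId)
    for (vi in vis) {
      x <- tab[[vi]]
      if (all(is.na(x)) || length(unique(x[is.finite(x)])) < 2L) {
        message("skipping ", vi, " under ", sc,
                ": missing or constant values")
        next
      }
      for (ph in phenotypeVars) {
        y <- phenotypes[[ph]][i]
        fit <- fitLinear(x, y)
        out[[length(out) + 1L]] <-
          cbind(data.frame(vi = vi, scenario = sc, phenotype = ph,
                           stringsAsFactors = FALSE), fit)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Compact letter display by insert-and-absorb over the significant pairs;
## groups ordered by decreasing mean so the highest mean carries "a".
compactLetters <- function(groups, diffPairs) {
  cols <- list(groups)
  for (k in seq_len(nrow(diffPairs))) {
    a <- diffPairs[k, 1L]; b <- diffPairs[k, 2L]
    for (ci in seq_along(cols)) {
      if (all(c(a, b) %in% cols[[ci]])) {
        cols <- append(cols, list(setdiff(cols[[ci]], a),
                                  setdiff(cols[[ci]], b)))
        cols[ci] <- NULL
        ## absorb: drop columns that are subsets of another
        keep <- rep(TRUE, length(cols))
        for (i in seq_along(cols)) for (j in seq_along(cols))
          if (i != j && keep[j] && all(cols[[i]] %in% cols[[j]]) &&
              (length(cols[[i]]) < length(cols[[j]]) || i > j))
            keep[i] <- FALSE
        cols <- cols[keep]
        break
      }
    }
  }
  cols <- cols[lengths(cols) > 0L]
  ## order letter columns by their best-ranked (highest-mean) member
  first <- vapply(cols, function(cc) min(match(cc, groups)), 0L)
  cols <- cols[order(first)]
  vapply(groups, function(gr) {
    paste(letters[which(vapply(cols, function(cc) gr %in% cc, TRUE))],
          collapse = "")
  }, "")
}

#' One-way ANOVA across species with Tukey grouping letters
#'
#' Fits a one-way ANOVA of the values on the species factor, runs Tukey
#' HSD pairwise comparisons at `alpha`, and assigns a compact letter
#' display with "a" for the highest mean. Species with fewer than two
#' plots are excluded with a warning.
#'
#' @param values numeric vector, one value per plot.
#' @param species character/factor vector of species labels per plot.
#' @param alpha significance level of the pairwise comparisons.
#' @return list with `means` (data.frame: `species`, `mean`, `n`,
#'   `letters`, ordered by decreasing mean), `fStatistic`, `p`, `tukey`
#'   (the TukeyHSD table), and `anova` (the aov fit).
#' @export
speciesAnova <- function(values, species, alpha = 0.05) {
  ok <- is.finite(values) & !is.na(species)
  values <- values[ok]; species <- as.character(species)[ok]
  cnt <- table(species)
  small <- names(cnt)[cnt < 2L]
  if (length(small)) {
    warning("excluding species with < 2 plots: ",
            paste(small, collapse = ", "))
    keep <- !species %in% small
    values <- values[keep]; species <- species[keep]
  }
  if (length(unique(species)) < 2L)
    stop("need at least 2 species with at least 2 plots each")
  sf <- factor(species)
  fit <- aov(values ~ sf)
  ss <- summary(fit)[[1L]]
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$sf
  means <- tapply(values, sf, mean)
  ord <- names(sort(means, decreasing = TRUE))
  pairNames <- strsplit(rownames(tk), "-", fixed = TRUE)
  diffPairs <- do.call(rbind,
                       pairNames[tk[, "p adj"] < alpha])
  if (is.null(diffPairs)) diffPairs <- matrix(character(), ncol = 2L)
  lets <- compactLetters(ord, diffPairs)
  means <- data.frame(species = ord, mean = as.numeric(means[ord]),
                      n = as.integer(table(sf)[ord]), letters = lets,
                      stringsAsFactors = FALSE)
  rownames(means) <- NULL
  list(means = means, fStatistic = ss$`F value`[1L], p = ss$`Pr(>F)`[1L],
       tukey = tk, anova = fit)
}
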