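#' Rank accessions by a fitted index-phenotype model
#'
#' Applies a fitted linear model to plot-level index values, averages the
#' predictions (and the observed phenotype) to accession level across
#' blocks, and orders accessions by decreasing mean predicted value, ties
#' broken by accession ID in lexicographic order. The prediction RMSE is
#' reported at plot level. Accessions with no non-missing plot are omitted
#' with a message.
#'
#' @param model a one-row model from [fitLinear()] / [scanModels()].
#' @param viValues data.frame with `plotId` and the index column named in
#'   `viColumn` (e.g. a [ts3()] table).
#' @param design a [TrialDesign-class].
#' @param observed phenotype table with `plotId` and the column
#'   `phenotypeColumn` (for validation; may be omitted).
#' @param viColumn name of the index column in `viValues`.
#' @param phenotypeColumn name of the observed phenotype column.
#' @return object of class `RankingResult`: list with `table` (data.frame
#'   `rank`, `accessionId`, `predicted`, `observed`, `nPlots`), `rmse`
#'   (plot-level), `spearman` (rank correlation of predicted vs observed
#'   accession means, NA without observations), `category` (the model's
#'   correlation category), and `model`.
#' @export
rankAccessions <- function(model, viValues, design, observed = NULL,
                           viColumn, phenotypeColumn = "ethanolYield") {
  stopifnot(is(design, "TrialDesign"), viColumn %in% names(viValues))
  p <- designPlots(design)
  p <- p[!p$empty, , drop = FALSE]
  acc <- p$accessionId[match(viValues$plotId, p$plotId)]
  pred <- model$intercept + model$slope * viValues[[viColumn]]
  obs <- if (!is.null(observed))
    observed[[phenotypeColumn]][match(viValues$plotId, observed$plotId)]
  else rep(NA_real_, length(pred))

  keep <- !is.na(acc)
  tab <- data.frame(accessionId = acc[keep], pred = pred[keep],
                    obs = obs[keep], stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(split(tab, tab$accessionId), function(g) {
    data.frame(accessionId = g$accessionId[1L],
               predicted = if (all(is.na(g$pred))) NA_real_
                           else mean(g$pred, na.rm = TRUE),
               observed = if (all(is.na(g$obs))) NA_real_
                          else mean(g$obs, na.rm = TRUE),
               nPlots = sum(!is.na(g$pred)), stringsAsFactors = FALSE)
  }))
  dropped <- agg$accessionId[is.na(agg$predicted)]
  if (length(dropped))
    message("omitting accession(s) with no non-missing plot: ",
            paste(dropped, collapse = ", "))
  agg <- agg[!is.na(agg$predicted), , drop = FALSE]
  agg <- agg[order(-agg$predicted, agg$accessionId), , drop = FALSE]
  agg <- cbind(rank = seq_len(nrow(agg)), agg)
  rownames(agg) <- NULL

  okPlot <- !is.na(tab$pred) & !is.na(tab$obs)
  rmse <- if (any(okPlot))
    sqrt(mean((tab$pred[okPlot] - tab$obs[okPlot])^2)) else NA_real_
  spearman <- if (sum(!is.na(agg$observed)) >= 3L)
    cor(agg$predicted, agg$observed, method = "spearman",
        use = "complete.obs") else NA_real_
  out <- list(table = agg, rmse = rmse, spearman = spearman,
              category = model$category %||% correlationCategory(model$r2),
              model = model)
  class(out) <- "RankingResult"
  out
}

#' @export
print.RankingResult <- function(x, ...) {
  cat(sprintf("RankingResult: %d accessions (model category: %s)\n",
              nrow(x$table), x$category))
  cat(sprintf("  plot-level prediction RMSE: %s\n",
              ifelse(is.na(x$rmse), "NA", format(x$rmse, digits = 3))))
  if (!is.na(x$spearman))
    cat(sprintf("  Spearman rho (predicted vs observed accession means): %.3f\n",
                x$spearman))
  print(utils::head(x$table, 10L))
  if (nrow(x$table) > 10L) cat("  ...\n")
  invisible(x)
}
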