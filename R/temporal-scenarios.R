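## Temporal aggregation of per-plot index time series.
##
## TS-1: one single flight date. TS-2: unweighted mean over the flights
## falling inside the accession's anthesis window (inclusive at both
## ends); when no flight falls inside, the two flights bracketing the
## window midpoint are averaged and the row is flagged as a fallback.
## TS-3: unweighted mean over all available flights.

viColumns <- function(tab) intersect(VI_NAMES, names(tab))

dropEmptyPlots <- function(tab) {
  if ("empty" %in% names(tab)) tab <- tab[!tab$empty %in% TRUE, , drop = FALSE]
  tab
}

#' Single-date temporal scenario (TS-1)
#'
#' Identity projection of one flight date's index values.
#'
#' @param records long plot table (one row per plot x date) with a `das`
#'   column and index columns.
#' @param date flight date (DAS); must be present in `records`.
#' @return data.frame: `plotId`, `scenario` (`"TS1@<date>"`), index columns.
#' @export
ts1 <- function(records, date) {
  records <- dropEmptyPlots(records)
  avail <- sort(unique(records$das))
  if (!date %in% avail)
    stop(sprintf("date %s is not a flight date; available: %s",
                 date, paste(avail, collapse = ", ")))
  sel <- records[records$das == date, , drop = FALSE]
  out <- data.frame(plotId = sel$plotId,
                    scenario = sprintf("TS1@%d", as.integer(date)),
                    sel[, viColumns(records), drop = FALSE],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Anthesis-window temporal scenario (TS-2)
#'
#' Per plot, the mean of each index over the flight dates within the
#' accession's anthesis window \[start, end\] (inclusive). Accession-level
#' phenology is used (anthesis is recorded per accession). When no flight
#' falls inside the window, the flights nearest below and above the window
#' midpoint are averaged instead and `fallback` is TRUE, so analysts can
#' exclude those plots. The dates used are recorded per plot.
#'
#' @param records long plot table with `plotId`, `das` and index columns.
#' @param phenology accession phenology from [generatePhenology()].
#' @param design a [TrialDesign-class] mapping plots to accessions.
#' @return data.frame: `plotId`, `scenario = "TS2"`, `datesUsed`
#'   (slash-separated), `fallback`, index columns.
#' @export
ts2 <- function(records, phenology, design) {
  records <- dropEmptyPlots(records)
  p <- designPlots(design)
  p <- p[!p$empty, , drop = FALSE]
  acc <- p$accessionId[match(records$plotId, p$plotId)]
  miss <- setdiff(unique(acc[!is.na(acc)]), phenology$accessionId)
  if (length(miss))
    stop("no phenology record for accession(s): ",
         paste(miss, collapse = ", "))
  i <- match(acc, phenology$accessionId)
  start <- phenology$anthesisStart[i]
  end <- phenology$anthesisEnd[i]
  vis <- viColumns(records)
  flights <- sort(unique(records$das))

  plots <- unique(records$plotId[!is.na(acc)])
  rows <- lapply(plots, function(pid) {
    k <- which(records$plotId == pid)
    w <- c(start[k[1L]], end[k[1L]])
    inWin <- flights[flights >= w[1L] & flights <= w[2L]]
    fallback <- FALSE
    if (!length(inWin)) {
      mid <- mean(w)
      below <- flights[flights < mid]
      above <- flights[flights >= mid]
      inWin <- c(if (length(below)) max(below),
                 if (length(above)) min(above))
      fallback <- TRUE
    }
    sel <- records[k, , drop = FALSE]
    sel <- sel[sel$das %in% inWin, , drop = FALSE]
    vals <- vapply(vis, function(v) {
      x <- sel[[v]]
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    }, 0)
    data.frame(plotId = pid, scenario = "TS2",
               datesUsed = paste(sort(inWin), collapse = "/"),
               fallback = fallback, t(vals), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$plotId, plots)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full-season temporal scenario (TS-3)
#'
#' Per plot, the unweighted mean of each index over all available flight
#' dates, ignoring missing values; the number of contributing dates is
#' recorded. Plots with all values missing yield missing output.
#'
#' @param records long plot table with `plotId`, `das` and index columns.
#' @return data.frame: `plotId`, `scenario = "TS3"`, `nDates`, index
#'   columns.
#' @export
ts3 <- function(records) {
  records <- dropEmptyPlots(records)
  vis <- viColumns(records)
  plots <- unique(records$plotId)
  rows <- lapply(plots, function(pid) {
    sel <- records[records$plotId == pid, , drop = FALSE]
    vals <- vapply(vis, function(v) {
      x <- sel[[v]]
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    }, 0)
    data.frame(plotId = pid, scenario = "TS3",
               nDates = sum(!is.na(sel[[vis[1L]]])),
               t(vals), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
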