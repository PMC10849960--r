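## Generic threshold-filter engine for metric tables: the computational
## gates (for example interface pAE < 10, mean pLDDT > 92, pTM > 0.8, RMSD
## to input < 1.75 A) applied to any numeric metric table, including
## externally computed network or energy metrics.

#' Apply strict threshold gates to a metric table
#'
#' Comparators are applied strictly as written: a record sitting exactly on
#' a "<" or ">" threshold fails. Every failed record lists all violated
#' gates; row order is preserved.
#'
#' @param records data.frame with a design id column and numeric metric
#'   columns.
#' @param gates data.frame with columns \code{metric}, \code{comparator}
#'   (one of "<", ">", "<=", ">=") and \code{threshold}.
#' @param idCol name of the design id column.
#' @return list with \code{passed} (data.frame) and \code{failed}
#'   (data.frame with an extra \code{reasons} column).
#' @examples
#' recs <- data.frame(design_id = c("d1", "d2"), pae = c(9, 10))
#' gates <- data.frame(metric = "pae", comparator = "<", threshold = 10)
#' applyGates(recs, gates)$failed$design_id
#' @export
applyGates <- function(records, gates, idCol = "design_id") {
  stopifnot(is.data.frame(records))
  if (is.null(gates) || nrow(gates) == 0)
    return(list(passed = records, failed = records[0, , drop = FALSE]))
  stopifnot(all(c("metric", "comparator", "threshold") %in% names(gates)))
  bad <- setdiff(gates$metric, names(records))
  if (length(bad))
    stop("metric(s) missing from records: ", paste(bad, collapse = ", "))
  reasons <- rep("", nrow(records))
  ok <- rep(TRUE, nrow(records))
  for (g in seq_len(nrow(gates))) {
    m <- gates$metric[g]; cmp <- gates$comparator[g]; th <- gates$threshold[g]
    v <- records[[m]]
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      id <- if (idCol %in% names(records)) records[[idCol]][i] else i
      stop("record ", id, " has no value for metric '", m, "'")
    }
    pass <- switch(cmp,
                   "<" = v < th, ">" = v > th,
                   "<=" = v <= th, ">=" = v >= th,
                   stop("unknown comparator: ", cmp))
    fail <- !pass
    reasons[fail] <- paste0(reasons[fail],
                            ifelse(nzchar(reasons[fail]), "; ", ""),
                            sprintf("%s %s %g violated (value %g)", m, cmp, th, v[fail]))
    ok <- ok & pass
  }
  failed <- records[!ok, , drop = FALSE]
  if (nrow(failed)) failed$reasons <- reasons[!ok]
  else failed$reasons <- character(0)
  list(passed = records[ok, , drop = FALSE], failed = failed)
}

#' Rank records by a key metric and keep the top n
#'
#' Stable sort on the key; ties broken by design id. Returns exactly
#' min(n, nrow) rows.
#'
#' @param records data.frame of metric records.
#' @param key name of the metric column to rank on.
#' @param n number of rows to keep.
#' @param decreasing rank direction (TRUE: larger is better).
#' @param idCol design id column used for tie-breaking.
#' @return data.frame of the top-n records.
#' @export
rankAndTake <- function(records, key, n, decreasing = TRUE, idCol = "design_id") {
  if (!key %in% names(records)) stop("key metric '", key, "' not in records")
  keyv <- records[[key]]
  tie <- if (idCol %in% names(records)) records[[idCol]] else seq_len(nrow(records))
  ord <- order(if (decreasing) -xtfrm(keyv) else xtfrm(keyv), tie)
  records[ord[seq_len(min(n, nrow(records)))], , drop = FALSE]
}

#' Read gate definitions from a config file
#'
#' YAML list of records with fields metric, comparator, threshold.
#'
#' @param path file path.
#' @return data.frame of gates as used by \code{\link{applyGates}}.
#' @export
readGates <- function(path) {
  g <- yaml::read_yaml(path)
  do.call(rbind, lapply(g, function(x)
    data.frame(metric = x$metric, comparator = x$comparator,
               threshold = as.numeric(x$threshold))))
}
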