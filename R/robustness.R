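## Jackknife (leave-one-species-out) robustness of the top-position set.

#' Jackknife the top response-determining positions
#'
#' Recomputes the top-k column set once per receptor, with that receptor's
#' sequence and response row removed, then summarizes (i) how often each
#' column appears across the recalculated top sets and (ii) how many of the
#' full-dataset top-k are retained in each recalculation.
#'
#' @param aln An \code{OrthologAlignment} (at least 4 receptors, so that each
#'   reduction still supports ranking).
#' @param m A \code{ResponseMatrix} over the same receptors.
#' @param k Top-set size (default 20).
#' @param minPairs Eligibility threshold for the ranking.
#' @return A \code{\linkS4class{JackknifeResult}}. Frequency ties straddling
#'   rank k are broken by the full-dataset score, then by reference index,
#'   then column.
#' @export
jackknifeTopPositions <- function(aln, m, k = 20L, minPairs = 1L) {
  checkReceptorsMatch(aln, m)
  ids <- receptorIds(aln)
  if (length(ids) < 4L)
    stop("jackknife requires at least 4 receptors")
  full <- rankPositions(aln, m, k = k, minPairs = minPairs)
  originalTop <- topPositions(full)

  perExclusion <- stats::setNames(vector("list", length(ids)), ids)
  retention <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  for (id in ids) {
    redAln <- dropReceptor(aln, id)
    redM <- ResponseMatrix(m@values[setdiff(ids, id), , drop = FALSE])
    top <- tryCatch(topPositions(rankPositions(redAln, redM, k = k,
                                               minPairs = minPairs)),
                    error = function(e) NULL)
    perExclusion[[id]] <- top
    if (!is.null(top))
      retention[[id]] <- length(intersect(top, originalTop))
  }

  counts <- table(unlist(perExclusion))
  fullTab <- scoreTable(full)
  L <- nrow(fullTab)
  count <- integer(L)
  count[as.integer(names(counts))] <- as.integer(counts)
  freqTab <- data.frame(column = fullTab$column, refIndex = fullTab$refIndex,
                        count = count, fullScore = fullTab$score)
  tieScore <- ifelse(is.na(freqTab$fullScore), -Inf, freqTab$fullScore)
  tieRef <- ifelse(is.na(freqTab$refIndex), Inf, freqTab$refIndex)
  ord <- order(-freqTab$count, -tieScore, tieRef, freqTab$column)
  freqTab <- freqTab[ord, , drop = FALSE]
  rownames(freqTab) <- NULL
  seen <- freqTab$column[freqTab$count > 0L]
  frequencyTop <- freqTab$column[seq_len(min(as.integer(k), length(seen)))]

  new("JackknifeResult", originalTop = originalTop,
      perExclusion = perExclusion, frequencyTable = freqTab,
      frequencyTop = as.integer(frequencyTop),
      retention = retention,
      meanRetention = mean(retention, na.rm = TRUE), k = as.integer(k))
}

#' Concordance between frequency-ranked and original top positions
#'
#' @param r A \code{JackknifeResult}.
#' @return List with \code{matched} (size of the intersection between the k
#'   most frequent jackknife positions and the full-dataset top-k) and
#'   \code{k}.
#' @export
frequencyConcordance <- function(r) {
  stopifnot(is(r, "JackknifeResult"))
  list(matched = length(intersect(r@frequencyTop, r@originalTop)), k = r@k)
}

#' Write jackknife results to TSV and JSON
#'
#' @param r A \code{JackknifeResult}.
#' @param tsvPath Path for the frequency table TSV; a second file with
#'   suffix \code{.retention.tsv} receives the per-exclusion retention.
#' @param jsonPath Optional JSON summary path.
#' @return Invisibly, \code{tsvPath}.
#' @export
writeJackknife <- function(r, tsvPath, jsonPath = NULL) {
  stopifnot(is(r, "JackknifeResult"))
  ft <- r@frequencyTable
  ft$fullScore <- formatNum(ft$fullScore)
  utils::write.table(ft, tsvPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  ret <- data.frame(excludedReceptor = names(r@retention),
                    retention = as.integer(r@retention))
  utils::write.table(ret, sub("\\.tsv$", ".retention.tsv", tsvPath),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  if (!is.null(jsonPath)) {
    fc <- frequencyConcordance(r)
    jsonlite::write_json(
      list(k = r@k, matched = fc$matched, meanRetention = r@meanRetention,
           retention = as.list(r@retention), originalTop = r@originalTop,
           frequencyTop = r@frequencyTop),
      jsonPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(tsvPath)
}
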