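#' Receptor labels of an object
#'
#' @param x An \code{OrthologAlignment} or \code{ResponseMatrix}.
#' @return Character vector of receptor/species labels, in storage order.
#' @examples
#' aln <- OrthologAlignment(c(a = "MAKG", b = "MVKG"), referenceId = "a")
#' receptorIds(aln)
#' @export
setGeneric("receptorIds", function(x) standardGeneric("receptorIds"))

#' @rdname receptorIds
#' @export
setMethod("receptorIds", "OrthologAlignment", function(x) names(x@seqs))

#' @rdname receptorIds
#' @export
setMethod("receptorIds", "ResponseMatrix", function(x) rownames(x@values))

#' Reference record label of an alignment
#' @param x An \code{OrthologAlignment}.
#' @return Character scalar.
#' @export
setGeneric("referenceId", function(x) standardGeneric("referenceId"))

#' @rdname referenceId
#' @export
setMethod("referenceId", "OrthologAlignment", function(x) x@referenceId)

#' Number of alignment columns
#' @param x An \code{OrthologAlignment}.
#' @return Integer scalar.
#' @export
setGeneric("alignmentLength", function(x) standardGeneric("alignmentLength"))

#' @rdname alignmentLength
#' @export
setMethod("alignmentLength", "OrthologAlignment",
          function(x) Biostrings::width(x@seqs)[1L])

#' Aligned sequences of an alignment
#' @param x An \code{OrthologAlignment}.
#' @return The underlying \code{\link[Biostrings]{AAStringSet}}.
#' @export
setGeneric("alignedSeqs", function(x) standardGeneric("alignedSeqs"))

#' @rdname alignedSeqs
#' @export
setMethod("alignedSeqs", "OrthologAlignment", function(x) x@seqs)

#' Odorant labels of a response matrix
#' @param x A \code{ResponseMatrix}.
#' @return Character vector.
#' @export
setGeneric("odorantIds", function(x) standardGeneric("odorantIds"))

#' @rdname odorantIds
#' @export
setMethod("odorantIds", "ResponseMatrix", function(x) colnames(x@values))

#' Response values as a plain matrix
#' @param x A \code{ResponseMatrix}.
#' @return Numeric matrix (receptors by odorants, spikes; NA = missing).
#' @export
setGeneric("responseValues", function(x) standardGeneric("responseValues"))

#' @rdname responseValues
#' @export
setMethod("responseValues", "ResponseMatrix", function(x) x@values)

#' Residue indices present in a structure model
#' @param x A \code{StructureModel}.
#' @return Integer vector of reference residue indices.
#' @export
setGeneric("refIndices", function(x) standardGeneric("refIndices"))

#' @rdname refIndices
#' @export
setMethod("refIndices", "StructureModel",
          function(x) as.integer(rownames(x@coords)))

#' Residue coordinates of a structure model
#' @param x A \code{StructureModel}.
#' @return Numeric n-by-3 matrix in Angstroms, rownames = residue indices.
#' @export
setGeneric("residueCoords", function(x) standardGeneric("residueCoords"))

#' @rdname residueCoords
#' @export
setMethod("residueCoords", "StructureModel", function(x) x@coords)

#' Top-ranked alignment columns
#' @param x A \code{PositionScoreTable} or \code{JackknifeResult}.
#' @return Integer vector of alignment columns, best first (for a
#'   \code{JackknifeResult}, the full-dataset top set).
#' @export
setGeneric("topPositions", function(x) standardGeneric("topPositions"))

#' @rdname topPositions
#' @export
setMethod("topPositions", "PositionScoreTable", function(x) x@topK)

#' @rdname topPositions
#' @export
setMethod("topPositions", "JackknifeResult", function(x) x@originalTop)

#' Full per-column score table
#' @param x A \code{PositionScoreTable}.
#' @return \code{data.frame}, one row per alignment column.
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' @rdname scoreTable
#' @export
setMethod("scoreTable", "PositionScoreTable", function(x) x@table)

#' Per-entry prediction results
#' @param x A \code{PredictionReport}.
#' @return \code{data.frame}, one row per (held-out receptor, odorant).
#' @export
setGeneric("predictionEntries", function(x) standardGeneric("predictionEntries"))

#' @rdname predictionEntries
#' @export
setMethod("predictionEntries", "PredictionReport", function(x) x@entries)

#' Summary statistics of a prediction report
#' @param x A \code{PredictionReport}.
#' @return Named list (overall mean errors and improvements).
#' @export
setGeneric("predictionSummary", function(x) standardGeneric("predictionSummary"))

#' @rdname predictionSummary
#' @export
setMethod("predictionSummary", "PredictionReport", function(x) x@summary)

setMethod("show", "OrthologAlignment", function(object) {
  cat("OrthologAlignment with", length(object@seqs), "records,",
      alignmentLength(object), "columns\n")
  cat("  reference:", object@referenceId, "\n")
  cat("  receptors:", paste(utils::head(receptorIds(object), 6), collapse = ", "),
      if (length(object@seqs) > 6) "..." else "", "\n")
})

setMethod("show", "ResponseMatrix", function(object) {
  v <- object@values
  cat("ResponseMatrix:", nrow(v), "receptors x", ncol(v), "odorants",
      sprintf("(%d missing)\n", sum(is.na(v))))
  cat(sprintf("  mean +/- SD = %.2f +/- %.2f spikes\n",
              mean(v, na.rm = TRUE), stats::sd(v, na.rm = TRUE)))
})

setMethod("show", "StructureModel", function(object) {
  cat("StructureModel: chain", object@chainId, "with",
      nrow(object@coords), "residues\n")
})

setMethod("show", "PositionScoreTable", function(object) {
  t <- object@table
  cat("PositionScoreTable:", nrow(t), "columns scored,",
      sum(t$eligible), "eligible; k =", object@k, "\n")
  top <- t[t$inTopK, , drop = FALSE]
  top <- top[order(top$rank), c("column", "refIndex", "score", "rank")]
  print(utils::head(top, 10), row.names = FALSE)
  if (nrow(top) > 10) cat("  ...\n")
})

setMethod("show", "PredictionReport", function(object) {
  s <- object@summary
  cat("PredictionReport over", length(unique(object@entries$heldoutId)),
      "held-out receptors\n")
  cat(sprintf("  mean D_Pred  = %.2f spikes\n", s$meanDPred))
  cat(sprintf("  mean D_Ctrl  = %.2f spikes\n", s$meanDCtrl))
  cat(sprintf("  improvement  = %.1f%% (overall means), %.1f%% (mean per receptor)\n",
              s$improvementPercent, s$meanPerReceptorImprovement))
})

setMethod("show", "JackknifeResult", function(object) {
  cat("JackknifeResult: k =", object@k, ",",
      length(object@perExclusion), "exclusions\n")
  cat(sprintf("  mean retention = %.2f / %d\n",
              object@meanRetention, object@k))
  cat("  frequency-top matches original:",
      length(intersect(object@frequencyTop, object@originalTop)), "/",
      object@k, "\n")
})

setMethod("show", "NeighborhoodEnrichment", function(object) {
  seed <- if (is.na(object@seedRefIndex)) "none (union/parameters-only)"
          else object@seedRefIndex
  cat("NeighborhoodEnrichment: seed", seed,
      if (!is.na(object@radius)) sprintf("(radius %.1f A)", object@radius),
      "\n")
  cat(sprintf("  overlap %d of n = %d (expected %.2f; N = %d, K = %d)\n",
              object@kOverlap, object@n, object@expected, object@N, object@K))
  cat(sprintf("  P(X >= %d) = %.3g\n", object@kOverlap, object@pValue))
})

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset with planted positions:",
      paste(object@truth$plantedPositions, collapse = ", "), "\n")
  show(object@alignment)
  show(object@responses)
})
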