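#' @import methods
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet width
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' Aligned orthologous receptor sequences
#'
#' An \code{OrthologAlignment} holds a protein multiple sequence alignment of
#' orthologous receptors, one record per species, together with the identity
#' of a designated reference record. All coordinates reported by the package
#' (alignment columns and reference residue indices) are 1-based; gaps are
#' \code{"-"}.
#'
#' @slot seqs An \code{\link[Biostrings]{AAStringSet}} of equal-width aligned
#'   sequences, named by receptor/species label.
#' @slot referenceId Character scalar; the name of the reference record whose
#'   ungapped numbering is used for reporting residue positions.
#'
#' @seealso \code{\link{readAlignment}}, \code{\link{buildReferenceMap}},
#'   \code{\link{pairwiseIdentity}}
#' @export
setClass("OrthologAlignment",
  slots = c(seqs = "AAStringSet", referenceId = "character"))

setValidity("OrthologAlignment", function(object) {
  s <- object@seqs
  msg <- character()
  if (length(s) < 1L) msg <- c(msg, "alignment must contain at least one record")
  ids <- names(s)
  if (is.null(ids) || any(!nzchar(ids)))
    msg <- c(msg, "all records must have non-empty names")
  else if (anyDuplicated(ids))
    msg <- c(msg, "receptor ids must be unique")
  if (length(s) >= 1L && length(unique(Biostrings::width(s))) > 1L)
    msg <- c(msg, "aligned sequences must all have the same length")
  if (length(object@referenceId) != 1L || !(object@referenceId %in% ids))
    msg <- c(msg, "referenceId must name one of the records")
  if (length(s) >= 1L) {
    chars <- strsplit(as.character(s), "", fixed = TRUE)
    if (any(vapply(chars, function(x) all(x == "-"), logical(1))))
      msg <- c(msg, "every record must contain at least one non-gap residue")
  }
  if (length(msg)) msg else TRUE
})

#' Receptor-by-odorant response matrix
#'
#' Physiological responses (spikes) of each receptor to each odorant.
#' Rows are receptors, columns odorants; \code{NA} marks a missing
#' measurement. Every receptor must have at least one measured response.
#'
#' @slot values Numeric matrix with unique, non-empty row (receptor) and
#'   column (odorant) names; entries in spikes, \code{NA} allowed.
#'
#' @seealso \code{\link{readResponseMatrix}}, \code{\link{responseDistance}}
#' @export
setClass("ResponseMatrix", slots = c(values = "matrix"))

setValidity("ResponseMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  rn <- rownames(v); cn <- colnames(v)
  if (is.null(rn) || any(!nzchar(rn)) || anyDuplicated(rn))
    msg <- c(msg, "receptor (row) names must be unique and non-empty")
  if (is.null(cn) || any(!nzchar(cn)) || anyDuplicated(cn))
    msg <- c(msg, "odorant (column) names must be unique and non-empty")
  if (nrow(v) < 1L || ncol(v) < 1L)
    msg <- c(msg, "matrix must have at least one receptor and one odorant")
  else if (any(rowSums(!is.na(v)) == 0L))
    msg <- c(msg, "every receptor must have at least one non-missing response")
  if (length(msg)) msg else TRUE
})

#' Residue-level structural model
#'
#' One representative (alpha-carbon) coordinate per residue of the reference
#' receptor, in Angstroms. Residue numbering is reference numbering.
#'
#' @slot coords Numeric n-by-3 matrix of coordinates; rownames are the
#'   1-based reference residue indices.
#' @slot chainId Character scalar chain label.
#'
#' @seealso \code{\link{readStructure}}, \code{\link{residueNeighborhood}}
#' @export
setClass("StructureModel", slots = c(coords = "matrix", chainId = "character"))

setValidity("StructureModel", function(object) {
  co <- object@coords
  msg <- character()
  if (!is.numeric(co) || ncol(co) != 3L)
    msg <- c(msg, "coords must be a numeric n-by-3 matrix")
  if (any(!is.finite(co))) msg <- c(msg, "coordinates must be finite")
  idx <- suppressWarnings(as.integer(rownames(co)))
  if (is.null(rownames(co)) || any(is.na(idx)))
    msg <- c(msg, "rownames must be integer reference residue indices")
  else {
    if (anyDuplicated(idx)) msg <- c(msg, "residue indices must be unique")
    if (any(idx < 1L)) msg <- c(msg, "residue indices must be >= 1")
  }
  if (length(object@chainId) != 1L) msg <- c(msg, "chainId must be a scalar")
  if (length(msg)) msg else TRUE
})

#' Per-column response-determination scores
#'
#' The scored alignment columns produced by \code{\link{rankPositions}}.
#' The score of a column is the mean pairwise response distance among
#' receptor pairs that differ at the column minus the mean among pairs that
#' match, in spikes; large positive scores mark columns whose residue
#' identity predicts response similarity.
#'
#' @slot table \code{data.frame} with one row per alignment column:
#'   \code{column}, \code{refIndex} (NA where the reference is gapped),
#'   \code{score}, \code{nMatchPairs}, \code{nMismatchPairs},
#'   \code{eligible}, \code{rank} (NA for ineligible), \code{inTopK}.
#' @slot topK Integer vector of alignment columns, best first.
#' @slot k Integer; the requested top-set size.
#' @export
setClass("PositionScoreTable",
  slots = c(table = "data.frame", topK = "integer", k = "integer"))

setValidity("PositionScoreTable", function(object) {
  msg <- character()
  need <- c("column", "refIndex", "score", "nMatchPairs", "nMismatchPairs",
            "eligible", "rank", "inTopK")
  if (!all(need %in% names(object@table)))
    msg <- c(msg, "table is missing required columns")
  else {
    elig <- object@table$column[object@table$eligible]
    if (!all(object@topK %in% elig))
      msg <- c(msg, "topK must be a subset of eligible columns")
    if (length(object@topK) != min(object@k, length(elig)))
      msg <- c(msg, "topK must have min(k, #eligible) entries")
  }
  if (length(msg)) msg else TRUE
})

#' Leave-one-receptor-out prediction report
#'
#' One entry per (held-out receptor, odorant): actual and predicted
#' responses, the mean shuffled-control prediction, and the absolute errors
#' dPred = |predicted - actual| and dCtrl (mean absolute error of the
#' shuffled control), all in spikes. \code{delta = dPred - dCtrl}; negative
#' delta means the sequence-informed prediction beat the control.
#'
#' @slot entries \code{data.frame} with columns \code{heldoutId},
#'   \code{odorantId}, \code{actual}, \code{predicted}, \code{control},
#'   \code{dPred}, \code{dCtrl}, \code{delta}.
#' @slot perReceptor \code{data.frame} of per-held-out-receptor averages.
#' @slot perOdorant \code{data.frame} of per-odorant averages.
#' @slot summary List with \code{meanDPred}, \code{meanDCtrl},
#'   \code{improvementPercent} (from the overall means),
#'   \code{meanPerReceptorImprovement} (mean of per-receptor improvements),
#'   \code{nMissingPredictions}, \code{k}, \code{nShuffles}, \code{seed}.
#' @export
setClass("PredictionReport",
  slots = c(entries = "data.frame", perReceptor = "data.frame",
            perOdorant = "data.frame", summary = "list"))

setValidity("PredictionReport", function(object) {
  e <- object@entries
  msg <- character()
  need <- c("heldoutId", "odorantId", "actual", "predicted", "control",
            "dPred", "dCtrl", "delta")
  if (!all(need %in% names(e)))
    msg <- c(msg, "entries is missing required columns")
  else {
    if (any(e$dPred < 0, na.rm = TRUE) || any(e$dCtrl < 0, na.rm = TRUE))
      msg <- c(msg, "absolute errors must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Jackknife robustness of the top-position set
#'
#' Leave-one-species-out recalculations of the top-K response-determining
#' positions: which positions recur across recalculations, and how many of
#' the original top-K are retained in each.
#'
#' @slot originalTop Integer vector; top-K columns from the full dataset.
#' @slot perExclusion Named list; for each excluded receptor the recalculated
#'   top-K column vector (or NULL if the reduced ranking failed).
#' @slot frequencyTable \code{data.frame} with \code{column},
#'   \code{refIndex}, \code{count} (appearances among recalculated top-K
#'   sets), \code{fullScore}, sorted by decreasing count.
#' @slot frequencyTop Integer vector; the K most frequent positions.
#' @slot retention Named integer vector; per-exclusion overlap with
#'   \code{originalTop} (NA where the reduced ranking failed).
#' @slot meanRetention Numeric; mean of the defined retentions.
#' @slot k Integer.
#' @export
setClass("JackknifeResult",
  slots = c(originalTop = "integer", perExclusion = "list",
            frequencyTable = "data.frame", frequencyTop = "integer",
            retention = "integer", meanRetention = "numeric", k = "integer"))

setValidity("JackknifeResult", function(object) {
  msg <- character()
  if (any(object@retention > object@k, na.rm = TRUE))
    msg <- c(msg, "retention cannot exceed k")
  ok <- !is.na(object@retention)
  if (any(object@retention[ok] < 0L))
    msg <- c(msg, "retention must be non-negative")
  if (any(object@frequencyTable$count > length(object@perExclusion)))
    msg <- c(msg, "frequency counts cannot exceed the number of exclusions")
  if (length(msg)) msg else TRUE
})

#' Structural-neighborhood enrichment of top positions
#'
#' The overlap between a fixed-radius residue neighborhood on the receptor
#' structure and the set of top response-determining positions, with its
#' expectation under random placement and an exact upper-tail hypergeometric
#' p-value.
#'
#' @slot seedRefIndex Integer; seed residue (reference numbering), NA for a
#'   union or parameters-only test.
#' @slot radius Numeric; neighborhood radius in Angstroms (NA when
#'   parameters-only).
#' @slot neighborhood Integer vector of member residues (empty when
#'   parameters-only).
#' @slot n Integer; neighborhood size.
#' @slot kOverlap Integer; members that are top positions.
#' @slot N Integer; protein length (population).
#' @slot K Integer; number of top positions.
#' @slot expected Numeric; n*K/N.
#' @slot pValue Numeric; P(X >= kOverlap), hypergeometric.
#' @export
setClass("NeighborhoodEnrichment",
  slots = c(seedRefIndex = "integer", radius = "numeric",
            neighborhood = "integer", n = "integer", kOverlap = "integer",
            N = "integer", K = "integer", expected = "numeric",
            pValue = "numeric"))

setValidity("NeighborhoodEnrichment", function(object) {
  msg <- character()
  if (object@kOverlap < 0L || object@kOverlap > min(object@n, object@K))
    msg <- c(msg, "kOverlap must lie in [0, min(n, K)]")
  if (length(object@neighborhood)) {
    if (object@n != length(object@neighborhood))
      msg <- c(msg, "n must equal the neighborhood size")
    if (!is.na(object@seedRefIndex) &&
        !(object@seedRefIndex %in% object@neighborhood))
      msg <- c(msg, "seed residue must belong to its own neighborhood")
  }
  if (!isTRUE(all.equal(object@expected,
                        object@n * object@K / object@N, tolerance = 1e-12)))
    msg <- c(msg, "expected must equal n*K/N")
  if (!(object@pValue > 0 && object@pValue <= 1))
    msg <- c(msg, "pValue must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Synthetic benchmark dataset
#'
#' Alignment, response matrix and structure generated with planted
#' response-determining positions and known noise, plus the ground truth.
#'
#' @slot alignment \code{OrthologAlignment}.
#' @slot responses \code{ResponseMatrix}.
#' @slot structure \code{StructureModel}.
#' @slot truth List: \code{plantedPositions} (reference indices),
#'   \code{backgroundPositions}, \code{beta} (effect array), \code{config}.
#' @export
setClass("SyntheticDataset",
  slots = c(alignment = "OrthologAlignment", responses = "ResponseMatrix",
            structure = "StructureModel", truth = "list"))
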