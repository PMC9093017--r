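## Scoring of alignment columns for response determination.
##
## The score of a column is the difference between the mean pairwise response
## distance of receptor pairs that DIFFER at the column and the mean of pairs
## that MATCH. Columns where residue identity tracks response similarity get
## large positive scores (in spikes).

#' Response distance between two receptors
#'
#' Mean absolute difference of responses over the odorants measured in both
#' receptors, in spikes.
#'
#' @param m A \code{ResponseMatrix}.
#' @param i,j Receptor ids (distinct).
#' @return Non-negative numeric scalar.
#' @examples
#' m <- ResponseMatrix(matrix(c(100, 0, 0, 100), 2, 2,
#'   dimnames = list(c("a", "b"), c("o1", "o2"))))
#' responseDistance(m, "a", "b")  # 100
#' @export
responseDistance <- function(m, i, j) {
  stopifnot(is(m, "ResponseMatrix"))
  if (identical(i, j)) stop("i and j must be distinct receptors")
  v <- m@values
  if (!i %in% rownames(v) || !j %in% rownames(v))
    stop("lookup error: unknown receptor id")
  shared <- !is.na(v[i, ]) & !is.na(v[j, ])
  if (!any(shared))
    stop("undefined distance: receptors '", i, "' and '", j,
         "' share no measured odorant")
  mean(abs(v[i, shared] - v[j, shared]))
}

## all-pairs distance matrix; NA where a pair shares no measured odorant
pairDistanceMatrix <- function(values) {
  n <- nrow(values)
  D <- matrix(NA_real_, n, n, dimnames = list(rownames(values),
                                              rownames(values)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      shared <- !is.na(values[i, ]) & !is.na(values[j, ])
      if (any(shared))
        D[i, j] <- D[j, i] <- mean(abs(values[i, shared] - values[j, shared]))
    }
  }
  diag(D) <- 0
  D
}

## residues of two receptors at a column count as a "match" only if both are
## non-gap, equal, and not the unknown letter X
scoreOneColumn <- function(resid, D, ii, jj, minPairs) {
  okI <- resid[ii] != "-"; okJ <- resid[jj] != "-"
  valid <- okI & okJ & !is.na(D[cbind(ii, jj)])
  if (!any(valid))
    return(list(score = NA_real_, nMatch = 0L, nMismatch = 0L,
                eligible = FALSE))
  eq <- resid[ii] == resid[jj] & resid[ii] != "X"
  mIdx <- valid & eq
  xIdx <- valid & !eq
  nM <- sum(mIdx); nX <- sum(xIdx)
  eligible <- nM >= minPairs && nX >= minPairs
  score <- if (eligible)
    mean(D[cbind(ii[xIdx], jj[xIdx])]) - mean(D[cbind(ii[mIdx], jj[mIdx])])
  else NA_real_
  list(score = score, nMatch = nM, nMismatch = nX, eligible = eligible)
}

#' Score a single alignment column
#'
#' Over all unordered receptor pairs with non-gap residues at the column,
#' pairs are split into matches (identical residues) and mismatches; the
#' score is mean mismatch-pair response distance minus mean match-pair
#' response distance. A column is eligible only if both sets are populated.
#'
#' @param aln An \code{OrthologAlignment}.
#' @param m A \code{ResponseMatrix} over the same receptors.
#' @param column Alignment column index (1-based).
#' @param minPairs Minimum matched and mismatched pair count for eligibility
#'   (default 1).
#' @return List with \code{score} (spikes; NA if ineligible),
#'   \code{nMatchPairs}, \code{nMismatchPairs}, \code{eligible}.
#' @export
positionScore <- function(aln, m, column, minPairs = 1L) {
  checkReceptorsMatch(aln, m)
  sm <- seqMatrix(aln)
  if (column < 1L || column > ncol(sm)) stop("column out of range")
  v <- m@values[rownames(sm), , drop = FALSE]
  D <- pairDistanceMatrix(v)
  n <- nrow(sm)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  r <- scoreOneColumn(sm[, column], D, pr[, 1], pr[, 2], minPairs)
  list(score = r$score, nMatchPairs = r$nMatch,
       nMismatchPairs = r$nMismatch, eligible = r$eligible)
}

checkReceptorsMatch <- function(aln, m) {
  stopifnot(is(aln, "OrthologAlignment"), is(m, "ResponseMatrix"))
  if (!setequal(receptorIds(aln), receptorIds(m)))
    stop("receptor sets of the alignment and the response matrix differ")
  invisible(TRUE)
}

#' Rank alignment columns by response determination
#'
#' Scores every column (see \code{\link{positionScore}}) and selects the
#' top-k eligible columns. Ties are broken by smaller reference residue
#' index, then smaller column index; columns where the reference is gapped
#' sort after mapped columns at equal score.
#'
#' @param aln An \code{OrthologAlignment} (at least 3 receptors).
#' @param m A \code{ResponseMatrix} over the same receptors.
#' @param k Size of the top set (default 20).
#' @param minPairs Eligibility threshold passed to the column scorer.
#' @return A \code{\linkS4class{PositionScoreTable}}.
#' @examples
#' aln <- OrthologAlignment(c(r1 = "MAKG", r2 = "MAKG",
#'                            r3 = "MVKG", r4 = "MVKG"), referenceId = "r1")
#' m <- ResponseMatrix(matrix(c(100, 100, 0, 0, 0, 0, 100, 100), 4, 2,
#'   dimnames = list(paste0("r", 1:4), c("o1", "o2"))))
#' topPositions(rankPositions(aln, m, k = 1))  # column 2
#' @export
rankPositions <- function(aln, m, k = 20L, minPairs = 1L) {
  checkReceptorsMatch(aln, m)
  if (length(receptorIds(aln)) < 3L)
    stop("ranking requires at least 3 receptors")
  sm <- seqMatrix(aln)
  v <- m@values[rownames(sm), , drop = FALSE]
  D <- pairDistanceMatrix(v)
  n <- nrow(sm)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ii <- pr[, 1]; jj <- pr[, 2]
  L <- ncol(sm)
  refMap <- buildReferenceMap(aln)$columnToRef

  score <- rep(NA_real_, L)
  nMatch <- nMismatch <- integer(L)
  eligible <- logical(L)
  for (c in seq_len(L)) {
    r <- scoreOneColumn(sm[, c], D, ii, jj, minPairs)
    score[c] <- r$score; nMatch[c] <- r$nMatch
    nMismatch[c] <- r$nMismatch; eligible[c] <- r$eligible
  }
  if (!any(eligible))
    stop("ranking error: no eligible column (no column varies across receptors)")

  eligCols <- which(eligible)
  tieRef <- ifelse(is.na(refMap[eligCols]), Inf, refMap[eligCols])
  ord <- eligCols[order(-score[eligCols], tieRef, eligCols)]
  kEff <- min(as.integer(k), length(ord))
  topK <- ord[seq_len(kEff)]

  rank <- rep(NA_integer_, L)
  rank[ord] <- seq_along(ord)
  tab <- data.frame(column = seq_len(L), refIndex = refMap, score = score,
                    nMatchPairs = nMatch, nMismatchPairs = nMismatch,
                    eligible = eligible, rank = rank,
                    inTopK = seq_len(L) %in% topK)
  new("PositionScoreTable", table = tab, topK = as.integer(topK),
      k = as.integer(k))
}

#' Write a position score table to TSV
#'
#' @param pst A \code{PositionScoreTable}.
#' @param path Output path.
#' @param aln Optional alignment; if given, a residue-profile column (the
#'   residues observed at each column) is included.
#' @return Invisibly, \code{path}.
#' @export
writePositionTable <- function(pst, path, aln = NULL) {
  stopifnot(is(pst, "PositionScoreTable"))
  tab <- pst@table
  if (!is.null(aln)) {
    sm <- seqMatrix(aln)
    tab$residueProfile <- apply(sm, 2, paste0, collapse = "")
  }
  tab$score <- formatNum(tab$score)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
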