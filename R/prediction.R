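## Leave-one-receptor-out response prediction from sequence similarity at the
## top response-determining positions, with a permutation (shuffled) control.

#' Sequence similarity restricted to a position set
#'
#' Fraction of the given alignment columns at which two receptors carry
#' identical residues, among columns where both are non-gap; 0 if no column
#' qualifies. \code{"X"} matches nothing.
#'
#' @param aln An \code{OrthologAlignment}.
#' @param positions Integer vector of alignment columns (non-empty).
#' @param a,b Receptor ids.
#' @return Numeric in [0, 1].
#' @export
similarityAtPositions <- function(aln, positions, a, b) {
  stopifnot(is(aln, "OrthologAlignment"), length(positions) >= 1L)
  sm <- seqMatrix(aln)
  ra <- sm[a, positions]; rb <- sm[b, positions]
  ok <- ra != "-" & rb != "-"
  if (!any(ok)) return(0)
  sum(ra[ok] == rb[ok] & ra[ok] != "X") / sum(ok)
}

## similarity of one receptor to each of several others, vectorized
similarityVector <- function(sm, positions, heldoutId, trainIds) {
  rh <- sm[heldoutId, positions, drop = TRUE]
  vapply(trainIds, function(t) {
    rt <- sm[t, positions, drop = TRUE]
    ok <- rh != "-" & rt != "-"
    if (!any(ok)) return(0)
    sum(rh[ok] == rt[ok] & rh[ok] != "X") / sum(ok)
  }, numeric(1))
}

## Weighted-mean prediction over training rows, one odorant at a time.
## Zero total weight (or zero-weight on all measured rows) falls back to the
## unweighted mean of the measured training responses.
predictWithWeights <- function(trainValues, w) {
  vapply(seq_len(ncol(trainValues)), function(o) {
    y <- trainValues[, o]
    avail <- !is.na(y)
    if (!any(avail)) return(NA_real_)
    ws <- sum(w[avail])
    if (ws == 0) mean(y[avail]) else sum(w[avail] * y[avail]) / ws
  }, numeric(1))
}

#' Predict a held-out receptor's odorant responses
#'
#' Each odorant response is predicted as the similarity-weighted mean of the
#' training receptors' responses, with weights
#' \code{similarityAtPositions(heldout, j)^alpha}. Training receptors missing
#' an odorant are excluded for that odorant; if every available weight is
#' zero the unweighted training mean is used; an odorant with no training
#' measurement yields NA.
#'
#' @param aln An \code{OrthologAlignment}.
#' @param m A \code{ResponseMatrix} over the same receptors.
#' @param positions Alignment columns carrying the predictive signal.
#' @param heldoutId Receptor to predict (its responses are not used).
#' @param alpha Weight exponent (default 1).
#' @return Named numeric vector of predicted responses (spikes), one per
#'   odorant.
#' @export
predictResponse <- function(aln, m, positions, heldoutId, alpha = 1) {
  checkReceptorsMatch(aln, m)
  ids <- receptorIds(aln)
  if (!heldoutId %in% ids) stop("lookup error: unknown held-out receptor")
  trainIds <- sort(setdiff(ids, heldoutId))
  if (length(trainIds) < 2L)
    stop("insufficient data: need at least 2 training receptors")
  sm <- seqMatrix(aln)
  w <- similarityVector(sm, positions, heldoutId, trainIds)^alpha
  trainValues <- m@values[trainIds, , drop = FALSE]
  pred <- predictWithWeights(trainValues, w)
  names(pred) <- odorantIds(m)
  pred
}

## all permutations of 1..n (n small), one per row
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                         drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

#' Shuffled-control prediction for a held-out receptor
#'
#' The sequence-to-response linkage of the training set is destroyed by
#' permuting the assignment of training response rows to training sequences;
#' prediction is re-run for each permutation. When the number of training
#' receptors is small enough that all permutations fit within
#' \code{nShuffles} (or \code{exhaustive = TRUE}), every permutation is
#' enumerated exactly once; otherwise \code{nShuffles} uniform random
#' permutations are drawn from the seeded generator.
#'
#' @inheritParams predictResponse
#' @param nShuffles Number of Monte-Carlo permutations (default 1000).
#' @param seed Integer seed.
#' @param exhaustive Force exact enumeration of all permutations.
#' @return List with \code{control} (mean shuffled prediction per odorant),
#'   \code{dCtrl} (mean absolute error of shuffled predictions vs the actual
#'   responses per odorant) and \code{nShufflesUsed}.
#' @export
shuffledControl <- function(aln, m, positions, heldoutId, nShuffles = 1000L,
                            seed = 1L, alpha = 1, exhaustive = FALSE) {
  checkReceptorsMatch(aln, m)
  ids <- receptorIds(aln)
  trainIds <- sort(setdiff(ids, heldoutId))
  if (length(trainIds) < 2L)
    stop("insufficient data: need at least 2 training receptors")
  sm <- seqMatrix(aln)
  w <- similarityVector(sm, positions, heldoutId, trainIds)^alpha
  trainValues <- m@values[trainIds, , drop = FALSE]
  actual <- m@values[heldoutId, ]
  nT <- length(trainIds)

  nPerm <- factorial(nT)
  if (exhaustive || nPerm <= nShuffles) {
    perms <- allPermutations(nT)
  } else {
    set.seed(seed)
    perms <- t(vapply(seq_len(nShuffles), function(s) sample.int(nT),
                      integer(nT)))
  }

  preds <- matrix(NA_real_, nrow(perms), ncol(trainValues))
  for (s in seq_len(nrow(perms))) {
    ## response row of training receptor perms[s, j] is assigned to sequence j
    preds[s, ] <- predictWithWeights(trainValues[perms[s, ], , drop = FALSE], w)
  }
  control <- colMeans(preds)
  dCtrl <- colMeans(abs(sweep(preds, 2, actual)))
  names(control) <- names(dCtrl) <- odorantIds(m)
  list(control = control, dCtrl = dCtrl, nShufflesUsed = nrow(perms))
}

#' Leave-one-receptor-out prediction evaluation
#'
#' For each receptor in turn: remove it, re-rank the alignment columns on the
#' remaining receptors, predict the held-out responses from sequence
#' similarity at the recomputed top-k positions, and compare the absolute
#' prediction error \code{dPred} against the shuffled-control error
#' \code{dCtrl}. Each held-out receptor gets its own random stream derived
#' from \code{seed} and the receptor's rank in alphabetical order, so results
#' do not depend on storage order.
#'
#' @param aln An \code{OrthologAlignment} (at least 3 receptors).
#' @param m A \code{ResponseMatrix} over the same receptors.
#' @param k Top-set size used for prediction (default 20).
#' @param nShuffles Permutations per control (default 1000).
#' @param seed Integer seed for the controls.
#' @param alpha Similarity weight exponent.
#' @param minPairs Eligibility threshold for the per-exclusion ranking.
#' @return A \code{\linkS4class{PredictionReport}}.
#' @export
looEvaluate <- function(aln, m, k = 20L, nShuffles = 1000L, seed = 1L,
                        alpha = 1, minPairs = 1L) {
  checkReceptorsMatch(aln, m)
  ids <- receptorIds(aln)
  if (length(ids) < 3L)
    stop("insufficient data: need at least 3 receptors")
  odorants <- odorantIds(m)
  sortedIds <- sort(ids)

  rows <- vector("list", length(ids))
  for (h in seq_along(ids)) {
    hid <- ids[[h]]
    redAln <- dropReceptor(aln, hid)
    redM <- ResponseMatrix(m@values[setdiff(ids, hid), , drop = FALSE])
    pst <- rankPositions(redAln, redM, k = k, minPairs = minPairs)
    positions <- topPositions(pst)
    pred <- predictResponse(aln, m, positions, hid, alpha = alpha)
    hSeed <- deriveSeed(seed, match(hid, sortedIds))
    ctrl <- shuffledControl(aln, m, positions, hid, nShuffles = nShuffles,
                            seed = hSeed, alpha = alpha)
    actual <- m@values[hid, ]
    rows[[h]] <- data.frame(
      heldoutId = hid, odorantId = odorants, actual = unname(actual),
      predicted = unname(pred), control = unname(ctrl$control),
      dPred = unname(abs(pred - actual)), dCtrl = unname(ctrl$dCtrl),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  entries <- do.call(rbind, rows)
  entries$delta <- entries$dPred - entries$dCtrl

  ok <- !is.na(entries$dPred) & !is.na(entries$dCtrl)
  meanDPred <- mean(entries$dPred[ok])
  meanDCtrl <- mean(entries$dCtrl[ok])
  improvement <- if (meanDCtrl > 0) 100 * (meanDCtrl - meanDPred) / meanDCtrl
                 else NA_real_

  perReceptor <- aggregateErrors(entries[ok, ], "heldoutId")
  perOdorant <- aggregateErrors(entries[ok, ], "odorantId")
  meanPerReceptorImprovement <- mean(perReceptor$improvementPercent,
                                     na.rm = TRUE)

  new("PredictionReport", entries = entries, perReceptor = perReceptor,
      perOdorant = perOdorant,
      summary = list(meanDPred = meanDPred, meanDCtrl = meanDCtrl,
                     improvementPercent = improvement,
                     meanPerReceptorImprovement = meanPerReceptorImprovement,
                     nMissingPredictions = sum(!ok),
                     k = as.integer(k), nShuffles = as.integer(nShuffles),
                     seed = as.integer(seed)))
}

aggregateErrors <- function(entries, by) {
  sp <- split(entries, entries[[by]])
  out <- do.call(rbind, lapply(names(sp), function(g) {
    e <- sp[[g]]
    mp <- mean(e$dPred); mc <- mean(e$dCtrl)
    data.frame(id = g, meanDPred = mp, meanDCtrl = mc,
               meanDelta = mean(e$delta),
               improvementPercent = if (mc > 0) 100 * (mc - mp) / mc
                                    else NA_real_,
               stringsAsFactors = FALSE)
  }))
  names(out)[1] <- by
  out[order(out[[by]]), , drop = FALSE]
}

dropReceptor <- function(aln, id) {
  keep <- setdiff(receptorIds(aln), id)
  refId <- if (referenceId(aln) == id) sort(keep)[[1]] else referenceId(aln)
  OrthologAlignment(aln@seqs[keep], refId)
}

#' Write a prediction report to TSV and JSON
#'
#' @param report A \code{PredictionReport}.
#' @param tsvPath Path for the per-entry TSV (one row per held-out receptor
#'   and odorant).
#' @param jsonPath Optional path for the JSON summary (overall means,
#'   improvements, per-receptor and per-odorant averages).
#' @return Invisibly, \code{tsvPath}.
#' @export
writePredictionReport <- function(report, tsvPath, jsonPath = NULL) {
  stopifnot(is(report, "PredictionReport"))
  e <- report@entries
  for (col in c("actual", "predicted", "control", "dPred", "dCtrl", "delta"))
    e[[col]] <- formatNum(e[[col]])
  utils::write.table(e, tsvPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  if (!is.null(jsonPath)) {
    payload <- c(report@summary,
                 list(perReceptor = report@perReceptor,
                      perOdorant = report@perOdorant))
    jsonlite::write_json(payload, jsonPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(tsvPath)
}
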