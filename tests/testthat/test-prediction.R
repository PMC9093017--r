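test_that("similarity at positions counts identical non-gap residues", {
  aln <- OrthologAlignment(c(a = "MVKG", b = "MAKG", c = "M-X-"),
                           referenceId = "a")
  expect_equal(similarityAtPositions(aln, 1:4, "a", "a"), 1)
  expect_equal(similarityAtPositions(aln, 2, "a", "b"), 0)
  expect_equal(similarityAtPositions(aln, 1:2, "a", "b"), 0.5)
  expect_equal(similarityAtPositions(aln, c(2, 4), "c", "b"), 0)  # gaps/X
})

test_that("held-out responses are similarity-weighted training means", {
  aln <- toyAlignment(); m <- toyResponses()
  pred <- predictResponse(aln, m, positions = 2, heldoutId = "r4")
  expect_equal(unname(pred), c(0, 100))  # all weight on r3
  expect_equal(sum(abs(pred - responseValues(m)["r4", ])), 0)

  # constant training responses: prediction is that constant
  mConst <- ResponseMatrix(matrix(7, 4, 2,
    dimnames = list(paste0("r", 1:4), c("o1", "o2"))))
  expect_equal(unname(predictResponse(aln, mConst, 2, "r4")), c(7, 7))

  # all weights zero -> unweighted training mean
  alnGap <- OrthologAlignment(c(r1 = "MAKG", r2 = "MCKG", r3 = "MDKG",
                                r4 = "M-KG"), referenceId = "r1")
  pred0 <- predictResponse(alnGap, m, positions = 2, heldoutId = "r4")
  expect_equal(unname(pred0),
               unname(colMeans(responseValues(m)[1:3, ])))

  two <- OrthologAlignment(c(a = "MA", b = "MV"), "a")
  m2 <- ResponseMatrix(matrix(1:2, 2, 1, dimnames = list(c("a", "b"), "o")))
  expect_error(predictResponse(two, m2, 1, "a"), "insufficient data")
})

test_that("predictions stay within the training response range", {
  for (seed in 1:5) {
    d <- randomDataset(6, 15, 5, seed = 200 + seed, gapProb = 0.05)
    ids <- receptorIds(d$aln)
    h <- ids[1 + (seed %% 6)]
    pred <- predictResponse(d$aln, d$m, positions = 1:6, heldoutId = h)
    train <- responseValues(d$m)[setdiff(ids, h), , drop = FALSE]
    for (o in seq_along(pred)) {
      if (is.na(pred[o])) next
      expect_gte(pred[o], min(train[, o], na.rm = TRUE) - 1e-9)
      expect_lte(pred[o], max(train[, o], na.rm = TRUE) + 1e-9)
    }
  }
})

test_that("shuffled control equals the prediction in permutation-invariant cases", {
  aln <- toyAlignment()
  mConst <- ResponseMatrix(matrix(3, 4, 2,
    dimnames = list(paste0("r", 1:4), c("o1", "o2"))))
  ctrl <- shuffledControl(aln, mConst, 2, "r4", nShuffles = 50, seed = 1)
  pred <- predictResponse(aln, mConst, 2, "r4")
  expect_equal(ctrl$dCtrl,
               abs(pred - responseValues(mConst)["r4", ]))

  # equal weights for every training receptor: shuffling changes nothing
  alnEq <- OrthologAlignment(c(r1 = "MAKG", r2 = "MAKG", r3 = "MAKG",
                               r4 = "MAKG"), referenceId = "r1")
  m <- toyResponses()
  ctrlEq <- shuffledControl(alnEq, m, 2, "r4", nShuffles = 50, seed = 1)
  predEq <- predictResponse(alnEq, m, 2, "r4")
  expect_equal(ctrlEq$dCtrl, abs(predEq - responseValues(m)["r4", ]))
})

test_that("the exhaustive control matches an independent permutation enumeration", {
  d <- randomDataset(5, 10, 3, seed = 33, gapProb = 0, naProb = 0.15)
  ids <- receptorIds(d$aln)
  h <- ids[2]
  positions <- 1:4
  ctrl <- shuffledControl(d$aln, d$m, positions, h, nShuffles = 100,
                          seed = 4)             # 4! = 24 <= 100 -> exhaustive
  expect_equal(ctrl$nShufflesUsed, 24L)

  trainIds <- sort(setdiff(ids, h))
  w <- sapply(trainIds, function(t)
    similarityAtPositions(d$aln, positions, h, t))
  R <- responseValues(d$m)[trainIds, , drop = FALSE]
  actual <- responseValues(d$m)[h, ]
  perms <- enumPermutations(length(trainIds))
  errs <- preds <- matrix(NA_real_, length(perms), ncol(R))
  for (pi in seq_along(perms)) {
    Rp <- R[perms[[pi]], , drop = FALSE]
    p <- sapply(seq_len(ncol(Rp)), function(o) {
      y <- Rp[, o]; ok <- !is.na(y)
      if (!any(ok)) return(NA_real_)
      if (sum(w[ok]) == 0) mean(y[ok]) else sum(w[ok] * y[ok]) / sum(w[ok])
    })
    preds[pi, ] <- p
    errs[pi, ] <- abs(p - actual)
  }
  expect_equal(unname(ctrl$dCtrl), colMeans(errs))
  expect_equal(unname(ctrl$control), colMeans(preds))
})

test_that("the leave-one-out report is reproducible and order-invariant", {
  d <- randomDataset(6, 25, 5, seed = 77, gapProb = 0, naProb = 0.05)
  r1 <- looEvaluate(d$aln, d$m, k = 4, nShuffles = 40, seed = 9)
  r2 <- looEvaluate(d$aln, d$m, k = 4, nShuffles = 40, seed = 9)
  expect_identical(predictionEntries(r1), predictionEntries(r2))

  perm <- permuteData(d$aln, d$m, recOrder = c(4, 2, 6, 1, 3, 5),
                      odoOrder = c(3, 1, 5, 2, 4))
  r3 <- looEvaluate(perm$aln, perm$m, k = 4, nShuffles = 40, seed = 9)
  key <- function(r) {
    e <- predictionEntries(r)
    e <- e[order(e$heldoutId, e$odorantId), ]
    rownames(e) <- NULL
    e
  }
  expect_equal(key(r3), key(r1))

  s <- predictionSummary(r1)
  e <- predictionEntries(r1)
  ok <- !is.na(e$dPred)
  expect_equal(s$meanDPred, mean(e$dPred[ok]))
  expect_equal(s$improvementPercent,
               100 * (s$meanDCtrl - s$meanDPred) / s$meanDCtrl)
  expect_true(all(e$dPred >= 0, na.rm = TRUE))

  two <- OrthologAlignment(c(a = "MA", b = "MV"), "a")
  m2 <- ResponseMatrix(matrix(1:2, 2, 1, dimnames = list(c("a", "b"), "o")))
  expect_error(looEvaluate(two, m2), "at least 3")
})
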