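test_that("response distance is the mean absolute difference over shared odorants", {
  m <- toyResponses()
  expect_equal(responseDistance(m, "r1", "r2"), 0)
  expect_equal(responseDistance(m, "r1", "r3"), 100)

  v <- matrix(c(10, 0, NA, 50), 2, dimnames = list(c("a", "b"),
                                                   c("o1", "o2")))
  m2 <- ResponseMatrix(v)
  expect_equal(responseDistance(m2, "a", "b"), 10)  # only o1 shared

  v2 <- matrix(c(1, NA, NA, 2), 2, dimnames = list(c("a", "b"),
                                                   c("o1", "o2")))
  expect_error(responseDistance(ResponseMatrix(v2), "a", "b"),
               "share no measured odorant")
  expect_error(responseDistance(m, "r1", "r1"), "distinct")
})

test_that("column scores separate match and mismatch pair distances", {
  aln <- toyAlignment(); m <- toyResponses()
  s2 <- positionScore(aln, m, 2)
  expect_true(s2$eligible)
  expect_equal(s2$score, 100)          # mismatch mean 100, match mean 0
  expect_equal(s2$nMatchPairs, 2L)
  expect_equal(s2$nMismatchPairs, 4L)

  s1 <- positionScore(aln, m, 1)       # invariant column
  expect_false(s1$eligible)
  expect_true(is.na(s1$score))
  expect_error(positionScore(aln, m, 99), "out of range")
})

test_that("positionScore agrees with a brute-force pair enumeration oracle", {
  for (seed in 1:6) {
    d <- randomDataset(nRec = sample(3:6, 1), nCol = 12, nOdo = 4,
                       seed = 100 + seed)
    for (col in sample(12, 4)) {
      got <- positionScore(d$aln, d$m, col)
      expect_equal(got$score, bruteForceScore(d$aln, d$m, col),
                   info = sprintf("seed %d column %d", seed, col))
    }
  }
})

test_that("ranking selects the determinant column and applies tie-breaks", {
  aln <- toyAlignment(); m <- toyResponses()
  pst <- rankPositions(aln, m, k = 1)
  expect_equal(topPositions(pst), 2L)

  # constant responses: every eligible column scores 0; ties resolved by
  # reference index then column
  mFlat <- ResponseMatrix(matrix(5, 4, 2,
    dimnames = list(paste0("r", 1:4), c("o1", "o2"))))
  aln2 <- OrthologAlignment(c(r1 = "MAKA", r2 = "MAKC", r3 = "MVKA",
                              r4 = "MVKC"), referenceId = "r1")
  pst2 <- rankPositions(aln2, mFlat, k = 2)
  tab <- scoreTable(pst2)
  expect_true(all(tab$score[tab$eligible] == 0))
  expect_equal(topPositions(pst2), c(2L, 4L))

  expect_error(rankPositions(
    OrthologAlignment(c(a = "MA", b = "MV"), "a"),
    ResponseMatrix(matrix(1:2, 2, 1, dimnames = list(c("a", "b"), "o")))),
    "at least 3")
  mono <- OrthologAlignment(c(a = "MA", b = "MA", c = "MA"), "a")
  mm <- ResponseMatrix(matrix(1:3, 3, 1,
                              dimnames = list(c("a", "b", "c"), "o")))
  expect_error(rankPositions(mono, mm, k = 1), "no eligible column")
})

test_that("ranking is invariant to receptor and odorant order", {
  d <- randomDataset(6, 20, 5, seed = 42, gapProb = 0.05)
  ref <- rankPositions(d$aln, d$m, k = 5)
  perm <- permuteData(d$aln, d$m, recOrder = c(3, 1, 6, 2, 5, 4),
                      odoOrder = c(4, 2, 5, 1, 3))
  got <- rankPositions(perm$aln, perm$m, k = 5)
  expect_equal(topPositions(got), topPositions(ref))
  expect_equal(scoreTable(got)$score, scoreTable(ref)$score)
})

test_that("scores are shift-invariant per odorant and scale-equivariant", {
  d <- randomDataset(5, 15, 4, seed = 7, naProb = 0)
  base <- scoreTable(rankPositions(d$aln, d$m, k = 3))$score

  v <- responseValues(d$m)
  shifted <- sweep(v, 2, c(10, -4, 0, 100), "+")
  sShift <- scoreTable(rankPositions(d$aln, ResponseMatrix(shifted),
                                     k = 3))$score
  expect_equal(sShift, base)

  scaled <- v * 2.5
  sScale <- scoreTable(rankPositions(d$aln, ResponseMatrix(scaled),
                                     k = 3))$score
  expect_equal(sScale, 2.5 * base)
})

test_that("planted determinants are recovered exactly at zero noise without background variation", {
  for (seed in 1:3) {
    cfg <- generatorConfig(nVariableBackground = 0L, substitutionProb = 0.5,
                           noiseSd = 0, seed = seed)
    ds <- generateDataset(cfg)
    pst <- rankPositions(ds@alignment, ds@responses, k = 5)
    expect_setequal(topPositions(pst), ds@truth$plantedPositions)
  }
})
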