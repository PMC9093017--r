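# Small fixtures shared across test files, built in code.

# 4 receptors whose responses are fully determined by column 2
toyAlignment <- function() {
  OrthologAlignment(c(r1 = "MAKG", r2 = "MAKG", r3 = "MVKG", r4 = "MVKG"),
                    referenceId = "r1")
}

toyResponses <- function() {
  ResponseMatrix(matrix(c(100, 100, 0, 0,
                          0, 0, 100, 100), nrow = 4,
                        dimnames = list(paste0("r", 1:4), c("o1", "o2"))))
}

# reorder receptors (and odorants) of both objects consistently
permuteData <- function(aln, m, recOrder, odoOrder = NULL) {
  ids <- receptorIds(aln)[recOrder]
  v <- responseValues(m)[ids, , drop = FALSE]
  if (!is.null(odoOrder)) v <- v[, odoOrder, drop = FALSE]
  list(aln = OrthologAlignment(as.character(alignedSeqs(aln))[recOrder],
                               referenceId = referenceId(aln)),
       m = ResponseMatrix(v))
}

# independent brute-force column scorer used as an oracle: explicit loops
# over unordered receptor pairs, reusing only responseDistance()
bruteForceScore <- function(aln, m, column) {
  ids <- receptorIds(aln)
  chars <- strsplit(as.character(alignedSeqs(aln)), "")
  names(chars) <- ids
  dM <- c(); dX <- c()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i >= j) next
      a <- chars[[ids[i]]][column]; b <- chars[[ids[j]]][column]
      if (a == "-" || b == "-") next
      d <- tryCatch(responseDistance(m, ids[i], ids[j]),
                    error = function(e) NA_real_)
      if (is.na(d)) next
      if (a == b && a != "X") dM <- c(dM, d) else dX <- c(dX, d)
    }
  }
  if (length(dM) >= 1 && length(dX) >= 1) mean(dX) - mean(dM) else NA_real_
}

# all permutations of seq_len(n), via recursion independent of the package
enumPermutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in enumPermutations(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
    }
  }
  out
}

# random small alignment + responses for property tests
randomDataset <- function(nRec, nCol, nOdo, seed, gapProb = 0.1,
                          naProb = 0.1) {
  set.seed(seed)
  letters20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  seqs <- replicate(nRec, {
    s <- sample(letters20[1:4], nCol, replace = TRUE)
    s[runif(nCol) < gapProb] <- "-"
    paste0(s, collapse = "")
  })
  # reference must be ungapped somewhere; force first record gap-free
  seqs[1] <- paste0(sample(letters20[1:4], nCol, replace = TRUE),
                    collapse = "")
  names(seqs) <- sprintf("r%02d", seq_len(nRec))
  v <- matrix(round(runif(nRec * nOdo, 0, 120), 1), nRec,
              dimnames = list(names(seqs), sprintf("od%d", seq_len(nOdo))))
  v[runif(length(v)) < naProb] <- NA
  # keep at least one measurement per row
  for (i in seq_len(nRec)) if (all(is.na(v[i, ]))) v[i, 1] <- 10
  list(aln = OrthologAlignment(seqs, referenceId = names(seqs)[1]),
       m = ResponseMatrix(v))
}
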