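test_that("alignment construction enforces the invariants", {
  aln <- OrthologAlignment(c(a = "makg", b = "mv.g"), referenceId = "a")
  expect_equal(as.character(alignedSeqs(aln)),
               c(a = "MAKG", b = "MV-G"))  # upper-cased, '.' -> '-'
  expect_equal(alignmentLength(aln), 4L)
  expect_error(OrthologAlignment(c(a = "MAKG", b = "MAKGA"), "a"),
               "unequal lengths")
  expect_error(OrthologAlignment(c(a = "MAKG", b = "MVKG"), "zz"),
               "reference id")
  expect_error(OrthologAlignment(c(a = "MAKG", a = "MVKG"), "a"))
  expect_error(OrthologAlignment(c(a = "----", b = "MVKG"), "a"))
})

test_that("aligned FASTA reading and writing round-trips", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MAKG", ">b", "MVKG"), f)
  aln <- readAlignment(f, "a")
  expect_equal(length(receptorIds(aln)), 2L)
  expect_equal(alignmentLength(aln), 4L)
  expect_error(readAlignment(f, "nope"), "reference id")
  expect_error(readAlignment(withr::local_tempfile(fileext = ".fa"),
                             "a"), "not found")

  ds <- generateDataset(generatorConfig(seed = 5))
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeAlignment(ds@alignment, f2)
  back <- readAlignment(f2, referenceId(ds@alignment))
  expect_identical(as.character(alignedSeqs(back)),
                   as.character(alignedSeqs(ds@alignment)))
})

test_that("reference map numbers non-gap reference columns consecutively", {
  aln <- OrthologAlignment(c(r = "M-KG", s = "MAKG"), referenceId = "r")
  rm <- buildReferenceMap(aln)
  expect_equal(rm$columnToRef, c(1L, NA, 2L, 3L))
  expect_equal(rm$refLength, 3L)

  ungapped <- OrthologAlignment(c(r = "MAKG", s = "MVKG"), referenceId = "r")
  expect_equal(buildReferenceMap(ungapped)$columnToRef, 1:4)

  # mapped-column count equals ungapped length, random gapped references
  for (seed in 1:5) {
    set.seed(seed)
    chars <- sample(c("A", "C", "-"), 60, replace = TRUE, prob = c(4, 4, 2))
    if (all(chars == "-")) chars[1] <- "A"
    aln <- OrthologAlignment(
      c(r = paste0(chars, collapse = ""),
        s = paste0(rep("A", 60), collapse = "")), referenceId = "r")
    rm <- buildReferenceMap(aln)
    expect_equal(sum(!is.na(rm$columnToRef)), sum(chars != "-"))
    mapped <- rm$columnToRef[!is.na(rm$columnToRef)]
    expect_equal(mapped, seq_len(rm$refLength))  # strictly increasing
  }
})

test_that("response CSV reader handles missing cells and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("receptor_id,o1,o2", "a,1.5,", "b,2,3"), f)
  m <- readResponseMatrix(f)
  expect_equal(responseValues(m)["a", "o2"], NA_real_)
  expect_equal(responseValues(m)["b", "o1"], 2)
  expect_equal(receptorIds(m), c("a", "b"))

  writeLines("receptor_id,o1,o2", f)
  expect_error(readResponseMatrix(f), "no receptor rows")
  writeLines(c("receptor_id,o1,o2", "a,1,2", "a,3,4"), f)
  expect_error(readResponseMatrix(f), "duplicate receptor")
  writeLines(c("receptor_id,o1,o2", "a,1,x"), f)
  expect_error(readResponseMatrix(f), "non-numeric")
})

test_that("generator-scale response matrix round-trips through CSV", {
  ds <- generateDataset(generatorConfig(seed = 9))
  f <- withr::local_tempfile(fileext = ".csv")
  writeResponseMatrix(ds@responses, f)
  back <- readResponseMatrix(f)
  expect_equal(dim(responseValues(back)), c(14L, 21L))
  expect_equal(responseValues(back), responseValues(ds@responses),
               tolerance = 1e-9)
})

test_that("PDB structures read one CA per residue and round-trip", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  ALA A   3       7.600   0.000   0.000  1.00  0.00           C",
    "END"), f)
  s <- readStructure(f, "A")
  expect_equal(refIndices(s), 1:3)
  expect_equal(unname(residueCoords(s)[2, ]), c(3.8, 0, 0))
  expect_error(readStructure(f, "Z"), "chain 'Z'")

  # residue 2 has only a CB -> skipped with a warning
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "END"), f)
  expect_warning(s2 <- readStructure(f, "A"), "without a CA")
  expect_equal(refIndices(s2), 1L)

  chain <- generateStructure(generatorConfig(seed = 2))
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(chain, f2)
  back <- readStructure(f2, "A", refLength = 397)
  expect_equal(refIndices(back), 1:397)
  expect_equal(residueCoords(back), residueCoords(chain), tolerance = 1e-3)
})

test_that("pairwise identity follows the shared-coverage denominator", {
  aln <- OrthologAlignment(c(a = "ACDE", b = "ACDE"), referenceId = "a")
  expect_equal(pairwiseIdentity(aln)["a", "b"], 100)

  aln <- OrthologAlignment(c(a = "ACDE", b = "ACEE"), referenceId = "a")
  expect_equal(pairwiseIdentity(aln)["a", "b"], 75)

  # both-gap columns drop out of the denominator
  aln <- OrthologAlignment(c(a = "AC--", b = "ACD-"), referenceId = "a")
  expect_equal(pairwiseIdentity(aln)["a", "b"], 200 / 3)

  # X matches nothing, not even X
  aln <- OrthologAlignment(c(a = "AXXE", b = "AXCE"), referenceId = "a")
  expect_equal(pairwiseIdentity(aln)["a", "b"], 50)

  for (seed in 1:4) {
    d <- randomDataset(5, 30, 3, seed)
    pid <- pairwiseIdentity(d$aln)
    expect_equal(pid, t(pid))
    expect_equal(unname(diag(pid)), rep(100, 5))
    expect_true(all(pid >= 0 & pid <= 100))
  }
})
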