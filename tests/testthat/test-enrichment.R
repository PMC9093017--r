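test_that("residue neighborhoods obey the inclusive radius rule", {
  chain <- generateStructure(generatorConfig(seed = 1))  # 3.8 A spacing
  expect_equal(residueNeighborhood(chain, 200, radius = 0), 200L)
  # 3 x 3.8 = 11.4 <= 15 < 4 x 3.8: three neighbors on each side
  expect_equal(residueNeighborhood(chain, 200, radius = 15), 197:203)
  expect_equal(residueNeighborhood(chain, 1, radius = 1e6), 1:397)
  expect_error(residueNeighborhood(chain, 999), "not in structure")

  # boundary: a pair at exactly 15.0 A is inside
  s <- StructureModel(rbind(c(0, 0, 0), c(15, 0, 0), c(30.1, 0, 0)), 1:3)
  expect_equal(residueNeighborhood(s, 1, radius = 15), c(1L, 2L))
})

test_that("neighborhood membership is invariant under rigid motion", {
  cfg <- generatorConfig(seed = 6)
  ds <- generateDataset(cfg, clusterPlanted = TRUE)
  co <- residueCoords(ds@structure)
  theta <- 0.83
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  moved <- StructureModel(co %*% t(R) + rep(c(5, -12, 40), each = nrow(co)),
                          refIndices(ds@structure))
  for (seedRes in c(10, 199, 390))
    expect_equal(residueNeighborhood(moved, seedRes),
                 residueNeighborhood(ds@structure, seedRes))
})

test_that("the upper-tail hypergeometric matches enumeration and phyper", {
  expect_equal(hypergeomUpperTail(10, 3, 4, 0), 1)
  expect_equal(hypergeomUpperTail(10, 3, 4, 2), 1 / 3)
  expect_error(hypergeomUpperTail(10, 11, 4, 2), "domain error")
  expect_error(hypergeomUpperTail(10, 3, 4, 4), "domain error")

  # exact choose() enumeration on a grid of small cases
  for (N in c(5, 12, 19)) {
    for (K in c(0, 2, N %/% 2, N)) {
      for (n in c(1, N %/% 3, N)) {
        for (k in unique(c(0, min(1, min(n, K)), min(n, K)))) {
          direct <- sum(sapply(k:min(n, K), function(x)
            choose(K, x) * choose(N - K, n - x))) / choose(N, n)
          expect_equal(hypergeomUpperTail(N, K, n, k), min(1, direct),
                       info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }

  # independent library route on larger parameters
  set.seed(1)
  for (i in 1:25) {
    N <- sample(50:400, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeomUpperTail(N, K, n, k),
                 stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }

  # p is non-increasing in k and 1 at k = 0
  p <- sapply(0:15, function(k) hypergeomUpperTail(397, 20, 41, k))
  expect_true(all(diff(p) <= 1e-15))
  expect_equal(p[1], 1)
})

test_that("enrichment composes neighborhoods with the exact test", {
  e <- hypergeomEnrichment(N = 397, K = 20, n = 41, k = 6)
  expect_equal(round(e@expected, 2), 2.07)
  expect_equal(round(e@pValue, 3), 0.011)

  e2 <- hypergeomEnrichment(N = 397, K = 20, n = 70, k = 7)
  expect_equal(round(e2@expected, 2), 3.53)
  expect_equal(round(e2@pValue, 3), 0.044)

  # structure-based route: disjoint top set gives overlap 0 and p = 1
  chain <- generateStructure(generatorConfig(seed = 2))
  far <- enrichmentTest(chain, top = 380:397, seedRefIndex = 10,
                        radius = 15, N = 397)
  expect_equal(far@kOverlap, 0L)
  expect_equal(far@pValue, 1)
  expect_equal(far@n, 7L)
  expect_equal(far@expected, 7 * 18 / 397)
})

test_that("union enrichment recomputes on the merged residue set", {
  chain <- generateStructure(generatorConfig(seed = 2))
  top <- c(1:5, 100:104, 200:209)
  e1 <- enrichmentTest(chain, top, 50, radius = 15, N = 397)
  e2 <- enrichmentTest(chain, top, 300, radius = 15, N = 397)
  expect_equal(e1@n, 7L)
  u <- unionEnrichment(e1, e2, top, 397)
  expect_equal(u@n, 14L)  # disjoint neighborhoods add
  expect_equal(u@kOverlap,
               length(intersect(u@neighborhood, top)))
  uSelf <- unionEnrichment(e1, e1, top, 397)
  expect_equal(uSelf@n, e1@n)
  expect_equal(uSelf@pValue, e1@pValue)
})

test_that("clustered planted residues are detected as enriched", {
  cfg <- generatorConfig(seed = 8)
  ds <- generateDataset(cfg, clusterPlanted = TRUE)
  seedRes <- as.integer(ceiling(397 / 2))
  top <- sort(c(ds@truth$plantedPositions,
                setdiff(ds@truth$backgroundPositions,
                        ds@truth$plantedPositions)[1:15]))
  e <- enrichmentTest(ds@structure, top, seedRes, radius = 15, N = 397)
  expect_gte(e@kOverlap, 5L)  # the 5 planted residues sit in the ball
  expect_lt(e@pValue, 0.05)
})
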