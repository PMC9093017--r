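## Structural-neighborhood enrichment of the top positions: fixed-radius
## alpha-carbon neighborhoods and exact upper-tail hypergeometric tests.

#' Residues within a fixed radius of a seed residue
#'
#' All residues whose alpha-carbon lies within \code{radius} Angstroms
#' (boundary inclusive) of the seed's alpha-carbon; the seed itself is a
#' member (distance 0).
#'
#' @param s A \code{StructureModel}.
#' @param seedRefIndex Seed residue (reference numbering).
#' @param radius Radius in Angstroms (default 15).
#' @return Sorted integer vector of member residue indices.
#' @export
residueNeighborhood <- function(s, seedRefIndex, radius = 15) {
  stopifnot(is(s, "StructureModel"))
  idx <- refIndices(s)
  pos <- match(as.integer(seedRefIndex), idx)
  if (is.na(pos))
    stop("lookup error: seed residue ", seedRefIndex, " not in structure")
  d <- sqrt(colSums((t(s@coords) - s@coords[pos, ])^2))
  sort(idx[d <= radius])
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) where X counts successes among \code{n} draws without
#' replacement from a population of \code{N} containing \code{K} successes.
#' Summed in log space over the upper tail for numerical stability.
#'
#' @param N Population size.
#' @param K Number of successes in the population.
#' @param n Number of draws.
#' @param k Observed successes.
#' @return p-value in (0, 1].
#' @examples
#' hypergeomUpperTail(10, 3, 4, 2)  # 1/3
#' @export
hypergeomUpperTail <- function(N, K, n, k) {
  if (N < 0 || K < 0 || K > N || n < 0 || n > N || k < 0 || k > min(n, K))
    stop("domain error: need 0 <= K <= N, 0 <= n <= N, 0 <= k <= min(n, K)")
  if (k == 0) return(1)
  x <- seq.int(k, min(n, K))
  x <- x[x >= max(0L, n - (N - K))]
  logp <- lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
  mx <- max(logp)
  min(1, exp(mx) * sum(exp(logp - mx)))
}

makeEnrichment <- function(neighborhood, top, N, seedRefIndex = NA_integer_,
                           radius = NA_real_, n = length(neighborhood),
                           kOverlap = length(intersect(neighborhood, top)),
                           K = length(top)) {
  new("NeighborhoodEnrichment",
      seedRefIndex = as.integer(seedRefIndex), radius = as.numeric(radius),
      neighborhood = as.integer(neighborhood), n = as.integer(n),
      kOverlap = as.integer(kOverlap), N = as.integer(N), K = as.integer(K),
      expected = n * K / N,
      pValue = hypergeomUpperTail(N, K, n, kOverlap))
}

#' Test enrichment of top positions in a structural neighborhood
#'
#' Builds the \code{radius}-Angstrom neighborhood around the seed residue and
#' tests whether it contains more of the top positions than expected by
#' chance (expected overlap n*K/N; exact upper-tail hypergeometric).
#'
#' @param s A \code{StructureModel}.
#' @param top Integer vector of top positions, in reference numbering.
#' @param seedRefIndex Seed residue (reference numbering).
#' @param radius Radius in Angstroms (default 15).
#' @param N Protein length (population size); defaults to the number of
#'   residues in the structure.
#' @return A \code{\linkS4class{NeighborhoodEnrichment}}.
#' @export
enrichmentTest <- function(s, top, seedRefIndex, radius = 15, N = NULL) {
  stopifnot(is(s, "StructureModel"))
  if (is.null(N)) N <- nrow(s@coords)
  top <- as.integer(top)
  if (any(top < 1L) || any(top > N))
    stop("top positions must lie in [1, N]")
  nb <- residueNeighborhood(s, seedRefIndex, radius)
  makeEnrichment(nb, top, N, seedRefIndex = seedRefIndex, radius = radius)
}

#' Enrichment on the union of two neighborhoods
#'
#' @param e1,e2 \code{NeighborhoodEnrichment} objects computed on the same
#'   structure with the same \code{N} and top-position set.
#' @param top The top-position set (reference numbering).
#' @param N Protein length.
#' @return A \code{NeighborhoodEnrichment} over the union of the two
#'   neighborhoods.
#' @export
unionEnrichment <- function(e1, e2, top, N) {
  stopifnot(is(e1, "NeighborhoodEnrichment"), is(e2, "NeighborhoodEnrichment"))
  if (e1@N != e2@N || e1@N != N)
    stop("the two tests must share the same population size N")
  nb <- sort(union(e1@neighborhood, e2@neighborhood))
  makeEnrichment(nb, as.integer(top), N)
}

#' Parameters-only enrichment test
#'
#' Computes expectation and exact hypergeometric p-value directly from the
#' printed counts (protein length N, K top positions, neighborhood size n,
#' overlap k) without a structure file.
#'
#' @param N Protein length.
#' @param K Number of top positions.
#' @param n Neighborhood size.
#' @param k Observed overlap.
#' @return A \code{\linkS4class{NeighborhoodEnrichment}} with an empty
#'   neighborhood slot.
#' @examples
#' hypergeomEnrichment(N = 397, K = 20, n = 41, k = 6)  # expected 2.07, p 0.011
#' @export
hypergeomEnrichment <- function(N, K, n, k) {
  makeEnrichment(integer(0), integer(0), N, n = n, kOverlap = k, K = K)
}

#' Write an enrichment result to JSON (and optionally its residue list)
#'
#' @param e A \code{NeighborhoodEnrichment}.
#' @param jsonPath Output JSON path.
#' @param tsvPath Optional path for the member-residue TSV.
#' @param top Optional top-position set, used to flag members.
#' @return Invisibly, \code{jsonPath}.
#' @export
writeEnrichment <- function(e, jsonPath, tsvPath = NULL, top = NULL) {
  stopifnot(is(e, "NeighborhoodEnrichment"))
  payload <- list(seedRefIndex = e@seedRefIndex, radius = e@radius,
                  n = e@n, kOverlap = e@kOverlap, N = e@N, K = e@K,
                  expected = e@expected,
                  pValue = signif(e@pValue, 3), pValueExact = e@pValue)
  payload <- payload[!vapply(payload, function(x) length(x) == 1 && is.na(x),
                             logical(1))]
  jsonlite::write_json(payload, jsonPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(tsvPath) && length(e@neighborhood)) {
    df <- data.frame(refIndex = e@neighborhood,
                     inTop = if (is.null(top)) NA
                             else e@neighborhood %in% top)
    utils::write.table(df, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  invisible(jsonPath)
}
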