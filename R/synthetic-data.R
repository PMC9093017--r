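## Seeded synthetic benchmark generator: an ortholog alignment with planted
## response-determining positions, a response matrix driven by those
## positions plus Gaussian noise, and a toy alpha-carbon structure.
##
## The defaults emulate the scale of a 14-species ortholog panel: 14
## receptors, a 397-residue reference, 21 odorants, responses centered at
## 28.78 spikes.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Configuration for the synthetic-data generator
#'
#' @param nReceptors Number of receptors/species (default 14).
#' @param refLength Reference protein length (default 397).
#' @param nOdorants Number of odorants (default 21).
#' @param plantedPositions Reference indices of the response-determining
#'   positions; NULL (default) draws \code{nPlanted} positions at generation
#'   time from the seeded stream.
#' @param nPlanted Number of planted positions when drawn (default 5).
#' @param nVariableBackground Number of variable but non-determinant
#'   positions (default 40).
#' @param substitutionProb Per-receptor probability of the alternative
#'   residue at each variable position (default 0.3).
#' @param effectScale Effect SD tau, spikes (default 30): each (planted
#'   position, residue, odorant) effect is Normal(0, tau^2).
#' @param noiseSd Measurement noise SD sigma, spikes (default 5).
#' @param responseBaseline Baseline response, spikes (default 28.78).
#' @param indelProb Probability that a non-reference receptor carries a gap
#'   at one designated background column (default 0).
#' @param seed Integer master seed (default 1); all generator streams derive
#'   from it.
#' @return Validated configuration list of class \code{GeneratorConfig}.
#' @export
generatorConfig <- function(nReceptors = 14L, refLength = 397L,
                            nOdorants = 21L, plantedPositions = NULL,
                            nPlanted = 5L, nVariableBackground = 40L,
                            substitutionProb = 0.3, effectScale = 30,
                            noiseSd = 5, responseBaseline = 28.78,
                            indelProb = 0, seed = 1L) {
  cfg <- list(nReceptors = as.integer(nReceptors),
              refLength = as.integer(refLength),
              nOdorants = as.integer(nOdorants),
              plantedPositions = if (is.null(plantedPositions)) NULL
                                 else as.integer(plantedPositions),
              nPlanted = as.integer(nPlanted),
              nVariableBackground = as.integer(nVariableBackground),
              substitutionProb = substitutionProb,
              effectScale = effectScale, noiseSd = noiseSd,
              responseBaseline = responseBaseline, indelProb = indelProb,
              seed = as.integer(seed))
  if (cfg$nReceptors < 2L) stop("need at least 2 receptors")
  if (cfg$substitutionProb < 0 || cfg$substitutionProb > 1 ||
      cfg$indelProb < 0 || cfg$indelProb > 1)
    stop("probabilities must lie in [0, 1]")
  if (cfg$effectScale < 0 || cfg$noiseSd < 0)
    stop("effectScale and noiseSd must be non-negative")
  if (!is.null(cfg$plantedPositions)) {
    if (any(cfg$plantedPositions < 1L) ||
        any(cfg$plantedPositions > cfg$refLength))
      stop("planted positions must lie in [1, refLength]")
    if (anyDuplicated(cfg$plantedPositions))
      stop("planted positions must be unique")
    cfg$nPlanted <- length(cfg$plantedPositions)
  }
  if (cfg$nPlanted + cfg$nVariableBackground > cfg$refLength)
    stop("more variable positions than columns")
  class(cfg) <- "GeneratorConfig"
  cfg
}

#' Generate a synthetic ortholog alignment with planted variable positions
#'
#' The reference receptor is the ancestor sequence (uniform over the 20
#' amino-acid letters, no gaps). Every other receptor carries, at each
#' planted or background position, a single position-specific alternative
#' residue with probability \code{substitutionProb}; variable columns are
#' redrawn until at least one receptor realizes the substitution, so every
#' designated column is variable by construction. All other columns are
#' invariant.
#'
#' @param cfg A \code{\link{generatorConfig}}.
#' @return List with \code{alignment} (\code{OrthologAlignment}; reference
#'   record \code{"ref"}), \code{plantedPositions} and
#'   \code{backgroundPositions} (reference indices; equal to alignment
#'   columns, since the reference is ungapped).
#' @export
generateAlignment <- function(cfg) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  set.seed(deriveSeed(cfg$seed, 1L))
  L <- cfg$refLength
  ancestor <- sample(AA20, L, replace = TRUE)

  planted <- cfg$plantedPositions
  if (is.null(planted)) planted <- sort(sample.int(L, cfg$nPlanted))
  background <- sort(sample(setdiff(seq_len(L), planted),
                            cfg$nVariableBackground))
  variable <- c(planted, background)

  nOther <- cfg$nReceptors - 1L
  ids <- c("ref", sprintf("sp%02d", seq_len(nOther)))
  seqm <- matrix(rep(ancestor, each = cfg$nReceptors), nrow = cfg$nReceptors,
                 dimnames = list(ids, NULL))
  for (p in variable) {
    alt <- sample(setdiff(AA20, ancestor[p]), 1L)
    ## redraw until the substitution is realized at least once, so every
    ## designated column is variable by construction (unless prob is 0)
    carry <- rep(FALSE, nOther)
    if (cfg$substitutionProb > 0) {
      repeat {
        carry <- stats::runif(nOther) < cfg$substitutionProb
        if (any(carry)) break
      }
    }
    seqm[which(carry) + 1L, p] <- alt
  }
  if (cfg$indelProb > 0 && length(background)) {
    gapCol <- background[[1L]]
    gapped <- stats::runif(nOther) < cfg$indelProb
    seqm[which(gapped) + 1L, gapCol] <- "-"
  }
  aln <- OrthologAlignment(apply(seqm, 1, paste0, collapse = ""),
                           referenceId = "ref")
  list(alignment = aln, plantedPositions = sort(planted),
       backgroundPositions = background)
}

#' Generate responses driven by the planted positions
#'
#' Response(i, o) = baseline + sum over planted positions p of
#' beta[p, residue(i, p), o] + Normal(0, sigma^2), where each
#' beta[p, residue, o] is an independent Normal(0, tau^2) draw. Receptors
#' sharing all planted residues therefore share their noiseless response
#' profile.
#'
#' @param aln The alignment from \code{\link{generateAlignment}}.
#' @param plantedPositions Reference indices of the determinant positions.
#' @param cfg The \code{\link{generatorConfig}} used to build \code{aln}.
#' @return List with \code{responses} (\code{ResponseMatrix}) and
#'   \code{beta} (effect array: position x residue x odorant).
#' @export
generateResponses <- function(aln, plantedPositions, cfg) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  set.seed(deriveSeed(cfg$seed, 2L))
  sm <- seqMatrix(aln)
  ids <- rownames(sm)
  odorants <- sprintf("od%02d", seq_len(cfg$nOdorants))
  nP <- length(plantedPositions)

  beta <- array(0, dim = c(nP, length(AA20), cfg$nOdorants),
                dimnames = list(as.character(plantedPositions), AA20,
                                odorants))
  if (nP > 0)
    beta[] <- stats::rnorm(length(beta), 0, cfg$effectScale)

  v <- matrix(cfg$responseBaseline, nrow = length(ids),
              ncol = cfg$nOdorants, dimnames = list(ids, odorants))
  for (pi in seq_len(nP)) {
    res <- sm[, plantedPositions[pi]]
    ok <- res %in% AA20
    v[ok, ] <- v[ok, ] + beta[pi, res[ok], ]
  }
  v <- v + stats::rnorm(length(v), 0, cfg$noiseSd)
  list(responses = ResponseMatrix(v), beta = beta)
}

#' Generate a toy alpha-carbon structure
#'
#' A straight chain along the x axis with 3.8 Angstrom spacing, one CA per
#' residue. With \code{clusterPlanted = TRUE} the planted residues are
#' relocated into a ball of 10 Angstrom diameter around the seed residue's
#' coordinate, so that a 15-Angstrom neighborhood around the seed captures
#' them.
#'
#' @param cfg A \code{\link{generatorConfig}}.
#' @param plantedPositions Reference indices to cluster (required when
#'   \code{clusterPlanted}).
#' @param clusterPlanted Relocate planted residues near the seed.
#' @param seedResidue Residue whose coordinate anchors the cluster (default:
#'   the chain midpoint).
#' @return A \code{\linkS4class{StructureModel}} of \code{refLength}
#'   residues, chain "A".
#' @export
generateStructure <- function(cfg, plantedPositions = integer(0),
                              clusterPlanted = FALSE, seedResidue = NULL) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  L <- cfg$refLength
  coords <- cbind(x = (seq_len(L) - 1) * 3.8, y = 0, z = 0)
  if (clusterPlanted && length(plantedPositions)) {
    set.seed(deriveSeed(cfg$seed, 3L))
    if (is.null(seedResidue)) seedResidue <- as.integer(ceiling(L / 2))
    center <- coords[seedResidue, ]
    for (p in plantedPositions) {
      repeat {  # rejection-sample a point in the radius-5 ball
        u <- stats::runif(3, -5, 5)
        if (sum(u^2) <= 25) break
      }
      coords[p, ] <- center + u
    }
  }
  StructureModel(coords, seq_len(L), chainId = "A")
}

#' Generate a complete synthetic dataset
#'
#' Composes the alignment, response and structure generators with
#' independent sub-streams derived from \code{cfg$seed}, optionally writing
#' the FASTA/CSV/PDB fixtures plus a JSON ground-truth file.
#'
#' @param cfg A \code{\link{generatorConfig}}.
#' @param dir Optional output directory; created if needed. Files written:
#'   \code{alignment.fasta}, \code{responses.csv}, \code{structure.pdb},
#'   \code{truth.json}.
#' @param clusterPlanted Passed to \code{\link{generateStructure}}.
#' @return A \code{\linkS4class{SyntheticDataset}}.
#' @examples
#' ds <- generateDataset(generatorConfig(seed = 7))
#' ds
#' @export
generateDataset <- function(cfg, dir = NULL, clusterPlanted = FALSE) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  ga <- generateAlignment(cfg)
  gr <- generateResponses(ga$alignment, ga$plantedPositions, cfg)
  st <- generateStructure(cfg, ga$plantedPositions,
                          clusterPlanted = clusterPlanted)
  ds <- new("SyntheticDataset", alignment = ga$alignment,
            responses = gr$responses, structure = st,
            truth = list(plantedPositions = ga$plantedPositions,
                         backgroundPositions = ga$backgroundPositions,
                         beta = gr$beta, config = unclass(cfg)))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeAlignment(ga$alignment, file.path(dir, "alignment.fasta"))
    writeResponseMatrix(gr$responses, file.path(dir, "responses.csv"))
    writeStructure(st, file.path(dir, "structure.pdb"))
    jsonlite::write_json(
      list(plantedPositions = ga$plantedPositions,
           backgroundPositions = ga$backgroundPositions,
           seed = cfg$seed,
           config = unclass(cfg)[setdiff(names(cfg), "plantedPositions")]),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  ds
}
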