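## Pipeline driver behind the command-line wrapper (inst/scripts/orthosdp.R):
## one entry point running any stage, or all of them, against a shared
## configuration, writing TSV/JSON outputs plus a machine-readable manifest.

#' Run configuration for the pipeline driver
#'
#' @param alignmentPath,responsesPath,structurePath Input file paths (only
#'   those needed by the invoked stage are required).
#' @param referenceId Reference record in the alignment.
#' @param k Top-set size (default 20).
#' @param radius Neighborhood radius in Angstroms (default 15).
#' @param seedResidues Reference indices seeding the structural
#'   neighborhoods (default \code{c(166, 265)}, the entrance and
#'   binding-pocket anchors).
#' @param alpha Similarity weight exponent (default 1).
#' @param nShuffles Control permutations (default 1000).
#' @param seed Integer seed (default 1).
#' @param outDir Output directory (default \code{"orthosdp-out"}).
#' @param enrichParams Optional list(N, K, n, k) for the parameters-only
#'   enrichment mode (no structure file needed).
#' @return Validated list of class \code{RunConfig}.
#' @export
runConfig <- function(alignmentPath = NULL, responsesPath = NULL,
                      structurePath = NULL, referenceId = NULL, k = 20L,
                      radius = 15, seedResidues = c(166L, 265L), alpha = 1,
                      nShuffles = 1000L, seed = 1L, outDir = "orthosdp-out",
                      enrichParams = NULL) {
  cfg <- list(alignmentPath = alignmentPath, responsesPath = responsesPath,
              structurePath = structurePath, referenceId = referenceId,
              k = as.integer(k), radius = radius,
              seedResidues = as.integer(seedResidues), alpha = alpha,
              nShuffles = as.integer(nShuffles), seed = as.integer(seed),
              outDir = outDir, enrichParams = enrichParams)
  if (cfg$k < 1L) stop("invalid config: k must be >= 1")
  if (cfg$radius <= 0) stop("invalid config: radius must be positive")
  if (cfg$nShuffles < 1L) stop("invalid config: nShuffles must be >= 1")
  class(cfg) <- "RunConfig"
  cfg
}

progressMsg <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}

loadInputs <- function(cfg, need = c("aln", "resp")) {
  out <- list()
  if ("aln" %in% need) {
    if (is.null(cfg$alignmentPath) || !file.exists(cfg$alignmentPath %||% ""))
      stop("alignment file not found: ", cfg$alignmentPath %||% "<unset>")
    if (is.null(cfg$referenceId)) stop("invalid config: referenceId required")
    out$aln <- readAlignment(cfg$alignmentPath, cfg$referenceId)
  }
  if ("resp" %in% need) {
    if (is.null(cfg$responsesPath) || !file.exists(cfg$responsesPath %||% ""))
      stop("responses file not found: ", cfg$responsesPath %||% "<unset>")
    out$resp <- readResponseMatrix(cfg$responsesPath)
  }
  if ("struct" %in% need) {
    if (is.null(cfg$structurePath) || !file.exists(cfg$structurePath %||% ""))
      stop("structure file not found: ", cfg$structurePath %||% "<unset>")
    out$struct <- readStructure(cfg$structurePath)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a pipeline stage
#'
#' Subcommands: \code{simulate} (write a synthetic dataset into the output
#' directory), \code{rank} (position scores + top-k), \code{loo}
#' (leave-one-out prediction report), \code{robustness} (jackknife),
#' \code{enrich} (structural enrichment at each seed residue plus their
#' union, or parameters-only if \code{enrichParams} is set), \code{all}
#' (rank, loo, robustness, enrich in sequence). Every run writes
#' \code{manifest.json} recording the inputs, configuration, package version
#' and config hash. On failure the stage's partial outputs are removed.
#'
#' @param subcommand One of \code{"simulate"}, \code{"rank"}, \code{"loo"},
#'   \code{"robustness"}, \code{"enrich"}, \code{"all"}.
#' @param cfg A \code{\link{runConfig}}.
#' @return Invisibly, a character vector of the files written.
#' @export
runPipeline <- function(subcommand, cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  subcommand <- match.arg(subcommand,
    c("simulate", "rank", "loo", "robustness", "enrich", "all"))
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  hash <- configHash(cfg[!vapply(cfg, is.null, logical(1))])
  written <- character(0)
  out <- function(f) file.path(cfg$outDir, f)

  run <- function(expr) {
    tryCatch(expr, error = function(e) {
      existing <- written[file.exists(written)]
      if (length(existing)) unlink(existing)
      stop(conditionMessage(e), call. = FALSE)
    })
  }

  run({
    if (subcommand == "simulate") {
      progressMsg("simulate: generating synthetic dataset (seed ",
                  cfg$seed, ")")
      gcfg <- generatorConfig(seed = cfg$seed)
      generateDataset(gcfg, dir = cfg$outDir)
      written <- c(written, out("alignment.fasta"), out("responses.csv"),
                   out("structure.pdb"), out("truth.json"))
    }
    if (subcommand %in% c("rank", "all")) {
      io <- loadInputs(cfg)
      progressMsg("rank: scoring ", alignmentLength(io$aln), " columns")
      pst <- rankPositions(io$aln, io$resp, k = cfg$k)
      writePositionTable(pst, out("positions.tsv"), aln = io$aln)
      idm <- pairwiseIdentity(io$aln)
      utils::write.table(
        data.frame(receptor_id = rownames(idm), formatNum(idm),
                   check.names = FALSE),
        out("pairwise_identity.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      written <- c(written, out("positions.tsv"),
                   out("pairwise_identity.tsv"))
    }
    if (subcommand %in% c("loo", "all")) {
      io <- loadInputs(cfg)
      progressMsg("loo: evaluating ", length(receptorIds(io$aln)),
                  " held-out receptors (", cfg$nShuffles, " shuffles each)")
      report <- looEvaluate(io$aln, io$resp, k = cfg$k,
                            nShuffles = cfg$nShuffles, seed = cfg$seed,
                            alpha = cfg$alpha)
      writePredictionReport(report, out("loo_predictions.tsv"),
                            out("loo_summary.json"))
      written <- c(written, out("loo_predictions.tsv"),
                   out("loo_summary.json"))
    }
    if (subcommand %in% c("robustness", "all")) {
      io <- loadInputs(cfg)
      progressMsg("robustness: jackknife over ",
                  length(receptorIds(io$aln)), " exclusions")
      jk <- jackknifeTopPositions(io$aln, io$resp, k = cfg$k)
      writeJackknife(jk, out("jackknife_frequency.tsv"),
                     out("jackknife_summary.json"))
      written <- c(written, out("jackknife_frequency.tsv"),
                   out("jackknife_frequency.retention.tsv"),
                   out("jackknife_summary.json"))
    }
    if (subcommand %in% c("enrich", "all")) {
      if (!is.null(cfg$enrichParams)) {
        p <- cfg$enrichParams
        progressMsg("enrich (parameters-only): N=", p$N, " K=", p$K,
                    " n=", p$n, " k=", p$k)
        e <- hypergeomEnrichment(p$N, p$K, p$n, p$k)
        writeEnrichment(e, out("enrichment_params.json"))
        written <- c(written, out("enrichment_params.json"))
      } else {
        io <- loadInputs(cfg, need = c("aln", "resp", "struct"))
        pst <- rankPositions(io$aln, io$resp, k = cfg$k)
        rm <- buildReferenceMap(io$aln)
        top <- rm$columnToRef[topPositions(pst)]
        top <- top[!is.na(top)]
        tests <- list()
        for (sr in cfg$seedResidues) {
          progressMsg("enrich: seed residue ", sr, ", radius ", cfg$radius)
          e <- enrichmentTest(io$struct, top, sr, radius = cfg$radius,
                              N = rm$refLength)
          f <- out(sprintf("enrichment_seed%d.json", sr))
          writeEnrichment(e, f,
                          out(sprintf("enrichment_seed%d.tsv", sr)),
                          top = top)
          written <- c(written, f, out(sprintf("enrichment_seed%d.tsv", sr)))
          tests[[as.character(sr)]] <- e
        }
        if (length(tests) >= 2L) {
          u <- unionEnrichment(tests[[1]], tests[[2]], top, tests[[1]]@N)
          writeEnrichment(u, out("enrichment_union.json"))
          written <- c(written, out("enrichment_union.json"))
        }
      }
    }
    manifest <- list(
      subcommand = subcommand,
      configHash = hash,
      config = cfg[!vapply(cfg, is.null, logical(1))],
      packageVersion = as.character(utils::packageVersion("OrthoSDP")),
      files = basename(written),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, out("manifest.json"))
  })
  invisible(written)
}
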