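## Constructors and readers/writers for the three input kinds (aligned FASTA,
## response CSV, PDB structure), the reference-numbering map, and the
## pairwise-identity matrix.

#' Construct an OrthologAlignment
#'
#' @param seqs Named character vector of aligned sequences (equal length, gap
#'   \code{"-"}) or an \code{\link[Biostrings]{AAStringSet}}.
#' @param referenceId Name of the reference record.
#' @return An \code{\linkS4class{OrthologAlignment}}. Letters are upper-cased
#'   and \code{"."} gaps normalized to \code{"-"}.
#' @examples
#' OrthologAlignment(c(mel = "MAKG", sim = "MVKG"), referenceId = "mel")
#' @export
OrthologAlignment <- function(seqs, referenceId) {
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (!is.character(seqs)) stop("seqs must be character or AAStringSet")
  seqs <- toupper(seqs)
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  w <- nchar(seqs)
  if (length(unique(w)) > 1L)
    stop("alignment error: records have unequal lengths (",
         paste(unique(w), collapse = ", "), ")")
  if (!referenceId %in% names(seqs))
    stop("lookup error: reference id '", referenceId,
         "' not among the records")
  new("OrthologAlignment", seqs = Biostrings::AAStringSet(seqs),
      referenceId = as.character(referenceId))
}

#' Read an aligned FASTA file of orthologous receptors
#'
#' @param path Path to an aligned FASTA file (equal-width records).
#' @param referenceId Record name to use as the reference.
#' @return An \code{\linkS4class{OrthologAlignment}}.
#' @seealso \code{\link{writeAlignment}}
#' @export
readAlignment <- function(path, referenceId) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e) stop("format error reading '", path,
                                          "': ", conditionMessage(e)))
  if (length(ss) == 0L) stop("format error: no FASTA records in ", path)
  ## keep only the first whitespace-delimited token of each header
  names(ss) <- sub("\\s.*$", "", names(ss))
  OrthologAlignment(ss, referenceId)
}

#' Write an alignment to FASTA
#'
#' @param aln An \code{OrthologAlignment}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeAlignment <- function(aln, path) {
  stopifnot(is(aln, "OrthologAlignment"))
  Biostrings::writeXStringSet(aln@seqs, filepath = path)
  invisible(path)
}

## alignment as a character matrix (receptors x columns)
seqMatrix <- function(aln) {
  m <- do.call(rbind, strsplit(as.character(aln@seqs), "", fixed = TRUE))
  rownames(m) <- receptorIds(aln)
  m
}

#' Map alignment columns to reference residue numbering
#'
#' Columns where the reference record carries a residue are numbered
#' consecutively 1..refLength; columns where the reference is gapped have no
#' reference index (NA).
#'
#' @param aln An \code{OrthologAlignment}.
#' @return List with \code{columnToRef} (integer vector, one entry per
#'   alignment column, NA where unmapped) and \code{refLength}.
#' @examples
#' aln <- OrthologAlignment(c(r = "M-KG", s = "MAKG"), referenceId = "r")
#' buildReferenceMap(aln)
#' @export
buildReferenceMap <- function(aln) {
  stopifnot(is(aln, "OrthologAlignment"))
  refChars <- strsplit(as.character(aln@seqs[[aln@referenceId]]), "",
                       fixed = TRUE)[[1]]
  isRes <- refChars != "-"
  columnToRef <- rep(NA_integer_, length(refChars))
  columnToRef[isRes] <- seq_len(sum(isRes))
  list(columnToRef = columnToRef, refLength = sum(isRes))
}

#' Construct a ResponseMatrix
#'
#' @param values Numeric matrix (receptors x odorants) with dimnames, or a
#'   data.frame coercible to one. NA marks a missing measurement.
#' @return A \code{\linkS4class{ResponseMatrix}}.
#' @export
ResponseMatrix <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("ResponseMatrix", values = values)
}

#' Read a receptor-by-odorant response CSV
#'
#' Expected layout: header row \code{receptor_id,<odorant>,...}; one row per
#' receptor; numeric cells, empty cell = missing.
#'
#' @param path Path to the CSV file.
#' @return A \code{\linkS4class{ResponseMatrix}} preserving row/column order.
#' @seealso \code{\link{writeResponseMatrix}}
#' @export
readResponseMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("format error: no receptor rows in ", path)
  if (ncol(df) < 2L) stop("format error: no odorant columns in ", path)
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("format error: duplicate receptor ids")
  odorants <- colnames(df)[-1]
  if (anyDuplicated(odorants)) stop("format error: duplicate odorant labels")
  cells <- as.matrix(df[, -1, drop = FALSE])
  cells[cells == ""] <- NA_character_
  bad <- !is.na(cells) & is.na(suppressWarnings(as.numeric(cells)))
  if (any(bad))
    stop("format error: non-numeric cell(s): ",
         paste(utils::head(cells[bad], 3), collapse = ", "))
  v <- matrix(suppressWarnings(as.numeric(cells)), nrow = nrow(cells),
              dimnames = list(ids, odorants))
  ResponseMatrix(v)
}

#' Write a response matrix to CSV
#'
#' @param m A \code{ResponseMatrix}.
#' @param path Output path. Missing entries are written as empty cells.
#' @return Invisibly, \code{path}.
#' @export
writeResponseMatrix <- function(m, path) {
  stopifnot(is(m, "ResponseMatrix"))
  v <- m@values
  chr <- matrix(ifelse(is.na(v), NA_character_, sprintf("%.12g", v)),
                nrow = nrow(v), dimnames = dimnames(v))
  df <- data.frame(receptor_id = rownames(v),
                   chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("receptor_id", colnames(v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Construct a StructureModel
#'
#' @param coords Numeric n-by-3 coordinate matrix (Angstroms).
#' @param refIndex Integer vector of 1-based reference residue indices.
#' @param chainId Chain label.
#' @return A \code{\linkS4class{StructureModel}}.
#' @export
StructureModel <- function(coords, refIndex, chainId = "A") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  rownames(coords) <- as.integer(refIndex)
  colnames(coords) <- c("x", "y", "z")
  new("StructureModel", coords = coords, chainId = as.character(chainId))
}

#' Read residue coordinates from a PDB file
#'
#' One representative alpha-carbon coordinate is taken per residue; the PDB
#' residue numbers are interpreted as reference numbering. Residues of the
#' chain lacking a CA atom are skipped with a warning.
#'
#' @param path Path to a PDB file.
#' @param chainId Chain to read (default \code{"A"}).
#' @param refLength Optional reference length; residues numbered outside
#'   \code{[1, refLength]} raise an error.
#' @return A \code{\linkS4class{StructureModel}}.
#' @seealso \code{\link{writeStructure}}
#' @export
readStructure <- function(path, chainId = "A", refLength = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path)
  atoms <- pdb$atom[pdb$atom$chain == chainId, , drop = FALSE]
  if (nrow(atoms) == 0L)
    stop("lookup error: chain '", chainId, "' not present in ", path)
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  missing <- setdiff(unique(atoms$resno), ca$resno)
  if (length(missing))
    warning("skipping ", length(missing),
            " residue(s) without a CA atom: ",
            paste(utils::head(missing, 5), collapse = ", "))
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  if (!is.null(refLength) &&
      (any(ca$resno < 1L) || any(ca$resno > refLength)))
    stop("residue number outside [1, ", refLength, "]")
  StructureModel(cbind(ca$x, ca$y, ca$z), ca$resno, chainId)
}

#' Write a structure model to PDB
#'
#' @param s A \code{StructureModel}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeStructure <- function(s, path) {
  stopifnot(is(s, "StructureModel"))
  idx <- refIndices(s)
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(s@coords)),
                   resno = idx,
                   resid = rep("ALA", length(idx)),
                   elety = rep("CA", length(idx)),
                   chain = rep(s@chainId, length(idx)))
  invisible(path)
}

#' Percent pairwise identity between aligned records
#'
#' For each pair, identity = 100 x (columns with identical non-gap residues)
#' / (columns where at least one of the two is non-gap); columns gapped in
#' both sequences are excluded from the denominator. \code{"X"} matches
#' nothing, including another \code{"X"}.
#'
#' @param aln An \code{OrthologAlignment} with at least two records.
#' @return Symmetric numeric matrix of percent identities, 100 on the
#'   diagonal.
#' @examples
#' aln <- OrthologAlignment(c(a = "ACDE", b = "ACEE"), referenceId = "a")
#' pairwiseIdentity(aln)  # 75 off the diagonal
#' @export
pairwiseIdentity <- function(aln) {
  stopifnot(is(aln, "OrthologAlignment"))
  m <- seqMatrix(aln)
  n <- nrow(m)
  if (n < 2L) stop("need at least two records")
  out <- matrix(100, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      a <- m[i, ]; b <- m[j, ]
      denom <- sum(a != "-" | b != "-")
      match <- sum(a == b & a != "-" & a != "X")
      out[i, j] <- out[j, i] <- 100 * match / denom
    }
  }
  out
}

## fixed 6-significant-digit formatting for deterministic text outputs
formatNum <- function(x) {
  if (is.matrix(x)) {
    y <- apply(x, 2, function(col)
      ifelse(is.na(col), NA_character_, format(signif(col, 6), trim = TRUE,
                                               scientific = FALSE)))
    dimnames(y) <- dimnames(x)
    return(y)
  }
  ifelse(is.na(x), NA_character_,
         format(signif(x, 6), trim = TRUE, scientific = FALSE))
}
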