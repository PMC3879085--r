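## Serialize a PDBStructure back to PDB text. Control records (MODEL,
## ENDMDL, TER, END) are regenerated, never copied from the input.

## One TER is emitted after each chain containing at least one residue with
## a non-HETATM atom (polymeric chain); pure-heteroatom chains (waters,
## ligands) get none. The TER consumes one serial in the atom numbering.
.chainIsPolymeric <- function(ch) {
  for (r in ch@residues)
    for (a in r@atoms) if (!a@isHetatm) return(TRUE)
  FALSE
}

## Flatten one chain's atoms into an AtomRecord data.frame (vectorized;
## one data.frame per chain, not per atom)
.chainRecords <- function(ch) {
  rs <- ch@residues
  nA <- vapply(rs, function(r) length(r@atoms), integer(1))
  atomsL <- unlist(lapply(rs, function(r) r@atoms), recursive = FALSE)
  if (!length(atomsL)) return(.emptyRecords())
  xyz <- vapply(atomsL, function(a) a@coord, numeric(3))
  data.frame(
    lineNo = NA_integer_,
    serial = vapply(atomsL, function(a) a@serial, integer(1)),
    name = vapply(atomsL, function(a) a@name, character(1)),
    altLoc = vapply(atomsL, function(a) a@altLoc, character(1)),
    resName = rep(vapply(rs, function(r) r@resName, character(1)), nA),
    chainId = ch@chainId,
    resSeq = rep(vapply(rs, function(r) r@resSeq, integer(1)), nA),
    insCode = rep(vapply(rs, function(r) r@insCode, character(1)), nA),
    x = xyz[1, ], y = xyz[2, ], z = xyz[3, ],
    occupancy = vapply(atomsL, function(a) a@occupancy, numeric(1)),
    bFactor = vapply(atomsL, function(a) a@bFactor, numeric(1)),
    segId = vapply(atomsL, function(a) a@segId, character(1)),
    element = vapply(atomsL, function(a) a@element, character(1)),
    charge = vapply(atomsL, function(a) a@charge, character(1)),
    isHetatm = vapply(atomsL, function(a) a@isHetatm, logical(1)),
    stringsAsFactors = FALSE)
}

.terLine <- function(serialNo, resNamec, chainIdc, resSeqv, insCodec) {
  sprintf("TER   %5d      %3s %1s%4d%1s", serialNo, resNamec, chainIdc,
          resSeqv, insCodec)
}

#' Write a structure as PDB text
#'
#' Emits leading metadata, then for each model the coordinate lines of its
#' chains with a `TER` after every polymeric chain, then trailing metadata
#' and a final `END`. `MODEL`/`ENDMDL` brackets are written for multi-model
#' structures (and for a lone model whose id is not 1, so that the id
#' survives a round trip). With `renumber = TRUE` atom serials are
#' regenerated per model in document order, the `TER` after each polymeric
#' chain consuming one serial.
#'
#' @param s a [PDBStructure-class].
#' @param renumber regenerate atom serials while writing; with the default
#'   `FALSE`, stored serials are used and must fit their 5-column field.
#' @return a single string of PDB text, every line at most 80 characters.
#' @examples
#' s <- syntheticStructure(fixtureSpec(nModels = 1, residuesPerChain = 2))
#' cat(substr(writePDB(s), 1, 200))
#' @export
writePDB <- function(s, renumber = FALSE) {
  stopifnot(is(s, "PDBStructure"))
  out <- character()
  out <- c(out, s@metaBefore)
  nm <- length(s@models)
  emitBrackets <- nm > 1L || (nm == 1L && s@models[[1]]@modelId != 1L)
  for (m in s@models) {
    if (emitBrackets) out <- c(out, sprintf("MODEL%9d", m@modelId))
    counter <- 0L
    for (ch in m@chains) {
      rec <- .chainRecords(ch)
      if (nrow(rec)) {
        if (renumber) {
          rec$serial <- counter + seq_len(nrow(rec))
          counter <- counter + nrow(rec)
        }
        out <- c(out, formatCoordLine(rec))
      }
      if (.chainIsPolymeric(ch) && nrow(rec)) {
        lastPoly <- NULL
        for (r in ch@residues)
          if (any(!vapply(r@atoms, isHetatm, logical(1)))) lastPoly <- r
        terSerial <- if (renumber) {
          counter <- counter + 1L
          counter
        } else rec$serial[nrow(rec)] + 1L
        out <- c(out, .terLine(min(terSerial, 99999L), lastPoly@resName,
                               ch@chainId, lastPoly@resSeq,
                               lastPoly@insCode))
      }
    }
    if (emitBrackets) out <- c(out, "ENDMDL")
  }
  out <- c(out, s@metaAfter, "END")
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Write a structure to a PDB file
#'
#' Paths ending in `.gz` are written gzip-compressed.
#'
#' @inheritParams writePDB
#' @param path output path; `.gz` suffix selects gzip output.
#' @return `path`, invisibly.
#' @export
writePDBFile <- function(s, path, renumber = FALSE) {
  txt <- writePDB(s, renumber = renumber)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeChar(txt, con, eos = NULL)
  invisible(path)
}

#' Normalize a structure for strict-format consumers
#'
#' Returns a copy whose written output passes a strict re-parse with zero
#' errors: string fields are stripped and truncated to their column widths,
#' atom serials are regenerated (the `TER` after each polymeric chain
#' consuming one serial), residue numbers are optionally rebuilt starting
#' from 1 per chain, and metadata lines outside the known record vocabulary
#' are dropped. Idempotent.
#'
#' @param s a [PDBStructure-class].
#' @param renumberRes also renumber residues 1..n per chain (clears
#'   insertion codes).
#' @return a normalized [PDBStructure-class].
#' @examples
#' s <- syntheticStructure(fixtureSpec())
#' res <- parsePDB(writePDB(clean(s)), strict = TRUE)
#' nrow(parseErrors(res))
#' @export
clean <- function(s, renumberRes = FALSE) {
  stopifnot(is(s, "PDBStructure"))
  clip <- function(x, w) substr(trimws(x), 1L, w)
  clip1 <- function(x) if (nchar(x) == 1L) x else substr(paste0(x, " "), 1L, 1L)
  s <- mapOver(s, "atom", function(a) {
    a@name <- clip(a@name, 4L)
    a@altLoc <- clip1(a@altLoc)
    a@segId <- clip(a@segId, 4L)
    a@element <- clip(a@element, 2L)
    a@charge <- clip(a@charge, 2L)
    a
  })
  s <- mapOver(s, "residue", function(r) {
    r@resName <- clip(r@resName, 3L)
    r@insCode <- clip1(r@insCode)
    r
  })
  s <- mapOver(s, "chain", function(ch) {
    ch@chainId <- clip1(ch@chainId)
    if (renumberRes) renumberResidues(ch) else ch
  })
  keep <- classifyLine(s@metaBefore) == "METADATA"
  s@metaBefore <- s@metaBefore[keep]
  keep <- classifyLine(s@metaAfter) == "METADATA"
  s@metaAfter <- s@metaAfter[keep]
  renumberAtoms(s)
}
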