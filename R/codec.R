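## Column-exact codec for single PDB coordinate-section lines.
## All column positions are 1-based, per the PDB v3.3 fixed-width layout:
##   record 1-6, serial 7-11, name 13-16, altLoc 17, resName 18-20,
##   chainID 22, resSeq 23-26, iCode 27, x 31-38, y 39-46, z 47-54,
##   occupancy 55-60, tempFactor 61-66, segID 73-76, element 77-78,
##   charge 79-80.

## Record names of the v3.3 vocabulary that this package does not interpret;
## lines carrying them are preserved verbatim as structure metadata.
.METADATA_RECORDS <- c(
  "HEADER", "OBSLTE", "TITLE", "SPLIT", "CAVEAT", "COMPND", "SOURCE",
  "KEYWDS", "EXPDTA", "NUMMDL", "MDLTYP", "AUTHOR", "REVDAT", "SPRSDE",
  "JRNL", "REMARK", "DBREF", "DBREF1", "DBREF2", "SEQADV", "SEQRES",
  "MODRES", "HET", "HETNAM", "HETSYN", "FORMUL", "HELIX", "SHEET",
  "SSBOND", "LINK", "CISPEP", "SITE", "CRYST1", "ORIGX1", "ORIGX2",
  "ORIGX3", "SCALE1", "SCALE2", "SCALE3", "MTRIX1", "MTRIX2", "MTRIX3",
  "ANISOU", "SIGATM", "SIGUIJ", "CONECT", "MASTER")

.RECORD_COLUMNS <- list(
  serial = c(7L, 11L), name = c(13L, 16L), altLoc = c(17L, 17L),
  resName = c(18L, 20L), chainId = c(22L, 22L), resSeq = c(23L, 26L),
  insCode = c(27L, 27L), x = c(31L, 38L), y = c(39L, 46L), z = c(47L, 54L),
  occupancy = c(55L, 60L), bFactor = c(61L, 66L), segId = c(73L, 76L),
  element = c(77L, 78L), charge = c(79L, 80L))

## Input is single-byte text: lines that are not valid UTF-8 are marked
## latin1 so substr/nchar slice them bytewise instead of erroring. Callers
## keep their own originals where verbatim storage is required.
.bytes <- function(x) {
  bad <- !validUTF8(x)
  if (any(bad)) {
    y <- x[bad]
    Encoding(y) <- "latin1"
    x[bad] <- y
  }
  x
}

#' Classify a PDB line by its record name
#'
#' Classification depends only on columns 1-6. Vectorized over lines.
#'
#' @param line character vector of lines, trailing newline removed.
#' @return character vector with values `"COORD"` (`ATOM`/`HETATM`),
#'   `"TER"`, `"MODEL"`, `"ENDMDL"`, `"END"`, `"METADATA"` (any other known
#'   v3.3 record name) or `"UNKNOWN"`.
#' @examples
#' classifyLine(c("ATOM      1  N   MET A   1", "REMARK 350", "FOOBAR"))
#' @export
classifyLine <- function(line) {
  line <- .bytes(line)
  rec <- substr(line, 1L, 6L)
  ## non-ASCII bytes can never be part of a record name; neutralize them
  ## so comparisons below stay bytewise-safe
  rec <- gsub("[^ -~]", "?", rec, useBytes = TRUE)
  name <- sub("[ ]+$", "", rec, useBytes = TRUE)
  kind <- rep("UNKNOWN", length(line))
  kind[rec == "ATOM  " | rec == "HETATM"] <- "COORD"
  kind[name == "TER"] <- "TER"
  kind[name == "MODEL"] <- "MODEL"
  kind[name == "ENDMDL"] <- "ENDMDL"
  kind[name == "END"] <- "END"
  kind[kind == "UNKNOWN" & name %in% .METADATA_RECORDS] <- "METADATA"
  kind
}

## bytewise trim, safe for lines that are not valid text in any encoding
.trimB <- function(x) gsub("^[ \t]+|[ \t]+$", "", x, useBytes = TRUE)

.padTo <- function(line, width) {
  n <- nchar(line)
  short <- n < width
  if (any(short))
    line[short] <- paste0(line[short],
                          strrep(" ", width - n[short]))
  line
}

## Vectorized decode of COORD lines. Returns list(records, errors) where
## records is the AtomRecord data.frame for the lines that decoded, errors
## the ParseError data.frame for those that did not.
.decodeCoordLines <- function(line, lineNo, strict = FALSE) {
  n <- length(line)
  if (!n) return(list(records = .emptyRecords(), errors = .emptyErrors()))
  raw <- line
  line <- .bytes(line)
  len <- nchar(line, type = "bytes")
  padded <- .padTo(line, 80L)
  fld <- function(key) {
    cc <- .RECORD_COLUMNS[[key]]
    substr(padded, cc[1], cc[2])
  }
  numfld <- function(key) suppressWarnings(as.numeric(fld(key)))
  blankfld <- function(key) !nzchar(.trimB(fld(key)))
  ## columns that exist only beyond the original line length are "absent",
  ## as opposed to present-but-blank
  absent <- function(key) len < .RECORD_COLUMNS[[key]][1]

  reason <- rep(NA_character_, n)
  note <- function(bad, msg) {
    hit <- bad & is.na(reason)
    reason[hit] <<- msg
  }

  serial <- numfld("serial")
  resSeq <- numfld("resSeq")
  x <- numfld("x"); y <- numfld("y"); z <- numfld("z")
  occ <- numfld("occupancy"); b <- numfld("bFactor")

  if (any(strict & len < 66L))
    note(strict & len < 66L, "line shorter than 66 columns (strict)")
  note(is.na(serial), "serial is not a number")
  note(is.na(resSeq), "residue sequence number is not a number")
  note(is.na(x), "x-coordinate is not a number")
  note(is.na(y), "y-coordinate is not a number")
  note(is.na(z), "z-coordinate is not a number")
  ## occupancy/B: lenient mode substitutes defaults for absent trailing
  ## columns; garbage in a present column is an error either way
  occAbsent <- absent("occupancy") | (!strict & blankfld("occupancy"))
  bAbsent <- absent("bFactor") | (!strict & blankfld("bFactor"))
  note(is.na(occ) & !occAbsent, "occupancy is not a number")
  note(is.na(b) & !bAbsent, "temperature factor is not a number")
  occ[occAbsent] <- 1.00
  b[bAbsent] <- 0.00

  ok <- is.na(reason)
  altLoc <- fld("altLoc"); altLoc[!nzchar(altLoc)] <- " "
  chainId <- fld("chainId"); chainId[!nzchar(chainId)] <- " "
  insCode <- fld("insCode"); insCode[!nzchar(insCode)] <- " "
  records <- data.frame(
    lineNo = lineNo[ok],
    serial = as.integer(serial[ok]),
    name = .trimB(fld("name"))[ok],
    altLoc = altLoc[ok],
    resName = .trimB(fld("resName"))[ok],
    chainId = chainId[ok],
    resSeq = as.integer(resSeq[ok]),
    insCode = insCode[ok],
    x = x[ok], y = y[ok], z = z[ok],
    occupancy = occ[ok], bFactor = b[ok],
    segId = .trimB(fld("segId"))[ok],
    element = .trimB(fld("element"))[ok],
    charge = .trimB(fld("charge"))[ok],
    isHetatm = (substr(padded, 1L, 6L) == "HETATM")[ok],
    stringsAsFactors = FALSE)
  errors <- data.frame(lineNo = lineNo[!ok], line = raw[!ok],
                       reason = reason[!ok], stringsAsFactors = FALSE)
  list(records = records, errors = errors)
}

.emptyRecords <- function() {
  data.frame(lineNo = integer(), serial = integer(), name = character(),
             altLoc = character(), resName = character(),
             chainId = character(), resSeq = integer(),
             insCode = character(), x = numeric(), y = numeric(),
             z = numeric(), occupancy = numeric(), bFactor = numeric(),
             segId = character(), element = character(),
             charge = character(), isHetatm = logical(),
             stringsAsFactors = FALSE)
}

.emptyErrors <- function() {
  data.frame(lineNo = integer(), line = character(), reason = character(),
             stringsAsFactors = FALSE)
}

#' Decode one ATOM/HETATM line
#'
#' Slices the fixed columns of a single coordinate record. In strict mode
#' the line must be at least 66 columns and every numeric field must parse;
#' in lenient mode absent trailing columns fall back to occupancy 1.00,
#' B-factor 0.00 and empty segID/element/charge. Failures are returned as a
#' value, never raised.
#'
#' @param line one line, trailing newline removed; `classifyLine(line)`
#'   must be `"COORD"`.
#' @param lineNo 1-based source line number recorded in the result.
#' @param strict require full-width, fully numeric records.
#' @return a one-row data.frame: class `AtomRecord` on success (columns
#'   `lineNo`, `serial`, `name`, `altLoc`, `resName`, `chainId`, `resSeq`,
#'   `insCode`, `x`, `y`, `z`, `occupancy`, `bFactor`, `segId`, `element`,
#'   `charge`, `isHetatm`), class `ParseError` (columns `lineNo`, `line`,
#'   `reason`) on failure. Test with [isParseError()].
#' @examples
#' rec <- parseCoordLine(
#'   "ATOM      1  N   MET A   1      38.000  12.000  -5.000  1.00 20.00           N")
#' rec$name
#' @export
parseCoordLine <- function(line, lineNo = 1L, strict = FALSE) {
  stopifnot(length(line) == 1L)
  out <- .decodeCoordLines(line, as.integer(lineNo), strict = strict)
  if (nrow(out$errors)) {
    structure(out$errors, class = c("ParseError", "data.frame"))
  } else {
    structure(out$records, class = c("AtomRecord", "data.frame"))
  }
}

#' Is this value a parse error?
#'
#' @param x a value returned by [parseCoordLine()] or [parseControlLine()].
#' @return `TRUE` if `x` carries a `ParseError`.
#' @export
isParseError <- function(x) inherits(x, "ParseError")

## Atom-name justification: one-character elements start at column 14,
## two-character elements at column 13; 4-character names fill 13-16.
## When the element field is empty the name's leading digit (e.g. "1HB2")
## marks a column-13 start, otherwise a one-character element is assumed.
.justifyAtomName <- function(name, element) {
  wide <- nchar(element) == 2L | nchar(name) >= 4L |
    grepl("^[0-9]", name)
  ifelse(wide, sprintf("%-4s", name), sprintf(" %-3s", substr(name, 1, 3)))
}

#' Encode an atom record as one 80-character coordinate line
#'
#' The exact inverse of [parseCoordLine()] for in-range fields: serials
#' `%5d`, residue numbers `%4d`, coordinates `%8.3f`, occupancy and
#' B-factor `%6.2f`, with standard atom-name justification (one-letter
#' elements start at column 14, two-letter at column 13). Vectorized over
#' the rows of `rec`.
#'
#' @param rec a data.frame with `AtomRecord` columns (minus `lineNo`,
#'   which is ignored).
#' @return character vector of 80-character lines.
#' @examples
#' rec <- parseCoordLine(
#'   "ATOM      1  N   MET A   1      38.000  12.000  -5.000  1.00 20.00           N")
#' formatCoordLine(rec)
#' @export
formatCoordLine <- function(rec) {
  if (!nrow(rec)) return(character())
  over <- rec$serial > 99999L | rec$serial < 0L
  if (any(over))
    stop("atom serial ", rec$serial[which(over)[1]],
         " does not fit the 5-column field; renumber before writing",
         call. = FALSE)
  over <- rec$resSeq > 9999L | rec$resSeq < -999L
  if (any(over))
    stop("residue number ", rec$resSeq[which(over)[1]],
         " does not fit the 4-column field", call. = FALSE)
  sprintf("%s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f      %-4s%2s%2s",
          ifelse(rec$isHetatm, "HETATM", "ATOM  "),
          rec$serial,
          .justifyAtomName(rec$name, rec$element),
          rec$altLoc, rec$resName, rec$chainId, rec$resSeq, rec$insCode,
          rec$x, rec$y, rec$z, rec$occupancy, rec$bFactor,
          rec$segId, rec$element, rec$charge)
}

#' Decode a control record (TER, MODEL, ENDMDL, END)
#'
#' The bare `"TER"` dialect (no serial or residue context) is accepted, as
#' many tools emit it. `MODEL` serials are read from columns 11-14.
#'
#' @param line one line; `classifyLine(line)` must be one of `"TER"`,
#'   `"MODEL"`, `"ENDMDL"`, `"END"`.
#' @param lineNo 1-based source line number.
#' @return a list of class `ControlRecord` with elements `kind` and, for
#'   `MODEL`, `modelId`; or a `ParseError` data.frame for a non-numeric
#'   model id.
#' @examples
#' parseControlLine("MODEL        2")$modelId
#' @export
parseControlLine <- function(line, lineNo = 1L) {
  kind <- classifyLine(line)
  stopifnot(kind %in% c("TER", "MODEL", "ENDMDL", "END"))
  if (kind == "MODEL") {
    idTxt <- substr(.padTo(.bytes(line), 14L), 11L, 14L)
    id <- suppressWarnings(as.integer(idTxt))
    if (is.na(id))
      return(structure(
        data.frame(lineNo = as.integer(lineNo), line = line,
                   reason = "MODEL serial is not a number",
                   stringsAsFactors = FALSE),
        class = c("ParseError", "data.frame")))
    return(structure(list(kind = "MODEL", modelId = id),
                     class = "ControlRecord"))
  }
  structure(list(kind = kind), class = "ControlRecord")
}
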