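#' @import methods
NULL

.isSingleChar <- function(x) is.character(x) && length(x) == 1L && nchar(x) == 1L

#' Atom: one atom location
#'
#' A single atom position as read from one `ATOM`/`HETATM` record. Alternate
#' locations of the same physical atom are distinct `Atom` objects (their
#' `altLoc` differs). Atom names are stored stripped of column padding; the
#' writer regenerates the PDB column justification.
#'
#' @slot serial atom serial number (non-negative integer).
#' @slot name atom name, stripped, at most 4 characters.
#' @slot altLoc alternate location indicator, single character (`" "` = none).
#' @slot coord numeric xyz coordinates in Angstrom.
#' @slot occupancy site occupancy (not constrained to \[0,1\]; real entries
#'   exceed it).
#' @slot bFactor isotropic temperature factor, Angstrom^2.
#' @slot segId segment identifier, at most 4 characters.
#' @slot element element symbol, stripped, at most 2 characters.
#' @slot charge formal charge as printed (e.g. `"2+"`), at most 2 characters.
#' @slot isHetatm `TRUE` for `HETATM` records; changes only the record name
#'   on output.
#' @export
setClass("Atom",
  representation(
    serial = "integer", name = "character", altLoc = "character",
    coord = "numeric", occupancy = "numeric", bFactor = "numeric",
    segId = "character", element = "character", charge = "character",
    isHetatm = "logical"),
  prototype(
    serial = 0L, name = "X", altLoc = " ", coord = c(0, 0, 0),
    occupancy = 1, bFactor = 0, segId = "", element = "", charge = "",
    isHetatm = FALSE),
  validity = function(object) {
    if (length(object@coord) != 3L || !all(is.finite(object@coord)))
      return("coord must be 3 finite numbers")
    if (length(object@serial) != 1L || is.na(object@serial) ||
        object@serial < 0L)
      return("serial must be a single non-negative integer")
    if (!.isSingleChar(object@altLoc))
      return("altLoc must be a single character")
    if (!is.character(object@name) || length(object@name) != 1L ||
        nchar(object@name) > 4L)
      return("name must be one string of at most 4 characters")
    if (nchar(object@element) > 2L) return("element exceeds 2 characters")
    TRUE
  })

#' Residue: one monomer
#'
#' An ordered run of atoms that share a residue name, sequence number and
#' insertion code. File order of atoms is preserved. Two atoms may share a
#' name only when their `altLoc` differs; real archive files violate this,
#' so it is reported by [lintStructure()] rather than enforced.
#'
#' @slot resName residue name, stripped, at most 3 characters.
#' @slot resSeq residue sequence number.
#' @slot insCode insertion code, single character (`" "` = none).
#' @slot atoms list of [Atom-class] objects in file order.
#' @export
setClass("Residue",
  representation(resName = "character", resSeq = "integer",
                 insCode = "character", atoms = "list"),
  prototype(resName = "UNK", resSeq = 1L, insCode = " ", atoms = list()),
  validity = function(object) {
    if (!.isSingleChar(object@insCode))
      return("insCode must be a single character")
    if (nchar(object@resName) > 3L) return("resName exceeds 3 characters")
    if (!all(vapply(object@atoms, is, logical(1), "Atom")))
      return("atoms must all be Atom objects")
    TRUE
  })

#' Chain: one polymer chain (or heteroatom run)
#'
#' @slot chainId chain identifier, single character (`" "` = blank).
#' @slot residues list of [Residue-class] objects in file order.
#' @export
setClass("Chain",
  representation(chainId = "character", residues = "list"),
  prototype(chainId = "A", residues = list()),
  validity = function(object) {
    if (!.isSingleChar(object@chainId))
      return("chainId must be a single character")
    if (!all(vapply(object@residues, is, logical(1), "Residue")))
      return("residues must all be Residue objects")
    TRUE
  })

#' Model: one model of the molecule
#'
#' X-ray entries usually hold one model; NMR ensembles hold many, bracketed
#' by `MODEL`/`ENDMDL` records.
#'
#' @slot modelId model serial number.
#' @slot chains list of [Chain-class] objects in file order.
#' @export
setClass("Model",
  representation(modelId = "integer", chains = "list"),
  prototype(modelId = 1L, chains = list()),
  validity = function(object) {
    if (length(object@modelId) != 1L || is.na(object@modelId))
      return("modelId must be a single integer")
    if (!all(vapply(object@chains, is, logical(1), "Chain")))
      return("chains must all be Chain objects")
    TRUE
  })

#' PDBStructure: a whole PDB entry
#'
#' The top of the hierarchy: models, plus all non-coordinate records kept as
#' verbatim text, tagged by whether they appeared before or after the
#' coordinate block. Metadata is never interpreted, only preserved.
#'
#' @slot models list of [Model-class] objects; model ids are unique.
#' @slot metaBefore character vector of verbatim metadata lines preceding
#'   the coordinate block.
#' @slot metaAfter character vector of verbatim metadata lines following it.
#' @export
setClass("PDBStructure",
  representation(models = "list", metaBefore = "character",
                 metaAfter = "character"),
  prototype(models = list(), metaBefore = character(),
            metaAfter = character()),
  validity = function(object) {
    if (!all(vapply(object@models, is, logical(1), "Model")))
      return("models must all be Model objects")
    ids <- vapply(object@models, function(m) m@modelId, integer(1))
    if (anyDuplicated(ids)) return("model ids must be unique")
    TRUE
  })

#' RigidTransform: rotation plus translation
#'
#' The rigid-body map `r' = R r + t` returned by [canonicalAxes()].
#'
#' @slot rotation 3x3 proper orthonormal matrix (checked to 1e-9).
#' @slot translation length-3 numeric, Angstrom.
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  prototype(rotation = diag(3), translation = c(0, 0, 0)),
  validity = function(object) {
    R <- object@rotation
    if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
    if (max(abs(R %*% t(R) - diag(3))) > 1e-9)
      return("rotation is not orthonormal within 1e-9")
    if (abs(det(R) - 1) > 1e-9)
      return("rotation must be proper (det = +1 within 1e-9)")
    if (length(object@translation) != 3L ||
        !all(is.finite(object@translation)))
      return("translation must be 3 finite numbers")
    TRUE
  })

#' PDBParseResult: parsed structure plus collected errors
#'
#' Parsing never aborts: every offending line becomes one row of `errors`
#' (columns `lineNo`, `line`, `reason`), ordered by line number, with the
#' offending text byte-identical to the input.
#'
#' @slot structure the assembled [PDBStructure-class].
#' @slot errors data.frame with columns `lineNo`, `line`, `reason`.
#' @export
setClass("PDBParseResult",
  representation(structure = "PDBStructure", errors = "data.frame"),
  prototype(structure = new("PDBStructure"),
            errors = data.frame(lineNo = integer(), line = character(),
                                reason = character(),
                                stringsAsFactors = FALSE)),
  validity = function(object) {
    e <- object@errors
    if (!all(c("lineNo", "line", "reason") %in% names(e)))
      return("errors must have columns lineNo, line, reason")
    if (is.unsorted(e$lineNo)) return("errors must be sorted by lineNo")
    if (nrow(e) && any(e$lineNo < 1L)) return("lineNo must be >= 1")
    TRUE
  })

## ---- constructors ----------------------------------------------------------

#' Construct an Atom
#'
#' @param serial atom serial number.
#' @param name atom name (stored stripped).
#' @param altLoc alternate location indicator.
#' @param coord numeric xyz, Angstrom.
#' @param occupancy,bFactor crystallographic occupancy and B-factor.
#' @param segId,element,charge trailing record fields (stripped strings).
#' @param isHetatm `TRUE` to emit as `HETATM`.
#' @return an [Atom-class] object.
#' @examples
#' Atom(1, "CA", coord = c(1, 2, 3), element = "C")
#' @export
Atom <- function(serial = 0L, name = "X", altLoc = " ", coord = c(0, 0, 0),
                 occupancy = 1, bFactor = 0, segId = "", element = "",
                 charge = "", isHetatm = FALSE) {
  new("Atom", serial = as.integer(serial), name = trimws(name),
      altLoc = altLoc, coord = as.numeric(coord),
      occupancy = as.numeric(occupancy), bFactor = as.numeric(bFactor),
      segId = segId, element = trimws(element), charge = charge,
      isHetatm = isHetatm)
}

#' Construct a Residue
#' @param resName residue name (e.g. `"ALA"`).
#' @param resSeq residue sequence number.
#' @param insCode insertion code.
#' @param atoms list of [Atom-class] objects.
#' @return a [Residue-class] object.
#' @export
Residue <- function(resName = "UNK", resSeq = 1L, insCode = " ",
                    atoms = list()) {
  new("Residue", resName = trimws(resName), resSeq = as.integer(resSeq),
      insCode = insCode, atoms = atoms)
}

#' Construct a Chain
#' @param chainId single-character chain identifier.
#' @param residues list of [Residue-class] objects.
#' @return a [Chain-class] object.
#' @export
Chain <- function(chainId = "A", residues = list()) {
  new("Chain", chainId = chainId, residues = residues)
}

#' Construct a Model
#' @param modelId model serial number.
#' @param chains list of [Chain-class] objects.
#' @return a [Model-class] object.
#' @export
Model <- function(modelId = 1L, chains = list()) {
  new("Model", modelId = as.integer(modelId), chains = chains)
}

#' Construct a PDBStructure
#' @param models list of [Model-class] objects.
#' @param metaBefore,metaAfter verbatim metadata lines before/after the
#'   coordinate block.
#' @return a [PDBStructure-class] object.
#' @export
PDBStructure <- function(models = list(), metaBefore = character(),
                         metaAfter = character()) {
  new("PDBStructure", models = models, metaBefore = metaBefore,
      metaAfter = metaAfter)
}

#' Construct a RigidTransform
#' @param rotation 3x3 proper orthonormal matrix.
#' @param translation length-3 numeric.
#' @return a [RigidTransform-class] object.
#' @export
RigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

## ---- show methods ----------------------------------------------------------

setMethod("show", "Atom", function(object) {
  cat(sprintf("Atom %d %s%s [%s] (%.3f, %.3f, %.3f) occ=%.2f B=%.2f %s\n",
              object@serial, object@name,
              if (object@altLoc != " ") paste0("/", object@altLoc) else "",
              if (object@isHetatm) "HETATM" else "ATOM",
              object@coord[1], object@coord[2], object@coord[3],
              object@occupancy, object@bFactor, object@element))
})

setMethod("show", "Residue", function(object) {
  cat(sprintf("Residue %s %d%s with %d atom(s)\n", object@resName,
              object@resSeq,
              if (object@insCode != " ") object@insCode else "",
              length(object@atoms)))
})

setMethod("show", "Chain", function(object) {
  cat(sprintf("Chain '%s' with %d residue(s)\n", object@chainId,
              length(object@residues)))
})

setMethod("show", "Model", function(object) {
  cat(sprintf("Model %d with %d chain(s)\n", object@modelId,
              length(object@chains)))
})

setMethod("show", "PDBStructure", function(object) {
  cat(sprintf(
    "PDBStructure: %d model(s), %d atom(s), %d metadata line(s)\n",
    length(object@models), countNodes(object, "atom"),
    length(object@metaBefore) + length(object@metaAfter)))
})

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform\n rotation:\n")
  print(round(object@rotation, 6))
  cat(" translation:", paste(sprintf("%.3f", object@translation),
                             collapse = " "), "\n")
})

setMethod("show", "PDBParseResult", function(object) {
  show(object@structure)
  cat(sprintf("with %d parse error(s)\n", nrow(object@errors)))
})
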