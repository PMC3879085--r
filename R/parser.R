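## Assemble the Structure -> Model -> Chain -> Residue -> Atom hierarchy
## from a PDB text stream. Parsing never aborts: every offending line is a
## row in the result's error table.

#' Parse PDB text into a structure plus collected errors
#'
#' Consecutive coordinate records are grouped in file order: a new residue
#' starts when (resName, resSeq, insCode) changes or a `TER` intervenes; a
#' new chain starts when the chain id changes or a `TER` intervenes; each
#' `MODEL` record opens a model (`ENDMDL` closes it). A file without any
#' `MODEL` record yields exactly one model with id 1. A chain id that
#' reappears after an intervening different chain opens a new chain object
#' (file-order fidelity; [lintStructure()] flags it). Coordinate records
#' falling after an `ENDMDL` but before the next `MODEL` are attached to a
#' fresh implicit model. Alternate locations stay as distinct atoms of the
#' same residue; nothing is filtered.
#'
#' Metadata records are preserved verbatim; unknown record names and
#' coordinate lines that fail to decode become [parseErrors()] entries,
#' sorted by line number.
#'
#' @param text a single string (may be empty) or a character vector of
#'   lines.
#' @param strict require full-width, fully numeric coordinate records (see
#'   [parseCoordLine()]); the default is lenient, as archived entries
#'   routinely fail strict interpretation.
#' @return a [PDBParseResult-class].
#' @examples
#' res <- parsePDB("ATOM      1  N   MET A   1      38.000  12.000  -5.000")
#' countNodes(parsedStructure(res), "atom")
#' @export
parsePDB <- function(text, strict = FALSE) {
  lines <- if (length(text) == 1L &&
               grepl("\n", text, fixed = TRUE, useBytes = TRUE)) {
    strsplit(text, "\n", fixed = TRUE, useBytes = TRUE)[[1]]
  } else if (length(text) == 1L && !nzchar(text)) {
    character()
  } else {
    text
  }
  lines <- sub("\r$", "", lines, useBytes = TRUE)
  .assemble(lines, strict = strict, workers = 1L)
}

#' Parse a PDB file, serially or in parallel
#'
#' Reads plain or gzip-compressed PDB files (compression is detected from
#' the stream, so any `.gz` path works). In parallel mode the input is
#' split at line boundaries into approximately `workers` chunks whose
#' coordinate records are decoded concurrently (fork-based); the hierarchy
#' is then assembled serially on the merged record stream, so the result is
#' bit-identical to a serial parse regardless of `workers`.
#'
#' @param path path to a PDB file, optionally gzip-compressed.
#' @param strict see [parsePDB()].
#' @param mode `"serial"` or `"parallel"`.
#' @param workers number of decoding workers for parallel mode.
#' @return a [PDBParseResult-class], identical across modes and worker
#'   counts.
#' @export
parsePDBFile <- function(path, strict = FALSE,
                         mode = c("serial", "parallel"), workers = 1L) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  lines <- readLines(path, warn = FALSE)  # file() decompresses gz
  lines <- sub("\r$", "", lines, useBytes = TRUE)
  nw <- if (mode == "parallel") max(1L, as.integer(workers)) else 1L
  .assemble(lines, strict = strict, workers = nw)
}

## Core assembly. `workers` > 1 decodes coordinate lines in parallel
## chunks; everything else is serial and order-preserving.
.assemble <- function(lines, strict, workers = 1L) {
  n <- length(lines)
  empty <- PDBStructure()
  if (!n) return(new("PDBParseResult", structure = empty,
                     errors = .emptyErrors()))
  kinds <- classifyLine(lines)
  lineNos <- seq_len(n)

  errors <- list()

  ## -- decode coordinate lines (the parallelizable part) --
  coordIdx <- which(kinds == "COORD")
  if (length(coordIdx)) {
    if (workers > 1L && .Platform$OS.type != "windows") {
      chunks <- split(coordIdx,
                      cut(seq_along(coordIdx), breaks = workers,
                          labels = FALSE))
      parts <- parallel::mclapply(chunks, function(ix)
        .decodeCoordLines(lines[ix], ix, strict = strict),
        mc.cores = workers)
      dec <- list(records = do.call(rbind, lapply(parts, `[[`, "records")),
                  errors = do.call(rbind, lapply(parts, `[[`, "errors")))
    } else {
      dec <- .decodeCoordLines(lines[coordIdx], coordIdx, strict = strict)
    }
  } else {
    dec <- list(records = .emptyRecords(), errors = .emptyErrors())
  }
  rec <- dec$records
  errors[[length(errors) + 1L]] <- dec$errors

  ## -- unknown records --
  unk <- which(kinds == "UNKNOWN")
  if (length(unk))
    errors[[length(errors) + 1L]] <-
      data.frame(lineNo = unk, line = lines[unk],
                 reason = "unknown record type", stringsAsFactors = FALSE)

  ## -- MODEL ids --
  modelLn <- which(kinds == "MODEL")
  modelIds <- rep(NA_integer_, length(modelLn))
  if (length(modelLn)) {
    idTxt <- substr(.padTo(.bytes(lines[modelLn]), 14L), 11L, 14L)
    modelIds <- suppressWarnings(as.integer(idTxt))
    bad <- is.na(modelIds)
    if (any(bad))
      errors[[length(errors) + 1L]] <-
        data.frame(lineNo = modelLn[bad], line = lines[modelLn][bad],
                   reason = "MODEL serial is not a number",
                   stringsAsFactors = FALSE)
  }

  ## -- assign each decoded record to a model region --
  ## region state walks MODEL/ENDMDL events; coordinate runs outside any
  ## MODEL...ENDMDL bracket form implicit models.
  ctrlLn <- which(kinds %in% c("MODEL", "ENDMDL"))
  regionOf <- function(ln) {
    ## index of last control line before ln (0 = before any control)
    findInterval(ln, ctrlLn)
  }
  regionModel <- integer(0)
  if (length(ctrlLn)) {
    ## state after each control line
    st <- integer(length(ctrlLn))  # model id opened, NA_integer_ if closed
    for (i in seq_along(ctrlLn)) {
      ln <- ctrlLn[i]
      if (kinds[ln] == "MODEL") {
        id <- modelIds[match(ln, modelLn)]
        st[i] <- if (is.na(id)) -1L else id  # -1: bad id, assign later
      } else st[i] <- NA_integer_
    }
    regionModel <- st
  }

  nRec <- nrow(rec)
  noModelRecords <- length(modelLn) == 0L
  if (nRec) {
    reg <- regionOf(rec$lineNo)
    inModel <- reg > 0L & !is.na(regionModel)[pmax(reg, 1L)] &
      reg <= length(regionModel)
    mid <- rep(NA_integer_, nRec)
    mid[inModel] <- regionModel[reg[inModel]]
    ## implicit models: contiguous runs of records outside brackets
    outside <- !inModel
    if (any(outside)) {
      if (noModelRecords) {
        mid[outside] <- 1L
      } else {
        runId <- cumsum(c(TRUE, diff(reg[outside]) != 0L))
        base <- max(c(0L, regionModel[!is.na(regionModel)],
                      mid[!is.na(mid)]), na.rm = TRUE)
        mid[outside] <- base + runId
      }
    }
    ## replace bad-id sentinel with fresh ids
    if (any(mid == -1L, na.rm = TRUE)) {
      bad <- which(mid == -1L)
      top <- max(c(0L, mid[mid != -1L]))
      for (r in unique(reg[bad])) {
        top <- top + 1L
        mid[bad[reg[bad] == r]] <- top
      }
    }
  } else mid <- integer()

  ## -- grouping keys --
  if (nRec) {
    terBefore <- findInterval(rec$lineNo, which(kinds == "TER"))
    newChain <- c(TRUE, mid[-1L] != mid[-nRec] |
                    rec$chainId[-1L] != rec$chainId[-nRec] |
                    terBefore[-1L] != terBefore[-nRec])
    chainIdx <- cumsum(newChain)
    newRes <- newChain | c(TRUE, rec$resName[-1L] != rec$resName[-nRec] |
                             rec$resSeq[-1L] != rec$resSeq[-nRec] |
                             rec$insCode[-1L] != rec$insCode[-nRec])
    resIdx <- cumsum(newRes)
  }

  ## -- metadata, tagged before/after the coordinate block --
  metaLn <- which(kinds == "METADATA")
  blockLn <- which(kinds %in% c("COORD", "MODEL", "ENDMDL", "TER"))
  firstBlock <- if (length(blockLn)) min(blockLn) else Inf
  metaBefore <- lines[metaLn[metaLn < firstBlock]]
  metaAfter <- lines[metaLn[metaLn >= firstBlock]]

  ## -- build the hierarchy --
  modelsOut <- list()
  if (nRec) {
    atomsAll <- .atomList(rec)
    resStart <- which(c(TRUE, diff(resIdx) != 0L))
    resEnd <- c(resStart[-1L] - 1L, nRec)
    residuesAll <- vector("list", length(resStart))
    for (k in seq_along(resStart)) {
      i <- resStart[k]
      residuesAll[[k]] <- new("Residue", resName = rec$resName[i],
                              resSeq = rec$resSeq[i],
                              insCode = rec$insCode[i],
                              atoms = atomsAll[resStart[k]:resEnd[k]])
    }
    chainOfRes <- chainIdx[resStart]
    chStart <- which(c(TRUE, diff(chainOfRes) != 0L))
    chEnd <- c(chStart[-1L] - 1L, length(residuesAll))
    chainsAll <- vector("list", length(chStart))
    for (k in seq_along(chStart)) {
      i <- resStart[chStart[k]]
      chainsAll[[k]] <- new("Chain", chainId = rec$chainId[i],
                            residues = residuesAll[chStart[k]:chEnd[k]])
    }
    modelOfChain <- mid[resStart[chStart]]
    for (u in unique(modelOfChain)) {  # unique() keeps document order
      modelsOut[[length(modelsOut) + 1L]] <-
        new("Model", modelId = u, chains = chainsAll[modelOfChain == u])
    }
  } else if (length(modelLn)) {
    ## explicit MODEL brackets with no atoms still yield (empty) models
    for (id in modelIds[!is.na(modelIds)])
      modelsOut[[length(modelsOut) + 1L]] <- new("Model", modelId = id)
  }

  errdf <- do.call(rbind, errors)
  if (is.null(errdf)) errdf <- .emptyErrors()
  errdf <- errdf[order(errdf$lineNo), , drop = FALSE]
  rownames(errdf) <- NULL

  ## duplicated model ids (malformed input) are made unique to keep the
  ## structure invariant; the duplicate is reported
  ids <- vapply(modelsOut, modelId, integer(1))
  if (anyDuplicated(ids)) {
    for (k in which(duplicated(ids))) {
      ids[k] <- max(ids) + 1L
      modelsOut[[k]]@modelId <- ids[k]
    }
  }

  structure <- new("PDBStructure", models = modelsOut,
                   metaBefore = metaBefore, metaAfter = metaAfter)
  new("PDBParseResult", structure = structure, errors = errdf)
}

## Fast single-Atom construction; slot checks skipped, for callers that
## already guarantee field shape.
.fastAtom <- function(serial, name, altLoc, coord, occupancy, bFactor,
                      element, isHetatm, proto = new("Atom")) {
  a <- proto
  attr(a, "serial") <- as.integer(serial)
  attr(a, "name") <- name
  attr(a, "altLoc") <- altLoc
  attr(a, "coord") <- coord
  attr(a, "occupancy") <- occupancy
  attr(a, "bFactor") <- bFactor
  attr(a, "element") <- element
  attr(a, "isHetatm") <- isHetatm
  a
}

## Fast Atom construction from the decoded record table; slot-level checks
## are skipped because the codec already guarantees field shape.
.atomList <- function(rec) {
  n <- nrow(rec)
  out <- vector("list", n)
  proto <- new("Atom")
  serial <- rec$serial; name <- rec$name; altLoc <- rec$altLoc
  x <- rec$x; y <- rec$y; z <- rec$z
  occ <- rec$occupancy; b <- rec$bFactor
  segId <- rec$segId; elem <- rec$element; charge <- rec$charge
  het <- rec$isHetatm
  for (i in seq_len(n)) {
    a <- proto
    attr(a, "serial") <- serial[i]
    attr(a, "name") <- name[i]
    attr(a, "altLoc") <- altLoc[i]
    attr(a, "coord") <- c(x[i], y[i], z[i])
    attr(a, "occupancy") <- occ[i]
    attr(a, "bFactor") <- b[i]
    attr(a, "segId") <- segId[i]
    attr(a, "element") <- elem[i]
    attr(a, "charge") <- charge[i]
    attr(a, "isHetatm") <- het[i]
    out[[i]] <- a
  }
  out
}

#' Split a multi-model structure into single-model structures
#'
#' Repackages each model as a stand-alone structure carrying a copy of the
#' parent's metadata, preserving model ids and order. The input is not
#' modified.
#'
#' @param s a [PDBStructure-class].
#' @return a list of [PDBStructure-class], one per model (empty list for a
#'   structure without models).
#' @examples
#' s <- syntheticStructure(fixtureSpec(nModels = 3))
#' length(splitModels(s))
#' @export
splitModels <- function(s) {
  stopifnot(is(s, "PDBStructure"))
  lapply(s@models, function(m)
    new("PDBStructure", models = list(m), metaBefore = s@metaBefore,
        metaAfter = s@metaAfter))
}

#' Report format lint on an assembled structure
#'
#' Checks the soft conventions that real archive files violate: duplicate
#' atom names within a residue that do not differ by altLoc, duplicate
#' chain ids within a model, and chain ids that reappear after an
#' intervening different chain.
#'
#' @param s a [PDBStructure-class].
#' @return character vector of human-readable warnings (empty when clean).
#' @export
lintStructure <- function(s) {
  stopifnot(is(s, "PDBStructure"))
  out <- character()
  for (m in s@models) {
    cids <- vapply(m@chains, chainId, character(1))
    runs <- rle(cids)$values
    if (anyDuplicated(runs))
      out <- c(out, sprintf(
        "model %d: chain id '%s' reappears after an intervening chain",
        m@modelId, runs[duplicated(runs)][1]))
    if (anyDuplicated(cids))
      out <- c(out, sprintf("model %d: duplicate chain id '%s'",
                            m@modelId, cids[duplicated(cids)][1]))
    for (ch in m@chains) for (r in ch@residues) {
      key <- paste(vapply(r@atoms, atomName, character(1)),
                   vapply(r@atoms, altLoc, character(1)))
      nm <- vapply(r@atoms, atomName, character(1))
      if (anyDuplicated(key))
        out <- c(out, sprintf(
          "model %d chain %s residue %s %d: atom name '%s' duplicated without distinct altLoc",
          m@modelId, ch@chainId, r@resName, r@resSeq,
          nm[duplicated(key)][1]))
    }
  }
  out
}
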