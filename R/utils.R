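## Shared plumbing: seeded evaluation, structural equality, flat views.

## Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  gl <- globalenv()
  old <- if (exists(".Random.seed", envir = gl, inherits = FALSE))
    get(".Random.seed", envir = gl, inherits = FALSE) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", envir = gl, inherits = FALSE))
      rm(".Random.seed", envir = gl)
  } else assign(".Random.seed", old, envir = gl))
  set.seed(seed)
  expr
}

#' Structural equality of two structures
#'
#' True iff the two hierarchies have identical shape, identical
#' non-coordinate fields (ids, names, codes, occupancies, B-factors,
#' serials, metadata) and coordinates equal component-wise within
#' `coordTol`. At `coordTol = 0` this is an equivalence relation.
#'
#' @param a,b [PDBStructure-class] objects.
#' @param coordTol non-negative absolute tolerance on each coordinate
#'   component.
#' @return `TRUE` or `FALSE`.
#' @examples
#' s <- syntheticStructure(fixtureSpec())
#' structureEqual(s, s)
#' @export
structureEqual <- function(a, b, coordTol = 0) {
  stopifnot(is(a, "PDBStructure"), is(b, "PDBStructure"), coordTol >= 0)
  if (!identical(a@metaBefore, b@metaBefore)) return(FALSE)
  if (!identical(a@metaAfter, b@metaAfter)) return(FALSE)
  if (length(a@models) != length(b@models)) return(FALSE)
  for (mi in seq_along(a@models)) {
    ma <- a@models[[mi]]; mb <- b@models[[mi]]
    if (ma@modelId != mb@modelId) return(FALSE)
    if (length(ma@chains) != length(mb@chains)) return(FALSE)
    for (ci in seq_along(ma@chains)) {
      ca <- ma@chains[[ci]]; cb <- mb@chains[[ci]]
      if (ca@chainId != cb@chainId) return(FALSE)
      if (length(ca@residues) != length(cb@residues)) return(FALSE)
      for (ri in seq_along(ca@residues)) {
        ra <- ca@residues[[ri]]; rb <- cb@residues[[ri]]
        if (ra@resName != rb@resName || ra@resSeq != rb@resSeq ||
            ra@insCode != rb@insCode) return(FALSE)
        if (length(ra@atoms) != length(rb@atoms)) return(FALSE)
        for (ai in seq_along(ra@atoms)) {
          xa <- ra@atoms[[ai]]; xb <- rb@atoms[[ai]]
          if (xa@serial != xb@serial || xa@name != xb@name ||
              xa@altLoc != xb@altLoc || xa@segId != xb@segId ||
              xa@element != xb@element || xa@charge != xb@charge ||
              xa@isHetatm != xb@isHetatm ||
              xa@occupancy != xb@occupancy || xa@bFactor != xb@bFactor)
            return(FALSE)
          if (any(abs(xa@coord - xb@coord) > coordTol)) return(FALSE)
        }
      }
    }
  }
  TRUE
}

#' Flat per-atom table of a structure
#'
#' Flattens the hierarchy to one row per atom in document order, with its
#' model/chain/residue context — convenient for comparison against flat
#' parsers and for ad-hoc analysis.
#'
#' @param s a [PDBStructure-class].
#' @return data.frame with columns `modelId`, `chainId`, `resName`,
#'   `resSeq`, `insCode`, `serial`, `name`, `altLoc`, `x`, `y`, `z`,
#'   `occupancy`, `bFactor`, `segId`, `element`, `charge`, `isHetatm`.
#' @export
atomTable <- function(s) {
  stopifnot(is(s, "PDBStructure"))
  rows <- list()
  for (m in s@models) for (ch in m@chains) {
    rec <- .chainRecords(ch)
    if (nrow(rec)) {
      rec$modelId <- m@modelId
      rows[[length(rows) + 1L]] <- rec
    }
  }
  if (!length(rows)) {
    out <- .emptyRecords(); out$modelId <- integer()
  } else out <- do.call(rbind, rows)
  out$lineNo <- NULL
  rownames(out) <- NULL
  out[, c("modelId", "chainId", "resName", "resSeq", "insCode", "serial",
          "name", "altLoc", "x", "y", "z", "occupancy", "bFactor",
          "segId", "element", "charge", "isHetatm")]
}
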