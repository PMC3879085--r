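## Worked analyses on the hierarchy: geometry statistics, recentering,
## renumbering, canonical-axes reorientation, sequence extraction.

## Standard atomic weights for the mass weighting scheme (IUPAC 2021
## abridged values).
.ATOMIC_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305, CA = 40.078,
  NA. = 22.990, CL = 35.45, K = 39.098, MN = 54.938, F = 18.998,
  BR = 79.904, I = 126.904, CU = 63.546, NI = 58.693, CO = 58.933,
  MO = 95.95, W = 183.84, D = 2.014)

.atomWeight <- function(a, weighting) {
  if (weighting == "uniform") return(1)
  el <- toupper(a@element)
  if (el == "NA") el <- "NA."   # sodium; avoid the NA name clash
  w <- .ATOMIC_MASS[el]
  if (is.na(w))
    stop("unknown element '", a@element, "' for atom serial ", a@serial,
         " under mass weighting", call. = FALSE)
  unname(w)
}

.checkWeighting <- function(weighting) {
  match.arg(tolower(weighting), c("uniform", "mass"))
}

#' Center of mass of all contained atoms
#'
#' Two accumulation passes over the atoms (weighted coordinate sum, then
#' weight sum), as left folds. The default weighting treats every atom as
#' unit weight, which is what bead-model and shape-reconstruction work
#' expects; `"mass"` weights by standard atomic weight looked up from the
#' element symbol (unknown elements are an error).
#'
#' @param root any hierarchy node containing at least one atom.
#' @param weighting `"uniform"` (default) or `"mass"`.
#' @return numeric length-3 center, Angstrom.
#' @examples
#' r <- Residue("GLY", 1, atoms = list(
#'   Atom(1, "C1", coord = c(0, 0, 0)), Atom(2, "C2", coord = c(2, 0, 0))))
#' centerOfMass(r)
#' @export
centerOfMass <- function(root, weighting = "uniform") {
  weighting <- .checkWeighting(weighting)
  n <- countNodes(root, "atom")
  if (n < 1L) stop("center of mass needs at least one atom", call. = FALSE)
  wsum <- foldOver(root, "atom",
                   function(acc, a) acc + .atomWeight(a, weighting) * a@coord,
                   c(0, 0, 0))
  wtot <- foldOver(root, "atom",
                   function(acc, a) acc + .atomWeight(a, weighting), 0)
  wsum / wtot
}

#' Translate a structure so its center of mass is at the origin
#'
#' @inheritParams centerOfMass
#' @return a root of the same class; its center of mass is (0,0,0) within
#'   1e-9.
#' @export
recenter <- function(root, weighting = "uniform") {
  ctr <- centerOfMass(root, weighting)
  mapOver(root, "atom", function(a) {
    a@coord <- a@coord - ctr
    a
  })
}

#' Radius of gyration
#'
#' `sqrt(sum(w_i * |r_i - c|^2) / sum(w_i))` with `c` the center of mass
#' under the same weighting — the size measure used for small-angle
#' scattering shape reconstructions (for which the unweighted default is
#' the convention).
#'
#' @inheritParams centerOfMass
#' @return radius of gyration in Angstrom.
#' @examples
#' r <- Residue("GLY", 1, atoms = list(
#'   Atom(1, "C1", coord = c(-1, 0, 0)), Atom(2, "C2", coord = c(1, 0, 0))))
#' radiusOfGyration(r)  # 1
#' @export
radiusOfGyration <- function(root, weighting = "uniform") {
  weighting <- .checkWeighting(weighting)
  ctr <- centerOfMass(root, weighting)
  ss <- foldOver(root, "atom", function(acc, a)
    acc + .atomWeight(a, weighting) * sum((a@coord - ctr)^2), 0)
  wtot <- foldOver(root, "atom",
                   function(acc, a) acc + .atomWeight(a, weighting), 0)
  sqrt(ss / wtot)
}

#' Renumber residues consecutively within a chain
#'
#' Residues receive `start, start+1, ...` in document order and insertion
#' codes are cleared (consecutive numbering leaves them no meaning).
#' Numbering is per chain: apply to each chain of a model so each begins
#' anew.
#'
#' @param chain a [Chain-class].
#' @param start first residue number.
#' @return the renumbered [Chain-class].
#' @examples
#' ch <- Chain("A", list(Residue("ALA", 5), Residue("GLY", 7),
#'                       Residue("SER", 7, insCode = "A")))
#' vapply(residues(renumberResidues(ch)), resSeq, integer(1))
#' @export
renumberResidues <- function(chain, start = 1L) {
  stopifnot(is(chain, "Chain"))
  mapWithState(chain, "residue", function(k, r) {
    r@resSeq <- as.integer(k)
    r@insCode <- " "
    list(state = k + 1L, node = r)
  }, as.integer(start))$root
}

#' Renumber atom serials, counting TER records
#'
#' Within each model a counter starts at 1 and each atom takes the next value
#' in document order; after each polymeric chain the counter advances once
#' more for the `TER` record that the writer will emit there, because the
#' PDB format counts `TER` along with the atoms. The counter restarts at 1
#' for every model.
#'
#' @param root a [PDBStructure-class] or [Model-class].
#' @return same class as `root`, with regenerated serials.
#' @examples
#' # chains of 3 and 2 atoms -> serials 1,2,3 | TER=4 | 5,6 | TER=7
#' @export
renumberAtoms <- function(root) {
  renumModel <- function(m) {
    counter <- 0L
    m@chains <- lapply(m@chains, function(ch) {
      out <- mapWithState(ch, "atom", function(k, a) {
        a@serial <- as.integer(k)
        list(state = k + 1L, node = a)
      }, counter + 1L)
      counter <<- out$state - 1L
      if (.chainIsPolymeric(ch)) counter <<- counter + 1L  # the TER slot
      out$root
    })
    m
  }
  if (is(root, "Model")) return(renumModel(root))
  stopifnot(is(root, "PDBStructure"))
  root@models <- lapply(root@models, renumModel)
  root
}

## Proper rotation taking unit vector a onto unit vector b
.rotationBetween <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth > 1 - 1e-12) return(diag(3))
  if (cth < -1 + 1e-12) {
    ## 180 degrees: rotate about any axis orthogonal to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * a) * a
    ax <- ax / sqrt(sum(ax^2))
    return(2 * outer(ax, ax) - diag(3))
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + cth)
}

#' Reorient a structure onto its canonical axes
#'
#' Rigidly moves the structure so that (1) its center of mass is at the
#' origin, (2) the longest diameter — the maximum-distance atom pair,
#' found by exact pairwise scan, lowest document-order pair on ties, its
#' vector flipped to non-negative y — lies along the Y axis, and (3) the
#' dominant direction of the XZ-projected second-moment matrix (the widest
#' cross-sectional direction) lies along the X axis, with its eigenvector
#' taken with non-negative x. All pairwise distances are preserved within
#' 1e-6.
#'
#' @param s a [PDBStructure-class] with at least two atoms.
#' @param weighting see [centerOfMass()]; also weights the cross-section
#'   moments.
#' @return `list(structure = <reoriented PDBStructure>,
#'   transform = <RigidTransform>)` where the transform maps original to
#'   new coordinates as `r' = R r + t`.
#' @export
canonicalAxes <- function(s, weighting = "uniform") {
  stopifnot(is(s, "PDBStructure"))
  weighting <- .checkWeighting(weighting)
  atomsL <- collectNodes(s, "atom")
  n <- length(atomsL)
  if (n < 2L)
    stop("canonical axes need at least two atoms", call. = FALSE)
  X <- t(vapply(atomsL, function(a) a@coord, numeric(3)))
  w <- vapply(atomsL, .atomWeight, numeric(1), weighting)
  ctr <- colSums(X * w) / sum(w)
  Xc <- sweep(X, 2, ctr)

  ## longest diameter by exact O(n^2) scan; ties -> lowest (i,j) pair in
  ## document order
  dm <- as.matrix(dist(Xc))
  dm[lower.tri(dm, diag = TRUE)] <- -Inf
  mx <- max(dm)
  hits <- which(dm == mx, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  i <- hits[1, 1]; j <- hits[1, 2]
  v <- Xc[j, ] - Xc[i, ]
  R1 <- diag(3)
  if (mx > 1e-12) {
    if (v[2] < 0) v <- -v
    R1 <- .rotationBetween(v / sqrt(sum(v^2)), c(0, 1, 0))
  }
  Y <- Xc %*% t(R1)

  ## widest cross-section: dominant eigenvector of the weighted 2x2
  ## second-moment matrix of the XZ projection, rotated onto +X
  P <- Y[, c(1, 3), drop = FALSE]
  M <- crossprod(P * w, P) / sum(w)
  R2 <- diag(3)
  ev <- eigen(M, symmetric = TRUE)
  if (ev$values[1] > 1e-12) {
    u <- ev$vectors[, 1]
    if (u[1] < 0 || (u[1] == 0 && u[2] < 0)) u <- -u
    ## rotation about Y taking direction (u_x, u_z) onto +X
    R2 <- matrix(c(u[1], 0, -u[2],
                   0, 1, 0,
                   u[2], 0, u[1]), 3, 3)
  }
  R <- R2 %*% R1
  tvec <- as.numeric(-R %*% ctr)
  out <- mapOver(s, "atom", function(a) {
    a@coord <- as.numeric(R %*% a@coord + tvec)
    a
  })
  list(structure = out,
       transform = RigidTransform(rotation = R, translation = tvec))
}

## 3-letter -> 1-letter residue translation. Amino acids come from
## inverting Biostrings' code table; one-letter nucleotide names for the
## standard RNA/DNA bases are appended.
.RES_CODE <- local({
  aa <- Biostrings::AMINO_ACID_CODE
  tab <- stats::setNames(names(aa), toupper(aa))
  nuc <- c(A = "A", C = "C", G = "G", U = "U", T = "T", I = "I",
           DA = "A", DC = "C", DG = "G", DT = "T", DU = "U", DI = "I")
  c(tab, nuc)
})

#' One-letter sequence of a chain
#'
#' One character per residue in document order: standard amino acids and
#' nucleotide bases translate to their one-letter codes, water residues
#' (HOH/WAT/DOD) are skipped, anything else becomes `"X"`.
#'
#' @param chain a [Chain-class].
#' @return a single string (empty for an empty chain).
#' @examples
#' ch <- Chain("A", list(Residue("ALA", 1), Residue("GLY", 2),
#'                       Residue("MET", 3)))
#' chainSequence(ch)  # "AGM"
#' @export
chainSequence <- function(chain) {
  stopifnot(is(chain, "Chain"))
  nm <- vapply(chain@residues, resName, character(1))
  nm <- nm[!nm %in% c("HOH", "WAT", "DOD")]
  if (!length(nm)) return("")
  code <- .RES_CODE[nm]
  code[is.na(code)] <- "X"
  paste(code, collapse = "")
}
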