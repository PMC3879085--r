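# Hand-built fixtures shared across tests. Everything is constructed in
# code; no files ship with the package.

# the reference coordinate line used throughout the codec tests (fields
# chosen so every column group is populated)
refCoordLine <- function() {
  paste0("ATOM      1  N   MET A   1      38.000  12.000  -5.000",
         "  1.00 20.00           N  ")
}

# model with a 3-atom chain A and a 2-atom chain B, both polymeric
twoChainModel <- function() {
  Model(1L, list(
    Chain("A", list(Residue("ALA", 1L, atoms = list(
      Atom(1, "N", coord = c(0, 0, 0), element = "N"),
      Atom(2, "CA", coord = c(1, 0, 0), element = "C"),
      Atom(3, "C", coord = c(2, 0, 0), element = "C"))))),
    Chain("B", list(Residue("GLY", 1L, atoms = list(
      Atom(5, "N", coord = c(0, 1, 0), element = "N"),
      Atom(6, "CA", coord = c(1, 1, 0), element = "C")))))))
}

oneModelStructure <- function() PDBStructure(list(twoChainModel()))

# brute-force recursive flatten, independent of the traversal module
bruteFlatten <- function(root, kind) {
  depthOf <- function(x) {
    if (is(x, "PDBStructure")) 0L else if (is(x, "Model")) 1L
    else if (is(x, "Chain")) 2L else if (is(x, "Residue")) 3L else 4L
  }
  target <- match(kind, c("model", "chain", "residue", "atom"))
  kidsOf <- function(x) {
    if (is(x, "PDBStructure")) x@models else if (is(x, "Model")) x@chains
    else if (is(x, "Chain")) x@residues else if (is(x, "Residue")) x@atoms
    else list()
  }
  out <- list()
  visit <- function(x) {
    d <- depthOf(x)
    if (d == target) {
      out[[length(out) + 1L]] <<- x
    } else if (d < target) {
      for (k in kidsOf(x)) visit(k)
    }
  }
  visit(root)
  out
}

# random in-range AtomRecord rows whose floats are exactly representable
# at the printed precision
randomRecords <- function(n, seed = 1) {
  set.seed(seed)
  q <- function(x, d) as.numeric(sprintf(paste0("%.", d, "f"), x))
  data.frame(
    lineNo = seq_len(n),
    serial = sample.int(99999L, n, replace = TRUE),
    name = sample(c("N", "CA", "C", "O", "CB", "OXT", "FE", "1HB2"), n,
                  replace = TRUE),
    altLoc = sample(c(" ", "A", "B"), n, replace = TRUE),
    resName = sample(c("ALA", "GLY", "HOH", "DG"), n, replace = TRUE),
    chainId = sample(c(LETTERS[1:4], " "), n, replace = TRUE),
    resSeq = sample(-999:9999, n, replace = TRUE),
    insCode = sample(c(" ", "A"), n, replace = TRUE),
    x = q(runif(n, -999, 999), 3),
    y = q(runif(n, -999, 999), 3),
    z = q(runif(n, -999, 999), 3),
    occupancy = q(runif(n, 0, 1), 2),
    bFactor = q(runif(n, 0, 99), 2),
    segId = sample(c("", "SEG1"), n, replace = TRUE),
    element = sample(c("C", "N", "O", "FE", "H"), n, replace = TRUE),
    charge = sample(c("", "1+", "2-"), n, replace = TRUE),
    isHetatm = sample(c(TRUE, FALSE), n, replace = TRUE),
    stringsAsFactors = FALSE)
}
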