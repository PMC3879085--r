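# Geometry, renumbering, canonical axes, sequences.

coordMatrix <- function(root)
  t(vapply(collectNodes(root, "atom"), coords, numeric(3)))

test_that("centerOfMass matches closed forms and the direct-mean oracle", {
  r <- Residue("GLY", 1, atoms = list(
    Atom(1, "C1", coord = c(0, 0, 0)), Atom(2, "C2", coord = c(2, 0, 0))))
  expect_equal(centerOfMass(r), c(1, 0, 0))
  single <- Atom(1, "X", coord = c(3, -2, 7))
  expect_equal(centerOfMass(single), c(3, -2, 7))
  s <- syntheticStructure(fixtureSpec(residuesPerChain = 34,
                                      atomsPerResidue = 3, seed = 31))
  expect_equal(centerOfMass(s), colMeans(coordMatrix(s)),
               tolerance = 1e-12)
  expect_error(centerOfMass(Chain("A")), "at least one atom")
})

test_that("mass weighting uses the element table and rejects unknowns", {
  r <- Residue("GLY", 1, atoms = list(
    Atom(1, "C", coord = c(0, 0, 0), element = "C"),
    Atom(2, "O", coord = c(1, 0, 0), element = "O")))
  com <- centerOfMass(r, "mass")
  expect_equal(com[1], 15.999 / (12.011 + 15.999))
  bad <- Residue("XXX", 1, atoms = list(Atom(1, "Q", element = "QQ")))
  expect_error(centerOfMass(bad, "mass"), "unknown element")
})

test_that("recenter zeroes the center and preserves pairwise distances", {
  s <- syntheticStructure(fixtureSpec(chainsPerModel = 2, seed = 19))
  rc <- recenter(s)
  expect_lt(sqrt(sum(centerOfMass(rc)^2)), 1e-9)
  expect_equal(as.numeric(dist(coordMatrix(rc))),
               as.numeric(dist(coordMatrix(s))), tolerance = 1e-9)
  expect_true(structureEqual(recenter(rc), rc, coordTol = 1e-9))
})

test_that("radius of gyration matches closed form and the direct formula", {
  r <- Residue("GLY", 1, atoms = list(
    Atom(1, "C1", coord = c(-1, 0, 0)), Atom(2, "C2", coord = c(1, 0, 0))))
  expect_equal(radiusOfGyration(r), 1.0)
  expect_equal(radiusOfGyration(Atom(1, "X", coord = c(5, 5, 5))), 0)
  s <- syntheticStructure(fixtureSpec(residuesPerChain = 50, seed = 37))
  X <- coordMatrix(s)
  ctr <- colMeans(X)
  oracle <- sqrt(mean(rowSums(sweep(X, 2, ctr)^2)))
  expect_equal(radiusOfGyration(s), oracle, tolerance = 1e-9)
  # rigid-motion invariance
  rc <- recenter(s)
  expect_equal(radiusOfGyration(rc), radiusOfGyration(s),
               tolerance = 1e-9)
})

test_that("renumberResidues assigns consecutive numbers and clears insertion codes", {
  ch <- Chain("A", list(
    Residue("ALA", 5), Residue("GLY", 7),
    Residue("SER", 7, insCode = "A"), Residue("THR", 8)))
  out <- renumberResidues(ch)
  expect_equal(vapply(residues(out), resSeq, integer(1)), 1:4)
  expect_true(all(vapply(residues(out), insCode, character(1)) == " "))
  expect_length(residues(renumberResidues(Chain("Z"))), 0L)
  # numbering begins anew with each chain of a model
  m <- twoChainModel()
  m2 <- mapOver(m, "chain", renumberResidues)
  firsts <- vapply(chains(m2), function(c) resSeq(residues(c)[[1]]),
                   integer(1))
  expect_equal(firsts, c(1L, 1L))
})

test_that("renumberAtoms counts TER with the atoms and restarts per model", {
  m <- renumberAtoms(twoChainModel())
  expect_equal(vapply(collectNodes(m, "atom"), serial, integer(1)),
               c(1L, 2L, 3L, 5L, 6L))  # TER takes 4 and 7
  s <- syntheticStructure(fixtureSpec(nModels = 2, chainsPerModel = 2,
                                      seed = 3))
  s2 <- renumberAtoms(s)
  for (mm in models(s2))
    expect_equal(serial(collectNodes(mm, "atom")[[1]]), 1L)
  # idempotent, shape preserving
  expect_true(structureEqual(renumberAtoms(s2), s2))
  expect_equal(countNodes(s2, "atom"), countNodes(s, "atom"))
})

test_that("canonicalAxes puts the longest diameter on Y and widest cross-section on X", {
  # two atoms at (+-d, 0, 0) land on the Y axis
  s2 <- PDBStructure(list(Model(1, list(Chain("A", list(Residue(
    "ALA", 1, atoms = list(Atom(1, "C1", coord = c(-3, 0, 0)),
                           Atom(2, "C2", coord = c(3, 0, 0))))))))))
  out <- canonicalAxes(s2)
  X <- coordMatrix(out$structure)
  expect_equal(abs(X[, 2]), c(3, 3), tolerance = 1e-9)
  expect_equal(X[, c(1, 3)], matrix(0, 2, 2), tolerance = 1e-9,
               ignore_attr = TRUE)

  s <- syntheticStructure(fixtureSpec(chainsPerModel = 2,
                                      residuesPerChain = 25, seed = 41))
  res <- canonicalAxes(s)
  Y <- coordMatrix(res$structure)
  X0 <- coordMatrix(s)
  # rigid: pairwise distances preserved
  expect_equal(as.numeric(dist(Y)), as.numeric(dist(X0)),
               tolerance = 1e-6)
  # brute-force max-distance pair differs only in y afterwards
  dm <- as.matrix(dist(X0))
  ij <- which(dm == max(dm), arr.ind = TRUE)[1, ]
  dxz <- Y[ij[1], c(1, 3)] - Y[ij[2], c(1, 3)]
  expect_lt(max(abs(dxz)), 1e-6)
  # the transform object reproduces the motion
  R <- res$transform@rotation
  tv <- res$transform@translation
  expect_equal(Y, t(R %*% t(X0) + tv), tolerance = 1e-9,
               ignore_attr = TRUE)
  # structure already in canonical pose moves at most by sign flips
  res2 <- canonicalAxes(res$structure)
  expect_equal(abs(coordMatrix(res2$structure)), abs(Y), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(canonicalAxes(PDBStructure(list(Model(1, list(Chain("A",
    list(Residue("ALA", 1, atoms = list(Atom(1, "CA")))))))))),
    "at least two")
})

test_that("chainSequence translates residues, skips waters, falls back to X", {
  ch <- Chain("A", list(Residue("ALA", 1), Residue("GLY", 2),
                        Residue("MET", 3)))
  expect_equal(chainSequence(ch), "AGM")
  expect_equal(chainSequence(Chain("B", list(Residue("XYZ", 1)))), "X")
  expect_equal(chainSequence(Chain("C")), "")
  mixed <- Chain("D", list(Residue("HOH", 1), Residue("DG", 2),
                           Residue("U", 3), Residue("TRP", 4)))
  expect_equal(chainSequence(mixed), "GUW")
})
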