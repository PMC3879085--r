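# Stream -> hierarchy assembly, error collection, parallel mode, splitting.

test_that("grouping rules build the hierarchy from consecutive records", {
  txt <- paste(
    "HEADER    TEST",
    "MODEL        1",
    refCoordLine(),
    "ENDMDL",
    "MODEL        2",
    refCoordLine(),
    "ENDMDL",
    sep = "\n")
  s <- parsedStructure(parsePDB(txt))
  expect_length(models(s), 2L)
  expect_equal(vapply(models(s), modelId, integer(1)), c(1L, 2L))
  expect_equal(countNodes(s, "atom"), 2L)
  expect_equal(metadataLines(s, "before"), "HEADER    TEST")
})

test_that("empty input yields an empty structure with no errors", {
  res <- parsePDB("")
  expect_length(models(parsedStructure(res)), 0L)
  expect_equal(nrow(parseErrors(res)), 0L)
})

test_that("garbage lines are collected as errors with line numbers", {
  lines <- c(refCoordLine(), refCoordLine(), "FOOBAR junk",
             refCoordLine(), refCoordLine(), refCoordLine())
  res <- parsePDB(paste(lines, collapse = "\n"))
  expect_equal(countNodes(parsedStructure(res), "atom"), 5L)
  e <- parseErrors(res)
  expect_equal(nrow(e), 1L)
  expect_equal(e$lineNo, 3L)
  expect_identical(e$line, "FOOBAR junk")
})

test_that("TER and chain-id changes open new chains and residues", {
  mk <- function(chain, seq) {
    l <- refCoordLine()
    substr(l, 22, 22) <- chain
    substr(l, 23, 26) <- sprintf("%4d", seq)
    l
  }
  # A1 A1 | TER | A2 -> two chains even though the id repeats
  txt <- paste(mk("A", 1), mk("A", 1), "TER", mk("A", 2), sep = "\n")
  s <- parsedStructure(parsePDB(txt))
  m <- models(s)[[1]]
  expect_length(chains(m), 2L)
  expect_length(residues(chains(m)[[1]]), 1L)
  expect_length(atoms(residues(chains(m)[[1]])[[1]]), 2L)
  # chain id change alone also splits
  txt2 <- paste(mk("A", 1), mk("B", 1), sep = "\n")
  expect_length(chains(models(parsedStructure(parsePDB(txt2)))[[1]]), 2L)
  # residue number change alone splits residues within one chain
  txt3 <- paste(mk("A", 1), mk("A", 2), sep = "\n")
  ch <- chains(models(parsedStructure(parsePDB(txt3)))[[1]])[[1]]
  expect_length(residues(ch), 2L)
})

test_that("coordinates after ENDMDL open a fresh implicit model", {
  txt <- paste("MODEL        1", refCoordLine(), "ENDMDL",
               refCoordLine(), sep = "\n")
  s <- parsedStructure(parsePDB(txt))
  expect_length(models(s), 2L)
  expect_equal(modelId(models(s)[[2]]), 2L)
})

test_that("altLoc records stay as distinct atoms of one residue", {
  l1 <- refCoordLine(); substr(l1, 17, 17) <- "A"
  l2 <- refCoordLine(); substr(l2, 17, 17) <- "B"
  s <- parsedStructure(parsePDB(paste(l1, l2, sep = "\n")))
  r <- residues(chains(models(s)[[1]])[[1]])[[1]]
  expect_length(atoms(r), 2L)
  expect_equal(vapply(atoms(r), altLoc, character(1)), c("A", "B"))
})

test_that("parallel parse equals serial parse, including errors", {
  spec <- fixtureSpec(nModels = 2, chainsPerModel = 3,
                      residuesPerChain = 40, atomsPerResidue = 4,
                      altlocFraction = 0.3, hetatmTail = 3, badLines = 5,
                      seed = 17)
  f <- tempfile(fileext = ".pdb")
  writeFixtureFile(spec, f)
  ser <- parsePDBFile(f, mode = "serial")
  for (w in c(1L, 2L, 4L)) {
    par <- parsePDBFile(f, mode = "parallel", workers = w)
    expect_true(structureEqual(parsedStructure(ser), parsedStructure(par)))
    expect_identical(parseErrors(ser), parseErrors(par))
  }
  unlink(f)
})

test_that("gzip input parses identically to plain text", {
  spec <- fixtureSpec(nModels = 1, chainsPerModel = 2, badLines = 2,
                      seed = 5)
  fp <- tempfile(fileext = ".pdb")
  fz <- tempfile(fileext = ".pdb.gz")
  writeFixtureFile(spec, fp)
  writeFixtureFile(spec, fz)
  a <- parsePDBFile(fp)
  b <- parsePDBFile(fz)
  expect_true(structureEqual(parsedStructure(a), parsedStructure(b)))
  expect_identical(parseErrors(a), parseErrors(b))
  unlink(c(fp, fz))
})

test_that("line accounting: every line is atom, control, metadata or error", {
  spec <- fixtureSpec(nModels = 2, chainsPerModel = 2, badLines = 4,
                      hetatmTail = 2, seed = 9)
  txt <- syntheticPDBText(spec)
  lines <- strsplit(txt, "\n")[[1]]
  res <- parsePDB(txt)
  s <- parsedStructure(res)
  kinds <- classifyLine(lines)
  nControl <- sum(kinds %in% c("TER", "MODEL", "ENDMDL", "END"))
  nMeta <- sum(kinds == "METADATA")
  expect_equal(countNodes(s, "atom") + nControl + nMeta +
                 nrow(parseErrors(res)), length(lines))
  expect_equal(length(metadataLines(s)), nMeta)
})

test_that("splitModels conserves atoms and preserves ids and metadata", {
  s <- syntheticStructure(fixtureSpec(nModels = 3, chainsPerModel = 2,
                                      seed = 2))
  parts <- splitModels(s)
  expect_length(parts, 3L)
  expect_equal(vapply(parts, function(p) modelId(models(p)[[1]]),
                      integer(1)), 1:3)
  expect_equal(sum(vapply(parts, countNodes, integer(1), "atom")),
               countNodes(s, "atom"))
  expect_identical(metadataLines(parts[[2]]), metadataLines(s))
  # single-model structure splits to one structure equal to the input
  s1 <- syntheticStructure(fixtureSpec(nModels = 1, seed = 2))
  expect_true(structureEqual(splitModels(s1)[[1]], s1))
})
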