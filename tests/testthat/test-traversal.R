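# Typed traversal: counting, mapping, folding, state threading.

test_that("countNodes multiplies out the hierarchy and obeys the singleton rule", {
  s <- syntheticStructure(fixtureSpec(nModels = 2, chainsPerModel = 1,
                                      residuesPerChain = 3,
                                      atomsPerResidue = 4, seed = 1))
  expect_equal(countNodes(s, "atom"), 24L)
  expect_equal(countNodes(s, "chain"), 2L)
  expect_equal(countNodes(s, "residue"), 6L)
  expect_equal(countNodes(s, "model"), 2L)
  a <- Atom(1, "CA")
  expect_equal(countNodes(a, "atom"), 1L)  # a node of kind K yields itself
  expect_equal(countNodes(a, "chain"), 0L)
  expect_equal(countNodes(Chain("A"), "chain"), 1L)
})

test_that("transitive counts agree across adjacent hierarchy levels", {
  s <- syntheticStructure(fixtureSpec(nModels = 2, chainsPerModel = 3,
                                      residuesPerChain = 4,
                                      altlocFraction = 0.5, hetatmTail = 1,
                                      seed = 11))
  expect_equal(countNodes(s, "atom"),
               sum(vapply(collectNodes(s, "chain"), countNodes,
                          integer(1), "atom")))
  expect_equal(countNodes(s, "atom"),
               sum(vapply(collectNodes(s, "residue"), countNodes,
                          integer(1), "atom")))
  expect_equal(countNodes(s, "residue"),
               sum(vapply(collectNodes(s, "model"), countNodes,
                          integer(1), "residue")))
})

test_that("mapOver satisfies the functor laws and preserves shape", {
  s <- syntheticStructure(fixtureSpec(nModels = 2, chainsPerModel = 2,
                                      altlocFraction = 0.3, seed = 7))
  expect_true(structureEqual(mapOver(s, "atom", identity), s))
  f <- function(a) { coords(a) <- coords(a) * 2; a }
  g <- function(a) { coords(a) <- coords(a) + c(1, 0, 0); a }
  expect_true(structureEqual(mapOver(s, "atom", function(a) f(g(a))),
                             mapOver(mapOver(s, "atom", g), "atom", f)))
  renamed <- mapOver(s, "residue", function(r) { resName(r) <- "GLY"; r })
  expect_equal(countNodes(renamed, "atom"), countNodes(s, "atom"))
  expect_true(structureEqual(s, s))  # input untouched by the maps above
})

test_that("mapOver shifts center of mass linearly and rejects wrong kinds", {
  s <- oneModelStructure()
  shifted <- mapOver(s, "atom", function(a) {
    coords(a) <- coords(a) + c(1, 0, 0)
    a
  })
  expect_equal(centerOfMass(shifted), centerOfMass(s) + c(1, 0, 0))
  expect_error(mapOver(s, "atom", function(a) Residue("ALA", 1)),
               "expected")
  expect_error(mapOver(s, "atom", function(a) stop("boom")), "atom #1")
})

test_that("fold directions differ for non-associative operations", {
  m <- twoChainModel()  # serials 1,2,3,5,6
  expect_equal(foldOver(m, "atom", function(acc, a) acc - serial(a), 0),
               ((((0 - 1) - 2) - 3) - 5) - 6)
  expect_equal(foldOver(m, "atom", function(a, acc) serial(a) - acc, 0,
                        direction = "right"),
               1 - (2 - (3 - (5 - (6 - 0)))))
})

test_that("counting fold equals countNodes and appends match the flatten oracle", {
  s <- syntheticStructure(fixtureSpec(nModels = 2, chainsPerModel = 2,
                                      altlocFraction = 0.4, hetatmTail = 2,
                                      seed = 23))
  for (kind in c("model", "chain", "residue", "atom")) {
    expect_equal(foldOver(s, kind, function(acc, x) acc + 1L, 0L),
                 countNodes(s, kind))
    left <- foldOver(s, kind, function(acc, x) c(acc, list(x)), list())
    right <- foldOver(s, kind, function(x, acc) c(list(x), acc), list(),
                      direction = "right")
    oracle <- bruteFlatten(s, kind)
    expect_identical(left, oracle)
    expect_identical(right, oracle)
  }
})

test_that("mapWithState threads state in document order", {
  ch <- Chain("A", list(Residue("ALA", 5), Residue("GLY", 7),
                        Residue("SER", 7, insCode = "A")))
  out <- mapWithState(ch, "residue", function(k, r) {
    resSeq(r) <- k
    list(state = k + 1L, node = r)
  }, 1L)
  expect_equal(vapply(residues(out$root), resSeq, integer(1)), 1:3)
  expect_equal(out$state, 4L)
  # constant state: final state is the initial state, shape unchanged
  s <- oneModelStructure()
  out2 <- mapWithState(s, "atom", function(st, a) list(state = st, node = a),
                       "s0")
  expect_equal(out2$state, "s0")
  expect_true(structureEqual(out2$root, s))
  # counting: final state = state0 + count
  out3 <- mapWithState(s, "atom",
                       function(st, a) list(state = st + 1L, node = a), 10L)
  expect_equal(out3$state, 10L + countNodes(s, "atom"))
})
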