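## Generic typed traversal over the hierarchy: one API visits all objects
## of a chosen level contained (directly or transitively) in any node, in
## document order. A node visited "for its own level" yields itself, so
## every operation is total over all root/level combinations.

.KIND_DEPTH <- c(model = 1L, chain = 2L, residue = 3L, atom = 4L)

.nodeDepth <- function(node) {
  if (is(node, "PDBStructure")) return(0L)
  if (is(node, "Model")) return(1L)
  if (is(node, "Chain")) return(2L)
  if (is(node, "Residue")) return(3L)
  if (is(node, "Atom")) return(4L)
  stop("not a hierarchy node: ", class(node)[1], call. = FALSE)
}

.normKind <- function(kind) {
  k <- tolower(kind)
  if (!k %in% names(.KIND_DEPTH))
    stop("kind must be one of 'model', 'chain', 'residue', 'atom'",
         call. = FALSE)
  k
}

.childrenOf <- function(node, depth) {
  switch(depth + 1L, node@models, node@chains, node@residues, node@atoms,
         list())
}

.withChildren <- function(node, depth, kids) {
  if (depth == 0L) node@models <- kids
  else if (depth == 1L) node@chains <- kids
  else if (depth == 2L) node@residues <- kids
  else if (depth == 3L) node@atoms <- kids
  node
}

#' Count contained nodes of one level
#'
#' Counts all objects of level `kind` contained in `root`, transitively;
#' a root of that very level counts itself (singleton rule).
#'
#' @param root any of [PDBStructure-class], [Model-class], [Chain-class],
#'   [Residue-class], [Atom-class].
#' @param kind `"model"`, `"chain"`, `"residue"` or `"atom"`.
#' @return integer count.
#' @examples
#' s <- syntheticStructure(fixtureSpec(nModels = 2, residuesPerChain = 3))
#' countNodes(s, "atom")
#' @export
countNodes <- function(root, kind) {
  target <- .KIND_DEPTH[[.normKind(kind)]]
  rec <- function(node, depth) {
    if (depth == target) return(1L)
    if (depth > target) return(0L)
    kids <- .childrenOf(node, depth)
    if (depth + 1L == target) return(length(kids))
    s <- 0L
    for (k in kids) s <- s + rec(k, depth + 1L)
    s
  }
  rec(root, .nodeDepth(root))
}

#' Collect contained nodes of one level in document order
#'
#' @inheritParams countNodes
#' @return list of nodes in document order (models, then chains within
#'   each model, then residues, then atoms, each in stored order).
#' @export
collectNodes <- function(root, kind) {
  target <- .KIND_DEPTH[[.normKind(kind)]]
  acc <- vector("list", countNodes(root, kind))
  i <- 0L
  rec <- function(node, depth) {
    if (depth == target) {
      i <<- i + 1L
      acc[[i]] <<- node
      return(invisible())
    }
    if (depth > target) return(invisible())
    for (k in .childrenOf(node, depth)) rec(k, depth + 1L)
    invisible()
  }
  rec(root, .nodeDepth(root))
  acc
}

#' Map a function over all contained nodes of one level
#'
#' Applies `fn` to every `kind`-level node in document order and rebuilds
#' the hierarchy around the results. The input is unchanged (value
#' semantics); `fn` must return a node of the same class. Errors raised by
#' `fn` are rethrown with the failing node's document-order position
#' attached.
#'
#' @inheritParams countNodes
#' @param fn function taking and returning a node of level `kind`.
#' @return a new root of identical shape.
#' @examples
#' s <- syntheticStructure(fixtureSpec())
#' shifted <- mapOver(s, "atom", function(a) {
#'   coords(a) <- coords(a) + c(1, 0, 0)
#'   a
#' })
#' @export
mapOver <- function(root, kind, fn) {
  k <- .normKind(kind)
  target <- .KIND_DEPTH[[k]]
  pos <- 0L
  rec <- function(node, depth) {
    if (depth == target) {
      pos <<- pos + 1L
      out <- tryCatch(fn(node), error = function(e)
        stop(sprintf("mapOver: error at %s #%d: %s", k, pos,
                     conditionMessage(e)), call. = FALSE))
      if (.nodeDepth(out) != target)
        stop(sprintf("mapOver: fn returned a %s where a %s was expected (%s #%d)",
                     class(out)[1], k, k, pos), call. = FALSE)
      return(out)
    }
    if (depth > target) return(node)
    kids <- .childrenOf(node, depth)
    .withChildren(node, depth, lapply(kids, rec, depth + 1L))
  }
  rec(root, .nodeDepth(root))
}

#' Fold over all contained nodes of one level
#'
#' Eagerly accumulates over the document-order sequence of `kind`-level
#' nodes. `direction = "left"` computes `fn(...fn(fn(init, x1), x2)..., xn)`
#' with `fn(acc, node)`; `direction = "right"` computes
#' `fn(x1, fn(x2, ...fn(xn, init)))` with `fn(node, acc)` — the classic
#' left/right fold argument orders, which differ observably for
#' non-associative `fn`.
#'
#' @inheritParams countNodes
#' @param fn accumulator function; argument order depends on `direction`
#'   as described above.
#' @param init initial accumulator.
#' @param direction `"left"` or `"right"`.
#' @return the final accumulator.
#' @examples
#' s <- syntheticStructure(fixtureSpec())
#' foldOver(s, "atom", function(acc, a) acc + 1, 0)  # == countNodes
#' @export
foldOver <- function(root, kind, fn, init, direction = c("left", "right")) {
  direction <- match.arg(direction)
  nodes <- collectNodes(root, kind)
  acc <- init
  if (direction == "left") {
    for (nd in nodes) acc <- fn(acc, nd)
  } else {
    for (nd in rev(nodes)) acc <- fn(nd, acc)
  }
  acc
}

#' Map with threaded state over all contained nodes of one level
#'
#' Visits `kind`-level nodes in document order, threading a state value
#' through `fn(state, node)`, which must return `list(state = <new state>,
#' node = <replacement node>)`. The workhorse behind renumbering.
#'
#' @inheritParams countNodes
#' @param fn function `(state, node) -> list(state=, node=)`.
#' @param state0 initial state.
#' @return `list(root = <new root>, state = <final state>)`.
#' @examples
#' ch <- Chain("A", list(Residue("ALA", 5), Residue("GLY", 9)))
#' out <- mapWithState(ch, "residue", function(k, r) {
#'   resSeq(r) <- k
#'   list(state = k + 1, node = r)
#' }, 1)
#' resSeq(residues(out$root)[[2]])
#' @export
mapWithState <- function(root, kind, fn, state0) {
  k <- .normKind(kind)
  target <- .KIND_DEPTH[[k]]
  state <- state0
  pos <- 0L
  rec <- function(node, depth) {
    if (depth == target) {
      pos <<- pos + 1L
      out <- tryCatch(fn(state, node), error = function(e)
        stop(sprintf("mapWithState: error at %s #%d: %s", k, pos,
                     conditionMessage(e)), call. = FALSE))
      if (!is.list(out) || !all(c("state", "node") %in% names(out)))
        stop("mapWithState: fn must return list(state=, node=)",
             call. = FALSE)
      if (.nodeDepth(out$node) != target)
        stop(sprintf("mapWithState: fn returned a %s where a %s was expected",
                     class(out$node)[1], k), call. = FALSE)
      state <<- out$state
      return(out$node)
    }
    if (depth > target) return(node)
    kids <- .childrenOf(node, depth)
    .withChildren(node, depth, lapply(kids, rec, depth + 1L))
  }
  newRoot <- rec(root, .nodeDepth(root))
  list(root = newRoot, state = state)
}
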