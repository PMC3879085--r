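## Deterministic synthetic structures and files: every parser, writer and
## analysis path is testable without downloading archive entries.

.AA20 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")
.ATOM_POOL <- data.frame(
  name = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "CZ", "OG",
           "SD", "NZ"),
  element = c("N", "C", "C", "O", "C", "C", "C", "C", "C", "O", "S", "N"),
  stringsAsFactors = FALSE)

#' Describe a synthetic fixture
#'
#' A recipe for a deterministic synthetic structure or PDB file: identical
#' spec and seed give byte-identical output. Coordinates are drawn
#' uniformly from a 100 Angstrom box and quantized to the format's 3
#' printed decimals, so codec round trips are exact by construction.
#'
#' @param nModels,chainsPerModel,residuesPerChain,atomsPerResidue hierarchy
#'   counts (`atomsPerResidue >= 1`).
#' @param altlocFraction fraction of amino-acid residues whose first atom
#'   gets a duplicate record with alternate location `B`.
#' @param hetatmTail number of HETATM water residues appended per chain.
#' @param badLines number of deliberately malformed lines injected by
#'   [syntheticPDBText()].
#' @param seed integer RNG seed.
#' @return a `FixtureSpec` list.
#' @export
fixtureSpec <- function(nModels = 1L, chainsPerModel = 1L,
                        residuesPerChain = 5L, atomsPerResidue = 3L,
                        altlocFraction = 0, hetatmTail = 0L,
                        badLines = 0L, seed = 1L) {
  stopifnot(nModels >= 0, chainsPerModel >= 0, residuesPerChain >= 0,
            atomsPerResidue >= 1, altlocFraction >= 0, altlocFraction <= 1,
            hetatmTail >= 0, badLines >= 0)
  structure(list(nModels = as.integer(nModels),
                 chainsPerModel = as.integer(chainsPerModel),
                 residuesPerChain = as.integer(residuesPerChain),
                 atomsPerResidue = as.integer(atomsPerResidue),
                 altlocFraction = altlocFraction,
                 hetatmTail = as.integer(hetatmTail),
                 badLines = as.integer(badLines),
                 seed = as.integer(seed)),
            class = "FixtureSpec")
}

.q3 <- function(x) as.numeric(sprintf("%.3f", x))
.q2 <- function(x) as.numeric(sprintf("%.2f", x))

#' Generate a synthetic structure
#'
#' Builds the hierarchy described by `spec`: residue names cycle through
#' the 20 standard amino acids, atom names through a backbone/side-chain
#' pool, coordinates are seeded uniform in a box and quantized to 3
#' decimals. An `altlocFraction` of residues carry an alternate-location
#' duplicate of their first atom (A/B at half occupancy); `hetatmTail`
#' water residues are appended per chain. Atom serials follow the PDB
#' numbering convention with `TER` slots counted. Geometry is random — no
#' bonding realism is attempted.
#'
#' @param spec a [fixtureSpec()].
#' @return a [PDBStructure-class].
#' @examples
#' countNodes(syntheticStructure(fixtureSpec(nModels = 2,
#'   chainsPerModel = 2, residuesPerChain = 5, atomsPerResidue = 3)),
#'   "atom")  # 60
#' @export
syntheticStructure <- function(spec) {
  stopifnot(inherits(spec, "FixtureSpec"))
  .withSeed(spec$seed, {
    proto <- new("Atom")
    apr <- spec$atomsPerResidue
    nm0 <- if (apr <= nrow(.ATOM_POOL)) .ATOM_POOL$name[seq_len(apr)] else
      c(.ATOM_POOL$name, sprintf("C%d", seq(nrow(.ATOM_POOL) + 1L, apr)))
    el0 <- if (apr <= nrow(.ATOM_POOL)) .ATOM_POOL$element[seq_len(apr)] else
      c(.ATOM_POOL$element, rep("C", apr - nrow(.ATOM_POOL)))
    modelsL <- vector("list", spec$nModels)
    for (mi in seq_len(spec$nModels)) {
      chainsL <- vector("list", spec$chainsPerModel)
      for (ci in seq_len(spec$chainsPerModel)) {
        cid <- LETTERS[(ci - 1L) %% 26L + 1L]
        nres <- spec$residuesPerChain
        dup <- stats::runif(nres) < spec$altlocFraction
        nAt <- nres * apr
        xyz <- matrix(.q3(stats::runif(3L * nAt, -50, 50)), nrow = 3L)
        bf <- .q2(stats::runif(nAt, 5, 50))
        resL <- vector("list", nres + spec$hetatmTail)
        for (ri in seq_len(nres)) {
          off <- (ri - 1L) * apr
          atomsL <- vector("list", apr)
          for (ai in seq_len(apr)) {
            atomsL[[ai]] <- .fastAtom(
              0L, nm0[ai],
              altLoc = if (ai == 1L && dup[ri]) "A" else " ",
              coord = xyz[, off + ai],
              occupancy = if (ai == 1L && dup[ri]) 0.5 else 1,
              bFactor = bf[off + ai], element = el0[ai],
              isHetatm = FALSE, proto = proto)
          }
          if (dup[ri]) {
            alt <- atomsL[[1L]]
            attr(alt, "altLoc") <- "B"
            attr(alt, "coord") <- .q3(attr(alt, "coord") +
                                        stats::runif(3, -0.4, 0.4))
            atomsL <- append(atomsL, list(alt), after = 1L)
          }
          resL[[ri]] <- Residue(.AA20[(ri - 1L) %% 20L + 1L], ri,
                                atoms = atomsL)
        }
        for (wi in seq_len(spec$hetatmTail)) {
          resL[[nres + wi]] <- Residue(
            "HOH", nres + wi,
            atoms = list(.fastAtom(0L, "O",
                                   altLoc = " ",
                                   coord = .q3(stats::runif(3, -50, 50)),
                                   occupancy = 1,
                                   bFactor = .q2(stats::runif(1, 5, 50)),
                                   element = "O", isHetatm = TRUE,
                                   proto = proto)))
        }
        chainsL[[ci]] <- Chain(cid, resL)
      }
      modelsL[[mi]] <- Model(mi, chainsL)
    }
    renumberAtoms(PDBStructure(
      models = modelsL,
      metaBefore = c(
        .padTo("HEADER    SYNTHETIC STRUCTURE                     01-JAN-00   XXXX", 80L),
        .padTo("REMARK   1 DETERMINISTIC SYNTHETIC FIXTURE, NOT AN ARCHIVE ENTRY", 80L))))
  })
}

#' Generate synthetic PDB text, optionally with malformed lines
#'
#' Writes [syntheticStructure()] to text and injects `spec$badLines`
#' deliberately malformed lines (unknown record names and coordinate lines
#' with non-numeric fields, alternating) at seeded positions inside the
#' coordinate block. Each injected line produces exactly one parse error
#' in both lenient and strict modes. The 1-based line numbers of the
#' injected lines are attached as attribute `"badLineNos"`.
#'
#' @param spec a [fixtureSpec()].
#' @return a single string of PDB text with attribute `badLineNos`.
#' @examples
#' txt <- syntheticPDBText(fixtureSpec(badLines = 3))
#' nrow(parseErrors(parsePDB(txt)))  # 3
#' @export
syntheticPDBText <- function(spec) {
  stopifnot(inherits(spec, "FixtureSpec"))
  s <- syntheticStructure(spec)
  lines <- strsplit(writePDB(s), "\n", fixed = TRUE)[[1]]
  badNos <- integer()
  if (spec$badLines > 0L) {
    nHead <- length(s@metaBefore)
    bad <- c("FOOBAR this is not a PDB record and must be reported",
             "ATOM  99999  XX  BAD Z 999      xx.xxx   0.000   0.000  1.00  0.00")
    .withSeed(spec$seed + 7919L, {
      gaps <- sort(sample(nHead:(length(lines) - 1L), spec$badLines,
                          replace = TRUE))
      for (k in seq_along(gaps)) {
        at <- gaps[k] + k  # account for lines already inserted
        lines <- append(lines, bad[(k - 1L) %% 2L + 1L], after = at - 1L)
        badNos <- c(badNos, at)
      }
    })
  }
  structure(paste0(paste(lines, collapse = "\n"), "\n"),
            badLineNos = badNos)
}

#' Write a synthetic fixture file
#'
#' Emits [syntheticPDBText()] to disk, gzip-compressed for `.gz` paths;
#' used by the command-line tests.
#'
#' @param spec a [fixtureSpec()].
#' @param path output path (plain or `.gz`).
#' @return `path` invisibly, with attribute `badLineNos` as in
#'   [syntheticPDBText()].
#' @export
writeFixtureFile <- function(spec, path) {
  txt <- syntheticPDBText(spec)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeChar(as.character(txt), con, eos = NULL)
  invisible(structure(path, badLineNos = attr(txt, "badLineNos")))
}
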