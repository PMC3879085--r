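---
title: "pdbkit: models, conventions and numerical choices"
author: "pdbkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pdbkit: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdbkit)
```

# The data model

A legacy PDB entry is a line-oriented, fixed-column text file. `pdbkit`
represents one entry as a five-level hierarchy of S4 objects:

* `PDBStructure` — the whole entry: a list of models plus every
  non-coordinate record preserved verbatim (tagged *before* or *after*
  the coordinate block, never interpreted);
* `Model` — one model of the molecule (NMR ensembles have many,
  bracketed by `MODEL`/`ENDMDL`);
* `Chain` — one polymer chain, or a run of heteroatom records sharing a
  chain id;
* `Residue` — one monomer: name, sequence number, insertion code, and
  its atoms in file order;
* `Atom` — one atom *location*. Alternate conformations are distinct
  `Atom` objects differing in `altLoc`; nothing is filtered at parse
  time, because which location to keep is an analysis decision, not a
  parsing one.

File order is preserved at every level. That is a deliberate fidelity
guarantee: renumbering, `TER` placement and round-trip identity are all
defined in terms of document order.

Two soft conventions are *linted* rather than enforced (duplicate atom
names within a residue that do not differ in `altLoc`; duplicate or
re-appearing chain ids within a model), because archived entries
routinely violate them and a parser that rejects real data is useless
for curation work. `lintStructure()` reports them.

A chain id that reappears after an intervening different chain (A, B, A)
opens a *new* `Chain` object rather than merging with the earlier one.
Merging would silently reorder atoms relative to the file; the no-merge
choice keeps the record stream intact and leaves any merging to the
caller.

# The codec and strictness

Fields are sliced at the PDB v3.3 fixed columns (record name 1–6,
serial 7–11, name 13–16, altLoc 17, resName 18–20, chainID 22,
resSeq 23–26, iCode 27, x/y/z 31–54, occupancy 55–60, B 61–66,
segID 73–76, element 77–78, charge 79–80). Two reading modes exist
because two use cases exist:

* **lenient** (default for reading): lines truncated after the
  coordinates get occupancy 1.00, B-factor 0.00 and empty trailing
  fields. Garbage in a *present* column is still an error — defaults
  substitute for absence, never for corruption.
* **strict** (default for the normalization path): the line must be at
  least 66 columns and every numeric field must parse.

Every decoding failure is returned as a `ParseError` value (line
number, verbatim line, reason) and collected; parsing never aborts and
never raises, a property fuzz-tested with random byte lines. Input is
treated as single-byte text: lines that are not valid UTF-8 are sliced
bytewise, and metadata lines are stored byte-identical to the input.

On output, atom names are re-justified from the element code
(one-letter elements start at column 14, two-letter at column 13,
four-character names fill 13–16), which is how the normalizer repairs
files written with sloppy name padding. Occupancy is not constrained to
[0, 1]; only finiteness is enforced, since real entries exceed 1.

**Overflow policy.** Serials above 99999 or residue numbers outside
−999..9999 do not fit their columns. Writing such a structure is an
error unless `renumber = TRUE` regenerates serials first. Hybrid-36 or
other extended encodings are out of scope; an error was preferred to a
silently wrapped serial.

# Parser assembly and the parallel contract

Grouping is purely local: a new residue starts when
`(resName, resSeq, iCode)` changes or a `TER` intervenes; a new chain
when the chain id changes or a `TER` intervenes; models come from
`MODEL`/`ENDMDL` brackets. A file with no `MODEL` record is one model
with id 1. Coordinate records after `ENDMDL` but before the next
`MODEL` open a fresh implicit model (id = one past the largest seen) —
they are evidence of a malformed file, but dropping them would violate
the never-lose-data rule.

Parallel parsing splits the input at line boundaries into roughly
`workers` chunks and decodes coordinate lines concurrently (fork-based
`mclapply`; sequential on platforms without forks). Hierarchy assembly
runs serially on the merged, file-ordered record stream. This division
of labour is what makes the contract *parallel output is bit-identical
to serial output, for any worker count* trivially true: the only
parallel work is per-line and order-independent, and it is the part
that dominates run time. Nothing about chunk scheduling can leak into
the result.

# Writer conventions

* One `TER` after each chain that contains at least one non-`HETATM`
  residue; pure-heteroatom chains (waters, ligands) get none. The
  `TER` consumes one serial, per the format's numbering rule.
* `MODEL`/`ENDMDL` brackets are emitted for multi-model structures.
  For a single-model structure they are suppressed — standard
  single-model entries carry none — *unless* the model id is not 1, in
  which case suppressing them would lose the id on a round trip (the
  parser must assign id 1 to unbracketed coordinates).
* Metadata is re-emitted verbatim: the before-block ahead of the
  coordinates, the after-block behind them. Metadata originally
  interleaved *inside* the coordinate block is hoisted to the after
  block; interleaving positions are a known fidelity limit.
* A trailing `END` is always written.

`clean()` is defined by its postcondition: the written output of a
cleaned structure re-parses strictly with zero errors. It strips and
truncates string fields to their column widths, regenerates serials
(counting `TER`), optionally renumbers residues, and drops metadata
lines whose record name is outside the v3.3 vocabulary. It is
idempotent.

# Traversal semantics

One API visits all objects of a chosen level (`"model"`, `"chain"`,
`"residue"`, `"atom"`) contained directly or transitively in any node,
in document order; a node visited for its own level yields itself. The
level is a runtime argument rather than a compile-time type, which is
the natural translation of typed-container iteration into a dynamic
language: one call site stays generic over all sixteen root/level
pairs.

`foldOver` follows the classical fold argument orders: `direction =
"left"` accumulates `fn(acc, node)` left-to-right; `direction =
"right"` computes `fn(x1, fn(x2, … fn(xn, init)))` with `fn(node,
acc)`. The orders differ observably for non-associative operations and
are tested against a brute-force flatten. Both folds are eager — no
deferred computation accumulates. `mapOver` has value semantics at the
interface: the input is never modified, and the functor laws (identity
and composition) are property-tested. `mapWithState` threads a state
value in document order and is the workhorse behind renumbering.

# Analyses

**Weighting.** `centerOfMass` and `radiusOfGyration` default to unit
weights. The main consumer of Rg here is shape-reconstruction work
(SAXS bead models), where beads are unweighted; crystallographic mass
weighting is available as `weighting = "mass"` using standard atomic
weights, with unknown element symbols a hard error rather than a
guessed carbon. The center of mass is computed as two eager fold
passes (weighted coordinate sum; weight sum).

**Renumbering.** Residues are renumbered consecutively *per chain*
(each chain begins anew), and insertion codes are cleared — with
consecutive numbers they no longer mean anything. Atom serials restart
at 1 per model and advance by one extra after each `TER`-bearing chain,
reproducing the format's `TER`-counted numbering; the hand-checked
sequence for chains of 3 and 2 atoms is 1, 2, 3, (TER = 4), 5, 6,
(TER = 7). Both operations are idempotent.

**Canonical axes.** The structure is (1) translated so its center is at
the origin, (2) rotated so the maximum-distance atom pair — found by
exact O(n²) scan, suitable at desk scale — lies along +Y, and (3)
rotated about Y so the dominant eigenvector of the weighted 2×2 second
moment of the XZ projection lies along +X. Tie-breaks are
deterministic: the lowest document-order pair on equal distances, the
diameter vector flipped to non-negative y, the cross-section
eigenvector to non-negative x. The moment-based reading of "widest
cross-sectional dimension" was chosen over a max-extent
(rotating-calipers) one because it is unique, stable under small
perturbations, and reduces to an eigendecomposition; with near-isotropic
cross-sections the two can disagree, which is accepted. Degenerate
inputs: fewer than two atoms is an error; a coincident point cloud
leaves the Y-rotation at identity; collinear structures (zero projected
moment) leave the X-rotation at identity. The returned
`RigidTransform` satisfies `r' = R r + t` with `R` proper orthonormal
to 1e-9; rigidity (pairwise distances preserved to 1e-6) is
property-tested.

**Sequences.** Three-letter residue names translate through the
standard amino-acid code table (inverted from Biostrings) plus
one-letter nucleotide names for the standard RNA/DNA bases; water
residues are skipped; anything unknown becomes `X`.

# The synthetic generator

`fixtureSpec()` fixes the study conditions for every test: hierarchy
counts, an `altlocFraction` of residues carrying an A/B alternate
location at half occupancy, a `hetatmTail` of water residues per chain,
a count of deliberately malformed lines, and a seed. Identical spec and
seed give identical output; the generator restores the caller's RNG
state.

Design choices worth knowing:

* Coordinates are uniform in a 100 Å box and quantized to the format's
  3 printed decimals **at generation time** (similarly occupancy/B to
  2), so "round trip at tolerance zero" is well defined: every float in
  a fixture is exactly the parse of its own printed form.
* Injected bad lines alternate between an unknown record name and a
  coordinate line with a non-numeric x field — the two failure classes
  that error under both lenient and strict reading — and their line
  numbers are returned, so error accounting can be checked one-for-one.
* The geometry is random. The generator emulates the *format* (records,
  grouping, altLocs, waters, multi-model layout), not chemistry: no
  bond lengths, no secondary structure, no realistic sequences.
  Passing tests therefore certify format handling and the algebraic
  properties of the operations, not biophysical plausibility, and say
  nothing about header-record semantics (which the package deliberately
  does not interpret).

Problem sizes used by the checked properties: 1,000 random records for
the codec round trip, 50 random specs for the structure round trip, one
100,080-atom fixture for the parallel-equals-serial check (workers 1,
2, 4, 8), and 10,000 random byte lines for the crash-freedom fuzz —
sizes at which every property is exercised well beyond its edge cases
while the whole suite stays desk-scale.

# Known limitations

* Header records (`SEQRES`, `HELIX`, `CONECT`, `ANISOU`, …) are
  preserved verbatim but never interpreted; `ANISOU` lines do not
  become atom attributes.
* Metadata interleaved inside the coordinate block is hoisted on
  output (order within each block is kept).
* Two *adjacent* chains with the same id and no separating `TER` merge
  on re-parse; the writer never produces such output for structures
  with distinct chain objects of distinct ids, but hand-built
  structures can trigger it.
* No mmCIF/PDBx, no automatic fetching, no connectivity model, no
  hybrid-36 serials.
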