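## Accessor generics. Slot access from user code should go through these.

#' @name accessors
#' @title Accessors for the PDB hierarchy
#'
#' @description Getters (and a few setters) for [Atom-class],
#' [Residue-class], [Chain-class], [Model-class], [PDBStructure-class] and
#' [PDBParseResult-class] objects. Replacement functions return a modified
#' copy; all hierarchy objects have value semantics.
#'
#' @param x,object a hierarchy object of the appropriate class.
#' @param value replacement value.
#' @return the slot value, or (for setters) the modified object.
#' @examples
#' a <- Atom(1, "CA", coord = c(0, 0, 0), element = "C")
#' coords(a)
#' coords(a) <- c(1, 1, 1)
NULL

#' @rdname accessors
#' @export
setGeneric("models", function(x) standardGeneric("models"))
#' @rdname accessors
#' @export
setGeneric("chains", function(x) standardGeneric("chains"))
#' @rdname accessors
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))
#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("modelId", function(x) standardGeneric("modelId"))
#' @rdname accessors
#' @export
setGeneric("chainId", function(x) standardGeneric("chainId"))
#' @rdname accessors
#' @export
setGeneric("resName", function(x) standardGeneric("resName"))
#' @rdname accessors
#' @export
setGeneric("resName<-", function(x, value) standardGeneric("resName<-"))
#' @rdname accessors
#' @export
setGeneric("resSeq", function(x) standardGeneric("resSeq"))
#' @rdname accessors
#' @export
setGeneric("resSeq<-", function(x, value) standardGeneric("resSeq<-"))
#' @rdname accessors
#' @export
setGeneric("insCode", function(x) standardGeneric("insCode"))
#' @rdname accessors
#' @export
setGeneric("insCode<-", function(x, value) standardGeneric("insCode<-"))
#' @rdname accessors
#' @export
setGeneric("atomName", function(x) standardGeneric("atomName"))
#' @rdname accessors
#' @export
setGeneric("altLoc", function(x) standardGeneric("altLoc"))
#' @rdname accessors
#' @export
setGeneric("serial", function(x) standardGeneric("serial"))
#' @rdname accessors
#' @export
setGeneric("serial<-", function(x, value) standardGeneric("serial<-"))
#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("coords<-", function(x, value) standardGeneric("coords<-"))
#' @rdname accessors
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))
#' @rdname accessors
#' @export
setGeneric("bFactor", function(x) standardGeneric("bFactor"))
#' @rdname accessors
#' @export
setGeneric("element", function(x) standardGeneric("element"))
#' @rdname accessors
#' @export
setGeneric("isHetatm", function(x) standardGeneric("isHetatm"))
#' @rdname accessors
#' @export
setGeneric("metadataLines",
           function(x, which = c("all", "before", "after"))
             standardGeneric("metadataLines"))
#' @rdname accessors
#' @export
setGeneric("parseErrors", function(x) standardGeneric("parseErrors"))
#' @rdname accessors
#' @export
setGeneric("parsedStructure", function(x) standardGeneric("parsedStructure"))

#' @rdname accessors
setMethod("models", "PDBStructure", function(x) x@models)
#' @rdname accessors
setMethod("chains", "Model", function(x) x@chains)
#' @rdname accessors
setMethod("residues", "Chain", function(x) x@residues)
#' @rdname accessors
setMethod("atoms", "Residue", function(x) x@atoms)
#' @rdname accessors
setMethod("modelId", "Model", function(x) x@modelId)
#' @rdname accessors
setMethod("chainId", "Chain", function(x) x@chainId)
#' @rdname accessors
setMethod("resName", "Residue", function(x) x@resName)
#' @rdname accessors
setMethod("resName<-", "Residue", function(x, value) {
  x@resName <- trimws(value); validObject(x); x
})
#' @rdname accessors
setMethod("resSeq", "Residue", function(x) x@resSeq)
#' @rdname accessors
setMethod("resSeq<-", "Residue", function(x, value) {
  x@resSeq <- as.integer(value); validObject(x); x
})
#' @rdname accessors
setMethod("insCode", "Residue", function(x) x@insCode)
#' @rdname accessors
setMethod("insCode<-", "Residue", function(x, value) {
  x@insCode <- value; validObject(x); x
})
#' @rdname accessors
setMethod("atomName", "Atom", function(x) x@name)
#' @rdname accessors
setMethod("altLoc", "Atom", function(x) x@altLoc)
#' @rdname accessors
setMethod("serial", "Atom", function(x) x@serial)
#' @rdname accessors
setMethod("serial<-", "Atom", function(x, value) {
  x@serial <- as.integer(value); validObject(x); x
})
#' @rdname accessors
setMethod("coords", "Atom", function(x) x@coord)
#' @rdname accessors
setMethod("coords<-", "Atom", function(x, value) {
  x@coord <- as.numeric(value); validObject(x); x
})
#' @rdname accessors
setMethod("occupancy", "Atom", function(x) x@occupancy)
#' @rdname accessors
setMethod("bFactor", "Atom", function(x) x@bFactor)
#' @rdname accessors
setMethod("element", "Atom", function(x) x@element)
#' @rdname accessors
setMethod("isHetatm", "Atom", function(x) x@isHetatm)
#' @rdname accessors
setMethod("metadataLines", "PDBStructure",
  function(x, which = c("all", "before", "after")) {
    switch(match.arg(which),
           all = c(x@metaBefore, x@metaAfter),
           before = x@metaBefore,
           after = x@metaAfter)
  })
#' @rdname accessors
setMethod("parseErrors", "PDBParseResult", function(x) x@errors)
#' @rdname accessors
setMethod("parsedStructure", "PDBParseResult", function(x) x@structure)
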