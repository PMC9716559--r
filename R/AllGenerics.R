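## Accessor generics. Slot access stays internal to the package; user code
## goes through these.

#' Accessors for registercheck S4 containers
#'
#' @param x an object of the documented class.
#' @return \code{chainLength}: the reference sequence length L.
#' @rdname accessors
#' @export
setGeneric("chainLength", function(x) standardGeneric("chainLength"))

#' @rdname accessors
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))

#' @rdname accessors
#' @export
setGeneric("repCoords", function(x) standardGeneric("repCoords"))

#' @rdname accessors
#' @export
setGeneric("chainSequence", function(x) standardGeneric("chainSequence"))

#' @rdname accessors
#' @export
setGeneric("contactPairs", function(x) standardGeneric("contactPairs"))

#' @rdname accessors
#' @export
setGeneric("contactCounts", function(x) standardGeneric("contactCounts"))

#' @rdname accessors
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))

#' @rdname accessors
#' @export
setGeneric("metricFlags", function(x) standardGeneric("metricFlags"))

#' @rdname accessors
#' @export
setGeneric("alignmentMapping", function(x) standardGeneric("alignmentMapping"))

#' @rdname accessors
#' @export
setGeneric("filterVerdicts", function(x) standardGeneric("filterVerdicts"))

#' @rdname accessors
#' @export
setGeneric("reportTable", function(x) standardGeneric("reportTable"))

#' @rdname accessors
setMethod("chainLength", "StructureChain", function(x) x@L)

#' @rdname accessors
setMethod("chainLength", "ContactMap", function(x) x@L)

#' @rdname accessors
setMethod("chainLength", "Distogram", function(x) nchar(x@sequence))

#' @rdname accessors
setMethod("residueTable", "StructureChain", function(x) x@residues)

#' @rdname accessors
setMethod("repCoords", "StructureChain", function(x) {
    m <- as.matrix(x@residues[, c("x", "y", "z")])
    rownames(m) <- x@residues$seqIndex
    m
})

#' @rdname accessors
setMethod("chainSequence", "StructureChain", function(x)
    paste(x@residues$aa, collapse = ""))

#' @rdname accessors
setMethod("chainSequence", "Distogram", function(x) x@sequence)

#' @rdname accessors
setMethod("contactPairs", "ContactMap", function(x) x@pairs)

#' @rdname accessors
setMethod("contactCounts", "PredictedContactMap", function(x) x@counts)

#' @rdname accessors
setMethod("metricValues", "MetricTable", function(x) x@metrics)

#' @rdname accessors
setMethod("metricFlags", "MetricTable", function(x) x@flags)

#' @rdname accessors
setMethod("alignmentMapping", "CMOAlignment", function(x) x@mapping)

#' @rdname accessors
setMethod("filterVerdicts", "RegisterShiftCall", function(x)
    x@filterVerdicts)

#' @rdname accessors
setMethod("reportTable", "ValidationReport", function(x) x@residues)
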