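#' Accessors
#'
#' @param x an object.
#' @param ... additional arguments.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("features", function(x, ...) standardGeneric("features"))

#' @rdname accessors
#' @export
setGeneric("genomeLengths", function(x, ...) standardGeneric("genomeLengths"))

#' @rdname accessors
#' @export
setGeneric("singles", function(x, ...) standardGeneric("singles"))

#' @rdname accessors
#' @export
setGeneric("chimeras", function(x, ...) standardGeneric("chimeras"))

#' @rdname accessors
#' @export
setGeneric("schimeraTable", function(x, ...) standardGeneric("schimeraTable"))

#' @rdname accessors
#' @export
setGeneric("guideTable", function(x, ...) standardGeneric("guideTable"))

#' Flip aligned strands to transcript strands
#'
#' For reverse-stranded libraries the sequenced strand is the reverse
#' complement of the transcript; this operation flips the aligned strand of
#' both mates when the object's `libraryReverse` flag is set, and is the
#' identity otherwise. Coordinates are unchanged. Applying it twice returns
#' the original strands.
#'
#' @param x a [MatePairs-class] object.
#' @param ... unused.
#' @return The object with strands flipped iff `libraryReverse` is `TRUE`.
#' @export
setGeneric("transcriptStrand", function(x, ...) standardGeneric("transcriptStrand"))

#' @rdname accessors
#' @export
setMethod("features", "FeatureSet", function(x) x@anno)

#' @rdname accessors
#' @export
setMethod("genomeLengths", "FeatureSet", function(x) seqlengths(x@anno))

#' @rdname accessors
#' @export
setMethod("singles", "FragmentSet", function(x) x@singles)

#' @rdname accessors
#' @export
setMethod("chimeras", "FragmentSet", function(x)
  list(rna1 = x@rna1, rna2 = x@rna2))

#' @rdname accessors
#' @export
setMethod("schimeraTable", "SChimeraSet", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("guideTable", "GuideSet", function(x) x@table)
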