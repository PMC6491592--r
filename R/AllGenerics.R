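#' @rdname plastome-accessors
#' @export
setGeneric("seqId", function(x) standardGeneric("seqId"))

#' @rdname plastome-accessors
#' @export
setGeneric("plastomeSeq", function(x) standardGeneric("plastomeSeq"))

#' @rdname plastome-accessors
#' @export
setGeneric("plastomeRegions", function(x) standardGeneric("plastomeRegions"))

#' @rdname plastome-accessors
#' @export
setGeneric("plastomeGenes", function(x) standardGeneric("plastomeGenes"))

#' @rdname plastome-accessors
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' @rdname geneSequence
#' @export
setGeneric("geneSequence", function(x, gene) standardGeneric("geneSequence"))

#' @rdname structure-accessors
#' @export
setGeneric("basePairs", function(x) standardGeneric("basePairs"))

#' @rdname structure-accessors
#' @export
setGeneric("dotBracket", function(x) standardGeneric("dotBracket"))

#' Accessors for Plastome objects
#'
#' @param x A [Plastome-class] object.
#' @return `seqId` the sequence identifier; `plastomeSeq` the
#'   [Biostrings::DNAString]; `plastomeRegions` / `plastomeGenes` the
#'   region and gene [GenomicRanges::GRanges]; `geneNames` the character
#'   vector of gene names.
#' @name plastome-accessors
#' @aliases seqId plastomeSeq plastomeRegions plastomeGenes geneNames
NULL

#' Accessors for RNAStructure objects
#'
#' @param x An [RNAStructure-class] object.
#' @return `basePairs` the two-column integer matrix of pairs;
#'   `dotBracket` the dot-bracket string.
#' @name structure-accessors
#' @aliases basePairs dotBracket
NULL

setMethod("seqId", "Plastome", function(x) x@seqId)
setMethod("plastomeSeq", "Plastome", function(x) x@sequence)
setMethod("plastomeRegions", "Plastome", function(x) x@regions)
setMethod("plastomeGenes", "Plastome", function(x) x@genes)
setMethod("geneNames", "Plastome",
          function(x) S4Vectors::mcols(x@genes)$gene)
setMethod("basePairs", "RNAStructure", function(x) x@pairs)
setMethod("dotBracket", "RNAStructure", function(x) x@dotBracket)
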