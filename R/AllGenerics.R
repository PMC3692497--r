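#' Number of alignment columns
#' @param x a [GeneAlignment-class].
#' @return integer site count.
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' Number of taxa
#' @param x a [GeneAlignment-class].
#' @return integer taxon count.
#' @export
setGeneric("nTaxa", function(x) standardGeneric("nTaxa"))

#' Taxon labels
#' @param x a [GeneAlignment-class].
#' @return character vector of labels.
#' @export
setGeneric("taxonNames", function(x) standardGeneric("taxonNames"))

#' Residue matrix
#' @param x a [GeneAlignment-class].
#' @return character matrix (taxa x sites).
#' @export
setGeneric("seqMatrix", function(x) standardGeneric("seqMatrix"))

#' Alignment alphabet
#' @param x a [GeneAlignment-class].
#' @return \code{"AA"} or \code{"DNA"}.
#' @export
setGeneric("seqAlphabet", function(x) standardGeneric("seqAlphabet"))

#' Gene partition table
#' @param x a [GeneAlignment-class].
#' @return data.frame with columns \code{gene}, \code{start}, \code{end}
#'   (0-based half-open).
#' @export
setGeneric("genePartitions", function(x) standardGeneric("genePartitions"))

#' @rdname nSites
#' @export
setMethod("nSites", "GeneAlignment", function(x) ncol(x@seqs))

#' @rdname nTaxa
#' @export
setMethod("nTaxa", "GeneAlignment", function(x) nrow(x@seqs))

#' @rdname taxonNames
#' @export
setMethod("taxonNames", "GeneAlignment", function(x) rownames(x@seqs))

#' @rdname seqMatrix
#' @export
setMethod("seqMatrix", "GeneAlignment", function(x) x@seqs)

#' @rdname seqAlphabet
#' @export
setMethod("seqAlphabet", "GeneAlignment", function(x) x@alphabet)

#' @rdname genePartitions
#' @export
setMethod("genePartitions", "GeneAlignment", function(x) x@partitions)
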