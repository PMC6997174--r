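#' Accessors for corephylo classes
#'
#' @param x a corephylo object.
#' @name accessors
NULL

#' @describeIn accessors sample identifiers held in an object.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @describeIn accessors reference contig layout (named lengths).
#' @export
setGeneric("contigLengths", function(x) standardGeneric("contigLengths"))

#' @describeIn accessors per-sample call tracks (named character vector).
#' @export
setGeneric("callTracks", function(x) standardGeneric("callTracks"))

#' @describeIn accessors global 1-based core column positions.
#' @export
setGeneric("corePositions", function(x) standardGeneric("corePositions"))

#' @describeIn accessors indices of SNP (polymorphic) core columns.
#' @export
setGeneric("snpColumns", function(x) standardGeneric("snpColumns"))

#' @describeIn accessors aligned fraction of the reference.
#' @export
setGeneric("alignedFraction", function(x) standardGeneric("alignedFraction"))

#' @describeIn accessors SNP records of a pairwise result.
#' @export
setGeneric("snpRecords", function(x) standardGeneric("snpRecords"))

#' @describeIn accessors reference sample id of an allele table.
#' @export
setGeneric("referenceId", function(x) standardGeneric("referenceId"))

#' @describeIn accessors repeat-mask logical vector (global frame).
#' @export
setGeneric("repeatMask", function(x) standardGeneric("repeatMask"))

setMethod("sampleIds", "AlleleTable", function(x) names(x@tracks))
setMethod("sampleIds", "CoreAlignment", function(x) x@samples)
setMethod("sampleIds", "PairwiseResult", function(x) x@sample)
setMethod("sampleIds", "CallTrack", function(x) x@sample)

setMethod("contigLengths", "AlleleTable", function(x) x@contigs)
setMethod("contigLengths", "CoreAlignment", function(x) x@contigs)
setMethod("contigLengths", "PairwiseResult", function(x) x@refLayout)
setMethod("contigLengths", "CallTrack", function(x) x@refLayout)

setMethod("callTracks", "AlleleTable", function(x) x@tracks)
setMethod("callTracks", "CallTrack", function(x) setNames(x@track, x@sample))

setMethod("corePositions", "CoreAlignment", function(x) x@positions)
setMethod("snpColumns", "CoreAlignment", function(x) x@snpCols)

setMethod("alignedFraction", "PairwiseResult", function(x) x@alignedFraction)

setMethod("snpRecords", "PairwiseResult", function(x) x@snps)

setMethod("referenceId", "AlleleTable", function(x) x@reference)
setMethod("repeatMask", "AlleleTable", function(x) x@mask)

#' Core alignment base matrix
#'
#' Extract the core alignment as a samples x columns character matrix
#' (single-character cells), optionally restricted to SNP columns.
#'
#' @param x a CoreAlignment.
#' @param snpOnly logical; restrict to SNP columns.
#' @return character matrix with one row per sample.
#' @export
coreBaseMatrix <- function(x, snpOnly = FALSE) {
  stopifnot(is(x, "CoreAlignment"))
  n <- length(x@positions)
  if (n == 0L)
    return(matrix(character(0), nrow = length(x@samples), ncol = 0,
                  dimnames = list(x@samples, NULL)))
  m <- do.call(rbind, lapply(x@samples, function(s)
    strsplit(x@bases[[s]], "", fixed = TRUE)[[1]]))
  rownames(m) <- x@samples
  if (snpOnly) m <- m[, x@snpCols, drop = FALSE]
  m
}
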