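#' Central S4 classes
#'
#' The pipeline's persistent data structures: MinHash sketches, pairwise
#' alignment results, per-sample call tracks, the allele table, and the
#' core alignment.
#'
#' @name corephylo-classes
NULL

#' MinHash bottom-s sketch of a genome
#'
#' Stores the s smallest distinct hash values of the canonical k-mers of a
#' genome under a fixed 64-bit mixer (the top 53 bits of each hash are kept
#' so values are exactly representable as doubles).
#'
#' @slot sample sample identifier.
#' @slot k k-mer length (bases).
#' @slot sketchSize target number of hashes s.
#' @slot hashes strictly increasing numeric vector, length <= s.
#' @slot genomeLength total genome length in bases.
#' @export
setClass("MinHashSketch",
  representation(sample = "character", k = "integer", sketchSize = "integer",
                 hashes = "numeric", genomeLength = "integer"))

setValidity("MinHashSketch", function(object) {
  if (object@k < 3L) return("k must be >= 3")
  if (length(object@hashes) > object@sketchSize)
    return("more hashes than sketchSize")
  if (is.unsorted(object@hashes, strictly = TRUE))
    return("hashes must be strictly increasing")
  TRUE
})

#' Pairwise whole-genome alignment of one sample against the reference
#'
#' @slot sample sample identifier.
#' @slot blocks data.frame of alignment blocks (1-based inclusive reference
#'   and query intervals, strand, chain weight).
#' @slot snps data.frame (contig, pos, ref_base, qry_base), 1-based.
#' @slot gaps data.frame (contig, start, end), 1-based inclusive reference
#'   intervals without a query base (unaligned or deleted in the query).
#' @slot track full-length per-reference-position call string over
#'   \{A,C,G,T,-,N\} in the global reference frame (mask not yet applied).
#' @slot alignedFraction aligned reference bases / total reference bases.
#' @slot refLayout named integer vector of reference contig lengths.
#' @export
setClass("PairwiseResult",
  representation(sample = "character", blocks = "data.frame",
                 snps = "data.frame", gaps = "data.frame",
                 track = "character", alignedFraction = "numeric",
                 refLayout = "integer"))

setValidity("PairwiseResult", function(object) {
  if (nchar(object@track) != sum(object@refLayout))
    return("track length must equal total reference length")
  if (object@alignedFraction < 0 || object@alignedFraction > 1)
    return("alignedFraction must be in [0,1]")
  TRUE
})

#' Per-sample consensus call track from read mapping
#'
#' @slot sample sample identifier.
#' @slot track per-reference-position call string over \{A,C,G,T,-,N\}:
#'   a base where depth and allele-fraction thresholds were met, N
#'   (ambiguous) where covered but no base reached the fraction, - (gap)
#'   where depth was below threshold or uncovered.
#' @slot depth integer read depth per position.
#' @slot fraction winning allele fraction per position (NA where depth 0).
#' @slot refLayout named integer vector of reference contig lengths.
#' @export
setClass("CallTrack",
  representation(sample = "character", track = "character",
                 depth = "integer", fraction = "numeric",
                 refLayout = "integer"))

setValidity("CallTrack", function(object) {
  L <- sum(object@refLayout)
  if (nchar(object@track) != L) return("track length != reference length")
  if (length(object@depth) != L) return("depth length != reference length")
  TRUE
})

#' The allele table: per-sample, per-reference-position calls
#'
#' The central orthology structure: one call in \{A,C,G,T,-,N\} for every
#' sample at every reference position, plus the repeat mask. Everything
#' downstream (core genome, SNP matrices, subset re-analysis, incremental
#' placement) reads from this table; no realignment is ever needed.
#'
#' @slot reference sample id of the reference genome.
#' @slot contigs named integer vector of reference contig lengths, in
#'   layout order.
#' @slot tracks named character vector; one full-length call string per
#'   sample (global reference frame). Masked positions are GAP for every
#'   sample, including the reference.
#' @slot sampleData DataFrame with columns sample and type
#'   (complete/contig/reads).
#' @slot mask logical vector over global positions; TRUE = repeat-masked.
#' @export
setClass("AlleleTable",
  representation(reference = "character", contigs = "integer",
                 tracks = "character", sampleData = "DataFrame",
                 mask = "logical"))

setValidity("AlleleTable", function(object) {
  L <- sum(object@contigs)
  if (length(object@mask) != L) return("mask length != reference length")
  if (any(nchar(object@tracks) != L))
    return("all tracks must have the reference length")
  if (!(object@reference %in% names(object@tracks)))
    return("reference sample missing from tracks")
  if (anyDuplicated(names(object@tracks))) return("duplicate sample ids")
  rt <- charToRaw(object@tracks[[object@reference]])
  bad <- !.is_base_raw(rt) & !object@mask
  if (any(bad))
    return("reference track must be a base at every unmasked position")
  TRUE
})

#' Core alignment: columns conserved and unambiguous in every sample
#'
#' @slot samples ordered kept-sample ids.
#' @slot contigs named integer vector of reference contig lengths.
#' @slot positions global 1-based reference positions of the core columns,
#'   in (contig order, position) order.
#' @slot bases named character vector: one core-alignment string per sample
#'   (length = number of core columns).
#' @slot snpCols integer indices (into positions) of columns with >= 2
#'   distinct bases.
#' @slot partition factor over columns with levels CDS/intergenic, or
#'   length 0 when no annotation was supplied.
#' @export
setClass("CoreAlignment",
  representation(samples = "character", contigs = "integer",
                 positions = "integer", bases = "character",
                 snpCols = "integer", partition = "factor"))

setValidity("CoreAlignment", function(object) {
  n <- length(object@positions)
  if (any(nchar(object@bases) != n))
    return("per-sample core strings must match the number of columns")
  if (!identical(sort(names(object@bases)), sort(object@samples)))
    return("bases names must match samples")
  if (length(object@snpCols) && max(object@snpCols) > n)
    return("snpCols out of range")
  if (length(object@partition) && length(object@partition) != n)
    return("partition length must match columns")
  TRUE
})

#' Run configuration
#'
#' Parsed control-file parameters plus the declared input samples.
#'
#' @slot referenceMode one of user_specified, random, minhash.
#' @slot referenceId reference sample id (required iff user_specified).
#' @slot alignedFractionCutoff minimum fraction of the reference a sample
#'   must cover to be retained, in [0,1].
#' @slot minDepth minimum read depth for a consensus call (>= 1).
#' @slot minAlleleFraction minimum winning allele fraction, in (0.5, 1].
#' @slot treeMethod nj or external.
#' @slot bootstrapReps bootstrap replicates (>= 0).
#' @slot seed run seed.
#' @slot geneticCodeTable NCBI genetic code table number.
#' @slot analysisScope all or cds_only.
#' @slot selectionScreen logical; run the dN/dS gene screen.
#' @slot outputDir output directory.
#' @slot samples DataFrame(sample, type, path1, path2) of declared inputs.
#' @slot gff path to the reference GFF3 annotation ("" if none).
#' @export
setClass("RunConfig",
  representation(referenceMode = "character", referenceId = "character",
                 alignedFractionCutoff = "numeric", minDepth = "integer",
                 minAlleleFraction = "numeric", treeMethod = "character",
                 bootstrapReps = "integer", seed = "integer",
                 geneticCodeTable = "integer", analysisScope = "character",
                 selectionScreen = "logical", outputDir = "character",
                 samples = "DataFrame", gff = "character"))

setValidity("RunConfig", function(object) {
  if (!object@referenceMode %in% c("user_specified", "random", "minhash"))
    return("invalid reference mode")
  if (object@referenceMode == "user_specified" && !nzchar(object@referenceId))
    return("reference_id required when reference_mode is user_specified")
  if (object@alignedFractionCutoff < 0 || object@alignedFractionCutoff > 1)
    return("aligned_fraction_cutoff must be in [0,1]")
  if (object@minAlleleFraction <= 0.5 || object@minAlleleFraction > 1)
    return("min_allele_fraction must be in (0.5, 1]")
  if (object@minDepth < 1L) return("min_depth must be >= 1")
  if (object@bootstrapReps < 0L) return("bootstrap must be >= 0")
  TRUE
})

# ---- show methods -----------------------------------------------------

setMethod("show", "MinHashSketch", function(object) {
  cat("MinHashSketch of", object@sample, "| k =", object@k,
      "| s =", object@sketchSize, "|", length(object@hashes), "hashes |",
      object@genomeLength, "bp\n")
})

setMethod("show", "PairwiseResult", function(object) {
  cat("PairwiseResult:", object@sample, "vs reference\n")
  cat(" ", nrow(object@blocks), "blocks,", nrow(object@snps), "SNPs,",
      nrow(object@gaps), "gap intervals, aligned fraction",
      sprintf("%.4f", object@alignedFraction), "\n")
})

setMethod("show", "CallTrack", function(object) {
  cov <- sum(object@depth > 0)
  cat("CallTrack:", object@sample, "|", cov, "/", length(object@depth),
      "positions covered | mean depth",
      sprintf("%.1f", mean(object@depth)), "\n")
})

setMethod("show", "AlleleTable", function(object) {
  cat("AlleleTable:", length(object@tracks), "samples x",
      sum(object@contigs), "reference positions (",
      length(object@contigs), "contigs ), reference =",
      object@reference, "\n")
  cat("  masked:", sum(object@mask), "positions\n")
})

setMethod("show", "CoreAlignment", function(object) {
  cat("CoreAlignment:", length(object@samples), "samples x",
      length(object@positions), "core columns,",
      length(object@snpCols), "SNP columns\n")
})

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig: reference", object@referenceMode,
      if (nzchar(object@referenceId)) object@referenceId else "",
      "| cutoff", object@alignedFractionCutoff,
      "| depth>=", object@minDepth,
      "| allele fraction>=", object@minAlleleFraction,
      "| tree", object@treeMethod, "x", object@bootstrapReps,
      "| seed", object@seed, "\n")
  cat("  samples:", nrow(object@samples), "\n")
})
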