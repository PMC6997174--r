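#' Default read-mapper parameters
#'
#' @return named list: seed length, repetitive-seed cutoff, identity floor,
#'   band pad and alignment scoring.
#' @export
mapParams <- function() {
  list(seedK = 15L, maxSeedHits = 64L, minIdentity = 0.85, bandPad = 16L,
       match = 1L, mismatch = -3L, gapOpen = -5L, gapExtend = -2L)
}

#' Build the reference seed index for read mapping
#'
#' Contigs are concatenated with N spacers (N-containing seeds are never
#' indexed, so no seed or alignment can span a contig junction). Seeds
#' occurring more than `maxSeedHits` times are marked repetitive and
#' skipped at query time.
#'
#' @param ref reference sequences.
#' @param seedK seed k-mer length (default 15).
#' @param maxSeedHits repetitive-seed cutoff (default 64).
#' @return a SeedIndex (list) with the padded reference string, contig
#'   layout, offsets and seed statistics (nSeeds = indexed seed positions,
#'   nRepetitive = distinct seeds above the cutoff).
#' @export
buildSeedIndex <- function(ref, seedK = 15L, maxSeedHits = 64L) {
  contigs <- .as_contig_chars(ref)
  if (sum(nchar(contigs)) == 0L) stop("empty reference")
  pad <- strrep("N", 50L)
  padded <- paste(contigs, collapse = pad)
  offs <- cumsum(c(0L, head(nchar(contigs) + 50L, -1L)))
  stats <- .cpp_seed_stats(padded, as.integer(seedK), as.integer(maxSeedHits))
  structure(list(padded = padded,
                 contigs = setNames(nchar(contigs), names(contigs)),
                 padOffsets = setNames(as.integer(offs), names(contigs)),
                 seedK = as.integer(seedK),
                 maxSeedHits = as.integer(maxSeedHits),
                 nSeeds = stats$n_positions,
                 nDistinctSeeds = stats$n_distinct,
                 nRepetitive = stats$n_repetitive),
            class = "SeedIndex")
}

#' @export
print.SeedIndex <- function(x, ...) {
  cat("SeedIndex:", length(x$contigs), "contigs,", sum(x$contigs),
      "bp | k =", x$seedK, "|", x$nSeeds, "seed positions,",
      x$nRepetitive, "repetitive seeds\n")
  invisible(x)
}

#' Map reads to the reference by unique-best seed-and-extend
#'
#' Candidate loci are gathered from seed votes on both strands and scored
#' by banded semi-global extension. A read is unmapped when its best score
#' is tied across two distinct loci or its identity over the aligned span
#' falls below `minIdentity`; mates of a pair are mapped independently.
#'
#' @param reads list of reads ([parseFastq()] records) or character vector
#'   of read sequences.
#' @param index a SeedIndex from [buildSeedIndex()].
#' @param params mapper parameters, see [mapParams()].
#' @return data.frame with one row per read: id, mapped, contig, pos
#'   (1-based leftmost reference position), strand, score, identity, ops
#'   (per-column string; read sequence strand-resolved to reference
#'   forward).
#' @export
mapReads <- function(reads, index, params = mapParams()) {
  if (is.list(reads)) {
    ids <- vapply(reads, `[[`, "", "id")
    seqs <- vapply(reads, `[[`, "", "residues")
  } else {
    seqs <- unname(reads)
    ids <- names(reads) %||% paste0("read", seq_along(seqs))
  }
  hits <- .cpp_map_reads(seqs, index$padded, params$seedK,
                         params$maxSeedHits, params$minIdentity,
                         params$bandPad, params$match, params$mismatch,
                         params$gapOpen, params$gapExtend)
  mapped <- hits$ref_start >= 0L
  # convert padded-frame position to (contig, pos)
  contig <- rep(NA_character_, length(seqs))
  pos <- rep(NA_integer_, length(seqs))
  if (any(mapped)) {
    bounds <- c(unname(index$padOffsets), nchar(index$padded))
    ci <- findInterval(hits$ref_start[mapped], bounds)
    contig[mapped] <- names(index$contigs)[ci]
    pos[mapped] <- hits$ref_start[mapped] - index$padOffsets[ci] + 1L
  }
  oriented <- ifelse(mapped & hits$strand < 0L,
                     vapply(seqs, .revcomp, "", USE.NAMES = FALSE), seqs)
  data.frame(id = ids, mapped = mapped, contig = contig, pos = pos,
             strand = ifelse(mapped, ifelse(hits$strand > 0L, "+", "-"), NA),
             score = hits$score, identity = hits$identity,
             ops = as.character(hits$ops), seq = oriented,
             stringsAsFactors = FALSE)
}

#' Build a pileup from read alignments
#'
#' Match and substitution columns contribute the read base; read-deletion
#' columns consume reference without contributing (they only reduce the
#' effective depth); insertions never touch reference coordinates.
#'
#' @param alignments data.frame from [mapReads()].
#' @param index the SeedIndex the reads were mapped against.
#' @return list with counts (4 x L integer matrix over A,C,G,T in the
#'   global unpadded reference frame) and depth (colSums).
#' @export
buildPileup <- function(alignments, index) {
  L <- sum(index$contigs)
  m <- alignments[alignments$mapped, , drop = FALSE]
  if (nrow(m) == 0L) {
    counts <- matrix(0L, 4L, L, dimnames = list(BASES, NULL))
    return(list(counts = counts, depth = integer(L)))
  }
  glob0 <- .contig_to_global(m$contig, m$pos, index$contigs) - 1L
  counts <- .cpp_pileup(L, as.integer(glob0), m$seq, m$ops)
  rownames(counts) <- BASES
  list(counts = counts, depth = as.integer(colSums(counts)))
}

#' Call a per-position consensus track from a pileup
#'
#' A base b is called where depth >= `minDepth` and counts[b]/depth >=
#' `minAlleleFraction` (the allele-fraction rule; the default 0.6 means a
#' 5/9 majority is still ambiguous). Covered positions where no base
#' reaches the fraction are ambiguous (N); positions below the depth floor
#' or uncovered are gaps.
#'
#' @param pileup list from [buildPileup()].
#' @param index the SeedIndex (for the contig layout).
#' @param sample sample id.
#' @param minDepth minimum depth (default 5).
#' @param minAlleleFraction minimum winning fraction, in (0.5, 1]
#'   (default 0.6).
#' @return a [CallTrack-class].
#' @export
callConsensus <- function(pileup, index, sample = "reads",
                          minDepth = 5L, minAlleleFraction = 0.6) {
  if (minAlleleFraction <= 0.5 || minAlleleFraction > 1)
    stop("minAlleleFraction must be in (0.5, 1]")
  counts <- pileup$counts
  depth <- pileup$depth
  L <- length(depth)
  top <- pmax(counts[1L, ], counts[2L, ], counts[3L, ], counts[4L, ])
  frac <- ifelse(depth > 0L, top / depth, NA_real_)
  win <- max.col(t(counts), ties.method = "first")
  call <- rep(GAP_CHAR, L)
  covered <- depth >= minDepth
  call[covered] <- AMBIG_CHAR
  ok <- covered & !is.na(frac) & frac >= minAlleleFraction
  call[ok] <- BASES[win[ok]]
  new("CallTrack", sample = sample, track = paste(call, collapse = ""),
      depth = depth, fraction = frac, refLayout = index$contigs)
}

#' Write a call track TSV and a minimal VCF of SNP calls
#'
#' The TSV has one row per reference position (contig, pos, call, depth,
#' fraction). The VCF lists positions whose call is a base differing from
#' the reference, with DP and AF in INFO.
#'
#' @param track a [CallTrack-class].
#' @param ref reference sequences (for VCF REF alleles).
#' @param prefix output prefix; writes `<prefix>.calls.tsv` and
#'   `<prefix>.vcf`.
#' @return invisibly, the two paths.
#' @export
writeCallTrack <- function(track, ref, prefix) {
  lens <- track@refLayout
  loc <- .global_to_contig(seq_len(sum(lens)), lens)
  calls <- strsplit(track@track, "", fixed = TRUE)[[1L]]
  tsv <- paste0(prefix, ".calls.tsv")
  df <- data.frame(contig = loc$contig, pos = loc$pos, call = calls,
                   depth = track@depth,
                   fraction = round(track@fraction, 4L))
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
  refg <- paste(.as_contig_chars(ref), collapse = "")
  rr <- charToRaw(refg); tr <- charToRaw(track@track)
  idx <- which(.is_base_raw(tr) & .is_base_raw(rr) & tr != rr)
  vcf <- paste0(prefix, ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Winning allele fraction\">",
           paste0("##source=corephylo sample=", track@sample),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- if (length(idx)) {
    l <- .global_to_contig(idx, lens)
    paste(l$contig, l$pos, ".", rawToChar(rr[idx], multiple = TRUE),
          rawToChar(tr[idx], multiple = TRUE), ".", "PASS",
          paste0("DP=", track@depth[idx], ";AF=",
                 round(track@fraction[idx], 4L)), sep = "\t")
  } else character(0)
  writeLines(c(hdr, rows), vcf)
  invisible(c(tsv, vcf))
}
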