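#' Default aligner parameters
#'
#' Anchor, chaining and scoring defaults for the internal MUM aligner:
#' exact on closely related genomes, which is the regime this tool targets.
#'
#' @return named list of parameters.
#' @export
alignParams <- function() {
  list(minAnchorLen = 20L, minRepeatLen = 50L, maxFill = 10000L,
       bandPad = 50L, match = 1L, mismatch = -3L,
       gapOpen = -5L, gapExtend = -2L)
}

#' Mask repeated regions of a genome by self-comparison
#'
#' Every position covered by an off-diagonal exact self-match of length >=
#' `minRepeatLen` (forward or reverse-complement, including across
#' contigs) is masked; both copies of a repeat are masked. Detection is by
#' canonical k-mer multiplicity at k = minRepeatLen, which covers exactly
#' the positions inside such matches.
#'
#' @param genome sequences (DNAStringSet, named character vector, or
#'   [parseFasta()] records).
#' @param minRepeatLen minimum self-match length to mask (default 50).
#' @return named list of [IRanges::IRanges] (1-based inclusive, merged) of
#'   masked intervals per contig; an empty mask is valid.
#' @export
maskRepeats <- function(genome, minRepeatLen = 50L) {
  contigs <- .as_contig_chars(genome)
  if (length(contigs) == 0L || all(!nzchar(contigs))) stop("empty genome")
  masks <- .cpp_repeat_mask(unname(contigs), as.integer(minRepeatLen))
  out <- lapply(masks, function(m) {
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    IRanges::reduce(IRanges(starts[keep], ends[keep]))
  })
  names(out) <- names(contigs)
  out
}

#' Flatten a repeat mask to a logical vector over global positions
#'
#' @param mask named list of IRanges from [maskRepeats()] (or NULL).
#' @param contigLengths named integer vector of contig lengths.
#' @return logical vector of length sum(contigLengths).
#' @export
maskToLogical <- function(mask, contigLengths) {
  out <- logical(sum(contigLengths))
  if (is.null(mask)) return(out)
  offs <- .contig_offsets(contigLengths)
  names(offs) <- names(contigLengths)
  for (ctg in names(mask)) {
    ir <- mask[[ctg]]
    if (length(ir) == 0L) next
    for (i in seq_along(ir))
      out[(offs[[ctg]] + start(ir)[i]):(offs[[ctg]] + end(ir)[i])] <- TRUE
  }
  out
}

#' Find maximal unique matches between two sequences
#'
#' Exact matches of length >= `minAnchorLen` occurring exactly once in each
#' sequence (per strand) and extendable in neither direction. N never
#' matches. The minus strand is searched against the reverse complement of
#' the query; coordinates are reported in the forward frames of both
#' sequences, with `qry_start_rc` retaining the reverse-complement-frame
#' start used for chaining.
#'
#' @param ref,qry sequences (character scalars).
#' @param minAnchorLen minimum match length (default 20).
#' @param strands strands to search.
#' @return data.frame(ref_start, qry_start, length, strand, qry_start_rc),
#'   0-based starts, sorted by ref_start.
#' @export
findMums <- function(ref, qry, minAnchorLen = 20L, strands = c("+", "-")) {
  out <- list()
  if ("+" %in% strands) {
    m <- .cpp_find_mums(ref, qry, as.integer(minAnchorLen))
    if (nrow(m)) {
      m$strand <- "+"
      m$qry_start_rc <- m$qry_start
      out[["+"]] <- m
    }
  }
  if ("-" %in% strands) {
    qlen <- nchar(qry)
    m <- .cpp_find_mums(ref, .revcomp(qry), as.integer(minAnchorLen))
    if (nrow(m)) {
      m$strand <- "-"
      m$qry_start_rc <- m$qry_start
      m$qry_start <- qlen - (m$qry_start + m$length)
      out[["-"]] <- m
    }
  }
  if (length(out) == 0L)
    return(data.frame(ref_start = integer(0), qry_start = integer(0),
                      length = integer(0), strand = character(0),
                      qry_start_rc = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$ref_start, res$qry_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Maximum-weight colinear chain of anchors
#'
#' Anchors must come from one (ref contig, qry contig, strand) group. The
#' chain maximizes total anchored length over subsets strictly increasing
#' in both coordinates; overlaps between consecutive chain members are
#' charged against the later anchor's weight (it is trimmed during gap
#' fill). Ties resolve to the earliest ref_start sequence.
#'
#' @param anchors data.frame with ref_start, qry_start_rc (chain-frame
#'   query start) and length.
#' @return the chained subset of `anchors` (possibly empty), in chain
#'   order, with attribute "weight".
#' @export
chainAnchors <- function(anchors) {
  k <- nrow(anchors)
  if (k == 0L) {
    attr(anchors, "weight") <- 0
    return(anchors)
  }
  a <- anchors[order(anchors$ref_start, anchors$qry_start_rc), , drop = FALSE]
  score <- as.numeric(a$length)
  prev <- rep(NA_integer_, k)
  for (j in seq_len(k)) {
    for (i in seq_len(j - 1L)) {
      if (a$ref_start[i] < a$ref_start[j] && a$qry_start_rc[i] < a$qry_start_rc[j]) {
        trim <- max(0L, a$ref_start[i] + a$length[i] - a$ref_start[j],
                    a$qry_start_rc[i] + a$length[i] - a$qry_start_rc[j])
        w <- score[i] + a$length[j] - trim
        if (w > score[j]) { score[j] <- w; prev[j] <- i }
      }
    }
  }
  best <- which.max(score)
  path <- integer(0)
  at <- best
  while (!is.na(at)) { path <- c(at, path); at <- prev[at] }
  out <- a[path, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "weight") <- score[best]
  out
}

#' Fill inter-anchor segments of a chain into alignment blocks
#'
#' Consecutive anchors are merged with banded affine-gap global alignments
#' of the inter-anchor segment pairs when both sides are <= `maxFill`
#' bases; larger segment pairs split the chain into separate blocks,
#' leaving the intervening reference interval unaligned.
#'
#' @param chain chained anchors from [chainAnchors()].
#' @param ref reference contig sequence (forward frame).
#' @param qryStrand query contig sequence in the chain's strand frame
#'   (reverse-complemented for minus-strand chains).
#' @param params aligner parameters, see [alignParams()].
#' @return list of blocks; each block has ref_start, qry_start (both
#'   0-based, chain frame) and ops (per-column string over =,X,D,I).
#' @export
fillGaps <- function(chain, ref, qryStrand, params = alignParams()) {
  if (nrow(chain) == 0L) return(list())
  blocks <- list()
  cur_ops <- character(0)
  cur_ref0 <- NA_integer_; cur_qry0 <- NA_integer_
  prev_ref_end <- NA_integer_; prev_qry_end <- NA_integer_
  # extend to the sequence ends when both flanks are small and the
  # extension aligns at least neutrally (guards against unrelated flanks)
  end_fill <- function(r0, r1, q0, q1) {
    gr <- r1 - r0; gq <- q1 - q0
    if (gr <= 0L || gq <= 0L) return(NULL)
    if (gr > params$maxFill || gq > params$maxFill) return(NULL)
    al <- .cpp_banded_global(substr(ref, r0 + 1L, r1),
                             substr(qryStrand, q0 + 1L, q1),
                             params$bandPad, params$match, params$mismatch,
                             params$gapOpen, params$gapExtend)
    ident <- mean(strsplit(al$ops, "", fixed = TRUE)[[1L]] == "=")
    if (!(gr <= 50L && gq <= 50L) && ident < 0.7) return(NULL)
    al$ops
  }
  flush <- function() {
    if (length(cur_ops))
      blocks[[length(blocks) + 1L]] <<- list(
        ref_start = cur_ref0, qry_start = cur_qry0,
        ops = paste(cur_ops, collapse = ""))
    cur_ops <<- character(0)
  }
  for (i in seq_len(nrow(chain))) {
    rs <- chain$ref_start[i]; qs <- chain$qry_start_rc[i]; ln <- chain$length[i]
    if (!is.na(prev_ref_end)) {
      trim <- max(0L, prev_ref_end - rs, prev_qry_end - qs)
      rs <- rs + trim; qs <- qs + trim; ln <- ln - trim
      if (ln <= 0L) next
      gr <- rs - prev_ref_end       # inter-anchor segment lengths
      gq <- qs - prev_qry_end
      if (gr <= params$maxFill && gq <= params$maxFill) {
        if (gr > 0L || gq > 0L) {
          seg_r <- substr(ref, prev_ref_end + 1L, rs)
          seg_q <- substr(qryStrand, prev_qry_end + 1L, qs)
          al <- .cpp_banded_global(seg_r, seg_q, params$bandPad,
                                   params$match, params$mismatch,
                                   params$gapOpen, params$gapExtend)
          cur_ops <- c(cur_ops, al$ops)
        }
      } else {
        flush()
        cur_ref0 <- rs; cur_qry0 <- qs
      }
    } else {
      cur_ref0 <- rs; cur_qry0 <- qs
      lead <- end_fill(0L, rs, 0L, qs)
      if (!is.null(lead)) {
        cur_ref0 <- 0L; cur_qry0 <- 0L
        cur_ops <- c(cur_ops, lead)
      }
    }
    cur_ops <- c(cur_ops, strrep("=", ln))
    prev_ref_end <- rs + ln
    prev_qry_end <- qs + ln
  }
  tail_ops <- end_fill(prev_ref_end, nchar(ref), prev_qry_end, nchar(qryStrand))
  if (!is.null(tail_ops)) cur_ops <- c(cur_ops, tail_ops)
  flush()
  blocks
}

#' Align a query sample (complete genome or contigs) to the reference
#'
#' Composition of MUM finding, colinear chaining and banded gap fill over
#' all (reference contig, query contig, strand) pairs. Overlapping block
#' claims on the reference are resolved in favor of the higher-weight
#' chain. Substitutions become SNPs only where both bases are in
#' \{A,C,G,T\} and the position is unmasked; deleted and unaligned
#' reference positions become gaps; columns with N on either side are
#' ambiguous. Query bases are reported reference-forward.
#'
#' @param ref reference sequences (DNAStringSet / named character /
#'   records).
#' @param qry query sequences, possibly multi-contig.
#' @param sample sample id for the result.
#' @param mask repeat mask from [maskRepeats()], or NULL.
#' @param params aligner parameters, see [alignParams()].
#' @return a [PairwiseResult-class].
#' @export
alignPair <- function(ref, qry, sample = "query", mask = NULL,
                      params = alignParams()) {
  refc <- .as_contig_chars(ref)
  qryc <- .as_contig_chars(qry)
  lens <- setNames(nchar(refc), names(refc))
  maskv <- maskToLogical(mask, lens)
  track_parts <- character(length(refc))
  all_blocks <- list()
  for (ri in seq_along(refc)) {
    rseq <- refc[[ri]]
    chains <- list()
    for (qi in seq_along(qryc)) {
      qseq <- qryc[[qi]]
      if (nchar(qseq) < params$minAnchorLen) next
      mums <- findMums(rseq, qseq, params$minAnchorLen)
      for (st in c("+", "-")) {
        grp <- mums[mums$strand == st, , drop = FALSE]
        if (nrow(grp) == 0L) next
        ch <- chainAnchors(grp)
        if (nrow(ch) == 0L) next
        qstr <- if (st == "+") qseq else .revcomp(qseq)
        blocks <- fillGaps(ch, rseq, qstr, params)
        if (length(blocks) == 0L) next
        chains[[length(chains) + 1L]] <- list(
          weight = attr(ch, "weight"), strand = st,
          qry_contig = names(qryc)[qi], qlen = nchar(qseq),
          qstr = qstr, blocks = blocks)
      }
    }
    if (length(chains)) {
      ord <- order(-vapply(chains, `[[`, 0, "weight"),
                   vapply(chains, function(c) c$blocks[[1L]]$ref_start, 0L))
      chains <- chains[ord]
      bstart <- integer(0); bqry <- character(0); bops <- character(0)
      for (ch in chains) {
        for (b in ch$blocks) {
          qlen_consumed <- sum(charToRaw(b$ops) != charToRaw("D")[1L])
          bstart <- c(bstart, b$ref_start)
          bqry <- c(bqry, substr(ch$qstr, b$qry_start + 1L,
                                 b$qry_start + qlen_consumed))
          bops <- c(bops, b$ops)
          # reporting coordinates (1-based inclusive, forward query frame)
          rlen_consumed <- sum(charToRaw(b$ops) != charToRaw("I")[1L])
          q0 <- if (ch$strand == "+") b$qry_start
                else ch$qlen - (b$qry_start + qlen_consumed)
          all_blocks[[length(all_blocks) + 1L]] <- data.frame(
            ref_contig = names(refc)[ri],
            ref_start = b$ref_start + 1L,
            ref_end = b$ref_start + rlen_consumed,
            qry_contig = ch$qry_contig,
            qry_start = q0 + 1L, qry_end = q0 + qlen_consumed,
            strand = ch$strand, weight = ch$weight,
            stringsAsFactors = FALSE)
        }
      }
      painted <- .cpp_paint_track(rseq, bstart, bqry, bops)
      track_parts[ri] <- painted$track
    } else {
      track_parts[ri] <- strrep(GAP_CHAR, nchar(rseq))
    }
  }
  track <- paste(track_parts, collapse = "")
  refglob <- paste(refc, collapse = "")
  tr <- charToRaw(track); rr <- charToRaw(refglob)
  aligned <- tr != charToRaw(GAP_CHAR)[1L]
  snp_idx <- which(.is_base_raw(tr) & .is_base_raw(rr) & tr != rr & !maskv)
  snps <- if (length(snp_idx)) {
    loc <- .global_to_contig(snp_idx, lens)
    data.frame(contig = loc$contig, pos = loc$pos,
               ref_base = rawToChar(rr[snp_idx], multiple = TRUE),
               qry_base = rawToChar(tr[snp_idx], multiple = TRUE),
               stringsAsFactors = FALSE)
  } else data.frame(contig = character(0), pos = integer(0),
                    ref_base = character(0), qry_base = character(0))
  gap_idx <- which(!aligned)
  gaps <- if (length(gap_idx)) {
    loc <- .global_to_contig(gap_idx, lens)
    brk <- c(TRUE, diff(gap_idx) != 1L | loc$contig[-1L] != loc$contig[-length(gap_idx)])
    grp <- factor(cumsum(brk), levels = unique(cumsum(brk)))
    ix <- split(seq_along(gap_idx), grp)
    data.frame(contig = vapply(ix, function(i) loc$contig[i[1L]], ""),
               start = vapply(ix, function(i) min(loc$pos[i]), 0L),
               end = vapply(ix, function(i) max(loc$pos[i]), 0L),
               stringsAsFactors = FALSE, row.names = NULL)
  } else data.frame(contig = character(0), start = integer(0), end = integer(0))
  blocks_df <- if (length(all_blocks)) do.call(rbind, all_blocks)
               else data.frame(ref_contig = character(0), ref_start = integer(0),
                               ref_end = integer(0), qry_contig = character(0),
                               qry_start = integer(0), qry_end = integer(0),
                               strand = character(0), weight = numeric(0))
  new("PairwiseResult", sample = sample, blocks = blocks_df, snps = snps,
      gaps = gaps, track = track,
      alignedFraction = sum(aligned) / length(tr),
      refLayout = lens)
}

#' Write per-sample SNP and gap reports
#'
#' Tab-separated, 1-based inclusive coordinates.
#'
#' @param pw a [PairwiseResult-class].
#' @param prefix output path prefix; writes `<prefix>.snps.tsv` and
#'   `<prefix>.gaps.tsv`.
#' @return invisibly, the two paths.
#' @export
writePairwiseReports <- function(pw, prefix) {
  sp <- paste0(prefix, ".snps.tsv")
  gp <- paste0(prefix, ".gaps.tsv")
  write.table(pw@snps, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(pw@gaps, gp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(sp, gp))
}
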