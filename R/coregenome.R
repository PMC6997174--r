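#' Fuse per-sample results into an allele table
#'
#' Genome/contig samples contribute their pairwise alignment tracks
#' (aligned positions get the query base, unaligned and deleted positions
#' GAP, N columns AMBIG); read samples contribute their consensus call
#' tracks verbatim. Repeat-masked positions are forced to GAP for every
#' sample, including the reference.
#'
#' @param ref reference sequences (DNAStringSet / named character /
#'   records).
#' @param refId sample id of the reference.
#' @param mask repeat mask from [maskRepeats()], or NULL.
#' @param pairwise list of [PairwiseResult-class] objects.
#' @param readTracks list of [CallTrack-class] objects.
#' @return an [AlleleTable-class].
#' @export
buildAlleleTable <- function(ref, refId = "reference", mask = NULL,
                             pairwise = list(), readTracks = list()) {
  contigs <- .as_contig_chars(ref)
  lens <- setNames(nchar(contigs), names(contigs))
  L <- sum(lens)
  maskv <- maskToLogical(mask, lens)
  ids <- c(refId,
           vapply(pairwise, function(p) p@sample, ""),
           vapply(readTracks, function(t) t@sample, ""))
  if (anyDuplicated(ids)) stop("duplicate sample ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  types <- c("complete",
             rep("assembly", length(pairwise)),
             rep("reads", length(readTracks)))
  tracks <- character(length(ids))
  tracks[1L] <- paste(contigs, collapse = "")
  i <- 1L
  for (p in pairwise) {
    if (!identical(unname(p@refLayout), unname(lens)))
      stop("track length mismatch for sample ", p@sample)
    i <- i + 1L
    tracks[i] <- p@track
  }
  for (t in readTracks) {
    if (!identical(unname(t@refLayout), unname(lens)))
      stop("track length mismatch for sample ", t@sample)
    i <- i + 1L
    tracks[i] <- t@track
  }
  names(tracks) <- ids
  if (any(maskv)) {
    gap <- charToRaw(GAP_CHAR)[1L]
    tracks <- vapply(tracks, function(tr) {
      r <- charToRaw(tr)
      r[maskv] <- gap
      rawToChar(r)
    }, "", USE.NAMES = TRUE)
  }
  new("AlleleTable", reference = refId, contigs = lens, tracks = tracks,
      sampleData = S4Vectors::DataFrame(sample = ids, type = types),
      mask = maskv)
}

#' Drop samples below an aligned-fraction cutoff
#'
#' Samples whose non-GAP fraction of the reference falls below `cutoff`
#' are removed (the aligned-fraction inclusion rule; e.g. a 15% floor for
#' distant relatives or a 99% floor for near-complete coverage). The
#' reference is never dropped.
#'
#' @param table an [AlleleTable-class].
#' @param cutoff fraction in [0,1].
#' @return the filtered table, with attribute "dropped" naming removed
#'   samples.
#' @export
filterSamples <- function(table, cutoff = 0) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  gap <- charToRaw(GAP_CHAR)[1L]
  frac <- vapply(table@tracks, function(tr) {
    r <- charToRaw(tr)
    1 - sum(r == gap) / length(r)
  }, 0)
  keep <- frac >= cutoff | names(table@tracks) == table@reference
  dropped <- names(table@tracks)[!keep]
  if (sum(keep) < 2L)
    stop("all non-reference samples dropped by cutoff ", cutoff,
         "; no analysis possible")
  out <- table
  out@tracks <- table@tracks[keep]
  out@sampleData <- table@sampleData[keep, , drop = FALSE]
  attr(out, "dropped") <- dropped
  if (length(dropped))
    message("dropped by aligned-fraction cutoff ", cutoff, ": ",
            paste(dropped, collapse = ", "))
  out
}

#' Compute the core alignment for a sample subset
#'
#' Core columns are the reference positions where every subset sample's
#' call is an unambiguous base; ambiguity excludes a position exactly like
#' a gap. SNP columns are core columns with at least two distinct bases.
#' Monomorphic columns are retained so downstream distances are per-site.
#'
#' @param table an [AlleleTable-class].
#' @param subset sample ids (default all); the reference is always
#'   included.
#' @param annotation optional feature data.frame from [parseGff3()]; when
#'   given, columns are partitioned into CDS/intergenic by the reference
#'   annotation.
#' @return a [CoreAlignment-class]. An empty core (all-gap sample, tiny
#'   overlap) is valid and warns.
#' @export
computeCore <- function(table, subset = NULL, annotation = NULL) {
  if (is.null(subset)) subset <- names(table@tracks)
  unknown <- setdiff(subset, names(table@tracks))
  if (length(unknown)) stop("unknown sample ids: ", paste(unknown, collapse = ", "))
  subset <- unique(c(table@reference, subset))
  subset <- names(table@tracks)[names(table@tracks) %in% subset]  # table order
  if (length(subset) < 2L) stop("core computation needs at least 2 samples")
  raws <- lapply(table@tracks[subset], charToRaw)
  ok <- .is_base_raw(raws[[1L]])
  for (i in seq_along(raws)[-1L]) ok <- ok & .is_base_raw(raws[[i]])
  pos <- which(ok)
  if (length(pos) == 0L) {
    warning("empty core alignment for this subset")
    return(new("CoreAlignment", samples = subset, contigs = table@contigs,
               positions = integer(0),
               bases = setNames(rep("", length(subset)), subset),
               snpCols = integer(0),
               partition = factor(character(0), levels = c("CDS", "intergenic"))))
  }
  sub <- lapply(raws, `[`, pos)
  poly <- rep(FALSE, length(pos))
  for (i in seq_along(sub)[-1L]) poly <- poly | (sub[[i]] != sub[[1L]])
  bases <- vapply(sub, rawToChar, "", USE.NAMES = TRUE)
  part <- if (!is.null(annotation)) .partition_columns(pos, table@contigs, annotation)
          else factor(character(0), levels = c("CDS", "intergenic"))
  new("CoreAlignment", samples = subset, contigs = table@contigs,
      positions = pos, bases = bases, snpCols = which(poly),
      partition = part)
}

# label global positions CDS/intergenic from reference annotation
.partition_columns <- function(pos, contigLengths, annotation) {
  cds <- annotation[annotation$type == "CDS", , drop = FALSE]
  lab <- rep("intergenic", length(pos))
  if (nrow(cds)) {
    g0 <- .contig_to_global(cds$seqid, cds$start, contigLengths)
    g1 <- .contig_to_global(cds$seqid, cds$end, contigLengths)
    in_cds <- logical(sum(contigLengths))
    for (i in seq_len(nrow(cds))) in_cds[g0[i]:g1[i]] <- TRUE
    lab[in_cds[pos]] <- "CDS"
  }
  factor(lab, levels = c("CDS", "intergenic"))
}

#' Pairwise SNP count matrices
#'
#' count[i, j] is the number of core columns where samples i and j differ;
#' the CDS and intergenic matrices restrict the count to annotated column
#' classes and sum to the core matrix when the annotation covers the
#' reference.
#'
#' @param core a [CoreAlignment-class].
#' @return list of symmetric integer matrices: core, cds, intergenic (the
#'   latter two NULL without annotation), plus coreLength.
#' @export
pairwiseMatrices <- function(core) {
  ids <- core@samples
  snp <- core@snpCols
  base_mat <- function(cols) {
    m <- .cpp_pair_diffs(unname(core@bases[ids]), as.integer(cols))
    dimnames(m) <- list(ids, ids)
    m
  }
  # differing columns can only be SNP columns; restricting is exact
  out <- list(core = base_mat(snp), cds = NULL, intergenic = NULL,
              coreLength = length(core@positions))
  if (length(core@partition)) {
    out$cds <- base_mat(snp[core@partition[snp] == "CDS"])
    out$intergenic <- base_mat(snp[core@partition[snp] == "intergenic"])
  }
  out
}

#' Recompute core and matrices for a sample subset
#'
#' Identical to a fresh [computeCore()] on the subset; no realignment is
#' performed, which is what makes stored allele tables a re-analysis
#' database. Core length is monotonically nonincreasing in subset size.
#'
#' @param table an [AlleleTable-class].
#' @param subset sample ids, size >= 2.
#' @param annotation optional annotation, as in [computeCore()].
#' @return list(core, matrices).
#' @export
subsetRecompute <- function(table, subset, annotation = NULL) {
  core <- computeCore(table, subset, annotation)
  list(core = core, matrices = pairwiseMatrices(core))
}

#' Add one sample to an existing allele table
#'
#' Extends the table by the new sample's track; existing tracks are
#' untouched, so recomputing the core afterwards equals a from-scratch run
#' including the new sample.
#'
#' @param table an [AlleleTable-class].
#' @param x a [PairwiseResult-class] or [CallTrack-class] aligned/mapped
#'   against the same reference.
#' @return the extended table.
#' @export
addSample <- function(table, x) {
  id <- sampleIds(x)
  if (id %in% names(table@tracks)) stop("sample id collision: ", id)
  if (!identical(unname(contigLengths(x)), unname(table@contigs)))
    stop("reference layout mismatch for sample ", id)
  tr <- if (is(x, "PairwiseResult")) x@track else x@track
  if (any(table@mask)) {
    r <- charToRaw(tr)
    r[table@mask] <- charToRaw(GAP_CHAR)[1L]
    tr <- rawToChar(r)
  }
  out <- table
  out@tracks <- c(table@tracks, setNames(tr, id))
  out@sampleData <- rbind(table@sampleData,
    S4Vectors::DataFrame(sample = id,
      type = if (is(x, "PairwiseResult")) "assembly" else "reads"))
  validObject(out)
  out
}

# ------------------------------------------------------------ persistence

#' Persist and reload an allele table
#'
#' Plain-text layout: `table.tsv` (sample, type plus header lines for the
#' contig layout, reference id and mask) and one run-length-encoded track
#' file per sample under `tracks/`. Subset re-analysis and incremental
#' placement read this store; no realignment is needed.
#'
#' @param table an [AlleleTable-class].
#' @param dir directory to write into (created if needed).
#' @return invisibly, `dir`.
#' @export
writeAlleleTable <- function(table, dir) {
  dir.create(file.path(dir, "tracks"), recursive = TRUE, showWarnings = FALSE)
  hdr <- c(paste0("#reference\t", table@reference),
           paste0("#contig\t", names(table@contigs), "\t", table@contigs),
           paste0("#mask\t", .rle_encode(rawToChar(as.raw(
             ifelse(table@mask, utf8ToInt("M"), utf8ToInt("U")))))),
           "sample\ttype")
  body <- paste(table@sampleData$sample, table@sampleData$type, sep = "\t")
  writeLines(c(hdr, body), file.path(dir, "table.tsv"))
  for (s in names(table@tracks))
    writeLines(.rle_encode(table@tracks[[s]]),
               file.path(dir, "tracks", paste0(s, ".rle")))
  invisible(dir)
}

#' @rdname writeAlleleTable
#' @export
readAlleleTable <- function(dir) {
  lines <- readLines(file.path(dir, "table.tsv"))
  refline <- strsplit(lines[startsWith(lines, "#reference")], "\t")[[1L]]
  ctg <- do.call(rbind, strsplit(lines[startsWith(lines, "#contig")], "\t"))
  contigs <- setNames(as.integer(ctg[, 3L]), ctg[, 2L])
  maskline <- strsplit(lines[startsWith(lines, "#mask")], "\t")[[1L]]
  mask <- charToRaw(.rle_decode(maskline[2L])) == charToRaw("M")[1L]
  body <- lines[!startsWith(lines, "#")][-1L]
  sd <- do.call(rbind, strsplit(body, "\t"))
  tracks <- vapply(sd[, 1L], function(s)
    .rle_decode(paste(readLines(file.path(dir, "tracks", paste0(s, ".rle"))),
                      collapse = "")), "")
  new("AlleleTable", reference = refline[2L], contigs = contigs,
      tracks = tracks,
      sampleData = S4Vectors::DataFrame(sample = sd[, 1L], type = sd[, 2L]),
      mask = mask)
}

.rle_encode <- function(s) {
  r <- rle(strsplit(s, "", fixed = TRUE)[[1L]])
  paste0(r$lengths, r$values, collapse = "")
}

.rle_decode <- function(s) {
  parts <- regmatches(s, gregexpr("[0-9]+[^0-9]", s))[[1L]]
  n <- as.integer(sub(".$", "", parts))
  ch <- substring(parts, nchar(parts), nchar(parts))
  paste(strrep(ch, n), collapse = "")
}

# ------------------------------------------------------------- exporters

#' Write core alignment products
#'
#' Emits `<prefix>_core.fasta` (full core alignment), `<prefix>_coreSNP.fasta`
#' (SNP columns only), the pairwise matrices (`<prefix>_coreMatrix.txt`,
#' and with annotation `<prefix>_CDSMatrix.txt` /
#' `<prefix>_intergenicMatrix.txt`), `<prefix>_snp_positions.tsv` and a
#' minimal multi-sample VCF `<prefix>_core.vcf`.
#'
#' @param core a [CoreAlignment-class].
#' @param matrices list from [pairwiseMatrices()].
#' @param prefix output path prefix.
#' @param refSample sample id providing VCF REF alleles (default first).
#' @return invisibly, the written paths.
#' @export
writeCoreOutputs <- function(core, matrices, prefix,
                             refSample = core@samples[1L]) {
  paths <- character(0)
  p <- paste0(prefix, "_core.fasta")
  writeFasta(core@bases, p); paths <- c(paths, p)
  snp_seqs <- vapply(core@samples, function(s)
    .chars_to_string(strsplit(core@bases[[s]], "", fixed = TRUE)[[1L]][core@snpCols]),
    "", USE.NAMES = TRUE)
  p <- paste0(prefix, "_coreSNP.fasta")
  writeFasta(snp_seqs, p); paths <- c(paths, p)
  wm <- function(m, path) {
    write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
    path
  }
  paths <- c(paths, wm(matrices$core, paste0(prefix, "_coreMatrix.txt")))
  if (!is.null(matrices$cds)) {
    paths <- c(paths, wm(matrices$cds, paste0(prefix, "_CDSMatrix.txt")))
    paths <- c(paths, wm(matrices$intergenic, paste0(prefix, "_intergenicMatrix.txt")))
  }
  loc <- .global_to_contig(core@positions[core@snpCols], core@contigs)
  snp_tab <- cbind(loc, as.data.frame(
    do.call(cbind, lapply(core@samples, function(s)
      strsplit(core@bases[[s]], "", fixed = TRUE)[[1L]][core@snpCols]))))
  names(snp_tab) <- c("contig", "pos", core@samples)
  p <- paste0(prefix, "_snp_positions.tsv")
  write.table(snp_tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  # minimal multi-sample VCF over SNP columns
  p <- paste0(prefix, "_core.vcf")
  refb <- strsplit(core@bases[[refSample]], "", fixed = TRUE)[[1L]][core@snpCols]
  others <- setdiff(core@samples, refSample)
  gtmat <- do.call(cbind, lapply(core@samples, function(s)
    strsplit(core@bases[[s]], "", fixed = TRUE)[[1L]][core@snpCols]))
  rows <- vapply(seq_along(core@snpCols), function(i) {
    alts <- setdiff(unique(gtmat[i, ]), refb[i])
    alleles <- c(refb[i], alts)
    gt <- match(gtmat[i, ], alleles) - 1L
    paste(loc$contig[i], loc$pos[i], ".", refb[i],
          paste(alts, collapse = ","), ".", "PASS", ".", "GT",
          paste(gt, collapse = "\t"), sep = "\t")
  }, "")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", core@samples), collapse = "\t"),
               rows), p)
  paths <- c(paths, p)
  invisible(paths)
}
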