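#' Build gene models from parsed annotation features
#'
#' CDS features are grouped into genes by their ID (falling back to
#' Parent, then locus_tag), ordered 5'->3' on the coding strand, and
#' checked for frame consistency: the total CDS length after phase
#' adjustment must be divisible by 3.
#'
#' @param features data.frame from [parseGff3()].
#' @return list of gene models: id, contig, strand, segments
#'   (data.frame start/end, 1-based inclusive), phase of the first coding
#'   segment.
#' @export
geneModels <- function(features) {
  cds <- features[features$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) return(list())
  gid <- ifelse(!is.na(cds$Parent), cds$Parent,
                ifelse(!is.na(cds$ID), cds$ID, cds$locus_tag))
  if (anyNA(gid)) stop("CDS feature without ID/Parent/locus_tag")
  out <- lapply(split(seq_len(nrow(cds)), gid), function(ix) {
    g <- cds[ix, , drop = FALSE]
    if (length(unique(g$seqid)) != 1L || length(unique(g$strand)) != 1L)
      stop("gene segments must share contig and strand")
    minus <- g$strand[1L] == "-"
    g <- g[order(g$start, decreasing = minus), , drop = FALSE]
    phase <- g$phase[1L]
    total <- sum(g$end - g$start + 1L) - phase
    if (total %% 3L != 0L)
      stop("CDS length not divisible by 3 after phase for gene ", gid[ix][1L])
    list(id = gid[ix][1L], contig = g$seqid[1L], strand = g$strand[1L],
         segments = data.frame(start = g$start, end = g$end), phase = phase)
  })
  out[order(names(out))]
}

# genomic positions (global 1-based) of a gene's codons, in coding order
.coding_positions <- function(gene, contigLengths) {
  if (!gene$contig %in% names(contigLengths))
    stop("gene ", gene$id, " is on unknown contig ", gene$contig)
  segs <- gene$segments
  pos <- unlist(lapply(seq_len(nrow(segs)), function(i) {
    p <- segs$start[i]:segs$end[i]
    if (gene$strand == "-") rev(p) else p
  }), use.names = FALSE)
  if (gene$phase > 0L) pos <- pos[-seq_len(gene$phase)]
  .contig_to_global(rep(gene$contig, length(pos)), pos, contigLengths)
}

.comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]

#' Classify SNPs by annotation and codon effect
#'
#' Each SNP is labeled CDS (with codon context computed on the coding
#' strand, reverse-complementing for minus-strand genes) or intergenic. A
#' SNP inside two overlapping genes yields one row per gene; the effect
#' may differ between frames. The alternative codon differs from the
#' reference codon at exactly the SNP's in-codon position.
#'
#' @param snps data.frame with contig, pos (1-based), ref_base, alt_base
#'   and optionally sample.
#' @param genes gene models from [geneModels()].
#' @param ref reference sequences.
#' @param codeTable NCBI genetic code table (default 11).
#' @return data.frame with one row per SNP x overlapping gene (or one
#'   intergenic row): region, gene, codon_index, codon_pos, ref_codon,
#'   alt_codon, effect.
#' @export
classifySnps <- function(snps, genes, ref, codeTable = 11L) {
  contigs <- .as_contig_chars(ref)
  lens <- setNames(nchar(contigs), names(contigs))
  refglob <- paste(contigs, collapse = "")
  code <- .genetic_code(codeTable)
  if (nrow(snps) && any(!snps$contig %in% names(lens)))
    stop("SNP position outside all contigs")
  gpos <- if (nrow(snps)) .contig_to_global(snps$contig, snps$pos, lens) else integer(0)
  # per-gene coding position lookup
  gmaps <- lapply(genes, .coding_positions, contigLengths = lens)
  rows <- list()
  for (i in seq_len(nrow(snps))) {
    hit <- FALSE
    for (k in seq_along(genes)) {
      ci <- match(gpos[i], gmaps[[k]])
      if (is.na(ci)) next
      hit <- TRUE
      gene <- genes[[k]]
      codon_index <- (ci - 1L) %/% 3L + 1L
      codon_pos <- (ci - 1L) %% 3L + 1L
      cpos <- gmaps[[k]][(codon_index - 1L) * 3L + 1:3]
      ref_codon <- paste(vapply(cpos, function(p) {
        b <- substr(refglob, p, p)
        if (gene$strand == "-") unname(.comp_base(b)) else b
      }, ""), collapse = "")
      alt <- if (gene$strand == "-") unname(.comp_base(snps$alt_base[i]))
             else snps$alt_base[i]
      alt_codon <- ref_codon
      substr(alt_codon, codon_pos, codon_pos) <- alt
      aa_ref <- .translate_codon(ref_codon, code)
      aa_alt <- .translate_codon(alt_codon, code)
      eff <- if (is.na(aa_ref) || is.na(aa_alt)) NA_character_
             else if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
      rows[[length(rows) + 1L]] <- data.frame(
        contig = snps$contig[i], pos = snps$pos[i],
        ref_base = snps$ref_base[i], alt_base = snps$alt_base[i],
        sample = if ("sample" %in% names(snps)) snps$sample[i] else NA_character_,
        region = "CDS", gene = gene$id, codon_index = codon_index,
        codon_pos = codon_pos, ref_codon = ref_codon,
        alt_codon = alt_codon, effect = eff, stringsAsFactors = FALSE)
    }
    if (!hit)
      rows[[length(rows) + 1L]] <- data.frame(
        contig = snps$contig[i], pos = snps$pos[i],
        ref_base = snps$ref_base[i], alt_base = snps$alt_base[i],
        sample = if ("sample" %in% names(snps)) snps$sample[i] else NA_character_,
        region = "intergenic", gene = NA_character_,
        codon_index = NA_integer_, codon_pos = NA_integer_,
        ref_codon = NA_character_, alt_codon = NA_character_,
        effect = NA_character_, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(contig = character(0), pos = integer(0),
                      ref_base = character(0), alt_base = character(0),
                      sample = character(0), region = character(0),
                      gene = character(0), codon_index = integer(0),
                      codon_pos = integer(0), ref_codon = character(0),
                      alt_codon = character(0), effect = character(0)))
  do.call(rbind, rows)
}

#' Reconstruct per-sample coding sequences for one gene
#'
#' A gene is eligible iff every sample has an unambiguous base across all
#' its CDS positions ("0 gapped regions") and at least one SNP falls
#' inside it; ineligible genes are rejected with the reason. Sequences
#' are positionally extracted from the allele table, so gap-free genes
#' are already aligned.
#'
#' @param table an [AlleleTable-class].
#' @param gene one gene model from [geneModels()].
#' @param samples sample ids (default all).
#' @return list(status = "ok"|"gapped"|"invariant", seqs = named
#'   character of equal-length in-frame coding-strand sequences when ok).
#' @export
reconstructGeneSequences <- function(table, gene, samples = NULL) {
  if (is.null(samples)) samples <- names(table@tracks)
  pos <- .coding_positions(gene, table@contigs)
  if (any(pos < 1L) || any(pos > sum(table@contigs)))
    stop("gene outside reference bounds: ", gene$id)
  seqs <- vapply(samples, function(s) {
    ch <- strsplit(table@tracks[[s]], "", fixed = TRUE)[[1L]][pos]
    paste(ch, collapse = "")
  }, "", USE.NAMES = TRUE)
  raws <- lapply(seqs, charToRaw)
  ok <- vapply(raws, function(r) all(.is_base_raw(r)), TRUE)
  if (!all(ok)) return(list(status = "gapped", seqs = NULL))
  poly <- FALSE
  for (i in seq_along(raws)[-1L])
    if (any(raws[[i]] != raws[[1L]])) { poly <- TRUE; break }
  if (!poly) return(list(status = "invariant", seqs = NULL))
  if (gene$strand == "-") {
    seqs <- vapply(seqs, function(s) {
      chartr("ACGT", "TGCA", s)   # positions already in coding order
    }, "", USE.NAMES = TRUE)
  }
  list(status = "ok", seqs = seqs)
}

# fraction of the 3 single-base changes at each codon position that are
# synonymous; mutation to a stop counts as nonsynonymous
.codon_syn_sites <- function(codon, code) {
  aa <- .translate_codon(codon, code)
  if (is.na(aa)) stop("untranslatable codon: ", codon)
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(BASES, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      if (identical(.translate_codon(mut, code), aa)) s <- s + 1 / 3
    }
  }
  s
}

# average synonymous/nonsynonymous differences between two codons over all
# minimal mutational pathways, equal path weighting
.codon_diffs <- function(ca, cb, code) {
  dpos <- which(strsplit(ca, "")[[1L]] != strsplit(cb, "")[[1L]])
  nd <- length(dpos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- if (nd == 1L) list(dpos)
           else if (nd == 2L) list(dpos, rev(dpos))
           else list(dpos[c(1, 2, 3)], dpos[c(1, 3, 2)], dpos[c(2, 1, 3)],
                     dpos[c(2, 3, 1)], dpos[c(3, 1, 2)], dpos[c(3, 2, 1)])
  sd_tot <- 0; nd_tot <- 0
  for (path in perms) {
    cur <- ca
    for (p in path) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (identical(.translate_codon(cur, code), .translate_codon(nxt, code)))
        sd_tot <- sd_tot + 1
      else nd_tot <- nd_tot + 1
      cur <- nxt
    }
  }
  c(sd = sd_tot / length(perms), nd = nd_tot / length(perms))
}

# memoized per-code-table tables: synonymous site counts per codon and
# pairwise pathway-averaged differences
.ng86_cache <- new.env(parent = emptyenv())

.ng86_tables <- function(codeTable) {
  key <- as.character(codeTable)
  if (!is.null(.ng86_cache[[key]])) return(.ng86_cache[[key]])
  code <- .genetic_code(codeTable)
  codons <- apply(expand.grid(BASES, BASES, BASES)[, 3:1], 1L, paste,
                  collapse = "")
  syn <- vapply(codons, .codon_syn_sites, 0, code = code)
  tab <- list(code = code, syn = syn, diffs = new.env(parent = emptyenv()))
  .ng86_cache[[key]] <- tab
  tab
}

.jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)   # saturated; undefined under JC
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori (1986) pairwise dN/dS with Jukes-Cantor correction
#'
#' Synonymous and nonsynonymous site counts are computed per codon by
#' enumerating all nine single-base mutations with fractional weighting
#' (averaged over the two sequences); differences per codon are averaged
#' over all minimal mutational pathways with equal weighting. Proportions
#' are Jukes-Cantor corrected, d = -(3/4) ln(1 - 4p/3); a proportion at or
#' above 3/4 is reported as NA (saturated). The test statistic is the
#' normal approximation of pN - pS with binomial variances, two-sided.
#'
#' @param a,b equal-length, in-frame coding sequences (character
#'   scalars); internal stop codons are an error.
#' @param codeTable NCBI genetic code table (default 11).
#' @return list: nCodons, S, N (site counts), Sd, Nd (differences), pS,
#'   pN, dS, dN, z, p.
#' @export
ng86Pair <- function(a, b, codeTable = 11L) {
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  if (nchar(a) %% 3L != 0L) stop("sequence length must be a multiple of 3")
  tabs <- .ng86_tables(codeTable)
  code <- tabs$code
  nc <- nchar(a) %/% 3L
  ca <- substring(a, 3L * seq_len(nc) - 2L, 3L * seq_len(nc))
  cb <- substring(b, 3L * seq_len(nc) - 2L, 3L * seq_len(nc))
  aa_a <- unname(code[ca]); aa_b <- unname(code[cb])
  if (anyNA(aa_a) || anyNA(aa_b)) stop("untranslatable codon")
  if (any(aa_a[-nc] == "*") || any(aa_b[-nc] == "*"))
    stop("internal stop codon")
  S <- (sum(tabs$syn[ca]) + sum(tabs$syn[cb])) / 2
  N <- 3 * nc - S
  pair_diffs <- function(x, y) {
    if (x == y) return(c(sd = 0, nd = 0))
    key <- paste0(x, y)
    hit <- tabs$diffs[[key]]
    if (!is.null(hit)) return(hit)
    v <- .codon_diffs(x, y, code)
    tabs$diffs[[key]] <- v
    v
  }
  diffs <- vapply(seq_len(nc), function(i) pair_diffs(ca[i], cb[i]),
                  c(sd = 0, nd = 0))
  Sd <- sum(diffs["sd", ]); Nd <- sum(diffs["nd", ])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  dS <- .jc_correct(pS); dN <- .jc_correct(pN)
  varS <- if (!is.na(pS) && S > 0) pS * (1 - pS) / S else NA_real_
  varN <- if (!is.na(pN) && N > 0) pN * (1 - pN) / N else NA_real_
  v <- varS + varN
  z <- if (is.na(v) || v <= 0) 0 else (pN - pS) / sqrt(v)
  list(nCodons = nc, S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       dS = dS, dN = dN, z = z, p = 2 * pnorm(-abs(z)))
}

#' Screen genes for selection with the counting dN/dS test
#'
#' For every eligible gene (unambiguous in all samples, at least one SNP),
#' pairwise dN and dS are averaged over all sample pairs and omega is the
#' ratio of the means; the gene-level test uses mean proportions and mean
#' site counts. p-values are Benjamini-Hochberg corrected across genes.
#' Classification: positive (omega > 1, q <= alpha), purifying (omega < 1,
#' q <= alpha), neutral (q > alpha), undetermined (dS undefined or zero).
#'
#' @param table an [AlleleTable-class].
#' @param genes gene models from [geneModels()].
#' @param codeTable NCBI genetic code table (default 11).
#' @param alpha significance level after FDR correction (default 0.05).
#' @param samples sample ids (default all).
#' @return data.frame: gene, status, n_codons, dN, dS, omega, z, p, q,
#'   class (rejected genes keep their rejection reason in status).
#' @export
screenGenes <- function(table, genes, codeTable = 11L, alpha = 0.05,
                        samples = NULL) {
  if (is.null(samples)) samples <- names(table@tracks)
  rows <- lapply(genes, function(gene) {
    rec <- reconstructGeneSequences(table, gene, samples)
    if (rec$status != "ok")
      return(data.frame(gene = gene$id, status = rec$status,
                        n_codons = NA_integer_, dN = NA_real_, dS = NA_real_,
                        omega = NA_real_, z = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    prs <- utils::combn(samples, 2L, simplify = FALSE)
    res <- tryCatch(
      lapply(prs, function(pr)
        ng86Pair(rec$seqs[[pr[1L]]], rec$seqs[[pr[2L]]], codeTable)),
      error = function(e) NULL)
    if (is.null(res))   # e.g. a substitution created an internal stop
      return(data.frame(gene = gene$id, status = "stop_codon",
                        n_codons = NA_integer_, dN = NA_real_, dS = NA_real_,
                        omega = NA_real_, z = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    mean_ <- function(f) mean(vapply(res, function(r) r[[f]] %||% NA_real_, 0))
    dN <- mean(vapply(res, function(r) r$dN, 0), na.rm = FALSE)
    dS <- mean(vapply(res, function(r) r$dS, 0), na.rm = FALSE)
    pN <- mean_("pN"); pS <- mean_("pS")
    S <- mean_("S"); N <- mean_("N")
    v <- pS * (1 - pS) / S + pN * (1 - pN) / N
    z <- if (is.na(v) || v <= 0) 0 else (pN - pS) / sqrt(v)
    data.frame(gene = gene$id, status = "ok",
               n_codons = res[[1L]]$nCodons, dN = dN, dS = dS,
               omega = if (!is.na(dS) && dS > 0) dN / dS else NA_real_,
               z = z, p = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out) || nrow(out) == 0L)
    return(data.frame(gene = character(0), status = character(0),
                      n_codons = integer(0), dN = numeric(0), dS = numeric(0),
                      omega = numeric(0), z = numeric(0), p = numeric(0),
                      q = numeric(0), class = character(0)))
  out$q <- NA_real_
  ok <- out$status == "ok"
  out$q[ok] <- p.adjust(out$p[ok], method = "BH")
  out$class <- "undetermined"
  sig <- ok & !is.na(out$omega) & !is.na(out$q)
  out$class[sig & out$omega > 1 & out$q <= alpha] <- "positive"
  out$class[sig & out$omega < 1 & out$q <= alpha] <- "purifying"
  out$class[sig & out$q > alpha] <- "neutral"
  out$class[!ok] <- "undetermined"
  out
}

#' Export per-gene alignments for external selection software
#'
#' Writes one FASTA per eligible gene under `dir/genes/`, for use with
#' external branch-site or codon-model programs.
#'
#' @param table an [AlleleTable-class].
#' @param genes gene models.
#' @param dir output directory.
#' @return invisibly, paths written.
#' @export
exportGeneAlignments <- function(table, genes, dir) {
  gd <- file.path(dir, "genes")
  dir.create(gd, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (gene in genes) {
    rec <- reconstructGeneSequences(table, gene)
    if (rec$status != "ok") next
    p <- file.path(gd, paste0(gene$id, ".fasta"))
    writeFasta(rec$seqs, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
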