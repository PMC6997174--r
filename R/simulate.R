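#' Simulation configuration
#'
#' Ground-truth generator settings. The defaults describe a small bacterial
#' clade: a 100 kb single-contig genome at 50% GC, five taxa on a random
#' topology with 0.5% expected substitutions per site on every branch, no
#' indels and no planted repeats.
#'
#' @param nTaxa number of leaves.
#' @param tree explicit Newick string, or NULL for a random topology with
#'   all branch lengths set to `branchLength`.
#' @param genomeLength root genome length (bases).
#' @param gc GC content of the root genome.
#' @param branchLength expected substitutions/site per branch when no tree
#'   is given.
#' @param indelRate expected indels per site per branch-equivalent,
#'   applied on each leaf (0 disables).
#' @param indelMeanLen geometric mean indel length.
#' @param repeatSpec list(count, length, copies) of repeats planted into
#'   the root genome, or NULL.
#' @param cdsFraction fraction of the genome tiled by synthetic
#'   non-overlapping frame-0 CDS genes (alternating strands).
#' @param geneLength length of each synthetic gene (multiple of 3).
#' @param seed RNG seed.
#' @return named list.
#' @export
simConfig <- function(nTaxa = 5L, tree = NULL, genomeLength = 100000L,
                      gc = 0.5, branchLength = 0.005, indelRate = 0,
                      indelMeanLen = 5, repeatSpec = NULL,
                      cdsFraction = 0.6, geneLength = 900L, seed = 42L) {
  stopifnot(branchLength >= 0, indelRate >= 0, gc > 0, gc < 1,
            geneLength %% 3L == 0L)
  list(nTaxa = as.integer(nTaxa), tree = tree,
       genomeLength = as.integer(genomeLength), gc = gc,
       branchLength = branchLength, indelRate = indelRate,
       indelMeanLen = indelMeanLen, repeatSpec = repeatSpec,
       cdsFraction = cdsFraction, geneLength = as.integer(geneLength),
       seed = as.integer(seed))
}

.random_genome <- function(L, gc) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(BASES, L, replace = TRUE, prob = probs), collapse = "")
}

# apply nmut substitutions (Poisson process: uniform positions, uniform
# different base); returns mutated string
.mutate <- function(seq, expected) {
  L <- nchar(seq)
  nmut <- rpois(1L, expected * L)
  if (nmut == 0L) return(seq)
  pos <- sample.int(L, nmut, replace = TRUE)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in pos) ch[p] <- sample(setdiff(BASES, ch[p]), 1L)
  paste(ch, collapse = "")
}

#' Simulate a clade of genomes with planted ground truth
#'
#' The root genome is drawn i.i.d. at the requested GC content (with
#' optional planted repeats), then evolved along each branch of the tree
#' under strict Jukes-Cantor substitutions: a Poisson number of events per
#' branch, uniform positions, uniform alternative base. Optional indels
#' are applied to each leaf after evolution, in root coordinates, so the
#' truth stays in a single frame; deletions remove their substitutions
#' from the truth. A synthetic GFF3 of non-overlapping frame-0 CDS genes
#' tiling `cdsFraction` of the root is generated. Everything is
#' reproducible from the seed.
#'
#' @param config list from [simConfig()].
#' @return list: tree (`phylo`, leaf labels s1..sn), root (character
#'   genome), genomes (named character of leaf genomes), truth (list with
#'   per-sample substitutions vs the root computed from the final
#'   sequences, deletions, insertions, repeat intervals), annotation
#'   (data.frame in [parseGff3()] layout, on the root/reference
#'   coordinates, seqid "chr1").
#' @export
simulateClade <- function(config = simConfig()) {
  set.seed(config$seed)
  n <- config$nTaxa
  tree <- if (!is.null(config$tree)) ape::read.tree(text = config$tree)
          else {
            t0 <- ape::rtree(n)
            t0$tip.label <- paste0("s", seq_len(n))
            t0$edge.length <- rep(config$branchLength, nrow(t0$edge))
            t0
          }
  if (length(tree$tip.label) != n)
    stop("tree has ", length(tree$tip.label), " leaves but nTaxa = ", n)
  L <- config$genomeLength
  root <- .random_genome(L, config$gc)
  annotation <- .synthetic_annotation(L, config$cdsFraction, config$geneLength)
  # gene regions carry open reading frames (ATG ... TAA, no internal
  # stops) so the selection screen is exercised on translatable genes
  if (nrow(annotation)) {
    stops <- c("TAA", "TAG", "TGA")
    codons <- apply(expand.grid(BASES, BASES, BASES), 1L, paste, collapse = "")
    sense <- setdiff(codons, stops)
    for (i in seq_len(nrow(annotation))) {
      ncod <- (annotation$end[i] - annotation$start[i] + 1L) %/% 3L
      orf <- paste(c("ATG", sample(sense, ncod - 2L, replace = TRUE), "TAA"),
                   collapse = "")
      if (annotation$strand[i] == "-") orf <- .revcomp(orf)
      substr(root, annotation$start[i], annotation$end[i]) <- orf
    }
  }
  if (!is.null(config$repeatSpec)) {
    rs <- config$repeatSpec
    reps <- list()
    for (i in seq_len(rs$count)) {
      src <- sample.int(L - rs$length, 1L)
      seg <- substr(root, src, src + rs$length - 1L)
      ivs <- data.frame(start = src, end = src + rs$length - 1L)
      for (cp in seq_len(rs$copies - 1L)) {
        dst <- sample.int(L - rs$length, 1L)
        substr(root, dst, dst + rs$length - 1L) <- seg
        ivs <- rbind(ivs, data.frame(start = dst, end = dst + rs$length - 1L))
      }
      reps[[i]] <- ivs
    }
    repeat_truth <- do.call(rbind, reps)
  } else repeat_truth <- data.frame(start = integer(0), end = integer(0))
  # evolve along edges from the root (preorder)
  nt <- length(tree$tip.label)
  seqs <- vector("list", nt + tree$Nnode)
  rooted <- if (ape::is.rooted(tree)) tree else ape::root(tree, 1L, resolve.root = TRUE)
  rootnode <- nt + 1L
  seqs[[rootnode]] <- root
  for (e in seq_len(nrow(rooted$edge))) { # cladewise: parents precede children
    p <- rooted$edge[e, 1L]; ch <- rooted$edge[e, 2L]
    bl <- if (is.null(rooted$edge.length)) config$branchLength
          else rooted$edge.length[e]
    seqs[[ch]] <- .mutate(seqs[[p]], bl)
  }
  genomes <- setNames(vapply(seq_len(nt), function(i) seqs[[i]], ""),
                      rooted$tip.label)
  deletions <- insertions <- list()
  if (config$indelRate > 0) {
    for (s in names(genomes)) {
      L0 <- nchar(genomes[[s]])
      nind <- rpois(1L, config$indelRate * L0)
      dels <- data.frame(start = integer(0), end = integer(0))
      ins <- data.frame(pos = integer(0), seq = character(0))
      for (i in seq_len(nind)) {
        len <- 1L + rgeom(1L, 1 / config$indelMeanLen)
        if (runif(1L) < 0.5) {
          st <- sample.int(L0 - len, 1L)
          dels <- rbind(dels, data.frame(start = st, end = st + len - 1L))
        } else {
          at <- sample.int(L0, 1L)
          ins <- rbind(ins, data.frame(pos = at,
            seq = .random_genome(len, config$gc), stringsAsFactors = FALSE))
        }
      }
      deletions[[s]] <- dels; insertions[[s]] <- ins
      genomes[[s]] <- .apply_indels(genomes[[s]], dels, ins)
    }
  }
  # truth substitutions computed from the final sequences (multiple hits
  # and reversions along the tree collapse to net differences)
  subs <- lapply(names(genomes), function(s) {
    if (config$indelRate > 0) return(NULL)  # root frame broken by indels
    a <- charToRaw(root); b <- charToRaw(genomes[[s]])
    ix <- which(a != b)
    if (length(ix) == 0L) return(NULL)
    data.frame(sample = s, pos = ix,
               ref_base = rawToChar(a[ix], multiple = TRUE),
               alt_base = rawToChar(b[ix], multiple = TRUE),
               stringsAsFactors = FALSE)
  })
  subs <- if (config$indelRate > 0) NULL else do.call(rbind, subs)
  if (is.null(subs) && config$indelRate == 0)
    subs <- data.frame(sample = character(0), pos = integer(0),
                       ref_base = character(0), alt_base = character(0))
  list(tree = if (nt >= 3L) ape::unroot(rooted) else rooted,
       root = setNames(root, "chr1"),
       genomes = genomes,
       truth = list(subs = subs, deletions = deletions,
                    insertions = insertions, repeats = repeat_truth),
       annotation = annotation)
}

.apply_indels <- function(seq, dels, ins) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  keep <- rep(TRUE, length(ch))
  for (i in seq_len(nrow(dels))) keep[dels$start[i]:dels$end[i]] <- FALSE
  add <- rep("", length(ch))
  for (i in seq_len(nrow(ins))) add[ins$pos[i]] <- ins$seq[i]
  paste(paste0(ifelse(keep, ch, ""), add), collapse = "")
}

# non-overlapping frame-0 CDS genes on alternating strands
.synthetic_annotation <- function(L, cdsFraction, geneLength) {
  spacing <- as.integer(geneLength / max(cdsFraction, 1e-6))
  starts <- seq(101L, L - geneLength - 100L, by = max(spacing, geneLength + 50L))
  if (length(starts) == 0L)
    return(data.frame(seqid = character(0), type = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), phase = integer(0),
                      ID = character(0), Parent = character(0),
                      locus_tag = character(0)))
  data.frame(seqid = "chr1", type = "CDS",
             start = starts, end = starts + geneLength - 1L,
             strand = rep(c("+", "-"), length.out = length(starts)),
             phase = 0L,
             ID = sprintf("gene%03d", seq_along(starts)),
             Parent = NA_character_, locus_tag = NA_character_,
             stringsAsFactors = FALSE)
}

#' Write a simulation's annotation as GFF3
#'
#' @param annotation data.frame from [simulateClade()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeGff3 <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(annotation)) {
    writeLines(paste(annotation$seqid, "corephylo_sim", annotation$type,
                     annotation$start, annotation$end, ".",
                     annotation$strand, annotation$phase,
                     paste0("ID=", annotation$ID), sep = "\t"), con)
  }
  invisible(path)
}

#' Fragment a genome into shuffled draft contigs
#'
#' The genome is cut at uniform positions; `dropFraction` of the fragments
#' (by count) are removed and the rest are shuffled and renamed.
#'
#' @param genome character scalar (or named length-1 vector).
#' @param nBreaks number of cut points.
#' @param dropFraction fraction of fragments to drop, in [0, 1).
#' @param seed RNG seed.
#' @return named character vector of contigs.
#' @export
fragmentContigs <- function(genome, nBreaks = 5L, dropFraction = 0,
                            seed = 42L) {
  set.seed(seed)
  g <- unname(.as_contig_chars(genome)[1L])
  L <- nchar(g)
  stopifnot(nBreaks < L, dropFraction >= 0, dropFraction < 1)
  cuts <- sort(sample.int(L - 1L, nBreaks))
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, L)
  frags <- substring(g, starts, ends)
  ndrop <- floor(dropFraction * length(frags))
  keep <- seq_along(frags)
  if (ndrop > 0L) keep <- sort(sample(keep, length(frags) - ndrop))
  frags <- frags[keep]
  ord <- sample(seq_along(frags))
  setNames(frags[ord], sprintf("contig%03d", seq_along(frags)))
}

#' Simulate shotgun reads from a genome
#'
#' Read count is ceiling(coverage * L / readLength); start positions are
#' uniform, strands equiprobable, and per-base errors substitute a uniform
#' different base at the given rate. Qualities are a constant Q30
#' placeholder. Paired mode emits opposing-orientation mates from
#' fragments with the given insert geometry.
#'
#' @param genome character scalar genome.
#' @param readLength read length (bases).
#' @param coverage mean fold coverage.
#' @param errorRate per-base substitution error rate.
#' @param paired logical; emit mate pairs.
#' @param insertMean,insertSd fragment length model for paired mode.
#' @param seed RNG seed.
#' @param prefix read id prefix.
#' @return list(reads = [parseFastq()]-style records, origin = data.frame
#'   (id, start, strand, mate)).
#' @export
simulateReads <- function(genome, readLength = 100L, coverage = 20,
                          errorRate = 0, paired = FALSE,
                          insertMean = 300L, insertSd = 30L, seed = 42L,
                          prefix = "r") {
  set.seed(seed)
  g <- unname(.as_contig_chars(genome)[1L])
  L <- nchar(g)
  stopifnot(readLength <= L)
  nreads <- as.integer(ceiling(coverage * L / readLength))
  grc <- .revcomp(g)
  mk <- function(n, ids, mate) {
    starts <- sample.int(L - readLength + 1L, n, replace = TRUE)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    seqs <- ifelse(strands == "+",
                   substring(g, starts, starts + readLength - 1L),
                   substring(grc, L - (starts + readLength - 1L) + 1L,
                             L - starts + 1L))
    nerr <- rbinom(n, readLength, errorRate)
    for (i in which(nerr > 0L)) {
      ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
      at <- sample.int(readLength, nerr[i])
      for (p in at) ch[p] <- sample(setdiff(BASES, ch[p]), 1L)
      seqs[i] <- paste(ch, collapse = "")
    }
    list(reads = lapply(seq_len(n), function(i)
           list(id = ids[i], residues = seqs[i],
                qualities = rep(30L, readLength), mate = mate)),
         origin = data.frame(id = ids, start = starts, strand = strands,
                             mate = mate, stringsAsFactors = FALSE))
  }
  if (!paired) {
    ids <- sprintf("%s%06d", prefix, seq_len(nreads))
    out <- mk(nreads, ids, 1L)
    return(list(reads = out$reads, origin = out$origin))
  }
  npairs <- as.integer(ceiling(nreads / 2))
  fstart <- sample.int(max(1L, L - insertMean - 3L * insertSd), npairs, replace = TRUE)
  flen <- pmax(2L * readLength,
               as.integer(round(insertMean + insertSd * rnorm(npairs))))
  flen <- pmin(flen, L - fstart + 1L)
  ids <- sprintf("%s%06d", prefix, seq_len(npairs))
  r1seq <- substring(g, fstart, fstart + readLength - 1L)
  r2pos <- fstart + flen - readLength
  r2seq <- vapply(substring(g, r2pos, r2pos + readLength - 1L), .revcomp, "",
                  USE.NAMES = FALSE)
  err <- function(seqs) {
    nerr <- rbinom(length(seqs), readLength, errorRate)
    for (i in which(nerr > 0L)) {
      ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
      for (p in sample.int(readLength, nerr[i]))
        ch[p] <- sample(setdiff(BASES, ch[p]), 1L)
      seqs[i] <- paste(ch, collapse = "")
    }
    seqs
  }
  r1seq <- err(r1seq); r2seq <- err(r2seq)
  reads <- c(lapply(seq_len(npairs), function(i)
               list(id = ids[i], residues = r1seq[i],
                    qualities = rep(30L, readLength), mate = 1L)),
             lapply(seq_len(npairs), function(i)
               list(id = ids[i], residues = r2seq[i],
                    qualities = rep(30L, readLength), mate = 2L)))
  origin <- rbind(data.frame(id = ids, start = fstart, strand = "+", mate = 1L),
                  data.frame(id = ids, start = r2pos, strand = "-", mate = 2L))
  list(reads = reads, origin = origin)
}

#' Mix target reads with background-genome reads into a metagenome
#'
#' Source read counts follow a multinomial draw at the given proportions;
#' the output is interleaved in shuffled order with per-read source labels
#' retained.
#'
#' @param targetReads read records (the strain of interest).
#' @param backgroundGenomes named character vector of background genomes.
#' @param proportions numeric vector (target first, then one per
#'   background genome); must sum to 1.
#' @param totalReads total reads to emit.
#' @param readLength read length for background reads.
#' @param errorRate per-base error rate for background reads.
#' @param seed RNG seed.
#' @return list(reads, labels = character source per read).
#' @export
mixMetagenome <- function(targetReads, backgroundGenomes, proportions,
                          totalReads, readLength = 100L, errorRate = 0,
                          seed = 42L) {
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("proportions must sum to 1")
  if (length(proportions) != length(backgroundGenomes) + 1L)
    stop("need one proportion for the target plus one per background genome")
  set.seed(seed)
  if (totalReads == 0L) return(list(reads = list(), labels = character(0)))
  counts <- as.vector(rmultinom(1L, totalReads, proportions))
  pool <- list(); labels <- character(0)
  ntarget <- min(counts[1L], length(targetReads))
  if (ntarget > 0L) {
    pool <- targetReads[sample.int(length(targetReads), ntarget)]
    labels <- rep("target", ntarget)
  }
  for (i in seq_along(backgroundGenomes)) {
    ni <- counts[i + 1L]
    if (ni == 0L) next
    sim <- simulateReads(backgroundGenomes[[i]],
                         readLength = readLength,
                         coverage = ni * readLength / nchar(backgroundGenomes[[i]]),
                         errorRate = errorRate,
                         seed = sample.int(2^30, 1L),
                         prefix = paste0("bg", i, "_"))
    take <- sim$reads[seq_len(min(ni, length(sim$reads)))]
    pool <- c(pool, take)
    labels <- c(labels, rep(names(backgroundGenomes)[i] %||% paste0("bg", i),
                            length(take)))
  }
  ord <- sample(seq_along(pool))
  list(reads = pool[ord], labels = labels[ord])
}

#' Polymorphic positions implied by the planted truth
#'
#' The positions (root frame) where at least two of the given samples
#' disagree, computed purely from the truth substitution table. With the
#' root itself included this is the planted SNP-column set.
#'
#' @param truth truth list from [simulateClade()].
#' @param samples sample names (leaf labels), optionally including
#'   "root".
#' @return sorted integer positions.
#' @export
trueSnpPositions <- function(truth, samples) {
  sub <- truth$subs[truth$subs$sample %in% samples, , drop = FALSE]
  if (nrow(sub) == 0L) return(integer(0))
  non_root <- setdiff(samples, "root")
  spl <- split(seq_len(nrow(sub)), sub$pos)
  poly <- vapply(spl, function(ix) {
    carriers <- sub$sample[ix]
    others <- setdiff(non_root, carriers)
    states <- c(sub$alt_base[ix],
                if (length(others) > 0L || "root" %in% samples)
                  sub$ref_base[ix][1L])
    length(unique(states)) >= 2L
  }, TRUE)
  sort(as.integer(names(spl))[poly])
}
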