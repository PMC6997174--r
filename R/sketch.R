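#' Build a MinHash bottom-s sketch of a genome
#'
#' Canonical k-mers (the lexicographic minimum of a k-mer and its reverse
#' complement, compared in 2-bit encoding) are hashed with a fixed 64-bit
#' mixer and the s smallest distinct values are retained. K-mers containing
#' non-ACGT bases are skipped.
#'
#' @param genome sequences: a DNAStringSet, named character vector, or
#'   record list from [parseFasta()].
#' @param k k-mer length (default 21).
#' @param s sketch size (default 1000).
#' @param sample sample identifier stored in the sketch.
#' @return a [MinHashSketch-class].
#' @examples
#' buildSketch(c(chr = "ACGTACGTACGTACGTACGTACGTACGT"), k = 5, s = 10)
#' @export
buildSketch <- function(genome, k = 21L, s = 1000L, sample = "genome") {
  contigs <- .as_contig_chars(genome)
  total <- sum(nchar(contigs))
  if (total < k) stop("genome shorter than k (", total, " < ", k, ")")
  hashes <- .cpp_minhash(unname(contigs), as.integer(k), as.integer(s))
  new("MinHashSketch", sample = sample, k = as.integer(k),
      sketchSize = as.integer(s), hashes = hashes,
      genomeLength = as.integer(total))
}

#' Mash distance between two sketches
#'
#' The Jaccard index is estimated from the bottom-s sketch of the union of
#' hash sets; the distance is the Mash transform
#' \eqn{-\frac{1}{k}\ln\frac{2j}{1+j}}. A Jaccard of zero saturates to a
#' distance of 1.0 rather than infinity.
#'
#' @param a,b [MinHashSketch-class] objects with equal k and sketch size.
#' @return list with elements jaccard and distance.
#' @export
mashDistance <- function(a, b) {
  stopifnot(is(a, "MinHashSketch"), is(b, "MinHashSketch"))
  if (a@k != b@k) stop("sketch k mismatch: ", a@k, " vs ", b@k)
  if (a@sketchSize != b@sketchSize)
    stop("sketch size mismatch: ", a@sketchSize, " vs ", b@sketchSize)
  s <- a@sketchSize
  u <- sort(unique(c(a@hashes, b@hashes)))
  u <- u[seq_len(min(s, length(u)))]
  shared <- sum(u %in% a@hashes & u %in% b@hashes)
  j <- if (length(u)) shared / length(u) else 0
  d <- if (j <= 0) 1.0 else -log(2 * j / (1 + j)) / a@k
  list(jaccard = j, distance = d)
}

#' Pairwise Mash distance matrix over sketches
#'
#' @param sketches named list of [MinHashSketch-class] objects.
#' @return symmetric numeric matrix of distances.
#' @export
sketchDistanceMatrix <- function(sketches) {
  ids <- vapply(sketches, function(s) s@sample, "")
  n <- length(sketches)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      d <- mashDistance(sketches[[i]], sketches[[j]])$distance
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Select the reference genome
#'
#' In minhash mode, the complete genome minimizing the total Mash distance
#' to all other samples is chosen (ties broken by lexicographically
#' smallest sample id); contigs and read sets contribute to the distance
#' sums but are never eligible. Random mode draws uniformly among complete
#' genomes with the run seed; user mode returns the requested id.
#'
#' @param sketches named list of [MinHashSketch-class] objects (names are
#'   sample ids).
#' @param types named character vector of sample data types
#'   (complete/contig/reads), aligned with sketches.
#' @param mode one of minhash, random, user_specified.
#' @param userId required sample id for user_specified mode.
#' @param seed run seed for random mode.
#' @return the selected sample id (character scalar).
#' @export
selectReference <- function(sketches, types, mode = c("minhash", "random", "user_specified"),
                            userId = NULL, seed = 42L) {
  mode <- match.arg(mode)
  ids <- names(sketches)
  if (is.null(ids)) ids <- vapply(sketches, function(s) s@sample, "")
  names(sketches) <- ids
  if (mode == "user_specified") {
    if (is.null(userId) || !userId %in% ids)
      stop("requested reference '", userId, "' is not among the samples")
    return(userId)
  }
  complete <- ids[types[ids] == "complete"]
  if (mode == "random") {
    if (length(complete) == 0L) stop("no complete genome available as reference")
    set.seed(seed)
    return(sample(sort(complete), 1L))
  }
  if (length(complete) < 2L && length(ids) < 2L)
    stop("minhash mode needs at least 2 samples")
  if (length(complete) == 0L)
    stop("minhash mode needs at least one complete genome")
  D <- sketchDistanceMatrix(sketches)
  totals <- rowSums(D)[complete]
  cand <- sort(complete[totals == min(totals)])
  cand[1L]
}

#' Write and read sketch TSV files
#'
#' One row per sketch: sample, k, s, genome_length, comma-joined hex hash
#' values.
#'
#' @param sketches named list of sketches.
#' @param path output path.
#' @return invisibly, the path (writer) or the sketch list (reader).
#' @export
writeSketches <- function(sketches, path) {
  num2hex <- function(v) {
    hi <- floor(v / 16^7)
    lo <- v - hi * 16^7
    paste0(sprintf("%x", as.integer(hi)), sprintf("%07x", as.integer(lo)))
  }
  rows <- vapply(sketches, function(s)
    paste(s@sample, s@k, s@sketchSize, s@genomeLength,
          paste(num2hex(s@hashes), collapse = ","), sep = "\t"), "")
  writeLines(c("sample\tk\ts\tgenome_length\thashes", rows), path)
  invisible(path)
}

#' @rdname writeSketches
#' @export
readSketches <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  hex2num <- function(h) {
    n <- nchar(h)
    if (n <= 7L) return(as.numeric(strtoi(h, 16L)))
    as.numeric(strtoi(substr(h, 1L, n - 7L), 16L)) * 16^7 +
      as.numeric(strtoi(substring(h, n - 6L), 16L))
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    hx <- strsplit(tab$hashes[i], ",", fixed = TRUE)[[1L]]
    new("MinHashSketch", sample = tab$sample[i], k = as.integer(tab$k[i]),
        sketchSize = as.integer(tab$s[i]),
        hashes = vapply(hx, hex2num, 0, USE.NAMES = FALSE),
        genomeLength = as.integer(tab$genome_length[i]))
  })
  names(out) <- tab$sample
  out
}
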