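#' Read a FASTA file of genome or contig sequences
#'
#' Wraps Biostrings FASTA input with the validation contracts this pipeline
#' relies on: records must be non-empty, residues are folded to uppercase,
#' and any character outside the IUPAC nucleotide alphabet is rejected with
#' its position. Record order is preserved.
#'
#' @param path path to a FASTA file.
#' @return list of records, each a list with elements id (first
#'   whitespace-delimited header token), description (remaining header
#'   text) and residues (uppercase string).
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">s1 demo", "acgt", "ACGT"), tf)
#' parseFasta(tf)[[1]]$residues
#' @export
parseFasta <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1L]) stop("not FASTA: first line must start with '>'")
  idx <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  recs <- vector("list", length(headers))
  allowed <- strsplit("ACGTNRYSWKMBDHV", "")[[1]]
  for (i in seq_along(headers)) {
    body <- lines[idx == i & !hdr]
    seq <- toupper(paste(body, collapse = ""))
    if (grepl("[[:space:]]", seq)) stop("whitespace inside sequence of record ", i)
    if (!nzchar(seq)) stop("record with empty sequence: ", headers[i])
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% allowed)
    if (length(bad))
      stop("non-IUPAC character '", chars[bad[1L]], "' at position ",
           bad[1L], " of record ", sub("\\s.*$", "", headers[i]))
    id <- sub("\\s.*$", "", headers[i])
    if (!nzchar(id)) stop("empty record id at record ", i)
    desc <- sub("^\\S+\\s*", "", headers[i])
    recs[[i]] <- list(id = id, description = desc, residues = seq)
  }
  recs
}

#' Write sequence records to FASTA
#'
#' @param records list of records as returned by [parseFasta()], or a named
#'   character vector of sequences.
#' @param path output path.
#' @param width line wrap width.
#' @return invisibly, the path.
#' @export
writeFasta <- function(records, path, width = 70L) {
  if (is.character(records)) {
    records <- Map(function(id, s) list(id = id, description = "", residues = s),
                   names(records), unname(records))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    hdr <- if (nzchar(r$description)) paste(r$id, r$description) else r$id
    writeLines(paste0(">", hdr), con)
    s <- r$residues
    if (nchar(s) > 0L) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    }
  }
  invisible(path)
}

#' Read FASTQ reads (single or paired, Phred+33)
#'
#' Paired inputs are flattened into one list with a mate tag; mates are
#' mapped independently downstream, so no interleaving is required.
#'
#' @param path path to a FASTQ file.
#' @param matePath optional path to the mate file of a pair.
#' @return list of reads, each a list with id, residues, qualities
#'   (integer Phred scores) and mate (1 or 2).
#' @export
parseFastq <- function(path, matePath = NULL) {
  one <- function(p, mate) {
    lines <- readLines(p)
    if (length(lines) %% 4L != 0L)
      stop("truncated FASTQ record in ", p, " (", length(lines), " lines)")
    n <- length(lines) %/% 4L
    out <- vector("list", n)
    for (i in seq_len(n)) {
      b <- 4L * (i - 1L)
      if (!startsWith(lines[b + 1L], "@")) stop("malformed FASTQ header at record ", i)
      res <- toupper(lines[b + 2L])
      qual <- lines[b + 4L]
      if (nchar(res) != nchar(qual))
        stop("length mismatch at record ", i, ": ", nchar(res), " bases vs ",
             nchar(qual), " quality characters")
      out[[i]] <- list(id = sub("^@", "", sub("\\s.*$", "", lines[b + 1L])),
                       residues = res,
                       qualities = utf8ToInt(qual) - 33L,
                       mate = mate)
    }
    out
  }
  reads <- one(path, 1L)
  if (!is.null(matePath)) reads <- c(reads, one(matePath, 2L))
  reads
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads list of reads as returned by [parseFastq()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeFastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in reads) {
    writeLines(c(paste0("@", r$id), r$residues, "+",
                 intToUtf8(r$qualities + 33L)), con)
  }
  invisible(path)
}

#' Read coordinate features from a GFF3 file
#'
#' Uses rtracklayer for the heavy lifting, then flattens to the feature
#' records the annotation layer consumes. Only coordinate-bearing lines are
#' returned; any trailing FASTA section is ignored by the importer.
#'
#' @param path path to a GFF3 file.
#' @return data.frame with columns seqid, type, start, end, strand, phase
#'   (NA unless CDS), and attribute columns ID, Parent, locus_tag (NA when
#'   absent).
#' @export
parseGff3 <- function(path) {
  lines <- readLines(path)
  fasta_at <- which(lines == "##FASTA")
  if (length(fasta_at)) lines <- lines[seq_len(fasta_at[1L] - 1L)]
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0L)
    return(data.frame(seqid = character(0), type = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), phase = integer(0),
                      ID = character(0), Parent = character(0),
                      locus_tag = character(0), stringsAsFactors = FALSE))
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(fields) < 9L)) stop("GFF3 line with fewer than 9 fields")
  st <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  en <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
  if (anyNA(st) || anyNA(en)) stop("non-integer coordinates in GFF3")
  if (any(st > en)) stop("GFF3 feature with start > end")
  if (any(st < 1L)) stop("GFF3 feature with start < 1")
  gr <- rtracklayer::import(path, format = "gff3")
  attr_get <- function(col) {
    if (col %in% names(mcols(gr))) as.character(mcols(gr)[[col]])
    else rep(NA_character_, length(gr))
  }
  ph <- if ("phase" %in% names(mcols(gr))) as.integer(mcols(gr)$phase)
        else rep(NA_integer_, length(gr))
  out <- data.frame(
    seqid = as.character(seqnames(gr)),
    type = as.character(mcols(gr)$type),
    start = start(gr), end = end(gr),
    strand = as.character(strand(gr)),
    phase = ph,
    ID = attr_get("ID"),
    Parent = vapply(as.list(mcols(gr)$Parent %||% rep(list(character(0)), length(gr))),
                    function(p) if (length(p)) p[[1L]] else NA_character_, ""),
    locus_tag = attr_get("locus_tag"),
    stringsAsFactors = FALSE)
  out$phase[out$type != "CDS"] <- NA_integer_
  if (any(out$type == "CDS" & is.na(out$phase)))
    stop("CDS feature without phase")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a plain-text control file into a RunConfig
#'
#' The dialect is `key = value` lines with `#` comments. Unknown keys warn
#' and are ignored; unspecified keys take the documented defaults
#' (cutoff 0, min_depth 5, min_allele_fraction 0.6, bootstrap 100, genetic
#' code 11, seed 42). Sample inputs are declared with repeatable keys
#' `genome`, `contig` and `reads`, each `name:path` (reads may carry a
#' comma-separated mate pair).
#'
#' @param path path to the control file.
#' @return a [RunConfig-class] object.
#' @export
parseControlFile <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- lapply(lines, function(l) {
    if (!grepl("=", l, fixed = TRUE)) stop("malformed control line: ", l)
    parts <- strsplit(l, "=", fixed = TRUE)[[1L]]
    c(trimws(parts[1L]), trimws(paste(parts[-1L], collapse = "=")))
  })
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, `[[`, "", 2L)
  known <- c("reference", "reference_id", "aligned_fraction_cutoff",
             "min_depth", "min_allele_fraction", "tree", "bootstrap",
             "seed", "genetic_code", "analysis_scope", "selection_screen",
             "output_dir", "genome", "contig", "reads", "gff")
  unknown <- setdiff(unique(keys), known)
  if (length(unknown))
    warning("unknown control keys ignored: ", paste(unknown, collapse = ", "))
  get1 <- function(k, default) {
    v <- vals[keys == k]
    if (length(v) == 0L) default else v[[length(v)]]
  }
  ref <- get1("reference", "minhash")
  mode <- if (ref %in% c("minhash", "random")) ref else "user_specified"
  refid <- if (mode == "user_specified") ref else get1("reference_id", "")
  num <- function(k, default, lo, hi, what) {
    v <- suppressWarnings(as.numeric(get1(k, default)))
    if (is.na(v) || v < lo || v > hi)
      stop("control key ", k, " out of range: must be ", what)
    v
  }
  samp <- list()
  for (typ in c("genome", "contig", "reads")) {
    for (v in vals[keys == typ]) {
      parts <- strsplit(v, ":", fixed = TRUE)[[1L]]
      if (length(parts) < 2L) stop("sample declaration must be name:path -- ", v)
      paths <- strsplit(parts[2L], ",", fixed = TRUE)[[1L]]
      samp[[length(samp) + 1L]] <- data.frame(
        sample = parts[1L],
        type = c(genome = "complete", contig = "contig", reads = "reads")[[typ]],
        path1 = trimws(paths[1L]),
        path2 = if (length(paths) > 1L) trimws(paths[2L]) else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  samples <- if (length(samp)) S4Vectors::DataFrame(do.call(rbind, samp))
             else S4Vectors::DataFrame(sample = character(0), type = character(0),
                                       path1 = character(0), path2 = character(0))
  maf <- num("min_allele_fraction", 0.6, 0, 1, "in (0.5, 1]")
  if (maf <= 0.5)
    stop("min_allele_fraction must exceed 0.5 so at most one allele qualifies")
  new("RunConfig",
      referenceMode = mode, referenceId = refid,
      alignedFractionCutoff = num("aligned_fraction_cutoff", 0.0, 0, 1, "in [0,1]"),
      minDepth = as.integer(num("min_depth", 5, 1, 1e9, ">= 1")),
      minAlleleFraction = maf,
      treeMethod = match.arg(get1("tree", "nj"), c("nj", "external")),
      bootstrapReps = as.integer(num("bootstrap", 100, 0, 1e9, ">= 0")),
      seed = as.integer(num("seed", 42, -2^31 + 1, 2^31 - 1, "an integer")),
      geneticCodeTable = as.integer(num("genetic_code", 11, 1, 33, "a code table")),
      analysisScope = match.arg(get1("analysis_scope", "all"), c("all", "cds_only")),
      selectionScreen = tolower(get1("selection_screen", "off")) %in% c("on", "true", "1"),
      outputDir = get1("output_dir", "corephylo_out"),
      samples = samples,
      gff = get1("gff", ""))
}

#' Default run configuration
#'
#' @param ... slot values overriding the documented defaults.
#' @return a [RunConfig-class].
#' @export
defaultConfig <- function(...) {
  cfg <- new("RunConfig",
      referenceMode = "minhash", referenceId = "",
      alignedFractionCutoff = 0.0, minDepth = 5L, minAlleleFraction = 0.6,
      treeMethod = "nj", bootstrapReps = 100L, seed = 42L,
      geneticCodeTable = 11L, analysisScope = "all",
      selectionScreen = FALSE, outputDir = "corephylo_out",
      samples = S4Vectors::DataFrame(sample = character(0), type = character(0),
                                     path1 = character(0), path2 = character(0)),
      gff = "")
  args <- list(...)
  for (nm in names(args)) slot(cfg, nm) <- args[[nm]]
  validObject(cfg)
  cfg
}
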