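# Internal coordinate and sequence helpers. Reference coordinates are
# handled in a single "global" 1-based frame over the concatenation of the
# reference contigs in layout order; all user-facing reports convert back
# to (contig, 1-based position).

BASES <- c("A", "C", "G", "T")
GAP_CHAR <- "-"
AMBIG_CHAR <- "N"

# named character vector of contig sequences from flexible input
.as_contig_chars <- function(x) {
  if (is(x, "DNAStringSet")) {
    out <- toupper(as.character(x))
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(toupper(x))
  }
  if (is.list(x) && all(vapply(x, function(r) is.list(r) && !is.null(r$residues), TRUE))) {
    out <- vapply(x, function(r) r$residues, "")
    names(out) <- vapply(x, function(r) r$id, "")
    return(toupper(out))
  }
  stop("cannot interpret input as contig sequences")
}

.contig_offsets <- function(lengths) {
  # 0-based global offset of each contig's first position
  c(0L, cumsum(as.integer(lengths)))[seq_along(lengths)]
}

# global 1-based positions -> data.frame(contig, pos 1-based)
.global_to_contig <- function(pos, contig_lengths) {
  offs <- .contig_offsets(contig_lengths)
  idx <- findInterval(pos - 1L, c(offs, sum(contig_lengths)))
  data.frame(contig = names(contig_lengths)[idx],
             pos = as.integer(pos - offs[idx]),
             stringsAsFactors = FALSE)
}

.contig_to_global <- function(contig, pos, contig_lengths) {
  offs <- .contig_offsets(contig_lengths)
  names(offs) <- names(contig_lengths)
  as.integer(offs[contig] + pos)
}

.revcomp <- function(s) .cpp_revcomp(s)

# vector of single characters -> one string and back
.chars_to_string <- function(v) paste(v, collapse = "")
.string_to_raw <- function(s) charToRaw(s)

.is_base_raw <- function(r) {
  r == charToRaw("A") | r == charToRaw("C") | r == charToRaw("G") | r == charToRaw("T")
}

# half-up rounding to one decimal, as used in run reports
.round1 <- function(x) floor(x * 10 + 0.5) / 10

.genetic_code <- function(table = 11L) {
  Biostrings::getGeneticCode(as.character(table))
}

.translate_codon <- function(codon, code) unname(code[codon])

# deterministic child seed derived from a run seed and a stage label
.derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) * 1009L + as.integer(h %% 99991L)) %% 2147483647L
}
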