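simple_gene <- function(start, end, strand = "+", id = "g1", contig = "chr") {
  list(id = id, contig = contig, strand = strand,
       segments = data.frame(start = start, end = end), phase = 0L)
}

test_that("SNPs are split into intergenic and CDS with codon context", {
  ref <- c(chr = "TTTATGAAACCCTGATTTTTT")     # CDS 4..15: ATG AAA CCC TGA
  genes <- list(simple_gene(4L, 15L))
  snps <- data.frame(contig = "chr", pos = c(2L, 9L, 10L),
                     ref_base = c("T", "A", "C"),
                     alt_base = c("G", "G", "A"))
  ann <- classifySnps(snps, genes, ref)
  expect_equal(ann$region, c("intergenic", "CDS", "CDS"))
  expect_equal(ann$codon_index[2], 2L)        # position 9 -> codon 2, slot 3
  expect_equal(ann$codon_pos[2], 3L)
  expect_equal(ann$ref_codon[2], "AAA")
  expect_equal(ann$alt_codon[2], "AAG")
  expect_equal(ann$effect[2], "synonymous")   # AAA and AAG are both Lys
  expect_equal(ann$codon_pos[3], 1L)
  expect_equal(ann$effect[3], "nonsynonymous")
})

test_that("minus-strand codon context matches the revcomp oracle", {
  set.seed(41)
  for (rep in 1:20) {
    orf <- paste(c("ATG",
                   sample(setdiff(apply(expand.grid(c("A","C","G","T"),
                                                    c("A","C","G","T"),
                                                    c("A","C","G","T")),
                                        1, paste, collapse = ""),
                                  c("TAA","TAG","TGA")), 8, replace = TRUE),
                   "TAA"), collapse = "")
    flank5 <- random_seq(7); flank3 <- random_seq(7)
    genome_plus <- paste0(flank5, orf, flank3)
    genome_minus <- revcomp_chr(genome_plus)
    L <- nchar(genome_plus)
    p_plus <- sample(8:(7 + nchar(orf)), 1)       # inside the gene
    base_plus <- substr(genome_plus, p_plus, p_plus)
    alt_plus <- sample(setdiff(c("A", "C", "G", "T"), base_plus), 1)
    gp <- list(simple_gene(8L, 7L + nchar(orf), "+"))
    gm <- list(simple_gene(L - (7L + nchar(orf)) + 1L, L - 7L, "-"))
    ap <- classifySnps(data.frame(contig = "chr", pos = p_plus,
                                  ref_base = base_plus, alt_base = alt_plus),
                       gp, c(chr = genome_plus))
    p_minus <- L - p_plus + 1L
    am <- classifySnps(data.frame(contig = "chr", pos = p_minus,
                                  ref_base = chartr("ACGT", "TGCA", base_plus),
                                  alt_base = chartr("ACGT", "TGCA", alt_plus)),
                       gm, c(chr = genome_minus))
    expect_equal(am$ref_codon, ap$ref_codon)
    expect_equal(am$alt_codon, ap$alt_codon)
    expect_equal(am$effect, ap$effect)
    expect_equal(am$codon_index, ap$codon_index)
  }
})

test_that("codon effects match translate-and-compare on random mutations", {
  code <- Biostrings::getGeneticCode("11")
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  n_checked <- 0
  while (n_checked < 1000) {
    codon <- paste(sample(bases, 3, replace = TRUE), collapse = "")
    slot <- sample(3, 1)
    alt <- sample(setdiff(bases, substr(codon, slot, slot)), 1)
    genome <- paste0("TT", codon, "TT")
    genes <- list(simple_gene(3L, 5L))
    pos <- 2L + slot
    ann <- classifySnps(data.frame(contig = "chr", pos = pos,
                                   ref_base = substr(codon, slot, slot),
                                   alt_base = alt),
                        genes, c(chr = genome))
    mut <- codon; substr(mut, slot, slot) <- alt
    expected <- if (code[[codon]] == code[[mut]]) "synonymous" else "nonsynonymous"
    expect_identical(ann$effect, expected)
    n_checked <- n_checked + 1
  }
})

test_that("per-codon site counts sum to 3 in code tables 11 and 1", {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  for (tab in c(11L, 1L)) {
    tabs <- corephylo:::.ng86_tables(tab)
    syn <- tabs$syn[codons]
    expect_true(all(syn >= 0 & syn <= 3))
    # nonsynonymous sites are 3 - syn by construction; verify against the
    # oracle's independent per-codon counter
    code <- Biostrings::getGeneticCode(as.character(tab))
    for (codon in sample(codons, 16)) {
      o <- oracle_ng86(codon, codon, code)
      expect_equal(unname(syn[codon]), o$S, tolerance = 1e-12)
      expect_equal(3 - unname(syn[codon]), o$N, tolerance = 1e-12)
    }
  }
})

test_that("NG86 matches the exhaustive pathway oracle", {
  code <- Biostrings::getGeneticCode("11")
  a <- "ATGAAACCCGGGTTTCAT"       # 6 codons
  b <- "ATGAAGCCATGGTTACAT"
  got <- ng86Pair(a, b)
  expected <- oracle_ng86(a, b, code)
  expect_equal(got$S, expected$S, tolerance = 1e-10)
  expect_equal(got$N, expected$N, tolerance = 1e-10)
  expect_equal(got$Sd, expected$Sd, tolerance = 1e-10)
  expect_equal(got$Nd, expected$Nd, tolerance = 1e-10)
  expect_equal(got$dS, expected$dS, tolerance = 1e-10)
  expect_equal(got$dN, expected$dN, tolerance = 1e-10)

  set.seed(43)
  sense <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                     c("A","C","G","T")), 1, paste,
                         collapse = ""), c("TAA", "TAG", "TGA"))
  for (rep in 1:5) {
    x <- paste(sample(sense, 5, replace = TRUE), collapse = "")
    y <- paste(sample(sense, 5, replace = TRUE), collapse = "")
    g <- ng86Pair(x, y); o <- oracle_ng86(x, y, code)
    expect_equal(g$Sd, o$Sd, tolerance = 1e-10)
    expect_equal(g$Nd, o$Nd, tolerance = 1e-10)
  }
})

test_that("NG86 handles trivial and degenerate pairs", {
  same <- ng86Pair("ATGAAA", "ATGAAA")
  expect_equal(same$dN, 0)
  expect_equal(same$dS, 0)
  phe <- ng86Pair("TTT", "TTC")               # both Phe
  expect_equal(phe$Sd, 1)                     # one synonymous difference
  expect_equal(phe$Nd, 0)
  expect_equal(phe$dN, 0)
  expect_gt(phe$pS, 0)
  # a single codon with pS = Sd/S = 3 is past the JC saturation point
  expect_true(is.na(phe$dS))
  expect_error(ng86Pair("ATG", "ATGAAA"), "equal length")
  expect_error(ng86Pair("TAAATG", "TAAATG"), "internal stop")
  # symmetry
  ab <- ng86Pair("ATGAAACCC", "ATGAAGCCA")
  ba <- ng86Pair("ATGAAGCCA", "ATGAAACCC")
  expect_equal(ab$dN, ba$dN)
  expect_equal(ab$dS, ba$dS)
})

test_that("gene reconstruction enforces gap-free and polymorphic rules", {
  tracks <- c(r = "TTATGAAACCCTAATT",
              a = "TTATGAAGCCCTAATT",
              b = "TTATGAAACCCTAATT")
  tab <- new("AlleleTable", reference = "r", contigs = c(chr = 16L),
             tracks = tracks,
             sampleData = S4Vectors::DataFrame(
               sample = names(tracks), type = rep("complete", 3)),
             mask = rep(FALSE, 16L))
  gene <- simple_gene(3L, 14L)
  rec <- reconstructGeneSequences(tab, gene)
  expect_equal(rec$status, "ok")
  expect_equal(unname(rec$seqs["r"]), "ATGAAACCCTAA")
  expect_equal(unname(rec$seqs["a"]), "ATGAAGCCCTAA")

  gapped <- tracks; substr(gapped[["a"]], 7, 7) <- "-"
  tabg <- tab; tabg@tracks <- gapped
  expect_equal(reconstructGeneSequences(tabg, gene)$status, "gapped")

  inv <- tracks; inv[["a"]] <- inv[["r"]]
  tabi <- tab; tabi@tracks <- inv
  expect_equal(reconstructGeneSequences(tabi, gene)$status, "invariant")
})

test_that("the selection screen flags planted nonsynonymous excess only", {
  # build coding sequences directly: 60 codons
  set.seed(44)
  sense <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                     c("A","C","G","T")), 1, paste,
                         collapse = ""), c("TAA", "TAG", "TGA"))
  core60 <- c("ATG", sample(sense, 58, replace = TRUE), "TAA")
  mk_variant <- function(n_nonsyn, n_syn, seed) {
    set.seed(seed)
    v <- core60
    # synonymous: swap Leu codons CTT->CTC etc (third position of 4-fold)
    four_fold <- which(substr(v, 1, 2) %in% c("CT", "GT", "TC", "CC", "AC",
                                              "GC", "CG", "GG"))
    for (i in sample(four_fold, n_syn))
      substr(v[i], 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(v[i], 3, 3))[1]
    # nonsynonymous: first-position flips (almost always change the aa)
    cand <- setdiff(2:59, four_fold)
    n_done <- 0
    for (i in sample(cand)) {
      if (n_done >= n_nonsyn) break
      old <- v[i]
      alt <- old
      substr(alt, 1, 1) <- setdiff(c("A", "C", "G", "T"), substr(old, 1, 1))[1]
      code <- Biostrings::getGeneticCode("11")
      if (alt %in% c("TAA", "TAG", "TGA")) next
      if (code[[alt]] != code[[old]]) { v[i] <- alt; n_done <- n_done + 1 }
    }
    v
  }
  gene_region <- function(codons) paste(codons, collapse = "")
  flank <- random_seq(10, 45)
  mk_track <- function(codons) paste0(flank, gene_region(codons), flank)
  tracks_pos <- c(r = mk_track(core60),
                  a = mk_track(mk_variant(12, 2, 1)),
                  b = mk_track(mk_variant(12, 2, 2)))
  tracks_syn <- c(r = mk_track(core60),
                  a = mk_track(mk_variant(0, 6, 3)),
                  b = mk_track(mk_variant(0, 6, 4)))
  mk_tab <- function(tracks) new("AlleleTable", reference = "r",
    contigs = c(chr = nchar(tracks[[1]])), tracks = tracks,
    sampleData = S4Vectors::DataFrame(sample = names(tracks),
                                      type = rep("complete", 3)),
    mask = rep(FALSE, nchar(tracks[[1]])))
  genes <- list(simple_gene(11L, 10L + 180L))
  sel_pos <- screenGenes(mk_tab(tracks_pos), genes, alpha = 0.1)
  expect_equal(sel_pos$status, "ok")
  expect_gt(sel_pos$omega, 1)
  sel_syn <- screenGenes(mk_tab(tracks_syn), genes, alpha = 0.05)
  expect_false(any(sel_syn$class == "positive"))
  expect_true(is.na(sel_syn$dN) || sel_syn$dN == 0 || sel_syn$omega < 1)
  # zero eligible genes -> empty-ish result with rejection reasons
  inv_tracks <- c(r = mk_track(core60), a = mk_track(core60),
                  b = mk_track(core60))
  sel_inv <- screenGenes(mk_tab(inv_tracks), genes)
  expect_equal(sel_inv$status, "invariant")
})

test_that("simulated neutral clades are never called positively selected", {
  sim <- sim_small_clade(seed = 46, L = 20000, bl = 0.01)
  ref <- c(chr1 = unname(sim$genomes[["s1"]]))   # annotation seqid is chr1
  pws <- lapply(paste0("s", 2:5), function(s)
    alignPair(ref, c(chr1 = unname(sim$genomes[[s]])), sample = s))
  tab <- buildAlleleTable(ref, refId = "s1", pairwise = pws)
  # annotation is on root coordinates; s1 has no indels so they coincide
  sel <- screenGenes(tab, geneModels(sim$annotation))
  expect_false(any(sel$class == "positive"))
  ok <- sel[sel$status == "ok", ]
  expect_gt(nrow(ok), 0)
  expect_true(all(is.finite(ok$p)))
})
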