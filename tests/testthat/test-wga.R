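test_that("repeat masking finds exactly the duplicated intervals", {
  set.seed(21)
  g <- random_seq(1000)
  seg <- substr(g, 101, 160)                  # 60 bp duplicated
  substr(g, 701, 760) <- seg
  # distinct flanking bases pin the repeat boundaries exactly
  substr(g, 100, 100) <- "A"; substr(g, 700, 700) <- "C"
  substr(g, 161, 161) <- "A"; substr(g, 761, 761) <- "C"
  oracle <- oracle_repeat_mask(g, 50)
  expect_true(any(oracle))                    # oracle confirms the repeat
  mask <- maskRepeats(c(chr = g), minRepeatLen = 50)
  got <- maskToLogical(mask, c(chr = 1000L))
  expect_identical(got, oracle)
  expect_equal(sum(got), 120L)                # both 60 bp copies
  expect_equal(as.integer(IRanges::start(mask$chr)), c(101L, 701L))
  expect_equal(as.integer(IRanges::end(mask$chr)), c(160L, 760L))
})

test_that("repeat-free sequence gives an empty mask", {
  g <- random_seq(1000, 22)
  expect_identical(oracle_repeat_mask(g, 50), rep(FALSE, 1000L))
  mask <- maskRepeats(c(chr = g), minRepeatLen = 50)
  expect_length(mask$chr, 0L)
})

test_that("a sequence followed by its reverse complement is fully masked", {
  half <- random_seq(300, 23)
  g <- paste0(half, revcomp_chr(half))
  mask <- maskRepeats(c(chr = g), minRepeatLen = 50)
  expect_identical(maskToLogical(mask, c(chr = 600L)), rep(TRUE, 600L))
})

test_that("MUM finding matches spec examples", {
  g <- random_seq(100, 31)
  m <- findMums(g, g, 20, strands = "+")
  expect_equal(nrow(m), 1L)
  expect_equal(m$length, 100L)
  expect_equal(m$ref_start, 0L)

  g101 <- random_seq(101, 32)
  q <- g101
  substr(q, 51, 51) <- setdiff(c("A", "C", "G", "T"), substr(g101, 51, 51))[1]
  m <- findMums(g101, q, 20, strands = "+")
  expect_equal(nrow(m), 2L)
  expect_equal(sort(m$length), c(50L, 50L))

  m <- findMums(g, revcomp_chr(g), 20)
  expect_equal(m$strand, "-")
  expect_equal(m$length, 100L)
})

test_that("MUM finding agrees with exhaustive enumeration", {
  for (seed in c(41, 42, 43)) {
    ref <- random_seq(80, seed)
    qry <- ref
    set.seed(seed + 100)
    for (p in sample(80, 3)) substr(qry, p, p) <-
      sample(setdiff(c("A", "C", "G", "T"), substr(qry, p, p)), 1)
    expected <- oracle_mums(ref, qry, 8)
    got <- findMums(ref, qry, 8, strands = "+")
    expect_equal(got$ref_start, expected$ref_start)
    expect_equal(got$qry_start, expected$qry_start)
    expect_equal(got$length, expected$length)
  }
})

test_that("N breaks anchors and never matches", {
  g <- random_seq(60, 44)
  q <- g
  substr(q, 30, 30) <- "N"
  m <- findMums(g, q, 10, strands = "+")
  expect_true(all(m$qry_start + m$length <= 29 | m$qry_start >= 30))
})

test_that("chaining keeps the maximum-weight colinear subset", {
  anchors <- data.frame(ref_start = c(0L, 40L, 80L),
                        qry_start_rc = c(0L, 40L, 80L),
                        length = c(30L, 30L, 30L))
  ch <- chainAnchors(anchors)
  expect_equal(nrow(ch), 3L)
  expect_equal(attr(ch, "weight"), 90)

  crossed <- data.frame(ref_start = c(0L, 40L),
                        qry_start_rc = c(50L, 0L),
                        length = c(30L, 10L))
  ch <- chainAnchors(crossed)          # B crosses A's order -> chain = {A}
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$length, 30L)

  empty <- chainAnchors(anchors[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("gap fill merges anchors across small interludes", {
  ref <- paste0(strrep("A", 0), random_seq(30, 51), "C", random_seq(30, 52))
  qry <- ref
  substr(qry, 31, 31) <- "G"            # single substitution between anchors
  ch <- findMums(ref, qry, 10, strands = "+")
  chain <- chainAnchors(ch)
  blocks <- fillGaps(chain, ref, qry)
  expect_length(blocks, 1L)
  expect_equal(sum(strsplit(blocks[[1]]$ops, "")[[1]] == "X"), 1L)

  # 3 vs 0 inter-anchor segment: a deletion in the query
  left <- random_seq(30, 53); right <- random_seq(30, 54)
  ref2 <- paste0(left, "TTT", right)
  qry2 <- paste0(left, right)
  chain2 <- chainAnchors(findMums(ref2, qry2, 10, strands = "+"))
  blocks2 <- fillGaps(chain2, ref2, qry2)
  expect_length(blocks2, 1L)
  expect_equal(sum(strsplit(blocks2[[1]]$ops, "")[[1]] == "D"), 3L)

  # interludes above maxFill split the chain into separate blocks
  big <- alignParams(); big$maxFill <- 10L
  mid_r <- random_seq(200, 55); mid_q <- random_seq(200, 56)
  ref3 <- paste0(left, mid_r, right)
  qry3 <- paste0(left, mid_q, right)
  chain3 <- chainAnchors(findMums(ref3, qry3, 10, strands = "+"))
  blocks3 <- fillGaps(chain3, ref3, qry3, params = big)
  expect_gte(length(blocks3), 2L)
})

test_that("pairwise alignment recovers planted substitutions exactly", {
  set.seed(61)
  ref <- random_seq(20000)
  qry <- ref
  planted <- sort(sample(20000, 10))
  for (p in planted) substr(qry, p, p) <-
    sample(setdiff(c("A", "C", "G", "T"), substr(qry, p, p)), 1)
  pw <- alignPair(c(chr = ref), c(chr = qry), sample = "q")
  expect_equal(pw@snps$pos, planted)
  expect_equal(pw@alignedFraction, 1.0)
  expect_equal(nrow(pw@gaps), 0L)
})

test_that("a deletion in the query becomes a reference gap with no SNPs inside", {
  set.seed(62)
  ref <- random_seq(20000)
  # distinct boundary bases make the deletion placement unambiguous
  substr(ref, 10000, 10000) <- "A"; substr(ref, 10100, 10100) <- "C"
  substr(ref, 9999, 9999) <- "G"; substr(ref, 10099, 10099) <- "T"
  qry <- paste0(substr(ref, 1, 9999), substr(ref, 10100, 20000))
  pw <- alignPair(c(chr = ref), c(chr = qry), sample = "q")
  expect_equal(nrow(pw@snps), 0L)
  expect_equal(nrow(pw@gaps), 1L)
  expect_equal(pw@gaps$start, 10000L)
  expect_equal(pw@gaps$end, 10099L)
})

test_that("unrelated sequences yield aligned fraction ~ 0, not an error", {
  pw <- alignPair(c(chr = random_seq(5000, 63)),
                  c(chr = random_seq(5000, 64)), sample = "q")
  expect_lt(pw@alignedFraction, 0.05)
})

test_that("self-alignment of a repeat-free genome is the identity", {
  g <- random_seq(10000, 65)
  pw <- alignPair(c(chr = g), c(chr = g), sample = "self")
  expect_equal(nrow(pw@snps), 0L)
  expect_equal(pw@alignedFraction, 1.0)
})

test_that("SNP counts are symmetric between A vs B and B vs A", {
  sim <- sim_small_clade(seed = 66, L = 20000, n = 2, bl = 0.01)
  a <- c(chr = unname(sim$genomes[[1]])); b <- c(chr = unname(sim$genomes[[2]]))
  ab <- alignPair(a, b, sample = "b")
  ba <- alignPair(b, a, sample = "a")
  expect_equal(nrow(ab@snps), nrow(ba@snps))
})

test_that("every reference position has exactly one state per sample", {
  sim <- sim_small_clade(seed = 67, L = 5000, n = 2, bl = 0.01)
  pw <- alignPair(c(chr = unname(sim$genomes[[1]])),
                  c(chr = unname(sim$genomes[[2]])), sample = "q")
  states <- strsplit(pw@track, "")[[1]]
  expect_length(states, 5000L)
  expect_true(all(states %in% c("A", "C", "G", "T", "-", "N")))
})

test_that("minus-strand and multi-contig queries align correctly", {
  set.seed(68)
  ref <- random_seq(10000)
  qry <- ref
  planted <- sort(sample(10000, 5))
  for (p in planted) substr(qry, p, p) <-
    sample(setdiff(c("A", "C", "G", "T"), substr(qry, p, p)), 1)
  pw <- alignPair(c(chr = ref), c(chr = revcomp_chr(qry)), sample = "rc")
  expect_equal(pw@snps$pos, planted)
  expect_true(all(pw@blocks$strand == "-"))
  frags <- fragmentContigs(qry, nBreaks = 4, dropFraction = 0, seed = 3)
  pwc <- alignPair(c(chr = ref), frags, sample = "contigs")
  expect_equal(pwc@snps$pos, planted)
  expect_gt(pwc@alignedFraction, 0.99)
})

test_that("masked positions never produce SNPs", {
  set.seed(69)
  g <- random_seq(2000)
  substr(g, 1501, 1600) <- substr(g, 101, 200)   # plant a repeat
  q <- g
  substr(q, 150, 150) <- setdiff(c("A", "C", "G", "T"), substr(g, 150, 150))[1]
  substr(q, 1000, 1000) <- setdiff(c("A", "C", "G", "T"), substr(g, 1000, 1000))[1]
  mask <- maskRepeats(c(chr = g), 50)
  pw <- alignPair(c(chr = g), c(chr = q), sample = "q", mask = mask)
  expect_equal(pw@snps$pos, 1000L)     # the in-repeat SNP is suppressed
})
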