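# small allele table built directly from strings
toy_table <- function(tracks, ref = names(tracks)[1],
                      mask = rep(FALSE, nchar(tracks[[1]]))) {
  L <- nchar(tracks[[1]])
  new("AlleleTable", reference = ref, contigs = c(chr = L),
      tracks = tracks,
      sampleData = S4Vectors::DataFrame(
        sample = names(tracks),
        type = c("complete", rep("assembly", length(tracks) - 1L))),
      mask = mask)
}

test_that("allele tables fuse alignment tracks and apply the mask", {
  set.seed(31)
  g <- random_seq(3000)
  substr(g, 2001, 2100) <- substr(g, 501, 600)    # plant a repeat
  mask <- maskRepeats(c(chr = g), 50)
  pw <- alignPair(c(chr = g), c(chr = g), sample = "twin", mask = mask)
  tab <- buildAlleleTable(c(chr = g), refId = "ref", mask = mask,
                          pairwise = list(pw))
  maskv <- maskToLogical(mask, c(chr = 3000L))
  ref_tr <- strsplit(tab@tracks[["ref"]], "")[[1]]
  twin_tr <- strsplit(tab@tracks[["twin"]], "")[[1]]
  expect_identical(twin_tr[!maskv], strsplit(g, "")[[1]][!maskv])
  expect_true(all(ref_tr[maskv] == "-"))
  expect_true(all(twin_tr[maskv] == "-"))
  expect_error(
    buildAlleleTable(c(chr = g), refId = "twin", pairwise = list(pw)),
    "duplicate")
})

test_that("an unalignable sample contributes an all-GAP track", {
  g <- random_seq(3000, 33)
  pw <- alignPair(c(chr = g), c(chr = random_seq(3000, 34)), sample = "junk")
  tab <- buildAlleleTable(c(chr = g), refId = "ref", pairwise = list(pw))
  expect_gt(mean(strsplit(tab@tracks[["junk"]], "")[[1]] == "-"), 0.95)
})

test_that("aligned-fraction filtering applies the inclusion rule", {
  L <- 1000L
  tracks <- c(ref = strrep("A", L),
              good = paste0(strrep("A", 995), strrep("-", 5)),
              poor = paste0(strrep("A", 100), strrep("-", 900)))
  tab <- toy_table(tracks)
  expect_identical(sampleIds(filterSamples(tab, 0)), names(tracks))
  f <- suppressMessages(filterSamples(tab, 0.15))
  expect_identical(attr(f, "dropped"), "poor")   # the 15% rule
  f99 <- suppressMessages(filterSamples(tab, 0.99))
  expect_true("good" %in% sampleIds(f99))        # 99.5% vs the 99% rule
  expect_error(suppressMessages(filterSamples(tab, 0.999)), "no analysis")
})

test_that("core columns are the all-sample unambiguous intersection", {
  tracks <- c(r = "ACGTACGTAC", a = "ACGTACGTAC", b = "ACGTACGTAC")
  core <- computeCore(toy_table(tracks))
  expect_equal(length(core@positions), 10L)
  expect_length(core@snpCols, 0L)

  tracks2 <- c(r = "ACGTACGTAC", a = "ACG-ACGTAC", b = "ACGTACNTAC")
  core2 <- computeCore(toy_table(tracks2))
  expect_equal(core2@positions, setdiff(1:10, c(4L, 7L)))  # GAP and AMBIG out

  tracks3 <- c(r = "ACGTACGTAC", a = "ACTTACGTAC", b = "ACGTACGGAC")
  core3 <- computeCore(toy_table(tracks3))
  expect_equal(core3@positions[core3@snpCols], c(3L, 8L))
})

test_that("core SNPs equal the planted truth on a simulated clade", {
  sim <- sim_small_clade(seed = 35, L = 20000)
  ref <- sim$genomes[["s1"]]
  pws <- lapply(paste0("s", 2:5), function(s)
    alignPair(c(chr = unname(ref)), c(chr = unname(sim$genomes[[s]])),
              sample = s))
  tab <- buildAlleleTable(c(chr = unname(ref)), refId = "s1", pairwise = pws)
  core <- computeCore(tab)
  got <- core@positions[core@snpCols]
  # truth: columns where any two of s1..s5 disagree
  mat <- do.call(rbind, lapply(sim$genomes, function(g)
    charToRaw(unname(g))))
  truth <- which(colSums(mat != mat[rep(1, nrow(mat)), ]) > 0)
  expect_identical(got, as.integer(truth))
})

test_that("pairwise matrices match the brute-force column count", {
  tracks <- c(r = "AAAAAAAAAA", a = "AAAATTAAAA", b = "AAAATTAAGG")
  tab <- toy_table(tracks)
  ann <- data.frame(seqid = "chr", type = "CDS", start = 1L, end = 6L,
                    strand = "+", phase = 0L, ID = "g1",
                    Parent = NA, locus_tag = NA)
  core <- computeCore(tab, annotation = ann)
  m <- pairwiseMatrices(core)
  chars <- lapply(tracks, function(t) strsplit(t, "")[[1]])
  brute <- function(x, y) sum(chars[[x]] != chars[[y]])
  for (x in names(tracks)) for (y in names(tracks))
    expect_equal(m$core[x, y], brute(x, y))
  expect_true(isSymmetric(m$core))
  expect_true(all(diag(m$core) == 0L))
  # partition additivity
  expect_equal(m$cds + m$intergenic, m$core)
  expect_equal(m$cds["r", "a"], 2L)
  expect_equal(m$intergenic["a", "b"], 2L)
})

test_that("matrices satisfy the Hamming triangle inequality", {
  set.seed(36)
  tracks <- vapply(1:4, function(i)
    paste(sample(c("A", "C"), 500, replace = TRUE), collapse = ""), "")
  names(tracks) <- c("r", "a", "b", "c")
  m <- pairwiseMatrices(computeCore(toy_table(tracks)))$core
  ids <- rownames(m)
  for (i in ids) for (j in ids) for (k in ids)
    expect_lte(m[i, j], m[i, k] + m[k, j])
})

test_that("subset recomputation equals a fresh run and is monotone", {
  sim <- sim_small_clade(seed = 37, L = 10000)
  ref <- sim$genomes[["s1"]]
  pws <- lapply(paste0("s", 2:5), function(s)
    alignPair(c(chr = unname(ref)), c(chr = unname(sim$genomes[[s]])),
              sample = s))
  tab <- buildAlleleTable(c(chr = unname(ref)), refId = "s1", pairwise = pws)
  full <- computeCore(tab)
  again <- subsetRecompute(tab, sampleIds(tab))
  expect_identical(again$core@bases, full@bases)       # idempotence
  sub <- subsetRecompute(tab, c("s1", "s2", "s3"))
  expect_gte(length(sub$core@positions), length(full@positions))
  expect_error(computeCore(tab, "s1"), "at least 2")
  expect_error(subsetRecompute(tab, c("s1", "nope")), "unknown sample")
})

test_that("adding a sample equals the from-scratch table", {
  sim <- sim_small_clade(seed = 38, L = 10000)
  ref <- sim$genomes[["s1"]]
  pws <- lapply(paste0("s", 2:5), function(s)
    alignPair(c(chr = unname(ref)), c(chr = unname(sim$genomes[[s]])),
              sample = s))
  tab4 <- buildAlleleTable(c(chr = unname(ref)), refId = "s1",
                           pairwise = pws[1:3])
  tab5 <- addSample(tab4, pws[[4]])
  scratch <- buildAlleleTable(c(chr = unname(ref)), refId = "s1",
                              pairwise = pws)
  expect_identical(tab5@tracks, scratch@tracks)
  expect_identical(computeCore(tab5)@bases, computeCore(scratch)@bases)
  # core length never grows when a sample is added
  expect_lte(length(computeCore(tab5)@positions),
             length(computeCore(tab4)@positions))
  expect_error(addSample(tab5, pws[[4]]), "collision")
  # duplicate of an existing genome: identical matrix row
  dup <- pws[[1]]; dup@sample <- "s2copy"
  tab6 <- addSample(tab5, dup)
  m <- pairwiseMatrices(computeCore(tab6))$core
  others <- setdiff(rownames(m), c("s2", "s2copy"))
  expect_equal(m["s2copy", others], m["s2", others])
})

test_that("an all-GAP sample empties the core", {
  tracks <- c(r = "ACGTACGTAC", a = "ACGTACGTAC")
  tab <- toy_table(tracks)
  gap <- new("CallTrack", sample = "void", track = strrep("-", 10),
             depth = integer(10), fraction = rep(NA_real_, 10),
             refLayout = c(chr = 10L))
  tab2 <- addSample(tab, gap)
  expect_warning(core <- computeCore(tab2), "empty core")
  expect_length(core@positions, 0L)
})

test_that("allele tables persist as text and reload identically", {
  sim <- sim_small_clade(seed = 39, L = 5000, n = 3)
  ref <- sim$genomes[["s1"]]
  g <- c(chr = unname(ref))
  substr(g[[1]], 2001, 2070) <- substr(g[[1]], 101, 170)
  mask <- maskRepeats(g, 50)
  pws <- lapply(c("s2", "s3"), function(s)
    alignPair(g, c(chr = unname(sim$genomes[[s]])), sample = s, mask = mask))
  tab <- buildAlleleTable(g, refId = "s1", mask = mask, pairwise = pws)
  dir <- withr::local_tempdir()
  writeAlleleTable(tab, dir)
  back <- readAlleleTable(dir)
  expect_identical(back@tracks, tab@tracks)
  expect_identical(back@mask, tab@mask)
  expect_identical(back@contigs, tab@contigs)
  expect_identical(back@reference, tab@reference)
})

test_that("core outputs are written in the documented formats", {
  tracks <- c(r = "ACGTACGTAC", a = "ACTTACGTAC", b = "ACGTACGGAC")
  tab <- toy_table(tracks)
  core <- computeCore(tab)
  m <- pairwiseMatrices(core)
  pre <- file.path(withr::local_tempdir(), "out")
  paths <- writeCoreOutputs(core, m, pre)
  expect_true(all(file.exists(paths)))
  fa <- parseFasta(paste0(pre, "_core.fasta"))
  expect_length(fa, 3L)
  expect_equal(nchar(fa[[1]]$residues), 10L)
  snp <- parseFasta(paste0(pre, "_coreSNP.fasta"))
  expect_equal(nchar(snp[[1]]$residues), 2L)
  vcf <- readLines(paste0(pre, "_core.vcf"))
  expect_equal(sum(!startsWith(vcf, "#")), 2L)
})
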