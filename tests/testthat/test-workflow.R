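test_that("report percentages reproduce the published worked examples", {
  # Escherichia/Shigella-scale worked example
  p <- reportPercentages(coreLength = 2159296, avgGenomeLength = 5078265,
                         snpCount = 266969, cdsSnpCount = 248243)
  expect_equal(p$pctCore, 42.5)
  expect_equal(p$pctCoreSnps, 12.4)
  expect_equal(p$pctCdsSnps, 93.0)
  # zero denominators give NA, half-up rounding at one decimal
  expect_true(is.na(reportPercentages(10, 0, 0, 0)$pctCore))
  expect_true(is.na(reportPercentages(100, 200, 0, 0)$pctCdsSnps))
  expect_equal(reportPercentages(125, 1000, 0, 0)$pctCore, 12.5)
  expect_equal(reportPercentages(1245, 10000, 0, 0)$pctCore, 12.5)  # half-up
})

wf_fixture <- function(outdir, seed = 91, L = 20000, reps = 10L,
                       screen = FALSE) {
  sim <- sim_small_clade(seed = seed, L = L)
  genomes <- lapply(sim$genomes, function(g) setNames(unname(g), "chr1"))
  rd <- simulateReads(sim$genomes[["s3"]], coverage = 20, errorRate = 0.01,
                      seed = seed + 1)
  cfg <- defaultConfig(outputDir = outdir, bootstrapReps = reps,
                       selectionScreen = screen)
  list(sim = sim, genomes = genomes, reads = rd$reads, cfg = cfg)
}

test_that("the full workflow runs end to end and reruns re-entrantly", {
  outdir <- withr::local_tempdir()
  fx <- wf_fixture(outdir)
  res <- suppressMessages(
    runWorkflow(fx$cfg, genomes = fx$genomes,
                reads = list(s3reads = fx$reads),
                annotation = fx$sim$annotation))
  expect_s4_class(res$core, "CoreAlignment")
  expect_equal(res$report$nReads, 1L)
  expect_equal(res$report$nComplete, 5L)
  expect_gt(res$report$coreLength, 0.95 * 20000)
  expect_true(file.exists(file.path(outdir, "run.nwk")))
  expect_true(file.exists(file.path(outdir, "manifest.json")))
  expect_true(file.exists(file.path(outdir, "run_coreMatrix.txt")))
  # the reads sample sits with its donor genome
  tree <- res$tree
  expect_true("s3reads" %in% tree$tip.label)
  expect_equal(rfDistance(ape::keep.tip(tree, paste0("s", 1:5)),
                          fx$sim$tree), 0)
  # manifest-driven rerun: stages skipped, identical report
  res2 <- suppressMessages(
    runWorkflow(fx$cfg, genomes = fx$genomes,
                reads = list(s3reads = fx$reads),
                annotation = fx$sim$annotation))
  expect_equal(res2$report$coreLength, res$report$coreLength)
  expect_equal(res2$report$snpCount, res$report$snpCount)
  expect_identical(ape::write.tree(res2$tree), ape::write.tree(res$tree))
  log <- readLines(file.path(outdir, "run.log.jsonl"))
  expect_true(any(grepl("stage_skipped", log)))
})

test_that("two identical genomes give a zero-SNP report and no tree", {
  outdir <- withr::local_tempdir()
  g <- random_seq(5000, 92)
  cfg <- defaultConfig(outputDir = outdir, bootstrapReps = 0L)
  res <- suppressMessages(
    runWorkflow(cfg, genomes = list(a = c(chr = g), b = c(chr = g))))
  expect_equal(res$report$snpCount, 0L)
  expect_null(res$tree)                 # 2 samples: no internal topology
  expect_null(res$selection)
})

test_that("placing a sample equals the from-scratch run bit for bit", {
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  fx <- wf_fixture(out1, seed = 93, reps = 0L)
  four <- fx$genomes[paste0("s", 1:4)]
  cfg1 <- defaultConfig(outputDir = out1, bootstrapReps = 0L,
                        referenceMode = "user_specified", referenceId = "s1")
  res4 <- suppressMessages(runWorkflow(cfg1, genomes = four))
  placed <- suppressMessages(
    placeSample(out1, "s5", genome = fx$genomes[["s5"]], config = cfg1))
  cfg2 <- defaultConfig(outputDir = out2, bootstrapReps = 0L,
                        referenceMode = "user_specified", referenceId = "s1")
  scratch <- suppressMessages(runWorkflow(cfg2, genomes = fx$genomes))
  expect_identical(placed$core@bases, scratch$core@bases)
  expect_identical(placed$core@positions, scratch$core@positions)
  expect_equal(placed$matrices$core[rownames(scratch$matrices$core),
                                    colnames(scratch$matrices$core)],
               scratch$matrices$core)
  expect_identical(ape::write.tree(placed$tree),
                   ape::write.tree(scratch$tree))
})

test_that("reads from a clade member place as sister to their donor", {
  outdir <- withr::local_tempdir()
  fx <- wf_fixture(outdir, seed = 94, reps = 0L)
  cfg <- defaultConfig(outputDir = outdir, bootstrapReps = 0L,
                       referenceMode = "user_specified", referenceId = "s1")
  suppressMessages(runWorkflow(cfg, genomes = fx$genomes))
  placed <- suppressMessages(
    placeSample(outdir, "s3reads", reads = fx$reads, config = cfg))
  tr <- placed$tree
  sis <- treeBipartitions(tr)
  canon <- function(side, tips) {
    if (!(sort(tips)[1] %in% side)) side <- setdiff(tips, side)
    paste(sort(side), collapse = ",")
  }
  expect_true(canon(c("s3", "s3reads"), tr$tip.label) %in% sis)
})

test_that("an all-background metagenome is dropped by the cutoff", {
  outdir <- withr::local_tempdir()
  fx <- wf_fixture(outdir, seed = 95, L = 10000, reps = 0L)
  cfg <- defaultConfig(outputDir = outdir, bootstrapReps = 0L,
                       alignedFractionCutoff = 0.5,
                       referenceMode = "user_specified", referenceId = "s1")
  suppressMessages(runWorkflow(cfg, genomes = fx$genomes))
  bg_reads <- simulateReads(random_seq(20000, 96), coverage = 20,
                            seed = 97)$reads
  placed <- suppressMessages(
    placeSample(outdir, "junkmeta", reads = bg_reads, config = cfg))
  expect_false("junkmeta" %in% sampleIds(placed$table))
})

test_that("the control-file driven CLI surface composes", {
  outdir <- withr::local_tempdir()
  fx <- wf_fixture(outdir, seed = 98, L = 5000, reps = 0L)
  fa_dir <- withr::local_tempdir()
  paths <- vapply(names(fx$genomes), function(s) {
    p <- file.path(fa_dir, paste0(s, ".fa"))
    writeFasta(setNames(unname(fx$genomes[[s]]), "chr1"), p)
    p
  }, "")
  gff <- file.path(fa_dir, "ref.gff3")
  writeGff3(fx$sim$annotation, gff)
  ctl <- file.path(fa_dir, "run.ctl")
  writeLines(c(paste0("genome = ", names(paths), ":", paths),
               "reference = s1",
               "bootstrap = 0",
               paste0("gff = ", gff),
               paste0("output_dir = ", outdir)), ctl)
  cfg <- parseControlFile(ctl)
  expect_equal(cfg@referenceId, "s1")
  res <- suppressMessages(runWorkflow(cfg))
  expect_gt(res$report$coreLength, 4000)
  expect_true(file.exists(file.path(outdir, "report.tsv")))
  rep_tab <- read.delim(file.path(outdir, "report.tsv"))
  expect_equal(rep_tab$core_length, res$report$coreLength)
})

test_that("the core alignment exports to relaxed PHYLIP for external tools", {
  tracks <- c(r = "ACGTACGTAC", a = "ACTTACGTAC", b = "ACGTACGGAC")
  tab <- new("AlleleTable", reference = "r", contigs = c(chr = 10L),
             tracks = tracks,
             sampleData = S4Vectors::DataFrame(sample = names(tracks),
                                               type = rep("complete", 3)),
             mask = rep(FALSE, 10L))
  core <- computeCore(tab)
  tf <- withr::local_tempfile(fileext = ".phy")
  writePhylip(core, tf)
  lines <- readLines(tf)
  expect_equal(lines[1], "3 10")
  expect_match(lines[2], "^r ACGTACGTAC$")
})
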