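#' Table-style percentage arithmetic for run reports
#'
#' The summary percentages reported for a run: percent core
#' (100 * core length / average genome length), percent core SNPs
#' (100 * core SNP count / core length) and percent CDS SNPs
#' (100 * CDS SNP count / core SNP count), each rounded half-up to one
#' decimal. Zero denominators yield NA.
#'
#' @param coreLength core genome length (bases).
#' @param avgGenomeLength average length of complete + assembly inputs.
#' @param snpCount core SNP columns.
#' @param cdsSnpCount core SNP columns inside CDS.
#' @return list(pctCore, pctCoreSnps, pctCdsSnps).
#' @examples
#' reportPercentages(2159296, 5078265, 266969, 248243)
#' @export
reportPercentages <- function(coreLength, avgGenomeLength, snpCount,
                              cdsSnpCount) {
  pct <- function(num, den) if (is.na(den) || den == 0) NA_real_
                            else .round1(100 * num / den)
  list(pctCore = pct(coreLength, avgGenomeLength),
       pctCoreSnps = pct(snpCount, coreLength),
       pctCdsSnps = pct(cdsSnpCount, snpCount))
}

#' Summarize a run into a report
#'
#' @param core a [CoreAlignment-class].
#' @param table the filtered [AlleleTable-class].
#' @param genomeLengths named integer vector: input genome length per
#'   complete/assembly sample (read-only samples are excluded from the
#'   average-length denominator).
#' @param dropped character vector of dropped sample ids.
#' @param referenceId reference sample id.
#' @return list of class "RunReport".
#' @export
summarizeRun <- function(core, table, genomeLengths, dropped = character(0),
                         referenceId = table@reference) {
  types <- setNames(table@sampleData$type, table@sampleData$sample)
  avg <- if (length(genomeLengths)) mean(genomeLengths) else NA_real_
  snp <- length(core@snpCols)
  cds_snp <- if (length(core@partition))
    sum(core@partition[core@snpCols] == "CDS") else NA_integer_
  pcts <- reportPercentages(length(core@positions), avg, snp,
                            if (is.na(cds_snp)) 0L else cds_snp)
  structure(list(
    nComplete = sum(types == "complete"),
    nAssembly = sum(types %in% c("assembly", "contig")),
    nReads = sum(types == "reads"),
    avgGenomeLength = avg,
    coreLength = length(core@positions),
    pctCore = pcts$pctCore,
    snpCount = snp,
    pctCoreSnps = pcts$pctCoreSnps,
    cdsSnpCount = cds_snp,
    pctCdsSnps = if (is.na(cds_snp)) NA_real_ else pcts$pctCdsSnps,
    dropped = dropped,
    reference = referenceId,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    class = "RunReport")
}

#' @export
print.RunReport <- function(x, ...) {
  cat("Run report (reference:", x$reference, ")\n")
  cat("  samples: ", x$nComplete, " complete, ", x$nAssembly,
      " assembly, ", x$nReads, " reads\n", sep = "")
  cat("  avg genome length:", round(x$avgGenomeLength), "\n")
  cat("  core genome: ", x$coreLength, " bp (", x$pctCore, "% of avg)\n",
      sep = "")
  cat("  core SNPs: ", x$snpCount, " (", x$pctCoreSnps, "% of core)\n",
      sep = "")
  if (!is.na(x$cdsSnpCount))
    cat("  CDS SNPs: ", x$cdsSnpCount, " (", x$pctCdsSnps,
        "% of core SNPs)\n", sep = "")
  if (length(x$dropped))
    cat("  dropped:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

.wf_log <- function(dir, event, ...) {
  entry <- c(list(time = format(Sys.time(), "%H:%M:%S"), event = event),
             list(...))
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
      file = file.path(dir, "run.log.jsonl"), append = TRUE)
}

# stage runner with manifest-based re-entrancy: a completed stage whose
# cache file still exists is loaded, not recomputed, unless force = TRUE
.stage <- function(state, name, force, compute) {
  cache <- file.path(state$dir, "stages", paste0(name, ".rds"))
  if (!force && !is.null(state$manifest$stages[[name]]) && file.exists(cache)) {
    .wf_log(state$dir, "stage_skipped", stage = name)
    return(list(value = readRDS(cache), state = state))
  }
  value <- compute()
  dir.create(dirname(cache), recursive = TRUE, showWarnings = FALSE)
  saveRDS(value, cache)
  state$manifest$stages[[name]] <- list(
    cache = basename(cache),
    md5 = unname(tools::md5sum(cache)))
  jsonlite::write_json(state$manifest, file.path(state$dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  .wf_log(state$dir, "stage_done", stage = name)
  list(value = value, state = state)
}

#' Run the full workflow from a configuration
#'
#' Executes reference selection (MinHash), repeat masking, pairwise
#' alignment of genome/contig samples, read mapping and consensus calling
#' of read samples, allele-table construction, aligned-fraction filtering,
#' core and SNP-matrix computation, annotation partitioning, tree
#' inference with bootstraps, and (optionally) the gene selection screen.
#' Every stage's outputs are written under the configured output
#' directory with a JSON manifest; completed stages are skipped on rerun
#' unless `force = TRUE`.
#'
#' @param config a [RunConfig-class]; its samples slot declares inputs by
#'   path, or supply in-memory inputs via `genomes` / `reads`.
#' @param genomes optional named list of in-memory genome/contig
#'   sequences (named character vectors); names are sample ids. Entries
#'   listed in config samples as type "contig" are treated as draft
#'   assemblies.
#' @param reads optional named list of in-memory read record lists.
#' @param annotation optional annotation data.frame ([parseGff3()]
#'   layout); read from `config@gff` when empty.
#' @param force recompute completed stages.
#' @return list: report (RunReport), core, matrices, tree (phylo or
#'   NULL), table (filtered AlleleTable), selection (data.frame or NULL),
#'   reference (sample id), outputDir.
#' @export
runWorkflow <- function(config, genomes = NULL, reads = NULL,
                        annotation = NULL, force = FALSE) {
  dir <- config@outputDir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- if (file.exists(file.path(dir, "manifest.json")))
    jsonlite::read_json(file.path(dir, "manifest.json")) else list(stages = list())
  state <- list(dir = dir, manifest = manifest)
  # ---- gather inputs
  samp <- as.data.frame(config@samples)
  gin <- list(); rin <- list(); types <- character(0)
  if (nrow(samp)) {
    for (i in seq_len(nrow(samp))) {
      id <- samp$sample[i]
      if (samp$type[i] %in% c("complete", "contig")) {
        gin[[id]] <- .as_contig_chars(parseFasta(samp$path1[i]))
        types[id] <- samp$type[i]
      } else {
        mate <- if (!is.na(samp$path2[i])) samp$path2[i] else NULL
        rin[[id]] <- parseFastq(samp$path1[i], mate)
        types[id] <- "reads"
      }
    }
  }
  for (id in names(genomes %||% list())) {
    gin[[id]] <- .as_contig_chars(genomes[[id]])
    declared <- samp$type[samp$sample == id]
    types[id] <- if (length(declared)) declared else "complete"
  }
  for (id in names(reads %||% list())) {
    rin[[id]] <- reads[[id]]
    types[id] <- "reads"
  }
  if (length(gin) + length(rin) < 2L) stop("need at least 2 samples")
  if (is.null(annotation) && nzchar(config@gff))
    annotation <- parseGff3(config@gff)
  # ---- reference selection
  st <- .stage(state, "refselect", force, function() {
    sketches <- list()
    for (id in names(gin))
      sketches[[id]] <- buildSketch(gin[[id]], sample = id)
    for (id in names(rin)) {
      seqs <- vapply(rin[[id]], `[[`, "", "residues")
      sketches[[id]] <- buildSketch(setNames(seqs, paste0(id, "_r", seq_along(seqs))),
                                    sample = id)
    }
    ref <- selectReference(sketches, types,
                           mode = config@referenceMode,
                           userId = config@referenceId,
                           seed = config@seed)
    writeSketches(sketches, file.path(dir, "sketches.tsv"))
    D <- sketchDistanceMatrix(sketches)
    write.table(D, file.path(dir, "mash_distances.tsv"), sep = "\t",
                quote = FALSE, col.names = NA)
    list(reference = ref)
  })
  state <- st$state; refId <- st$value$reference
  if (!refId %in% names(gin))
    stop("selected reference ", refId, " has no genome sequence")
  refSeq <- gin[[refId]]
  writeFasta(refSeq, file.path(dir, "reference.fasta"))
  .wf_log(dir, "reference_selected", reference = refId)
  # ---- repeat masking
  st <- .stage(state, "mask", force, function() {
    mask <- maskRepeats(refSeq)
    nmask <- sum(vapply(mask, function(ir) sum(width(ir)), 0))
    .wf_log(dir, "repeats_masked", bases = nmask)
    mask
  })
  state <- st$state; mask <- st$value
  # ---- align genome/contig samples
  st <- .stage(state, "align", force, function() {
    lapply(setdiff(names(gin), refId), function(id) {
      pw <- alignPair(refSeq, gin[[id]], sample = id, mask = mask)
      writePairwiseReports(pw, file.path(dir, id))
      pw
    })
  })
  state <- st$state; pairwise <- st$value
  # ---- map read samples
  st <- .stage(state, "map", force, function() {
    index <- buildSeedIndex(refSeq)
    lapply(names(rin), function(id) {
      aln <- mapReads(rin[[id]], index)
      pu <- buildPileup(aln, index)
      tr <- callConsensus(pu, index, sample = id,
                          minDepth = config@minDepth,
                          minAlleleFraction = config@minAlleleFraction)
      writeCallTrack(tr, refSeq, file.path(dir, id))
      .wf_log(dir, "reads_mapped", sample = id,
              mapped = sum(aln$mapped), total = nrow(aln))
      tr
    })
  })
  state <- st$state; tracks <- st$value
  # ---- allele table + filter
  st <- .stage(state, "table", force, function() {
    tab <- buildAlleleTable(refSeq, refId = refId, mask = mask,
                            pairwise = pairwise, readTracks = tracks)
    # record declared contig samples as such
    tab@sampleData$type[match(names(types), tab@sampleData$sample)] <-
      ifelse(types == "contig", "assembly", types)[names(types)]
    tab@sampleData$type[tab@sampleData$sample == refId] <- "complete"
    writeAlleleTable(tab, file.path(dir, "allele_table"))
    tab
  })
  state <- st$state; table <- st$value
  filtered <- filterSamples(table, config@alignedFractionCutoff)
  dropped <- attr(filtered, "dropped")
  for (d in dropped) .wf_log(dir, "sample_dropped", sample = d,
                             cutoff = config@alignedFractionCutoff)
  # ---- core + matrices
  st <- .stage(state, "core", force, function() {
    core <- computeCore(filtered, annotation = annotation)
    matrices <- pairwiseMatrices(core)
    writeCoreOutputs(core, matrices, file.path(dir, "run"),
                     refSample = refId)
    list(core = core, matrices = matrices)
  })
  state <- st$state
  core <- st$value$core; matrices <- st$value$matrices
  # ---- tree
  tree <- NULL
  if (config@treeMethod == "nj" && length(core@positions) > 0L &&
      length(core@samples) >= 3L) {
    st <- .stage(state, "tree", force, function() {
      tr <- if (config@bootstrapReps > 0L)
        bootstrapSupport(core, config@bootstrapReps, seed = config@seed)
      else njTree(distanceMatrix(core))
      writeNewickFile(tr, file.path(dir, "run.nwk"))
      tr
    })
    state <- st$state; tree <- st$value
  } else if (length(core@positions) == 0L) {
    .wf_log(dir, "tree_skipped", reason = "empty core")
  } else if (config@treeMethod == "external") {
    writePhylip(core, file.path(dir, "run_core.phy"))
    .wf_log(dir, "tree_external", alignment = "run_core.phy")
  }
  # ---- selection screen
  selection <- NULL
  if (config@selectionScreen && !is.null(annotation)) {
    st <- .stage(state, "selection", force, function() {
      genes <- geneModels(annotation)
      sel <- screenGenes(filtered, genes, codeTable = config@geneticCodeTable)
      write.table(sel, file.path(dir, "run_gene_selection.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      sel
    })
    state <- st$state; selection <- st$value
  }
  # ---- SNP annotation
  if (!is.null(annotation) && length(core@snpCols)) {
    st <- .stage(state, "annotate", force, function() {
      ann <- annotateCoreSnps(core, annotation, refSeq,
                              codeTable = config@geneticCodeTable,
                              refSample = refId)
      write.table(ann, file.path(dir, "run_snp_annotation.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      ann
    })
    state <- st$state
  }
  # ---- report
  glens <- vapply(gin, function(g) sum(nchar(g)), 0)
  glens <- glens[names(glens) %in% sampleIds(filtered)]
  report <- summarizeRun(core, filtered, glens, dropped = dropped,
                         referenceId = refId)
  rep_df <- data.frame(
    reference = report$reference, n_complete = report$nComplete,
    n_assembly = report$nAssembly, n_reads = report$nReads,
    avg_genome_length = report$avgGenomeLength,
    core_length = report$coreLength, pct_core = report$pctCore,
    core_snps = report$snpCount, pct_core_snps = report$pctCoreSnps,
    cds_snps = report$cdsSnpCount, pct_cds_snps = report$pctCdsSnps)
  write.table(rep_df, file.path(dir, "report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "NA")
  list(report = report, core = core, matrices = matrices, tree = tree,
       table = filtered, selection = selection, reference = refId,
       outputDir = dir)
}

#' Annotate core SNP columns against the reference annotation
#'
#' Builds the SNP records (unique position x alternative allele over all
#' non-reference samples) and classifies each by gene and codon effect.
#'
#' @param core a [CoreAlignment-class].
#' @param annotation annotation data.frame.
#' @param ref reference sequences.
#' @param codeTable genetic code table.
#' @param refSample the reference sample id.
#' @return data.frame from [classifySnps()].
#' @export
annotateCoreSnps <- function(core, annotation, ref, codeTable = 11L,
                             refSample = core@samples[1L]) {
  if (length(core@snpCols) == 0L)
    return(classifySnps(data.frame(contig = character(0), pos = integer(0),
                                   ref_base = character(0),
                                   alt_base = character(0)),
                        geneModels(annotation), ref, codeTable))
  m <- coreBaseMatrix(core, snpOnly = TRUE)
  loc <- .global_to_contig(core@positions[core@snpCols], core@contigs)
  refb <- m[refSample, ]
  rows <- list()
  for (s in setdiff(rownames(m), refSample)) {
    d <- which(m[s, ] != refb)
    if (length(d))
      rows[[s]] <- data.frame(contig = loc$contig[d], pos = loc$pos[d],
                              ref_base = refb[d], alt_base = m[s, d],
                              sample = s, stringsAsFactors = FALSE)
  }
  snps <- if (length(rows)) do.call(rbind, rows)
          else data.frame(contig = character(0), pos = integer(0),
                          ref_base = character(0), alt_base = character(0))
  snps <- unique(snps[, c("contig", "pos", "ref_base", "alt_base")])
  classifySnps(snps, geneModels(annotation), ref, codeTable)
}

#' Write a core alignment in relaxed PHYLIP for external tree programs
#'
#' @param core a [CoreAlignment-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writePhylip <- function(core, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(length(core@samples), length(core@positions)), con)
  for (s in core@samples)
    writeLines(paste(s, core@bases[[s]]), con)
  invisible(path)
}

#' Place one new sample onto an existing run
#'
#' Reads the persisted allele table, aligns or maps the new sample to the
#' stored reference, extends the table, and recomputes core, matrices and
#' tree. Existing per-sample tracks are untouched, so the result equals a
#' from-scratch run with the enlarged sample set.
#'
#' @param runDir the output directory of a completed [runWorkflow()].
#' @param sampleId new sample id.
#' @param genome named character vector (genome/contig sample), or NULL.
#' @param reads read records (read sample), or NULL.
#' @param config a [RunConfig-class] for thresholds (defaults used when
#'   NULL).
#' @param annotation optional annotation for partitioning.
#' @return list(report, core, matrices, tree, table).
#' @export
placeSample <- function(runDir, sampleId, genome = NULL, reads = NULL,
                        config = NULL, annotation = NULL) {
  if (is.null(config)) config <- defaultConfig()
  table <- readAlleleTable(file.path(runDir, "allele_table"))
  refFa <- file.path(runDir, "reference.fasta")
  if (!file.exists(refFa)) stop("no stored reference in ", runDir)
  refSeq <- .as_contig_chars(parseFasta(refFa))
  if (!identical(unname(nchar(refSeq)), unname(table@contigs)) ||
      !identical(names(refSeq), names(table@contigs)))
    stop("stored reference does not match the allele table contig layout")
  newx <- if (!is.null(genome)) {
    alignPair(refSeq, genome, sample = sampleId)
  } else if (!is.null(reads)) {
    index <- buildSeedIndex(refSeq)
    aln <- mapReads(reads, index)
    callConsensus(buildPileup(aln, index), index, sample = sampleId,
                  minDepth = config@minDepth,
                  minAlleleFraction = config@minAlleleFraction)
  } else stop("supply either genome or reads")
  table2 <- addSample(table, newx)
  filtered <- filterSamples(table2, config@alignedFractionCutoff)
  dropped <- attr(filtered, "dropped")
  if (sampleId %in% dropped)
    message("placed sample ", sampleId,
            " was dropped by the aligned-fraction cutoff")
  core <- computeCore(filtered, annotation = annotation)
  matrices <- pairwiseMatrices(core)
  tree <- if (length(core@positions) > 0L && length(core@samples) >= 3L) {
    if (config@bootstrapReps > 0L)
      bootstrapSupport(core, config@bootstrapReps, seed = config@seed)
    else njTree(distanceMatrix(core))
  } else NULL
  writeAlleleTable(table2, file.path(runDir, "allele_table"))
  if (!is.null(tree)) writeNewickFile(tree, file.path(runDir, "run.nwk"))
  glens <- setNames(rep(NA_real_, 0), character(0))
  report <- summarizeRun(core, filtered, glens, dropped = dropped)
  list(report = report, core = core, matrices = matrices, tree = tree,
       table = filtered)
}
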