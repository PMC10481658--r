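# End-to-end orchestration: synth -> binding -> som -> corecruit ->
# programs -> controls -> dediff, driven by one plain-text (YAML) config
# with a single root seed, writing plain-text outputs and a tab-separated
# manifest of file hashes.

pipelineStages <- c("synth", "binding", "som", "corecruit", "programs",
                    "controls", "dediff")

#' Default pipeline run configuration
#'
#' Nested list of stage parameters. \code{synthetic} entries are handed to
#' \code{\link{syntheticConfig}}; the remaining blocks parameterize the
#' analysis stages. Desk-scale demo choices (SOM epochs, control
#' iterations) are documented in the package vignette.
#'
#' @param seed root seed; fans out to every stage.
#' @param outdir output directory.
#' @return a validated list of class \code{RunConfig}.
#' @export
defaultRunConfig <- function(seed = 1L, outdir = tempfile("promcore_run")) {
  cfg <- list(
    seed = as.integer(seed),
    outdir = outdir,
    synthetic = list(),
    som = list(rows = NULL, cols = NULL, epochs = 25L, k = 7L),
    corecruit = list(minSupport = 0.5, sizeMin = 2L, sizeMax = NULL,
                     mdsDims = 2L),
    programs = list(nComponents = 5L, k = 3L, rankThreshold = 10L),
    controls = list(k = 4L, nIter = 1000L),
    dediff = list(minStudies = 1L))
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys absent from the file keep their defaults; unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @param seed,outdir overrides applied after reading.
#' @return a \code{RunConfig}.
#' @export
readRunConfig <- function(path, seed = NULL, outdir = NULL) {
  user <- yaml::read_yaml(path)
  cfg <- defaultRunConfig()
  known <- names(cfg)
  bad <- setdiff(names(user), known)
  stopIfNot(length(bad) == 0L,
            paste("configuration error: unknown key(s):",
                  paste(bad, collapse = ", ")))
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      if (k != "synthetic") {
        badSub <- setdiff(names(user[[k]]), names(cfg[[k]]))
        stopIfNot(length(badSub) == 0L,
                  paste0("configuration error: unknown key(s) in ", k,
                         ": ", paste(badSub, collapse = ", ")))
      }
      cfg[[k]][names(user[[k]])] <- user[[k]]
    } else cfg[[k]] <- user[[k]]
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(outdir)) cfg$outdir <- outdir
  class(cfg) <- "RunConfig"
  cfg
}

runMessage <- function(...) message("[PromCoRe] ", ...)

stageOutputs <- function(stage, outdir) {
  file.path(outdir, switch(stage,
    synth = "synth", binding = "binding", som = "som",
    corecruit = "corecruit", programs = "programs",
    controls = "controls", dediff = "dediff"))
}

manifestPath <- function(outdir) file.path(outdir, "manifest.tsv")

writeManifest <- function(entries, outdir) {
  write.table(entries, manifestPath(outdir), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(entries)
}

manifestEntries <- function(stage, files, seed, elapsed) {
  data.frame(stage = stage,
             file = basename(files),
             md5 = unname(tools::md5sum(files)),
             seed = seed, seconds = round(elapsed, 3L),
             row.names = NULL)
}

# ---- individual stage implementations ------------------------------------

stageSynth <- function(config) {
  scfg <- do.call(syntheticConfig,
                  c(config$synthetic, list(rngSeed = config$seed)))
  dir_ <- stageOutputs("synth", config$outdir)
  dir.create(dir_, recursive = TRUE, showWarnings = FALSE)
  cis <- generateCistromes(scfg)
  tssr <- generateTssAnnotation(scfg)
  trk <- generateSignalTracks(scfg, tssr$truth)
  atl <- generateExpressionAtlas(scfg)
  prt <- generatePerturbationDataset(scfg, tssr$truth)
  dds <- generateDifferentiationSeries(scfg)
  files <- character(0)
  for (tf in names(cis$cistromes))
    files <- c(files, writeBedFile(cis$cistromes[[tf]],
                                   file.path(dir_, paste0("cistrome_", tf,
                                                          ".bed"))))
  tssOut <- tssr$tss
  mcols(tssOut)$name <- mcols(tssOut)$gene_id
  files <- c(files, writeBedFile(tssOut, file.path(dir_, "tss.bed")))
  for (t_ in c("dhs", "h3k27ac", "h3k4me3", "control"))
    files <- c(files, writeBedGraphFile(trk[[t_]],
                                        file.path(dir_, paste0(t_,
                                                               ".bedGraph"))))
  files <- c(files, writeBedFile(trk$domains,
                                 file.path(dir_, "h3k4me3_domains.bed")))
  files <- c(files, writeMatrixTsv(cbind(expression = trk$expression),
                                   file.path(dir_, "promoter_expression.tsv")))
  for (sp in names(atlasMatrices(atl$atlas)))
    files <- c(files, writeMatrixTsv(atlasMatrices(atl$atlas)[[sp]],
                                     file.path(dir_, paste0("atlas_", sp,
                                                            ".tsv"))))
  for (st in names(prt$studies)) {
    f <- file.path(dir_, paste0("perturb_", st, ".tsv"))
    write.table(prt$studies[[st]], f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(files, f)
  }
  files <- c(files, writeMatrixTsv(dds$reference,
                                   file.path(dir_, "dediff_reference.tsv")))
  for (st in names(dds$injuries))
    files <- c(files, writeMatrixTsv(dds$injuries[[st]],
                                     file.path(dir_, paste0("dediff_", st,
                                                            ".tsv"))))
  truth <- dds$truth
  truth$ambiguousGenes <- tssr$truth$ambiguousGenes
  files <- c(files, writeGroundTruth(truth, file.path(dir_, "truth.tsv")))
  anchorDf <- data.frame(batch = rep(names(dds$anchors),
                                     lengths(dds$anchors)),
                         sample = unlist(dds$anchors), row.names = NULL)
  f <- file.path(dir_, "dediff_anchors.tsv")
  write.table(anchorDf, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  files
}

requireStage <- function(config, stage, files) {
  miss <- files[!file.exists(files)]
  stopIfNot(length(miss) == 0L,
            paste0("missing input from upstream stage '", stage, "': ",
                   paste(basename(miss), collapse = ", "),
                   "; run that stage first"))
}

stageBinding <- function(config) {
  synthDir <- stageOutputs("synth", config$outdir)
  dir_ <- stageOutputs("binding", config$outdir)
  dir.create(dir_, recursive = TRUE, showWarnings = FALSE)
  cisFiles <- list.files(synthDir, pattern = "^cistrome_.*\\.bed$",
                         full.names = TRUE)
  requireStage(config, "synth",
               c(file.path(synthDir, c("tss.bed", "truth.tsv",
                                       "dhs.bedGraph", "h3k27ac.bedGraph",
                                       "promoter_expression.tsv"))))
  stopIfNot(length(cisFiles) >= 2L,
            "missing input from upstream stage 'synth': cistrome BED files")
  cistromes <- lapply(cisFiles, readBedFile)
  names(cistromes) <- sub("^cistrome_(.*)\\.bed$", "\\1",
                          basename(cisFiles))
  tssBed <- readBedFile(file.path(synthDir, "tss.bed"))
  tss <- GRanges(seqnames(tssBed), IRanges(start = start(tssBed),
                                           width = 1L),
                 gene_id = mcols(tssBed)$name)
  truth <- readGroundTruth(file.path(synthDir, "truth.tsv"))
  crms <- mergePeaksToCrms(cistromes)
  records <- mapCrmsToPromoters(crms, tss,
                                geneFilter = names(truth$promoterCluster))
  bm <- buildBindingMatrix(records, tfUniverse = sort(names(cistromes)))
  dhs <- readBedGraphFile(file.path(synthDir, "dhs.bedGraph"))
  k27 <- readBedGraphFile(file.path(synthDir, "h3k27ac.bedGraph"))
  expr <- readMatrixTsv(file.path(synthDir, "promoter_expression.tsv"))
  genes <- rownames(bindingMatrix(bm))
  feats <- cbind(dhs = extractPromoterSignal(dhs, records)[genes],
                 h3k27ac = extractPromoterSignal(k27, records)[genes],
                 expression = expr[genes, 1L])
  rownames(feats) <- genes
  c(writeMatrixTsv(bindingMatrix(bm),
                   file.path(dir_, "binding_matrix.tsv")),
    writeMatrixTsv(feats, file.path(dir_, "promoter_features.tsv")))
}

stageSom <- function(config) {
  bindDir <- stageOutputs("binding", config$outdir)
  dir_ <- stageOutputs("som", config$outdir)
  dir.create(dir_, recursive = TRUE, showWarnings = FALSE)
  requireStage(config, "binding",
               file.path(bindDir, "binding_matrix.tsv"))
  m <- readMatrixTsv(file.path(bindDir, "binding_matrix.tsv"))
  p <- config$som
  grid <- trainSOM(m, rows = p$rows, cols = p$cols, epochs = p$epochs,
                   seed = deriveSeed(config$seed, 101L))
  prot <- binarizePrototypes(grid)
  hom <- homogeneityAnalysis(prot)
  k <- if (is.null(p$k)) hom$suggestedK else p$k
  cl <- clusterSomCells(prot, k = k)
  genes <- promoterClusters(grid, cl$cellCluster)
  co <- gridCoords(somDim(grid)[1L], somDim(grid)[2L])
  a <- somAssignment(grid)
  assignDf <- data.frame(gene = names(a), cell = unname(a),
                         row = co[a, 1L], col = co[a, 2L],
                         cluster = as.character(genes), row.names = NULL)
  f1 <- file.path(dir_, "som_assignments.tsv")
  write.table(assignDf, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  cb <- somCodebook(grid)
  rownames(cb) <- paste0("cell", seq_len(nrow(cb)))
  f2 <- writeMatrixTsv(cb, file.path(dir_, "som_codebook.tsv"))
  homDf <- data.frame(k = hom$k, homogeneity = unname(hom$homogeneity),
                      suggested = hom$k == hom$suggestedK)
  f3 <- file.path(dir_, "homogeneity.tsv")
  write.table(homDf, f3, sep = "\t", quote = FALSE, row.names = FALSE)
  rownames(prot) <- paste0("cell", seq_len(nrow(prot)))
  f4 <- writeMatrixTsv(prot, file.path(dir_, "som_prototypes.tsv"))
  c(f1, f2, f3, f4)
}

stageCorecruit <- function(config) {
  bindDir <- stageOutputs("binding", config$outdir)
  somDir <- stageOutputs("som", config$outdir)
  dir_ <- stageOutputs("corecruit", config$outdir)
  dir.create(dir_, recursive = TRUE, showWarnings = FALSE)
  requireStage(config, "binding", file.path(bindDir, "binding_matrix.tsv"))
  requireStage(config, "som", file.path(somDir, "som_assignments.tsv"))
  m <- readMatrixTsv(file.path(bindDir, "binding_matrix.tsv"))
  asg <- read.table(file.path(somDir, "som_assignments.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
  p <- config$corecruit
  clusters <- sort(unique(asg$cluster))
  allItems <- list(); occ <- list()
  for (cl in clusters) {
    sub <- m[asg$gene[asg$cluster == cl], , drop = FALSE]
    its <- mineFrequentItemsets(sub, minSupport = p$minSupport,
                                sizeMin = p$sizeMin, sizeMax = p$sizeMax)
    if (nrow(its)) its$cluster <- cl
    allItems[[cl]] <- its
    occ[[cl]] <- coreNodeOccurrence(its, colnames(m))
  }
  keep <- vapply(allItems, nrow, 1L) > 0L
  items <- if (any(keep)) do.call(rbind, allItems[keep]) else
    data.frame(items = character(0), size = integer(0),
               support = numeric(0), count = integer(0),
               cluster = character(0))
  f1 <- file.path(dir_, "core_itemsets.tsv")
  write.table(items, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  occM <- do.call(cbind, occ)
  colnames(occM) <- clusters
  f2 <- writeMatrixTsv(occM, file.path(dir_, "core_node_occurrence.tsv"))
  tan <- tanimotoDistanceMatrix(m)
  f3 <- writeMatrixTsv(tan, file.path(dir_, "tanimoto.tsv"))
  f4 <- writeMatrixTsv(mdsEmbedding(tan, dims = p$mdsDims),
                       file.path(dir_, "mds.tsv"))
  c(f1, f2, f3, f4)
}

stagePrograms <- function(config) {
  synthDir <- stageOutputs("synth", config$outdir)
  somDir <- stageOutputs("som", config$outdir)
  dir_ <- stageOutputs("programs", config$outdir)
  dir.create(dir_, recursive = TRUE, showWarnings = FALSE)
  atlFiles <- list.files(synthDir, pattern = "^atlas_.*\\.tsv$",
                         full.names = TRUE)
  stopIfNot(length(atlFiles) >= 1L,
            "missing input from upstream stage 'synth': atlas TSV files")
  mats <- lapply(atlFiles, readMatrixTsv)
  names(mats) <- sub("^atlas_(.*)\\.tsv$", "\\1", basename(atlFiles))
  atlas <- new("ExpressionAtlas", matrices = mats, focalCell = "MPH")
  p <- config$programs
  fit <- mfa(atlasMatrices(atlas), nComponents = p$nComponents)
  programs <- clusterTfPrograms(fit$scores, atlas, k = p$k)
  connect <- selectConnectTfs(atlas, rankThreshold = p$rankThreshold)
  connect$program <- programs[connect$tf]
  f1 <- writeMatrixTsv(fit$scores, file.path(dir_, "mfa_scores.tsv"))
  f2 <- file.path(dir_, "programs.tsv")
  write.table(data.frame(tf = names(programs), program = unname(programs)),
              f2, sep = "\t", quote = FALSE, row.names = FALSE)
  f3 <- file.path(dir_, "connect.tsv")
  write.table(connect, f3, sep = "\t", quote = FALSE, row.names = FALSE)
  c(f1, f2, f3)
}

stageControls <- function(config) {
  synthDir <- stageOutputs("synth", config$outdir)
  bindDir <- stageOutputs("binding", config$outdir)
  dir_ <- stageOutputs("controls", config$outdir)
  dir.create(dir_, recursive = TRUE, showWarnings = FALSE)
  requireStage(config, "binding",
               file.path(bindDir, "promoter_features.tsv"))
  requireStage(config, "synth", file.path(synthDir, "truth.tsv"))
  feats <- readMatrixTsv(file.path(bindDir, "promoter_features.tsv"))
  truth <- readGroundTruth(file.path(synthDir, "truth.tsv"))
  p <- config$controls
  strata <- activityStrata(feats, k = p$k)
  identity_ <- intersect(truth$identityTfs, names(strata))
  pool <- setdiff(names(strata), identity_)
  ens <- sampleMatchedControls(identity_, pool, strata, nIter = p$nIter,
                               seed = deriveSeed(config$seed, 202L))
  studyFiles <- list.files(synthDir, pattern = "^perturb_.*\\.tsv$",
                           full.names = TRUE)
  stopIfNot(length(studyFiles) >= 1L,
            "missing input from upstream stage 'synth': perturbation tables")
  study1 <- read.table(studyFiles[1L], header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
  vals <- setNames(study1$log2fc, study1$gene)
  ens <- selectRepresentativeSet(ens, vals)
  f1 <- file.path(dir_, "strata.tsv")
  write.table(data.frame(gene = names(strata), stratum = unname(strata)),
              f1, sep = "\t", quote = FALSE, row.names = FALSE)
  f2 <- file.path(dir_, "control_pvalues.tsv")
  write.table(data.frame(iteration = seq_along(setPvalues(ens)),
                         p = setPvalues(ens),
                         representative = seq_along(setPvalues(ens)) ==
                           representativeIndex(ens)),
              f2, sep = "\t", quote = FALSE, row.names = FALSE)
  f3 <- file.path(dir_, "representative_set.tsv")
  write.table(data.frame(gene = representativeSet(ens)), f3, sep = "\t",
              quote = FALSE, row.names = FALSE)
  c(f1, f2, f3)
}

stageDediff <- function(config) {
  synthDir <- stageOutputs("synth", config$outdir)
  dir_ <- stageOutputs("dediff", config$outdir)
  dir.create(dir_, recursive = TRUE, showWarnings = FALSE)
  requireStage(config, "synth",
               file.path(synthDir, c("dediff_reference.tsv",
                                     "dediff_anchors.tsv")))
  reference <- readMatrixTsv(file.path(synthDir, "dediff_reference.tsv"))
  anchors <- read.table(file.path(synthDir, "dediff_anchors.tsv"),
                        header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
  injFiles <- list.files(synthDir, pattern = "^dediff_injury.*\\.tsv$",
                         full.names = TRUE)
  refAnchors <- anchors$sample[anchors$batch == "reference"]
  model <- fitDifferentiationAxis(reference, refAnchors)
  proj <- projectSamples(model, reference)
  proj$study <- "reference"
  fcs <- list()
  for (f in injFiles) {
    st <- sub("^dediff_(injury[0-9]+)\\.tsv$", "\\1", basename(f))
    m <- readMatrixTsv(f)
    stAnchors <- anchors$sample[anchors$batch == st]
    corr <- batchCorrectMeanOnly(reference, m, refAnchors, stAnchors)
    pj <- projectSamples(model, corr)
    pj$study <- st
    proj <- rbind(proj, pj)
    cases <- setdiff(colnames(m), stAnchors)
    fcs[[st]] <- rowMeans(corr[, cases, drop = FALSE]) -
      rowMeans(corr[, stAnchors, drop = FALSE])
  }
  meta <- metaFoldChange(fcs, minStudies = config$dediff$minStudies)
  f1 <- file.path(dir_, "projection.tsv")
  write.table(proj, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  f2 <- writeMatrixTsv(cbind(median_log2fc = meta),
                       file.path(dir_, "meta_fold_change.tsv"))
  c(f1, f2)
}

# ---- orchestration --------------------------------------------------------

#' Run one pipeline stage
#'
#' Executes a single stage against \code{config$outdir}, appends its files
#' to the run manifest and returns the manifest entries.
#'
#' @param name stage name, one of synth, binding, som, corecruit,
#'   programs, controls, dediff.
#' @param config a \code{RunConfig} from \code{\link{defaultRunConfig}} or
#'   \code{\link{readRunConfig}}.
#' @return data.frame of manifest entries for the stage (invisibly).
#' @export
runStage <- function(name, config) {
  stopIfNot(name %in% pipelineStages,
            paste0("unknown stage '", name, "'; valid stages: ",
                   paste(pipelineStages, collapse = ", ")))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  fn <- switch(name, synth = stageSynth, binding = stageBinding,
               som = stageSom, corecruit = stageCorecruit,
               programs = stagePrograms, controls = stageControls,
               dediff = stageDediff)
  runMessage("stage ", name, " (seed ", config$seed, ")")
  t0 <- proc.time()[["elapsed"]]
  files <- fn(config)
  elapsed <- proc.time()[["elapsed"]] - t0
  entries <- manifestEntries(name, files, config$seed, elapsed)
  mp <- manifestPath(config$outdir)
  if (file.exists(mp)) {
    old <- read.table(mp, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    old <- old[old$stage != name, , drop = FALSE]
    entries <- rbind(old, entries)
  }
  writeManifest(entries, config$outdir)
  invisible(entries)
}

stageUpToDate <- function(name, config) {
  mp <- manifestPath(config$outdir)
  if (!file.exists(mp)) return(FALSE)
  man <- read.table(mp, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  man <- man[man$stage == name, , drop = FALSE]
  if (!nrow(man)) return(FALSE)
  paths <- file.path(stageOutputs(name, config$outdir), man$file)
  all(file.exists(paths)) &&
    identical(unname(tools::md5sum(paths)), man$md5) &&
    all(man$seed == config$seed)
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order. With \code{resume = TRUE},
#' stages whose outputs already exist with manifest-matching hashes (and
#' the same seed) are skipped, so an interrupted run picks up from the
#' last completed stage. \code{dryRun} prints the plan without writing.
#'
#' @param config a \code{RunConfig}.
#' @param stages subset of stages to run (dependency order is enforced).
#' @param resume reuse cached stage outputs when hashes match.
#' @param dryRun print the plan only.
#' @return the manifest data.frame (invisibly); for a dry run, the planned
#'   stage names.
#' @export
runAll <- function(config = defaultRunConfig(), stages = pipelineStages,
                   resume = FALSE, dryRun = FALSE) {
  stopIfNot(all(stages %in% pipelineStages),
            paste("unknown stage(s):",
                  paste(setdiff(stages, pipelineStages), collapse = ", ")))
  plan <- pipelineStages[pipelineStages %in% stages]
  if (dryRun) {
    runMessage("dry run; would execute: ", paste(plan, collapse = " -> "),
               " into ", config$outdir)
    return(invisible(plan))
  }
  for (s in plan) {
    if (resume && stageUpToDate(s, config)) {
      runMessage("stage ", s, " up to date; skipping")
      next
    }
    runStage(s, config)
  }
  man <- read.table(manifestPath(config$outdir), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  invisible(man)
}
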