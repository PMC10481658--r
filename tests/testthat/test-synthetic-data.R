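test_that("config validation rejects bad parameters", {
  expect_error(syntheticConfig(nPromoters = 0), "positive count")
  expect_error(syntheticConfig(bindingNoise = 1.5), "\\[0,1\\]")
  expect_error(syntheticConfig(nTfs = 4, clusterTfSets = list(c("R01", "ZZ")),
                               nBindingClusters = 1),
               "unknown regulators")
  expect_error(tinyConfig(nAmbiguous = 3), "even")
})

test_that("zero-noise cistromes carry exactly the planted cluster peaks", {
  cfg <- syntheticConfig(nTfs = 4, nPromoters = 4, nBindingClusters = 2,
                         tfNames = c("A", "B", "C", "D"),
                         clusterTfSets = list(c("A", "B"), c("C", "D")),
                         bindingNoise = 0, nAtlasTfs = 10,
                         programSizes = c(CTS = 2, CTE = 3, UBQ = 5),
                         nIdentityTfs = 1, nConnectPlanted = 1,
                         nEffectors = 4, rngSeed = 1)
  cis <- generateCistromes(cfg)
  m <- cis$membership
  expect_equal(unname(m[1:2, ]), matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 2))
  expect_equal(unname(m[3:4, ]), matrix(c(0, 0, 0, 0, 1, 1, 1, 1), 2))
  # peaks overlap their promoter TSS
  ov <- countOverlaps(cis$promoters, unlist(cis$cistromes))
  expect_true(all(ov >= 2))
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- tinyConfig(bindingNoise = 0.2)
  for (gen in list(generateCistromes, generateTssAnnotation,
                   function(c) generateSignalTracks(c),
                   generateExpressionAtlas,
                   function(c) generatePerturbationDataset(c),
                   generateDifferentiationSeries)) {
    expect_identical(gen(cfg), gen(cfg))
  }
  # different seed changes stochastic output
  cfg2 <- tinyConfig(bindingNoise = 0.2, rngSeed = 99)
  expect_false(identical(generateCistromes(cfg)$membership,
                         generateCistromes(cfg2)$membership))
})

test_that("off-cluster binding frequency matches the flip probability", {
  cfg <- tinyConfig(nTfs = 10, nPromoters = 400, bindingNoise = 0.5,
                    nAtlasTfs = 500, programSizes = NULL, rngSeed = 21)
  cis <- generateCistromes(cfg)
  truth <- cis$truth
  planted <- matrix(0L, cfg$nPromoters, cfg$nTfs,
                    dimnames = dimnames(cis$membership))
  for (j in seq_along(cfg$clusterTfSets))
    planted[truth$promoterCluster == j, cfg$clusterTfSets[[j]]] <- 1L
  off <- cis$membership[planted == 0L]
  n <- length(off)
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(off) - 0.5), 3 * se)
})

test_that("TSS annotation plants ambiguous records and stays sorted", {
  cfg <- tinyConfig(nPromoters = 10, nAmbiguous = 0)
  t0 <- generateTssAnnotation(cfg)
  expect_length(t0$tss, 10L)
  expect_false(anyDuplicated(mcols(t0$tss)$gene_id) > 0)
  cfg2 <- tinyConfig(nPromoters = 10, nAmbiguous = 2)
  t2 <- generateTssAnnotation(cfg2)
  expect_equal(sum(mcols(t2$tss)$ambiguous), 2L)
  expect_true(all(diff(start(t2$tss)) >= 0))
  expect_true(all(width(t2$tss) == 1L))
})

test_that("signal means are ordered by planted activity stratum", {
  cfg <- tinyConfig(signalNoise = 0)
  trk <- generateSignalTracks(cfg)
  tss <- generateTssAnnotation(cfg)$tss
  tss <- tss[!mcols(tss)$ambiguous]
  win <- GRanges(seqnames(tss), IRanges(start(tss) - 400, start(tss) + 400),
                 gene_id = mcols(tss)$gene_id)
  sig <- extractPromoterSignal(trk$h3k27ac, win)
  strata <- trk$truth$activityStratum[names(sig)]
  means <- tapply(sig, strata, mean)
  expect_true(all(diff(means) > 0))
  # planted identity genes get the broad domains, centered on their TSS
  breadth <- assignH3k4me3Breadth(trk$domains, tss)
  expect_true(all(breadth[trk$truth$identityTfs] == cfg$identityBreadth))
  others <- setdiff(names(breadth), trk$truth$identityTfs)
  expect_true(all(breadth[others] == cfg$backgroundBreadth))
})

test_that("atlas plants specific, connect and ubiquitous patterns", {
  cfg <- tinyConfig(exprNoise = 0)
  atl <- generateExpressionAtlas(cfg)
  mats <- atlasMatrices(atl$atlas)
  expect_identical(sort(rownames(mats[[1]])), sort(rownames(mats[[2]])))
  truth <- atl$truth
  cts <- names(truth$tfProgram)[truth$tfProgram == "CTS"]
  expect_true(all(rowSums(mats[[1]][cts, ] > 0) == 1))
  focalCol <- mats[[1]][, focalCell(atl$atlas)]
  for (tf in truth$connectTfs)
    expect_equal(which.max(mats[[1]][tf, ]), c(MPH = 1L))
})

test_that("perturbation tables carry the planted shift and are null at 0", {
  cfg0 <- tinyConfig(fcEffectSize = -1, fcNoise = 0)
  p0 <- generatePerturbationDataset(cfg0)
  s1 <- setNames(p0$studies[[1]]$log2fc, p0$studies[[1]]$gene)
  expect_true(all(s1[p0$truth$identityTfs] == -1))
  expect_true(all(s1[setdiff(names(s1), c(p0$truth$identityTfs,
                                          p0$truth$connectTfs,
                                          p0$truth$effectorGenes))] == 0))
  # effect 0: group-shift p-values over replicated generations are uniform
  ps <- vapply(1:120, function(s) {
    cfg <- tinyConfig(fcEffectSize = 0, fcNoise = 0.3, rngSeed = s)
    pd <- generatePerturbationDataset(cfg)
    v <- setNames(pd$studies[[1]]$log2fc, pd$studies[[1]]$gene)
    groupShiftTest(v[pd$truth$identityTfs],
                   v[setdiff(names(v), pd$truth$identityTfs)], "less")
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, punif))$p.value, 0.01)
})

test_that("differentiation series has a dominant planted axis and offsets", {
  cfg <- tinyConfig(dediffNoise = 0.1)
  dd <- generateDifferentiationSeries(cfg)
  pc <- prcomp(t(dd$reference), center = TRUE)   # oracle PCA
  stages <- dd$truth$sampleInfo$stage[dd$truth$sampleInfo$study ==
                                        "reference"]
  expect_gt(abs(cor(pc$x[, 1], stages)), 0.99)
  # batch offset: anchor-mean difference equals the planted constant
  si <- dd$truth$sampleInfo
  st <- names(dd$injuries)[1]
  off <- unique(si$batchOffset[si$study == st])
  ctrl <- si$sample[si$study == st & si$anchor]
  refA <- dd$anchors$reference
  d <- mean(dd$injuries[[st]][, ctrl]) - mean(dd$reference[, refA])
  expect_equal(d, off, tolerance = 0.05)
})

test_that("ground truth round-trips through serialization", {
  cfg <- tinyConfig()
  dd <- generateDifferentiationSeries(cfg)
  truth <- dd$truth
  truth$ambiguousGenes <- generateTssAnnotation(cfg)$truth$ambiguousGenes
  path <- tempfile(fileext = ".tsv")
  writeGroundTruth(truth, path)
  back <- readGroundTruth(path)
  for (f in c("promoterCluster", "activityStratum", "identityTfs",
              "connectTfs", "effectorGenes", "tfProgram", "connectFlag",
              "ambiguousGenes"))
    expect_equal(back[[f]], truth[[f]], info = f)
  expect_equal(back$sampleInfo, truth$sampleInfo)
  # truth covers every generated promoter gene exactly once
  expect_identical(names(truth$promoterCluster),
                   sprintf("G%04d", seq_len(cfg$nPromoters)))
})
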