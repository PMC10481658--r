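#' Configuration for the synthetic-data generators
#'
#' Collects every tunable of the synthetic cistrome/expression/perturbation
#' generators in one validated object. Defaults emulate the study conditions
#' of a liver-scale promoter co-recruitment analysis: 49 regulator
#' cistromes over 925 active TF-encoding gene promoters grouped in 7 planted
#' co-binding clusters, 13 planted identity TFs and 26 planted
#' identity-connected TFs, a two-species expression atlas (39 + 126 cell
#' types over 1,009 TFs), 4 promoter activity strata, and a differentiation
#' reference series with batch-offset injury studies.
#'
#' @param nTfs number of regulator cistromes.
#' @param nPromoters number of TF-encoding gene promoters.
#' @param nBindingClusters number of planted co-binding clusters.
#' @param clusterTfSets optional list of regulator subsets, one per cluster;
#'   defaults to disjoint blocks of increasing size (cluster complexity
#'   rises with the cluster index).
#' @param bindingNoise Bernoulli flip probability for binding calls in [0,1].
#' @param tfNames optional regulator names (default \code{R01..}).
#' @param nCelltypes integer vector of cell-type counts per species
#'   (default \code{c(mouse = 39, human = 126)}).
#' @param programSizes named counts of CTS/CTE/UBQ TFs in the atlas.
#' @param nAtlasTfs size of the atlas TF universe (>= \code{nPromoters}).
#' @param nConnectPlanted number of planted identity-connected TFs.
#' @param nIdentityTfs number of planted identity TFs.
#' @param activityLevels number of planted promoter activity strata.
#' @param fcEffectSize planted perturbation shift, log2 units.
#' @param fcNoise SD of perturbation log2 fold-change noise.
#' @param exprNoise SD of atlas expression noise.
#' @param signalNoise SD of signal-track noise.
#' @param nAmbiguous number of planted ambiguous TSS records (even).
#' @param peakWidth cistrome peak width, bp.
#' @param promoterSpacing distance between promoter loci, bp; must exceed
#'   twice the largest emitted feature so features never merge across
#'   promoters.
#' @param identityBreadth,backgroundBreadth H3K4me3 domain widths (bp) for
#'   planted identity genes and background genes.
#' @param nStudies number of perturbation studies.
#' @param nEffectors number of planted identity effector (non-TF) genes.
#' @param nGenesDediff,nRefSamples,nInjuryStudies,nInjurySamples sizes of
#'   the differentiation series (genes, reference samples, injury studies,
#'   case samples per study; each study also carries as many controls).
#' @param stageShift planted dedifferentiation shift of injured samples on
#'   the latent stage scale (negative).
#' @param batchOffsetSd SD of the per-study constant batch offsets.
#' @param dediffNoise SD of differentiation-series expression noise.
#' @param rngSeed root seed; every generator derives its own stream from it.
#'
#' @return a validated list of class \code{SyntheticConfig}.
#' @examples
#' cfg <- syntheticConfig(nTfs = 6, nPromoters = 40, nBindingClusters = 2,
#'                        rngSeed = 7)
#' @export
syntheticConfig <- function(nTfs = 49L, nPromoters = 925L,
                            nBindingClusters = 7L, clusterTfSets = NULL,
                            bindingNoise = 0.02, tfNames = NULL,
                            nCelltypes = c(mouse = 39L, human = 126L),
                            programSizes = NULL, nAtlasTfs = 1009L,
                            nConnectPlanted = 26L, nIdentityTfs = 13L,
                            activityLevels = 4L, fcEffectSize = -1,
                            fcNoise = 0.3, exprNoise = 0.25,
                            signalNoise = 0.25, nAmbiguous = 2L,
                            peakWidth = 200L, promoterSpacing = NULL,
                            identityBreadth = 5000L,
                            backgroundBreadth = 1000L, nStudies = 4L,
                            nEffectors = 100L, nGenesDediff = 500L,
                            nRefSamples = 12L, nInjuryStudies = 5L,
                            nInjurySamples = 3L, stageShift = -0.5,
                            batchOffsetSd = 1, dediffNoise = 0.25,
                            rngSeed = 1L) {
  if (is.null(tfNames))
    tfNames <- sprintf("R%02d", seq_len(nTfs))
  nTfs <- length(tfNames)
  if (is.null(clusterTfSets)) {
    # disjoint blocks of increasing size: complexity grows with cluster index
    sizes <- rep(floor(nTfs / nBindingClusters), nBindingClusters)
    extra <- nTfs - sum(sizes)
    if (extra > 0)
      sizes[seq(nBindingClusters - extra + 1L, nBindingClusters)] <-
        sizes[seq(nBindingClusters - extra + 1L, nBindingClusters)] + 1L
    cum <- cumsum(c(0L, sizes))
    clusterTfSets <- lapply(seq_len(nBindingClusters), function(j)
      tfNames[seq(cum[j] + 1L, cum[j + 1L])])
  }
  if (is.null(programSizes)) {
    # CTS:CTE:UBQ split; unstated in any source, chosen once (see vignette)
    cts <- round(0.2 * nAtlasTfs); cte <- round(0.3 * nAtlasTfs)
    programSizes <- c(CTS = cts, CTE = cte, UBQ = nAtlasTfs - cts - cte)
  }
  if (is.null(promoterSpacing))
    promoterSpacing <- max(4L * peakWidth, 2L * identityBreadth)
  cfg <- list(nTfs = as.integer(nTfs), nPromoters = as.integer(nPromoters),
              nBindingClusters = as.integer(nBindingClusters),
              clusterTfSets = clusterTfSets,
              bindingNoise = bindingNoise, tfNames = tfNames,
              nCelltypes = as.integer(nCelltypes),
              programSizes = programSizes,
              nAtlasTfs = as.integer(nAtlasTfs),
              nConnectPlanted = as.integer(nConnectPlanted),
              nIdentityTfs = as.integer(nIdentityTfs),
              activityLevels = as.integer(activityLevels),
              fcEffectSize = fcEffectSize, fcNoise = fcNoise,
              exprNoise = exprNoise, signalNoise = signalNoise,
              nAmbiguous = as.integer(nAmbiguous),
              peakWidth = as.integer(peakWidth),
              promoterSpacing = as.integer(promoterSpacing),
              identityBreadth = as.integer(identityBreadth),
              backgroundBreadth = as.integer(backgroundBreadth),
              nStudies = as.integer(nStudies),
              nEffectors = as.integer(nEffectors),
              nGenesDediff = as.integer(nGenesDediff),
              nRefSamples = as.integer(nRefSamples),
              nInjuryStudies = as.integer(nInjuryStudies),
              nInjurySamples = as.integer(nInjurySamples),
              stageShift = stageShift, batchOffsetSd = batchOffsetSd,
              dediffNoise = dediffNoise, rngSeed = as.integer(rngSeed))
  class(cfg) <- "SyntheticConfig"
  validateSyntheticConfig(cfg)
  cfg
}

validateSyntheticConfig <- function(cfg) {
  counts <- c("nTfs", "nPromoters", "nBindingClusters", "activityLevels",
              "nAtlasTfs", "nConnectPlanted", "nIdentityTfs", "peakWidth",
              "promoterSpacing", "nStudies", "nGenesDediff", "nRefSamples",
              "nInjuryStudies", "nInjurySamples")
  for (f in counts)
    stopIfNot(length(cfg[[f]]) == 1L && cfg[[f]] > 0L,
              paste0("configuration error: ", f, " must be a positive count"))
  for (f in c("bindingNoise"))
    stopIfNot(cfg[[f]] >= 0 && cfg[[f]] <= 1,
              paste0("configuration error: ", f, " must lie in [0,1]"))
  bad <- setdiff(unlist(cfg$clusterTfSets), cfg$tfNames)
  stopIfNot(length(bad) == 0L,
            paste0("configuration error: clusterTfSets reference unknown ",
                   "regulators: ", paste(bad, collapse = ", ")))
  stopIfNot(length(cfg$clusterTfSets) == cfg$nBindingClusters,
            "configuration error: one TF set per binding cluster required")
  stopIfNot(sum(cfg$programSizes) <= cfg$nAtlasTfs,
            "configuration error: program sizes exceed the atlas TF universe")
  stopIfNot(cfg$nAtlasTfs >= cfg$nPromoters,
            "configuration error: nAtlasTfs must cover the promoter genes")
  stopIfNot(cfg$nAmbiguous %% 2L == 0L,
            "configuration error: nAmbiguous must be even")
  invisible(cfg)
}

# Gene identifiers shared by all generators.
promoterGeneIds <- function(n) sprintf("G%04d", seq_len(n))
effectorGeneIds <- function(n) sprintf("E%04d", seq_len(n))
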