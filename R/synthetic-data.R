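#' @include synthetic-config.R
NULL

# ---- planted ground truth -------------------------------------------------

#' Planted ground truth for a synthetic configuration
#'
#' Deterministic function of the configuration (no RNG): promoter -> planted
#' co-binding cluster (contiguous blocks of increasing complexity), gene ->
#' planted activity stratum (cyclic over gene index), the planted identity
#' and identity-connected TF sets (taken from the most complex cluster),
#' and TF -> planted expression program over the atlas universe.
#'
#' @param config a \code{\link{syntheticConfig}} object.
#' @return a list of class \code{GroundTruth}.
#' @export
groundTruth <- function(config) {
  cfg <- validateSyntheticConfig(config)
  genes <- promoterGeneIds(cfg$nPromoters)
  k <- cfg$nBindingClusters
  block <- ceiling(cfg$nPromoters / k)
  promoterCluster <- setNames(pmin(((seq_len(cfg$nPromoters) - 1L) %/%
                                      block) + 1L, k), genes)
  lastBlock <- genes[promoterCluster == k]
  nId <- min(cfg$nIdentityTfs, length(lastBlock))
  identityTfs <- lastBlock[seq_len(nId)]
  nCo <- min(cfg$nConnectPlanted, max(0L, length(lastBlock) - nId))
  connectTfs <- lastBlock[nId + seq_len(nCo)]

  effectors <- effectorGeneIds(cfg$nEffectors)
  allStrat <- c(genes, effectors)
  activityStratum <- setNames(((seq_along(allStrat) - 1L) %%
                                 cfg$activityLevels) + 1L, allStrat)

  atlasIds <- promoterGeneIds(cfg$nAtlasTfs)
  tfProgram <- setNames(rep(NA_character_, cfg$nAtlasTfs), atlasIds)
  tfProgram[identityTfs] <- "CTS"
  tfProgram[connectTfs] <- "CTE"
  remaining <- atlasIds[is.na(tfProgram)]
  want <- c(CTS = cfg$programSizes[["CTS"]] - sum(tfProgram == "CTS",
                                                  na.rm = TRUE),
            CTE = cfg$programSizes[["CTE"]] - sum(tfProgram == "CTE",
                                                  na.rm = TRUE),
            UBQ = cfg$programSizes[["UBQ"]])
  want <- pmax(want, 0L)
  lab <- rep(c("CTS", "CTE", "UBQ"), times = want)
  lab <- c(lab, rep("UBQ", max(0L, length(remaining) - length(lab))))
  tfProgram[remaining] <- lab[seq_along(remaining)]

  truth <- list(promoterCluster = promoterCluster,
                activityStratum = activityStratum,
                identityTfs = identityTfs,
                connectTfs = connectTfs,
                effectorGenes = effectors,
                tfProgram = tfProgram,
                connectFlag = setNames(atlasIds %in% connectTfs, atlasIds),
                ambiguousGenes = character(0),
                sampleInfo = NULL)
  class(truth) <- "GroundTruth"
  truth
}

promoterCenters <- function(cfg) {
  as.integer(seq_len(cfg$nPromoters)) * cfg$promoterSpacing
}

# ---- cistromes ------------------------------------------------------------

#' Generate synthetic per-TF cistromes with planted co-binding clusters
#'
#' Each promoter locus receives one peak from every regulator of its planted
#' cluster's TF set; with probability \code{bindingNoise} each
#' (promoter, regulator) membership is flipped (spurious additions and
#' drop-outs). Peaks are \code{peakWidth}-bp intervals centered on the
#' promoter TSS on the synthetic chromosome \code{chrS}.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return list with \code{cistromes} (named \code{GRangesList}, one element
#'   per regulator), \code{membership} (binary promoter x regulator matrix
#'   of planted-plus-noise binding), \code{promoters} (\code{GRanges} of the
#'   loci with \code{gene_id} and planted \code{cluster}), and \code{truth}.
#' @examples
#' cfg <- syntheticConfig(nTfs = 4, nPromoters = 8, nBindingClusters = 2,
#'                        bindingNoise = 0, rngSeed = 1)
#' cis <- generateCistromes(cfg)
#' lengths(cis$cistromes)
#' @export
generateCistromes <- function(config) {
  cfg <- validateSyntheticConfig(config)
  truth <- groundTruth(cfg)
  centers <- promoterCenters(cfg)
  genes <- names(truth$promoterCluster)
  planted <- matrix(0L, cfg$nPromoters, cfg$nTfs,
                    dimnames = list(genes, cfg$tfNames))
  for (j in seq_len(cfg$nBindingClusters))
    planted[truth$promoterCluster == j, cfg$clusterTfSets[[j]]] <- 1L
  membership <- withSeed(deriveSeed(cfg$rngSeed, 1L), {
    flips <- matrix(rbinom(length(planted), 1L, cfg$bindingNoise),
                    nrow(planted))
    (planted + flips) %% 2L
  })
  dimnames(membership) <- dimnames(planted)
  half <- cfg$peakWidth %/% 2L
  cistromes <- GRangesList(lapply(setNames(cfg$tfNames, cfg$tfNames),
    function(tf) {
      idx <- which(membership[, tf] == 1L)
      GRanges("chrS", IRanges(start = centers[idx] - half,
                              width = cfg$peakWidth))
    }))
  promoters <- GRanges("chrS", IRanges(start = centers, width = 1L),
                       gene_id = genes,
                       cluster = unname(truth$promoterCluster))
  list(cistromes = cistromes, membership = membership,
       promoters = promoters, truth = truth)
}

# ---- TSS annotation -------------------------------------------------------

#' Generate the active-TSS annotation, with planted ambiguous records
#'
#' One width-1 TSS per promoter locus carrying its gene id, plus
#' \code{nAmbiguous} extra records planted on dedicated loci beyond the
#' promoter array: alternating cases of one TSS shared by two gene ids and
#' one gene id carrying two TSSs (both directions of non-unique TSS-gene
#' association, which downstream mapping discards).
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return list with \code{tss} (sorted \code{GRanges} with \code{gene_id}
#'   and \code{ambiguous} flag) and \code{truth} (with
#'   \code{ambiguousGenes} filled in).
#' @export
generateTssAnnotation <- function(config) {
  cfg <- validateSyntheticConfig(config)
  truth <- groundTruth(cfg)
  centers <- promoterCenters(cfg)
  genes <- names(truth$promoterCluster)
  pos <- centers
  ids <- genes
  amb <- rep(FALSE, length(genes))
  nextPos <- centers[length(centers)] + cfg$promoterSpacing
  nPairs <- cfg$nAmbiguous %/% 2L
  for (j in seq_len(nPairs)) {
    if (j %% 2L == 1L) {            # one TSS <-> two genes
      pos <- c(pos, nextPos, nextPos)
      ids <- c(ids, sprintf("AMBS%02da", j), sprintf("AMBS%02db", j))
      nextPos <- nextPos + cfg$promoterSpacing
    } else {                        # one gene <-> two TSSs
      pos <- c(pos, nextPos, nextPos + cfg$promoterSpacing %/% 2L)
      ids <- c(ids, rep(sprintf("AMBM%02d", j), 2L))
      nextPos <- nextPos + cfg$promoterSpacing
    }
    amb <- c(amb, TRUE, TRUE)
  }
  o <- order(pos, ids)
  tss <- GRanges("chrS", IRanges(start = pos[o], width = 1L),
                 gene_id = ids[o], ambiguous = amb[o])
  truth$ambiguousGenes <- unique(ids[amb])
  list(tss = tss, truth = truth)
}

# ---- signal tracks --------------------------------------------------------

#' Generate activity-correlated signal tracks and H3K4me3 domains
#'
#' Binned (50 bp) bedGraph-style tracks over each promoter's +/- 500 bp
#' window for DHS, H3K27ac and H3K4me3: the per-bin mean equals the
#' promoter's planted activity stratum (1..\code{activityLevels}) plus
#' i.i.d. Gaussian noise. A constant unit \code{control} track covers the
#' same windows. Planted identity genes receive H3K4me3 domains of width
#' \code{identityBreadth}, all other promoters \code{backgroundBreadth},
#' centered on the TSS.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @param truth a \code{GroundTruth} carrying activity strata (defaults to
#'   \code{groundTruth(config)}).
#' @return list with \code{dhs}, \code{h3k27ac}, \code{h3k4me3},
#'   \code{control} (scored \code{GRanges} tracks), \code{domains}
#'   (\code{GRanges}), \code{expression} (a stratum-correlated per-gene
#'   expression level completing the activity-feature triplet) and
#'   \code{truth}.
#' @export
generateSignalTracks <- function(config, truth = groundTruth(config)) {
  cfg <- validateSyntheticConfig(config)
  stopIfNot(!is.null(truth$activityStratum),
            "truth must contain activity strata")
  centers <- promoterCenters(cfg)
  genes <- promoterGeneIds(cfg$nPromoters)
  strata <- truth$activityStratum[genes]
  binw <- 50L; nbin <- 20L
  starts <- as.vector(vapply(centers, function(ct)
    ct - 500L + binw * (seq_len(nbin) - 1L), numeric(nbin)))
  bins <- GRanges("chrS", IRanges(start = starts, width = binw))
  base <- rep(as.numeric(strata), each = nbin)
  mkTrack <- function(offsetSeed) {
    score <- withSeed(deriveSeed(cfg$rngSeed, offsetSeed),
                      base + rnorm(length(base), 0, cfg$signalNoise))
    tr <- bins
    mcols(tr)$score <- score
    tr
  }
  control <- bins
  mcols(control)$score <- rep(1, length(bins))
  widths <- ifelse(genes %in% truth$identityTfs,
                   cfg$identityBreadth, cfg$backgroundBreadth)
  domains <- GRanges("chrS", IRanges(start = centers - widths %/% 2L,
                                     width = widths))
  expression <- withSeed(deriveSeed(cfg$rngSeed, 34L),
    setNames(pmax(as.numeric(strata) +
                    rnorm(length(strata), 0, cfg$signalNoise), 0), genes))
  list(dhs = mkTrack(31L), h3k27ac = mkTrack(32L), h3k4me3 = mkTrack(33L),
       control = control, domains = domains, expression = expression,
       truth = truth)
}

# ---- expression atlas -----------------------------------------------------

#' Generate a two-species expression atlas with planted programs
#'
#' TFs follow their planted program: CTS TFs are expressed in exactly one
#' home cell type per species, CTE TFs in a small subset (3 cells) with low
#' background, UBQ TFs uniformly. Planted identity-connected TFs are CTE
#' TFs whose subset includes the focal cell ("MPH", species 1) with a
#' boosted focal value, so that by construction the focal cell ranks first
#' and the log2 fold-difference versus the mean of the other cells is
#' positive. Gaussian noise (truncated at 0) is added everywhere.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return list with \code{atlas} (an \code{\link{ExpressionAtlas}}) and
#'   \code{truth}.
#' @export
generateExpressionAtlas <- function(config) {
  cfg <- validateSyntheticConfig(config)
  truth <- groundTruth(cfg)
  ids <- names(truth$tfProgram)
  sp <- names(cfg$nCelltypes)
  if (is.null(sp)) sp <- paste0("species", seq_along(cfg$nCelltypes))
  cellNames <- list(c("MPH", sprintf("MC%02d", seq_len(cfg$nCelltypes[[1L]]
                                                        ) + 1L)[
                       seq_len(cfg$nCelltypes[[1L]] - 1L)]),
                    if (length(cfg$nCelltypes) > 1L)
                      sprintf("HC%03d", seq_len(cfg$nCelltypes[[2L]])))
  cellNames <- cellNames[!vapply(cellNames, is.null, TRUE)]
  mats <- withSeed(deriveSeed(cfg$rngSeed, 4L), {
    lapply(seq_along(cellNames), function(s) {
      cells <- cellNames[[s]]
      nc <- length(cells)
      m <- matrix(0, length(ids), nc, dimnames = list(ids, cells))
      for (i in seq_along(ids)) {
        prog <- truth$tfProgram[[i]]
        isConnect <- truth$connectFlag[[i]]
        isIdentity <- ids[i] %in% truth$identityTfs
        if (prog == "CTS") {
          home <- if (isIdentity) 1L else (i %% (nc - 1L)) + 2L
          m[i, home] <- 10
        } else if (prog == "CTE") {
          if (isConnect) {
            others <- ((i + seq_len(2L)) %% (nc - 1L)) + 2L
            m[i, ] <- 1
            m[i, others] <- 3
            m[i, 1L] <- 12   # focal (first cell) boosted: rank 1, FC > 0
          } else {
            subset <- ((i + seq_len(3L)) %% (nc - 1L)) + 2L
            m[i, ] <- 1
            m[i, subset] <- 8
          }
        } else {
          m[i, ] <- 5
        }
      }
      if (cfg$exprNoise > 0)
        m <- pmax(m + matrix(rnorm(length(m), 0, cfg$exprNoise), nrow(m)), 0)
      m
    })
  })
  names(mats) <- sp[seq_along(mats)]
  atlas <- new("ExpressionAtlas", matrices = mats, focalCell = "MPH")
  list(atlas = atlas, truth = truth)
}

# ---- perturbation datasets ------------------------------------------------

#' Generate per-study log2 fold-change tables with a planted group shift
#'
#' Planted identity TFs and identity effector genes receive a mean shift of
#' \code{fcEffectSize} log2 units, planted identity-connected TFs half that
#' shift (their responses track the identity program with lower amplitude),
#' and all other genes mean 0, with i.i.d. Gaussian noise of SD
#' \code{fcNoise} per study.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @param truth a \code{GroundTruth} defining the gene groups.
#' @return list with \code{studies} (named list of data.frames with columns
#'   \code{gene}, \code{log2fc}) and \code{truth}.
#' @export
generatePerturbationDataset <- function(config,
                                        truth = groundTruth(config)) {
  cfg <- validateSyntheticConfig(config)
  genes <- c(promoterGeneIds(cfg$nPromoters), truth$effectorGenes)
  shift <- setNames(rep(0, length(genes)), genes)
  shift[truth$identityTfs] <- cfg$fcEffectSize
  shift[truth$effectorGenes] <- cfg$fcEffectSize
  shift[truth$connectTfs] <- cfg$fcEffectSize / 2
  studies <- withSeed(deriveSeed(cfg$rngSeed, 5L), {
    lapply(seq_len(cfg$nStudies), function(j)
      data.frame(gene = genes,
                 log2fc = shift + rnorm(length(genes), 0, cfg$fcNoise),
                 row.names = NULL))
  })
  names(studies) <- sprintf("study%02d", seq_len(cfg$nStudies))
  list(studies = studies, truth = truth)
}

# ---- differentiation series ----------------------------------------------

#' Generate a differentiation reference series plus batch-offset injury
#' samples
#'
#' Reference samples vary along one dominant latent axis (the planted stage
#' score, 0 = immature to 1 = mature); the most mature quarter of the
#' samples is labeled as the "adult" anchor group. Each injury study
#' contributes control samples at stage 1 (its anchors) and injured samples
#' shifted negatively on the stage scale (severity varies per sample,
#' uniformly within 0.5-1.5 times \code{stageShift}), with one constant
#' batch offset per study added to every value of that study.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return list with \code{reference} (genes x samples matrix),
#'   \code{injuries} (named list of genes x samples matrices),
#'   \code{anchors} (named list: reference anchor sample names and per-study
#'   control sample names), and \code{truth} with \code{sampleInfo}.
#' @export
generateDifferentiationSeries <- function(config) {
  cfg <- validateSyntheticConfig(config)
  truth <- groundTruth(cfg)
  genes <- sprintf("D%04d", seq_len(cfg$nGenesDediff))
  out <- withSeed(deriveSeed(cfg$rngSeed, 6L), {
    load <- rnorm(cfg$nGenesDediff)
    base <- rnorm(cfg$nGenesDediff, 5, 1)
    mkSample <- function(stage)
      base + load * stage * 5 + rnorm(cfg$nGenesDediff, 0, cfg$dediffNoise)
    stages <- seq(0, 1, length.out = cfg$nRefSamples)
    refNames <- sprintf("ref%02d", seq_len(cfg$nRefSamples))
    reference <- vapply(stages, mkSample, numeric(cfg$nGenesDediff))
    dimnames(reference) <- list(genes, refNames)
    nAnchor <- max(1L, ceiling(cfg$nRefSamples / 4))
    refAnchors <- refNames[order(stages, decreasing = TRUE)[seq_len(nAnchor)]]
    info <- data.frame(sample = refNames, study = "reference",
                       stage = stages, batchOffset = 0,
                       anchor = refNames %in% refAnchors)
    injuries <- list(); injAnchors <- list()
    for (j in seq_len(cfg$nInjuryStudies)) {
      off <- rnorm(1L, 0, cfg$batchOffsetSd)
      ctrl <- sprintf("inj%02d_ctrl%d", j, seq_len(cfg$nInjurySamples))
      case <- sprintf("inj%02d_case%d", j, seq_len(cfg$nInjurySamples))
      # injury severity varies between animals: each case sample gets its
      # own dedifferentiation shift around the planted study-level shift
      stg <- c(rep(1, cfg$nInjurySamples),
               1 + cfg$stageShift * runif(cfg$nInjurySamples, 0.5, 1.5))
      m <- vapply(stg, mkSample, numeric(cfg$nGenesDediff)) + off
      dimnames(m) <- list(genes, c(ctrl, case))
      injuries[[sprintf("injury%02d", j)]] <- m
      injAnchors[[sprintf("injury%02d", j)]] <- ctrl
      info <- rbind(info, data.frame(sample = c(ctrl, case),
                                     study = sprintf("injury%02d", j),
                                     stage = stg, batchOffset = off,
                                     anchor = c(ctrl, case) %in% ctrl))
    }
    list(reference = reference, injuries = injuries,
         refAnchors = refAnchors, injAnchors = injAnchors, info = info)
  })
  truth$sampleInfo <- out$info
  list(reference = out$reference, injuries = out$injuries,
       anchors = c(list(reference = out$refAnchors), out$injAnchors),
       truth = truth)
}
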