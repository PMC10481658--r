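# Activity-matched control gene sets: promoter activity strata, stratified
# resampling without replacement, representative-set selection at the mode
# of the p-value distribution, and the rank-based group tests used
# downstream.

#' Stratify genes by promoter activity
#'
#' Per-feature \code{log2(x + pseudocount)} then z-scaling, Ward clustering
#' (\code{ward.D2}) into \code{k} strata, numbered by ascending mean scaled
#' activity (stratum 1 = least active).
#'
#' @param features numeric matrix or data.frame, genes x features
#'   (accessibility, acetylation, expression), rownames = gene ids.
#' @param k number of strata (default 4).
#' @param pseudocount added before the log (default 0.01).
#' @return named integer vector, gene -> stratum 1..k.
#' @export
activityStrata <- function(features, k = 4L, pseudocount = 0.01) {
  stopIfNot(k >= 2L, "input error: k must be >= 2")
  m <- as.matrix(features)
  stopIfNot(!is.null(rownames(m)), "input error: features need gene ids")
  if (anyNA(m)) {
    bad <- rownames(m)[apply(m, 1L, anyNA)]
    stop("input error: missing feature for gene(s): ",
         paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  lm_ <- log2(m + pseudocount)
  if (nrow(unique(lm_)) < k)
    stop("degenerate input: fewer than k distinct feature profiles",
         call. = FALSE)
  sds <- apply(lm_, 2L, sd)
  z <- sweep(sweep(lm_, 2L, colMeans(lm_)), 2L, ifelse(sds > 0, sds, 1),
             "/")
  cl <- cutree(hclust(dist(z), method = "ward.D2"), k = k)
  act <- tapply(rowMeans(z), cl, mean)
  relabel <- setNames(seq_len(k), names(sort(act)))
  setNames(as.integer(relabel[as.character(cl)]), rownames(m))
}

#' Sample activity-matched control gene sets
#'
#' Each iteration draws, within every stratum, exactly as many candidate
#' genes as the identity set has in that stratum, without replacement
#' within the iteration and always excluding the identity genes.
#'
#' @param identityGenes character vector of identity genes.
#' @param candidatePool character vector of eligible control genes
#'   (identity genes are removed if present).
#' @param strata named integer vector covering identity and candidates.
#' @param nIter number of iterations (default 1000).
#' @param seed RNG seed.
#' @return a \code{\link{ControlSetEnsemble}} (p-values unset).
#' @export
sampleMatchedControls <- function(identityGenes, candidatePool, strata,
                                  nIter = 1000L, seed = 1L) {
  stopIfNot(nIter >= 1L, "input error: nIter must be >= 1")
  candidatePool <- setdiff(candidatePool, identityGenes)
  miss <- setdiff(c(identityGenes, candidatePool), names(strata))
  stopIfNot(length(miss) == 0L,
            paste("input error: no stratum for:",
                  paste(head(miss, 5L), collapse = ", ")))
  idStrat <- strata[identityGenes]
  need <- table(idStrat)
  poolByStrat <- split(candidatePool, strata[candidatePool])
  for (s in names(need)) {
    have <- length(poolByStrat[[s]])
    if (is.null(poolByStrat[[s]]) || have < need[[s]])
      stop("insufficient candidates in stratum ", s, ": need ", need[[s]],
           ", have ", have, call. = FALSE)
  }
  sets <- withSeed(seed, {
    lapply(seq_len(nIter), function(i) {
      unname(unlist(lapply(names(need), function(s)
        sample(poolByStrat[[s]], need[[s]]))))
    })
  })
  new("ControlSetEnsemble", identity = identityGenes, sets = sets,
      pvalues = rep(NA_real_, nIter), representative = NA_integer_)
}

#' Select the representative control set at the p-value mode
#'
#' Computes one p-value per control set (identity values against control
#' values) and selects the set whose p-value sits at the mode of the
#' p-value distribution. Rank-test p-values are discrete, so by default
#' the mode is the most frequent exact p-value (ties broken towards the
#' smaller value); the representative is the set whose p is closest to the
#' mode (ties towards the lowest set index). A fixed-width histogram mode
#' is available through \code{binWidth}; it is not the default because the
#' discreteness of rank-test p-values concentrates binned counts at the
#' extremes of the distribution rather than at its bulk.
#'
#' @param ensemble a \code{\link{ControlSetEnsemble}}.
#' @param values named numeric vector covering identity and control genes
#'   (e.g. log2 fold changes).
#' @param statFn function(identityValues, controlValues) -> p-value;
#'   defaults to a two-sided Wilcoxon rank-sum test.
#' @param binWidth optional histogram bin width (e.g. 0.01); \code{NULL}
#'   (default) uses the exact discrete mode.
#' @return the ensemble with \code{pvalues} and \code{representative}
#'   filled in.
#' @export
selectRepresentativeSet <- function(ensemble, values, statFn = NULL,
                                    binWidth = NULL) {
  if (is.null(statFn))
    statFn <- function(a, b) groupShiftTest(a, b, "two.sided")
  idVals <- values[ensemble@identity]
  p <- vapply(ensemble@sets, function(s) statFn(idVals, values[s]),
              numeric(1L))
  if (is.null(binWidth)) {
    tab <- table(p)
    modal <- min(as.numeric(names(tab)[tab == max(tab)]))
  } else {
    nbin <- ceiling(1 / binWidth)
    bin <- pmin(pmax(floor(p / binWidth) + 1L, 1L), nbin)
    counts <- tabulate(bin, nbins = nbin)
    modal <- (which.max(counts) - 0.5) * binWidth   # ties -> lower bin
  }
  rep_ <- which.min(abs(p - modal))                 # ties -> lowest index
  ensemble@pvalues <- p
  ensemble@representative <- as.integer(rep_)
  validObject(ensemble)
  ensemble
}

#' Wilcoxon rank-sum group-shift test
#'
#' Exact enumeration when both samples are small (min n <= 10) and free of
#' ties; normal approximation with continuity correction otherwise.
#' Degenerate all-tied input returns p = 1 with a warning.
#'
#' @param valuesA,valuesB numeric samples.
#' @param alternative "two.sided", "less" or "greater" (A relative to B).
#' @param paired use the signed-rank test for paired samples.
#' @return the p-value.
#' @export
groupShiftTest <- function(valuesA, valuesB,
                           alternative = c("two.sided", "less", "greater"),
                           paired = FALSE) {
  alternative <- match.arg(alternative)
  stopIfNot(length(valuesA) > 0L && length(valuesB) > 0L,
            "input error: both groups must be non-empty")
  if (length(unique(c(valuesA, valuesB))) == 1L) {
    warning("degenerate all-tied data; p = 1")
    return(1)
  }
  ties <- anyDuplicated(c(valuesA, valuesB)) > 0L
  exact <- !ties && min(length(valuesA), length(valuesB)) <= 10L && !paired
  suppressWarnings(wilcox.test(valuesA, valuesB,
                               alternative = alternative, paired = paired,
                               exact = exact, correct = TRUE))$p.value
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate control.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values, same order as the input.
#' @export
bhAdjust <- function(p) {
  stopIfNot(all(p >= 0 & p <= 1, na.rm = TRUE),
            "input error: p-values must lie in [0,1]")
  p.adjust(p, method = "BH")
}

#' Log2 odds ratio with Fisher exact test
#'
#' Sample odds ratio \code{(a d) / (b c)} for the 2x2 table
#' (in-group hits/misses vs out-group hits/misses), with the
#' Haldane-Anscombe 0.5 correction applied when any cell is 0; the
#' two-sided Fisher exact p-value is computed on the uncorrected table.
#' A zero table margin yields \code{NA} (undefined).
#'
#' @param inHits,inMisses,outHits,outMisses non-negative integer cells.
#' @return list with \code{log2OR} and \code{p.value}.
#' @export
enrichmentOddsRatio <- function(inHits, inMisses, outHits, outMisses) {
  cells <- c(inHits, inMisses, outHits, outMisses)
  stopIfNot(all(cells >= 0) && all(cells == round(cells)),
            "input error: cells must be non-negative integers")
  tab <- matrix(cells, 2L, 2L, byrow = TRUE)
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
    return(list(log2OR = NA_real_, p.value = NA_real_))
  h <- if (any(cells == 0L)) cells + 0.5 else cells
  or <- (h[1L] * h[4L]) / (h[2L] * h[3L])
  list(log2OR = log2(or), p.value = fisher.test(tab)$p.value)
}

#' Kruskal-Wallis omnibus with BH-corrected pairwise rank-sum tests
#'
#' Kruskal-Wallis H (tie-corrected) over all groups, followed by all
#' pairwise Wilcoxon rank-sum comparisons adjusted with
#' Benjamini-Hochberg across the pairwise family.
#'
#' @param groups named list of numeric vectors.
#' @param alternative passed to the pairwise tests (default two-sided).
#' @return list with \code{omnibus.p}, \code{pairwise} (data.frame with
#'   \code{groupA}, \code{groupB}, \code{p}, \code{q}).
#' @export
kruskalPairwise <- function(groups, alternative = "two.sided") {
  stopIfNot(length(groups) >= 2L && all(lengths(groups) > 0L),
            "input error: need >= 2 non-empty groups")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  om <- kruskal.test(groups)$p.value
  pairs <- combn(names(groups), 2L)
  p <- apply(pairs, 2L, function(gg)
    groupShiftTest(groups[[gg[1L]]], groups[[gg[2L]]], alternative))
  pw <- data.frame(groupA = pairs[1L, ], groupB = pairs[2L, ], p = p,
                   q = bhAdjust(p))
  list(omnibus.p = om, pairwise = pw)
}
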