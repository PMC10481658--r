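# TF expression-program classification: expression deciles, tissue
# specificity (Tau), multiple factor analysis of multi-species atlases with
# a Ward cut into CTS/CTE/UBQ programs, and selection of identity-connected
# TFs by focal-cell rank and fold-difference.

#' Split genes into expression deciles
#'
#' Deciles of ascending value; bin populations differ by at most one (the
#' remainder goes to the lowest deciles), ties broken by the stable input
#' gene order. Decile 10 holds the highest values.
#'
#' @param values named numeric vector, gene -> expression.
#' @return named integer vector, gene -> decile 1..10.
#' @export
expressionDeciles <- function(values) {
  n <- length(values)
  stopIfNot(n >= 10L, "input error: at least 10 genes required")
  ord <- order(values, seq_len(n))      # stable: ties keep input order
  base <- n %/% 10L; extra <- n %% 10L
  sizes <- rep(base, 10L) + c(rep(1L, extra), rep(0L, 10L - extra))
  dec <- rep(seq_len(10L), times = sizes)
  out <- integer(n)
  out[ord] <- dec
  setNames(out, names(values))
}

#' Log2 specificity ratio of focal versus other tissues
#'
#' \code{log2((focal + eps) / (mean(others) + eps))}.
#'
#' @param focal expression in the focal tissue (scalar or vector).
#' @param others numeric vector of expression in the other tissues.
#' @param pseudocount eps added to both terms (default 0.01).
#' @return log2 ratio.
#' @export
specificityRatio <- function(focal, others, pseudocount = 0.01) {
  log2((focal + pseudocount) / (mean(others) + pseudocount))
}

#' Two-sample KS test on decile distributions
#'
#' Two-sided two-sample Kolmogorov-Smirnov D and asymptotic p-value
#' between a gene subset's decile values and the background's.
#'
#' @param subsetDeciles,backgroundDeciles numeric vectors of decile values.
#' @return list with \code{statistic} (D) and \code{p.value}.
#' @export
decileDistributionTest <- function(subsetDeciles, backgroundDeciles) {
  stopIfNot(length(subsetDeciles) > 0L && length(backgroundDeciles) > 0L,
            "input error: both samples must be non-empty")
  kt <- suppressWarnings(ks.test(subsetDeciles, backgroundDeciles,
                                 exact = FALSE))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

#' Tau index of tissue-specific expression
#'
#' \code{Tau = sum(1 - x_i / max(x)) / (n - 1)}: 1 for single-tissue
#' expression, 0 for a perfectly uniform profile.
#'
#' @param expr non-negative expression vector over >= 2 tissues.
#' @return Tau in [0, 1], or \code{NA} for an all-zero profile.
#' @export
computeTau <- function(expr) {
  stopIfNot(length(expr) >= 2L, "input error: need >= 2 tissues")
  stopIfNot(all(expr >= 0), "input error: expression must be >= 0")
  mx <- max(expr)
  if (mx == 0) return(NA_real_)
  sum(1 - expr / mx) / (length(expr) - 1L)
}

#' Multiple factor analysis of grouped variables
#'
#' Each group's columns are centered and unit-scaled, the group is weighted
#' by the inverse of its first PCA eigenvalue (so no single table dominates
#' the compromise), and a global PCA (SVD) is run on the weighted
#' concatenation. Row (TF) scores, per-group weights and explained-variance
#' fractions are returned.
#'
#' @param groups named list of numeric matrices sharing rownames (the TFs).
#' @param nComponents number of components to keep (default 5).
#' @return list with \code{scores} (TF x components), \code{groupWeights},
#'   \code{varExplained} (fractions, non-increasing) and \code{loadings}.
#' @export
mfa <- function(groups, nComponents = 5L) {
  stopIfNot(length(groups) >= 1L, "input error: at least one group")
  rn <- rownames(groups[[1L]])
  for (g in groups)
    stopIfNot(identical(sort(rownames(g)), sort(rn)),
              "input error: groups must share the TF universe")
  scaled <- lapply(seq_along(groups), function(i) {
    g <- as.matrix(groups[[i]])[rn, , drop = FALSE]
    sds <- apply(g, 2L, sd)
    if (any(sds == 0)) {
      bad <- colnames(g)[sds == 0]
      stop("input error: constant column(s) in group ",
           if (!is.null(names(groups))) names(groups)[i] else i, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    scale(g)
  })
  weights <- vapply(scaled, function(g) {
    lambda1 <- svd(g, nu = 0L, nv = 0L)$d[1L]^2 / (nrow(g) - 1L)
    1 / lambda1
  }, numeric(1L))
  x <- do.call(cbind, lapply(seq_along(scaled), function(i)
    scaled[[i]] * sqrt(weights[i])))
  sv <- svd(x)
  nComponents <- min(nComponents, length(sv$d))
  scores <- sv$u[, seq_len(nComponents), drop = FALSE] %*%
    diag(sv$d[seq_len(nComponents)], nComponents)
  rownames(scores) <- rn
  colnames(scores) <- paste0("comp", seq_len(nComponents))
  names(weights) <- names(groups)
  list(scores = scores, groupWeights = weights,
       varExplained = (sv$d^2 / sum(sv$d^2))[seq_len(nComponents)],
       loadings = sv$v[, seq_len(nComponents), drop = FALSE])
}

#' Cluster TFs into expression programs (CTS / CTE / UBQ)
#'
#' Ward cut (\code{ward.D2}) of the MFA row scores into \code{k} clusters.
#' Labels are assigned by the ascending mean number of cell types in which
#' a TF is highly expressed (> 25% of its own maximum, pooled over all
#' atlas matrices): the cluster with the fewest such cell types is CTS, the
#' one with the most is UBQ.
#'
#' @param scores TF x component score matrix from \code{\link{mfa}}.
#' @param atlas an \code{\link{ExpressionAtlas}} (used only for the
#'   label-ordering statistic).
#' @param k number of programs (default 3).
#' @return named character vector, TF -> label in CTS/CTE/UBQ (for k > 3,
#'   intermediate clusters are labeled CTE1, CTE2, ...).
#' @export
clusterTfPrograms <- function(scores, atlas, k = 3L) {
  stopIfNot(k >= 2L && k <= nrow(scores),
            "input error: k must lie in [2, number of TFs]")
  cl <- cutree(hclust(dist(scores), method = "ward.D2"), k = k)
  expr <- do.call(cbind, atlasMatrices(atlas))[rownames(scores), ,
                                               drop = FALSE]
  nHigh <- rowSums(sweep(expr, 1L, 0.25 * apply(expr, 1L, max), ">"))
  ordStat <- tapply(nHigh, cl, mean)
  labs <- if (k == 3L) c("CTS", "CTE", "UBQ") else
    c("CTS", paste0("CTE", seq_len(k - 2L)), "UBQ")
  relabel <- setNames(labs, names(sort(ordStat)))
  setNames(unname(relabel[as.character(cl)]), rownames(scores))
}

#' Select identity-connected TFs by focal-cell rank and fold-difference
#'
#' For each TF, cells of the focal species are ranked by decreasing
#' expression (rank 1 = highest; ties receive the average rank, then the
#' focal rank is ceiled); the fold-difference is
#' \code{log2((focal + eps) / (mean(others) + eps))}. A TF is selected when
#' its focal rank is <= \code{rankThreshold} and the fold-difference is
#' positive.
#'
#' @param atlas an \code{\link{ExpressionAtlas}} with a focal cell.
#' @param focalCellName focal cell-type column (defaults to the atlas').
#' @param rankThreshold maximum focal rank (default 10).
#' @param pseudocount eps for the log ratio (default 0.01).
#' @param tfSubset optional TF ids to restrict to (e.g. the CTE/UBQ TFs of
#'   one promoter cluster).
#' @return data.frame with columns \code{tf}, \code{rank},
#'   \code{log2fd} and \code{selected}.
#' @export
selectConnectTfs <- function(atlas, focalCellName = focalCell(atlas),
                             rankThreshold = 10L, pseudocount = 0.01,
                             tfSubset = NULL) {
  stopIfNot(rankThreshold >= 1L, "input error: rankThreshold must be >= 1")
  mats <- atlasMatrices(atlas)
  hasFocal <- vapply(mats, function(m) focalCellName %in% colnames(m),
                     logical(1L))
  stopIfNot(any(hasFocal), "input error: focal cell not in atlas")
  m <- mats[[which(hasFocal)[1L]]]
  if (!is.null(tfSubset)) m <- m[rownames(m) %in% tfSubset, , drop = FALSE]
  focalIdx <- match(focalCellName, colnames(m))
  ranks <- apply(-m, 1L, function(v) ceiling(rank(v)[focalIdx]))
  fd <- vapply(seq_len(nrow(m)), function(i)
    specificityRatio(m[i, focalIdx], m[i, -focalIdx], pseudocount),
    numeric(1L))
  data.frame(tf = rownames(m), rank = as.integer(ranks), log2fd = fd,
             selected = ranks <= rankThreshold & fd > 0,
             row.names = NULL)
}
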