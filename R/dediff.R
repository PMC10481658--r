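# Dedifferentiation scoring: anchor-referenced mean-only batch correction
# with parametric empirical-Bayes shrinkage, gene-centered PCA of the
# reference differentiation series, projection of perturbed samples on the
# first component, and the meta median fold change across studies.

#' Anchor-referenced mean-only batch correction
#'
#' Per gene, the batch offset is estimated as the difference between the
#' target batch's anchor-sample mean and the reference anchor mean. The
#' per-gene offsets are shrunk towards their grand mean with a parametric
#' (normal) empirical-Bayes prior whose moments are estimated from the
#' offset distribution (method of moments), then subtracted from every
#' target sample. Variances are untouched. With zero between-gene offset
#' variance the raw offsets are used unchanged, so a constant planted
#' offset is removed exactly.
#'
#' @param reference genes x samples matrix of the reference batch.
#' @param target genes x samples matrix of the batch to correct.
#' @param refAnchors,targetAnchors column names of the anchor (control)
#'   samples in each batch.
#' @return the corrected target matrix, with the per-gene shrunk offsets
#'   in \code{attr(, "offsets")}.
#' @export
batchCorrectMeanOnly <- function(reference, target, refAnchors,
                                 targetAnchors) {
  stopIfNot(identical(rownames(reference), rownames(target)),
            "input error: reference and target must share the gene universe")
  stopIfNot(all(refAnchors %in% colnames(reference)),
            "batch 'reference' has no such anchor samples")
  stopIfNot(all(targetAnchors %in% colnames(target)),
            "batch 'target' has no such anchor samples")
  stopIfNot(length(refAnchors) >= 1L && length(targetAnchors) >= 1L,
            "each batch must contain at least one anchor sample")
  ra <- reference[, refAnchors, drop = FALSE]
  ta <- target[, targetAnchors, drop = FALSE]
  d <- rowMeans(ta) - rowMeans(ra)
  # per-gene sampling variance of the offset from anchor replicates
  nr <- ncol(ra); nt <- ncol(ta)
  s2 <- if (nr + nt > 2L) {
    num <- (if (nr > 1L) rowSums((ra - rowMeans(ra))^2) else 0) +
      (if (nt > 1L) rowSums((ta - rowMeans(ta))^2) else 0)
    num / (nr + nt - 2L)
  } else rep(0, length(d))
  se2 <- s2 * (1 / nr + 1 / nt)
  gbar <- mean(d)
  tau2 <- max(var(d) - mean(se2), 0)
  denom <- tau2 + se2
  shrunk <- ifelse(denom > 0, (tau2 * d + se2 * gbar) / denom, d)
  corrected <- target - shrunk
  attr(corrected, "offsets") <- shrunk
  corrected
}

#' Fit the reference differentiation axis
#'
#' Gene-wise centering (no unit scaling), SVD; component signs are
#' oriented so the designated mature anchor group has a positive mean PC1
#' score.
#'
#' @param reference genes x samples matrix (>= 3 samples).
#' @param matureAnchors column names of the mature anchor samples.
#' @param nComponents components to keep (default 2; truncated with a
#'   warning if it exceeds the available rank).
#' @return a \code{\link{ReferenceModel}}.
#' @export
fitDifferentiationAxis <- function(reference, matureAnchors,
                                   nComponents = 2L) {
  stopIfNot(ncol(reference) >= 3L,
            "input error: need >= 3 reference samples")
  stopIfNot(all(matureAnchors %in% colnames(reference)),
            "input error: unknown anchor samples")
  ctr <- rowMeans(reference)
  xc <- reference - ctr
  maxComp <- min(dim(xc)) - 1L
  if (nComponents > maxComp) {
    warning("truncating to ", maxComp, " components")
    nComponents <- maxComp
  }
  sv <- svd(xc, nu = nComponents, nv = nComponents)
  scores <- sv$v %*% diag(sv$d[seq_len(nComponents)], nComponents)
  rownames(scores) <- colnames(reference)
  loadings <- sv$u
  rownames(loadings) <- rownames(reference)
  for (a in seq_len(nComponents)) {
    if (mean(scores[matureAnchors, a]) < 0) {
      scores[, a] <- -scores[, a]
      loadings[, a] <- -loadings[, a]
    }
  }
  colnames(scores) <- colnames(loadings) <-
    paste0("PC", seq_len(nComponents))
  new("ReferenceModel", center = setNames(ctr, rownames(reference)),
      loadings = loadings,
      varExplained = (sv$d^2 / sum(sv$d^2))[seq_len(nComponents)],
      scores = scores, anchors = matureAnchors)
}

#' Project samples on the reference differentiation axis
#'
#' Centers by the model's gene means and takes the dot product with the
#' PC1 loading; projecting the reference itself reproduces its fitted
#' scores.
#'
#' @param model a \code{\link{ReferenceModel}}.
#' @param samples genes x samples matrix over the model's gene universe.
#' @return data.frame with columns \code{sample} and \code{score}.
#' @export
projectSamples <- function(model, samples) {
  missing_ <- setdiff(rownames(model@loadings), rownames(samples))
  if (length(missing_))
    stop("input error: sample matrix lacks model genes: ",
         paste(head(missing_, 5L), collapse = ", "), call. = FALSE)
  x <- samples[rownames(model@loadings), , drop = FALSE] - model@center
  sc <- drop(crossprod(x, model@loadings[, 1L]))
  data.frame(sample = colnames(samples), score = as.numeric(sc),
             row.names = NULL)
}

#' Median log2 fold change across studies
#'
#' Per gene, the median of its log2 fold changes across the studies where
#' it is present; genes present in fewer than \code{minStudies} studies
#' are dropped.
#'
#' @param perStudyFc list of named numeric vectors (gene -> log2FC) or of
#'   data.frames with columns \code{gene}, \code{log2fc}.
#' @param minStudies minimum number of studies per gene (default 1).
#' @return named numeric vector, gene -> median log2FC.
#' @export
metaFoldChange <- function(perStudyFc, minStudies = 1L) {
  stopIfNot(length(perStudyFc) >= 1L, "input error: need >= 1 study")
  vecs <- lapply(perStudyFc, function(s) {
    if (is.data.frame(s)) setNames(s$log2fc, s$gene) else s
  })
  genes <- unique(unlist(lapply(vecs, names)))
  vals <- lapply(vecs, function(v) v[genes])
  m <- do.call(cbind, vals)
  rownames(m) <- genes
  nObs <- rowSums(!is.na(m))
  med <- apply(m, 1L, median, na.rm = TRUE)
  med[nObs >= minStudies]
}
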