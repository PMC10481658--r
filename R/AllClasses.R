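#' @include utils.R
NULL

#' Binary promoter-by-regulator binding matrix
#'
#' Rows are TF-encoding gene promoters derived from cis-regulatory modules
#' (CRMs, regions bound by at least two distinct regulators), columns are
#' transcriptional regulators; entries are 0/1 binding indicators. Row sums
#' are therefore always >= 2. The optional \code{promoters} slot keeps the
#' promoter CRM intervals aligned with the rows.
#'
#' @slot binding binary integer matrix, genes x regulators, with dimnames.
#' @slot promoters \code{GRanges} parallel to rows (may be empty).
#' @export
setClass("BindingMatrix",
  representation(binding = "matrix", promoters = "GRanges"),
  prototype(binding = matrix(integer(0), 0, 0),
            promoters = GenomicRanges::GRanges()))

setValidity("BindingMatrix", function(object) {
  b <- object@binding
  if (length(b) && !all(b %in% c(0L, 1L)))
    return("binding values must be 0/1")
  if (nrow(b) && (is.null(rownames(b)) || is.null(colnames(b))))
    return("binding matrix must carry gene and regulator dimnames")
  if (nrow(b) && anyDuplicated(rownames(b)))
    return("duplicate gene ids in rows")
  if (nrow(b) && any(rowSums(b) < 2L))
    return("every promoter row must be bound by >= 2 regulators")
  if (length(object@promoters) && length(object@promoters) != nrow(b))
    return("promoters must be parallel to matrix rows")
  TRUE
})

#' @describeIn BindingMatrix number of promoters and regulators
#' @param x,object a \code{BindingMatrix}
#' @export
setMethod("dim", "BindingMatrix", function(x) dim(x@binding))

#' Accessors for BindingMatrix
#'
#' \code{bindingMatrix} returns the raw 0/1 matrix, \code{regulatorNames}
#' the column (regulator) names, \code{promoterRanges} the promoter CRM
#' intervals.
#'
#' @param object a \code{BindingMatrix}
#' @return matrix, character vector, or \code{GRanges} respectively.
#' @export
setGeneric("bindingMatrix", function(object) standardGeneric("bindingMatrix"))

#' @rdname bindingMatrix
#' @export
setMethod("bindingMatrix", "BindingMatrix", function(object) object@binding)

#' @rdname bindingMatrix
#' @export
setGeneric("regulatorNames", function(object) standardGeneric("regulatorNames"))

#' @rdname bindingMatrix
#' @export
setMethod("regulatorNames", "BindingMatrix",
          function(object) colnames(object@binding))

#' @rdname bindingMatrix
#' @export
setGeneric("promoterRanges", function(object) standardGeneric("promoterRanges"))

#' @rdname bindingMatrix
#' @export
setMethod("promoterRanges", "BindingMatrix", function(object) object@promoters)

setMethod("show", "BindingMatrix", function(object) {
  cat("BindingMatrix:", nrow(object@binding), "promoters x",
      ncol(object@binding), "regulators\n")
  if (nrow(object@binding))
    cat("  mean regulators per promoter:",
        round(mean(rowSums(object@binding)), 2), "\n")
})

#' Toroidal self-organizing map
#'
#' Codebook and promoter assignments of a SOM trained on a binary binding
#' matrix. The grid wraps around in both dimensions (toroidal topology);
#' cells are stored row-major, cell 1 at (row 0, col 0).
#'
#' @slot rows,cols grid dimensions.
#' @slot codebook numeric matrix, (rows*cols) x regulators, values in [0,1].
#' @slot assignment named integer vector, gene -> cell index (row-major).
#' @slot meta list of training metadata (epochs, alpha, radius, seed).
#' @export
setClass("SOMGrid",
  representation(rows = "integer", cols = "integer", codebook = "matrix",
                 assignment = "integer", meta = "list"))

setValidity("SOMGrid", function(object) {
  nc <- object@rows * object@cols
  if (nc < 4L) return("grid must have at least 4 cells")
  if (nrow(object@codebook) != nc)
    return("codebook must have one row per grid cell")
  if (any(object@codebook < 0 | object@codebook > 1))
    return("codebook values must lie in [0,1]")
  if (length(object@assignment) &&
      (is.null(names(object@assignment)) ||
       any(object@assignment < 1L | object@assignment > nc)))
    return("assignment must map named genes to valid cell indices")
  TRUE
})

#' SOMGrid accessors
#'
#' \code{somCodebook} returns the codebook matrix, \code{somAssignment} the
#' gene-to-cell index vector, \code{somDim} the (rows, cols) grid size.
#'
#' @param object a \code{SOMGrid}
#' @export
setGeneric("somCodebook", function(object) standardGeneric("somCodebook"))

#' @rdname somCodebook
#' @export
setMethod("somCodebook", "SOMGrid", function(object) object@codebook)

#' @rdname somCodebook
#' @export
setGeneric("somAssignment", function(object) standardGeneric("somAssignment"))

#' @rdname somCodebook
#' @export
setMethod("somAssignment", "SOMGrid", function(object) object@assignment)

#' @rdname somCodebook
#' @export
setGeneric("somDim", function(object) standardGeneric("somDim"))

#' @rdname somCodebook
#' @export
setMethod("somDim", "SOMGrid",
          function(object) c(rows = object@rows, cols = object@cols))

setMethod("show", "SOMGrid", function(object) {
  cat("SOMGrid:", object@rows, "x", object@cols, "toroidal grid,",
      ncol(object@codebook), "regulators,",
      length(object@assignment), "promoters assigned\n")
})

#' Multi-species expression atlas
#'
#' Per-species TF x cell-type expression matrices sharing one TF universe,
#' with a designated focal cell type (e.g. hepatocytes) in one species.
#'
#' @slot matrices named list of non-negative matrices with identical rownames.
#' @slot focalCell column name of the focal cell type.
#' @export
setClass("ExpressionAtlas",
  representation(matrices = "list", focalCell = "character"))

setValidity("ExpressionAtlas", function(object) {
  m <- object@matrices
  if (!length(m)) return("at least one species matrix required")
  rn <- rownames(m[[1L]])
  for (x in m) {
    if (!is.matrix(x) || is.null(rownames(x)))
      return("each species entry must be a matrix with TF rownames")
    if (!identical(sort(rownames(x)), sort(rn)))
      return("species matrices must share the TF universe")
    if (any(x < 0)) return("expression must be non-negative")
  }
  if (length(object@focalCell) &&
      !object@focalCell %in% unlist(lapply(m, colnames)))
    return("focalCell not found among cell types")
  TRUE
})

#' ExpressionAtlas accessors
#'
#' \code{atlasMatrices} returns the per-species matrix list (rows aligned to
#' the shared TF universe), \code{focalCell} the focal cell-type name.
#'
#' @param object an \code{ExpressionAtlas}
#' @export
setGeneric("atlasMatrices", function(object) standardGeneric("atlasMatrices"))

#' @rdname atlasMatrices
#' @export
setMethod("atlasMatrices", "ExpressionAtlas", function(object) {
  rn <- rownames(object@matrices[[1L]])
  lapply(object@matrices, function(x) x[rn, , drop = FALSE])
})

#' @rdname atlasMatrices
#' @export
setGeneric("focalCell", function(object) standardGeneric("focalCell"))

#' @rdname atlasMatrices
#' @export
setMethod("focalCell", "ExpressionAtlas", function(object) object@focalCell)

setMethod("show", "ExpressionAtlas", function(object) {
  cat("ExpressionAtlas:", nrow(object@matrices[[1L]]), "TFs;",
      paste(vapply(object@matrices, ncol, 1L), collapse = " + "),
      "cell types (", paste(names(object@matrices), collapse = ", "), ")\n")
  if (length(object@focalCell)) cat("  focal cell:", object@focalCell, "\n")
})

#' Ensemble of activity-matched control gene sets
#'
#' Stratified resamples of non-identity genes matching the identity set's
#' per-stratum counts, optionally annotated with per-set test p-values and
#' the representative set selected at the mode of the p-value distribution.
#'
#' @slot identity character, the identity gene set.
#' @slot sets list of character vectors, one control set per iteration.
#' @slot pvalues numeric, per-set p-values (NA until annotated).
#' @slot representative integer index of the selected set (NA until chosen).
#' @export
setClass("ControlSetEnsemble",
  representation(identity = "character", sets = "list",
                 pvalues = "numeric", representative = "integer"))

setValidity("ControlSetEnsemble", function(object) {
  n0 <- length(object@identity)
  for (s in object@sets) {
    if (length(s) != n0) return("control sets must match identity set size")
    if (any(s %in% object@identity))
      return("control sets must exclude identity genes")
  }
  if (length(object@pvalues) && length(object@pvalues) != length(object@sets))
    return("pvalues must be parallel to sets")
  TRUE
})

#' ControlSetEnsemble accessors
#'
#' @param object a \code{ControlSetEnsemble}
#' @export
setGeneric("controlSets", function(object) standardGeneric("controlSets"))

#' @rdname controlSets
#' @export
setMethod("controlSets", "ControlSetEnsemble", function(object) object@sets)

#' @rdname controlSets
#' @export
setGeneric("setPvalues", function(object) standardGeneric("setPvalues"))

#' @rdname controlSets
#' @export
setMethod("setPvalues", "ControlSetEnsemble", function(object) object@pvalues)

#' @rdname controlSets
#' @export
setGeneric("representativeIndex",
           function(object) standardGeneric("representativeIndex"))

#' @rdname controlSets
#' @export
setMethod("representativeIndex", "ControlSetEnsemble",
          function(object) object@representative)

#' @rdname controlSets
#' @export
setGeneric("representativeSet",
           function(object) standardGeneric("representativeSet"))

#' @rdname controlSets
#' @export
setMethod("representativeSet", "ControlSetEnsemble", function(object) {
  i <- object@representative
  if (is.na(i)) stop("no representative selected yet; ",
                     "run selectRepresentativeSet()", call. = FALSE)
  object@sets[[i]]
})

setMethod("show", "ControlSetEnsemble", function(object) {
  cat("ControlSetEnsemble:", length(object@sets), "control sets of size",
      length(object@identity), "\n")
  if (length(object@pvalues) && !all(is.na(object@pvalues)))
    cat("  p-values annotated; representative index:",
        object@representative, "\n")
})

#' Reference differentiation-axis model
#'
#' Gene-centered PCA of a reference differentiation series. PC1 is oriented
#' so the mature anchor samples have positive scores; perturbed samples are
#' scored by projecting onto PC1 after anchor-referenced batch correction.
#'
#' @slot center per-gene means of the reference matrix.
#' @slot loadings orthonormal gene loadings (genes x components).
#' @slot varExplained per-component explained-variance fractions.
#' @slot scores reference sample scores (samples x components).
#' @slot anchors names of the mature anchor samples.
#' @export
setClass("ReferenceModel",
  representation(center = "numeric", loadings = "matrix",
                 varExplained = "numeric", scores = "matrix",
                 anchors = "character"))

setValidity("ReferenceModel", function(object) {
  if (ncol(object@loadings) != length(object@varExplained))
    return("one explained-variance fraction per component")
  if (sum(object@varExplained) > 1 + 1e-8)
    return("explained-variance fractions must sum to <= 1")
  g <- crossprod(object@loadings)
  if (max(abs(g - diag(ncol(g)))) > 1e-6)
    return("loadings must be orthonormal")
  TRUE
})

setMethod("show", "ReferenceModel", function(object) {
  cat("ReferenceModel:", nrow(object@loadings), "genes,",
      ncol(object@loadings), "components; PC1 explains",
      sprintf("%.1f%%", 100 * object@varExplained[1L]), "of variance\n")
})
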