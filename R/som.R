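# Toroidal online self-organizing map on the binary binding matrix, plus
# prototype binarization, Ward cuts of the prototypes and homogeneity
# analysis guiding the number of clusters.

#' Toroidal grid distance between SOM cells
#'
#' Euclidean distance on wrap-around (toroidal) grid coordinates: the
#' per-axis delta is \code{min(|d|, size - |d|)}.
#'
#' @param cellA,cellB integer (row, col) pairs, 0-based.
#' @param rows,cols grid dimensions.
#' @return numeric distance.
#' @examples
#' toroidalGridDistance(c(0, 0), c(9, 0), 10, 10)  # 1: wraps around
#' @export
toroidalGridDistance <- function(cellA, cellB, rows, cols) {
  ok <- function(c_) c_[1L] >= 0 && c_[1L] < rows && c_[2L] >= 0 &&
    c_[2L] < cols
  stopIfNot(ok(cellA) && ok(cellB), "input error: cell outside grid")
  dr <- abs(cellA[1L] - cellB[1L]); dc <- abs(cellA[2L] - cellB[2L])
  sqrt(min(dr, rows - dr)^2 + min(dc, cols - dc)^2)
}

# Full cell x cell toroidal distance matrix (cells row-major).
toroidalCellDistances <- function(rows, cols) {
  co <- gridCoords(rows, cols)
  dr <- abs(outer(co[, 1L], co[, 1L], "-")); dr <- pmin(dr, rows - dr)
  dc <- abs(outer(co[, 2L], co[, 2L], "-")); dc <- pmin(dc, cols - dc)
  sqrt(dr^2 + dc^2)
}

#' Train a toroidal SOM on a binary binding matrix
#'
#' Online training with Euclidean distance on the binary rows: each
#' presentation moves the best-matching unit (BMU) and all cells within the
#' current neighborhood radius (toroidal grid distance, bubble
#' neighborhood) towards the presented row. The learning rate decays
#' linearly from \code{alpha[1]} to \code{alpha[2]} and the radius linearly
#' from \code{radius} to 1 over all presentations. The codebook is
#' initialized from randomly drawn data rows, so its entries stay in [0,1]
#' under the convex updates. BMU ties resolve to the lowest (row, col) in
#' lexicographic order; assignments are nearest-codebook cells after
#' training.
#'
#' @param x a \code{\link{BindingMatrix}} or binary matrix with rownames.
#' @param rows,cols grid dimensions; default
#'   \code{ceiling(sqrt(5 * sqrt(N)))} each (scale-adaptive heuristic).
#' @param epochs passes over the data (default 100, i.e. 100 N
#'   presentations).
#' @param seed RNG seed for initialization and presentation order.
#' @param alpha learning-rate schedule endpoints.
#' @param radius initial neighborhood radius; default
#'   \code{max(rows, cols) / 2}.
#' @return a \code{\link{SOMGrid}}.
#' @export
trainSOM <- function(x, rows = NULL, cols = NULL, epochs = 100L, seed = 1L,
                     alpha = c(0.05, 0.01), radius = NULL) {
  if (is(x, "BindingMatrix")) x <- bindingMatrix(x)
  stopIfNot(is.matrix(x) && nrow(x) > 0L, "input error: empty matrix")
  stopIfNot(epochs >= 1L, "input error: epochs must be >= 1")
  n <- nrow(x)
  if (is.null(rows)) rows <- max(2L, ceiling(sqrt(5 * sqrt(n))))
  if (is.null(cols)) cols <- rows
  rows <- as.integer(rows); cols <- as.integer(cols)
  stopIfNot(rows * cols <= n,
            "input error: grid larger than the number of promoters")
  if (is.null(radius)) radius <- max(rows, cols) / 2
  ncell <- rows * cols
  cellDist <- toroidalCellDistances(rows, cols)
  total <- as.numeric(epochs) * n
  codebook <- NULL
  withSeed(seed, {
    codebook <- x[sample.int(n, ncell, replace = ncell > n), , drop = FALSE]
    storage.mode(codebook) <- "double"
    t_ <- 0
    xt <- t(x)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (i in ord) {
        frac <- t_ / max(total - 1, 1)
        a <- alpha[1L] + (alpha[2L] - alpha[1L]) * frac
        r <- radius + (1 - radius) * frac
        v <- xt[, i]
        d2 <- colSums((t(codebook) - v)^2)
        bmu <- which.min(d2)          # row-major: lowest (row,col) on ties
        nb <- which(cellDist[bmu, ] <= r)
        codebook[nb, ] <- codebook[nb, , drop = FALSE] +
          a * (rep(v, each = length(nb)) -
                 codebook[nb, , drop = FALSE])
        t_ <- t_ + 1
      }
    }
  })
  rownames(codebook) <- NULL
  assign_ <- assignToCells(x, codebook)
  new("SOMGrid", rows = rows, cols = cols, codebook = codebook,
      assignment = assign_,
      meta = list(epochs = as.integer(epochs), alpha = alpha,
                  radius = radius, seed = as.integer(seed)))
}

# Nearest-codebook cell per row; ties -> lowest cell index (row-major).
assignToCells <- function(x, codebook) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(codebook))) -
    2 * x %*% t(codebook) + outer(rep(1, nrow(x)), rowSums(codebook^2))
  setNames(apply(d2, 1L, which.min), rownames(x))
}

#' Binarize SOM cell prototypes
#'
#' The representative regulator combination of a cell is its codebook
#' vector thresholded at \code{threshold} (default 0.5: majority vote of
#' the cell's members at convergence).
#'
#' @param grid a \code{\link{SOMGrid}}.
#' @param threshold value in (0, 1).
#' @return binary matrix, cells x regulators.
#' @export
binarizePrototypes <- function(grid, threshold = 0.5) {
  stopIfNot(threshold > 0 && threshold < 1,
            "input error: threshold must lie in (0,1)")
  p <- (somCodebook(grid) >= threshold) + 0L
  p
}

#' Cut SOM cell prototypes into promoter clusters
#'
#' Ward linkage (\code{hclust} method \code{ward.D2}) on Euclidean
#' distances between cell prototypes, cut at \code{k}. Cluster letters
#' "A", "B", ... are assigned in ascending order of the mean prototype sum,
#' i.e. of co-recruitment complexity.
#'
#' @param prototypes binary matrix from \code{\link{binarizePrototypes}}.
#' @param k number of clusters (>= 2).
#' @return list with \code{cellCluster} (factor, one letter per cell),
#'   \code{tree} (the \code{hclust} object) and \code{complexity} (mean
#'   prototype sum per cluster).
#' @export
clusterSomCells <- function(prototypes, k) {
  stopIfNot(k >= 2L, "input error: k must be >= 2")
  nDistinct <- nrow(unique(prototypes))
  stopIfNot(k <= nDistinct,
            "input error: k exceeds the number of distinct prototypes")
  tree <- hclust(dist(prototypes), method = "ward.D2")
  raw <- cutree(tree, k = k)
  complexity <- tapply(rowSums(prototypes), raw, mean)
  ord <- order(complexity, as.integer(names(complexity)))
  relabel <- setNames(clusterLetters(k), names(complexity)[ord])
  lab <- factor(relabel[as.character(raw)], levels = clusterLetters(k))
  list(cellCluster = lab, tree = tree,
       complexity = setNames(as.numeric(complexity[ord]), relabel))
}

#' Assign promoter genes to clusters through their SOM cells
#'
#' @param grid a \code{\link{SOMGrid}}.
#' @param cellCluster factor of per-cell labels from
#'   \code{\link{clusterSomCells}}.
#' @return named factor, gene -> cluster letter.
#' @export
promoterClusters <- function(grid, cellCluster) {
  a <- somAssignment(grid)
  setNames(cellCluster[a], names(a))
}

#' Homogeneity analysis of the prototype clustering
#'
#' For each candidate k, homogeneity is 1 minus the ratio of the mean
#' squared Euclidean distance to the cluster centroid over the mean squared
#' distance to the grand centroid (a within-SS / total-SS form, which is
#' monotone non-decreasing over nested Ward cuts and reaches 1 at
#' k = number of cells). The suggested k is the elbow: the interior k
#' maximizing the drop in marginal homogeneity gain,
#' \code{(f(k)-f(k-1)) - (f(k+1)-f(k))}.
#'
#' @param prototypes binary matrix of cell prototypes.
#' @param kRange integer vector of candidate k within
#'   \code{[2, nrow - 1]}.
#' @return list with \code{k}, \code{homogeneity} (the curve) and
#'   \code{suggestedK}.
#' @export
homogeneityAnalysis <- function(prototypes, kRange = NULL) {
  n <- nrow(prototypes)
  if (is.null(kRange)) kRange <- seq(2L, max(2L, n - 1L))
  stopIfNot(all(kRange >= 2L & kRange <= n),
            "input error: kRange outside [2, n_cells]")
  tree <- hclust(dist(prototypes), method = "ward.D2")
  ssFor <- function(labels) {
    sum(vapply(split(seq_len(n), labels), function(i) {
      ctr <- colMeans(prototypes[i, , drop = FALSE])
      sum(sweep(prototypes[i, , drop = FALSE], 2L, ctr)^2)
    }, numeric(1L)))
  }
  ssTot <- ssFor(rep(1L, n))
  homAt <- function(k) {
    if (ssTot == 0) return(1)
    1 - ssFor(cutree(tree, k = k)) / ssTot
  }
  ks <- sort(unique(as.integer(kRange)))
  hom <- vapply(ks, homAt, numeric(1L))
  # elbow on the extended curve (k-1 and k+1 neighbors, f(1) = 0)
  extK <- c(min(ks) - 1L, ks, min(max(ks) + 1L, n))
  extK <- unique(pmax(extK, 1L))
  extH <- vapply(extK, homAt, numeric(1L))
  idx <- match(ks, extK)
  inner <- idx[idx > 1L & idx < length(extK)]
  suggested <- if (length(inner)) {
    bend <- (extH[inner] - extH[inner - 1L]) - (extH[inner + 1L] - extH[inner])
    extK[inner[which.max(bend)]]
  } else ks[1L]
  list(k = ks, homogeneity = setNames(hom, ks), suggestedK = suggested)
}

#' Per-cell mean of a gene-level value
#'
#' Arithmetic mean over the genes assigned to each cell; cells without
#' genes are \code{NA}, not 0.
#'
#' @param grid a \code{\link{SOMGrid}} (or named integer assignment).
#' @param geneValues named numeric vector over assigned genes.
#' @return numeric matrix, rows x cols, of cell means.
#' @export
cellSummaryMap <- function(grid, geneValues) {
  a <- if (is(grid, "SOMGrid")) somAssignment(grid) else grid
  dims <- if (is(grid, "SOMGrid")) somDim(grid) else
    stop("grid dimensions unavailable", call. = FALSE)
  stopIfNot(all(names(a) %in% names(geneValues)),
            "geneValues must cover all assigned genes")
  v <- geneValues[names(a)]
  means <- tapply(v, factor(a, seq_len(dims[1L] * dims[2L])), mean)
  matrix(as.numeric(means), nrow = dims[1L], ncol = dims[2L], byrow = TRUE)
}
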