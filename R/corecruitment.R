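# Co-recruitment structure within promoter clusters: Tanimoto (Jaccard)
# distance matrices, classical MDS, frequent-itemset core nodes, per-TF
# node occurrence, and the Szekely distance correlation of binding signals.

#' Tanimoto distance matrix between regulators
#'
#' d(s, t) = 1 - |P_s intersect P_t| / |P_s union P_t| over the regulators'
#' bound-promoter sets. Regulators binding nothing are at distance 1 from
#' every other regulator (and 0 from themselves).
#'
#' @param x a \code{\link{BindingMatrix}} or binary matrix
#'   (promoters x regulators).
#' @return symmetric numeric matrix in [0, 1] with zero diagonal.
#' @export
tanimotoDistanceMatrix <- function(x) {
  if (is(x, "BindingMatrix")) x <- bindingMatrix(x)
  storage.mode(x) <- "double"
  inter <- crossprod(x)
  sizes <- diag(inter)
  uni <- outer(sizes, sizes, "+") - inter
  d <- 1 - ifelse(uni > 0, inter / uni, 0)
  diag(d) <- 0
  dimnames(d) <- list(colnames(x), colnames(x))
  d
}

#' Classical (Torgerson) MDS embedding
#'
#' Double-centers the squared distance matrix, takes the top \code{dims}
#' eigenvectors scaled by the square root of their eigenvalues; negative
#' eigenvalues are truncated at 0 and axes beyond the positive-eigenvalue
#' count are zero-padded. For determinism the first nonzero loading of each
#' axis is made positive.
#'
#' @param d symmetric distance matrix.
#' @param dims number of output dimensions (>= 1).
#' @return numeric matrix, points x dims, rownames from \code{d}.
#' @export
mdsEmbedding <- function(d, dims = 2L) {
  stopIfNot(dims >= 1L, "input error: dims must be >= 1")
  d <- as.matrix(d)
  n <- nrow(d)
  j <- diag(n) - 1 / n
  b <- -0.5 * j %*% (d^2) %*% j
  b <- (b + t(b)) / 2
  e <- eigen(b, symmetric = TRUE)
  lambda <- pmax(e$values, 0)
  nPos <- sum(lambda > .Machine$double.eps * max(lambda, 1) * n)
  coords <- matrix(0, n, dims)
  useD <- min(dims, nPos)
  if (useD > 0)
    coords[, seq_len(useD)] <- e$vectors[, seq_len(useD), drop = FALSE] %*%
      diag(sqrt(lambda[seq_len(useD)]), useD)
  for (a in seq_len(dims)) {
    nz <- which(abs(coords[, a]) > 1e-12)
    if (length(nz) && coords[nz[1L], a] < 0) coords[, a] <- -coords[, a]
  }
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("dim", seq_len(dims))
  coords
}

# support of an itemset = fraction of promoters binding all members
itemsetSupport <- function(m, items) {
  mean(rowSums(m[, items, drop = FALSE]) == length(items))
}

#' Mine frequent regulator itemsets (core co-recruitment nodes)
#'
#' Apriori-style levelwise search for every regulator set of size in
#' [\code{sizeMin}, \code{sizeMax}] whose members are simultaneously bound
#' in at least \code{minSupport} of the cluster's promoters
#' (market-basket semantics: transactions are promoters). Defaults follow
#' the core-node definition: support 0.5, sizes from 2 up to the number of
#' regulators.
#'
#' @param x a \code{\link{BindingMatrix}} or binary matrix restricted to
#'   one cluster's promoters.
#' @param minSupport minimum support in (0, 1].
#' @param sizeMin,sizeMax itemset size window; \code{sizeMin} must be >= 2,
#'   \code{sizeMax} is clamped to the number of regulators.
#' @return data.frame with columns \code{items} (comma-joined, members
#'   sorted), \code{size}, \code{support} and \code{count}, sorted by
#'   decreasing support then items.
#' @export
mineFrequentItemsets <- function(x, minSupport = 0.5, sizeMin = 2L,
                                 sizeMax = NULL) {
  if (is(x, "BindingMatrix")) x <- bindingMatrix(x)
  stopIfNot(minSupport > 0 && minSupport <= 1,
            "input error: minSupport must lie in (0,1]")
  stopIfNot(sizeMin >= 2L, "input error: sizeMin must be >= 2")
  if (is.null(sizeMax)) sizeMax <- ncol(x)
  sizeMax <- min(sizeMax, ncol(x))
  n <- nrow(x)
  tfs <- colnames(x)
  emptyRes <- data.frame(items = character(0), size = integer(0),
                         support = numeric(0), count = integer(0))
  if (n == 0L || sizeMax < sizeMin) return(emptyRes)
  freq1 <- sort(tfs[colMeans(x) >= minSupport])
  level <- as.list(freq1)
  out <- list(); outSup <- numeric(0)
  size <- 1L
  while (length(level) && size < sizeMax) {
    prev <- new.env(hash = TRUE)
    for (s in level) assign(paste(s, collapse = "\r"), TRUE, envir = prev)
    nextLevel <- list(); nextSup <- numeric(0)
    for (s in level) {
      # join: extend with lexicographically later frequent singletons
      for (t in freq1[freq1 > s[length(s)]]) {
        c_ <- c(s, t)
        # apriori prune: every size-`size` subset must itself be frequent
        ok <- all(vapply(seq_along(c_), function(i)
          exists(paste(c_[-i], collapse = "\r"), envir = prev),
          logical(1L)))
        if (!ok) next
        sup <- itemsetSupport(x, c_)
        if (sup >= minSupport) {
          nextLevel[[length(nextLevel) + 1L]] <- c_
          nextSup <- c(nextSup, sup)
        }
      }
    }
    level <- nextLevel
    size <- size + 1L
    if (size >= sizeMin) {
      out <- c(out, nextLevel)
      outSup <- c(outSup, nextSup)
    }
  }
  if (!length(out)) return(emptyRes)
  res <- data.frame(items = vapply(out, paste, "", collapse = ","),
                    size = lengths(out), support = outSup,
                    count = as.integer(round(outSup * n)))
  res[order(-res$support, res$items), , drop = FALSE]
}

#' Percentage occurrence of each regulator in the core nodes
#'
#' @param itemsets data.frame from \code{\link{mineFrequentItemsets}}.
#' @param tfUniverse character vector of all regulators.
#' @return named numeric vector of percentages (all 0 when no itemsets).
#' @export
coreNodeOccurrence <- function(itemsets, tfUniverse) {
  res <- setNames(rep(0, length(tfUniverse)), tfUniverse)
  if (!nrow(itemsets)) return(res)
  members <- strsplit(itemsets$items, ",", fixed = TRUE)
  tab <- table(factor(unlist(members), levels = tfUniverse))
  setNames(100 * as.numeric(tab) / nrow(itemsets), tfUniverse)
}

#' Szekely distance correlation
#'
#' Sample distance correlation between two samples of n observations
#' (vectors or matrices with observations in rows): doubly-centered
#' pairwise Euclidean distance matrices, dCov normalized by
#' \code{sqrt(dVar_x * dVar_y)}; defined as 0 when either dVar is 0. The
#' default is the biased V-statistic; \code{unbiased = TRUE} switches to
#' U-centering.
#'
#' @param x,y numeric vectors or matrices with equal observation counts
#'   (n >= 4).
#' @param unbiased use the unbiased (U-centered) estimator.
#' @return value in [0, 1] (the unbiased estimator may be slightly
#'   negative; it is returned as the signed square root).
#' @export
distanceCorrelation <- function(x, y, unbiased = FALSE) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  stopIfNot(nrow(y) == n, "input error: sample counts differ")
  stopIfNot(n >= 4L, "input error: need n >= 4 observations")
  a <- as.matrix(dist(x)); b <- as.matrix(dist(y))
  if (!unbiased) {
    ctr <- function(m) sweep(sweep(m, 1L, rowMeans(m)), 2L, colMeans(m)) +
      mean(m)
    A <- ctr(a); B <- ctr(b)
    dcov2 <- mean(A * B)
    dvx <- mean(A * A); dvy <- mean(B * B)
  } else {
    uctr <- function(m) {
      rm_ <- rowSums(m) / (n - 2); cm_ <- colSums(m) / (n - 2)
      g <- sum(m) / ((n - 1) * (n - 2))
      u <- m - outer(rm_, rep(1, n)) - outer(rep(1, n), cm_) + g
      diag(u) <- 0
      u
    }
    A <- uctr(a); B <- uctr(b)
    dcov2 <- sum(A * B) / (n * (n - 3))
    dvx <- sum(A * A) / (n * (n - 3)); dvy <- sum(B * B) / (n * (n - 3))
  }
  if (dvx <= 0 || dvy <= 0) return(0)
  r2 <- dcov2 / sqrt(dvx * dvy)
  sign(r2) * sqrt(abs(r2))
}
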