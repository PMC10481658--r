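# Independent brute-force oracles used to freeze expected values.
# Each is written against first principles (O(n^2) scans, exhaustive
# enumeration) and never shares code with the implementation it checks.

suppressPackageStartupMessages(library(GenomicRanges))

adjRandIndex <- function(a, b) mclust::adjustedRandIndex(a, b)

# Connected components of the >=1 bp interval-overlap graph, with the TF
# sets of each component; components with < 2 distinct TFs dropped.
bruteForceCrms <- function(cistromes) {
  peaks <- do.call(rbind, lapply(names(cistromes), function(tf) {
    gr <- cistromes[[tf]]
    if (!length(gr)) return(NULL)
    data.frame(tf = tf, start = start(gr), end = end(gr))
  }))
  if (is.null(peaks)) return(NULL)
  n <- nrow(peaks)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && peaks$start[i] <= peaks$end[j] &&
        peaks$start[j] <= peaks$end[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  out <- lapply(split(seq_len(n), comp), function(idx)
    list(start = min(peaks$start[idx]), end = max(peaks$end[idx]),
         tfs = sort(unique(peaks$tf[idx]))))
  out <- Filter(function(x) length(x$tfs) >= 2L, out)
  out[order(vapply(out, `[[`, 1, "start"))]
}

# Exhaustive frequent-itemset enumeration over all subsets.
bruteForceItemsets <- function(m, minSupport, sizeMin, sizeMax) {
  tfs <- colnames(m)
  res <- list()
  for (k in seq(sizeMin, min(sizeMax, length(tfs)))) {
    sets <- combn(sort(tfs), k, simplify = FALSE)
    for (s in sets) {
      sup <- mean(rowSums(m[, s, drop = FALSE]) == k)
      if (sup >= minSupport)
        res[[length(res) + 1L]] <- data.frame(
          items = paste(s, collapse = ","), size = k, support = sup)
    }
  }
  if (!length(res))
    return(data.frame(items = character(0), size = integer(0),
                      support = numeric(0)))
  df <- do.call(rbind, res)
  df[order(-df$support, df$items), , drop = FALSE]
}

# Set-arithmetic Tanimoto distances.
bruteForceTanimoto <- function(m) {
  tfs <- colnames(m)
  d <- matrix(0, length(tfs), length(tfs), dimnames = list(tfs, tfs))
  for (i in seq_along(tfs)) for (j in seq_along(tfs)) {
    if (i == j) next
    a <- which(m[, i] == 1); b <- which(m[, j] == 1)
    u <- length(union(a, b))
    d[i, j] <- if (u == 0) 1 else 1 - length(intersect(a, b)) / u
  }
  d
}

# Greedy Ward agglomeration: merge the pair minimizing the increase in the
# total within-cluster sum of squares; returns the partition at each k.
bruteForceWardPartitions <- function(x) {
  n <- nrow(x)
  ess <- function(idx) {
    ctr <- colMeans(x[idx, , drop = FALSE])
    sum(sweep(x[idx, , drop = FALSE], 2L, ctr)^2)
  }
  clusters <- as.list(seq_len(n))
  partitions <- list()
  partitions[[n]] <- seq_len(n)
  while (length(clusters) > 1L) {
    best <- NULL; bestInc <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      inc <- ess(c(clusters[[i]], clusters[[j]])) -
        ess(clusters[[i]]) - ess(clusters[[j]])
      if (inc < bestInc - 1e-12) { bestInc <- inc; best <- c(i, j) }
    }
    merged <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters <- c(clusters[-best], list(merged))
    lab <- integer(n)
    for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
    partitions[[length(clusters)]] <- lab
  }
  partitions
}

# Two-sided Fisher exact p by hypergeometric point-mass enumeration.
bruteForceFisherP <- function(a, b, c_, d) {
  m <- a + b; n_ <- c_ + d; k <- a + c_
  lo <- max(0L, k - n_); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) dhyper(x, m, n_, k), numeric(1L))
  pObs <- dhyper(a, m, n_, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Reference BH step-up.
bruteForceBH <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  for (i in seq(n - 1L, 1L)) q[i] <- min(q[i], q[i + 1L])
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# Sort-and-pick per-gene median across studies.
bruteForceMetaMedian <- function(fcList) {
  genes <- unique(unlist(lapply(fcList, names)))
  sapply(genes, function(g) {
    v <- as.numeric(unlist(lapply(fcList, function(s) unname(s[g]))))
    v <- sort(v[!is.na(v)])
    if (length(v) %% 2 == 1) v[(length(v) + 1) / 2] else
      mean(v[length(v) / 2 + 0:1])
  })
}

# Small default config for fast tests.
tinyConfig <- function(...) {
  args <- list(...)
  defaults <- list(nTfs = 8, nPromoters = 40, nBindingClusters = 2,
                   bindingNoise = 0, nAtlasTfs = 60,
                   programSizes = c(CTS = 12, CTE = 18, UBQ = 30),
                   nCelltypes = c(mouse = 12, human = 15),
                   nConnectPlanted = 5, nIdentityTfs = 4, nEffectors = 20,
                   nGenesDediff = 120, nAmbiguous = 2, rngSeed = 11)
  merged <- utils::modifyList(defaults, args)
  if (is.null(args$nAtlasTfs) && merged$nPromoters > merged$nAtlasTfs) {
    merged$nAtlasTfs <- merged$nPromoters + 20
    merged$programSizes <- NULL
  }
  do.call(syntheticConfig, merged)
}
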