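# From peak sets, TSS annotations and signal tracks to the binary
# promoter-by-regulator binding matrix and per-promoter signal features.
# All interval arithmetic is strand-ignored (ChIP peaks are unstranded) and
# overlap means >= 1 shared base.

#' Merge cistromes into cis-regulatory modules (CRMs)
#'
#' Pools all peaks, merges them by single-linkage overlap (>= 1 bp; touching
#' but non-overlapping intervals stay separate), annotates every merged
#' region with the set of regulators contributing at least one peak, and
#' discards regions bound by fewer than two distinct regulators.
#'
#' @param cistromes named list or \code{GRangesList} of per-regulator peak
#'   \code{GRanges}.
#' @return \code{GRanges} of CRMs with a \code{bound_tfs} CharacterList
#'   column; \code{n_tfs} gives the regulator count per CRM.
#' @examples
#' library(GenomicRanges)
#' cis <- list(TF1 = GRanges("chr1", IRanges(101, 200)),
#'             TF2 = GRanges("chr1", IRanges(151, 250)),
#'             TF3 = GRanges("chr1", IRanges(301, 400)))
#' mergePeaksToCrms(cis)  # one CRM 101-250 bound by TF1,TF2
#' @export
mergePeaksToCrms <- function(cistromes) {
  stopIfNot(length(cistromes) >= 2L,
            "input error: at least two cistromes required")
  stopIfNot(!is.null(names(cistromes)) && !anyDuplicated(names(cistromes)),
            "input error: cistromes must carry unique regulator names")
  grl <- GRangesList(lapply(cistromes, granges))
  all <- unlist(grl, use.names = FALSE)
  tf <- rep(names(cistromes), lengths(grl))
  if (!length(all))
    return(GRanges(bound_tfs = IRanges::CharacterList(), n_tfs = integer(0)))
  merged <- reduce(all, min.gapwidth = 0L, ignore.strand = TRUE)
  hits <- findOverlaps(merged, all, ignore.strand = TRUE)
  sets <- lapply(split(tf[subjectHits(hits)],
                       factor(queryHits(hits), seq_along(merged))),
                 function(x) sort(unique(x)))
  keep <- lengths(sets) >= 2L
  crms <- merged[keep]
  mcols(crms)$bound_tfs <- IRanges::CharacterList(sets[keep])
  mcols(crms)$n_tfs <- lengths(sets[keep])
  crms
}

#' Map CRMs to active promoters
#'
#' Keeps one record per gene whose TSS overlaps a CRM. Ambiguous TSS-gene
#' associations are discarded in both directions (a TSS position shared by
#' several gene ids, and a gene id carrying several TSSs). Genes outside
#' \code{geneFilter} (e.g. the TF-encoding gene list) are dropped. When a
#' gene's TSS overlaps several CRMs, their intervals and bound-regulator
#' sets are unioned: the promoter is treated as one binding locus.
#'
#' @param crms CRM \code{GRanges} from \code{\link{mergePeaksToCrms}}.
#' @param tss \code{GRanges} of width-1 TSS records with a \code{gene_id}
#'   metadata column.
#' @param geneFilter optional character vector; keep only these gene ids.
#' @return \code{GRanges} of promoter records (the unioned CRM interval)
#'   with columns \code{gene_id}, \code{tss_start} and \code{bound_tfs}.
#' @export
mapCrmsToPromoters <- function(crms, tss, geneFilter = NULL) {
  stopIfNot(!is.null(mcols(tss)$gene_id),
            "input error: TSS records must carry gene ids")
  gid <- as.character(mcols(tss)$gene_id)
  key <- paste(seqnames(tss), start(tss))
  multiGene <- names(which(table(gid) > 1L))          # gene with >1 TSS
  tssGenes <- split(gid, key)
  sharedKeys <- names(which(vapply(tssGenes,
                                   function(g) length(unique(g)), 1L) > 1L))
  drop <- gid %in% multiGene | key %in% sharedKeys |
    gid %in% unlist(tssGenes[sharedKeys])
  keep <- tss[!drop]
  gid <- gid[!drop]
  if (!is.null(geneFilter)) {
    sel <- gid %in% geneFilter
    keep <- keep[sel]; gid <- gid[sel]
  }
  hits <- findOverlaps(keep, crms, ignore.strand = TRUE)
  if (!length(hits))
    return(GRanges(gene_id = character(0), tss_start = integer(0),
                   bound_tfs = IRanges::CharacterList()))
  byGene <- split(subjectHits(hits), gid[queryHits(hits)])
  genes <- names(byGene)
  idx <- match(genes, gid)
  iv <- t(vapply(byGene, function(j)
    c(min(start(crms)[j]), max(end(crms)[j])), numeric(2L)))
  sets <- lapply(byGene, function(j)
    sort(unique(unlist(mcols(crms)$bound_tfs[j]))))
  out <- GRanges(rep(as.character(seqnames(keep)[idx])),
                 IRanges(start = iv[, 1L], end = iv[, 2L]),
                 gene_id = genes, tss_start = start(keep)[idx],
                 bound_tfs = IRanges::CharacterList(sets))
  out[order(start(out), out$gene_id)]
}

#' Build the binary binding matrix from promoter records
#'
#' @param records promoter \code{GRanges} from
#'   \code{\link{mapCrmsToPromoters}}.
#' @param tfUniverse optional regulator universe fixing the column order;
#'   defaults to the sorted union of bound regulators.
#' @return a \code{\link{BindingMatrix}}.
#' @export
buildBindingMatrix <- function(records, tfUniverse = NULL) {
  stopIfNot(length(records) > 0L, "input error: no promoter records")
  genes <- as.character(mcols(records)$gene_id)
  stopIfNot(!anyDuplicated(genes), "input error: duplicate gene ids")
  sets <- mcols(records)$bound_tfs
  if (is.null(tfUniverse))
    tfUniverse <- sort(unique(unlist(sets)))
  m <- matrix(0L, length(genes), length(tfUniverse),
              dimnames = list(genes, tfUniverse))
  for (i in seq_along(genes)) m[i, unlist(sets[[i]])] <- 1L
  new("BindingMatrix", binding = m, promoters = granges(records))
}

# Per-interval maximum of a binned track; uncovered bases read as 0.
trackMaxOver <- function(track, intervals) {
  hits <- findOverlaps(intervals, track, ignore.strand = TRUE)
  q <- queryHits(hits); s <- subjectHits(hits)
  ow <- pmin(end(intervals)[q], end(track)[s]) -
    pmax(start(intervals)[q], start(track)[s]) + 1L
  f <- factor(q, seq_along(intervals))
  mx <- tapply(mcols(track)$score[s], f, max)
  cov <- tapply(ow, f, sum)
  mx <- ifelse(is.na(mx), -Inf, mx)
  cov <- ifelse(is.na(cov), 0, cov)
  # any uncovered base contributes a 0 candidate to the maximum
  as.numeric(ifelse(cov < width(intervals), pmax(mx, 0), mx))
}

#' Maximum signal over each promoter CRM
#'
#' Per gene, the maximum track value over the promoter's CRM interval;
#' bases not covered by the track read as 0 (enrichment-track semantics).
#'
#' @param track scored \code{GRanges} with non-overlapping bins.
#' @param records promoter \code{GRanges} with \code{gene_id}.
#' @return named numeric vector, gene -> max signal.
#' @export
extractPromoterSignal <- function(track, records) {
  setNames(trackMaxOver(track, granges(records)),
           as.character(mcols(records)$gene_id))
}

#' Assign H3K4me3 domain breadth to genes
#'
#' A gene receives the length of the closest domain only when its TSS
#' distance to that domain is 0 (overlap); otherwise it is unassigned
#' (\code{NA}). Distance ties are resolved by the first domain in sorted
#' order.
#'
#' @param domains \code{GRanges} of H3K4me3-enriched regions.
#' @param tss \code{GRanges} of width-1 TSS records with \code{gene_id}.
#' @return named numeric vector, gene -> breadth in bp (\code{NA} when
#'   unassigned).
#' @export
assignH3k4me3Breadth <- function(domains, tss) {
  domains <- sort(domains, ignore.strand = TRUE)
  res <- setNames(rep(NA_real_, length(tss)),
                  as.character(mcols(tss)$gene_id))
  if (!length(domains)) return(res)
  # distance 0 means actual overlap (>= 1 shared base); a TSS one base
  # outside every domain stays unassigned even when ranges are adjacent
  hits <- findOverlaps(tss, domains, ignore.strand = TRUE)
  if (!length(hits)) return(res)
  first <- tapply(subjectHits(hits), queryHits(hits), min)
  res[as.integer(names(first))] <- width(domains)[first]
  res
}

#' Count peaks within a window around each TSS
#'
#' Peaks overlapping the closed window \code{[tss - window, tss + window]}
#' by at least one base are counted; a peak starting 10,001 bp away from a
#' TSS is outside a 10 kb window.
#'
#' @param cistrome peak \code{GRanges} for one regulator.
#' @param tss \code{GRanges} of width-1 TSS records with \code{gene_id}.
#' @param window half-window in bp (default 10000).
#' @return named integer vector, gene -> peak count.
#' @export
countPeaksNearTss <- function(cistrome, tss, window = 10000L) {
  stopIfNot(window > 0L, "input error: window must be positive")
  win <- GRanges(seqnames(tss),
                 IRanges(start = pmax(start(tss) - window, 1L),
                         end = start(tss) + window))
  setNames(countOverlaps(win, cistrome, ignore.strand = TRUE),
           as.character(mcols(tss)$gene_id))
}

# Mean of a binned track over an interval, uncovered bases read as 0.
trackMeanOver <- function(track, intervals) {
  hits <- findOverlaps(intervals, track, ignore.strand = TRUE)
  tot <- numeric(length(intervals))
  if (length(hits)) {
    q <- queryHits(hits); s <- subjectHits(hits)
    ow <- pmin(end(intervals)[q], end(track)[s]) -
      pmax(start(intervals)[q], start(track)[s]) + 1L
    contrib <- ow * mcols(track)$score[s]
    agg <- tapply(contrib, factor(q, seq_along(intervals)), sum)
    tot <- ifelse(is.na(agg), 0, agg)
  }
  as.numeric(tot) / width(intervals)
}

#' Filter TSS candidates by H3K27ac enrichment over control
#'
#' Keeps TSSs whose mean signal in a +/- 500 bp window is at least
#' \code{foldCutoff}-fold the control's window mean (a pseudocount guards
#' against zero control signal), then retains per gene only the TSS with
#' the highest signal.
#'
#' @param tss candidate \code{GRanges} with \code{gene_id}.
#' @param signal,control scored \code{GRanges} tracks.
#' @param foldCutoff enrichment cutoff (default 2).
#' @param halfWindow half-window in bp (default 500).
#' @param pseudocount added to both window means (default 0.1).
#' @return filtered \code{GRanges} with an added \code{window_signal}
#'   column.
#' @export
selectActiveTss <- function(tss, signal, control, foldCutoff = 2,
                            halfWindow = 500L, pseudocount = 0.1) {
  win <- GRanges(seqnames(tss),
                 IRanges(start = pmax(start(tss) - halfWindow, 1L),
                         end = start(tss) + halfWindow))
  s <- trackMeanOver(signal, win)
  ctl <- trackMeanOver(control, win)
  keep <- (s + pseudocount) / (ctl + pseudocount) >= foldCutoff
  out <- tss[keep]
  mcols(out)$window_signal <- s[keep]
  gid <- as.character(mcols(out)$gene_id)
  best <- tapply(seq_along(out), gid, function(i)
    i[which.max(mcols(out)$window_signal[i])])
  out <- out[sort(as.integer(best))]
  out
}
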