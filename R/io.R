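# Plain-text interchange: BED (0-based half-open), bedGraph, TSV matrices,
# and the ground-truth key-value format. rtracklayer handles the coordinate
# convention shift between BED files and in-memory GRanges.

#' Read and write interval and matrix files
#'
#' \code{writeBedFile}/\code{readBedFile} round-trip \code{GRanges} through
#' BED (0-based half-open on disk; a \code{name} metadata column is kept).
#' \code{writeBedGraphFile}/\code{readBedGraphFile} do the same for scored
#' tracks. \code{writeMatrixTsv}/\code{readMatrixTsv} store numeric
#' matrices as TSV with a header row of sample/cell names and a first
#' column of gene identifiers.
#'
#' @param gr a \code{GRanges} (with a \code{score} column for bedGraph).
#' @param x a numeric matrix with dimnames.
#' @param path file path.
#' @return readers return the parsed object; writers return \code{path}
#'   invisibly.
#' @export
writeBedFile <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname writeBedFile
#' @export
readBedFile <- function(path) rtracklayer::import(path, format = "BED")

#' @rdname writeBedFile
#' @export
writeBedGraphFile <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname writeBedFile
#' @export
readBedGraphFile <- function(path) {
  rtracklayer::import(path, format = "bedGraph")
}

#' @rdname writeBedFile
#' @export
writeMatrixTsv <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBedFile
#' @export
readMatrixTsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Serialize ground truth as a key-value text file
#'
#' One record per line: \code{section<TAB>key<TAB>value}. Numeric values
#' are written with full precision so the round trip is lossless.
#'
#' @param truth a \code{GroundTruth} list.
#' @param path file path.
#' @return \code{writeGroundTruth} returns \code{path} invisibly;
#'   \code{readGroundTruth} the reconstructed \code{GroundTruth}.
#' @export
writeGroundTruth <- function(truth, path) {
  fmt <- function(v) {
    if (is.numeric(v)) vapply(v, format, "", digits = 17L) else as.character(v)
  }
  lines <- character(0)
  for (sec in c("promoterCluster", "activityStratum", "tfProgram",
                "connectFlag")) {
    v <- truth[[sec]]
    if (length(v))
      lines <- c(lines, paste(sec, names(v), fmt(v), sep = "\t"))
  }
  for (sec in c("identityTfs", "connectTfs", "effectorGenes",
                "ambiguousGenes")) {
    v <- truth[[sec]]
    if (length(v)) lines <- c(lines, paste(sec, v, "1", sep = "\t"))
  }
  si <- truth$sampleInfo
  if (!is.null(si))
    lines <- c(lines, paste("sampleInfo", si$sample,
                            paste(si$study, fmt(si$stage),
                                  fmt(si$batchOffset), si$anchor,
                                  sep = "|"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, quote = "",
                   stringsAsFactors = FALSE,
                   col.names = c("section", "key", "value"))
  pick <- function(sec) df[df$section == sec, , drop = FALSE]
  asNamed <- function(sec, mode) {
    d <- pick(sec)
    if (!nrow(d)) return(NULL)
    v <- switch(mode, int = as.integer(d$value), chr = d$value,
                lgl = as.logical(d$value))
    setNames(v, d$key)
  }
  truth <- list(promoterCluster = asNamed("promoterCluster", "int"),
                activityStratum = asNamed("activityStratum", "int"),
                identityTfs = pick("identityTfs")$key,
                connectTfs = pick("connectTfs")$key,
                effectorGenes = pick("effectorGenes")$key,
                tfProgram = asNamed("tfProgram", "chr"),
                connectFlag = asNamed("connectFlag", "lgl"),
                ambiguousGenes = pick("ambiguousGenes")$key,
                sampleInfo = NULL)
  si <- pick("sampleInfo")
  if (nrow(si)) {
    parts <- do.call(rbind, strsplit(si$value, "|", fixed = TRUE))
    truth$sampleInfo <- data.frame(sample = si$key, study = parts[, 1L],
                                   stage = as.numeric(parts[, 2L]),
                                   batchOffset = as.numeric(parts[, 3L]),
                                   anchor = as.logical(parts[, 4L]))
  }
  class(truth) <- "GroundTruth"
  truth
}
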