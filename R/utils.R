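# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stage seed from a root seed; kept below 2^31.
deriveSeed <- function(root, offset) {
  as.integer((as.numeric(root) * 48271 + offset) %% 2147483647)
}

stopIfNot <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# Cluster letters "A", "B", ... "Z", "AA", ...
clusterLetters <- function(n) {
  if (n <= 26L) return(LETTERS[seq_len(n)])
  c(LETTERS, paste0(rep(LETTERS, each = 26L), LETTERS))[seq_len(n)]
}

# Row-major (row, col) coordinates for cells 1..rows*cols (0-based coords).
gridCoords <- function(rows, cols) {
  cbind(row = rep(seq_len(rows) - 1L, each = cols),
        col = rep(seq_len(cols) - 1L, times = rows))
}
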