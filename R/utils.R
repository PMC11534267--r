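# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Deterministic per-stream sub-seed derivation (kept below 2^31).
derive_seed <- function(seed, ...) {
  parts <- c(...)
  s <- as.double(seed) %% 2147483647
  for (p in parts) s <- (s * 48271 + as.double(p)) %% 2147483647
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fread with transparent gzip support (no optional decompression deps).
fread_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    lines <- readLines(con)
    if (!length(lines)) return(data.table::data.table())
    data.table::fread(text = lines, header = FALSE, sep = "\t", fill = TRUE,
                      colClasses = list(character = 1), showProgress = FALSE)
  } else {
    data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                      colClasses = list(character = 1), showProgress = FALSE)
  }
}

# Weighted Pearson correlation; returns 0 when either side is degenerate.
weighted_pearson <- function(x, y, w) {
  sw <- sum(w)
  if (sw <= 0) return(0)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  cxy <- sum(w * (x - mx) * (y - my))
  cxx <- sum(w * (x - mx)^2)
  cyy <- sum(w * (y - my)^2)
  if (cxx <= 0 || cyy <= 0) return(0)
  cxy / sqrt(cxx * cyy)
}
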