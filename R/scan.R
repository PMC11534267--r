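# PWM scanning with exact dynamic-programming match p-values.
#
# Log-odds scores use a FIMO-style pseudocount of 0.1/nsites added to each
# PPM cell. Match p-values come from the exact null distribution of the
# score under the background model, computed by dynamic programming over
# log-odds scores discretized into `nbins` bins.

# Pseudocount-adjusted log2-odds matrix (4 x L).
motif_log_odds <- function(motif) {
  pc <- 0.1 / motif$nsites
  padj <- (motif$ppm + pc) / (1 + 4 * pc)
  log2(padj / motif$background)
}

# Discretize a log-odds matrix and compute the exact null tail distribution.
# Returns list(int: integer 4 x L, delta, offset, tail: P(S_int >= s) for
# s = 0..max_int).
pwm_null_distribution <- function(lod, background, nbins = 1000L) {
  L <- ncol(lod)
  col_min <- apply(lod, 2L, min)
  shifted <- sweep(lod, 2L, col_min)
  rng <- sum(apply(shifted, 2L, max))
  if (rng <= 0) {
    # degenerate: every word scores the same
    return(list(int = matrix(0L, 4L, L), delta = 0, offset = sum(col_min),
                tail = 1))
  }
  delta <- rng / nbins
  int <- matrix(as.integer(round(shifted / delta)), 4L, L)
  max_int <- sum(apply(int, 2L, max))
  pmf <- numeric(max_int + 1L)
  pmf[1L] <- 1
  for (l in seq_len(L)) {
    new <- numeric(max_int + 1L)
    for (b in 1:4) {
      k <- int[b, l]
      if (background[b] > 0)
        new[(k + 1L):(max_int + 1L)] <- new[(k + 1L):(max_int + 1L)] +
          background[b] * pmf[1:(max_int + 1L - k)]
    }
    pmf <- new
  }
  tail <- rev(cumsum(rev(pmf)))
  tail <- pmin(tail, 1)
  list(int = int, delta = delta, offset = sum(col_min), tail = tail)
}

# Encode sequences as integer codes (A=1, C=2, G=3, T=4, other NA) and
# concatenate with NA spacers so one vector scan covers all sequences.
encode_sequences <- function(sequences, spacer) {
  if (inherits(sequences, "DNAStringSet") || inherits(sequences, "DNAString"))
    sequences <- as.character(sequences)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  codes <- lapply(sequences, function(s)
    match(strsplit(toupper(s), "")[[1L]], DNA_BASES))
  lens <- lengths(codes)
  gap <- rep(NA_integer_, spacer)
  x <- unlist(lapply(codes, function(cc) c(cc, gap)), use.names = FALSE)
  starts <- cumsum(c(0L, utils::head(lens + spacer, -1L)))  # 0-based start of each seq in x
  list(x = x, seq_names = names(sequences), seq_starts = starts, seq_lens = lens)
}

# Sliding-window scores of a lod/int matrix over an encoded vector.
scan_scores <- function(x, lut_real, lut_int) {
  L <- ncol(lut_real)
  n <- length(x) - L + 1L
  if (n < 1L) return(list(real = numeric(0), int = integer(0)))
  real <- numeric(n)
  intv <- numeric(n)
  for (l in seq_len(L)) {
    xs <- x[l:(n + l - 1L)]
    real <- real + lut_real[, l][xs]
    intv <- intv + lut_int[, l][xs]
  }
  list(real = real, int = intv)
}

#' Scan sequences with a motif
#'
#' Scores every window on both strands with the pseudocount-adjusted
#' log2-odds of the motif and reports windows whose match p-value (from the
#' exact discretized null distribution under the background model) is below
#' `pval_threshold`.
#'
#' @param motif A `MotifModel`.
#' @param sequences Named `DNAStringSet` or character vector (e.g. peak
#'   sequences).
#' @param pval_threshold Report matches with `p < pval_threshold`
#'   (default 1e-4).
#' @param nbins Number of discretization bins for the null distribution.
#' @return `data.table` with columns `motif`, `seqname`, `start` (0-based
#'   offset within the sequence), `end`, `strand`, `score` (log2-odds), `p`.
#' @export
scan_sequences <- function(motif, sequences, pval_threshold = 1e-4, nbins = 1000L) {
  if (pval_threshold <= 0 || pval_threshold >= 1)
    stop("pval_threshold must be in (0, 1)")
  L <- ncol(motif$ppm)
  enc <- encode_sequences(sequences, spacer = L)
  out <- list()
  for (str in c("+", "-")) {
    m <- if (str == "+") motif else motif_revcomp(motif)
    lod <- motif_log_odds(m)
    null <- pwm_null_distribution(lod, m$background, nbins = nbins)
    if (null$delta == 0) next   # uniform scores: p = 1 everywhere
    sc <- scan_scores(enc$x, lod, null$int)
    p <- rep(NA_real_, length(sc$int))
    ok <- !is.na(sc$int)
    p[ok] <- null$tail[pmin(sc$int[ok], length(null$tail) - 1L) + 1L]
    hit <- which(ok & p < pval_threshold)
    if (!length(hit)) next
    pos0 <- hit - 1L                                  # 0-based position in x
    seq_idx <- findInterval(pos0, enc$seq_starts)
    off <- pos0 - enc$seq_starts[seq_idx]
    keep <- off + L <= enc$seq_lens[seq_idx]          # window inside one sequence
    hit <- hit[keep]; seq_idx <- seq_idx[keep]; off <- off[keep]
    if (!length(hit)) next
    out[[str]] <- data.table::data.table(
      motif = motif$name, seqname = enc$seq_names[seq_idx],
      start = as.integer(off), end = as.integer(off + L), strand = str,
      score = sc$real[hit], p = p[hit])
  }
  if (!length(out))
    return(data.table::data.table(motif = character(), seqname = character(),
                                  start = integer(), end = integer(),
                                  strand = character(), score = numeric(),
                                  p = numeric()))
  res <- data.table::rbindlist(out)
  data.table::setorder(res, seqname, start, strand)
  res[]
}

#' Scan sequences with a motif collection
#'
#' @param motifs List of `MotifModel`s.
#' @inheritParams scan_sequences
#' @return Combined match `data.table` (see [scan_sequences()]).
#' @export
scan_motifs <- function(motifs, sequences, pval_threshold = 1e-4, nbins = 1000L) {
  data.table::rbindlist(lapply(motifs, scan_sequences, sequences = sequences,
                               pval_threshold = pval_threshold, nbins = nbins))
}

#' Build a peak x motif match matrix
#'
#' @param matches Match table from [scan_motifs()] with `seqname` equal to
#'   peak ids.
#' @param peaks `GRanges` peak set (defines row order).
#' @param motifs List of `MotifModel`s (defines column order).
#' @return A `MatchMatrix`: list with logical `indicator`, numeric `score`
#'   (max log-odds per peak, 0 where no match) and `scaled_score`
#'   (score / per-motif max, in `[0, 1]`).
#' @export
build_match_matrix <- function(matches, peaks, motifs) {
  pid <- peaks$peak_id
  mnames <- vapply(motifs, function(m) m$name, character(1))
  ind <- matrix(FALSE, length(pid), length(mnames), dimnames = list(pid, mnames))
  sco <- matrix(0, length(pid), length(mnames), dimnames = list(pid, mnames))
  if (nrow(matches)) {
    agg <- matches[, list(score = max(score)), by = c("motif", "seqname")]
    agg <- agg[agg$seqname %in% pid & agg$motif %in% mnames]
    idx <- cbind(match(agg$seqname, pid), match(agg$motif, mnames))
    ind[idx] <- TRUE
    sco[idx] <- agg$score
  }
  mx <- apply(sco, 2L, max)
  scaled <- sweep(sco, 2L, ifelse(mx > 0, mx, 1), "/")
  structure(list(indicator = ind, score = sco, scaled_score = scaled),
            class = "MatchMatrix")
}

#' @export
print.MatchMatrix <- function(x, ...) {
  cat("MatchMatrix:", nrow(x$indicator), "peaks x", ncol(x$indicator),
      "motifs;", sum(x$indicator), "matches\n")
  invisible(x)
}
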