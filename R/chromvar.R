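# chromVAR-style bias-corrected deviations and z-scores.

new_activity_scores <- function(mat, kind, normalization = "none") {
  structure(mat, class = c("ActivityScores", class(mat)),
            kind = kind, normalization = normalization)
}

#' @export
print.ActivityScores <- function(x, ...) {
  cat("ActivityScores (", attr(x, "kind"), "): ", nrow(x), " motifs x ",
      ncol(x), " samples\n", sep = "")
  invisible(x)
}

#' GC/accessibility-matched background peak sets
#'
#' For each peak, the candidate pool is its `k_pool` nearest neighbors
#' (self included) in standardized (GC, log1p mean count) space; each of
#' the `B` background iterations samples one pool member per peak.
#'
#' @param counts Peaks x samples count matrix.
#' @param peak_gc Per-peak GC fraction.
#' @param B Number of background iterations (default 2000).
#' @param k_pool Pool size (default 50).
#' @param seed RNG seed.
#' @return A `BackgroundSets`: list with `pools` (peaks x k_pool integer
#'   matrix) and `iterations` (peaks x B integer matrix of sampled
#'   background peak indices).
#' @export
chromvar_background_sets <- function(counts, peak_gc, B = 2000L, k_pool = 50L,
                                     seed = 1L) {
  n <- nrow(counts)
  if (B < 1L) stop("B must be >= 1")
  if (length(peak_gc) != n) stop("peak_gc length must match peaks")
  if (n <= k_pool) {
    warning("fewer peaks than k_pool; using all peaks as pool")
    k_pool <- n
  }
  feat <- cbind(scale(peak_gc), scale(log1p(rowMeans(counts))))
  feat[is.na(feat)] <- 0
  pools <- matrix(0L, n, k_pool)
  block <- 1024L
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    d2 <- outer(feat[s:e, 1L], feat[, 1L], "-")^2 +
          outer(feat[s:e, 2L], feat[, 2L], "-")^2
    for (i in seq_len(e - s + 1L))
      pools[s + i - 1L, ] <- order(d2[i, ])[seq_len(k_pool)]
  }
  iterations <- with_seed(seed, {
    matrix(pools[cbind(rep(seq_len(n), B),
                       sample.int(k_pool, n * B, replace = TRUE))], n, B)
  })
  structure(list(pools = pools, iterations = iterations, seed = seed),
            class = "BackgroundSets")
}

#' chromVAR-style deviations and z-scores
#'
#' For motif m and sample j, with per-peak fractional accessibility
#' `q_i = rowSums(X)/sum(X)` and sample depth `T_j`: the expected count is
#' `E_mj = T_j * sum_i M_im q_i`, the observed `O_mj = sum_i M_im X_ij`,
#' and the raw deviation `Y_mj = (O_mj - E_mj)/E_mj`. The same quantity is
#' computed for every background iteration with the motif's peaks replaced
#' by their matched background peaks; the bias-corrected deviation is
#' `D = Y - mean_b(Y^b)` and the z-score `z = D / sd_b(Y^b)`.
#'
#' @param counts Peaks x samples count matrix.
#' @param matches A `MatchMatrix` or logical indicator matrix
#'   (peaks x motifs).
#' @param bg A `BackgroundSets` from [chromvar_background_sets()].
#' @return List with `deviations` and `z` (`ActivityScores`,
#'   motifs x samples) and `raw` (the uncorrected `Y`).
#' @export
chromvar_scores <- function(counts, matches, bg) {
  M <- if (inherits(matches, "MatchMatrix")) matches$indicator else matches
  storage.mode(M) <- "double"
  if (nrow(M) != nrow(counts)) stop("matches and counts must share peaks")
  keep <- colSums(M) > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " motif(s) with no matched peaks")
    M <- M[, keep, drop = FALSE]
  }
  X <- as.matrix(counts)
  Tj <- colSums(X)
  q <- rowSums(X) / sum(X)
  tM <- t(M)
  O <- tM %*% X
  Eq <- as.vector(tM %*% q)          # expected fraction per motif
  E <- outer(Eq, Tj)
  Y <- (O - E) / E
  B <- ncol(bg$iterations)
  sum_b <- matrix(0, nrow(Y), ncol(Y))
  sumsq_b <- matrix(0, nrow(Y), ncol(Y))
  for (b in seq_len(B)) {
    idx <- bg$iterations[, b]
    Ob <- tM %*% X[idx, , drop = FALSE]
    Eqb <- as.vector(tM %*% q[idx])
    Eb <- outer(Eqb, Tj)
    Yb <- (Ob - Eb) / Eb
    sum_b <- sum_b + Yb
    sumsq_b <- sumsq_b + Yb^2
  }
  mean_b <- sum_b / B
  var_b <- pmax(sumsq_b / B - mean_b^2, 0) * B / max(B - 1L, 1L)
  sd_b <- sqrt(var_b)
  D <- Y - mean_b
  z <- D / sd_b
  if (any(sd_b == 0)) {
    warning("background sd of 0 for some motif/sample; z set to NA")
    z[sd_b == 0] <- NA_real_
  }
  dimnames(D) <- dimnames(z) <- list(colnames(M), colnames(X))
  dimnames(Y) <- dimnames(D)
  list(deviations = new_activity_scores(D, "deviation"),
       z = new_activity_scores(z, "z"),
       raw = Y)
}

# Column-wise (per-sample) normalization of an activity matrix.
normalize_scores <- function(mat, normalization = c("none", "center", "scale",
                                                    "quantile")) {
  normalization <- match.arg(normalization)
  if (normalization != "none" && ncol(mat) < 2L)
    stop("score normalization needs >= 2 samples")
  out <- switch(normalization,
    none = mat,
    center = sweep(mat, 2L, apply(mat, 2L, stats::median, na.rm = TRUE)),
    scale = {
      c0 <- sweep(mat, 2L, apply(mat, 2L, stats::median, na.rm = TRUE))
      md <- apply(c0, 2L, stats::mad, na.rm = TRUE)
      sweep(c0, 2L, ifelse(md > 0, md, 1), "/")
    },
    quantile = quantile_normalize(mat)
  )
  dimnames(out) <- dimnames(mat)
  out
}

#' Differential analysis of per-sample activity scores
#'
#' Applies a per-sample normalization across score columns, then a
#' per-motif moderated t-test (or the plain pooled two-sample t-test, the
#' native chromVAR-style comparator) between the two groups.
#'
#' @param scores Motifs x samples `ActivityScores` or matrix.
#' @param groups Two-group factor per sample.
#' @param normalization One of `"quantile"` (default), `"none"`,
#'   `"center"`, `"scale"`.
#' @param test `"moderated_t"` (default) or `"t_test"`.
#' @return A `DifferentialTable` sorted by (p ascending, |effect|
#'   descending).
#' @export
differential_from_scores <- function(scores, groups,
                                     normalization = c("quantile", "none",
                                                       "center", "scale"),
                                     test = c("moderated_t", "t_test")) {
  normalization <- match.arg(normalization)
  test <- match.arg(test)
  mat <- normalize_scores(unclass(scores), normalization)
  drop <- rowSums(!is.finite(mat)) > 0
  if (any(drop)) {
    warning("dropping ", sum(drop), " motif(s) with non-finite scores")
    mat <- mat[!drop, , drop = FALSE]
  }
  tbl <- if (test == "moderated_t") moderated_t(mat, groups)
         else moderated_t(mat, groups, d0 = 0)
  sort_differential(tbl)
}

# Sort a DifferentialTable by (p asc, |effect| desc, id asc).
sort_differential <- function(tbl) {
  ord <- order(tbl$p, -abs(tbl$effect), tbl$id)
  out <- tbl[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("DifferentialTable", "data.frame")
  attr(out, "d0") <- attr(tbl, "d0")
  out
}
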