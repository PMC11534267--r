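# Multivariate and univariate linear-model activity methods.

# Prune near-duplicate (|r| > threshold) columns, keeping the first.
prune_collinear <- function(M, threshold = 0.999) {
  if (ncol(M) < 2L) return(M)
  sds <- apply(M, 2L, stats::sd)
  const <- sds == 0
  if (any(const)) {
    warning("dropping ", sum(const), " constant motif column(s): ",
            paste(utils::head(colnames(M)[const], 5L), collapse = ", "))
    M <- M[, !const, drop = FALSE]
  }
  if (ncol(M) < 2L) return(M)
  r <- suppressWarnings(stats::cor(M))
  drop <- logical(ncol(M))
  for (j in 2:ncol(M))
    if (any(abs(r[j, seq_len(j - 1L)][!drop[seq_len(j - 1L)]]) > threshold))
      drop[j] <- TRUE
  if (any(drop)) {
    warning("pruning ", sum(drop), " collinear motif column(s): ",
            paste(utils::head(colnames(M)[drop], 5L), collapse = ", "))
    M <- M[, !drop, drop = FALSE]
  }
  M
}

#' Multivariate motif activity model (fastMLM)
#'
#' For each sample, the standardized peak values are regressed jointly on
#' all (standardized) motif indicator columns plus an intercept; the
#' activity score of a motif in a sample is the t-value of its
#' coefficient. Differential activity across groups uses the moderated
#' t-test. Intended to be run on GC smooth quantile normalized log-CPM
#' (see [gc_smooth_quantile_normalize()]).
#'
#' @param norm Peaks x samples normalized matrix (log-CPM scale).
#' @param matches A `MatchMatrix` or binary peaks x motifs matrix.
#' @param groups Two-group factor per sample.
#' @return List with `scores` (`ActivityScores`, kind `"mlm_t"`) and
#'   `table` (`DifferentialTable`).
#' @export
mlm_activity <- function(norm, matches, groups) {
  M <- if (inherits(matches, "MatchMatrix")) matches$indicator else matches
  storage.mode(M) <- "double"
  if (nrow(M) != nrow(norm)) stop("matches and matrix must share peaks")
  M <- prune_collinear(M)
  if (nrow(norm) <= ncol(M) + 1L)
    stop("need more peaks than motifs + 1")
  X <- cbind(`(Intercept)` = 1, scale(M))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient motif design after pruning; offending motifs: ",
         paste(bad, collapse = ", "))
  }
  Y <- scale(unclass(norm))
  coefs <- qr.coef(qrX, Y)
  res <- qr.resid(qrX, Y)
  dfres <- nrow(X) - ncol(X)
  s2 <- colSums(res^2) / dfres
  XtXinv_diag <- diag(chol2inv(qr.R(qrX)))[order(qrX$pivot)]
  se <- sqrt(outer(XtXinv_diag, s2))
  tval <- coefs / se
  tval <- tval[-1L, , drop = FALSE]         # drop intercept
  dimnames(tval) <- list(colnames(M), colnames(norm))
  sc <- new_activity_scores(tval, "mlm_t")
  list(scores = sc,
       table = differential_from_scores(sc, groups, normalization = "none"))
}

#' Univariate per-motif regression of peak log fold-changes
#'
#' Each motif's activity is the slope of an ordinary least-squares
#' regression of per-peak logFC on the motif's match indicator (or scaled
#' match score), optionally with peak GC content as a covariate
#' (`"binary+GC"`). Exact ties in the logFC vector are broken by a small
#' seeded jitter (factor 0.001 of the value range).
#'
#' @param logfc Per-peak log fold-change vector.
#' @param matches A `MatchMatrix` (or binary indicator matrix when
#'   `variant != "scores"`).
#' @param variant One of `"binary"`, `"scores"`, `"binary+GC"`.
#' @param peak_gc Per-peak GC fraction (required for `"binary+GC"`).
#' @param jitter_seed Seed for the tie-breaking jitter.
#' @return A `DifferentialTable` with `effect` = slope.
#' @export
ulm_logfc <- function(logfc, matches, variant = c("binary", "scores",
                                                  "binary+GC"),
                      peak_gc = NULL, jitter_seed = 1L) {
  variant <- match.arg(variant)
  if (any(!is.finite(logfc))) stop("logfc must be finite")
  M <- if (inherits(matches, "MatchMatrix")) {
    if (variant == "scores") matches$scaled_score else matches$indicator
  } else matches
  storage.mode(M) <- "double"
  if (variant == "binary+GC") {
    if (is.null(peak_gc)) stop("peak_gc is required for the binary+GC variant")
    if (length(peak_gc) != length(logfc)) stop("peak_gc length mismatch")
  }
  if (anyDuplicated(logfc)) {
    rng <- diff(range(logfc))
    logfc <- with_seed(jitter_seed,
                       logfc + stats::runif(length(logfc), -1, 1) *
                         0.001 * max(rng, 1e-6))
  }
  n <- length(logfc)
  motifs <- colnames(M)
  drop <- apply(M, 2L, function(x) stats::sd(x) == 0)
  if (any(drop)) {
    warning("dropping ", sum(drop),
            " motif(s) matching all or no peaks (undefined slope)")
    M <- M[, !drop, drop = FALSE]
    motifs <- motifs[!drop]
  }
  eff <- tv <- pv <- numeric(length(motifs))
  dfres <- n - (if (variant == "binary+GC") 3L else 2L)
  for (k in seq_along(motifs)) {
    X <- if (variant == "binary+GC") cbind(1, M[, k], peak_gc)
         else cbind(1, M[, k])
    fit <- stats::lm.fit(X, logfc)
    s2 <- sum(fit$residuals^2) / dfres
    R <- qr.R(fit$qr)
    xtxinv <- chol2inv(R)[order(fit$qr$pivot), order(fit$qr$pivot)]
    se <- sqrt(s2 * xtxinv[2L, 2L])
    eff[k] <- fit$coefficients[2L]
    tv[k] <- eff[k] / se
    pv[k] <- 2 * stats::pt(-abs(tv[k]), dfres)
  }
  out <- data.frame(id = motifs, effect = eff, t = tv, df = dfres, p = pv,
                    p_adj = bh_adjust(pv), row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("DifferentialTable", "data.frame")
  sort_differential(out)
}

#' Combine two per-sample activity score matrices
#'
#' Each input is restricted to the shared motifs and samples,
#' column-quantile-normalized across samples and row-wise z-scaled, and the
#' combination is the element-wise mean. Downstream differential analysis
#' goes through [differential_from_scores()].
#'
#' @param a,b `ActivityScores` (or matrices) with motif row names and
#'   sample column names.
#' @return Combined `ActivityScores` (kind `"combined"`).
#' @export
combine_activity_scores <- function(a, b) {
  motifs <- intersect(rownames(a), rownames(b))
  samples <- intersect(colnames(a), colnames(b))
  if (!length(motifs) || !length(samples))
    stop("no shared motifs/samples between score matrices")
  message("combining scores over ", length(motifs), " motifs and ",
          length(samples), " samples")
  std <- function(m) {
    m <- quantile_normalize(unclass(m)[motifs, samples, drop = FALSE])
    mu <- rowMeans(m)
    sd <- apply(m, 1L, stats::sd)
    sweep(sweep(m, 1L, mu), 1L, ifelse(sd > 0, sd, 1), "/")
  }
  new_activity_scores((std(a) + std(b)) / 2, "combined")
}
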