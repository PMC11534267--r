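# Count normalization: TMM size factors, log-CPM, quantile and
# GC smooth-quantile normalization.

# Single pairwise TMM factor of obs vs ref (weighted trimmed mean of
# M-values with delta-method precision weights).
tmm_pair <- function(obs, ref, logratio_trim = 0.30, sum_trim = 0.05) {
  obs <- as.numeric(obs); ref <- as.numeric(ref)
  nO <- sum(obs); nR <- sum(ref)
  logR <- log2((obs / nO) / (ref / nR))
  absE <- (log2(obs / nO) + log2(ref / nR)) / 2
  v <- (nO - obs) / nO / obs + (nR - ref) / nR / ref
  fin <- is.finite(logR) & is.finite(absE) & (absE > -1e10)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (!length(logR) || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1; hiS <- n + 1 - loS
  keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
          (rank(absE) >= loS & rank(absE) <= hiS)
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' TMM size factors
#'
#' Trimmed-mean-of-M-values normalization factors (M trim 0.30, A trim
#' 0.05). The reference sample is the one whose 75th count-per-library
#' percentile is closest to the mean 75th percentile; factors are
#' normalized to geometric mean 1. Multiply library sizes by these factors
#' to obtain effective library sizes.
#'
#' @param counts Non-negative integer matrix, peaks x samples (>= 2
#'   samples).
#' @return Named numeric vector of per-sample factors.
#' @export
tmm_size_factors <- function(counts) {
  if (ncol(counts) < 2L) stop("TMM needs >= 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample(s) with all-zero counts: ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  f75 <- apply(sweep(counts, 2L, lib, "/"), 2L, stats::quantile, probs = 0.75)
  ref <- if (min(f75) < 1e-20) which.max(colSums(sqrt(counts)))
         else which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)),
              function(j) tmm_pair(counts[, j], counts[, ref]), numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' Log2 counts-per-million and per-peak log fold-change
#'
#' Computes log2 CPM with a prior count on effective (size-factor-scaled)
#' library sizes, and the per-peak group-2 minus group-1 mean difference as
#' the log fold-change.
#'
#' @param counts Peaks x samples count matrix.
#' @param groups Factor/vector of two group labels, one per sample.
#' @param normalization `"TMM"` (default), `"libsize"`, or a numeric vector
#'   of size factors.
#' @param prior_count Prior count added before the log (default 0.5).
#' @return List with `logcpm` (matrix, `normalization` attribute set),
#'   `logfc` (named per-peak vector), `size_factors`, `groups`.
#' @export
log_cpm_and_fc <- function(counts, groups, normalization = "TMM",
                           prior_count = 0.5) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups are required")
  if (any(table(groups) == 0L)) stop("each group needs >= 1 sample")
  lib <- colSums(counts)
  sf <- if (is.numeric(normalization)) normalization
        else switch(normalization,
                    TMM = tmm_size_factors(counts),
                    libsize = stats::setNames(rep(1, ncol(counts)), colnames(counts)),
                    stop("unknown normalization: ", normalization))
  eff <- lib * sf
  logcpm <- log2(t(t(counts + prior_count) / (eff + 2 * prior_count)) * 1e6)
  g2 <- levels(groups)[2L]
  logfc <- rowMeans(logcpm[, groups == g2, drop = FALSE]) -
           rowMeans(logcpm[, groups != g2, drop = FALSE])
  attr(logcpm, "normalization") <- if (is.numeric(normalization)) "custom"
                                   else normalization
  list(logcpm = logcpm, logfc = logfc, size_factors = sf, groups = groups)
}

#' Quantile normalization
#'
#' Every column's sorted values are replaced by the cross-column mean of
#' sorted values; ties receive the mean of their would-be quantiles.
#'
#' @param mat Numeric matrix (>= 2 columns).
#' @return Normalized matrix of the same shape.
#' @export
quantile_normalize <- function(mat) {
  if (ncol(mat) < 2L) stop("quantile normalization needs >= 2 columns")
  n <- nrow(mat)
  qbar <- rowMeans(apply(mat, 2L, sort))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    tmp <- numeric(n)
    tmp[order(mat[, j])] <- qbar
    out[, j] <- stats::ave(tmp, mat[, j], FUN = mean)
  }
  dimnames(out) <- dimnames(mat)
  out
}

# Smooth quantile normalization of one matrix block (samples in columns):
# per sorted quantile u, normalized value = w(u) * overall mean quantile +
# (1 - w(u)) * group mean quantile, with w(u) = 1 - runmed(SSB/SST)(u)
# clipped to [0, 1]. Values are mapped back through each column's ranks so
# within-column order is preserved.
qsmooth_block <- function(mat, groups) {
  n <- nrow(mat)
  if (n < 2L) return(mat)
  groups <- as.factor(groups)
  ord <- apply(mat, 2L, order)
  sorted <- vapply(seq_len(ncol(mat)), function(j) mat[ord[, j], j],
                   numeric(n))
  qbar <- rowMeans(sorted)
  gmeans <- vapply(levels(groups), function(g)
    rowMeans(sorted[, groups == g, drop = FALSE]), numeric(n))
  ng <- table(groups)
  ssb <- as.vector(gmeans^2 %*% as.numeric(ng)) - ncol(mat) * qbar^2
  sst <- rowSums(sorted^2) - ncol(mat) * qbar^2
  rat <- ifelse(sst > 1e-12, pmax(ssb, 0) / sst, 0)
  k <- max(3L, round(0.05 * n))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (n %% 2L == 1L) n else n - 1L)
  w <- 1 - stats::runmed(rat, k)
  w <- pmin(pmax(w, 0), 1)
  normed <- matrix(0, n, ncol(mat))
  for (j in seq_len(ncol(mat))) {
    target <- w * qbar + (1 - w) * gmeans[, as.integer(groups)[j]]
    tmp <- numeric(n)
    tmp[ord[, j]] <- target
    normed[, j] <- stats::ave(tmp, mat[, j], FUN = mean)   # ties averaged
  }
  dimnames(normed) <- dimnames(mat)
  normed
}

#' GC smooth quantile normalization
#'
#' Stratifies peaks into equal-occupancy GC bins and applies smooth
#' quantile normalization within each bin: normalized quantiles interpolate
#' between the overall mean quantile and the group-specific mean quantile,
#' weighted by `w(u) = 1 - runmed(SSB/SST)` at quantile `u` (so quantiles
#' where groups genuinely differ retain their group signal, while purely
#' technical differences are removed). Operates on the log2 CPM scale.
#'
#' @param counts Peaks x samples count matrix.
#' @param peak_gc Per-peak GC fraction.
#' @param groups Two-group factor per sample.
#' @param n_bins Number of equal-occupancy GC bins (default 20).
#' @param min_bin_size Bins with fewer peaks are merged with their neighbor
#'   (default 10), with a warning.
#' @param prior_count Prior count for the log-CPM transform.
#' @return List as in [log_cpm_and_fc()] with `logcpm` normalized within GC
#'   bins (`normalization` attribute `"gc_qsmooth"`) and `logfc` recomputed
#'   from the normalized matrix.
#' @export
gc_smooth_quantile_normalize <- function(counts, peak_gc, groups, n_bins = 20L,
                                         min_bin_size = 10L, prior_count = 0.5) {
  if (length(peak_gc) != nrow(counts)) stop("peak_gc length must match rows")
  groups <- as.factor(groups)
  if (!nlevels(groups) %in% 1:2) stop("groups must have one or two levels")
  lib <- colSums(counts)
  logcpm <- log2(t(t(counts + prior_count) / (lib + 2 * prior_count)) * 1e6)
  qs <- unique(stats::quantile(peak_gc, probs = seq(0, 1, length.out = n_bins + 1L)))
  bin <- cut(peak_gc, breaks = qs, include.lowest = TRUE, labels = FALSE)
  # merge undersized bins into their left neighbor (rightward for bin 1)
  tab <- tabulate(bin, nbins = max(bin))
  if (any(tab > 0 & tab < min_bin_size)) {
    warning("GC bin(s) with < ", min_bin_size, " peaks merged with neighbor")
    repeat {
      tab <- tabulate(bin, nbins = max(bin))
      small <- which(tab > 0 & tab < min_bin_size)
      if (!length(small) || length(unique(bin)) == 1L) break
      b <- small[1L]
      nb <- if (b > 1L && tab[b - 1L] > 0) b - 1L else b + 1L
      bin[bin == b] <- nb
    }
  }
  out <- logcpm
  for (b in unique(bin)) {
    idx <- which(bin == b)
    out[idx, ] <- qsmooth_block(logcpm[idx, , drop = FALSE], groups)
  }
  logfc <- if (nlevels(groups) == 2L) {
    g2 <- levels(groups)[2L]
    rowMeans(out[, groups == g2, drop = FALSE]) -
      rowMeans(out[, groups != g2, drop = FALSE])
  } else NULL
  attr(out, "normalization") <- "gc_qsmooth"
  list(logcpm = out, logfc = logfc,
       size_factors = stats::setNames(rep(1, ncol(counts)), colnames(counts)),
       groups = groups)
}
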