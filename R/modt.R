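# Empirical-Bayes moderated t-statistics for two-group row-wise contrasts.

# Invert the trigamma function by Newton iteration (monotone decreasing).
trigamma_inverse <- function(y) {
  out <- y
  ok <- is.finite(y) & y > 0
  out[!ok & !is.na(y) & y <= 0] <- Inf
  x <- 0.5 + 1 / y[ok]
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y[ok]) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (max(-dif / x, na.rm = TRUE) < 1e-10) break
  }
  out[ok] <- x
  out
}

# Moment-match log sample variances to a scaled F distribution:
# s^2 ~ s0^2 * F(df, d0). Returns list(d0, s02).
fit_f_dist <- function(s2, df) {
  s2 <- pmax(s2, 1e-12)
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- mean(s2)
  }
  list(d0 = d0, s02 = s02)
}

#' Moderated t-test between two groups
#'
#' Row-wise ordinary-least-squares group contrast with empirical-Bayes
#' variance moderation: the prior degrees of freedom `d0` and prior
#' variance `s0^2` are estimated by moment-matching the log sample
#' variances to a scaled F distribution; each row's posterior variance is
#' `(d0 s0^2 + d s^2) / (d0 + d)` and the moderated t-statistic is referred
#' to a t distribution on `d0 + d` degrees of freedom. The effect estimate
#' is the plain group-mean difference regardless of moderation.
#'
#' @param mat Numeric matrix, features x samples.
#' @param groups Two-group factor per sample; the effect is
#'   level2 - level1.
#' @param d0 Optional prior df override: `0` gives ordinary per-row
#'   t-tests, `Inf` a fully pooled variance.
#' @return A `DifferentialTable`: `data.frame` with columns `id`, `effect`,
#'   `t`, `df`, `p`, `p_adj` (Benjamini-Hochberg), plus attributes `d0`,
#'   `s02`.
#' @export
moderated_t <- function(mat, groups, d0 = NULL) {
  mat <- as.matrix(mat)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups are required")
  n1 <- sum(groups == levels(groups)[1L])
  n2 <- sum(groups == levels(groups)[2L])
  if (n1 < 1L || n2 < 1L) stop("each group needs >= 1 sample")
  d <- n1 + n2 - 2L
  if (d < 1L)
    stop("zero residual degrees of freedom; increase the number of samples")
  m1 <- rowMeans(mat[, groups == levels(groups)[1L], drop = FALSE])
  m2 <- rowMeans(mat[, groups == levels(groups)[2L], drop = FALSE])
  effect <- m2 - m1
  ss <- rowSums((mat[, groups == levels(groups)[1L], drop = FALSE] - m1)^2) +
        rowSums((mat[, groups == levels(groups)[2L], drop = FALSE] - m2)^2)
  s2 <- ss / d
  v <- 1 / n1 + 1 / n2
  if (is.null(d0)) {
    fit <- fit_f_dist(s2, d)
    d0 <- fit$d0
    s02 <- fit$s02
    if (!is.finite(d0) || d0 <= 0) {
      if (d0 <= 0) warning("moment estimator gave d0 <= 0; using d0 = Inf")
      d0 <- Inf
      s02 <- fit$s02
    }
  } else {
    s02 <- if (is.finite(d0) && d0 > 0) fit_f_dist(s2, d)$s02
           else mean(pmax(s2, 1e-12))
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
             else (d0 * s02 + d * s2) / (d0 + d)
  s2_post <- pmax(s2_post, 1e-300)
  tstat <- effect / sqrt(s2_post * v)
  df_tot <- d0 + d
  p <- 2 * stats::pt(-abs(tstat), df = df_tot)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  ids <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  out <- data.frame(id = ids, effect = effect, t = tstat, df = df_tot,
                    p = p, p_adj = bh_adjust(p), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  class(out) <- c("DifferentialTable", "data.frame")
  out
}

#' Write a differential table as TSV
#' @param tbl A `DifferentialTable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_differential_table <- function(tbl, path) {
  cols <- c("id", "effect", "t", "df", "p", "p_adj")
  data.table::fwrite(as.data.frame(tbl)[, cols], path, sep = "\t")
  invisible(path)
}
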