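# P-value combination and multiple-testing utilities.

#' Fisher combination of two p-values
#'
#' `X = -2 (ln p1 + ln p2)` referred to the upper tail of a chi-squared
#' distribution with 4 degrees of freedom.
#'
#' @param p1,p2 P-values in (0, 1] (vectorized).
#' @return Combined p-value(s).
#' @export
fisher_combine <- function(p1, p2) {
  if (any(p1 <= 0) || any(p2 <= 0)) stop("p-values must be > 0")
  stats::pchisq(-2 * (log(p1) + log(p2)), df = 4, lower.tail = FALSE)
}

#' Aggregate a vector of dependent p-values
#'
#' Methods: `simes` = min over sorted p of `n * p_(i) / i`; `cauchy` = tail
#' probability of the mean Cauchy-transformed statistic
#' `mean(tan((0.5 - p) * pi))`; `mean` and `geometric_mean` of the
#' p-values, clipped to (0, 1].
#'
#' @param pvec Non-empty vector of p-values in (0, 1].
#' @param method One of `"simes"`, `"cauchy"`, `"mean"`,
#'   `"geometric_mean"`.
#' @return A single aggregated p-value.
#' @export
aggregate_pvalues <- function(pvec, method = c("simes", "cauchy", "mean",
                                               "geometric_mean")) {
  method <- match.arg(method)
  if (!length(pvec)) stop("empty p-value vector")
  if (any(pvec <= 0 | pvec > 1)) stop("p-values must be in (0, 1]")
  n <- length(pvec)
  out <- switch(method,
    simes = min(n * sort(pvec) / seq_len(n)),
    cauchy = {
      stat <- mean(tan((0.5 - pvec) * pi))
      stats::pcauchy(stat, lower.tail = FALSE)
    },
    mean = mean(pvec),
    geometric_mean = exp(mean(log(pvec)))
  )
  min(max(out, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' input order is preserved.
#'
#' @param pvec Vector of p-values.
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(pvec) {
  stats::p.adjust(pvec, method = "BH")
}
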