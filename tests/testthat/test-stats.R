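test_that("TMM factors are scale-invariant and match edgeR", {
  x <- matrix(rep(c(5L, 20L, 80L, 10L), 3), ncol = 3)
  colnames(x) <- paste0("s", 1:3)
  expect_equal(unname(tmm_size_factors(x)), rep(1, 3))

  set.seed(21)
  y <- matrix(rnbinom(200 * 4, mu = 50, size = 2), 200, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  # column2 = 2 x column1: proportions match, factors cancel the doubling
  dbl <- cbind(s1 = y[, 1], s2 = 2L * y[, 1])
  fd <- tmm_size_factors(dbl)
  eff <- t(t(dbl) / (colSums(dbl) * fd))
  expect_equal(eff[, 1], eff[, 2], tolerance = 1e-12, ignore_attr = TRUE)

  f <- tmm_size_factors(y)
  expect_equal(unname(f), unname(edgeR::calcNormFactors(y, method = "TMM")),
               tolerance = 1e-6)
  bad <- y
  bad[, 1] <- 0L
  expect_error(tmm_size_factors(bad), "all-zero")
})

test_that("log-CPM fold-changes follow the CPM definition", {
  set.seed(22)
  counts <- matrix(rnbinom(100 * 6, mu = 60, size = 5), 100, 6,
                   dimnames = list(paste0("p", 1:100), paste0("s", 1:6)))
  groups <- factor(rep(c("a", "b"), each = 3))
  r <- log_cpm_and_fc(counts, groups, normalization = "libsize")
  # oracle: direct evaluation of the stated transform
  lib <- colSums(counts)
  lc <- log2(t(t(counts + 0.5) / (lib + 1)) * 1e6)
  expect_equal(unclass(r$logcpm), lc, ignore_attr = TRUE)
  expect_equal(r$logfc, rowMeans(lc[, 4:6]) - rowMeans(lc[, 1:3]))

  # equal group means give logFC 0
  same <- cbind(counts[, 1:3], counts[, 1:3])
  colnames(same) <- paste0("s", 1:6)
  expect_equal(unname(log_cpm_and_fc(same, groups,
                                     normalization = "libsize")$logfc),
               rep(0, 100))

  # invariant to sample order within groups
  r2 <- log_cpm_and_fc(counts[, c(2, 3, 1, 6, 4, 5)], groups,
                       normalization = "libsize")
  expect_equal(r2$logfc, r$logfc)
  expect_error(log_cpm_and_fc(counts, factor(rep("a", 6))), "two groups")
})

test_that("doubling one group's counts at one peak shifts logFC by +1", {
  set.seed(23)
  counts <- matrix(rnbinom(2000 * 6, mu = 50, size = 10), 2000, 6,
                   dimnames = list(paste0("p", 1:2000), paste0("s", 1:6)))
  groups <- factor(rep(c("a", "b"), each = 3))
  base <- log_cpm_and_fc(counts, groups)$logfc
  mod <- counts
  mod["p7", 4:6] <- mod["p7", 4:6] * 2L
  shifted <- log_cpm_and_fc(mod, groups)$logfc
  expect_equal(shifted["p7"] - base["p7"], c(p7 = 1), tolerance = 0.02)
})

test_that("quantile normalization equalizes sorted values and averages ties", {
  out <- quantile_normalize(cbind(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(out, cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))
  m <- matrix(rnorm(30), 10, 3)
  same <- cbind(m[, 1], m[, 1], m[, 1])
  expect_equal(quantile_normalize(same), same)
  qn <- quantile_normalize(m)
  expect_equal(sort(qn[, 1]), sort(qn[, 2]))
  expect_equal(sort(qn[, 2]), sort(qn[, 3]))
})

test_that("GC smooth quantile normalization has the stated limit cases", {
  set.seed(24)
  counts <- matrix(rnbinom(400 * 6, mu = 40, size = 3), 400, 6,
                   dimnames = list(paste0("p", 1:400), paste0("s", 1:6)))
  gc <- runif(400, 0.3, 0.7)
  # single group: exactly quantile normalization within each GC bin
  r1 <- gc_smooth_quantile_normalize(counts, gc, factor(rep("a", 6)),
                                     n_bins = 4)
  qs <- unique(quantile(gc, probs = seq(0, 1, length.out = 5)))
  bin <- cut(gc, qs, include.lowest = TRUE, labels = FALSE)
  lib <- colSums(counts)
  lc <- log2(t(t(counts + 0.5) / (lib + 1)) * 1e6)
  ref <- lc
  for (b in unique(bin))
    ref[bin == b, ] <- quantile_normalize(lc[bin == b, , drop = FALSE])
  expect_equal(unclass(r1$logcpm), ref, ignore_attr = TRUE)

  # identical group distributions: close to full within-bin QN
  g <- factor(rep(c("a", "b"), each = 3))
  r2 <- gc_smooth_quantile_normalize(counts, gc, g, n_bins = 4)
  expect_gt(cor(as.vector(r2$logcpm), as.vector(ref)), 0.995)

  # within-bin rank order preserved per sample
  for (b in unique(bin)) {
    idx <- which(bin == b)
    for (j in 1:6)
      expect_equal(order(r2$logcpm[idx, j]), order(lc[idx, j]))
  }

  expect_warning(gc_smooth_quantile_normalize(counts, gc, g, n_bins = 100),
                 "merged")
})

test_that("qsmooth removes injected sample-specific GC bias", {
  set.seed(25)
  n <- 800
  gc <- runif(n, 0.3, 0.7)
  base <- matrix(rnbinom(n * 6, mu = 80, size = 8), n, 6,
                 dimnames = list(paste0("p", 1:n), paste0("s", 1:6)))
  bias <- outer(gc - 0.5, c(2, -1.5, 1, -2, 1.5, -1))  # monotone GC effect
  counts <- round(base * 2^bias)
  g <- factor(rep(c("a", "b"), each = 3))
  lib <- colSums(counts)
  raw_lc <- log2(t(t(counts + 0.5) / (lib + 1)) * 1e6)
  fixed <- gc_smooth_quantile_normalize(counts, gc, g, n_bins = 20)$logcpm
  raw_cor <- mean(abs(apply(raw_lc, 2, cor, y = gc, method = "spearman")))
  new_cor <- mean(abs(apply(fixed, 2, cor, y = gc, method = "spearman")))
  expect_lt(new_cor, 0.2 * raw_cor)
})

test_that("moderated t has exact ordinary and pooled limits and matches limma", {
  set.seed(26)
  m <- matrix(rnorm(300 * 8, sd = rep(runif(300, 0.5, 2), 8)), 300, 8,
              dimnames = list(paste0("g", 1:300), NULL))
  grp <- factor(rep(c("a", "b"), each = 4))

  plain <- moderated_t(m, grp, d0 = 0)
  tt <- apply(m, 1, function(r)
    stats::t.test(r[5:8], r[1:4], var.equal = TRUE)$statistic)
  expect_equal(plain$t, unname(tt), tolerance = 1e-12)
  expect_equal(plain$df, rep(6, 300))

  pooled <- moderated_t(m, grp, d0 = Inf)
  expect_equal(length(unique(round(pooled$effect / pooled$t, 10))), 1L)

  eb <- limma::eBayes(limma::lmFit(m, cbind(1, as.integer(grp) - 1)))
  mine <- moderated_t(m, grp)
  expect_equal(attr(mine, "d0"), eb$df.prior, tolerance = 1e-6)
  expect_equal(mine$t, unname(eb$t[, 2]), tolerance = 1e-6)
  expect_equal(mine$p, unname(eb$p.value[, 2]), tolerance = 1e-6)
  expect_equal(mine$effect, unname(eb$coefficients[, 2]), tolerance = 1e-12)
})

test_that("moderated t p-values are uniform under the null", {
  set.seed(27)
  m <- matrix(rnorm(500 * 6), 500, 6, dimnames = list(paste0("g", 1:500), NULL))
  grp <- factor(rep(c("a", "b"), each = 3))
  res <- moderated_t(m, grp)
  ks <- suppressWarnings(stats::ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Fisher combination follows the chi-squared(4) tail", {
  expect_equal(fisher_combine(1, 1), 1)
  expect_equal(fisher_combine(0.05, 0.05),
               stats::pchisq(-2 * 2 * log(0.05), 4, lower.tail = FALSE))
  expect_equal(fisher_combine(0.05, 0.05), 0.0174, tolerance = 5e-3)
  expect_equal(fisher_combine(0.2, 0.7), fisher_combine(0.7, 0.2))
  expect_error(fisher_combine(0, 0.5), "> 0")
})

test_that("p-value aggregation methods satisfy their contracts", {
  expect_equal(aggregate_pvalues(c(0.01, 0.04, 0.03), "simes"), 0.03)
  for (meth in c("simes", "cauchy", "mean", "geometric_mean")) {
    expect_equal(aggregate_pvalues(0.2, meth), 0.2, tolerance = 1e-9)
    expect_equal(aggregate_pvalues(rep(1, 5), meth), 1)
    set.seed(28)
    p <- runif(7)
    expect_equal(aggregate_pvalues(p, meth),
                 aggregate_pvalues(sample(p), meth))
  }
  p <- c(0.003, 0.2, 0.9, 0.04)
  expect_lte(aggregate_pvalues(p, "simes"), length(p) * min(p))
  expect_error(aggregate_pvalues(numeric(0)), "empty")
})

test_that("BH adjustment reproduces the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(29)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})
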