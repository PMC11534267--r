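# Toy fragment cohort around two motif-match windows, used by the
# insertion-profile and footprint tests.
toy_insertion_setup <- function() {
  genomelen <- 4000L
  peaks <- peak_set("chr1", c(500, 2500), c(1500, 3500))
  matches <- data.table::data.table(
    motif = "M1", seqname = c("peak_00001", "peak_00002"),
    start = 490L, end = 500L, strand = "+", score = 10, p = 1e-6)
  list(peaks = peaks, matches = matches)
}

test_that("insertion model reproduces a hand-computed weighted score", {
  setup <- toy_insertion_setup()
  # match windows centered at 0-based 994/995 (peak1) and 2994/2995 (peak2)
  frags <- list(
    s1 = ft("chr1", c(990, 990, 1100), c(1040, 1040, 1160)),
    s2 = ft("chr1", c(986, 900), c(1080, 1004)),
    s3 = ft("chr1", 2990, 3050),
    s4 = ft("chr1", 2990, 3050))
  groups <- factor(c("a", "a", "b", "b"), levels = c("a", "b"))
  names(groups) <- names(frags)
  res <- suppressWarnings(
    insertion_model(frags, setup$matches, setup$peaks, groups,
                    half_width = 200, smooth_window = 1))
  # independent recomputation: accumulate shifted sites, weight by the
  # symmetrized global profile, CPM scale, log1p
  prof <- lapply(frags, function(fr) {
    m <- count_insertions(fr, matches_to_granges(setup$matches, setup$peaks),
                          half_width = 200)
    colSums(m)
  })
  g <- Reduce(`+`, prof)
  g <- (g + rev(g)) / 2
  w <- g / sum(g)
  expected <- vapply(prof, function(p)
    log1p(sum(w * p) / max(sum(p), 1) * 1e6), numeric(1))
  expect_equal(as.vector(unclass(res$scores)["M1", ]), unname(expected),
               tolerance = 1e-12)
})

test_that("a flat global profile weights all offsets equally", {
  # symmetrization of an already symmetric profile is the identity
  x <- c(1, 3, 5, 3, 1)
  expect_equal((x + rev(x)) / 2, x)
  # flat profile: weighted sum reduces to mean insertion count scaling
  setup <- toy_insertion_setup()
  set.seed(41)
  st <- sample(600:1400, 400, replace = TRUE)
  frags <- list(s1 = ft("chr1", st, st + 60),
                s2 = ft("chr1", st + 3, st + 55),
                s3 = ft("chr1", st - 2, st + 51),
                s4 = ft("chr1", st + 1, st + 62))
  groups <- stats::setNames(factor(c("a", "a", "b", "b")), names(frags))
  res <- suppressWarnings(
    insertion_model(frags, setup$matches, setup$peaks, groups,
                    half_width = 200, smooth_window = 401))
  expect_true(all(is.finite(unclass(res$scores))))
})

test_that("footprint test reacts to interior depletion, not flank changes", {
  set.seed(42)
  peaks <- peak_set("chr1", seq(0, 19000, by = 2000),
                    seq(0, 19000, by = 2000) + 1000)
  centers <- GenomicRanges::start(peaks) - 1L + 500L
  matches <- data.table::data.table(
    motif = "M1", seqname = peaks$peak_id, start = 495L, end = 505L,
    strand = "+", score = 8, p = 1e-6)
  mk_sample <- function(depleted) {
    st <- unlist(lapply(centers, function(ct) {
      flank <- ct + sample(c(-180:-30, 30:180), 120, replace = TRUE)
      inter <- ct + sample(-5:5, if (depleted) 4 else 40, replace = TRUE)
      c(flank, inter)
    }))
    ft("chr1", st - 4, st + 60)  # insertion site (start+4) lands on st
  }
  frags <- list(s1 = mk_sample(FALSE), s2 = mk_sample(FALSE), s3 = mk_sample(FALSE),
                s4 = mk_sample(TRUE), s5 = mk_sample(TRUE), s6 = mk_sample(TRUE))
  groups <- stats::setNames(factor(rep(c("a", "b"), each = 3)), names(frags))
  tbl <- bagfoot_like(frags, matches, peaks, groups)
  expect_lt(tbl$p_fpd[tbl$id == "M1"], 0.01)
  # footprint depth rises in the depleted group (relative flank excess)
  expect_gt(tbl$effect_fpd[tbl$id == "M1"], 0)

  # null case: no group difference
  frags0 <- list(s1 = mk_sample(FALSE), s2 = mk_sample(FALSE), s3 = mk_sample(FALSE),
                 s4 = mk_sample(FALSE), s5 = mk_sample(FALSE), s6 = mk_sample(FALSE))
  tbl0 <- bagfoot_like(frags0, matches, peaks, groups)
  expect_gt(tbl0$p[tbl0$id == "M1"], 0.05)
})

test_that("multivariate activity model recovers a planted motif signal", {
  set.seed(43)
  n <- 400
  M <- matrix(runif(n * 2) < 0.25, n, 2,
              dimnames = list(paste0("p", 1:n), c("m1", "m2")))
  groups <- factor(rep(c("a", "b"), each = 3))
  Y <- matrix(rnorm(n * 6, sd = 0.5), n, 6,
              dimnames = list(paste0("p", 1:n), paste0("s", 1:6)))
  Y[, 4:6] <- Y[, 4:6] + 2 * M[, 1]           # signal on motif 1 in group b
  res <- mlm_activity(Y, M, groups)
  rk <- rank_results(res$table)
  expect_equal(rk$id[1], "m1")
  expect_lt(res$table$p[res$table$id == "m1"], 1e-3)
  expect_gt(res$table$p[res$table$id == "m2"], 0.05)
})

test_that("multivariate activity t-values are null when motifs are uninformative", {
  set.seed(44)
  n <- 5000
  M <- matrix(runif(n * 8) < 0.2, n, 8,
              dimnames = list(paste0("p", 1:n), paste0("m", 1:8)))
  Y <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(paste0("p", 1:n), paste0("s", 1:4)))
  res <- mlm_activity(Y, M, factor(rep(c("a", "b"), each = 2)))
  tv <- unclass(res$scores)
  # null t-values are centered on zero with unit dispersion
  expect_lt(abs(mean(tv)), 0.1)
  expect_lt(abs(sd(tv) - 1), 0.2)
  expect_lt(mean(abs(tv) > 3), 0.01)
})

test_that("duplicated motif columns are pruned with a warning", {
  set.seed(45)
  n <- 200
  M <- matrix(runif(n * 2) < 0.3, n, 2,
              dimnames = list(paste0("p", 1:n), c("m1", "m2")))
  M <- cbind(M, m3 = M[, 1])
  Y <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(paste0("p", 1:n), paste0("s", 1:4)))
  expect_warning(res <- mlm_activity(Y, M, factor(rep(c("a", "b"), each = 2))),
                 "collinear")
  expect_setequal(rownames(res$scores), c("m1", "m2"))
})

test_that("univariate logFC regression finds exact fits and drops degenerate motifs", {
  n <- 300
  M <- matrix(FALSE, n, 3, dimnames = list(paste0("p", 1:n),
                                           c("hit", "all", "none")))
  M[1:60, "hit"] <- TRUE
  M[, "all"] <- TRUE
  logfc <- ifelse(M[, "hit"], -1, 0)
  expect_warning(tbl <- ulm_logfc(logfc, M, "binary"), "all or no peaks")
  expect_equal(tbl$id, "hit")
  expect_equal(tbl$effect, -1, tolerance = 0.01)   # up to tie-break jitter
  expect_lt(tbl$p, 1e-20)

  const <- rep(2, n)
  tbl0 <- ulm_logfc(const, M[, "hit", drop = FALSE], "binary")
  expect_lt(abs(tbl0$effect), 0.01)   # only tie-break jitter remains
})

test_that("a GC covariate absorbs a GC-driven confound", {
  set.seed(46)
  n <- 2000
  gc <- runif(n, 0.3, 0.7)
  M <- cbind(conf = gc > 0.55 & runif(n) < 0.9, other = runif(n) < 0.1)
  rownames(M) <- paste0("p", 1:n)
  logfc <- 1.5 * (gc - mean(gc)) + rnorm(n, 0, 0.02)
  plain <- ulm_logfc(logfc, M, "binary")
  adj <- ulm_logfc(logfc, M, "binary+GC", peak_gc = gc)
  s_plain <- plain$effect[plain$id == "conf"]
  s_adj <- adj$effect[adj$id == "conf"]
  expect_lt(abs(s_adj), 0.1 * abs(s_plain))
})

test_that("score combination standardizes, aligns by id and averages", {
  set.seed(47)
  a <- matrix(rnorm(30), 5, 6, dimnames = list(paste0("m", 1:5),
                                               paste0("s", 1:6)))
  self <- suppressMessages(combine_activity_scores(a, a))
  std <- quantile_normalize(a)
  std <- sweep(sweep(std, 1, rowMeans(std)), 1, apply(std, 1, sd), "/")
  expect_equal(unclass(self), std, ignore_attr = TRUE)

  b <- a[sample(5), ]
  perm <- suppressMessages(combine_activity_scores(a, b))
  expect_equal(unclass(perm)[rownames(self), ], unclass(self)[rownames(self), ],
               ignore_attr = TRUE)

  # combining a planted signal with pure noise attenuates but keeps its sign
  groups <- factor(rep(c("a", "b"), each = 3))
  sig <- matrix(rnorm(50 * 6, sd = 0.3), 50, 6,
                dimnames = list(paste0("m", 1:50), paste0("s", 1:6)))
  sig["m1", 4:6] <- sig["m1", 4:6] + 3
  noise <- matrix(rnorm(50 * 6), 50, 6, dimnames = dimnames(sig))
  comb <- suppressMessages(combine_activity_scores(sig, noise))
  t_sig <- differential_from_scores(sig, groups, "none")
  t_comb <- differential_from_scores(comb, groups, "none")
  e_sig <- t_sig$effect[t_sig$id == "m1"]
  e_comb <- t_comb$effect[t_comb$id == "m1"]
  expect_gt(sign(e_comb) * sign(e_sig), 0)
  expect_lt(abs(e_comb), abs(e_sig) + 1e-9)

  expect_error(suppressMessages(
    combine_activity_scores(a, matrix(0, 2, 2,
                                      dimnames = list(c("x", "y"),
                                                      c("u", "v"))))),
    "shared")
})
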