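test_that("enrichment quantile matching assigns rank-matched fold-changes", {
  ref <- data.frame(enrichment = c(1, 2, 3, 4), log2FC = c(-2, -1.5, -1, -0.5))
  # identical enrichments: identity mapping
  out <- assign_reference_foldchanges(c(3, 1, 4, 2), ref)
  expect_equal(out$log2FC, c(-1, -2, -0.5, -1.5))
  # single-row reference: everyone gets that logFC
  one <- assign_reference_foldchanges(c(5, 9), ref[2, ])
  expect_equal(one$log2FC, c(-1.5, -1.5))
  expect_error(assign_reference_foldchanges(c(1, NA), ref), "non-finite")
})

test_that("fold-change matching equals a brute-force quantile + NN oracle", {
  set.seed(51)
  ref <- data.frame(enrichment = rlnorm(100), log2FC = -runif(100, 0.1, 2))
  enr <- rlnorm(100, meanlog = 0.5)
  got <- assign_reference_foldchanges(enr, ref, seed = 7)
  ord <- order(ref$enrichment)
  ref_e <- ref$enrichment[ord]; ref_fc <- ref$log2FC[ord]
  u <- rank(enr, ties.method = "average") / length(enr)
  for (i in seq_along(enr)) {
    target <- ref_e[max(1, ceiling(u[i] * 100))]
    cand <- which(abs(ref_e - target) == min(abs(ref_e - target)))
    expect_true(got$log2FC[i] %in% ref_fc[cand])
  }
})

test_that("downsampling follows n_ijs = min(ceil(n0 * FC^p), n0)", {
  # direct evaluations of the sampling rule
  mk <- function(n0, fc, p, seed = 1) {
    peaks <- peak_set("chr1", 1000, 1300)
    peaks$fc <- fc
    frags <- list(t1 = ft("chr1", rep(1100, n0), rep(1200, n0), "t1"),
                  c1 = ft("chr1", rep(1100, n0), rep(1200, n0), "c1"))
    groups <- stats::setNames(factor(c("trt", "ctl"), levels = c("ctl", "trt")),
                              c("t1", "c1"))
    downsample_peak_fragments(frags, peaks, p, groups, "trt", seed = seed)
  }
  r <- mk(10, 0.25, 1)
  expect_equal(nrow(r$fragments$t1), 3L)       # ceil(10 * 0.25) = 3
  expect_equal(nrow(r$fragments$c1), 10L)      # control untouched (FC < 1)
  r2 <- mk(10, 0.5, 3)
  expect_equal(nrow(r2$fragments$t1), 2L)      # ceil(10 * 0.125) = 2
  r0 <- mk(10, 0.25, 0)
  expect_equal(nrow(r0$fragments$t1), 10L)     # strength 0: untouched
  # FC > 1: the control group is downsampled instead
  r3 <- mk(10, 4, 1)
  expect_equal(nrow(r3$fragments$t1), 10L)
  expect_equal(nrow(r3$fragments$c1), 3L)      # ceil(10 * 4^-1) = 3
  expect_error(mk(10, 0.5, -1), "strength")
})

test_that("kept counts match a brute-force evaluation over random (n0, FC, p)", {
  set.seed(52)
  # brute force: accumulate kept fragments one at a time up to the target
  ns_brute <- function(n0, f) {
    target <- n0 * f
    kept <- 0L
    while (kept < target && kept < n0) kept <- kept + 1L
    kept
  }
  for (p in c(0.25, 0.5, 1, 3)) {
    n_peaks <- 250L
    n0 <- sample(0:40, n_peaks, replace = TRUE)
    fc <- round(runif(n_peaks, 0.05, 0.95), 3)
    starts <- seq(0, by = 1000L, length.out = n_peaks)
    peaks <- peak_set("chr1", starts, starts + 300L)
    peaks$fc <- fc
    frags <- ft("chr1", rep(starts + 50L, n0), rep(starts + 150L, n0), "t1")
    groups <- stats::setNames(factor(c("trt", "ctl"), levels = c("ctl", "trt")),
                              c("t1", "c1"))
    res <- downsample_peak_fragments(
      list(t1 = frags, c1 = frags[0]), peaks, p, groups, "trt", seed = p * 100)
    man <- res$manifest[res$manifest$sample == "t1"]
    expect_equal(man$n0, n0)
    expect_equal(man$ns, vapply(seq_len(n_peaks),
                                function(i) ns_brute(n0[i], fc[i]^p),
                                integer(1)))
    # the output fragment counts per peak agree with the manifest
    got <- tabulate(tfab:::best_overlap_peak(res$fragments$t1, peaks), n_peaks)
    expect_equal(got, man$ns)
  }
})

test_that("downsampling is monotone in strength and passes non-peak fragments through", {
  set.seed(53)
  starts <- seq(0, by = 2000L, length.out = 50L)
  peaks <- peak_set("chr1", starts, starts + 300L)
  peaks$fc <- runif(50, 0.2, 0.9)
  inpeak <- ft("chr1", rep(starts + 10L, 20L), rep(starts + 250L, 20L), "t1")
  outside <- ft("chr1", starts + 1000L, starts + 1120L, "t1")
  frags <- data.table::rbindlist(list(inpeak, outside))
  data.table::setorder(frags, chrom, start)
  groups <- stats::setNames(factor(c("trt", "ctl"), levels = c("ctl", "trt")),
                            c("t1", "c1"))
  prev <- Inf
  for (p in c(0, 0.5, 1, 2, 3)) {
    res <- downsample_peak_fragments(list(t1 = frags, c1 = frags[0]), peaks,
                                     p, groups, "trt", seed = 4)
    kept <- nrow(res$fragments$t1)
    expect_lte(kept, prev)
    prev <- kept
    # fragments outside perturbed peaks are bit-identical pass-through
    out_kept <- res$fragments$t1[res$fragments$t1$start %in% outside$start]
    expect_equal(out_kept, outside[order(outside$start)], ignore_attr = TRUE)
    # no fragment is ever created
    expect_true(all(paste(res$fragments$t1$start, res$fragments$t1$end) %in%
                      paste(frags$start, frags$end)))
  }
})

test_that("GC bias injection reshapes the fragment GC distribution", {
  fx <- shared_fixture()
  coh <- generate_baseline_cohort(fx$cfg, fx$ref)
  frags <- data.table::rbindlist(coh[1:2])     # ~1e5 fragments
  frags$sample_id <- "s1"
  # target = current empirical distribution: everything is kept
  cur <- tilted_gc_target(frags, fx$ref$genome, tilt = 0)
  same <- inject_gc_bias(frags, fx$ref$genome, cur, seed = 2)
  expect_equal(nrow(same), nrow(frags))

  # a smooth tilted target is approached within TV 0.05
  tgt <- tilted_gc_target(frags, fx$ref$genome, tilt = 5)
  out <- inject_gc_bias(frags, fx$ref$genome, tgt, seed = 2)
  gc <- fragment_gc(out, fx$ref$genome)
  bins <- findInterval(gc, tgt$breaks, rightmost.closed = TRUE,
                       all.inside = TRUE)
  emp <- tabulate(bins, length(tgt$probs)) / length(bins)
  expect_lt(tv_distance(emp, tgt$probs), 0.05)

  # target concentrated on one bin keeps only that bin
  gc_all <- fragment_gc(frags, fx$ref$genome)
  bin_all <- findInterval(gc_all, tgt$breaks, rightmost.closed = TRUE,
                          all.inside = TRUE)
  modal <- which.max(tabulate(bin_all, length(tgt$probs)))
  conc <- list(breaks = tgt$breaks,
               probs = replace(rep(0, length(tgt$probs)), modal, 1))
  only <- inject_gc_bias(frags, fx$ref$genome, conc, seed = 2)
  gco <- fragment_gc(only, fx$ref$genome)
  expect_true(all(findInterval(gco, tgt$breaks, rightmost.closed = TRUE,
                               all.inside = TRUE) == modal))
})

test_that("fragment-length bias injection hits the target class mixture", {
  fx <- shared_fixture()
  coh <- generate_baseline_cohort(fx$cfg, fx$ref)
  frags <- data.table::rbindlist(coh[1:2])
  cls <- classify_fragment_length(frags$end - frags$start)
  cur <- prop.table(table(cls))
  ident <- inject_fraglen_bias(frags, as.numeric(cur) |>
                                 stats::setNames(names(cur)), seed = 3)
  expect_equal(nrow(ident), nrow(frags))

  tgt <- c(NF = 0.7, mono = 0.2, di = 0.08, multi = 0.02)
  out <- inject_fraglen_bias(frags, tgt, seed = 3)
  emp <- prop.table(table(classify_fragment_length(out$end - out$start)))
  expect_lt(tv_distance(as.numeric(emp[names(tgt)]), tgt), 0.05)

  noNF <- inject_fraglen_bias(frags, c(NF = 0, mono = 0.6, di = 0.3,
                                       multi = 0.1), seed = 3)
  expect_true(all(noNF$end - noNF$start > 120))
})

test_that("cohort simulation is deterministic and tracks assigned fold-changes", {
  fx <- shared_fixture()
  coh <- generate_baseline_cohort(fx$cfg, fx$ref)
  chip <- generate_chip_peaks(fx$ref, "MOTIF001", frac_with_motif = 0.2,
                              n_chip = 200)
  sim0 <- simulate_cohort(coh, chip, fx$ref_tab, 0, fx$groups, "g2", seed = 6)
  expect_identical(sim0$fragments, coh)        # strength 0: byte-identical

  sim1 <- simulate_cohort(coh, chip, fx$ref_tab, 1, fx$groups, "g2", seed = 6)
  sim1b <- simulate_cohort(coh, chip, fx$ref_tab, 1, fx$groups, "g2", seed = 6)
  expect_identical(sim1$fragments, sim1b$fragments)
  expect_identical(sim1$truth$peak_fc, sim1b$truth$peak_fc)

  # per-peak group count ratios track the assigned fold-changes
  counts <- count_fragments_in_peaks(sim1$fragments, chip)
  g2 <- names(fx$groups)[fx$groups == "g2"]
  g1 <- names(fx$groups)[fx$groups == "g1"]
  ratio <- (rowSums(counts[, g2]) + 1) / (rowSums(counts[, g1]) + 1)
  expect_gt(cor(ratio, sim1$truth$peak_fc$fc, method = "spearman"), 0.8)

  expect_error(simulate_cohort(coh, chip, fx$ref_tab, 1,
                               stats::setNames(factor(rep("g1", 6)),
                                               names(fx$groups)), "g1"),
               "two groups")
})
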