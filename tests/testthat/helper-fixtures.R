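# Shared fixture objects (built once per test run) and independent oracles.

.shared <- new.env(parent = emptyenv())

# Standard benchmark fixture: reference genome/motifs/peaks, scanned match
# matrix, peak GC, group design, ChIP-like peak sets at two motif
# informativeness levels, and the activation reference fold-change table.
shared_fixture <- function() {
  if (is.null(.shared$fx)) {
    cfg <- fixture_config(seed = 3)
    ref <- generate_reference(cfg)
    seqs <- peak_sequences(ref$peaks, ref$genome)
    matches <- scan_motifs(ref$motifs, seqs)
    mm <- build_match_matrix(matches, ref$peaks, ref$motifs)
    .shared$fx <- list(
      cfg = cfg, ref = ref, seqs = seqs, matches = matches, mm = mm,
      gc = gc_annotate(ref$peaks, ref$genome)$gc,
      groups = fixture_groups(cfg),
      chip = generate_chip_peaks(ref, "MOTIF001", frac_with_motif = 0.8,
                                 n_chip = 40),
      chip_low = generate_chip_peaks(ref, "MOTIF001", frac_with_motif = 0.2,
                                     n_chip = 40),
      ref_tab = reference_fc_table("activation", seed = 5))
  }
  .shared$fx
}

# One chromVAR(z) > quantile > moderated-t analysis of a fragment cohort.
chromvar_differential <- function(frags, fx, B = 250L, bg_seed = 1L) {
  counts <- count_fragments_in_peaks(frags, fx$ref$peaks)
  bg <- chromvar_background_sets(counts, fx$gc, B = B, seed = bg_seed)
  cv <- chromvar_scores(counts, fx$mm, bg)
  differential_from_scores(cv$z, fx$groups, normalization = "quantile")
}

# ---- independent oracles -------------------------------------------------

# Quadratic brute-force overlap count (0-based half-open fragments vs
# 1-based closed GRanges peaks).
brute_force_count <- function(frags, peaks) {
  ps <- GenomicRanges::start(peaks) - 1L
  pe <- GenomicRanges::end(peaks)
  pc <- as.character(GenomicRanges::seqnames(peaks))
  out <- integer(length(peaks))
  for (i in seq_along(peaks)) {
    out[i] <- sum(frags$chrom == pc[i] & frags$start < pe[i] &
                    frags$end > ps[i])
  }
  out
}

# Naive per-site insertion accumulation around window centers.
brute_force_insertions <- function(frags, windows, half_width,
                                   pre_shifted = FALSE) {
  sites <- insertion_sites(frags, pre_shifted = pre_shifted)
  nw <- length(windows)
  centers <- floor((GenomicRanges::start(windows) - 1L +
                      GenomicRanges::end(windows) - 1L) / 2)
  wc <- as.character(GenomicRanges::seqnames(windows))
  ws <- as.character(GenomicRanges::strand(windows))
  out <- matrix(0L, nw, 2L * half_width + 1L)
  for (k in seq_len(nrow(sites))) {
    for (i in seq_len(nw)) {
      if (sites$chrom[k] != wc[i]) next
      off <- sites$pos[k] - centers[i]
      if (ws[i] == "-") off <- -off
      if (abs(off) <= half_width)
        out[i, off + half_width + 1L] <- out[i, off + half_width + 1L] + 1L
    }
  }
  out
}

# Fragment-table constructor for terse test setup.
ft <- function(chrom, start, end, sample_id = "s1") {
  data.table::data.table(chrom = chrom, start = as.integer(start),
                         end = as.integer(end), sample_id = sample_id)
}

# Sharp (informative) motif with a given consensus string.
consensus_motif <- function(name, consensus, p_main = 0.94) {
  codes <- match(strsplit(consensus, "")[[1L]], c("A", "C", "G", "T"))
  ppm <- matrix((1 - p_main) / 3, 4L, length(codes))
  ppm[cbind(codes, seq_along(codes))] <- p_main
  motif_model(name, sweep(ppm, 2L, colSums(ppm), "/"))
}

# Empirical distribution helpers.
tv_distance <- function(p, q) 0.5 * sum(abs(p - q))
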