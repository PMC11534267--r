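# Insertion-profile and footprint-based activity methods.

#' Convert peak-relative matches to genomic ranges
#'
#' @param matches Match table from [scan_motifs()] with `seqname` equal to
#'   peak ids.
#' @param peaks `GRanges` peak set with `peak_id`.
#' @return `GRanges` of motif matches with `motif` metadata and strand.
#' @export
matches_to_granges <- function(matches, peaks) {
  idx <- match(matches$seqname, peaks$peak_id)
  if (any(is.na(idx))) stop("matches reference unknown peak ids")
  ps <- GenomicRanges::start(peaks)[idx]    # 1-based peak start
  gr <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(peaks)[idx],
    IRanges::IRanges(start = ps + matches$start,
                     end = ps + matches$end - 1L),
    strand = matches$strand)
  gr$motif <- matches$motif
  gr
}

# Per-motif insertion profiles for one sample: motif x offset matrix.
motif_insertion_profiles <- function(frags, match_gr, half_width = 200L,
                                     stranded = FALSE, pre_shifted = FALSE) {
  w <- match_gr
  if (!stranded) GenomicRanges::strand(w) <- "*"
  ins <- count_insertions(frags, w, half_width = half_width,
                          pre_shifted = pre_shifted)
  rowsum(ins, group = w$motif)
}

# Centered moving average with edge replication.
smooth_profile <- function(x, window = 11L) {
  if (window <= 1L) return(x)
  h <- floor(window / 2)
  xp <- c(rep(x[1L], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / window, window), sides = 2L))[(h + 1L):(h + length(x))]
}

#' Insertion-profile motif activity model
#'
#' Counts shifted Tn5 insertions in +/- `half_width` bp windows around
#' in-peak motif matches. For each motif, the global (summed across
#' samples) insertion profile is smoothed by a centered moving average and
#' symmetrized, then normalized into positional weights. Each sample's
#' score is the weighted sum of its insertion counts, scaled to counts per
#' million of the sample's total in-window insertions and log1p
#' transformed; differential activity uses the moderated t-test.
#'
#' @param frag_list Named list of per-sample fragment tables.
#' @param matches Match table (see [scan_motifs()]) over the peak set.
#' @param peaks `GRanges` peak set (matches are restricted to it).
#' @param groups Two-group factor per sample.
#' @param half_width Window half width in bp (default 200).
#' @param smooth_window Moving-average window in bp (default 11).
#' @param stranded Orient windows by match strand (default FALSE).
#' @param pre_shifted Fragment endpoints already Tn5-corrected.
#' @return List with `scores` (`ActivityScores`, kind `"insertion"`) and
#'   `table` (`DifferentialTable`).
#' @export
insertion_model <- function(frag_list, matches, peaks, groups,
                            half_width = 200L, smooth_window = 11L,
                            stranded = FALSE, pre_shifted = FALSE) {
  match_gr <- matches_to_granges(matches, peaks)
  samples <- names(frag_list)
  profs <- lapply(frag_list, motif_insertion_profiles, match_gr = match_gr,
                  half_width = half_width, stranded = stranded,
                  pre_shifted = pre_shifted)
  motifs <- rownames(profs[[1L]])
  global <- Reduce(`+`, profs)
  keep <- rowSums(global) > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " motif(s) with no in-peak insertions")
    motifs <- motifs[keep]
  }
  scores <- matrix(0, length(motifs), length(samples),
                   dimnames = list(motifs, samples))
  tot <- vapply(profs, sum, numeric(1))          # in-window insertions per sample
  for (m in motifs) {
    g <- smooth_profile(global[m, ], smooth_window)
    g <- (g + rev(g)) / 2                        # symmetrize around the match
    wgt <- g / sum(g)
    for (j in seq_along(samples))
      scores[m, j] <- sum(wgt * profs[[j]][m, ])
  }
  scores <- log1p(sweep(scores, 2L, pmax(tot, 1), "/") * 1e6)
  sc <- new_activity_scores(scores, "insertion")
  list(scores = sc,
       table = differential_from_scores(sc, groups, normalization = "none"))
}

#' Footprint-depth plus flanking-accessibility test
#'
#' For each motif and sample, insertions are aggregated over in-peak
#' matches in three zones: the motif interior (`m`), the 20 bp footprint
#' flanks on each side (`f`), and the 200 bp accessibility flanks on each
#' side (`a`). Footprint depth is
#' `FPD = log2((f + eps)/|flank| / ((m + eps)/|motif|))` and flanking
#' accessibility `FA = log2(CPM(a) + 1)`. Group differences in FPD and FA
#' are tested separately with the moderated t-test and the two p-values
#' combined with Fisher's method; BH adjustment is applied to the combined
#' p-values. Sequence-bias correction is deliberately omitted (it cancels
#' across samples in a relative analysis).
#'
#' @param frag_list Named list of per-sample fragment tables.
#' @param matches Match table over the peak set.
#' @param peaks `GRanges` peak set.
#' @param groups Two-group factor per sample.
#' @param flank_fp Footprint flank width in bp (default 20).
#' @param flank_acc Accessibility flank width in bp (default 200).
#' @param eps Pseudocount added to aggregated counts (default 1).
#' @param pre_shifted Fragment endpoints already Tn5-corrected.
#' @return A `DifferentialTable` with `effect` = flanking-accessibility
#'   group difference and extra columns `effect_fpd`, `p_fpd`, `p_fa`.
#' @export
bagfoot_like <- function(frag_list, matches, peaks, groups, flank_fp = 20L,
                         flank_acc = 200L, eps = 1, pre_shifted = FALSE) {
  match_gr <- matches_to_granges(matches, peaks)
  GenomicRanges::strand(match_gr) <- "*"
  half_width <- flank_acc + max(GenomicRanges::width(match_gr))
  samples <- names(frag_list)
  motif_w <- GenomicRanges::width(match_gr)
  motifs <- sort(unique(match_gr$motif))
  mcount <- fcount <- acount <- matrix(0, length(motifs), length(samples),
                                       dimnames = list(motifs, samples))
  interior_len <- rowsum(2 * floor(motif_w / 2) + 1, match_gr$motif)[motifs, ]
  tot_ins <- numeric(length(samples))
  offs <- -half_width:half_width
  for (j in seq_along(samples)) {
    ins <- count_insertions(frag_list[[j]], match_gr, half_width = half_width,
                            pre_shifted = pre_shifted)
    tot_ins[j] <- sum(ins)
    hw <- floor(motif_w / 2)       # motif interior: center +/- hw
    inside <- abs(matrix(offs, nrow(ins), length(offs), byrow = TRUE)) <=
              matrix(hw, nrow(ins), length(offs))
    fpzone <- !inside &
      abs(matrix(offs, nrow(ins), length(offs), byrow = TRUE)) <=
      matrix(hw + flank_fp, nrow(ins), length(offs))
    aczone <- !inside & !fpzone
    mcount[, j] <- rowsum(rowSums(ins * inside), match_gr$motif)[motifs, ]
    fcount[, j] <- rowsum(rowSums(ins * fpzone), match_gr$motif)[motifs, ]
    acount[, j] <- rowsum(rowSums(ins * aczone), match_gr$motif)[motifs, ]
  }
  keep <- rowSums(mcount + fcount + acount) > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " motif(s) with zero insertion counts")
    mcount <- mcount[keep, , drop = FALSE]
    fcount <- fcount[keep, , drop = FALSE]
    acount <- acount[keep, , drop = FALSE]
    interior_len <- interior_len[keep]
    motifs <- motifs[keep]
  }
  nmatch <- as.vector(table(match_gr$motif)[motifs])
  flank_len <- 2 * flank_fp * nmatch
  motif_len <- interior_len
  fpd <- log2(((fcount + eps) / flank_len) / ((mcount + eps) / motif_len))
  fa <- log2(sweep(acount, 2L, pmax(tot_ins, 1), "/") * 1e6 + 1)
  t_fpd <- moderated_t(fpd, groups)
  t_fa <- moderated_t(fa, groups)
  t_fpd <- t_fpd[match(motifs, t_fpd$id), ]
  t_fa <- t_fa[match(motifs, t_fa$id), ]
  p <- fisher_combine(t_fpd$p, t_fa$p)
  out <- data.frame(id = motifs, effect = t_fa$effect, t = t_fa$t,
                    df = t_fa$df, p = p, p_adj = bh_adjust(p),
                    effect_fpd = t_fpd$effect, p_fpd = t_fpd$p,
                    p_fa = t_fa$p, row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("DifferentialTable", "data.frame")
  sort_differential(out)
}
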