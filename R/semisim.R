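# Semi-simulation engine: reference fold-change assignment, Eq-style
# peak-level fragment downsampling, and technical bias injection.

#' Assign reference fold-changes to ChIP peaks by enrichment matching
#'
#' ChIP peak enrichments are mapped onto the reference enrichment
#' distribution by rank (empirical quantile transform, nearest rank), and
#' each peak receives the log2 fold-change of the reference peak with the
#' closest transformed enrichment; ties among equally close reference
#' peaks are broken by a seeded uniform choice.
#'
#' @param enrichment Per-ChIP-peak enrichment scores (finite).
#' @param reference `data.frame` with columns `enrichment` and `log2FC`
#'   (>= 1 row).
#' @param seed RNG seed for tie breaking.
#' @return `data.table` with `enrichment`, matched `log2FC` and linear
#'   `fc = 2^log2FC` per peak.
#' @export
assign_reference_foldchanges <- function(enrichment, reference, seed = 1L) {
  if (any(!is.finite(enrichment)))
    stop("non-finite enrichment for peak(s): ",
         paste(utils::head(which(!is.finite(enrichment)), 5L), collapse = ", "))
  if (!all(c("enrichment", "log2FC") %in% names(reference)))
    stop("reference needs columns enrichment and log2FC")
  m <- nrow(reference)
  if (m < 1L) stop("reference table is empty")
  ord <- order(reference$enrichment)
  ref_e <- reference$enrichment[ord]
  ref_fc <- reference$log2FC[ord]
  n <- length(enrichment)
  u <- rank(enrichment, ties.method = "average") / n
  target <- ref_e[pmax(1L, ceiling(u * m))]      # nearest-rank quantile transform
  log2fc <- with_seed(seed, vapply(target, function(t) {
    d <- abs(ref_e - t)
    cand <- which(d == min(d))
    if (length(cand) > 1L) cand <- sample(cand, 1L)
    ref_fc[cand]
  }, numeric(1)))
  data.table::data.table(enrichment = enrichment, log2FC = log2fc,
                         fc = 2^log2fc)
}

# Assign each fragment of one sample to at most one perturbed peak: the
# peak with the largest overlap, ties toward the lower peak_id.
best_overlap_peak <- function(frags, peaks) {
  gr <- fragments_to_granges(frags)
  hits <- GenomicRanges::findOverlaps(gr, peaks)
  if (!length(hits)) return(rep(NA_integer_, nrow(frags)))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(IRanges::pintersect(gr[qh], peaks[sh]))
  dt <- data.table::data.table(q = qh, s = sh, ov = ov,
                               pid = peaks$peak_id[sh])
  data.table::setorder(dt, q, -ov, pid)
  dt <- dt[!duplicated(dt$q)]
  out <- rep(NA_integer_, nrow(frags))
  out[dt$q] <- dt$s
  out
}

#' Downsample fragments in perturbed peaks (per-peak fold-changes)
#'
#' For each perturbed peak i and each sample j of the group to be
#' downsampled, `n_ijs = min(ceil(n_ij0 * f_i), n_ij0)` fragments are kept
#' (sampled without replacement, seeded), with `f_i = FC_i^p` when
#' `log2(FC_i) < 0` (the perturbed group is downsampled) and
#' `f_i = FC_i^(-p)` when `log2(FC_i) > 0` (the control group is
#' downsampled). Strength 0 gives `f = 1` and reproduces the input
#' exactly. Fragments outside perturbed peaks pass through untouched; a
#' fragment overlapping several perturbed peaks is assigned to the one
#' with the largest overlap (ties toward the lower peak id).
#'
#' @param frag_list Named list of per-sample fragment tables.
#' @param peaks `GRanges` of perturbed (ChIP) peaks with `peak_id` and a
#'   per-peak `fc` column (linear fold-change).
#' @param strength Perturbation strength `p >= 0`.
#' @param groups Named two-level factor (names = sample ids).
#' @param perturbed_group Level of `groups` that carries the perturbation.
#' @param seed Master RNG seed; per-sample substreams are derived from it.
#' @return List with `fragments` (downsampled per-sample tables) and
#'   `manifest` (`data.table` with peak_id, fc, f, sample, group, n0, ns).
#' @export
downsample_peak_fragments <- function(frag_list, peaks, strength, groups,
                                      perturbed_group, seed = 1L) {
  if (strength < 0) stop("strength must be >= 0")
  if (is.null(peaks$fc) || any(peaks$fc <= 0)) stop("peaks need fc > 0")
  groups <- stats::setNames(as.factor(groups), names(groups))
  if (!perturbed_group %in% levels(groups))
    stop("perturbed_group not a level of groups")
  lfc <- log2(peaks$fc)
  f <- ifelse(lfc < 0, peaks$fc^strength, peaks$fc^(-strength))
  target_grp <- ifelse(lfc < 0, perturbed_group,
                       setdiff(levels(groups), perturbed_group))
  manifest <- list()
  out <- frag_list
  for (sname in names(frag_list)) {
    frags <- frag_list[[sname]]
    grp <- as.character(groups[[sname]])
    assigned <- best_overlap_peak(frags, peaks)
    rel_peaks <- which(target_grp == grp & abs(lfc) > 0)
    n0 <- tabulate(assigned, nbins = length(peaks))
    keep <- rep(TRUE, nrow(frags))
    sseed <- derive_seed(seed, match(sname, names(frag_list)))
    rows <- with_seed(sseed, {
      lapply(rel_peaks, function(i) {
        idx <- which(assigned == i)
        ns <- min(ceiling(n0[i] * f[i]), n0[i])
        if (ns < n0[i]) setdiff(idx, sort(sample(idx, ns))) else integer(0)
      })
    })
    drop_rows <- unlist(rows, use.names = FALSE)
    if (length(drop_rows)) keep[drop_rows] <- FALSE
    out[[sname]] <- frags[keep]
    ns_vec <- n0
    if (length(rel_peaks))
      ns_vec[rel_peaks] <- as.integer(pmin(ceiling(n0[rel_peaks] * f[rel_peaks]),
                                           n0[rel_peaks]))
    manifest[[sname]] <- data.table::data.table(
      peak_id = peaks$peak_id, fc = peaks$fc, f = f,
      group_downsampled = target_grp, sample = sname, group = grp,
      n0 = n0, ns = as.integer(ifelse(seq_along(peaks) %in% rel_peaks, ns_vec, n0)),
      downsampled = seq_along(peaks) %in% rel_peaks)
  }
  list(fragments = out, manifest = data.table::rbindlist(manifest))
}

# Rejection-sample fragments toward a target distribution over bins.
# keep probability per bin is target/current, scaled so the max is 1.
rejection_sample_bins <- function(frags, bin, target_probs, seed) {
  nb <- length(target_probs)
  cur <- tabulate(bin, nbins = nb) / max(length(bin), 1L)
  tp <- target_probs
  empty <- cur == 0 & tp > 0
  if (any(empty)) {
    warning("target mass on empty bin(s); renormalizing")
    tp[empty] <- 0
    tp <- tp / sum(tp)
  }
  ratio <- ifelse(cur > 0, tp / cur, 0)
  if (max(ratio) == 0) return(frags[0L])
  pkeep <- ratio / max(ratio)
  keep <- with_seed(seed, stats::runif(length(bin)) <= pkeep[bin])
  frags[keep]
}

#' Per-fragment GC content
#'
#' GC fraction of each fragment's sequence; ambiguous bases excluded from
#' the denominator.
#'
#' @param frags Fragment table.
#' @param genome `DNAStringSet` or FASTA path.
#' @return Numeric vector of GC fractions.
#' @export
fragment_gc <- function(frags, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gc <- numeric(nrow(frags))
  for (chr in unique(frags$chrom)) {
    idx <- which(frags$chrom == chr)
    subj <- genome[[chr]]
    st <- pmax(frags$start[idx] + 1L, 1L)
    en <- pmin(frags$end[idx], length(subj))
    v <- Biostrings::Views(subj, start = st, end = en)
    freq <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    denom <- pmax(rowSums(freq), 1L)
    gc[idx] <- (freq[, "C"] + freq[, "G"]) / denom
  }
  gc
}

#' Build a tilted GC target distribution from a fragment cohort
#'
#' Takes the empirical fragment GC histogram and reweights it by a
#' monotone exponential tilt `exp(tilt * (gc - center))`, emulating a
#' sample with a shifted GC preference while keeping the target inside
#' the support of the observed distribution.
#'
#' @param frags Fragment table defining the current distribution.
#' @param genome `DNAStringSet` or FASTA path.
#' @param tilt Tilt strength (default 5; 0 returns the empirical
#'   distribution).
#' @param bin_width GC bin width (default 0.05).
#' @return List with `breaks` and `probs` (a GC target for
#'   [inject_gc_bias()]).
#' @export
tilted_gc_target <- function(frags, genome, tilt = 5, bin_width = 0.05) {
  gc <- fragment_gc(frags, genome)
  breaks <- seq(0, 1, by = bin_width)
  mids <- breaks[-1L] - bin_width / 2
  bins <- findInterval(gc, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  cur <- tabulate(bins, nbins = length(mids)) / length(bins)
  probs <- cur * exp(tilt * (mids - mean(gc)))
  list(breaks = breaks, probs = probs / sum(probs))
}

#' Inject sample-specific GC-content bias
#'
#' Computes each fragment's GC fraction from the genome and keeps
#' fragments by seeded rejection sampling so the output GC histogram
#' approximates the target distribution (keep probability proportional to
#' target/current per bin, scaled so the maximum is 1).
#'
#' @param frags Fragment table of one sample.
#' @param genome `DNAStringSet` or FASTA path.
#' @param target List with `breaks` (bin edges covering `[0, 1]`) and
#'   `probs` (summing to 1).
#' @param seed RNG seed.
#' @return Filtered fragment table.
#' @export
inject_gc_bias <- function(frags, genome, target, seed = 1L) {
  stopifnot(abs(sum(target$probs) - 1) < 1e-9, all(target$probs >= 0))
  gc <- fragment_gc(frags, genome)
  bin <- findInterval(gc, target$breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  rejection_sample_bins(frags, bin, target$probs, seed)
}

#' Inject fragment-length class bias
#'
#' Same rejection-sampling contract as [inject_gc_bias()], over the four
#' nucleosome classes of [classify_fragment_length()].
#'
#' @param frags Fragment table of one sample.
#' @param class_probs Named probabilities for `NF`, `mono`, `di`, `multi`
#'   (summing to 1).
#' @param seed RNG seed.
#' @return Filtered fragment table.
#' @export
inject_fraglen_bias <- function(frags, class_probs, seed = 1L) {
  cls <- c("NF", "mono", "di", "multi")
  stopifnot(all(cls %in% names(class_probs)),
            abs(sum(class_probs) - 1) < 1e-9)
  bin <- as.integer(classify_fragment_length(frags$end - frags$start))
  rejection_sample_bins(frags, bin, as.numeric(class_probs[cls]), seed)
}

#' Run a full semi-simulation on a baseline cohort
#'
#' Pipeline: split samples into groups, match reference fold-changes to
#' the ChIP peaks by enrichment ([assign_reference_foldchanges()]),
#' downsample fragments in perturbed peaks
#' ([downsample_peak_fragments()]), then optionally inject GC and/or
#' fragment-length biases per sample. Fully reproducible from (inputs,
#' seed).
#'
#' @param frag_list Named list of baseline per-sample fragment tables
#'   (>= 1 sample per group).
#' @param chip_peaks `GRanges` of ChIP peaks with `peak_id` and `score`
#'   (enrichment).
#' @param reference Reference `data.frame` (enrichment, log2FC).
#' @param strength Perturbation strength (>= 0).
#' @param groups Named two-level factor over the samples.
#' @param perturbed_group Group label carrying the perturbation.
#' @param gc_bias Optional named list sample -> GC target (see
#'   [inject_gc_bias()]); requires `genome`.
#' @param fraglen_bias Optional named list sample -> class probabilities.
#' @param genome Genome (`DNAStringSet` or FASTA path) for GC bias.
#' @param scenario Label recorded in the truth manifest.
#' @param true_motif Name of the perturbed motif, recorded in the truth.
#' @param seed Master seed.
#' @return List with `fragments` and `truth` (scenario, strength, seed,
#'   true motif, per-peak fold-changes, downsampling manifest).
#' @export
simulate_cohort <- function(frag_list, chip_peaks, reference, strength,
                            groups, perturbed_group, gc_bias = NULL,
                            fraglen_bias = NULL, genome = NULL,
                            scenario = "activation", true_motif = NA_character_,
                            seed = 1L) {
  groups <- stats::setNames(as.factor(groups), names(groups) %||% names(frag_list))
  if (nlevels(groups) != 2L || any(table(groups) < 1L))
    stop("need two groups with >= 1 sample each")
  fcs <- assign_reference_foldchanges(chip_peaks$score, reference,
                                      seed = derive_seed(seed, 1L))
  chip_peaks$fc <- fcs$fc
  ds <- downsample_peak_fragments(frag_list, chip_peaks, strength, groups,
                                  perturbed_group,
                                  seed = derive_seed(seed, 2L))
  frags <- ds$fragments
  if (!is.null(gc_bias)) {
    if (is.null(genome)) stop("genome required for GC bias injection")
    for (sname in names(gc_bias))
      frags[[sname]] <- inject_gc_bias(frags[[sname]], genome,
                                       gc_bias[[sname]],
                                       seed = derive_seed(seed, 3L,
                                                          match(sname, names(frags))))
  }
  if (!is.null(fraglen_bias)) {
    for (sname in names(fraglen_bias))
      frags[[sname]] <- inject_fraglen_bias(frags[[sname]],
                                            fraglen_bias[[sname]],
                                            seed = derive_seed(seed, 4L,
                                                               match(sname, names(frags))))
  }
  truth <- list(scenario = scenario, strength = strength, seed = seed,
                true_motif = true_motif, perturbed_group = perturbed_group,
                peak_fc = data.table::data.table(peak_id = chip_peaks$peak_id,
                                                 enrichment = chip_peaks$score,
                                                 log2FC = fcs$log2FC,
                                                 fc = fcs$fc),
                manifest = ds$manifest)
  list(fragments = frags, truth = truth)
}
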