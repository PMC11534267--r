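# Deterministic synthetic fixture generator: genome, motifs, peaks,
# ChIP-like binding sets and baseline fragment cohorts. Everything is
# synthetic and generated in code; no external data is required.

#' Default fixture configuration
#'
#' Scale: 2 chromosomes x 500 kb, 500 non-overlapping 300 bp peaks, 50
#' motifs of length 8-12, two groups of 3 samples, negative-binomial peak
#' counts (dispersion 0.2) with ~100 fragments per peak plus a uniform
#' genome-wide background, and an NF/mono/di/multi fragment-length
#' mixture.
#'
#' @param ... Overrides for any default field.
#' @return Named list of configuration values.
#' @export
fixture_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_chroms = 2L,
    chrom_length = 500000L,
    genome_gc = 0.41,
    n_peaks = 500L,
    peak_width = 300L,
    n_motifs = 50L,
    motif_length_range = c(8L, 12L),
    planted_motif_fraction = 0.10,   # peaks per motif carrying an instance
    n_per_group = 3L,
    mean_frags_per_peak = 100,
    dispersion = 0.2,
    len_mixture = list(weights = c(NF = 0.55, mono = 0.33, di = 0.10,
                                   multi = 0.02),
                       means = c(70, 200, 400, 620),
                       sds = c(15, 35, 45, 60)),
    background_rate = 2e-5            # background fragments per bp per sample
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  utils::modifyList(cfg, over)
}

# Random informative PPM: each column concentrated on one base.
random_ppm <- function(len) {
  ppm <- matrix(0, 4L, len)
  for (l in seq_len(len)) {
    main <- sample.int(4L, 1L)
    p_main <- stats::runif(1L, 0.75, 0.97)
    rest <- stats::runif(3L)
    rest <- rest / sum(rest) * (1 - p_main)
    ppm[-main, l] <- rest
    ppm[main, l] <- p_main
  }
  ppm
}

#' Generate a synthetic reference: genome, motifs, peaks, planted matches
#'
#' Builds a random genome at the configured GC, places non-overlapping
#' peaks, draws informative random motifs, and writes sampled motif
#' instances into a random subset of peaks. The returned truth table
#' records every planted instance. Fully deterministic from the config
#' seed.
#'
#' @param config From [fixture_config()].
#' @return List with `genome` (`DNAStringSet`), `motifs`, `peaks`
#'   (`GRanges` with `peak_id`, `accessibility`), `truth` (`data.table`
#'   peak_id/motif/offset), `config`.
#' @export
generate_reference <- function(config = fixture_config()) {
  with_seed(config$seed, {
    gc <- config$genome_gc
    base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    genome <- Biostrings::DNAStringSet(vapply(seq_len(config$n_chroms),
      function(i) paste(sample(DNA_BASES, config$chrom_length, replace = TRUE,
                               prob = base_p), collapse = ""), character(1)))
    names(genome) <- paste0("chr", seq_len(config$n_chroms))
    # non-overlapping peak placement on a grid with random jitter
    per_chrom <- ceiling(config$n_peaks / config$n_chroms)
    slots <- floor(config$chrom_length / (config$peak_width * 3L))
    if (per_chrom > slots) stop("peaks do not fit in the genome")
    chrom <- character(0); start <- integer(0)
    for (i in seq_len(config$n_chroms)) {
      pick <- sort(sample.int(slots, per_chrom))
      s <- (pick - 1L) * config$peak_width * 3L +
        sample.int(config$peak_width, per_chrom, replace = TRUE)
      chrom <- c(chrom, rep(names(genome)[i], per_chrom))
      start <- c(start, s)
    }
    keep <- seq_len(config$n_peaks)
    peaks <- peak_set(chrom[keep], start[keep], start[keep] + config$peak_width)
    peaks$accessibility <- stats::rlnorm(length(peaks), meanlog = 0, sdlog = 0.5)
    lens <- sample(seq(config$motif_length_range[1L],
                       config$motif_length_range[2L]),
                   config$n_motifs, replace = TRUE)
    motifs <- lapply(seq_len(config$n_motifs), function(k)
      motif_model(sprintf("MOTIF%03d", k), random_ppm(lens[k])))
    names(motifs) <- vapply(motifs, function(m) m$name, character(1))
    # plant instances, avoiding overlaps between planted sites in a peak
    gchars <- lapply(as.character(genome), function(s) strsplit(s, "")[[1L]])
    occupied <- vector("list", length(peaks))   # occupied offsets per peak
    truth <- list()
    n_plant <- round(config$planted_motif_fraction * length(peaks))
    for (m in if (n_plant > 0L) motifs else list()) {
      L <- ncol(m$ppm)
      # instances are drawn from the PPM conditional on being strong
      # matches (p < 1e-5): planted sites represent bound, functional sites
      lod <- motif_log_odds(m)
      null <- pwm_null_distribution(lod, m$background)
      draw_instance <- function() {
        for (try in 1:50) {
          codes <- vapply(seq_len(L), function(l)
            sample.int(4L, 1L, prob = m$ppm[, l]), integer(1))
          sint <- sum(null$int[cbind(codes, seq_len(L))])
          if (null$tail[sint + 1L] < 1e-5) return(DNA_BASES[codes])
        }
        DNA_BASES[apply(m$ppm, 2L, which.max)]   # fall back to consensus
      }
      tgt <- sample(seq_along(peaks), n_plant)
      rec_peak <- character(0); rec_off <- integer(0)
      for (i in tgt) {
        off <- NA_integer_
        for (try in 1:20) {
          cand <- sample.int(config$peak_width - L, 1L)
          if (!any((cand:(cand + L - 1L)) %in% occupied[[i]])) {
            off <- cand
            break
          }
        }
        if (is.na(off)) next      # peak too crowded; skip this plant
        occupied[[i]] <- c(occupied[[i]], off:(off + L - 1L))
        inst <- draw_instance()
        chr <- as.character(GenomicRanges::seqnames(peaks)[i])
        pos <- GenomicRanges::start(peaks)[i] + off - 1L    # 1-based
        gchars[[chr]][pos:(pos + L - 1L)] <- inst
        rec_peak <- c(rec_peak, peaks$peak_id[i])
        rec_off <- c(rec_off, off - 1L)
      }
      truth[[m$name]] <- data.table::data.table(
        peak_id = rec_peak, motif = m$name, offset = rec_off)
    }
    genome <- Biostrings::DNAStringSet(vapply(gchars, paste, character(1),
                                              collapse = ""))
    truth <- if (length(truth)) data.table::rbindlist(truth) else
      data.table::data.table(peak_id = character(), motif = character(),
                             offset = integer())
    list(genome = genome, motifs = motifs, peaks = peaks,
         truth = truth, config = config)
  })
}

# Draw fragment lengths from the configured nucleosome-class mixture.
draw_fragment_lengths <- function(n, mix) {
  cls <- sample.int(4L, n, replace = TRUE, prob = mix$weights)
  len <- round(stats::rnorm(n, mean = mix$means[cls], sd = mix$sds[cls]))
  pmax(len, 20L)
}

#' Generate a baseline fragment cohort
#'
#' Per peak and sample, a negative-binomial fragment count with mean
#' proportional to the peak's accessibility; fragment midpoints are placed
#' around peak centers (Gaussian, sd = peak width / 4), lengths drawn from
#' the NF/mono/di/multi mixture, plus uniform genome-wide background
#' fragments.
#'
#' @param config From [fixture_config()].
#' @param reference From [generate_reference()].
#' @param seed Optional seed override (defaults to `config$seed + 1`).
#' @return Named list of per-sample fragment `data.table`s (samples
#'   `s1..s{2n}`; the first `n_per_group` belong to group "g1").
#' @export
generate_baseline_cohort <- function(config, reference, seed = NULL) {
  seed <- seed %||% (config$seed + 1L)
  n_samples <- 2L * config$n_per_group
  peaks <- reference$peaks
  centers <- floor((GenomicRanges::start(peaks) + GenomicRanges::end(peaks)) / 2)
  chroms <- as.character(GenomicRanges::seqnames(peaks))
  chrom_len <- stats::setNames(Biostrings::width(reference$genome),
                               names(reference$genome))
  mu <- config$mean_frags_per_peak * peaks$accessibility /
        mean(peaks$accessibility)
  with_seed(seed, {
    out <- list()
    for (j in seq_len(n_samples)) {
      counts <- stats::rnbinom(length(peaks), mu = mu,
                               size = 1 / config$dispersion)
      pk <- rep(seq_along(peaks), counts)
      mid <- round(stats::rnorm(length(pk), mean = centers[pk],
                                sd = config$peak_width / 4))
      len <- draw_fragment_lengths(length(pk), config$len_mixture)
      st <- mid - floor(len / 2)
      n_bg <- stats::rpois(1L, config$background_rate * sum(chrom_len))
      bg_chr <- sample(names(chrom_len), n_bg, replace = TRUE,
                       prob = chrom_len / sum(chrom_len))
      bg_len <- draw_fragment_lengths(n_bg, config$len_mixture)
      bg_st <- floor(stats::runif(n_bg) * (chrom_len[bg_chr] - bg_len))
      dt <- data.table::data.table(
        chrom = c(chroms[pk], bg_chr),
        start = as.integer(c(st, bg_st)),
        end = as.integer(c(st + len, bg_st + bg_len)),
        sample_id = sprintf("s%d", j))
      dt <- dt[dt$start >= 0L & dt$end <= chrom_len[dt$chrom]]
      data.table::setorder(dt, chrom, start, end)
      out[[sprintf("s%d", j)]] <- dt
    }
    out
  })
}

#' Default group assignment for a fixture cohort
#' @param config From [fixture_config()].
#' @return Named factor sample -> group (`g1`, `g2`).
#' @export
fixture_groups <- function(config) {
  n <- config$n_per_group
  stats::setNames(factor(rep(c("g1", "g2"), each = n)),
                  sprintf("s%d", seq_len(2L * n)))
}

#' Generate a synthetic ChIP-like binding peak set for one motif
#'
#' The ChIP set is a sample of the motif's planted peaks (a fraction
#' `frac_with_motif` of the set) topped up with motif-free peaks, with
#' lognormal enrichment scores whose median is higher for motif-bearing
#' peaks. `frac_with_motif = 1` emulates a highly motif-informative
#' (CTCF-like) factor; low values emulate factors whose binding is poorly
#' captured by the motif.
#'
#' @param reference From [generate_reference()].
#' @param motif Motif name to perturb.
#' @param frac_with_motif Fraction of ChIP peaks carrying a planted match.
#' @param n_chip Number of ChIP peaks (default 200).
#' @param seed RNG seed (defaults to `config$seed + 2`).
#' @return `GRanges` ChIP peak set with `peak_id`, `score` (enrichment)
#'   and `has_motif` metadata.
#' @export
generate_chip_peaks <- function(reference, motif, frac_with_motif = 0.8,
                                n_chip = 200L, seed = NULL) {
  seed <- seed %||% (reference$config$seed + 2L)
  if (!motif %in% names(reference$motifs)) stop("unknown motif: ", motif)
  planted <- unique(reference$truth$peak_id[reference$truth$motif == motif])
  n_with <- round(frac_with_motif * n_chip)
  if (n_with > length(planted))
    stop("not enough motif-bearing peaks: have ", length(planted),
         ", need ", n_with)
  with_seed(seed, {
    with_ids <- sample(planted, n_with)
    free <- setdiff(reference$peaks$peak_id, planted)
    without_ids <- sample(free, n_chip - n_with)
    ids <- c(with_ids, without_ids)
    has <- c(rep(TRUE, n_with), rep(FALSE, n_chip - n_with))
    enr <- stats::rlnorm(n_chip, meanlog = ifelse(has, 1.2, 0.4), sdlog = 0.5)
    chip <- reference$peaks[match(ids, reference$peaks$peak_id)]
    chip$score <- enr
    chip$has_motif <- has
    chip$accessibility <- NULL
    chip
  })
}

#' Synthetic reference fold-change tables for the two scenarios
#'
#' Emulates the joint (enrichment, log2FC) structure of the two
#' differential-binding scenarios driving the downsampler: `activation`
#' (virtually all sites affected, high-occupancy sites most strongly, log
#' fold-changes often large) and `haploinsufficiency` (overall mild
#' changes that preferentially spare high-occupancy sites). Both tables
#' are synthetic stand-ins generated from these qualitative shapes, not
#' fits to any real dataset. All log2FCs are negative, so the perturbed
#' group is the one downsampled.
#'
#' @param scenario `"activation"` or `"haploinsufficiency"`.
#' @param n Number of reference peaks (default 1000).
#' @param seed RNG seed.
#' @return `data.table` with columns `enrichment`, `log2FC`.
#' @export
reference_fc_table <- function(scenario = c("activation", "haploinsufficiency"),
                               n = 1000L, seed = 1L) {
  scenario <- match.arg(scenario)
  with_seed(seed, {
    enr <- stats::rlnorm(n, meanlog = 1, sdlog = 0.6)
    u <- rank(enr) / n
    lfc <- if (scenario == "activation")
      -abs(stats::rnorm(n, mean = 2.8 * u + 0.5, sd = 0.35)) - 0.1
    else
      -abs(stats::rnorm(n, mean = 0.8 * (1 - u) + 0.1, sd = 0.2))
    data.table::data.table(enrichment = enr, log2FC = lfc)
  })
}
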