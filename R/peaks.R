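#' Construct a peak set
#'
#' Builds a `GRanges` peak set from 0-based half-open coordinates, assigning
#' unique peak identifiers.
#'
#' @param chrom,start,end Vectors of coordinates (BED convention).
#' @param peak_id Optional identifiers; generated when `NULL`.
#' @param score Optional per-peak score (e.g. ChIP enrichment).
#' @return `GRanges` with `peak_id` (and optionally `score`) metadata.
#' @export
peak_set <- function(chrom, start, end, peak_id = NULL, score = NULL) {
  if (any(start < 0L)) stop("peak coordinates must be non-negative")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1L, end = end))
  if (is.null(peak_id))
    peak_id <- sprintf("peak_%05d", seq_along(gr))
  if (anyDuplicated(peak_id)) stop("peak_ids must be unique")
  gr$peak_id <- as.character(peak_id)
  if (!is.null(score)) gr$score <- score
  gr
}

#' Read peaks from a BED file
#'
#' Accepts BED3 to BED6; column 4 is used as `peak_id`, column 5 as `score`.
#'
#' @param path BED file path (optionally gzipped).
#' @return `GRanges` peak set.
#' @export
read_peaks <- function(path) {
  dt <- fread_maybe_gz(path)
  if (nrow(dt) == 0L) stop("empty peak file: ", path)
  peak_set(as.character(dt[[1L]]), as.integer(dt[[2L]]), as.integer(dt[[3L]]),
           peak_id = if (ncol(dt) >= 4L) as.character(dt[[4L]]) else NULL,
           score = if (ncol(dt) >= 5L) as.numeric(dt[[5L]]) else NULL)
}

#' Write peaks to BED
#'
#' @param peaks `GRanges` peak set.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end   = GenomicRanges::end(peaks),
    name  = peaks$peak_id %||% sprintf("peak_%05d", seq_along(peaks)),
    score = peaks$score %||% 0
  )
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, compress = "auto")
  invisible(path)
}

#' Merge peak sets and resize to a fixed width
#'
#' Takes the union of the input peak sets, merges overlapping or adjacent
#' intervals, then re-centers each merged interval and fixes it to `width`
#' bp. Merged intervals are non-overlapping before resizing; resized peaks
#' may re-overlap, which is allowed. For even widths the center ties toward
#' the lower coordinate. Peaks extending below position 0 are clipped with a
#' warning.
#'
#' @param peaksets A `GRanges` or list of `GRanges`.
#' @param width Target width in bp (default 300).
#' @return `GRanges` peak set with fresh `peak_id`s.
#' @export
resize_and_merge_peaks <- function(peaksets, width = 300L) {
  if (width < 1L) stop("width must be >= 1")
  if (!is.list(peaksets)) peaksets <- list(peaksets)
  all <- suppressWarnings(do.call(c, lapply(peaksets, function(g) {
    GenomicRanges::granges(g)
  })))
  merged <- GenomicRanges::reduce(all)
  s0 <- GenomicRanges::start(merged) - 1L         # 0-based
  e0 <- GenomicRanges::end(merged)                # half-open end
  center <- floor((s0 + e0) / 2)
  new_s <- center - floor(width / 2)
  if (any(new_s < 0L)) {
    warning("resized peak(s) clipped at position 0")
    new_s <- pmax(new_s, 0L)
  }
  peak_set(as.character(GenomicRanges::seqnames(merged)), new_s, new_s + width)
}

#' Annotate peaks with GC content
#'
#' GC fraction is (G+C)/(A+C+G+T) over the peak sequence; ambiguous bases
#' are excluded from the denominator.
#'
#' @param peaks `GRanges` peak set.
#' @param genome A `DNAStringSet` (named by chromosome) or FASTA path.
#' @return The peak set with a `gc` metadata column.
#' @export
gc_annotate <- function(peaks, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  chroms <- as.character(GenomicRanges::seqnames(peaks))
  missing <- setdiff(unique(chroms), names(genome))
  if (length(missing))
    stop("chromosome(s) missing from genome: ", paste(missing, collapse = ", "))
  gc <- numeric(length(peaks))
  for (chr in unique(chroms)) {
    idx <- which(chroms == chr)
    subj <- genome[[chr]]
    st <- pmax(GenomicRanges::start(peaks)[idx], 1L)
    en <- pmin(GenomicRanges::end(peaks)[idx], length(subj))
    v <- Biostrings::Views(subj, start = st, end = en)
    freq <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    denom <- rowSums(freq)
    gc[idx] <- ifelse(denom > 0, (freq[, "C"] + freq[, "G"]) / denom, NA_real_)
  }
  peaks$gc <- gc
  peaks
}

#' Extract peak sequences
#'
#' @param peaks `GRanges` peak set with `peak_id`.
#' @param genome `DNAStringSet` or FASTA path.
#' @return `DNAStringSet` named by `peak_id`.
#' @export
peak_sequences <- function(peaks, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  chroms <- as.character(GenomicRanges::seqnames(peaks))
  seqs <- vector("list", length(peaks))
  for (chr in unique(chroms)) {
    idx <- which(chroms == chr)
    subj <- genome[[chr]]
    st <- pmax(GenomicRanges::start(peaks)[idx], 1L)
    en <- pmin(GenomicRanges::end(peaks)[idx], length(subj))
    seqs[idx] <- as.list(as.character(Biostrings::Views(subj, start = st, end = en)))
  }
  out <- Biostrings::DNAStringSet(unlist(seqs))
  names(out) <- peaks$peak_id
  out
}
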