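#' Read an ATAC fragment table
#'
#' Reads a BED-like tab-separated fragment file (plain or gzipped) with
#' columns chrom, start, end and optionally a sample/barcode column.
#' Coordinates are 0-based half-open (BED convention) and are kept that way
#' in memory. The returned table is sorted by (chrom, start, end).
#'
#' @param path Path to a TSV/BED fragment file, optionally gzipped.
#' @param sample_id Sample label to assign; if `NULL` and the file has a
#'   fourth column, that column is used.
#' @return A `data.table` with columns `chrom`, `start`, `end`, `sample_id`.
#' @export
read_fragments <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("fragment file not found: ", path)
  dt <- fread_maybe_gz(path)
  if (nrow(dt) == 0L) stop("empty fragment file: ", path)
  if (ncol(dt) < 3L) stop("fragment file must have >= 3 tab-separated columns: ", path)
  out <- data.table::data.table(
    chrom = as.character(dt[[1L]]),
    start = suppressWarnings(as.integer(dt[[2L]])),
    end   = suppressWarnings(as.integer(dt[[3L]]))
  )
  bad <- which(is.na(out$start) | is.na(out$end))
  if (length(bad))
    stop("unparseable coordinates in ", path, " at line(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  bad <- which(out$start >= out$end | out$start < 0L)
  if (length(bad))
    stop("invalid fragment interval (need 0 <= start < end) in ", path,
         " at line(s): ", paste(utils::head(bad, 5L), collapse = ", "))
  if (is.null(sample_id)) {
    out$sample_id <- if (ncol(dt) >= 4L) as.character(dt[[4L]]) else basename(path)
  } else {
    out$sample_id <- as.character(sample_id)
  }
  data.table::setorder(out, chrom, start, end)
  out[]
}

#' Write a fragment table to BED-like TSV
#'
#' @param frags Fragment `data.table` (chrom, start, end, sample_id).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(frags, path) {
  data.table::fwrite(frags[, c("chrom", "start", "end", "sample_id"), with = FALSE],
                     path, sep = "\t", col.names = FALSE, compress = "auto")
  invisible(path)
}

#' Filter fragments by length
#'
#' Keeps fragments whose length (end - start) lies within the closed interval
#' `[min_len, max_len]`. Defaults select nucleosome-free fragments
#' (30--120 bp). Input order is preserved.
#'
#' @param frags Fragment `data.table`.
#' @param min_len,max_len Inclusive length bounds in bp.
#' @return Filtered fragment `data.table`.
#' @export
filter_fragments_by_length <- function(frags, min_len = 30L, max_len = 120L) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  len <- frags$end - frags$start
  frags[len >= min_len & len <= max_len]
}

#' Classify fragment lengths into nucleosome classes
#'
#' Fixed thresholds define nucleosome-free (NF), mono-, di- and
#' multi-nucleosome fragments: (0, 120], (120, 300], (300, 500], (500, Inf).
#'
#' @param length Integer vector of fragment lengths (bp), all >= 1.
#' @return Factor with levels `NF`, `mono`, `di`, `multi`.
#' @export
classify_fragment_length <- function(length) {
  if (any(length <= 0)) stop("fragment lengths must be >= 1")
  cut(length, breaks = c(0, 120, 300, 500, Inf),
      labels = c("NF", "mono", "di", "multi"), right = TRUE)
}

# Convert a 0-based half-open fragment table to a 1-based GRanges.
fragments_to_granges <- function(frags) {
  GenomicRanges::GRanges(frags$chrom,
                         IRanges::IRanges(start = frags$start + 1L, end = frags$end))
}

#' Count fragments overlapping peaks
#'
#' Cell (i, j) is the number of sample-j fragments overlapping peak i by at
#' least 1 bp. A fragment overlapping several peaks increments every one of
#' them (in contrast to the simulator, which assigns each fragment to a
#' single best-overlap peak).
#'
#' @param frags Either a single fragment `data.table` with a `sample_id`
#'   column covering several samples, or a named list of per-sample tables.
#' @param peaks A `GRanges` of peaks with a `peak_id` metadata column.
#' @return Integer matrix peaks x samples with dimnames.
#' @export
count_fragments_in_peaks <- function(frags, peaks) {
  if (length(peaks) == 0L) stop("peaks must be non-empty")
  if (is.data.frame(frags)) frags <- split(frags, frags$sample_id)
  samples <- names(frags)
  m <- matrix(0L, nrow = length(peaks), ncol = length(samples),
              dimnames = list(peaks$peak_id, samples))
  for (j in seq_along(samples)) {
    gr <- fragments_to_granges(frags[[j]])
    m[, j] <- GenomicRanges::countOverlaps(peaks, gr, minoverlap = 1L)
  }
  m
}

#' Shifted Tn5 insertion sites of fragments
#'
#' Each fragment contributes two insertion sites: `start + 4` and `end - 5`
#' in 0-based coordinates (the standard Tn5 offset correction). With
#' `pre_shifted = TRUE` the fragment endpoints are taken as already
#' corrected, i.e. sites at `start` and `end - 1`.
#'
#' @param frags Fragment `data.table`.
#' @param pre_shifted Logical; disable the +4/-5 shift.
#' @return `data.table` with columns `chrom`, `pos` (0-based site).
#' @export
insertion_sites <- function(frags, pre_shifted = FALSE) {
  if (pre_shifted) {
    s1 <- frags$start; s2 <- frags$end - 1L
  } else {
    s1 <- frags$start + 4L; s2 <- frags$end - 5L
  }
  data.table::data.table(chrom = rep(frags$chrom, 2L), pos = c(s1, s2))
}

#' Count Tn5 insertions around window centers
#'
#' Accumulates shifted insertion events per relative offset in
#' `[-half_width, +half_width]` around each window center. Windows on the
#' minus strand have their offset axis reversed.
#'
#' @param frags Fragment `data.table` (one sample).
#' @param windows `GRanges` of windows; the window center is the midpoint.
#'   An optional strand orients the offset axis.
#' @param half_width Half window width in bp (default 200).
#' @param pre_shifted Passed to [insertion_sites()].
#' @return Integer matrix windows x offsets; column names are the offsets
#'   `-half_width:half_width`.
#' @export
count_insertions <- function(frags, windows, half_width = 200L, pre_shifted = FALSE) {
  offs <- -half_width:half_width
  nw <- length(windows)
  out <- matrix(0L, nrow = nw, ncol = length(offs),
                dimnames = list(NULL, as.character(offs)))
  if (nrow(frags) == 0L || nw == 0L) return(out)
  sites <- insertion_sites(frags, pre_shifted = pre_shifted)
  sgr <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(start = sites$pos + 1L, width = 1L))
  centers0 <- floor((GenomicRanges::start(windows) - 1L + GenomicRanges::end(windows) - 1L) / 2)
  wgr <- GenomicRanges::GRanges(GenomicRanges::seqnames(windows),
                                IRanges::IRanges(start = centers0 + 1L - half_width,
                                                 end = centers0 + 1L + half_width))
  hits <- GenomicRanges::findOverlaps(wgr, sgr)
  if (length(hits) == 0L) return(out)
  qh <- S4Vectors::queryHits(hits)
  off <- sites$pos[S4Vectors::subjectHits(hits)] - centers0[qh]
  neg <- as.character(GenomicRanges::strand(windows))[qh] == "-"
  off[neg] <- -off[neg]
  idx <- (off + half_width) * nw + qh   # column-major linear index
  tab <- tabulate(idx, nbins = nw * length(offs))
  out[] <- as.integer(tab)
  out
}
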