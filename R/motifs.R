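DNA_BASES <- c("A", "C", "G", "T")

#' Construct a motif model
#'
#' A motif model is a position probability matrix (PPM) with 4 rows
#' (A, C, G, T), an effective site count used for pseudocounts and merging,
#' and a background base distribution.
#'
#' @param name Motif name.
#' @param ppm 4 x L numeric matrix of column-stochastic base probabilities.
#' @param nsites Effective number of sites behind the PPM (default 100).
#' @param background Background base probabilities (default uniform).
#' @return An object of class `MotifModel`.
#' @export
motif_model <- function(name, ppm, nsites = 100, background = rep(0.25, 4)) {
  ppm <- as.matrix(ppm)
  if (nrow(ppm) != 4L) stop("ppm must have 4 rows (A, C, G, T)")
  if (any(ppm < 0)) stop("ppm probabilities must be >= 0")
  cs <- colSums(ppm)
  if (any(abs(cs - 1) > 1e-9)) stop("ppm columns must sum to 1")
  rownames(ppm) <- DNA_BASES
  stopifnot(length(background) == 4L, abs(sum(background) - 1) < 1e-6)
  structure(list(name = as.character(name), ppm = ppm,
                 nsites = nsites, background = as.numeric(background)),
            class = "MotifModel")
}

#' @export
print.MotifModel <- function(x, ...) {
  cat("MotifModel", x$name, "-", ncol(x$ppm), "positions, nsites", x$nsites, "\n")
  cat("consensus:", motif_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a motif (most probable base per column)
#' @param motif A `MotifModel`.
#' @return Character scalar.
#' @export
motif_consensus <- function(motif) {
  paste(DNA_BASES[apply(motif$ppm, 2L, which.max)], collapse = "")
}

#' Per-column information content of a PPM
#'
#' IC of a column is `2 + sum(p * log2(p))` bits (0 log 0 taken as 0),
#' i.e. 2 minus the column entropy.
#'
#' @param motif A `MotifModel` or a bare 4 x L PPM.
#' @return Numeric vector of length L.
#' @export
motif_ic <- function(motif) {
  ppm <- if (inherits(motif, "MotifModel")) motif$ppm else motif
  apply(ppm, 2L, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

#' Reverse complement of a motif
#' @param motif A `MotifModel`.
#' @return A `MotifModel` on the opposite strand.
#' @export
motif_revcomp <- function(motif) {
  ppm <- motif$ppm[4:1, rev(seq_len(ncol(motif$ppm))), drop = FALSE]
  rownames(ppm) <- DNA_BASES
  motif_model(motif$name, ppm, nsites = motif$nsites, background = motif$background)
}

#' Read motifs in JASPAR text format
#'
#' Parses the four-row `A [ ... ]` count/frequency block per motif. Counts
#' are converted to probabilities; `nsites` is the median column total
#' (or 100 if the matrix is already probabilities).
#'
#' @param path JASPAR-format text file.
#' @return Named list of `MotifModel`s.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no JASPAR motif headers found in ", path)
  out <- list()
  for (i in seq_along(hdr)) {
    name <- sub("^>\\s*", "", lines[hdr[i]])
    name <- strsplit(name, "\\s+")[[1L]]
    name <- if (length(name) >= 2L) name[2L] else name[1L]
    block <- lines[(hdr[i] + 1L):(if (i < length(hdr)) hdr[i + 1L] - 1L else length(lines))]
    rows <- lapply(block[1:4], function(l) {
      l <- sub("^\\s*[ACGT]", "", l)
      as.numeric(regmatches(l, gregexpr("[0-9.eE+-]+", l))[[1L]])
    })
    counts <- do.call(rbind, rows)
    tot <- colSums(counts)
    nsites <- if (all(abs(tot - 1) < 1e-6)) 100 else stats::median(tot)
    ppm <- sweep(counts, 2L, tot, "/")
    out[[name]] <- motif_model(name, ppm, nsites = nsites)
  }
  out
}

#' Write motifs in JASPAR text format
#' @param motifs List of `MotifModel`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(paste0(">", m$name, " ", m$name), con)
    counts <- round(m$ppm * m$nsites, 4)
    for (b in 1:4)
      writeLines(sprintf("%s  [ %s ]", DNA_BASES[b],
                         paste(format(counts[b, ], trim = TRUE), collapse = " ")), con)
  }
  invisible(path)
}

#' Read motifs in MEME minimal format
#' @param path MEME-format text file.
#' @return Named list of `MotifModel`s.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  midx <- grep("^MOTIF\\s", lines)
  if (!length(midx)) stop("no MOTIF blocks found in ", path)
  bg <- rep(0.25, 4)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl) && bgl[1L] < length(lines)) {
    nums <- as.numeric(regmatches(lines[bgl[1L] + 1L],
                                  gregexpr("[0-9.eE+-]+", lines[bgl[1L] + 1L]))[[1L]])
    if (length(nums) >= 8L) bg <- nums[c(2, 4, 6, 8)]
  }
  out <- list()
  for (i in seq_along(midx)) {
    name <- strsplit(trimws(sub("^MOTIF", "", lines[midx[i]])), "\\s+")[[1L]][1L]
    j <- midx[i]
    while (j <= length(lines) && !grepl("letter-probability matrix", lines[j])) j <- j + 1L
    if (j > length(lines)) stop("motif ", name, " lacks a letter-probability matrix")
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
    ns <- if (grepl("nsites=", lines[j]))
      as.numeric(sub(".*nsites=\\s*([0-9.]+).*", "\\1", lines[j])) else 100
    rows <- lines[(j + 1L):(j + w)]
    mat <- t(unname(vapply(rows, function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1L]][1:4]), numeric(4))))
    ppm <- t(mat)
    ppm <- sweep(ppm, 2L, colSums(ppm), "/")
    out[[name]] <- motif_model(name, ppm, nsites = ns, background = bg)
  }
  out
}

#' Write motifs in MEME minimal format
#' @param motifs List of `MotifModel`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bg <- motifs[[1L]]$background
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]), ""),
             con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= %g E= 0",
                       ncol(m$ppm), m$nsites), con)
    for (l in seq_len(ncol(m$ppm)))
      writeLines(paste(sprintf("%.6f", m$ppm[, l]), collapse = "  "), con)
    writeLines("", con)
  }
  invisible(path)
}
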