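# Motif similarity, archetype clustering and ALLR merging.

# Align two PPMs at a given offset of b relative to a (offset = start of b
# minus start of a, in columns), filling overhangs with the background.
# Returns list(a_cols, b_cols): 4 x n aligned matrices.
align_ppms <- function(ppm_a, ppm_b, offset, background) {
  la <- ncol(ppm_a); lb <- ncol(ppm_b)
  lo <- min(0L, offset); hi <- max(la, offset + lb)
  n <- hi - lo
  bgcol <- matrix(background, 4L, n)
  a_cols <- bgcol; b_cols <- bgcol
  a_idx <- (1L - lo):(la - lo)
  a_cols[, a_idx] <- ppm_a
  b_idx <- (offset + 1L - lo):(offset + lb - lo)
  b_cols[, b_idx] <- ppm_b
  list(a = a_cols, b = b_cols,
       overlap = length(intersect(a_idx, b_idx)))
}

#' Similarity between two motif models
#'
#' Pearson correlation of the aligned position probability matrices, with
#' each aligned position weighted by the summed information content of the
#' two aligned columns. All ungapped offsets with at least `min_overlap`
#' overlapping columns are considered, in both the given and the
#' reverse-complement orientation of `b`; unaligned overhang columns are
#' filled with the background distribution. The maximum over offsets and
#' orientations is returned.
#'
#' @param a,b `MotifModel`s.
#' @param min_overlap Minimum overlapping columns per offset (default 4).
#' @return Correlation in `[-1, 1]`.
#' @export
motif_similarity <- function(a, b, min_overlap = 4L) {
  bg <- a$background
  best <- -1
  la <- ncol(a$ppm)
  for (orient in 1:2) {
    ppm_b <- if (orient == 1L) b$ppm else motif_revcomp(b)$ppm
    lb <- ncol(ppm_b)
    mo <- min(min_overlap, la, lb)
    for (off in (-lb + mo):(la - mo)) {
      al <- align_ppms(a$ppm, ppm_b, off, bg)
      ic <- motif_ic(al$a) + motif_ic(al$b)
      w <- rep(ic, each = 4L)
      r <- weighted_pearson(as.vector(al$a), as.vector(al$b), w)
      if (r > best) best <- r
    }
  }
  best
}

#' Pairwise motif similarity matrix
#' @param motifs List of `MotifModel`s.
#' @param min_overlap Passed to [motif_similarity()].
#' @return Symmetric matrix of correlations.
#' @export
motif_similarity_matrix <- function(motifs, min_overlap = 4L) {
  n <- length(motifs)
  nm <- vapply(motifs, function(m) m$name, character(1))
  s <- diag(1, n)
  dimnames(s) <- list(nm, nm)
  if (n >= 2L)
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      s[i, j] <- s[j, i] <- motif_similarity(motifs[[i]], motifs[[j]],
                                             min_overlap = min_overlap)
    }
  s
}

# ALLR score of two aligned count-weighted columns:
# sum_x [ n_b p_bx log2(p_ax / bg) + n_a p_ax log2(p_bx / bg) ] / (n_a + n_b)
allr_column <- function(pa, pb, na, nb, background, eps = 1e-4) {
  pa2 <- (pa + eps * background) / (1 + eps)
  pb2 <- (pb + eps * background) / (1 + eps)
  sum(nb * pb * log2(pa2 / background) + na * pa * log2(pb2 / background)) / (na + nb)
}

# Best alignment (offset, orientation) of motif b against a count profile,
# scored by summed ALLR over overlapping columns.
best_allr_alignment <- function(counts_a, na, motif_b) {
  bg <- motif_b$background
  ppm_a <- sweep(counts_a, 2L, pmax(colSums(counts_a), 1e-12), "/")
  la <- ncol(ppm_a)
  best <- list(score = -Inf, offset = 0L, rc = FALSE)
  for (orient in 1:2) {
    mb <- if (orient == 1L) motif_b else motif_revcomp(motif_b)
    lb <- ncol(mb$ppm)
    offs <- (-lb + 1L):(la - 1L)
    for (off in offs[order(abs(offs))]) {   # ties prefer central alignment
      cols_a <- max(1L, off + 1L):min(la, off + lb)
      if (!length(cols_a)) next
      sc <- 0                               # total ALLR over the overlap
      for (ca in cols_a) {
        cb <- ca - off
        sc <- sc + allr_column(ppm_a[, ca], mb$ppm[, cb], na, mb$nsites, bg)
      }
      if (sc > best$score + 1e-12)
        best <- list(score = sc, offset = off, rc = orient == 2L)
    }
  }
  best
}

#' Merge a cluster of motifs into one model
#'
#' Progressive alignment to the highest-information-content member: each
#' remaining motif is aligned (ALLR column score, both orientations, all
#' ungapped offsets) to the running count profile, its count matrix
#' (PPM x nsites) added at the best offset, and the summed counts
#' renormalized to a PPM at the end.
#'
#' @param members List of `MotifModel`s (>= 1).
#' @param name Name of the merged model; default concatenates member names.
#' @return A `MotifModel`.
#' @export
merge_motif_cluster <- function(members, name = NULL) {
  if (!length(members)) stop("cannot merge an empty motif list")
  if (is.null(name)) {
    name <- paste(vapply(members, function(m) m$name, character(1)), collapse = "/")
    if (nchar(name) > 40L) name <- substr(name, 1L, 40L)
  }
  if (length(members) == 1L) {
    out <- members[[1L]]
    out$name <- name
    return(out)
  }
  total_ic <- vapply(members, function(m) sum(motif_ic(m)), numeric(1))
  ord <- order(total_ic, decreasing = TRUE)
  ref <- members[[ord[1L]]]
  counts <- ref$ppm * ref$nsites
  n_eff <- ref$nsites
  for (k in ord[-1L]) {
    m <- members[[k]]
    al <- best_allr_alignment(counts, n_eff, m)
    mm <- if (al$rc) motif_revcomp(m) else m
    add <- mm$ppm * mm$nsites
    lb <- ncol(add); la <- ncol(counts)
    lo <- min(0L, al$offset); hi <- max(la, al$offset + lb)
    new <- matrix(0, 4L, hi - lo)
    new[, (1L - lo):(la - lo)] <- counts
    bi <- (al$offset + 1L - lo):(al$offset + lb - lo)
    new[, bi] <- new[, bi] + add
    counts <- new
    n_eff <- n_eff + m$nsites
  }
  ppm <- sweep(counts, 2L, colSums(counts), "/")
  motif_model(name, ppm, nsites = n_eff, background = members[[1L]]$background)
}

#' Cluster motifs into archetypes
#'
#' Complete-linkage hierarchical clustering on distance
#' `1 - motif_similarity`, cut at `cut_height`; one merged model
#' (see [merge_motif_cluster()]) per cluster.
#'
#' @param motifs List of `MotifModel`s (>= 2).
#' @param cut_height Tree cut height in `[0, 2]` (e.g. 0.35 for mouse,
#'   0.45 for human collections).
#' @param similarity Optional precomputed similarity matrix.
#' @return An `ArchetypeAssignment`: list with `assignment` (named integer
#'   vector motif -> cluster), `archetypes` (list of merged `MotifModel`s,
#'   one per cluster) and `members` (list of member name vectors).
#' @export
cluster_into_archetypes <- function(motifs, cut_height, similarity = NULL) {
  if (length(motifs) < 2L) stop("need >= 2 motifs to cluster")
  if (cut_height < 0 || cut_height > 2) stop("cut_height must be in [0, 2]")
  nm <- vapply(motifs, function(m) m$name, character(1))
  names(motifs) <- nm
  if (is.null(similarity)) similarity <- motif_similarity_matrix(motifs)
  d <- stats::as.dist(1 - similarity)
  hc <- stats::hclust(d, method = "complete")
  cl <- stats::cutree(hc, h = cut_height)
  k <- max(cl)
  archetypes <- vector("list", k)
  members <- vector("list", k)
  for (i in seq_len(k)) {
    mem <- nm[cl == i]
    members[[i]] <- mem
    aname <- paste(mem, collapse = "/")
    if (nchar(aname) > 40L) aname <- substr(aname, 1L, 40L)
    aname <- paste0(aname, "_A", i)
    archetypes[[i]] <- merge_motif_cluster(motifs[mem], name = aname)
  }
  names(archetypes) <- vapply(archetypes, function(m) m$name, character(1))
  structure(list(assignment = cl, archetypes = archetypes, members = members),
            class = "ArchetypeAssignment")
}

#' @export
print.ArchetypeAssignment <- function(x, ...) {
  cat("ArchetypeAssignment:", length(x$assignment), "motifs in",
      length(x$archetypes), "archetypes\n")
  invisible(x)
}
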