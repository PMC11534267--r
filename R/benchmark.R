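# Evaluation metrics and cross-method ranking.

#' Rank motifs from a differential table
#'
#' Stable sort by uncorrected p-value ascending, then absolute effect size
#' descending, then name; ranks run 1..n. Motifs with missing p-values are
#' placed last with a warning.
#'
#' @param tbl A `DifferentialTable` (columns `id`, `effect`, `p`).
#' @return `data.table` with columns `id`, `rank`.
#' @export
rank_results <- function(tbl) {
  if (any(is.na(tbl$p)))
    warning("motif(s) with missing p-value placed last")
  ord <- order(is.na(tbl$p), tbl$p, -abs(tbl$effect), tbl$id)
  data.table::data.table(id = tbl$id[ord], rank = seq_along(ord))
}

#' Best rank of any true motif
#'
#' @param ranking Character vector of motif ids in rank order, or the
#'   output of [rank_results()].
#' @param true_motifs Character vector of true motif names.
#' @return Integer best (minimum) rank, or `NA` with a warning when no
#'   true motif appears in the ranking.
#' @export
true_motif_rank <- function(ranking, true_motifs) {
  ids <- if (is.data.frame(ranking)) ranking$id else ranking
  pos <- match(true_motifs, ids)
  if (all(is.na(pos))) {
    warning("no true motif present in the ranking")
    return(NA_integer_)
  }
  as.integer(min(pos, na.rm = TRUE))
}

#' Normalized top-k membership AUC (network/archetype score)
#'
#' For k = 1..k_max, `P(k)` is the proportion of the top k motifs that are
#' members; the score is `sum_k P(k)` divided by the maximum theoretically
#' obtainable AUC `sum_k min(k, |members|)/k`.
#'
#' @param ranking Character vector of motif ids in rank order (or
#'   [rank_results()] output).
#' @param members Character set of member motifs (non-empty).
#' @param k_max Depth of the curve (default 100); truncated to the ranking
#'   length.
#' @return Score in `[0, 1]`.
#' @export
member_auc_score <- function(ranking, members, k_max = 100L) {
  ids <- if (is.data.frame(ranking)) ranking$id else ranking
  if (!length(ids)) stop("empty ranking")
  if (!length(members)) stop("members must be non-empty")
  k_max <- min(k_max, length(ids))
  k <- seq_len(k_max)
  hits <- cumsum(ids[k] %in% members)
  auc <- sum(hits / k)
  ideal <- sum(pmin(k, length(members)) / k)
  auc / ideal
}

#' Precision and recall at a significance threshold
#'
#' Precision is computed over `positives` (by default the union of true
#' motifs, network members and archetype members); recall is the fraction
#' of true motifs selected.
#'
#' @param tbl A `DifferentialTable` with `p_adj`, or `NULL` when
#'   `selected` is given.
#' @param truth List with `true_motifs` and optionally `network_members`,
#'   `archetype_members`.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param selected Optional explicit selection set (overrides `p_adj`),
#'   supporting methods without p-values.
#' @param positives Optional explicit positive set.
#' @return List with `precision` (`NA` when nothing is selected) and
#'   `recall`.
#' @export
precision_recall <- function(tbl, truth, alpha = 0.05, selected = NULL,
                             positives = NULL) {
  if (is.null(selected)) selected <- tbl$id[tbl$p_adj <= alpha]
  if (is.null(positives))
    positives <- unique(c(truth$true_motifs, truth$network_members,
                          truth$archetype_members))
  precision <- if (length(selected))
    sum(selected %in% positives) / length(selected) else NA_real_
  recall <- if (length(truth$true_motifs))
    sum(truth$true_motifs %in% selected) / length(truth$true_motifs) else NA_real_
  list(precision = precision, recall = recall)
}

#' Inverse-logit rank transformation
#'
#' `T(r) = 2 exp(-sqrt(r)) / (1 + exp(-sqrt(r)))`: maps rank 1 to about
#' 0.538, decays toward 0 for large ranks so that differences among very
#' poor ranks stop mattering.
#'
#' @param rank Integer rank(s) >= 1.
#' @return Transformed value(s) in (0, 1).
#' @export
rank_transform <- function(rank) {
  if (any(rank < 1, na.rm = TRUE)) stop("ranks must be >= 1")
  x <- sqrt(rank)
  2 * exp(-x) / (1 + exp(-x))
}

#' Rank methods across datasets
#'
#' Each (dataset, method) cell carries three scores: the transformed true
#' motif rank, the network score and the archetype score. Missing cells
#' are imputed with the worse of the median and the mean of that dataset's
#' available values for that metric; methods are ordered by the mean over
#' all dataset-by-metric cells, descending.
#'
#' @param report `data.frame` with columns `dataset`, `method`, `rank`,
#'   `network_score`, `archetype_score` (NA allowed).
#' @return `data.table` with `method`, `mean_score`, ordered best first.
#' @export
rank_methods <- function(report) {
  report <- as.data.frame(report)
  stopifnot(all(c("dataset", "method", "rank", "network_score",
                  "archetype_score") %in% names(report)))
  report$transformed_rank <- ifelse(is.na(report$rank), NA_real_,
                                    rank_transform(pmax(report$rank, 1)))
  metrics <- c("transformed_rank", "network_score", "archetype_score")
  methods <- unique(report$method)
  datasets <- unique(report$dataset)
  all_missing <- vapply(methods, function(m)
    all(is.na(unlist(report[report$method == m, metrics]))), logical(1))
  if (any(all_missing)) {
    warning("excluding method(s) missing on all datasets: ",
            paste(methods[all_missing], collapse = ", "))
    methods <- methods[!all_missing]
  }
  cells <- expand.grid(method = methods, dataset = datasets,
                       stringsAsFactors = FALSE)
  scores <- matrix(NA_real_, nrow(cells), length(metrics),
                   dimnames = list(NULL, metrics))
  for (i in seq_len(nrow(cells))) {
    row <- report[report$method == cells$method[i] &
                  report$dataset == cells$dataset[i], metrics]
    if (nrow(row)) scores[i, ] <- as.numeric(row[1L, ])
  }
  for (dset in datasets) for (met in metrics) {
    idx <- which(cells$dataset == dset)
    vals <- scores[idx, met]
    if (any(is.na(vals)) && any(!is.na(vals))) {
      imp <- min(stats::median(vals, na.rm = TRUE), mean(vals, na.rm = TRUE))
      scores[idx[is.na(vals)], met] <- imp
    }
  }
  mean_score <- vapply(methods, function(m)
    mean(scores[cells$method == m, ], na.rm = TRUE), numeric(1))
  out <- data.table::data.table(method = methods, mean_score = mean_score)
  data.table::setorder(out, -mean_score, method)
  out[]
}

#' Combine several motif rankings by mean rank
#'
#' Rankings are restricted to their shared motif set; motifs are ordered
#' by mean rank across methods, ties by the best (minimum) individual
#' rank, then name.
#'
#' @param rankings List (>= 2) of character vectors of motif ids in rank
#'   order.
#' @return Character vector: the aggregated ranking.
#' @export
combine_method_rankings <- function(rankings) {
  if (length(rankings) < 2L) stop("need >= 2 rankings")
  shared <- Reduce(intersect, rankings)
  if (!length(shared)) stop("rankings share no motifs")
  rk <- vapply(rankings, function(r) match(shared, r), numeric(length(shared)))
  mean_rank <- rowMeans(rk)
  min_rank <- apply(rk, 1L, min)
  shared[order(mean_rank, min_rank, shared)]
}
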