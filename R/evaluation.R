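#' Nearest-neighbour classification
#'
#' Predicts the query's category at a chosen level of the classification
#' hierarchy as the category of the database structure nearest to the query
#' under the SProt distance (distance ties broken by database id).
#'
#' @param query A [sprot_structure()], or `NULL` when `distances` is given.
#' @param database Named list of labeled [sprot_structure()] objects.
#' @param level One of `"family"`, `"superfamily"`, `"fold"`.
#' @param params,ecdf_table Measure parameters and calibration table (only
#'   needed when `distances` is not supplied).
#' @param distances Optional named numeric vector of precomputed distances
#'   from the query to each database structure.
#' @return The predicted label (character scalar).
#' @export
nn_classify <- function(query = NULL, database, level = "family",
                        params = sprot_params(), ecdf_table = NULL,
                        distances = NULL) {
  level <- match.arg(level, c("family", "superfamily", "fold"))
  stopifnot(length(database) >= 1, !is.null(names(database)))
  labels <- vapply(database, function(s) {
    if (is.null(s$label)) stop("database structure lacks a label")
    s$label[[level]]
  }, "")
  if (is.null(distances)) {
    stopifnot(!is.null(query), !is.null(ecdf_table))
    distances <- vapply(names(database), function(id)
      sprot_distance(query, database[[id]], params, ecdf_table), 0)
  }
  stopifnot(all(names(database) %in% names(distances)))
  distances <- distances[names(database)]
  best <- names(database)[order(distances, names(database))[1]]
  unname(labels[best])
}

#' Precision-recall analysis of one ranked result
#'
#' Computes per-rank precision and recall from relevance flags in rank
#' order, the average precision (mean of the precisions at the ranks of the
#' relevant items), and the mean interpolated precision over the 10 standard
#' recall levels 10%..100% (interpolated precision at level `l` = maximum
#' precision at any recall `>= l`).
#'
#' @param relevant Logical vector: relevance of each result, best rank
#'   first.
#' @param n_relevant_total Total number of relevant items in the database
#'   (defaults to `sum(relevant)`, i.e. assuming the ranking is complete).
#' @return List with `precision`, `recall` (per rank), `average_precision`,
#'   and `ap_standard_recall`; the scalars are `NA` when no relevant item
#'   exists.
#' @export
precision_recall <- function(relevant, n_relevant_total = sum(relevant)) {
  relevant <- as.logical(relevant)
  n <- length(relevant)
  if (n == 0 || n_relevant_total == 0)
    return(list(precision = numeric(0), recall = numeric(0),
                average_precision = NA_real_,
                ap_standard_recall = NA_real_))
  hits <- cumsum(relevant)
  precision <- hits / seq_len(n)
  recall <- hits / n_relevant_total
  ap <- mean(precision[relevant])
  levels <- seq(0.1, 1, by = 0.1)
  interp <- vapply(levels, function(l) {
    ok <- recall >= l - 1e-12
    if (any(ok)) max(precision[ok]) else 0
  }, 0)
  list(precision = precision, recall = recall, average_precision = ap,
       ap_standard_recall = mean(interp))
}

#' Mean average precision over a query set
#'
#' @param relevance_list List of logical relevance vectors (one per query,
#'   rank order).
#' @param n_relevant_totals Optional integer vector of total relevant counts
#'   per query.
#' @return List with `map` (mean average precision) and
#'   `mean_ap_standard_recall`, averaged over queries with at least one
#'   relevant item.
#' @export
mean_average_precision <- function(relevance_list, n_relevant_totals = NULL) {
  if (is.null(n_relevant_totals))
    n_relevant_totals <- vapply(relevance_list, sum, 0)
  pr <- Map(precision_recall, relevance_list, n_relevant_totals)
  ap <- vapply(pr, `[[`, 0, "average_precision")
  sr <- vapply(pr, `[[`, 0, "ap_standard_recall")
  list(map = mean(ap, na.rm = TRUE),
       mean_ap_standard_recall = mean(sr, na.rm = TRUE))
}

#' Cover and RMSD of a structure alignment
#'
#' @param alignment A `"sprot_alignment"`.
#' @return List with `cover` (percent of query residues aligned) and `rmsd`
#'   (Angstrom, over aligned pairs under the alignment's superposition).
#' @export
alignment_stats <- function(alignment) {
  stopifnot(inherits(alignment, "sprot_alignment"))
  list(cover = alignment$cover, rmsd = alignment$rmsd_aligned)
}
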