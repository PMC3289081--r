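#' Log SM-score matrix of two sphere sequences
#'
#' Entry `(i, j)` is `log(max(SM-score(x_i, y_j), sm_floor))`: the SM-raw
#' values come from the compiled all-pairs kernel, are passed through the
#' calibrated ECDF of their quantity-characteristic bucket and scaled by the
#' quantity factor, then floored before the logarithm so the dynamic
#' programming matrix stays finite. All entries are `<= 0`.
#'
#' @param query_spheres,target_spheres Sphere lists from
#'   [build_all_spheres()], built with the radius recorded in the table's
#'   fingerprint.
#' @param params A [sprot_params()].
#' @param ecdf_table Calibration table from [build_ecdf_table()].
#' @return Numeric matrix (`length(query) x length(target)`) of log scores.
#' @export
build_log_score_matrix <- function(query_spheres, target_spheres,
                                   params = sprot_params(), ecdf_table) {
  stopifnot(inherits(ecdf_table, "sprot_ecdf"))
  if (!identical(ecdf_table$fingerprint, params_fingerprint(params)))
    stop("calibration table was built under different parameters (",
         ecdf_table$fingerprint, ")")
  raw <- sm_raw_matrix(query_spheres, target_spheres, params)
  qx <- t(vapply(query_spheres, function(s) s$qc, integer(4)))
  qy <- t(vapply(target_spheres, function(s) s$qc, integer(4)))
  # quantity factors, category by category
  f <- matrix(1, nrow(qx), nrow(qy))
  for (c in 1:4) {
    mn <- outer(qx[, c], qy[, c], pmin)
    mx <- outer(qx[, c], qy[, c], pmax)
    f <- f * (1 + mn) / (1 + mx)
  }
  # ECDF lookup grouped by bucket key
  kx <- apply(qx, 1, function(q) paste(downsample_qc(q), collapse = "."))
  ky <- apply(qy, 1, function(q) paste(downsample_qc(q), collapse = "."))
  keys <- outer(kx, ky, paste, sep = "|")
  p <- matrix(0, nrow(raw), ncol(raw))
  for (k in unique(as.vector(keys))) {
    sel <- keys == k
    s <- ecdf_table$buckets[[resolve_bucket(ecdf_table, k)]]
    p[sel] <- findInterval(raw[sel], s) / length(s)
  }
  log(pmax(p * f, params$sm_floor))
}

#' Global alignment by Needleman-Wunsch with a linear gap model
#'
#' Returns the order-preserving residue pairing maximizing the sum of match
#' scores plus `gap_penalty` per gap position (no separate gap-open cost).
#' Traceback is deterministic: match preferred over a gap in the query
#' (advancing the target) over a gap in the target. `-Inf` entries forbid a
#' match.
#'
#' @param score_matrix Numeric matrix of match scores.
#' @param gap_penalty Penalty per gap position (negative).
#' @return Integer matrix of 1-based index pairs, columns `x`, `y`.
#' @export
needleman_wunsch_global <- function(score_matrix, gap_penalty) {
  if (length(score_matrix) == 0) stop("empty score matrix")
  out <- nw_cpp(score_matrix, gap_penalty)
  colnames(out) <- c("x", "y")
  out
}

#' TM-score superposition of an aligned structure pair
#'
#' Given a fixed residue pairing, searches for the rigid superposition of the
#' query onto the target maximizing
#'
#' `TM = (1 / L_T) * sum_i 1 / (1 + (d_i / d0(L_T))^2)`
#'
#' over all aligned pairs, where `L_T` is the query length and
#' `d0(L) = 1.24 (L - 15)^{1/3} - 1.8`, clamped below at `d0_min`. The search
#' seeds Kabsch superpositions on contiguous windows of the pairing (lengths
#' `L_A`, `L_A/2`, `L_A/4`, minimum 4) and refines each by iterating
#' keep-close-pairs / re-superpose to a fixed point for distance cutoffs from
#' `d0` to 8 Angstrom.
#'
#' @param pairs Integer matrix of (query, target) residue index pairs,
#'   strictly increasing in both columns.
#' @param query,target [sprot_structure()] objects.
#' @param params A [sprot_params()].
#' @return An object of class `"sprot_alignment"`: pairs, `L_A`, `L_T`,
#'   `superposition` (mapping the query onto the target), `tm_score`,
#'   `cover` (percent of query residues aligned), `rmsd_aligned`, and
#'   per-pair `distances`.
#' @export
tm_score_superposition <- function(pairs, query, target,
                                   params = sprot_params()) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) == 0) stop("empty pairing")
  stopifnot(all(pairs[, 1] >= 1), all(pairs[, 1] <= length(query)),
            all(pairs[, 2] >= 1), all(pairs[, 2] <= length(target)))
  L_T <- length(query)
  res <- tmscore_cpp(pairs, query$ca, target$ca, L_T, params$d0_min)
  sup <- structure(list(rotation = res$rotation,
                        translation = as.numeric(res$translation),
                        rmsd = sqrt(mean(res$d^2))),
                   class = "sprot_superposition")
  new_sprot_alignment(pairs, L_T, sup, res$score, as.numeric(res$d),
                      query, target)
}

new_sprot_alignment <- function(pairs, L_T, sup, score, d, query, target) {
  colnames(pairs) <- c("query", "target")
  structure(list(pairs = pairs, L_A = nrow(pairs), L_T = L_T,
                 superposition = sup, tm_score = score,
                 cover = 100 * nrow(pairs) / L_T,
                 rmsd_aligned = sqrt(mean(d^2)), distances = d,
                 query_id = query$id, target_id = target$id),
            class = "sprot_alignment")
}

#' @export
print.sprot_alignment <- function(x, ...) {
  cat(sprintf("structure alignment %s -> %s\n", x$query_id, x$target_id))
  cat(sprintf("  %d pairs (cover %.1f%% of %d query residues)\n",
              x$L_A, x$cover, x$L_T))
  cat(sprintf("  TM-score %.4f, aligned RMSD %.3f A\n",
              x$tm_score, x$rmsd_aligned))
  invisible(x)
}

#' Align two protein structures
#'
#' The full pipeline: aa-spheres for both structures, the calibrated log
#' SM-score matrix, global Needleman-Wunsch with the linear gap model, and
#' the TM-score superposition of the resulting pairing. With
#' `tm_optimize = TRUE` the alignment is additionally refined by
#' [tm_optimize()].
#'
#' @param query,target [sprot_structure()] objects. `L_T` in the TM-score is
#'   the query's length, so the roles are not interchangeable.
#' @param params A [sprot_params()].
#' @param ecdf_table Calibration table from [build_ecdf_table()].
#' @param tm_optimize Iterate alignment/superposition improvement after the
#'   initial alignment? Default `FALSE`.
#' @param spheres_query,spheres_target Optional precomputed sphere lists
#'   (from [build_all_spheres()]) to avoid rebuilding them across many
#'   comparisons.
#' @return A `"sprot_alignment"` (see [tm_score_superposition()]).
#' @export
sprot_align <- function(query, target, params = sprot_params(), ecdf_table,
                        tm_optimize = FALSE,
                        spheres_query = NULL, spheres_target = NULL) {
  stopifnot(length(query) >= 1, length(target) >= 1)
  if (is.null(spheres_query))
    spheres_query <- build_all_spheres(query, params$radius)
  if (is.null(spheres_target))
    spheres_target <- build_all_spheres(target, params$radius)
  S <- build_log_score_matrix(spheres_query, spheres_target, params,
                              ecdf_table)
  pairs <- needleman_wunsch_global(S, params$gap_penalty)
  if (nrow(pairs) == 0) {
    # pathological matrix: fall back to pairing the single best cell
    best <- arrayInd(which.max(S), dim(S))
    pairs <- matrix(as.integer(best), 1, 2)
  }
  aln <- tm_score_superposition(pairs, query, target, params)
  if (tm_optimize) aln <- tm_optimize(query, target, aln, params)
  aln
}

#' SProt distance between two structures
#'
#' `d(query, target) = 1 - TM-score(query, target)`; zero for identical
#' structures and asymmetric in general because the TM-score normalizes by
#' the query length.
#'
#' @inheritParams sprot_align
#' @return Distance in `[0, 1)`.
#' @export
sprot_distance <- function(query, target, params = sprot_params(),
                           ecdf_table, ...) {
  1 - sprot_align(query, target, params, ecdf_table, ...)$tm_score
}

#' Both directed SProt distances of a structure pair
#'
#' `d(x, y)` and `d(y, x)` differ only through the length used to normalize
#' the TM-score; the underlying residue pairing is shared, so the second
#' direction costs almost nothing once the first is computed. The alignment
#' is built with `x` as the query.
#'
#' @param x,y [sprot_structure()] objects.
#' @inheritParams sprot_align
#' @param spheres_x,spheres_y Optional precomputed sphere lists.
#' @return List with `d_xy`, `d_yx`, and the shared `pairs`.
#' @export
sprot_distance_pair <- function(x, y, params = sprot_params(), ecdf_table,
                                spheres_x = NULL, spheres_y = NULL) {
  aln <- sprot_align(x, y, params, ecdf_table,
                     spheres_query = spheres_x, spheres_target = spheres_y)
  rev_pairs <- aln$pairs[, 2:1, drop = FALSE]
  aln_rev <- tm_score_superposition(rev_pairs, y, x, params)
  list(d_xy = 1 - aln$tm_score, d_yx = 1 - aln_rev$tm_score,
       pairs = aln$pairs)
}

#' Iterative TM-score optimization of an alignment
#'
#' Alternates between re-alignment and re-superposition: under the current
#' superposition, a zero-gap Needleman-Wunsch with match score
#' `1 / (1 + (d_ij / d0(L_T))^2)` — matches beyond `3 d0(L_T)` forbidden —
#' produces a new pairing, which the TM-score search then re-superposes. The
#' loop keeps the best alignment seen and stops when the score improves by
#' no more than `params$tol` or after `params$max_tm_iterations` rounds, so
#' the reported score is non-decreasing.
#'
#' @param query,target [sprot_structure()] objects.
#' @param initial A `"sprot_alignment"` to start from.
#' @param params A [sprot_params()].
#' @return The refined `"sprot_alignment"`.
#' @export
tm_optimize <- function(query, target, initial, params = sprot_params()) {
  stopifnot(inherits(initial, "sprot_alignment"))
  best <- initial
  d0 <- tm_d0(initial$L_T, params$d0_min)
  for (it in seq_len(params$max_tm_iterations)) {
    qt <- apply_superposition(best$superposition, query$ca)
    D <- cross_dist(qt, target$ca)
    S <- dist_score(D, d0)
    S[D > 3 * d0] <- -Inf
    pairs <- needleman_wunsch_global(S, 0)
    if (nrow(pairs) == 0) break
    cand <- tm_score_superposition(pairs, query, target, params)
    if (cand$tm_score > best$tm_score + params$tol) {
      best <- cand
    } else {
      if (cand$tm_score > best$tm_score) best <- cand
      break
    }
  }
  best
}
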