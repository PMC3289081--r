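#' Rational Bezier quadratic distance modifier
#'
#' A similarity-preserving modifier: a strictly increasing map of `[0, 1]`
#' onto itself given by the rational quadratic Bezier curve through
#' `(0, 0)`, the control point `(a, b)` and `(1, 1)` with middle weight `w`.
#' Larger weights pull the curve toward the control point; with the default
#' control point `(0.7, 0.15)` this expands the crowded upper range of the
#' distance distribution at the expense of the lower range, tightening
#' object clusters and improving indexability. `w = 0` degenerates to the
#' identity map.
#'
#' @param w Curve weight, `>= 0`.
#' @param a,b Control point (defaults 0.7, 0.15).
#' @return An object of class `"rbq_modifier"`.
#' @export
rbq_modifier <- function(w, a = 0.7, b = 0.15) {
  stopifnot(w >= 0, a > 0, a < 1, b >= 0, b <= 1)
  structure(list(a = a, b = b, w = w), class = "rbq_modifier")
}

#' @export
print.rbq_modifier <- function(x, ...) {
  cat(sprintf("RBQ(%g,%g) modifier, weight %g\n", x$a, x$b, x$w))
  invisible(x)
}

#' Apply an RBQ modifier to distances
#'
#' Evaluates the curve ordinate at the parameter where the curve abscissa
#' equals `d`; the parameter is found by bisection (the abscissa is strictly
#' increasing in the parameter) to an interval of 1e-12.
#'
#' @param modifier An [rbq_modifier()]; `NULL` means the identity.
#' @param d Distances in `[0, 1]` (vectorized).
#' @return Modified distances in `[0, 1]`.
#' @export
rbq_apply <- function(modifier, d) {
  if (is.null(modifier)) return(d)
  stopifnot(inherits(modifier, "rbq_modifier"))
  if (any(d < -1e-12 | d > 1 + 1e-12)) stop("distances must lie in [0, 1]")
  d <- pmin(pmax(d, 0), 1)
  w <- modifier$w
  if (w == 0) return(d)
  a <- modifier$a
  b <- modifier$b
  bez <- function(t, p1) {
    u <- 1 - t
    den <- u^2 + 2 * w * u * t + t^2
    (2 * w * u * t * p1 + t^2) / den
  }
  lo <- rep(0, length(d))
  hi <- rep(1, length(d))
  for (it in 1:48) {  # bisection: |hi - lo| <= 2^-48 < 1e-12
    mid <- (lo + hi) / 2
    xm <- bez(mid, a)
    below <- xm < d
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  out <- bez((lo + hi) / 2, b)
  out[d == 0] <- 0
  out[d == 1] <- 1
  out
}

#' Asymmetric triangle lower bound
#'
#' Lower bound on `d(q, o)` from a pivot `p` when the distance is not
#' symmetric, built from the two directed triangle inequalities that use
#' exactly the four available quantities: `d(q, p)`, `d(p, q)` and the two
#' stored pivot distances. For a symmetric distance it reduces to the
#' classical `|d(q, p) - d(p, o)|`.
#'
#' @param dq_p Distance `d(q, p)` from the query to the pivot.
#' @param dp_q Distance `d(p, q)` from the pivot to the query.
#' @param dp_o Stored distance `d(p, o)` pivot to object (vectorized).
#' @param do_p Stored distance `d(o, p)` object to pivot (vectorized).
#' @return `max(dq_p - do_p, dp_o - dp_q, 0)`, vectorized over objects.
#' @export
lower_bound <- function(dq_p, dp_q, dp_o, do_p) {
  pmax(dq_p - do_p, dp_o - dp_q, 0)
}

#' Build a pivot index for approximate nearest-neighbour search
#'
#' Precomputes, for every pivot `p` and database object `o`, both directed
#' distances `d(p, o)` and `d(o, p)` (one call to the distance closure per
#' pair; implementations can share the underlying alignment between the two
#' directions). Distances are stored in modified space when a modifier is
#' given.
#'
#' @param ids Character vector of database object identifiers.
#' @param pivot_ids Subset of `ids` used as pivots.
#' @param distance Function `(id_a, id_b)` returning a list with elements
#'   `d_ab` and `d_ba`, the two directed distances in `[0, 1]` (see
#'   [structure_distance_fn()] for the SProt closure).
#' @param modifier Optional [rbq_modifier()] applied to all stored
#'   distances.
#' @param fingerprint Parameter fingerprint recorded in the index; queries
#'   refuse to run against a mismatching closure fingerprint.
#' @return An object of class `"sprot_pivot_index"` with matrices `D_po`
#'   (`d(p, o)`) and `D_op` (`d(o, p)`), both `#pivots x #objects`.
#' @export
build_pivot_index <- function(ids, pivot_ids, distance, modifier = NULL,
                              fingerprint = "") {
  ids <- as.character(ids)
  pivot_ids <- as.character(pivot_ids)
  stopifnot(length(pivot_ids) >= 1, all(pivot_ids %in% ids),
            !anyDuplicated(ids))
  np <- length(pivot_ids)
  no <- length(ids)
  D_po <- matrix(0, np, no, dimnames = list(pivot_ids, ids))
  D_op <- matrix(0, np, no, dimnames = list(pivot_ids, ids))
  for (p in seq_len(np)) {
    for (o in seq_len(no)) {
      if (pivot_ids[p] == ids[o]) next  # d(x, x) = 0 both ways
      dd <- distance(pivot_ids[p], ids[o])
      D_po[p, o] <- dd$d_ab
      D_op[p, o] <- dd$d_ba
    }
  }
  structure(list(version = 1L, ids = ids, pivot_ids = pivot_ids,
                 D_po = rbq_apply(modifier, D_po),
                 D_op = rbq_apply(modifier, D_op),
                 modifier = modifier, fingerprint = fingerprint),
            class = "sprot_pivot_index")
}

#' @export
print.sprot_pivot_index <- function(x, ...) {
  cat(sprintf("pivot index: %d objects, %d pivots%s\n",
              length(x$ids), length(x$pivot_ids),
              if (is.null(x$modifier)) "" else
                sprintf(", RBQ weight %g", x$modifier$w)))
  invisible(x)
}

#' Select pivots for an index
#'
#' One object per family when labels are available (the first id of each
#' family in id order); otherwise seeded farthest-point (max-min) sampling
#' on the modified distance, starting from the lowest id.
#'
#' @param ids Database object ids.
#' @param families Optional character vector of family labels parallel to
#'   `ids`.
#' @param n_pivots Number of pivots for the unlabeled strategy.
#' @param distance,modifier As in [build_pivot_index()]; only needed for the
#'   unlabeled strategy.
#' @param seed Seed for the unlabeled strategy (tie-breaking only; the
#'   max-min choice itself is deterministic).
#' @return Character vector of pivot ids.
#' @export
select_pivots <- function(ids, families = NULL, n_pivots = NULL,
                          distance = NULL, modifier = NULL, seed = 1L) {
  ids <- as.character(ids)
  if (!is.null(families)) {
    stopifnot(length(families) == length(ids))
    return(ids[!duplicated(families)])
  }
  stopifnot(!is.null(n_pivots), n_pivots >= 1, !is.null(distance))
  chosen <- ids[which.min(ids)]
  dmin <- rep(Inf, length(ids))
  names(dmin) <- ids
  while (length(chosen) < n_pivots) {
    p <- chosen[length(chosen)]
    for (o in ids) {
      if (o %in% chosen) next
      dd <- distance(p, o)
      dmin[o] <- min(dmin[o], rbq_apply(modifier, dd$d_ab))
    }
    dmin[chosen] <- -Inf
    cand <- names(dmin)[dmin == max(dmin)]
    chosen <- c(chosen, sort(cand)[1])
  }
  chosen
}

#' Approximate k-nearest-neighbour search
#'
#' Pivot-table search in the style of LAESA, adapted to a non-metric
#' distance. Objects are eliminated only when their lower-bound estimation
#' exceeds the current threshold (the k-th best distance so far) by more
#' than `v` percent; pivots are protected from elimination during the first
#' `protected_steps` iterations; and after the candidate set empties, up to
#' `r` eliminated objects with the smallest estimations are re-examined,
#' counted since the last change of the result set.
#'
#' @param index A [build_pivot_index()] object.
#' @param query_id Identifier of the query (only used to skip a self-match
#'   if present in the database; pass something not in the database
#'   otherwise).
#' @param distance Function `(query_id, object_id)` returning
#'   `list(d_ab, d_ba)` raw directed distances (query first).
#' @param k Number of neighbours.
#' @param v Approximation error tolerance factor, percent (default 2.5).
#' @param r Order error tolerance factor, count (default 128).
#' @param protected_steps Iterations during which pivots cannot be
#'   eliminated; default half the number of pivots, rounded up.
#' @param fingerprint Fingerprint of the distance closure; must match the
#'   index.
#' @return List with `ids` (ascending modified distance, ties by id),
#'   `dist_mod`, `dist_raw`, and `n_dist`, the number of full distance
#'   computations performed.
#' @export
knn_search <- function(index, query_id, distance, k, v = 2.5, r = 128L,
                       protected_steps = NULL, fingerprint = "") {
  stopifnot(inherits(index, "sprot_pivot_index"), k >= 1)
  if (!identical(fingerprint, index$fingerprint))
    stop("distance closure fingerprint does not match the index (",
         index$fingerprint, ")")
  ids <- setdiff(index$ids, query_id)
  if (k > length(ids)) stop("k exceeds the database size")
  if (is.null(protected_steps))
    protected_steps <- ceiling(length(index$pivot_ids) / 2)
  modifier <- index$modifier

  e <- setNames(rep(0, length(ids)), ids)       # lower-bound estimations
  in_S <- setNames(rep(TRUE, length(ids)), ids) # candidate set membership
  processed <- setNames(rep(FALSE, length(ids)), ids)
  d_mod <- setNames(rep(NA_real_, length(ids)), ids)
  d_raw <- setNames(rep(NA_real_, length(ids)), ids)
  is_pivot <- setNames(ids %in% index$pivot_ids, ids)
  n_dist <- 0L
  reselections <- 0L
  step <- 0L

  # smallest-estimation selection, ties by id (names are sorted upfront)
  ord <- order(names(e))
  e <- e[ord]; in_S <- in_S[ord]; processed <- processed[ord]
  d_mod <- d_mod[ord]; d_raw <- d_raw[ord]; is_pivot <- is_pivot[ord]
  ids <- names(e)

  current_R <- function() {
    done <- names(d_mod)[processed]
    done[order(d_mod[done], done)][seq_len(min(k, length(done)))]
  }
  R <- character(0)

  # first selection: the pivot with the lowest id
  piv_sorted <- sort(intersect(index$pivot_ids, ids))
  s <- if (length(piv_sorted) > 0) piv_sorted[1] else ids[1]

  while (!is.na(s)) {
    step <- step + 1L
    in_S[s] <- FALSE
    dd <- distance(query_id, s)
    n_dist <- n_dist + 1L
    d_raw[s] <- dd$d_ab
    d_mod[s] <- rbq_apply(modifier, dd$d_ab)
    processed[s] <- TRUE
    newR <- current_R()
    if (!identical(newR, R)) {
      R <- newR
      reselections <- 0L
    }
    if (is_pivot[s]) {
      dq_p <- d_mod[s]
      dp_q <- rbq_apply(modifier, dd$d_ba)
      lb <- lower_bound(dq_p, dp_q, index$D_po[s, ids], index$D_op[s, ids])
      e <- pmax(e, lb)
    }
    # elimination
    theta <- if (length(R) == k) max(d_mod[R]) else Inf
    if (is.finite(theta)) {
      elim <- in_S & e > theta * (1 + v / 100)
      if (step <= protected_steps) elim <- elim & !is_pivot
      in_S[elim] <- FALSE
    }
    # next selection
    s <- NA_character_
    cand_p <- ids[in_S & is_pivot]
    cand_o <- ids[in_S]
    if (length(cand_p) > 0) {
      s <- cand_p[which.min(e[cand_p])]
    } else if (length(cand_o) > 0) {
      s <- cand_o[which.min(e[cand_o])]
    } else if (reselections < r) {
      pool <- ids[!processed]
      if (length(pool) > 0) {
        s <- pool[which.min(e[pool])]
        reselections <- reselections + 1L
      }
    }
  }
  list(ids = R, dist_mod = unname(d_mod[R]), dist_raw = unname(d_raw[R]),
       n_dist = n_dist)
}

#' Sequential-scan k-nearest neighbours
#'
#' Exact reference: computes the distance from the query to every database
#' object and returns the k smallest (modified-space ordering, ties by id).
#'
#' @inheritParams knn_search
#' @param ids Database object ids.
#' @param modifier Optional [rbq_modifier()].
#' @return Same shape as [knn_search()]; `n_dist` equals the database size.
#' @export
sequential_scan <- function(ids, query_id, distance, k, modifier = NULL) {
  ids <- sort(setdiff(as.character(ids), query_id))
  stopifnot(k >= 1, k <= length(ids))
  d_raw <- vapply(ids, function(o) distance(query_id, o)$d_ab, 0)
  d_mod <- rbq_apply(modifier, d_raw)
  ord <- order(d_mod, ids)[seq_len(k)]
  list(ids = ids[ord], dist_mod = unname(d_mod[ord]),
       dist_raw = unname(d_raw[ord]), n_dist = length(ids))
}

#' Retrieval error of an approximate result
#'
#' Percentage of the sequential-scan result missing from the approximate
#' result.
#'
#' @param R Ids returned by the approximate search.
#' @param R_seq Ids returned by the sequential scan.
#' @return Percentage in `[0, 100]`.
#' @export
retrieval_error <- function(R, R_seq) {
  if (length(R_seq) == 0) stop("empty reference result")
  100 * length(setdiff(R_seq, R)) / length(R_seq)
}

#' Category-restricted retrieval error
#'
#' Retrieval error counted only over the structures of the sequential-scan
#' result that share the query's category (family, superfamily or fold).
#' Returns `NA` when the reference result contains no such structure.
#'
#' @inheritParams retrieval_error
#' @param S_L Ids of all structures sharing the query's category at the
#'   chosen level.
#' @return Percentage in `[0, 100]`, or `NA` if undefined.
#' @export
scop_retrieval_error <- function(R, R_seq, S_L) {
  rel <- intersect(R_seq, S_L)
  if (length(rel) == 0) return(NA_real_)
  100 * length(setdiff(rel, R)) / length(rel)
}

#' Write a pivot index to a text file
#'
#' Versioned plain-text container; distances are written with full double
#' precision so the round-trip through [read_pivot_index()] is exact.
#'
#' @param index A [build_pivot_index()] object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pivot_index <- function(index, path) {
  stopifnot(inherits(index, "sprot_pivot_index"))
  con <- file(path, "w")
  on.exit(close(con))
  mod <- index$modifier
  writeLines(c("sprot-index\tv1",
               paste0("fingerprint\t", index$fingerprint),
               paste0("modifier\t", if (is.null(mod)) "none" else
                 sprintf("rbq %.17g %.17g %.17g", mod$a, mod$b, mod$w)),
               paste0("objects\t", paste(index$ids, collapse = " ")),
               paste0("pivots\t", paste(index$pivot_ids, collapse = " "))),
             con)
  fmt <- function(m) apply(m, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(paste0("D_po ", fmt(index$D_po)),
               paste0("D_op ", fmt(index$D_op))), con)
  invisible(path)
}

#' Read a pivot index written by [write_pivot_index()]
#'
#' @param path Path to the index file.
#' @return A `"sprot_pivot_index"`.
#' @export
read_pivot_index <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 5 || !startsWith(lines[1], "sprot-index"))
    stop("not an sprot index file: ", path)
  field <- function(i) strsplit(lines[i], "\t")[[1]][2]
  ids <- strsplit(field(4), " ")[[1]]
  pivot_ids <- strsplit(field(5), " ")[[1]]
  modline <- field(3)
  modifier <- if (identical(modline, "none")) NULL else {
    p <- as.numeric(strsplit(modline, " ")[[1]][-1])
    rbq_modifier(w = p[3], a = p[1], b = p[2])
  }
  body <- lines[-(1:5)]
  parse_rows <- function(tag) {
    rows <- body[startsWith(body, paste0(tag, " "))]
    m <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(sub(paste0("^", tag, " "), "", r), " ")[[1]])))
    dimnames(m) <- list(pivot_ids, ids)
    m
  }
  structure(list(version = 1L, ids = ids, pivot_ids = pivot_ids,
                 D_po = parse_rows("D_po"), D_op = parse_rows("D_op"),
                 modifier = modifier, fingerprint = field(2)),
            class = "sprot_pivot_index")
}

#' SProt distance closure over a structure database
#'
#' Builds the `(id_a, id_b) -> list(d_ab, d_ba)` closure used by
#' [build_pivot_index()] and [knn_search()], with aa-spheres cached per
#' structure and results memoised per ordered pair, so repeated requests for
#' a comparison are free. The two directions share one alignment (see
#' [sprot_distance_pair()]).
#'
#' @param structures Named list of [sprot_structure()] objects (names are
#'   the database ids). Queries not in the database can be supplied through
#'   `extra`.
#' @param params A [sprot_params()].
#' @param ecdf_table Calibration table.
#' @param extra Optional named list of additional (query) structures.
#' @return A function `(id_a, id_b)` returning `list(d_ab, d_ba)`.
#' @export
structure_distance_fn <- function(structures, params = sprot_params(),
                                  ecdf_table, extra = list()) {
  all_s <- c(structures, extra)
  stopifnot(!is.null(names(all_s)), !anyDuplicated(names(all_s)))
  sphere_cache <- new.env(parent = emptyenv())
  pair_cache <- new.env(parent = emptyenv())
  get_spheres <- function(id) {
    if (is.null(sphere_cache[[id]]))
      sphere_cache[[id]] <- build_all_spheres(all_s[[id]], params$radius)
    sphere_cache[[id]]
  }
  function(id_a, id_b) {
    key <- paste0(id_a, "\r", id_b)
    hit <- pair_cache[[key]]
    if (!is.null(hit)) return(hit)
    dd <- sprot_distance_pair(all_s[[id_a]], all_s[[id_b]], params,
                              ecdf_table,
                              spheres_x = get_spheres(id_a),
                              spheres_y = get_spheres(id_b))
    out <- list(d_ab = dd$d_xy, d_ba = dd$d_yx)
    pair_cache[[key]] <- out
    out
  }
}
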