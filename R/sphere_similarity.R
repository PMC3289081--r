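#' Seed alignment of two spherical backbones
#'
#' Gapless alignment of the spherical backbones of two aa-spheres: the
#' centres are paired, upstream backbone residues are paired outward from the
#' centres and truncated to the shorter side, and likewise downstream. The
#' alignment is unique by construction.
#'
#' @param x,y aa-spheres (see [build_aa_sphere()]).
#' @return Integer matrix with columns `x`, `y` of paired residue indices,
#'   ordered by sequence position.
#' @export
seed_backbone_alignment <- function(x, y) {
  stopifnot(inherits(x, "aa_sphere"), inherits(y, "aa_sphere"))
  n_ub <- min(x$qc["ub"], y$qc["ub"])
  n_db <- min(x$qc["db"], y$qc["db"])
  up <- if (n_ub > 0) cbind(x$center - (n_ub:1), y$center - (n_ub:1))
  dn <- if (n_db > 0) cbind(x$center + (1:n_db), y$center + (1:n_db))
  out <- rbind(up, cbind(x$center, y$center), dn)
  colnames(out) <- c("x", "y")
  out
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rigid superposition of two paired point sets: finds the
#' proper rotation `R` and translation `t` minimizing the RMSD of
#' `X[i,] - (Y[i,] %*% t(R) + t)`, i.e. mapping `Y` onto `X`. Reflections are
#' excluded (`det(R) = +1`). Degenerate inputs (a single point, or all points
#' coincident) yield the identity rotation with the centroid-matching
#' translation.
#'
#' @param X,Y Numeric `n x 3` matrices of paired coordinates.
#' @return An object of class `"sprot_superposition"`: list with `rotation`
#'   (3x3), `translation` (length 3), and `rmsd`.
#' @export
kabsch_superposition <- function(X, Y) {
  X <- matrix(as.numeric(X), ncol = 3)
  Y <- matrix(as.numeric(Y), ncol = 3)
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= 1)
  cx <- colMeans(X)
  cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx)
  Yc <- sweep(Y, 2, cy)
  H <- crossprod(Yc, Xc)  # 3x3 cross-covariance
  if (sum(H^2) < 1e-18) {
    R <- diag(3)
  } else {
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  }
  t_vec <- cx - as.numeric(R %*% cy)
  Yt <- Y %*% t(R) + matrix(t_vec, nrow(Y), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((X - Yt)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd),
            class = "sprot_superposition")
}

#' Apply a superposition to coordinates
#'
#' @param superposition A `"sprot_superposition"`.
#' @param coords Numeric `n x 3` matrix.
#' @return Transformed `n x 3` matrix.
#' @export
apply_superposition <- function(superposition, coords) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  coords %*% t(superposition$rotation) +
    matrix(superposition$translation, nrow(coords), 3, byrow = TRUE)
}

#' @export
print.sprot_superposition <- function(x, ...) {
  cat(sprintf("rigid superposition, rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

# distance score of Angstrom distance d at scale d_s
dist_score <- function(d, d_s) 1 / (1 + (d / d_s)^2)

# Global alignment with a linear gap model, maximizing
# sum(match scores) + gap * (#gap positions). Deterministic traceback
# preference: match, then gap in the row sequence (advance column), then gap
# in the column sequence. S may contain -Inf to forbid matches.
nw_align_r <- function(S, gap) {
  n <- nrow(S)
  m <- ncol(S)
  if (n == 0 || m == 0) return(matrix(integer(0), 0, 2))
  M <- matrix(0, n + 1, m + 1)
  M[1, ] <- gap * (0:m)
  M[, 1] <- gap * (0:n)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- max(M[i, j] + S[i, j], M[i + 1, j] + gap,
                             M[i, j + 1] + gap)
    }
  }
  pairs <- matrix(integer(0), 0, 2)
  i <- n; j <- m
  while (i > 0 && j > 0) {
    here <- M[i + 1, j + 1]
    if (here == M[i, j] + S[i, j]) {
      pairs <- rbind(c(i, j), pairs)
      i <- i - 1; j <- j - 1
    } else if (here == M[i + 1, j] + gap) {
      j <- j - 1
    } else {
      i <- i - 1
    }
  }
  colnames(pairs) <- c("x", "y")
  pairs
}

#' Align the neighbourhoods of two superposed aa-spheres
#'
#' Runs global dynamic programming separately on the upstream and downstream
#' neighbourhoods of the two spheres, after mapping `y`'s coordinates into
#' `x`'s frame with the backbone superposition. Match scores are
#' `1 / (1 + (d_ij / d_s)^2)` over alpha-carbon distances; gaps cost nothing,
#' so the alignment is the maximum-weight order-preserving matching.
#'
#' @param x,y aa-spheres.
#' @param superposition Backbone superposition mapping `y` onto `x` (from
#'   [kabsch_superposition()] on the seed alignment).
#' @param params A [sprot_params()].
#' @return List with `pairs` (residue index pairs, columns `x`, `y`) and
#'   `distances` (post-superposition alpha-carbon distances).
#' @export
align_neighborhoods <- function(x, y, superposition, params = sprot_params()) {
  one_side <- function(cx, cy, ix, iy) {
    if (nrow(cx) == 0 || nrow(cy) == 0)
      return(list(pairs = matrix(integer(0), 0, 2), distances = numeric(0)))
    cyt <- apply_superposition(superposition, cy)
    D <- cross_dist(cx, cyt)
    p <- nw_align_r(dist_score(D, params$d_s), 0)
    list(pairs = cbind(ix[p[, 1]], iy[p[, 2]]),
         distances = D[cbind(p[, 1], p[, 2])])
  }
  up <- one_side(x$coords$un, y$coords$un,
                 x$upstream_neighborhood, y$upstream_neighborhood)
  dn <- one_side(x$coords$dn, y$coords$dn,
                 x$downstream_neighborhood, y$downstream_neighborhood)
  pairs <- rbind(up$pairs, dn$pairs)
  colnames(pairs) <- c("x", "y")
  list(pairs = pairs, distances = c(up$distances, dn$distances))
}

# coordinates of backbone seed pairs in both spheres
seed_pair_coords <- function(x, y, seed) {
  coord_of <- function(s, idx) {
    out <- matrix(0, length(idx), 3)
    for (k in seq_along(idx)) {
      i <- idx[k]
      out[k, ] <- if (i == s$center) s$center_ca
      else if (i < s$center) s$coords$ub[i - (s$center - s$qc[["ub"]]) + 1, ]
      else s$coords$db[i - s$center, ]
    }
    out
  }
  list(x = coord_of(x, seed[, 1]), y = coord_of(y, seed[, 2]))
}

#' Raw spherical similarity (SM-raw)
#'
#' Computes the raw similarity of two aa-spheres: a gapless seed alignment of
#' the spherical backbones, a Kabsch superposition from the seed, global
#' alignment of the neighbourhoods under that superposition, and finally
#'
#' `SM-raw = (1 / max_norm) * sum_i 1 / (1 + (d_i / d_s)^2)`
#'
#' over all aligned pairs, where `max_norm = 1 + sum_c min(q_c(x), q_c(y))`
#' over the four categories is the maximal sum attainable for spheres with
#' these quantity characteristics. `SM-raw` lies in (0, 1] and equals 1 for
#' identical spheres.
#'
#' @inheritParams align_neighborhoods
#' @return An object of class `"sphere_similarity"`: list with `sm_raw`,
#'   `max_norm`, `alignment` (pairs + distances of the full spherical
#'   alignment, ordered by position in `x`), and `superposition`.
#' @export
sm_raw <- function(x, y, params = sprot_params()) {
  stopifnot(inherits(x, "aa_sphere"), inherits(y, "aa_sphere"))
  if (!isTRUE(all.equal(x$radius, y$radius)))
    stop("spheres built with different radii cannot be compared")
  seed <- seed_backbone_alignment(x, y)
  sc <- seed_pair_coords(x, y, seed)
  sup <- kabsch_superposition(sc$x, sc$y)
  seed_d <- sqrt(rowSums((sc$x - apply_superposition(sup, sc$y))^2))
  nb <- align_neighborhoods(x, y, sup, params)
  pairs <- rbind(nb$pairs[nb$pairs[, 1] < x$center - x$qc[["ub"]], ,
                          drop = FALSE],
                 seed,
                 nb$pairs[nb$pairs[, 1] > x$center + x$qc[["db"]], ,
                          drop = FALSE])
  dists <- c(nb$distances[nb$pairs[, 1] < x$center - x$qc[["ub"]]],
             seed_d,
             nb$distances[nb$pairs[, 1] > x$center + x$qc[["db"]]])
  max_norm <- 1 + sum(pmin(x$qc, y$qc))
  raw <- sum(dist_score(dists, params$d_s)) / max_norm
  structure(list(sm_raw = raw, max_norm = max_norm,
                 alignment = list(pairs = pairs, distances = dists),
                 superposition = sup),
            class = "sphere_similarity")
}

#' Quantity-characteristic factor
#'
#' Penalizes differences in the quantity characteristics of two aa-spheres:
#'
#' `f = prod_c (1 + min(q_c(x), q_c(y))) / (1 + max(q_c(x), q_c(y)))`
#'
#' over the four categories. `f = 1` exactly when all four counts agree and
#' strictly decreases as any category diverges. The algebraic form is a
#' package choice satisfying those constraints and is kept in this single
#' function so it can be swapped.
#'
#' @param qx,qy Quantity characteristics: integer 4-vectors
#'   `(ub, db, un, dn)` or aa-spheres (whose `qc` is used).
#' @return Scalar in (0, 1].
#' @export
quantity_factor <- function(qx, qy) {
  if (inherits(qx, "aa_sphere")) qx <- qx$qc
  if (inherits(qy, "aa_sphere")) qy <- qy$qc
  stopifnot(length(qx) == 4, length(qy) == 4, all(qx >= 0), all(qy >= 0))
  prod((1 + pmin(qx, qy)) / (1 + pmax(qx, qy)))
}

#' Normalized spherical similarity (SM-score)
#'
#' The full sphere similarity: the SM-raw value is converted to the
#' probability that no better value would arise by chance for spheres of the
#' same (downsampled) quantity characteristics, via the calibrated empirical
#' distribution, then scaled by the quantity factor:
#'
#' `SM-score(x, y) = ECDF_bucket(x, y)(SM-raw(x, y)) * f(qc_x, qc_y)`
#'
#' @inheritParams sm_raw
#' @param ecdf_table A calibration table from [build_ecdf_table()].
#' @return A `"sphere_similarity"` object with additional fields `f`,
#'   `ecdf_value` and `sm_score`.
#' @export
sm_score <- function(x, y, params = sprot_params(), ecdf_table) {
  if (missing(ecdf_table) || is.null(ecdf_table))
    stop("an ECDF calibration table is required; build one with ",
         "build_ecdf_table()")
  res <- sm_raw(x, y, params)
  key <- bucket_key(downsample_qc(x$qc), downsample_qc(y$qc))
  p <- ecdf_evaluate(ecdf_table, key, res$sm_raw)
  res$f <- quantity_factor(x$qc, y$qc)
  res$ecdf_value <- p
  res$sm_score <- p * res$f
  res
}

#' @export
print.sphere_similarity <- function(x, ...) {
  cat(sprintf("sphere similarity: SM-raw = %.4f (max_norm %d, %d pairs)",
              x$sm_raw, x$max_norm, nrow(x$alignment$pairs)))
  if (!is.null(x$sm_score))
    cat(sprintf(", SM-score = %.4f (ECDF %.4f x f %.4f)",
                x$sm_score, x$ecdf_value, x$f))
  cat("\n")
  invisible(x)
}
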