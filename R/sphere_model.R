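#' Spherical amino-acid neighbourhoods (aa-spheres)
#'
#' An aa-sphere represents one residue by the set of residues whose heavy
#' atoms come within a fixed radius of its alpha-carbon. The members split
#' into four ordered categories:
#'
#' * *upstream / downstream spherical backbone* — the maximal
#'   sequence-contiguous run of members containing the centre, on either side
#'   of it;
#' * *upstream / downstream neighbourhood* — remaining members preceding /
#'   following the centre in sequence.
#'
#' The per-category member counts are the sphere's *quantity
#' characteristics* `(q_ub, q_db, q_un, q_dn)`.
#'
#' @param structure A [sprot_structure()].
#' @param center Residue index (1-based) of the sphere centre.
#' @param radius Sphere radius in Angstrom (default 9).
#'
#' @return An object of class `"aa_sphere"`: a list with the centre index,
#'   the four ascending index vectors (`upstream_backbone`,
#'   `downstream_backbone`, `upstream_neighborhood`,
#'   `downstream_neighborhood`), the quantity characteristics `qc`
#'   (named integer vector `ub, db, un, dn`), the radius, the centre's
#'   alpha-carbon position `center_ca`, and `coords`, the alpha-carbon
#'   coordinates of each category's members.
#' @export
#' @examples
#' s <- make_backbone("helix", 20, seed = 1)
#' sph <- build_aa_sphere(s, 10, radius = 9)
#' sph$qc
build_aa_sphere <- function(structure, center, radius = 9) {
  stopifnot(inherits(structure, "sprot_structure"), radius > 0)
  n <- length(structure)
  if (center < 1 || center > n) stop("center index out of range")
  members <- sphere_members(structure, center, radius)
  new_aa_sphere(structure, center, members, radius)
}

# Membership by brute-force distance test: residue r belongs to the sphere
# iff any of its heavy atoms lies within `radius` of the centre's CA.
sphere_members <- function(structure, center, radius) {
  c0 <- structure$ca[center, ]
  hits <- vapply(structure$atoms, function(m) {
    d2 <- (m[, 1] - c0[1])^2 + (m[, 2] - c0[2])^2 + (m[, 3] - c0[3])^2
    any(d2 <= radius^2)
  }, logical(1))
  hits[center] <- TRUE
  which(hits)
}

new_aa_sphere <- function(structure, center, members, radius) {
  # spherical backbone: maximal contiguous run of members containing center
  is_mem <- logical(length(structure))
  is_mem[members] <- TRUE
  lo <- center
  while (lo > 1 && is_mem[lo - 1]) lo <- lo - 1
  hi <- center
  while (hi < length(is_mem) && is_mem[hi + 1]) hi <- hi + 1
  ub <- if (lo < center) lo:(center - 1) else integer(0)
  db <- if (hi > center) (center + 1):hi else integer(0)
  rest <- setdiff(members, c(lo:hi))
  un <- rest[rest < lo]
  dn <- rest[rest > hi]
  qc <- c(ub = length(ub), db = length(db), un = length(un), dn = length(dn))
  ca <- structure$ca
  structure(list(center = center,
                 upstream_backbone = ub, downstream_backbone = db,
                 upstream_neighborhood = un, downstream_neighborhood = dn,
                 qc = qc, radius = radius,
                 center_ca = ca[center, ],
                 coords = list(ub = ca[ub, , drop = FALSE],
                               db = ca[db, , drop = FALSE],
                               un = ca[un, , drop = FALSE],
                               dn = ca[dn, , drop = FALSE])),
            class = "aa_sphere")
}

#' @export
print.aa_sphere <- function(x, ...) {
  cat(sprintf("aa-sphere @ residue %d (radius %.3g A): qc = (%d, %d, %d, %d)\n",
              x$center, x$radius, x$qc[1], x$qc[2], x$qc[3], x$qc[4]))
  invisible(x)
}

# all member indices, ascending
sphere_member_indices <- function(sph) {
  sort(c(sph$upstream_neighborhood, sph$upstream_backbone, sph$center,
         sph$downstream_backbone, sph$downstream_neighborhood))
}

#' Build the aa-sphere of every residue
#'
#' Models the whole protein as a sequence of aa-spheres, one per residue, in
#' residue order.
#'
#' @inheritParams build_aa_sphere
#' @return A list of [build_aa_sphere()] objects, one per residue.
#' @export
build_all_spheres <- function(structure, radius = 9) {
  stopifnot(inherits(structure, "sprot_structure"), radius > 0)
  n <- length(structure)
  # one distance pass: residue-vs-residue min heavy-atom distance to each CA
  atom_xyz <- do.call(rbind, structure$atoms)
  atom_res <- rep(seq_len(n), vapply(structure$atoms, nrow, 0L))
  r2 <- radius^2
  lapply(seq_len(n), function(center) {
    c0 <- structure$ca[center, ]
    d2 <- (atom_xyz[, 1] - c0[1])^2 + (atom_xyz[, 2] - c0[2])^2 +
      (atom_xyz[, 3] - c0[3])^2
    members <- sort(unique(c(center, atom_res[d2 <= r2])))
    new_aa_sphere(structure, center, members, radius)
  })
}

#' Dump spheres as a table
#'
#' Debug helper: one row per sphere member with its category.
#'
#' @param spheres List of aa-spheres (from [build_all_spheres()]).
#' @param path Optional TSV output path.
#' @return A data frame with columns `center`, `category`, `member`.
#' @export
spheres_as_table <- function(spheres, path = NULL) {
  rows <- lapply(spheres, function(s) {
    cats <- list(upstream_neighborhood = s$upstream_neighborhood,
                 upstream_backbone = s$upstream_backbone,
                 center = s$center,
                 downstream_backbone = s$downstream_backbone,
                 downstream_neighborhood = s$downstream_neighborhood)
    data.frame(center = s$center,
               category = rep(names(cats), lengths(cats)),
               member = unlist(cats, use.names = FALSE))
  })
  df <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
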