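# Synthetic structure generator: deterministic alpha-carbon traces with one
# pseudo side-chain atom per residue, grouped into labeled families. Stands
# in for a curated structure collection so the whole pipeline is testable
# without external data.

# place the next point given three predecessors and internal coordinates
# (bond length, planar angle, dihedral), NeRF-style
place_next <- function(p1, p2, p3, length, angle, dihedral) {
  bc <- p3 - p2
  bc <- bc / sqrt(sum(bc^2))
  ab <- p2 - p1
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-length * cos(angle),
         length * sin(angle) * cos(dihedral),
         length * sin(angle) * sin(dihedral))
  p3 + d[1] * bc + d[2] * m + d[3] * n
}

# per-template pseudo-bond geometry of the CA trace (radians)
.template_geometry <- function(template, n, seed) {
  deg <- pi / 180
  switch(template,
         helix = list(angle = rep(91 * deg, n), dihedral = rep(50 * deg, n)),
         strand = list(angle = rep(123 * deg, n),
                       dihedral = rep(-170 * deg, n)),
         mixed = {
           # helix half, tight turn, strand half
           h <- n %/% 2
           t <- min(3, n - h)
           s <- n - h - t
           list(angle = c(rep(91 * deg, h), rep(80 * deg, t),
                          rep(123 * deg, s)),
                dihedral = c(rep(50 * deg, h), rep(-60 * deg, t),
                             rep(-170 * deg, s)))
         },
         stop("unknown template: ", template))
}

#' Generate a synthetic protein backbone
#'
#' Builds a deterministic alpha-carbon trace of the requested fold template
#' with consecutive CA-CA distances of 3.8 +/- 0.05 Angstrom, plus one
#' pseudo side-chain centroid atom (named `CB`) per residue, offset
#' 1.5-2.5 Angstrom from the CA in a seeded direction — so heavy-atom sphere
#' membership genuinely differs from a CA-only membership test.
#'
#' @param template `"helix"` (ideal alpha-helix trace geometry: ~1.5 A rise,
#'   ~100 degrees per residue), `"strand"` (extended), or `"mixed"`
#'   (helix-turn-strand).
#' @param length Number of residues (`>= 1`).
#' @param seed Integer seed; identical seeds give identical structures.
#' @param id Structure id.
#' @param label Optional label (see [sprot_structure()]).
#' @return A [sprot_structure()].
#' @export
make_backbone <- function(template = c("helix", "strand", "mixed"), length,
                          seed = 1L, id = NULL, label = NULL) {
  template <- match.arg(template)
  stopifnot(length >= 1)
  if (is.null(id)) id <- sprintf("%s%03d", template, seed %% 1000)
  with_seed(seed, {
    geo <- .template_geometry(template, length)
    bl <- 3.8 + runif(length, -0.03, 0.03)
    ca <- matrix(0, length, 3)
    if (length >= 2) ca[2, ] <- c(bl[2], 0, 0)
    if (length >= 3)
      ca[3, ] <- ca[2, ] + bl[3] * c(-cos(geo$angle[3]), sin(geo$angle[3]), 0)
    if (length >= 4) {
      for (i in 4:length) {
        ca[i, ] <- place_next(ca[i - 3, ], ca[i - 2, ], ca[i - 1, ],
                              bl[i], geo$angle[i], geo$dihedral[i])
      }
    }
    # pseudo side-chain centroid per residue
    dir <- matrix(rnorm(3 * length), length, 3)
    dir <- dir / sqrt(rowSums(dir^2))
    off <- runif(length, 1.5, 2.5)
    cb <- ca + dir * off
    aa <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], length,
                 replace = TRUE)
    atoms <- lapply(seq_len(length), function(i) {
      m <- rbind(ca[i, ], cb[i, ])
      rownames(m) <- c("CA", "CB")
      m
    })
    sprot_structure(id = id, aa = aa, ca = ca, atoms = atoms, label = label)
  })
}

# uniform random rotation matrix (via normalized quaternion)
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# apply coordinate noise and a random rigid motion to a structure
perturb_structure <- function(template, sigma, id, label) {
  R <- random_rotation()
  tr <- runif(3, -25, 25)
  move <- function(m) {
    m <- m + matrix(rnorm(base::length(m), sd = sigma), nrow(m), 3)
    m %*% t(R) + matrix(tr, nrow(m), 3, byrow = TRUE)
  }
  # perturb all heavy atoms first so sigma is structural noise, then apply
  # one rigid motion to the whole structure
  atoms <- lapply(template$atoms, function(m) {
    out <- move(m)
    rownames(out) <- rownames(m)
    out
  })
  ca <- do.call(rbind, lapply(atoms, function(m) m["CA", ]))
  sprot_structure(id = id, aa = template$aa, ca = ca, atoms = atoms,
                  aa3 = template$aa3, label = label)
}

#' Generate a labeled synthetic family dataset
#'
#' For each family, a fold template is built with [make_backbone()] and each
#' member is produced by adding Gaussian coordinate noise (standard
#' deviation `sigma`, applied before the rigid motion so it is structural
#' rather than positional noise) and a random rigid motion (uniform
#' rotation, translation in a 50 Angstrom box). Families cycle through the
#' three templates; the hierarchy groups families pairwise into
#' superfamilies and by template into folds.
#'
#' @param n_families Number of families.
#' @param members Members per family.
#' @param length_range Integer 2-vector: chain length range sampled per
#'   family.
#' @param sigma Within-family coordinate noise, Angstrom.
#' @param seed Integer seed; the dataset is a pure function of the
#'   arguments.
#' @param out_dir Optional directory: write each member as a PDB file.
#' @return List with `structures` (named list of labeled
#'   [sprot_structure()]), `labels` (data frame: id, family, superfamily,
#'   fold), and `templates` (the unperturbed family templates).
#' @export
make_family_dataset <- function(n_families = 3, members = 4,
                                length_range = c(25, 40), sigma = 0.5,
                                seed = 1L, out_dir = NULL) {
  stopifnot(n_families >= 1, members >= 1, sigma >= 0,
            length_range[1] >= 1, length_range[2] >= length_range[1])
  templates <- c("helix", "strand", "mixed")
  with_seed(seed, {
    structures <- list()
    templates_out <- list()
    rows <- list()
    for (f in seq_len(n_families)) {
      fam <- sprintf("F%02d", f)
      sfam <- sprintf("S%02d", ceiling(f / 2))
      tmpl_name <- templates[(f - 1) %% 3 + 1]
      len <- sample(length_range[1]:length_range[2], 1)
      label <- list(family = fam, superfamily = sfam, fold = tmpl_name)
      tmpl <- make_backbone(tmpl_name, len,
                            seed = sample.int(.Machine$integer.max, 1),
                            id = paste0(fam, "_template"), label = label)
      templates_out[[fam]] <- tmpl
      for (m in seq_len(members)) {
        id <- sprintf("%s_m%02d", fam, m)
        structures[[id]] <- perturb_structure(tmpl, sigma, id, label)
        rows[[id]] <- data.frame(id = id, family = fam, superfamily = sfam,
                                 fold = tmpl_name)
      }
    }
    labels <- do.call(rbind, rows)
    rownames(labels) <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      for (id in names(structures))
        write_structure_pdb(structures[[id]],
                            file.path(out_dir, paste0(id, ".pdb")))
      utils::write.table(labels, file.path(out_dir, "labels.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(structures = structures, labels = labels, templates = templates_out)
  })
}
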