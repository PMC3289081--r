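# Shared fixtures, built lazily and cached for the whole test run.
.cache <- new.env(parent = emptyenv())

# evaluate under a temporary RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

cached <- function(name, expr) {
  if (is.null(.cache[[name]])) .cache[[name]] <- force(expr)
  .cache[[name]]
}

std_params <- function() sprot_params()

# the standard 12-structure fixture set: 3 families x 4 members, sigma 0.5
std_dataset <- function() {
  cached("std_dataset",
         make_family_dataset(3, 4, c(25, 40), sigma = 0.5, seed = 1))
}

# calibration table from an independent synthetic set
std_ecdf <- function() {
  cached("std_ecdf", {
    cal <- make_family_dataset(4, 2, c(25, 40), sigma = 1.0, seed = 42)
    build_ecdf_table(cal$structures, std_params(), seed = 1,
                     calibration_id = "synthetic-calibration")
  })
}

# all ordered pairwise SProt distances over the standard fixture set
std_distance_matrix <- function() {
  cached("std_distmat", {
    ds <- std_dataset()
    ids <- names(ds$structures)
    dist <- structure_distance_fn(ds$structures, std_params(), std_ecdf())
    D <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    for (a in seq_along(ids)) {
      for (b in seq_along(ids)) {
        if (a < b) {
          dd <- dist(ids[a], ids[b])
          D[a, b] <- dd$d_ab
          D[b, a] <- dd$d_ba
        }
      }
    }
    D
  })
}

# 100-structure database for the index-fidelity check: five families of
# close homologues (sigma 0.3 A) so the database has genuine cluster
# structure for the pivot bounds to exploit
search_dataset <- function() {
  cached("search_dataset",
         make_family_dataset(5, 20, c(25, 40), sigma = 0.3, seed = 1))
}

# a CA-only structure from explicit coordinates (one atom per residue)
ca_only_structure <- function(ca, id = "caonly") {
  ca <- matrix(ca, ncol = 3)
  atoms <- lapply(seq_len(nrow(ca)), function(i) {
    m <- ca[i, , drop = FALSE]
    rownames(m) <- "CA"
    m
  })
  sprot_structure(id = id, aa = rep("A", nrow(ca)), ca = ca, atoms = atoms)
}

# random rigid motion applied to every atom of a structure
rigid_move <- function(structure, seed) {
  with_seed(seed, {
    q <- rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z),
                  2 * (x * z + w * y),
                  2 * (x * y + w * z), 1 - 2 * (x^2 + z^2),
                  2 * (y * z - w * x),
                  2 * (x * z - w * y), 2 * (y * z + w * x),
                  1 - 2 * (x^2 + y^2)), 3, 3, byrow = TRUE)
    tr <- runif(3, -20, 20)
    atoms <- lapply(structure$atoms, function(m) {
      out <- m %*% t(R) + matrix(tr, nrow(m), 3, byrow = TRUE)
      rownames(out) <- rownames(m)
      out
    })
    ca <- structure$ca %*% t(R) + matrix(tr, nrow(structure$ca), 3,
                                         byrow = TRUE)
    sprot_structure(structure$id, structure$aa, ca, atoms,
                    aa3 = structure$aa3, label = structure$label)
  })
}

# minimal hand-built calibration table for direct ECDF checks
toy_ecdf <- function(buckets, fingerprint = params_fingerprint(sprot_params())) {
  structure(list(version = 1L, fingerprint = fingerprint,
                 calibration_id = "toy", n_pairs = sum(lengths(buckets)),
                 buckets = lapply(buckets, sort),
                 key_matrix = sprot:::parse_bucket_keys(names(buckets))),
            class = "sprot_ecdf")
}
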