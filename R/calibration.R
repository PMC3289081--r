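#' Downsample quantity characteristics
#'
#' Maps the quantity characteristics of an aa-sphere onto the coarser grid
#' used to key the calibration tables: the upstream and downstream
#' neighbourhood counts are halved (floor), backbone counts of 0 and 1 fall
#' into one bin (both map to 1), and every component is then capped at 7.
#' The order of operations (halve, merge, cap) is fixed.
#'
#' @param qc Integer 4-vector `(ub, db, un, dn)` or an aa-sphere.
#' @return Integer 4-vector on the downsampled grid, each component in 0..7.
#' @export
#' @examples
#' downsample_qc(c(0, 1, 5, 4))   # -> 1 1 2 2
#' downsample_qc(c(9, 3, 20, 0))  # -> 7 3 7 0
downsample_qc <- function(qc) {
  if (inherits(qc, "aa_sphere")) qc <- qc$qc
  stopifnot(length(qc) == 4, all(qc >= 0))
  out <- c(max(qc[[1]], 1), max(qc[[2]], 1),
           qc[[3]] %/% 2, qc[[4]] %/% 2)
  out <- pmin(out, 7L)
  names(out) <- c("ub", "db", "un", "dn")
  as.integer(out)
}

# bucket key string for an ordered pair of downsampled characteristics
bucket_key <- function(dx, dy) {
  paste(paste(dx, collapse = "."), paste(dy, collapse = "."), sep = "|")
}

parse_bucket_keys <- function(keys) {
  comp <- strsplit(gsub("\\|", ".", keys), ".", fixed = TRUE)
  mat <- matrix(as.integer(unlist(comp)), ncol = 8, byrow = TRUE)
  rownames(mat) <- keys
  mat
}

#' Build an SM-raw calibration table
#'
#' Computes SM-raw for sphere pairs drawn from cross-protein comparisons
#' over a calibration set and pools the values into empirical distributions
#' keyed by the ordered pair of downsampled quantity characteristics. Since
#' SM-raw is symmetric in its arguments, each evaluated pair contributes a
#' sample to both key orderings. Buckets exceeding `max_per_bucket` samples
#' are reduced by seeded subsampling, so the build is deterministic for a
#' given seed.
#'
#' @param calibration_set List of [sprot_structure()] objects.
#' @param params A [sprot_params()].
#' @param max_per_bucket Sample cap per bucket (default 50000).
#' @param seed Integer seed for the subsampling.
#' @param calibration_id Free-text identifier stored in the table metadata.
#' @return An object of class `"sprot_ecdf"`.
#' @export
build_ecdf_table <- function(calibration_set, params = sprot_params(),
                             max_per_bucket = 50000L, seed = 1L,
                             calibration_id = "unnamed") {
  stopifnot(length(calibration_set) >= 1)
  spheres <- lapply(calibration_set, build_all_spheres, radius = params$radius)
  keys <- lapply(spheres, function(ss)
    vapply(ss, function(s) paste(downsample_qc(s$qc), collapse = "."), ""))
  buckets <- new.env(parent = emptyenv())
  add <- function(key, vals) {
    cur <- buckets[[key]]
    buckets[[key]] <- if (is.null(cur)) vals else c(cur, vals)
  }
  n_pairs <- 0L
  np <- length(calibration_set)
  idx_pairs <- if (np >= 2) utils::combn(np, 2) else
    matrix(c(1L, 1L), nrow = 2)  # single structure: self cross-comparison
  for (col in seq_len(ncol(idx_pairs))) {
    a <- idx_pairs[1, col]; b <- idx_pairs[2, col]
    M <- sm_raw_matrix(spheres[[a]], spheres[[b]], params)
    # SM-raw is symmetric, so one evaluation covers both ordered
    # comparisons: the value is pooled under both key orderings
    n_pairs <- n_pairs + 2L * length(M)
    kx <- keys[[a]]; ky <- keys[[b]]
    for (i in seq_along(kx)) {
      for (uy in unique(ky)) {
        vals <- M[i, ky == uy]
        add(paste(kx[i], uy, sep = "|"), vals)
        add(paste(uy, kx[i], sep = "|"), vals)
      }
    }
  }
  key_names <- sort(ls(buckets))
  samples <- lapply(key_names, function(k) {
    v <- buckets[[k]]
    if (length(v) > max_per_bucket) {
      v <- with_seed(seed, v[sort(sample.int(length(v), max_per_bucket))])
    }
    sort(v)
  })
  names(samples) <- key_names
  structure(list(version = 1L, fingerprint = params_fingerprint(params),
                 calibration_id = calibration_id, n_pairs = n_pairs,
                 buckets = samples,
                 key_matrix = parse_bucket_keys(key_names)),
            class = "sprot_ecdf")
}

#' @export
print.sprot_ecdf <- function(x, ...) {
  cat(sprintf(
    "SM-raw calibration table: %d buckets, %d samples (%d pairs evaluated)\n",
    length(x$buckets), sum(lengths(x$buckets)), x$n_pairs))
  cat("  ", x$fingerprint, "\n")
  invisible(x)
}

# resolve a requested key to a populated bucket: exact hit, else nearest
# populated key by L1 distance over the 8 components, ties broken by
# lexicographically smallest key
resolve_bucket <- function(table, key) {
  if (!is.null(table$buckets[[key]])) return(key)
  want <- parse_bucket_keys(key)[1, ]
  km <- table$key_matrix
  d <- rowSums(abs(sweep(km, 2, want)))
  cand <- which(d == min(d))
  perm <- do.call(order, as.data.frame(km[cand, , drop = FALSE]))
  rownames(km)[cand[perm[1]]]
}

#' Evaluate a calibrated ECDF
#'
#' Right-continuous empirical distribution: the fraction of stored SM-raw
#' samples less than or equal to `value` in the requested bucket. Requests
#' for unpopulated buckets fall back to the nearest populated bucket by L1
#' distance on the eight downsampled components (ties resolved to the
#' lexicographically smallest key).
#'
#' @param table A `"sprot_ecdf"` from [build_ecdf_table()].
#' @param key Bucket key string (`"u.d.u.d|u.d.u.d"`), or a list of the two
#'   downsampled 4-vectors.
#' @param value SM-raw value(s) to evaluate.
#' @return Probability in `[0, 1]`, vectorized over `value`.
#' @export
ecdf_evaluate <- function(table, key, value) {
  stopifnot(inherits(table, "sprot_ecdf"))
  if (is.list(key)) key <- bucket_key(key[[1]], key[[2]])
  s <- table$buckets[[resolve_bucket(table, key)]]
  findInterval(value, s) / length(s)
}

#' Write a calibration table to a text file
#'
#' Versioned plain-text container; sample values are written with full
#' double precision so the round-trip through [read_ecdf_table()] is exact.
#'
#' @param table A `"sprot_ecdf"`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ecdf_table <- function(table, path) {
  stopifnot(inherits(table, "sprot_ecdf"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("sprot-ecdf\tv1",
               paste0("fingerprint\t", table$fingerprint),
               paste0("calibration\t", table$calibration_id),
               paste0("n_pairs\t", table$n_pairs),
               paste0("buckets\t", length(table$buckets))), con)
  for (k in names(table$buckets)) {
    writeLines(paste0(k, "\t",
                      paste(sprintf("%.17g", table$buckets[[k]]),
                            collapse = " ")), con)
  }
  invisible(path)
}

#' Read a calibration table written by [write_ecdf_table()]
#'
#' @param path Path to the table file.
#' @return A `"sprot_ecdf"`.
#' @export
read_ecdf_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 5 || !startsWith(lines[1], "sprot-ecdf"))
    stop("not an sprot calibration table: ", path)
  hdr <- strsplit(lines[1:5], "\t")
  meta <- setNames(vapply(hdr, `[`, "", 2), vapply(hdr, `[`, "", 1))
  nb <- as.integer(meta[["buckets"]])
  body <- strsplit(lines[5 + seq_len(nb)], "\t")
  keys <- vapply(body, `[`, "", 1)
  samples <- lapply(body, function(x) as.numeric(strsplit(x[2], " ")[[1]]))
  names(samples) <- keys
  structure(list(version = 1L, fingerprint = meta[["fingerprint"]],
                 calibration_id = meta[["calibration"]],
                 n_pairs = as.integer(meta[["n_pairs"]]),
                 buckets = samples, key_matrix = parse_bucket_keys(keys)),
            class = "sprot_ecdf")
}

# fast path: SM-raw for every sphere pair of two sphere lists (C++ kernel)
#' All-pairs SM-raw matrix
#'
#' Computes the SM-raw value for every pair of spheres from two sphere lists
#' (rows: first list, columns: second). This is the compiled fast path used
#' by calibration and by the global score matrix; it agrees with per-pair
#' [sm_raw()] to numerical precision.
#'
#' @param spheres_x,spheres_y Sphere lists from [build_all_spheres()].
#' @param params A [sprot_params()].
#' @return Numeric matrix of SM-raw values.
#' @export
sm_raw_matrix <- function(spheres_x, spheres_y, params = sprot_params()) {
  px <- pack_spheres(spheres_x)
  py <- pack_spheres(spheres_y)
  sm_raw_matrix_cpp(px, py, params$d_s)
}

# flatten a sphere list into the plain structure the C++ kernel expects
pack_spheres <- function(spheres) {
  lapply(spheres, function(s) {
    list(center = as.numeric(s$center_ca),
         ub = s$coords$ub, db = s$coords$db,
         un = s$coords$un, dn = s$coords$dn)
  })
}
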