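# Independent oracles used to validate the optimized implementations.

# brute-force sphere membership: straightforward double loop
brute_sphere_members <- function(structure, center, radius) {
  hits <- integer(0)
  for (r in seq_along(structure$atoms)) {
    m <- structure$atoms[[r]]
    for (a in seq_len(nrow(m))) {
      if (sqrt(sum((m[a, ] - structure$ca[center, ])^2)) <= radius) {
        hits <- c(hits, r)
        break
      }
    }
  }
  sort(unique(c(hits, center)))
}

# exhaustive global-alignment optimum: recursion over all alignments
# (no memoization, so every alignment is enumerated)
nw_brute_score <- function(S, gap) {
  n <- nrow(S)
  m <- ncol(S)
  rec <- function(i, j) {
    if (i > n && j > m) return(0)
    if (i > n) return(gap * (m - j + 1))
    if (j > m) return(gap * (n - i + 1))
    best <- max(gap + rec(i + 1, j), gap + rec(i, j + 1))
    if (is.finite(S[i, j])) best <- max(best, S[i, j] + rec(i + 1, j + 1))
    best
  }
  rec(1, 1)
}

# score of a pairing under the linear gap model
nw_pair_score <- function(S, gap, pairs) {
  np <- nrow(pairs)
  matched <- if (np > 0) sum(S[pairs]) else 0
  matched + gap * (nrow(S) - np + ncol(S) - np)
}

# dense rotation grid (ZYZ Euler angles, 2 degree steps), built once
rotation_grid <- function(step_deg = 2) {
  cached(paste0("rotgrid", step_deg), {
    deg <- pi / 180
    a <- seq(0, 360 - step_deg, by = step_deg) * deg
    b <- seq(0, 180, by = step_deg) * deg
    g <- expand.grid(a = a, b = b, c = a)
    ca <- cos(g$a); sa <- sin(g$a)
    cb <- cos(g$b); sb <- sin(g$b)
    cc <- cos(g$c); sc <- sin(g$c)
    # R = Rz(a) Ry(b) Rz(c), entries in column-major order
    cbind(ca * cb * cc - sa * sc,  sa * cb * cc + ca * sc,  -sb * cc,
          -ca * cb * sc - sa * cc, -sa * cb * sc + ca * cc,  sb * sc,
          ca * sb,                 sa * sb,                  cb)
  })
}

# minimum RMSD over the rotation grid (optimal translation analytic)
grid_min_rmsd <- function(X, Y, step_deg = 2) {
  G <- rotation_grid(step_deg)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  B <- crossprod(Yc, Xc)  # sum_i Yc_i Xc_i^T
  const <- sum(Xc^2) + sum(Yc^2)
  tr <- as.numeric(G %*% as.vector(t(B)))
  sqrt(max(0, const - 2 * max(tr)) / nrow(X))
}

# exhaustive maximum-weight order-preserving matching (zero gap cost)
matching_brute <- function(S) nw_brute_score(S, 0)

# brute-force k nearest neighbours in a toy points space
toy_space <- function(n = 200, seed = 7) {
  cached(paste0("toyspace", n, "_", seed), {
    pts <- with_seed(seed, matrix(runif(2 * (n + 1)), n + 1, 2))
    ids <- c(sprintf("o%03d", seq_len(n)), "query")
    rownames(pts) <- ids
    list(pts = pts, ids = ids[seq_len(n)],
         dist = function(a, b) {
           d <- sqrt(sum((pts[a, ] - pts[b, ])^2)) / sqrt(2)
           list(d_ab = d, d_ba = d)
         })
  })
}
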