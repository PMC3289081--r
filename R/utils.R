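# Run code under a local RNG state, restoring the caller's stream after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# pairwise Euclidean distance matrix between two coordinate sets
cross_dist <- function(A, B) {
  D2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  D2[D2 < 0] <- 0
  sqrt(D2)
}
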