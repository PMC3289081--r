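test_that("log score matrix is floored, non-positive, and self-dominant", {
  p <- std_params()
  tab <- std_ecdf()
  s <- std_dataset()$structures[[1]]
  sph <- build_all_spheres(s, p$radius)
  S <- build_log_score_matrix(sph, sph, p, tab)
  expect_true(all(S <= 0))
  expect_true(all(S >= log(p$sm_floor) - 1e-12))
  # self-comparison diagonal entries are row maxima (SM-raw = 1, f = 1)
  for (i in seq_len(nrow(S))) expect_equal(S[i, i], max(S[i, ]))
  expect_true(all(diag(S) == 0))
})

test_that("parameter fingerprints are enforced", {
  p2 <- sprot_params(radius = 7)
  s <- std_dataset()$structures[[1]]
  sph <- build_all_spheres(s, 7)
  expect_error(build_log_score_matrix(sph, sph, p2, std_ecdf()),
               "different parameters")
})

test_that("1x1 alignments choose match or gaps by total score", {
  gp <- log(0.75)
  # -0.1 > 2 * log(0.75): matched
  expect_equal(nrow(needleman_wunsch_global(matrix(-0.1, 1, 1), gp)), 1)
  # -1.0 < 2 * log(0.75): double gap preferred
  expect_equal(nrow(needleman_wunsch_global(matrix(-1.0, 1, 1), gp)), 0)
})

test_that("global NW equals exhaustive enumeration on random matrices", {
  gp <- log(0.75)
  for (seed in 1:20) {
    dims <- with_seed(seed, sample(1:6, 2, replace = TRUE))
    S <- with_seed(seed + 300,
                   matrix(log(runif(prod(dims), 1e-4, 1)), dims[1], dims[2]))
    pairs <- needleman_wunsch_global(S, gp)
    expect_equal(nw_pair_score(S, gp, pairs), nw_brute_score(S, gp),
                 tolerance = 1e-12)
    if (nrow(pairs) > 1) {
      expect_true(all(diff(pairs[, 1]) > 0))
      expect_true(all(diff(pairs[, 2]) > 0))
    }
  }
})

test_that("TM-score is 1 for identical structures and rigid copies", {
  s <- std_dataset()$structures[[4]]
  pairs <- cbind(seq_len(length(s)), seq_len(length(s)))
  aln <- tm_score_superposition(pairs, s, s)
  expect_equal(aln$tm_score, 1, tolerance = 1e-9)
  expect_equal(aln$rmsd_aligned, 0, tolerance = 1e-9)
  expect_equal(aln$cover, 100)

  moved <- rigid_move(s, seed = 13)
  aln2 <- tm_score_superposition(pairs, s, moved)
  expect_equal(aln2$tm_score, 1, tolerance = 1e-6)
})

test_that("the TM search is at least as good as Kabsch on all pairs", {
  ds <- std_dataset()
  x <- ds$structures[[1]]
  y <- ds$structures[[2]]
  n <- min(length(x), length(y))
  pairs <- cbind(seq_len(n), seq_len(n))
  aln <- tm_score_superposition(pairs, x, y)
  sup <- kabsch_superposition(y$ca[pairs[, 2], ], x$ca[pairs[, 1], ])
  d <- sqrt(rowSums((apply_superposition(sup, x$ca[pairs[, 1], ]) -
                       y$ca[pairs[, 2], ])^2))
  d0 <- sprot:::tm_d0(length(x))
  plain <- sum(1 / (1 + (d / d0)^2)) / length(x)
  expect_gte(aln$tm_score + 1e-12, plain)
})

test_that("the SProt distance is zero on self and lies in [0, 1)", {
  p <- std_params()
  tab <- std_ecdf()
  ds <- std_dataset()
  x <- ds$structures[[1]]
  expect_equal(sprot_distance(x, x, p, tab), 0, tolerance = 1e-12)
  D <- std_distance_matrix()
  expect_true(all(D >= 0 & D < 1))
  expect_true(all(diag(D) == 0))
})

test_that("both directed distances share one alignment", {
  p <- std_params()
  tab <- std_ecdf()
  ds <- std_dataset()
  x <- ds$structures[["F01_m01"]]
  y <- ds$structures[["F01_m03"]]
  both <- sprot_distance_pair(x, y, p, tab)
  # forward direction agrees with the standalone computation
  expect_equal(both$d_xy, sprot_distance(x, y, p, tab), tolerance = 1e-12)
  # reverse direction re-scores the same pair set with roles swapped
  rev_aln <- tm_score_superposition(both$pairs[, 2:1], y, x, p)
  expect_equal(both$d_yx, 1 - rev_aln$tm_score, tolerance = 1e-12)
})

test_that("TM optimization is a fixed point on a perfect self-alignment", {
  p <- std_params()
  s <- std_dataset()$structures[[7]]
  pairs <- cbind(seq_len(length(s)), seq_len(length(s)))
  aln <- tm_score_superposition(pairs, s, s)
  opt <- tm_optimize(s, s, aln, p)
  expect_equal(opt$tm_score, 1, tolerance = 1e-9)
  expect_equal(opt$pairs, aln$pairs)
})

test_that("TM optimization never lowers the score and can extend cover", {
  p <- std_params()
  ds <- std_dataset()
  x <- ds$structures[["F02_m01"]]
  y <- ds$structures[["F02_m02"]]
  # initial alignment deliberately omits an alignable tail
  n <- min(length(x), length(y))
  half <- seq_len(floor(n / 2))
  init <- tm_score_superposition(cbind(half, half), x, y, p)
  opt <- tm_optimize(x, y, init, p)
  expect_gte(opt$tm_score, init$tm_score)
  expect_gte(opt$cover, init$cover)

  # score sequence across iterations is monotone non-decreasing
  pairs_idx <- list(c(1, 2), c(5, 6), c(9, 12), c(2, 7), c(3, 11))
  ids <- names(ds$structures)
  for (pr in pairs_idx) {
    a <- ds$structures[[ids[pr[1]]]]
    b <- ds$structures[[ids[pr[2]]]]
    init <- sprot_align(a, b, p, std_ecdf())
    scores <- init$tm_score
    for (it in 1:4) {
      pp <- sprot_params(max_tm_iterations = it)
      scores <- c(scores, tm_optimize(a, b, init, pp)$tm_score)
    }
    expect_true(all(diff(scores) >= -1e-12))
  }
})

test_that("TM-score is invariant under rigid motions of either input", {
  p <- std_params()
  ds <- std_dataset()
  x <- ds$structures[[3]]
  y <- ds$structures[[4]]
  n <- min(length(x), length(y))
  pairs <- cbind(seq_len(n), seq_len(n))
  ref <- tm_score_superposition(pairs, x, y, p)$tm_score
  for (seed in 1:5) {
    expect_equal(tm_score_superposition(pairs, rigid_move(x, seed), y,
                                        p)$tm_score, ref, tolerance = 1e-6)
    expect_equal(tm_score_superposition(pairs, x, rigid_move(y, seed + 40),
                                        p)$tm_score, ref, tolerance = 1e-6)
  }
})
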