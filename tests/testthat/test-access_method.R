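test_that("RBQ modifiers fix the endpoints and increase strictly", {
  grid <- seq(0, 1, length.out = 10001)
  for (w in c(0, 0.5, 1, 4)) {
    m <- rbq_modifier(w)
    y <- rbq_apply(m, grid)
    expect_equal(y[1], 0)
    expect_equal(y[length(y)], 1)
    expect_true(all(diff(y) > 0))
  }
  expect_equal(rbq_apply(rbq_modifier(0), grid), grid, tolerance = 1e-9)
  expect_error(rbq_apply(rbq_modifier(1), 1.5), "must lie in")
})

test_that("RBQ evaluation matches dense parametric sampling of the curve", {
  w <- 4
  m <- rbq_modifier(w)
  tt <- seq(0, 1, length.out = 1e6)
  den <- (1 - tt)^2 + 2 * w * tt * (1 - tt) + tt^2
  cx <- (2 * w * tt * (1 - tt) * 0.7 + tt^2) / den
  cy <- (2 * w * tt * (1 - tt) * 0.15 + tt^2) / den
  for (d in c(0.3, 0.7, 0.95)) {
    expect_equal(rbq_apply(m, d), cy[which.min(abs(cx - d))],
                 tolerance = 1e-5)
  }
})

test_that("the asymmetric lower bound evaluates its defining form", {
  # symmetric toy inputs reduce to |d(q,p) - d(p,o)| (scaled into [0,1])
  expect_equal(lower_bound(0.5, 0.5, 0.2, 0.2), 0.3)
  expect_equal(lower_bound(0.5, 0.4, 0.2, 0.1), 0.4)
  expect_equal(lower_bound(0.3, 0.3, 0.3, 0.3), 0)
})

test_that("the lower bound never exceeds the true distance in a metric space", {
  pts <- with_seed(21, matrix(runif(100), 50, 2))
  D <- as.matrix(dist(pts)) / sqrt(2)
  for (q in 1:10) {
    for (p in 1:50) {
      for (o in 1:50) {
        expect_lte(lower_bound(D[q, p], D[p, q], D[p, o], D[o, p]),
                   D[q, o] + 1e-12)
      }
    }
  }
})

test_that("the pivot index stores both directed matrices deterministically", {
  sp <- toy_space()
  pivots <- sp$ids[c(1, 10, 20)]
  idx <- build_pivot_index(sp$ids, pivots, sp$dist, fingerprint = "toy")
  expect_equal(dim(idx$D_po), c(3, 200))
  expect_equal(dim(idx$D_op), c(3, 200))
  for (p in pivots) expect_equal(idx$D_po[p, p], 0)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_pivot_index(idx, f1)
  idx2 <- build_pivot_index(sp$ids, pivots, sp$dist, fingerprint = "toy")
  write_pivot_index(idx2, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_pivot_index(f1)
  expect_equal(back$D_po, idx$D_po)
  expect_equal(back$D_op, idx$D_op)
  expect_identical(back$pivot_ids, idx$pivot_ids)
})

test_that("labelled pivot selection takes one structure per family", {
  ds <- std_dataset()
  pivots <- select_pivots(ds$labels$id, families = ds$labels$family)
  expect_length(pivots, length(unique(ds$labels$family)))
  expect_equal(unname(vapply(pivots, function(i)
    ds$labels$family[ds$labels$id == i], "")),
    unique(ds$labels$family))
})

test_that("exact search (v = 0, r = 0) matches the sequential scan", {
  sp <- toy_space()
  pivots <- sp$ids[seq(1, 200, by = 10)]
  idx <- build_pivot_index(sp$ids, pivots, sp$dist, fingerprint = "toy")
  for (k in c(1, 5, 10)) {
    res <- knn_search(idx, "query", sp$dist, k = k, v = 0, r = 0,
                      fingerprint = "toy")
    ref <- sequential_scan(sp$ids, "query", sp$dist, k = k)
    expect_identical(res$ids, ref$ids)
    expect_equal(res$dist_mod, ref$dist_mod)
    expect_lt(res$n_dist, ref$n_dist)
  }
})

test_that("k equal to the database size returns the whole ordered database", {
  sp <- toy_space(n = 30, seed = 9)
  idx <- build_pivot_index(sp$ids, sp$ids[1:3], sp$dist, fingerprint = "toy")
  res <- knn_search(idx, "query", sp$dist, k = 30, v = 0, r = 0,
                    fingerprint = "toy")
  ref <- sequential_scan(sp$ids, "query", sp$dist, k = 30)
  expect_identical(res$ids, ref$ids)
  expect_error(knn_search(idx, "query", sp$dist, k = 31, v = 0, r = 0,
                          fingerprint = "toy"), "exceeds")
})

test_that("a huge tolerance factor disables elimination entirely", {
  sp <- toy_space(n = 50, seed = 3)
  idx <- build_pivot_index(sp$ids, sp$ids[c(2, 17)], sp$dist,
                           fingerprint = "toy")
  res <- knn_search(idx, "query", sp$dist, k = 5, v = 1e9, r = 0,
                    fingerprint = "toy")
  ref <- sequential_scan(sp$ids, "query", sp$dist, k = 5)
  expect_identical(res$ids, ref$ids)
  expect_equal(res$n_dist, 50)
})

test_that("fingerprint mismatches are refused", {
  sp <- toy_space(n = 20, seed = 2)
  idx <- build_pivot_index(sp$ids, sp$ids[1:2], sp$dist, fingerprint = "A")
  expect_error(knn_search(idx, "query", sp$dist, k = 1, fingerprint = "B"),
               "fingerprint")
})

test_that("retrieval errors follow their definitions", {
  expect_equal(retrieval_error(letters[1:10], letters[1:10]), 0)
  expect_equal(retrieval_error(letters[1:8], letters[1:10]), 20)
  expect_equal(retrieval_error(letters[11:20], letters[1:10]), 100)
  expect_error(retrieval_error(letters[1:3], character(0)), "empty")

  expect_equal(scop_retrieval_error(letters[1:10], letters[1:10],
                                    letters[1:4]), 0)
  expect_equal(scop_retrieval_error(character(0), letters[1:10],
                                    letters[1:4]), 100)
  expect_equal(scop_retrieval_error(letters[2:10], letters[1:10],
                                    letters[1:4]), 25)
  expect_true(is.na(scop_retrieval_error(letters[1:3], letters[1:3], "z")))
})

test_that("modified distances preserve ordering", {
  m <- rbq_modifier(2)
  d <- with_seed(10, runif(100))
  expect_equal(order(rbq_apply(m, d)), order(d))
})
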