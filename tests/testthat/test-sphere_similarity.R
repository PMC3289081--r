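sphere_with_qc <- function(qc, seed = 1) {
  # build a CA-only structure whose middle sphere has roughly the wanted
  # backbone shape; used only for seed-alignment shape checks
  n <- qc[1] + qc[2] + 1
  ca <- cbind((seq_len(n)) * 3.8, 0, 0)
  s <- ca_only_structure(ca)
  build_aa_sphere(s, qc[1] + 1, radius = 3.8 * max(qc[1], qc[2], 1) + 0.1)
}

test_that("seed backbone alignment pairs outward and truncates gaplessly", {
  s <- make_backbone("helix", 20, seed = 1)
  sph <- build_all_spheres(s, 9)
  x <- sph[[10]]
  p <- seed_backbone_alignment(x, x)
  expect_equal(p[, "x"], p[, "y"])
  expect_equal(nrow(p), 1 + sum(pmin(x$qc[1:2], x$qc[1:2])))
  expect_true(any(p[, "x"] == x$center))

  # qc (3,1) vs (1,4): one upstream, centre, one downstream
  a <- sphere_with_qc(c(3, 1))
  b <- sphere_with_qc(c(1, 4))
  expect_equal(unname(a$qc[1:2]), c(3L, 1L))
  expect_equal(unname(b$qc[1:2]), c(1L, 4L))
  p <- seed_backbone_alignment(a, b)
  expect_equal(nrow(p), 3)
  expect_equal(p[, "x"], c(a$center - 1L, a$center, a$center + 1L))
  expect_equal(p[, "y"], c(b$center - 1L, b$center, b$center + 1L))

  # both backbones empty: single centre pair
  s1 <- ca_only_structure(c(0, 0, 0))
  e <- build_aa_sphere(s1, 1, 9)
  expect_equal(nrow(seed_backbone_alignment(e, e)), 1)
})

test_that("Kabsch recovers exact rigid motions and excludes reflections", {
  X <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0.3, 0.4, 1.2), 4, 3,
              byrow = TRUE)
  sup <- kabsch_superposition(X, X)
  expect_equal(sup$rotation, diag(3), tolerance = 1e-12)
  expect_equal(sup$translation, rep(0, 3), tolerance = 1e-12)
  expect_equal(sup$rmsd, 0, tolerance = 1e-12)

  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Y <- X %*% t(Rz) + matrix(c(1, 2, 3), 4, 3, byrow = TRUE)
  sup <- kabsch_superposition(X, Y)
  expect_equal(sup$rmsd, 0, tolerance = 1e-9)
  expect_equal(apply_superposition(sup, Y), X, tolerance = 1e-9)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)

  # degenerate: all points coincide
  Z <- matrix(1, 3, 3)
  sup <- kabsch_superposition(Z, Z + 5)
  expect_equal(sup$rotation, diag(3))
  expect_equal(sup$rmsd, 0)
})

test_that("Kabsch RMSD beats a dense rotation-grid search on noisy pairs", {
  for (seed in 1:3) {
    X <- with_seed(seed, matrix(rnorm(18, sd = 3), 6, 3))
    Y <- with_seed(seed + 100, X + matrix(rnorm(18, sd = 0.3), 6, 3))
    sup <- kabsch_superposition(X, Y)
    expect_lte(sup$rmsd, grid_min_rmsd(X, Y) + 1e-3)
  }
})

test_that("neighbourhood alignment equals brute-force matching enumeration", {
  p <- std_params()
  for (seed in 1:5) {
    nx <- 4; ny <- 5
    cx <- with_seed(seed, matrix(runif(3 * nx, 0, 8), nx, 3))
    cy <- with_seed(seed + 50, matrix(runif(3 * ny, 0, 8), ny, 3))
    D <- sqrt(outer(rowSums(cx^2), rowSums(cy^2), "+") - 2 * cx %*% t(cy))
    S <- 1 / (1 + (D / p$d_s)^2)
    got <- sprot:::nw_align_r(S, 0)
    expect_equal(sum(S[got]), matching_brute(S), tolerance = 1e-12)
    # order-preserving
    expect_true(all(diff(got[, 1]) > 0) && all(diff(got[, 2]) > 0))
  }
})

test_that("identical neighbourhoods under identity superposition pair perfectly", {
  s <- make_backbone("mixed", 30, seed = 4)
  sph <- build_all_spheres(s, 9)
  has_nb <- which(vapply(sph, function(x) sum(x$qc[3:4]) > 0, TRUE))
  x <- sph[[has_nb[1]]]
  idsup <- structure(list(rotation = diag(3), translation = rep(0, 3),
                          rmsd = 0), class = "sprot_superposition")
  nb <- align_neighborhoods(x, x, idsup, std_params())
  expect_equal(nrow(nb$pairs), sum(x$qc[3:4]))
  expect_equal(unname(nb$pairs[, 1]), unname(nb$pairs[, 2]))
  expect_equal(nb$distances, rep(0, nrow(nb$pairs)), tolerance = 1e-12)
})

test_that("SM-raw is 1 on self-comparison for every sphere of the fixture set", {
  p <- std_params()
  ds <- std_dataset()
  for (id in names(ds$structures)[c(1, 5, 9)]) {
    sph <- build_all_spheres(ds$structures[[id]], p$radius)
    raw <- vapply(sph, function(x) sm_raw(x, x, p)$sm_raw, 0)
    expect_equal(raw, rep(1, length(sph)), tolerance = 1e-12)
  }
})

test_that("a subset sphere reaches maximal SM-raw but is penalized by f", {
  s <- make_backbone("mixed", 34, seed = 8)
  sph <- build_all_spheres(s, 9)
  nb_size <- vapply(sph, function(x) sum(x$qc[3:4]), 0L)
  zi <- which.max(nb_size)
  expect_gte(nb_size[zi], 1)
  z <- sph[[zi]]
  # delete every neighbourhood member from a copy of z
  w <- z
  w$upstream_neighborhood <- integer(0)
  w$downstream_neighborhood <- integer(0)
  w$coords$un <- z$coords$un[0, , drop = FALSE]
  w$coords$dn <- z$coords$dn[0, , drop = FALSE]
  w$qc[3:4] <- 0L
  expect_equal(sm_raw(w, z, std_params())$sm_raw, 1, tolerance = 1e-12)
  f <- quantity_factor(w$qc, z$qc)
  expect_lt(f, 1)
  # so the full score is below the ECDF value alone
  tab <- toy_ecdf(setNames(
    list(c(0.3, 0.6, 1.0)),
    bucket_key(downsample_qc(w$qc), downsample_qc(z$qc))))
  sc <- sm_score(w, z, std_params(), tab)
  expect_equal(sc$sm_score, sc$ecdf_value * f, tolerance = 1e-12)
  expect_lt(sc$sm_score, sc$ecdf_value)
})

test_that("SM-raw matches an independent recomputation from its own parts", {
  p <- std_params()
  ds <- std_dataset()
  sx <- build_all_spheres(ds$structures[[1]], p$radius)
  sy <- build_all_spheres(ds$structures[[6]], p$radius)
  for (pair in list(c(3, 7), c(10, 2), c(20, 15))) {
    r <- sm_raw(sx[[pair[1]]], sy[[pair[2]]], p)
    redo <- sum(1 / (1 + (r$alignment$distances / p$d_s)^2)) / r$max_norm
    expect_equal(r$sm_raw, redo, tolerance = 1e-12)
    expect_gt(r$sm_raw, 0)
    expect_lte(r$sm_raw, 1)
  }
})

test_that("SM-raw is invariant under a rigid motion of one protein", {
  p <- std_params()
  s <- std_dataset()$structures[[2]]
  s2 <- rigid_move(s, seed = 77)
  M1 <- sm_raw_matrix(build_all_spheres(s, p$radius),
                      build_all_spheres(std_dataset()$structures[[5]],
                                        p$radius), p)
  M2 <- sm_raw_matrix(build_all_spheres(s2, p$radius),
                      build_all_spheres(std_dataset()$structures[[5]],
                                        p$radius), p)
  expect_equal(M1, M2, tolerance = 1e-9)
})

test_that("the compiled SM-raw matrix equals the per-pair reference", {
  p <- std_params()
  ds <- std_dataset()
  sx <- build_all_spheres(ds$structures[[3]], p$radius)
  sy <- build_all_spheres(ds$structures[[10]], p$radius)
  M <- sm_raw_matrix(sx, sy, p)
  idx <- with_seed(5, cbind(sample(length(sx), 12), sample(length(sy), 12)))
  for (k in seq_len(nrow(idx))) {
    expect_equal(M[idx[k, 1], idx[k, 2]],
                 sm_raw(sx[[idx[k, 1]]], sy[[idx[k, 2]]], p)$sm_raw,
                 tolerance = 1e-12)
  }
})

test_that("the quantity factor matches its defining form", {
  expect_equal(quantity_factor(c(2, 2, 0, 0), c(2, 2, 0, 0)), 1)
  expect_equal(quantity_factor(c(2, 2, 0, 0), c(2, 2, 2, 2)), 1 / 9)
  expect_equal(quantity_factor(c(0, 0, 0, 0), c(1, 0, 0, 0)), 1 / 2)
  # strictly decreasing as any category diverges
  f0 <- quantity_factor(c(3, 3, 2, 2), c(3, 3, 2, 2))
  f1 <- quantity_factor(c(3, 3, 2, 2), c(3, 3, 2, 4))
  f2 <- quantity_factor(c(3, 3, 2, 2), c(3, 3, 2, 6))
  expect_true(f0 > f1 && f1 > f2)
})

test_that("SM-score combines the ECDF value and the factor, capped by f", {
  p <- std_params()
  s <- make_backbone("helix", 20, seed = 9)
  sph <- build_all_spheres(s, p$radius)
  x <- sph[[10]]
  key_self <- bucket_key(downsample_qc(x$qc), downsample_qc(x$qc))
  tab <- toy_ecdf(setNames(list(c(0.2, 0.4, 0.4, 0.9)), key_self))
  # identical spheres: SM-raw 1 >= all samples, ECDF 1, f 1
  expect_equal(sm_score(x, x, p, tab)$sm_score, 1)
  # any pair is bounded by its quantity factor
  y <- sph[[3]]
  sc <- sm_score(x, y, p, tab)
  expect_lte(sc$sm_score, quantity_factor(x$qc, y$qc))
  expect_error(sm_score(x, y, p, NULL), "calibration table")
})
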