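test_that("bundles of adjacent helices are extracted deterministically", {
  mono <- make_toy_pilin(seed = 1)
  fil <- build_filament(mono, sym_par, 9)

  b1 <- extract_bundle(fil, k = 1, residue_range = 1:135)
  expect_identical(nrow(b1$xyz), 135L)

  b5 <- extract_bundle(fil, k = 5, residue_range = 1:35)
  expect_identical(nrow(b5$xyz), 175L)
  expect_identical(unique(b5$labels$chain), 0:4)

  # helical symmetry: bundles starting anywhere superpose exactly
  b5c <- extract_bundle(fil, k = 5, residue_range = 1:35, start_chain = 3)
  expect_lt(superpose(b5, b5c)$rmsd, 1e-6)

  expect_error(extract_bundle(fil, k = 20), "chains")
})

test_that("superposition is exact on rigid copies and symmetric in its arguments", {
  mono <- make_toy_pilin(seed = 1)
  b <- extract_bundle(build_filament(mono, sym_par, 9), 5, 1:35)
  set.seed(11)
  R <- random_rotation()
  moved <- sweep(b$xyz %*% t(R), 2, c(4, -7, 12), `+`)
  fit <- superpose(b$xyz, moved)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(crossprod(fit$rotation), diag(3), tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)

  b2 <- extract_bundle(build_filament(mono, sym_sso, 9), 5, 1:35)
  expect_equal(superpose(b, b2)$rmsd, superpose(b2, b)$rmsd,
               tolerance = 1e-9)

  # invariance under pre-transformation of either input
  r0 <- superpose(b, b2)$rmsd
  b2m <- b2
  b2m$xyz <- sweep(b2$xyz %*% t(R), 2, c(-3, 5, 1), `+`)
  expect_equal(superpose(b, b2m)$rmsd, r0, tolerance = 1e-9)

  expect_error(superpose(b$xyz[1:2, ], moved[1:2, ]), "3 point")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "degenerate|collinear")

  # independent cross-check against bio3d's least-squares fit
  rmsd_bio3d <- bio3d::rmsd(as.numeric(t(b$xyz)), as.numeric(t(b2$xyz)),
                            fit = TRUE)
  expect_equal(superpose(b, b2)$rmsd, rmsd_bio3d, tolerance = 1e-3)
})

test_that("analytic superposition matches a dense rotation-grid search on small sets", {
  set.seed(3)
  for (i in 1:3) {
    n <- sample(4:6, 1)
    P <- matrix(rnorm(3 * n, sd = 2), ncol = 3)
    Q <- matrix(rnorm(3 * n, sd = 2), ncol = 3)
    analytic <- superpose(P, Q)$rmsd
    grid <- grid_search_rmsd(P, Q, step_deg = 2)
    expect_gte(grid, analytic - 1e-9)
    expect_lt(grid - analytic, 0.01)
  }
})

test_that("RMSD matrices are symmetric with a zero diagonal and flag unmappable pairs", {
  mono <- make_toy_pilin(seed = 1)
  b <- extract_bundle(build_filament(mono, sym_par, 9), 5, 1:35)
  b2 <- extract_bundle(build_filament(mono, sym_sso, 9), 5, 1:35)

  expect_identical(rmsd_matrix(list(b)), matrix(0, 1, 1))

  set.seed(4)
  brot <- b
  brot$xyz <- b$xyz %*% t(random_rotation())
  M <- rmsd_matrix(list(b, brot, b2))
  expect_equal(M, t(M))
  expect_equal(diag(M), rep(0, 3))
  expect_lt(M[1, 2], 1e-6)
  expect_gt(M[1, 3], 0.1)
  expect_equal(M[1, 3], superpose(b, b2)$rmsd, tolerance = 1e-9)

  short <- coord_set(b$xyz[1:10, ])
  M2 <- rmsd_matrix(list(b, short))
  expect_true(is.na(M2[1, 2]))
})

test_that("TM-scores are 1 for identity, length-normalised and low for random clouds", {
  mono <- make_toy_pilin(seed = 1)
  b <- extract_bundle(build_filament(mono, sym_par, 9), 5, 1:35)
  expect_identical(tm_score(b, b), 1)
  expect_equal(tm_d0(135), 4.316, tolerance = 1e-3)
  expect_equal(tm_d0(135), 1.24 * (135 - 15)^(1 / 3) - 1.8, tolerance = 1e-12)
  expect_error(tm_score(b, b, L_norm = 15), "L_norm")
  expect_error(tm_d0(15))

  b2 <- extract_bundle(build_filament(mono, sym_sso, 9), 5, 1:35)
  expect_equal(tm_score(b, b2), tm_score(b2, b), tolerance = 1e-6)
  expect_gt(tm_score(b, b2), 0.5)  # same monomer, slightly different packing

  set.seed(42)
  r1 <- matrix(runif(300, 0, 30), ncol = 3)
  r2 <- matrix(runif(300, 0, 30), ncol = 3)
  expect_lt(tm_score(r1, r2), 0.3)
})

test_that("disulfide candidates are found from Calpha geometry", {
  none <- coord_set(matrix(rnorm(9), 3), resno = 1:3,
                    resid = c("ALA", "GLY", "SER"))
  expect_identical(nrow(cys_pair_candidates(none)), 0L)

  cc <- coord_set(rbind(c(0, 0, 0), c(5, 0, 0), c(0, 12, 0), c(1, 1, 1)),
                  chain = "A", resno = c(80, 139, 200, 50),
                  resid = c("CYS", "CYS", "CYS", "ALA"))
  pairs <- cys_pair_candidates(cc)
  expect_identical(nrow(pairs), 1L)
  expect_identical(c(pairs$resno1, pairs$resno2), c(80, 139))
  expect_true(pairs$intra_chain)
  expect_equal(pairs$distance, 5)

  far <- coord_set(rbind(c(0, 0, 0), c(12, 0, 0), c(30, 30, 30)),
                   resno = 1:3, resid = c("CYS", "CYS", "ALA"))
  expect_identical(nrow(cys_pair_candidates(far)), 0L)

  expect_error(cys_pair_candidates(coord_set(matrix(rnorm(9), 3))),
               "resid")
})
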