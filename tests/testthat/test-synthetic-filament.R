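test_that("toy pilin monomer has the two-domain geometry", {
  mono <- make_toy_pilin()
  expect_identical(nrow(mono$sites), 135L)
  helix <- mono$sites[mono$sites$role == "helix", ]
  expect_identical(nrow(helix), 35L)
  expect_equal(max(helix$z) - min(helix$z), 34 * 1.5)
  # helix axis at radial_offset: xy distance from (radial_offset, 0) is 2.3
  expect_equal(sqrt((helix$x - 8)^2 + helix$y^2), rep(2.3, 35),
               tolerance = 1e-9)

  expect_identical(make_toy_pilin(seed = 4)$sites, make_toy_pilin(seed = 4)$sites)
  expect_false(identical(make_toy_pilin(seed = 4)$sites,
                         make_toy_pilin(seed = 5)$sites))

  all_helix <- make_toy_pilin(n_residues = 40, helix_len = 40)
  expect_true(all(all_helix$sites$role == "helix"))
  expect_error(make_toy_pilin(n_residues = 30, helix_len = 35), "helix_len")
})

test_that("glycan decoration appends outward pseudo-atoms without touching the protein", {
  mono <- make_toy_pilin(seed = 1)
  gly <- surface_residues(mono, 7)
  expect_length(gly, 7)
  dec <- decorate_glycans(mono, gly)
  expect_identical(nrow(dec$sites), nrow(mono$sites) + 7L)
  expect_identical(dec$sites[seq_len(nrow(mono$sites)), ], mono$sites)
  g <- dec$sites[dec$sites$role == "glycan", ]
  expect_setequal(g$resno, gly)
  base <- mono$sites[match(g$resno, mono$sites$resno), ]
  expect_equal(sqrt(g$x^2 + g$y^2) - sqrt(base$x^2 + base$y^2),
               rep(5, 7), tolerance = 1e-9)
  expect_equal(g$z, base$z)

  expect_identical(decorate_glycans(mono, integer(0)), mono)
  one <- decorate_glycans(mono, gly[1])
  expect_identical(nrow(one$sites), nrow(mono$sites) + 1L)
  expect_error(decorate_glycans(mono, 999), "outside")
  expect_error(decorate_glycans(mono, 10), "globular")
})

test_that("surface residues are globular, separated and exposed", {
  mono <- make_toy_pilin(seed = 1)
  gly <- surface_residues(mono, 7)
  expect_true(all(gly > 35))
  s <- mono$sites[mono$sites$resno %in% gly, ]
  expect_true(min(dist(s[, c("x", "y", "z")])) >= 8)
})

test_that("filament assembly applies the screw operation per chain", {
  mono <- make_toy_pilin(seed = 1)
  f1 <- build_filament(mono, sym_par, 1)
  expect_equal(f1$sites[, c("x", "y", "z")], mono$sites[, c("x", "y", "z")])

  fil <- build_filament(mono, sym_par, 30)
  expect_identical(length(unique(fil$sites$chain)), 30L)
  expect_gt(fil$outer_diameter, 70)
  expect_lt(fil$outer_diameter, 90)

  # direct transform oracle for chain k = 2, residue 1
  s0 <- fil$sites[fil$sites$chain == 0 & fil$sites$resno == 1, ]
  s2 <- fil$sites[fil$sites$chain == 2 & fil$sites$resno == 1, ]
  a <- 2 * 101.69 * pi / 180
  expect_equal(s2$x, s0$x * cos(a) - s0$y * sin(a), tolerance = 1e-12)
  expect_equal(s2$y, s0$x * sin(a) + s0$y * cos(a), tolerance = 1e-12)
  expect_equal(s2$z, s0$z + 2 * 5.26, tolerance = 1e-12)

  expect_error(build_filament(mono, sym_par, 0), "n_subunits")
})

test_that("rasterization conserves mass and is linear in the weights", {
  mono <- make_toy_pilin(n_residues = 20, helix_len = 20)
  fil <- build_filament(mono, sym_par, 3)
  map <- rasterize(fil, voxel = 1.08, resolution = 7)
  expect_equal(sum(map$values) * 1.08^3, sum(fil$sites$weight),
               tolerance = 0.01)

  fil2 <- fil
  fil2$sites$weight <- 2 * fil$sites$weight
  map2 <- rasterize(fil2, resolution = 7, like = map)
  expect_equal(map2$values, 2 * map$values, tolerance = 1e-12)

  # empty model on an explicit grid renders to zero
  empty <- list(sites = fil$sites[integer(0), ])
  map0 <- rasterize(empty, voxel = 1.08, resolution = 7, box = c(8, 8, 8))
  expect_true(all(map0$values == 0))

  # single unit-weight atom at the grid centre
  one <- list(sites = data.frame(x = 0, y = 0, z = 0, weight = 1,
                                 chain = 0L, resno = 1L, role = "helix"))
  m1 <- rasterize(one, voxel = 1.08, resolution = 7, box = c(21, 21, 21))
  ctr <- c(11, 11, 11)
  expect_identical(which(m1$values == max(m1$values)),
                   as.integer((ctr[3] - 1) * 441 + (ctr[2] - 1) * 21 + ctr[1]))
  expect_equal(sum(m1$values) * 1.08^3, 1, tolerance = 0.01)

  expect_error(rasterize(fil, voxel = 1.08, resolution = 1.5), "Nyquist|resolution")
  expect_warning(rasterize(fil, voxel = 1.08, resolution = 7, box = c(10, 10, 10)),
                 "clipped")
})

test_that("rasterized maps carry the helical symmetry they were built with", {
  fil <- build_filament(make_toy_pilin(seed = 2), sym_par, 24)
  map <- rasterize(fil, voxel = 0.6, resolution = 7)
  expect_gte(helical_self_correlation(map, sym_par), 0.99)
})

test_that("projection and power spectrum have the Fourier symmetries of a real image", {
  z0 <- density_map(array(0, c(8, 8, 16)), 1)
  sp0 <- project_and_spectrum(z0)
  expect_true(all(sp0$projection == 0))
  expect_true(all(sp0$power == 0))

  fil <- build_filament(make_toy_pilin(seed = 2), sym_par, 6)
  sp <- project_and_spectrum(rasterize(fil, voxel = 1.08, resolution = 7))
  pw <- sp$power
  nz <- nrow(pw); ny <- ncol(pw)
  # point inversion: P(k) = P(-k)
  inv <- pw[c(1, nz:2), c(1, ny:2)]
  expect_equal(pw, inv, tolerance = 1e-9)
  expect_equal(sp$axial_step, 1 / (nz * 1.08))
})

test_that("seeded noise is reproducible and correctly scaled", {
  m <- density_map(array(0, c(64, 64, 64)), 1)
  expect_identical(add_noise(m, 0, seed = 1), m)
  n1 <- add_noise(m, 0.5, seed = 9)
  n2 <- add_noise(m, 0.5, seed = 9)
  expect_identical(n1$values, n2$values)
  expect_equal(sd(n1$values - m$values), 0.5, tolerance = 0.05)
  # global RNG state untouched
  set.seed(123); before <- .Random.seed
  invisible(add_noise(m, 1, seed = 4))
  expect_identical(.Random.seed, before)
})

test_that("the glyco fixture builder yields matched decorated/control filaments", {
  fx <- make_glyco_fixture(seed = 3, n_subunits = 4)
  expect_length(fx$glycan_residues, 7)
  expect_identical(fx$filament$n_subunits, 4L)
  n_per_chain <- nrow(fx$monomer$sites)
  expect_identical(nrow(fx$filament_glyco$sites) - nrow(fx$filament$sites),
                   7L * 4L)
})
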