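# Shared fixtures. Expensive simulation products are memoised so several
# test files can reuse them within one run.

sym_par <- helical_symmetry(5.26, 101.69)   # P. arsenaticum-like lattice
sym_sso <- helical_symmetry(4.97, 104.57)   # S. solfataricus-like lattice

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# matched decorated/control filaments + rendered maps at 1.08 A/voxel
glyco_maps <- function() {
  memo("glyco_maps", {
    fx <- make_glyco_fixture(seed = 1)
    exp_g <- rasterize(fx$filament_glyco, voxel = 1.08, resolution = 7)
    model <- rasterize(fx$filament, resolution = 7, like = exp_g)
    c(fx, list(exp_map = exp_g, model_map = model))
  })
}

# long filament spectrum for indexing tests (the heavy simulation)
indexing_spectrum <- function() {
  memo("indexing_spectrum", {
    mono <- make_toy_pilin(seed = 7)
    fil <- build_filament(mono, sym_par, 120)
    map <- suppressWarnings(
      rasterize(fil, voxel = 1.08, resolution = 7, box = c(96, 256, 512)))
    list(filament = fil, spectrum = project_and_spectrum(map),
         radius = fil$outer_diameter / 2)
  })
}

# brute-force rigid-superposition oracle: dense z-x-z Euler-angle grid
# (2 degree steps), optimal translation by centroid alignment. With
# H = Qc^T Pc, rmsd^2(R) = c0 - (2/n) tr(R H); for R = Rz(c) Rx(b) Rz(a)
# and G = Rx(b) Rz(a) H, tr(R H) = cos(c)(G11+G22) + sin(c)(G12-G21) + G33,
# so the innermost angle is evaluated vectorised without materialising
# every rotation matrix.
grid_search_rmsd <- function(P, Q, step_deg = 2) {
  n <- nrow(P)
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  H <- t(Qc) %*% Pc
  c0 <- mean(rowSums(Pc^2)) + mean(rowSums(Qc^2))
  ang <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  rotz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3)
  rotx <- function(t) matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3)
  cosc <- cos(ang); sinc <- sin(ang)
  best <- -Inf
  for (a in ang) {
    Ra <- rotz(a)
    for (b in ang[ang <= pi + 1e-9]) {   # beta in [0, 180] covers SO(3)
      G <- rotx(b) %*% Ra %*% H
      val <- max(cosc * (G[1, 1] + G[2, 2]) + sinc * (G[1, 2] - G[2, 1]) +
                   G[3, 3])
      if (val > best) best <- val
    }
  }
  sqrt(max(0, c0 - 2 * best / n))
}

random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3)
  qr_dec <- qr(M)
  R <- qr.Q(qr_dec)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
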