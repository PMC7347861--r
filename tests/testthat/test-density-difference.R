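test_that("lowpass preserves the mean, is spectrally compact and composes", {
  const <- density_map(array(3.7, c(16, 16, 16)), 1.08)
  expect_equal(lowpass(const, 7)$values, const$values, tolerance = 1e-12)

  gm <- glyco_maps()
  lp1 <- lowpass(gm$exp_map, 7)
  expect_equal(mean(lp1$values), mean(gm$exp_map$values), tolerance = 1e-12)

  # power above the cutoff frequency < 1% of total after filtering
  d <- dim(lp1$values)
  kk <- sqrt(outer(outer(pilihelix:::fft_freq(d[1], 1.08)^2,
                         pilihelix:::fft_freq(d[2], 1.08)^2, `+`),
                   pilihelix:::fft_freq(d[3], 1.08)^2, `+`))
  pw <- Mod(stats::fft(lp1$values))^2
  expect_lt(sum(pw[kk > 1 / 7]) / sum(pw), 0.01)

  # filtering twice equals one pass of the composed (squared) kernel
  lp2 <- lowpass(lp1, 7)
  H <- pilihelix:::lowpass_transfer(d, 1.08, 7)
  comp <- Re(stats::fft(stats::fft(gm$exp_map$values) * H * H,
                        inverse = TRUE)) / prod(d)
  expect_lt(sqrt(mean((lp2$values - comp)^2)),
            0.01 * sqrt(mean((lp1$values - lp2$values)^2)))

  expect_error(lowpass(const, 1.5), "Nyquist")
})

test_that("least-squares map scaling recovers known scale factors", {
  gm <- glyco_maps()
  m <- gm$model_map
  e2 <- m; e2$values <- 2 * m$values
  expect_equal(scale_to(m, e2), 2, tolerance = 1e-12)

  # orthogonal: scale against a map with no overlap
  shift <- m
  shift$values <- array(0, dim(m$values))
  mask <- m$values > 0.1 * max(m$values)
  shift$values[!mask] <- max(m$values)
  masked_model <- m
  masked_model$values[!mask] <- 0
  expect_equal(scale_to(masked_model, shift), 0, tolerance = 1e-12)

  e15 <- add_noise(m, sigma = 0.1 * sd(m$values), seed = 5)
  e15$values <- 1.5 * m$values + (e15$values - m$values)
  expect_equal(scale_to(m, e15), 1.5, tolerance = 0.02 * 1.5)

  zero <- m; zero$values <- array(0, dim(m$values))
  expect_error(scale_to(zero, m), "zero")
  bad <- density_map(array(0, c(4, 4, 4)), 1)
  expect_error(difference_map(m, bad), "grid")
})

test_that("self-subtraction is null and planted glycans are recovered exactly", {
  gm <- glyco_maps()
  d0 <- difference_map(gm$exp_map, gm$exp_map)
  expect_lt(sqrt(mean(d0$values^2)),
            1e-6 * sqrt(mean(gm$exp_map$values^2)))

  dg <- difference_map(gm$exp_map, gm$model_map)
  calls <- call_glyco_sites(dg, gm$filament)
  expect_setequal(unique(calls$resno), gm$glycan_residues)
  expect_identical(sum(!calls$resno %in% gm$glycan_residues), 0L)
  # every chain recovers all 7 sites on this noiseless fixture
  per_chain <- split(calls$resno, calls$chain)
  expect_true(all(vapply(per_chain, function(z)
    setequal(z, gm$glycan_residues), logical(1))))
  expect_identical(nrow(attr(calls, "unassigned")), 0L)

  # a single planted glycan yields a single call
  mono1 <- decorate_glycans(gm$monomer, gm$glycan_residues[1])
  f1 <- build_filament(mono1, sym_par, gm$filament$n_subunits)
  e1 <- rasterize(f1, resolution = 7, like = gm$exp_map)
  d1 <- difference_map(e1, gm$model_map)
  c1 <- call_glyco_sites(d1, gm$filament)
  expect_identical(unique(c1$resno), gm$glycan_residues[1])

  # zero-noise undecorated control: no calls at all
  ctrl <- rasterize(gm$filament, resolution = 7, like = gm$exp_map)
  dz <- difference_map(ctrl, gm$model_map)
  expect_identical(nrow(call_glyco_sites(dz, gm$filament)), 0L)
})

test_that("glycans are still recovered from noisy maps at moderate SNR", {
  gm <- glyco_maps()
  d0 <- difference_map(gm$exp_map, gm$model_map)
  peak <- max(d0$values)
  # filtered-noise calibration: sd of unit raw noise after the 7 A filter
  blank <- density_map(array(0, dim(gm$exp_map$values)), gm$exp_map$voxel,
                       gm$exp_map$origin)
  s_filt <- sd(lowpass(add_noise(blank, 1, seed = 99), 7)$values)
  # raw noise level such that glycan peaks stand at 5x the filtered noise
  en <- add_noise(gm$exp_map, peak / (5 * s_filt), seed = 42)
  dn <- difference_map(en, gm$model_map)
  calls <- call_glyco_sites(dn, gm$filament)
  recalled <- sum(gm$glycan_residues %in% unique(calls$resno))
  expect_gte(recalled, 6)
})

test_that("extra-density fractions are monotone and order decorated above control", {
  gm <- glyco_maps()
  dg <- difference_map(gm$exp_map, gm$model_map)

  zero <- dg
  zero$values <- array(0, dim(dg$values))
  expect_equal(extra_density_fraction(zero)$fraction, c(0, 0, 0))

  ef_g <- extra_density_fraction(dg)
  expect_identical(ef_g$threshold, c(3, 5, 8))
  expect_true(all(diff(ef_g$fraction) <= 0))

  ctrl <- add_noise(rasterize(gm$filament, resolution = 7, like = gm$exp_map),
                    sigma = 0.002, seed = 3)
  dc <- difference_map(ctrl, gm$model_map)
  ef_c <- extra_density_fraction(dc)
  expect_true(all(ef_g$fraction > ef_c$fraction))
  # an unglycosylated filament explains its own model map: almost no
  # extra density at any display threshold
  expect_true(all(ef_c$fraction < 0.01))
})

test_that("radial profiles localise the filament envelope and the glycan shell", {
  uni <- density_map(array(2, c(24, 24, 8)), 1)
  rp_u <- radial_profile(uni, bin = 2)
  expect_equal(rp_u$mean_density, rep(2, nrow(rp_u)))

  gm <- glyco_maps()
  rp <- radial_profile(gm$model_map, bin = 1)
  outer_r <- max(rp$radius[rp$mean_density > 0.01 * max(rp$mean_density)])
  expect_gte(outer_r, 35)
  expect_lte(outer_r, 46)

  rp_g <- radial_profile(gm$exp_map, bin = 1)
  excess <- rp_g$mean_density - rp$mean_density[match(rp_g$radius, rp$radius)]
  excess[is.na(excess)] <- 0
  expect_true(all(excess > -1e-9))
  ctrl_outer <- max(rp$radius[rp$mean_density > 0.02 * max(rp$mean_density)])
  expect_gt(rp_g$radius[which.max(excess)], ctrl_outer - 8)
})
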