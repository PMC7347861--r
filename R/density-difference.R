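#' Low-pass filter a density map
#'
#' Fourier-space filter retaining frequencies below the cutoff
#' kc = 1/resolution: flat to kc - 3 * edge * kc, then a Gaussian roll-off
#' of width edge * kc, so that the response has decayed to ~1 percent at
#' the cutoff itself (negligible power is retained beyond 1/resolution). A
#' hard cutoff is avoided because its real-space ringing halo around
#' strong features would contaminate difference maps. The zero-frequency
#' term (map mean) is preserved exactly.
#'
#' @param map a [density_map()].
#' @param resolution cutoff resolution in Angstrom (>= 2 * voxel).
#' @param edge Gaussian roll-off width as a fraction of the cutoff
#'   frequency (default 1/8).
#' @return the filtered [density_map()].
#' @export
lowpass <- function(map, resolution, edge = 1 / 8) {
  stopifnot(inherits(map, "density_map"))
  if (resolution < 2 * map$voxel)
    stop("'resolution' is beyond the Nyquist limit (2 * voxel)")
  H <- lowpass_transfer(dim(map$values), map$voxel, resolution, edge)
  ft <- stats::fft(map$values)
  map$values <- Re(stats::fft(ft * H, inverse = TRUE)) / length(ft)
  map
}

# 3-D transfer function: flat to kc - 3w, Gaussian edge of width w beyond
# (response ~ 1% at kc itself)
lowpass_transfer <- function(dims, voxel, resolution, edge = 1 / 8) {
  kc <- 1 / resolution
  w <- edge * kc
  k0 <- kc - 3 * w
  ax <- lapply(dims, function(n) fft_freq(n, voxel))
  kx <- array(rep(ax[[1]], times = dims[2] * dims[3]), dim = dims)
  ky <- array(rep(rep(ax[[2]], each = dims[1]), times = dims[3]), dim = dims)
  kz <- array(rep(ax[[3]], each = dims[1] * dims[2]), dim = dims)
  k <- sqrt(kx^2 + ky^2 + kz^2)
  H <- array(1, dim = dims)
  hi <- k > k0
  H[hi] <- exp(-((k[hi] - k0)^2) / (2 * w^2))
  H
}

# unshifted FFT sample frequencies (cycles per Angstrom)
fft_freq <- function(n, voxel) {
  i <- seq_len(n) - 1
  i[i > n / 2] <- i[i > n / 2] - n
  i / (n * voxel)
}

#' Least-squares scale of a model map onto an experimental map
#'
#' @param model_map,exp_map [density_map()]s on the same grid.
#' @param mask logical array (same dims) restricting the fit; `NULL` uses
#'   all voxels.
#' @return scalar alpha minimizing sum over the mask of
#'   (exp - alpha * model)^2: <exp * model> / <model^2>.
#' @export
scale_to <- function(model_map, exp_map, mask = NULL) {
  check_same_grid(model_map, exp_map)
  m <- model_map$values; e <- exp_map$values
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(m)))
    m <- m[mask]; e <- e[mask]
  }
  denom <- sum(m * m)
  if (denom == 0) stop("model map is all zero inside the mask")
  sum(e * m) / denom
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)) ||
      !isTRUE(all.equal(a$voxel, b$voxel)) ||
      !isTRUE(all.equal(a$origin, b$origin)))
    stop("maps are not on the same grid")
  invisible(TRUE)
}

#' Model envelope mask
#'
#' Voxels where the low-passed model map exceeds `level` of its maximum,
#' dilated by one voxel. Used both to restrict the scaling fit and to
#' classify difference density as inside/outside the modelled molecule.
#'
#' @param model_map a [density_map()] (already low-passed).
#' @param level fraction of the map maximum (default 0.1).
#' @return logical array.
#' @export
model_envelope <- function(model_map, level = 0.1) {
  v <- model_map$values
  env <- v > level * max(v)
  dilate1(env)
}

# 6-neighbour dilation by one voxel
dilate1 <- function(mask) {
  d <- dim(mask)
  out <- mask
  out[-1, , ] <- out[-1, , ] | mask[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | mask[-1, , ]
  out[, -1, ] <- out[, -1, ] | mask[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | mask[, -1, ]
  out[, , -1] <- out[, , -1] | mask[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | mask[, , -1]
  out
}

#' Difference map: experimental minus scaled model density
#'
#' Both maps are low-passed to a common resolution (default 7 Angstrom:
#' coarse enough that partially occupied, flexible surface glycans become
#' visible as coherent extra density), the model map is scaled to the
#' experimental one by least squares inside the model envelope, and
#' subtracted.
#'
#' @param exp_map experimental (or simulated "experimental") map.
#' @param model_map map rendered from the atomic model.
#' @param resolution common filter resolution in Angstrom (default 7).
#' The model is scaled to the experimental map by least squares over the
#' model core (voxels above half the model-map maximum) so that peripheral
#' unmodelled density cannot bias the scale; the reported `envelope`
#' (model above 10 percent of max, dilated one voxel) is the
#' inside/outside classifier used downstream.
#'
#' @return a `difference_map`: a [density_map()] whose values are
#'   exp - alpha * model, with fields `scale_factor`, `filter_resolution`
#'   and `envelope` (logical array).
#' @export
difference_map <- function(exp_map, model_map, resolution = 7) {
  check_same_grid(exp_map, model_map)
  e <- lowpass(exp_map, resolution)
  m <- lowpass(model_map, resolution)
  env <- model_envelope(m)
  # scale on the model core (> 50% of max): peripheral unmodelled density
  # (the signal we are after) must not leak into the scale factor
  alpha <- scale_to(m, e, m$values > 0.5 * max(m$values))
  out <- density_map(e$values - alpha * m$values, e$voxel, e$origin)
  out$scale_factor <- alpha
  out$filter_resolution <- resolution
  out$envelope <- env
  class(out) <- c("difference_map", class(out))
  out
}

# robust sigma of a difference map: 1.4826 * MAD, falling back to the
# ordinary SD for noiseless maps whose median deviation is exactly zero
robust_sigma <- function(x) {
  s <- stats::mad(x, center = stats::median(x))
  if (s == 0) s <- stats::sd(x)
  s
}

#' Fraction of extra (unmodelled) density at display thresholds
#'
#' For each threshold k, the fraction of all voxels that lie above
#' k * sigma of the difference map AND outside the model envelope — the
#' quantitative counterpart of displaying unmodelled density at several
#' contour levels. sigma is robust (1.4826 * MAD).
#'
#' @param diff a [difference_map()] (or any [density_map()]).
#' @param envelope logical array; defaults to the difference map's own.
#' @param thresholds multiples of sigma (default 3, 5, 8).
#' @return data.frame (`threshold`, `fraction`).
#' @export
extra_density_fraction <- function(diff, envelope = NULL,
                                   thresholds = c(3, 5, 8)) {
  stopifnot(all(thresholds > 0))
  if (is.null(envelope)) envelope <- diff$envelope
  stopifnot(!is.null(envelope))
  v <- diff$values
  s <- robust_sigma(v)
  frac <- vapply(thresholds, function(k) {
    if (s == 0) return(0)
    sum(v > k * s & !envelope) / length(v)
  }, numeric(1))
  data.frame(threshold = thresholds, fraction = frac)
}

#' Cylindrical radial density profile
#'
#' Mean density in annular bins of helical radius about the filament
#' (z) axis.
#'
#' @param map a [density_map()], axis along z at x = y = 0.
#' @param bin bin width in Angstrom.
#' @return data.frame (`radius` = bin midpoint, `mean_density`).
#' @export
radial_profile <- function(map, bin = 1) {
  stopifnot(bin > 0)
  xs <- map_axis(map, 1); ys <- map_axis(map, 2)
  d <- dim(map$values)
  r <- sqrt(outer(xs^2, ys^2, `+`))
  rall <- rep(as.numeric(r), times = d[3])
  idx <- floor(rall / bin)
  means <- tapply(as.numeric(map$values), idx, mean)
  ib <- as.numeric(names(means))
  data.frame(radius = (ib + 0.5) * bin, mean_density = as.numeric(means))
}

#' Call putative glycosylation sites from a difference map
#'
#' Local maxima of the difference map above `min_peak` * sigma are
#' assigned to the nearest model residue within `max_dist` Angstrom; one
#' call per (chain, residue), keeping the strongest peak. Peaks with no
#' residue in range are reported in the `unassigned` attribute.
#'
#' @param diff a [difference_map()] on the model's coordinate frame.
#' @param model a `filament_model` (glycan sites, if present, are ignored
#'   for assignment — calls are made against protein residues).
#' @param min_peak peak threshold in robust-sigma units (default 5).
#' @param max_dist maximum peak-to-residue distance (Angstrom, default 6,
#'   accommodating glycan density one sugar ring away from the Calpha).
#' @param min_frac absolute floor on peaks as a fraction of the
#'   difference-map maximum (default 0.25). On (near-)noiseless maps the
#'   robust sigma collapses towards zero and filter-ripple maxima would
#'   otherwise be called; on noisy maps with peaks above ~5 sigma the
#'   floor sits below the sigma threshold and is inert.
#' @return data.frame (`chain`, `resno`, `peak_value`, `distance`), sorted
#'   by decreasing peak value; attribute `unassigned` is a data.frame of
#'   orphan peaks.
#' @export
call_glyco_sites <- function(diff, model, min_peak = 5, max_dist = 6,
                             min_frac = 0.25) {
  v <- diff$values
  s <- robust_sigma(v)
  thr <- max(min_peak * s, min_frac * max(v))
  pk <- local_maxima3(v, thr)
  if (nrow(pk) == 0) {
    out <- data.frame(chain = integer(0), resno = integer(0),
                      peak_value = numeric(0), distance = numeric(0))
    attr(out, "unassigned") <- pk
    return(out)
  }
  # sub-voxel peak localization: 3-point parabolic fit per axis
  sub <- vapply(seq_len(nrow(pk)), function(r) {
    refine_peak(v, pk$i[r], pk$j[r], pk$k[r])
  }, numeric(3))
  pk$x <- diff$origin[1] + (sub[1, ] - 1) * diff$voxel
  pk$y <- diff$origin[2] + (sub[2, ] - 1) * diff$voxel
  pk$z <- diff$origin[3] + (sub[3, ] - 1) * diff$voxel
  prot <- model$sites[model$sites$role != "glycan", ]
  nn <- vapply(seq_len(nrow(pk)), function(i) {
    d2 <- (prot$x - pk$x[i])^2 + (prot$y - pk$y[i])^2 + (prot$z - pk$z[i])^2
    j <- which.min(d2)
    c(j, sqrt(d2[j]))
  }, numeric(2))
  pk$site <- nn[1, ]; pk$distance <- nn[2, ]
  ok <- pk$distance <= max_dist
  unas <- pk[!ok, c("x", "y", "z", "value", "distance")]
  pk <- pk[ok, , drop = FALSE]
  if (nrow(pk) > 0) {
    pk$chain <- prot$chain[pk$site]
    pk$resno <- prot$resno[pk$site]
    # one call per residue: keep the strongest peak
    pk <- pk[order(-pk$value), ]
    pk <- pk[!duplicated(pk[, c("chain", "resno")]), ]
    out <- data.frame(chain = pk$chain, resno = pk$resno,
                      peak_value = pk$value, distance = pk$distance)
  } else {
    out <- data.frame(chain = integer(0), resno = integer(0),
                      peak_value = numeric(0), distance = numeric(0))
  }
  rownames(out) <- NULL
  attr(out, "unassigned") <- unas
  out
}

# parabolic sub-voxel refinement of a local maximum (fractional indices)
refine_peak <- function(v, i, j, k) {
  para <- function(a, b, c) {
    den <- a - 2 * b + c
    if (den >= 0) return(0)           # not a strict quadratic maximum
    max(-0.5, min(0.5, 0.5 * (a - c) / den))
  }
  c(i + para(v[i - 1, j, k], v[i, j, k], v[i + 1, j, k]),
    j + para(v[i, j - 1, k], v[i, j, k], v[i, j + 1, k]),
    k + para(v[i, j, k - 1], v[i, j, k], v[i, j, k + 1]))
}

# strict 26-neighbourhood local maxima above a threshold (interior voxels)
local_maxima3 <- function(v, thr) {
  d <- dim(v)
  cand <- which(v > thr)
  if (length(cand) == 0)
    return(data.frame(i = integer(0), j = integer(0), k = integer(0),
                      value = numeric(0)))
  ijk <- arrayInd(cand, d)
  interior <- ijk[, 1] > 1 & ijk[, 1] < d[1] &
    ijk[, 2] > 1 & ijk[, 2] < d[2] &
    ijk[, 3] > 1 & ijk[, 3] < d[3]
  ijk <- ijk[interior, , drop = FALSE]
  if (nrow(ijk) == 0)
    return(data.frame(i = integer(0), j = integer(0), k = integer(0),
                      value = numeric(0)))
  keep <- logical(nrow(ijk))
  for (r in seq_len(nrow(ijk))) {
    i <- ijk[r, 1]; j <- ijk[r, 2]; k <- ijk[r, 3]
    nb <- v[(i - 1):(i + 1), (j - 1):(j + 1), (k - 1):(k + 1)]
    keep[r] <- v[i, j, k] >= max(nb)
  }
  ijk <- ijk[keep, , drop = FALSE]
  data.frame(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
             value = v[ijk])
}
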