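#' Toy two-domain pilin monomer
#'
#' Builds a coarse-grained (one pseudo-atom per residue, Calpha-like) model
#' of an archaeal type IV pilin: an N-terminal alpha-helical tail (ideal
#' helix: 1.5 Angstrom rise/residue, 2.3 Angstrom helix radius, 100
#' deg/residue) running parallel to the future filament axis at
#' `radial_offset` from it, plus a globular domain of the remaining
#' residues placed (seeded, reproducibly) inside a ball of radius
#' `globular_radius` centred radially outward of the helix. Assembled
#' filaments from the defaults are ~80 Angstrom in outer diameter.
#'
#' @param n_residues total residues (default 135).
#' @param helix_len residues in the N-terminal helix (default 35).
#' @param globular_radius radius (Angstrom) of the globular-domain ball.
#' @param radial_offset distance (Angstrom) of the helix axis from the
#'   filament axis.
#' @param seed integer seed for the globular-domain placement; the global
#'   RNG state is left untouched.
#' @return a `pilin_model` with `sites` (data.frame x, y, z, weight, chain,
#'   resno, role), `n_residues`, `helix_range`, `radial_offset`.
#' @export
make_toy_pilin <- function(n_residues = 135, helix_len = 35,
                           globular_radius = 14, radial_offset = 8,
                           seed = 1) {
  stopifnot(n_residues >= 1)
  if (helix_len > n_residues) stop("'helix_len' must be <= 'n_residues'")
  i <- seq_len(helix_len)
  ang <- deg2rad((i - 1) * 100)
  hx <- radial_offset + 2.3 * cos(ang)
  hy <- 2.3 * sin(ang)
  hz <- (i - 1) * 1.5
  n_glob <- n_residues - helix_len
  if (n_glob > 0) {
    centre <- c(radial_offset + 2.3 + globular_radius + 6, 0,
                max(hz) * 0.6)
    # uniform in the ball but with a hard-core minimum spacing, as real
    # Calpha positions have (~4 Angstrom); plain uniform sampling gives
    # unphysically close pairs
    min_spacing <- min(4, 1.2 * globular_radius * n_glob^(-1 / 3))
    pts <- with_seed(seed, {
      acc <- matrix(numeric(0), ncol = 3)
      tries <- 0L
      while (nrow(acc) < n_glob && tries < 200000L) {
        cand <- stats::runif(3, -1, 1)
        tries <- tries + 1L
        if (sum(cand^2) > 1) next
        if (nrow(acc) > 0 &&
            min(sqrt(colSums((t(acc) - cand)^2))) * globular_radius <
              min_spacing) next
        acc <- rbind(acc, cand)
      }
      if (nrow(acc) < n_glob)
        stop("could not place globular residues at the required spacing; ",
             "increase 'globular_radius'")
      acc
    })
    gx <- centre[1] + globular_radius * pts[, 1]
    gy <- centre[2] + globular_radius * pts[, 2]
    gz <- centre[3] + globular_radius * pts[, 3]
  } else {
    gx <- gy <- gz <- numeric(0)
  }
  sites <- data.frame(
    x = c(hx, gx), y = c(hy, gy), z = c(hz, gz),
    weight = 1,
    chain = 0L,
    resno = seq_len(n_residues),
    role = c(rep("helix", helix_len), rep("globular", n_glob)),
    stringsAsFactors = FALSE)
  structure(list(sites = sites, n_residues = as.integer(n_residues),
                 helix_range = c(1L, as.integer(helix_len)),
                 radial_offset = radial_offset),
            class = "pilin_model")
}

#' Add glycan pseudo-atoms to a pilin monomer
#'
#' Places one glycan-role site per listed residue, `offset` Angstrom
#' radially outward (from the filament axis, in the xy plane) of that
#' residue's site. Only globular-domain residues may carry glycans.
#'
#' @param monomer a [make_toy_pilin()] model.
#' @param residues residue indices to decorate.
#' @param offset radial displacement in Angstrom (default 5, roughly the
#'   first sugar ring's distance from the modified side chain's Calpha).
#' @param weight scattering weight of each glycan site. Default 3 (three
#'   residue-equivalents): the real glycan mass is unknown, this is an
#'   arbitrary but documented stand-in.
#' @return the monomer with glycan sites appended; original sites unchanged.
#' @export
decorate_glycans <- function(monomer, residues, offset = 5, weight = 3) {
  stopifnot(inherits(monomer, "pilin_model"))
  if (length(residues) == 0) return(monomer)
  residues <- as.integer(residues)
  if (any(residues < 1 | residues > monomer$n_residues))
    stop("glycan residue outside the monomer")
  if (any(residues <= monomer$helix_range[2]))
    stop("glycans may only decorate globular-domain residues")
  s <- monomer$sites
  idx <- match(residues, s$resno[s$role != "glycan"])
  base <- s[s$role != "glycan", ][idx, ]
  r <- sqrt(base$x^2 + base$y^2)
  scale <- (r + offset) / r
  gly <- data.frame(x = base$x * scale, y = base$y * scale, z = base$z,
                    weight = weight, chain = base$chain, resno = base$resno,
                    role = "glycan", stringsAsFactors = FALSE)
  monomer$sites <- rbind(s, gly)
  monomer
}

#' Most radially exposed globular residues of a monomer
#'
#' Glycosylation is observed on surface-exposed residues; when planting
#' synthetic glycans, picking the outermost globular residues mimics that
#' and keeps the glycan density clear of other protein mass.
#'
#' @param monomer a [make_toy_pilin()] model.
#' @param n number of residues to return.
#' @param min_separation minimum pairwise distance (Angstrom) between the
#'   returned residues (default 8): sites closer than the effective blur of a
#'   typical difference analysis would merge into one density peak.
#' @param glycan_offset radial offset (Angstrom) at which a glycan would be
#'   placed; a residue is only eligible if no other residue sits within
#'   `glycan_offset + 0.5` of that point, so that a glycan's density peak is
#'   unambiguously nearest to its own residue.
#' @return integer residue indices, sorted; greedily the most radially
#'   distant globular residues subject to the constraints.
#' @export
surface_residues <- function(monomer, n = 7, min_separation = 8,
                             glycan_offset = 5) {
  s <- monomer$sites[monomer$sites$role == "globular", ]
  if (nrow(s) < n) stop("fewer globular residues than requested")
  s <- s[order(-sqrt(s$x^2 + s$y^2)), ]
  r <- sqrt(s$x^2 + s$y^2)
  gx <- s$x * (r + glycan_offset) / r
  gy <- s$y * (r + glycan_offset) / r
  picked <- integer(0)
  for (i in seq_len(nrow(s))) {
    if (length(picked) == n) break
    # exposure: every other residue farther than offset + 0.5 from the
    # would-be glycan position
    d_gly <- sqrt((s$x - gx[i])^2 + (s$y - gy[i])^2 + (s$z - s$z[i])^2)
    if (any(d_gly[-i] <= glycan_offset + 0.5)) next
    if (length(picked) > 0) {
      dmin <- min(sqrt((s$x[picked] - s$x[i])^2 + (s$y[picked] - s$y[i])^2 +
                       (s$z[picked] - s$z[i])^2))
      if (dmin < min_separation) next
    }
    picked <- c(picked, i)
  }
  if (length(picked) < n)
    stop("cannot pick ", n, " exposed residues at >= ", min_separation,
         " Angstrom separation")
  sort(s$resno[picked])
}

#' Build a matched glycosylated/control filament pair
#'
#' Convenience constructor for difference-density studies: a toy monomer,
#' `n_glycans` surface sites, and the decorated and undecorated filaments.
#' Not every random globular domain can host the requested number of
#' well-separated exposed sites; monomer seeds `seed`, `seed + 1`, ... are
#' tried (deterministically) until one can.
#'
#' @param seed base seed.
#' @param sym a [helical_symmetry()] (default the 5.26 Angstrom / 101.69
#'   degree lattice).
#' @param n_subunits subunits per filament (default 9).
#' @param n_glycans surface glycans per subunit (default 7).
#' @param max_tries monomer seeds attempted before giving up.
#' @return list with `monomer`, `glycan_residues`, `filament` (control),
#'   `filament_glyco` (decorated), and `seed_used`.
#' @export
make_glyco_fixture <- function(seed = 1, sym = helical_symmetry(5.26, 101.69),
                               n_subunits = 9, n_glycans = 7,
                               max_tries = 25) {
  for (s in seed + seq_len(max_tries) - 1L) {
    mono <- tryCatch(make_toy_pilin(seed = s), error = function(e) NULL)
    if (is.null(mono)) next
    gly <- tryCatch(surface_residues(mono, n_glycans),
                    error = function(e) NULL)
    if (is.null(gly)) next
    return(list(monomer = mono, glycan_residues = gly,
                filament = build_filament(mono, sym, n_subunits),
                filament_glyco = build_filament(
                  decorate_glycans(mono, gly), sym, n_subunits),
                seed_used = s))
  }
  stop("no viable monomer found in ", max_tries, " attempts")
}

#' Assemble a filament from a monomer and a helical symmetry
#'
#' Chain k (k = 0 .. n_subunits-1) is the monomer rotated by k * twist
#' about the z axis and translated by k * rise along z. The filament axis
#' is +z with the helical origin at chain 0.
#'
#' @param monomer a [make_toy_pilin()] model.
#' @param sym a [helical_symmetry()].
#' @param n_subunits number of subunits (>= 1).
#' @return a `filament_model` with expanded `sites`, the `symmetry`, the
#'   `monomer` and `outer_diameter` (2 x max radial site distance, Angstrom).
#' @export
build_filament <- function(monomer, sym, n_subunits = 30) {
  stopifnot(inherits(monomer, "pilin_model"))
  sym <- as_helical_symmetry(sym)
  if (!is.numeric(n_subunits) || n_subunits < 1)
    stop("'n_subunits' must be >= 1")
  n_subunits <- as.integer(n_subunits)
  s0 <- monomer$sites
  all <- vector("list", n_subunits)
  for (k in seq_len(n_subunits) - 1L) {
    a <- deg2rad(k * sym$twist)
    sk <- s0
    sk$x <- s0$x * cos(a) - s0$y * sin(a)
    sk$y <- s0$x * sin(a) + s0$y * cos(a)
    sk$z <- s0$z + k * sym$rise
    sk$chain <- k
    all[[k + 1L]] <- sk
  }
  sites <- do.call(rbind, all)
  structure(list(monomer = monomer, symmetry = sym,
                 n_subunits = n_subunits, sites = sites,
                 outer_diameter = 2 * max(sqrt(sites$x^2 + sites$y^2))),
            class = "filament_model")
}

#' @export
print.filament_model <- function(x, ...) {
  cat(sprintf("filament: %d subunits, rise %.4g / twist %.6g, outer diameter %.3g Angstrom\n",
              x$n_subunits, x$symmetry$rise, x$symmetry$twist,
              x$outer_diameter))
  invisible(x)
}

#' Density map container
#'
#' A 3-D scalar field on a regular isotropic grid. Voxel (i, j, k)
#' (1-based) is centred at `origin + (i-1, j-1, k-1) * voxel` Angstrom;
#' the filament axis convention is along z.
#'
#' @param values 3-D numeric array.
#' @param voxel isotropic voxel size in Angstrom (> 0).
#' @param origin Angstrom coordinates of the centre of voxel (1,1,1).
#' @return a `density_map`.
#' @export
density_map <- function(values, voxel, origin = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3,
            all(dim(values) >= 2), is.numeric(voxel), voxel > 0,
            length(origin) == 3)
  structure(list(values = values, voxel = voxel, origin = as.numeric(origin)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("density map: %d x %d x %d voxels at %.4g Angstrom/voxel\n",
              d[1], d[2], d[3], x$voxel))
  invisible(x)
}

# voxel-centre coordinates along each axis
map_axis <- function(map, axis) {
  n <- dim(map$values)[axis]
  map$origin[axis] + (seq_len(n) - 1) * map$voxel
}

#' Rasterize a model to a density map
#'
#' Renders each pseudo-atom as an isotropic 3-D Gaussian of width
#' sigma = resolution / (2 * pi * sqrt(2)) (so that the rendered map is
#' approximately band-limited at 1/resolution), normalised so the map
#' integral (sum x voxel^3) equals the summed site weights.
#'
#' @param model a `filament_model` or `pilin_model`.
#' @param voxel grid step in Angstrom (default 1.08, a typical physical
#'   pixel size for modern direct detectors).
#' @param resolution nominal resolution in Angstrom (>= 2 * voxel);
#'   default 7, the scale used for model-vs-map difference analysis.
#' @param box integer grid dimensions (nx, ny, nz); `NULL` fits the model
#'   with 4 sigma + 3 voxel padding, centred on the filament axis (x=y=0).
#' @param like a [density_map()] whose grid (dims, voxel, origin) to reuse,
#'   guaranteeing voxel-exact comparability (e.g. for difference maps);
#'   overrides `voxel` and `box`.
#' @return a [density_map()]. Attribute `clipped` counts atoms whose
#'   centre fell outside the box (rendered contributions are clipped; a
#'   warning is raised when any are).
#' @export
rasterize <- function(model, voxel = 1.08, resolution = 7, box = NULL,
                      like = NULL) {
  if (!is.null(like)) {
    stopifnot(inherits(like, "density_map"))
    voxel <- like$voxel
  }
  stopifnot(voxel > 0)
  if (resolution < 2 * voxel)
    stop("'resolution' must be >= 2 * voxel (Nyquist)")
  sites <- model$sites
  sigma <- resolution / (2 * pi * sqrt(2))
  pad <- 4 * sigma + 3 * voxel
  if (!is.null(like)) {
    dims <- dim(like$values)
    origin <- like$origin
  } else if (is.null(box)) {
    if (nrow(sites) == 0) stop("cannot auto-size a box for an empty model")
    half_xy <- max(abs(c(sites$x, sites$y))) + pad
    nxy <- 2L * as.integer(ceiling(half_xy / voxel)) + 1L
    zlo <- min(sites$z) - pad; zhi <- max(sites$z) + pad
    nz <- as.integer(ceiling((zhi - zlo) / voxel)) + 1L
    origin <- c(-((nxy - 1) / 2) * voxel, -((nxy - 1) / 2) * voxel, zlo)
    dims <- c(nxy, nxy, nz)
  } else {
    dims <- as.integer(box)
    stopifnot(length(dims) == 3, all(dims >= 2))
    origin <- c(-((dims[1] - 1) / 2) * voxel, -((dims[2] - 1) / 2) * voxel,
                if (nrow(sites) > 0)
                  mean(range(sites$z)) - ((dims[3] - 1) / 2) * voxel
                else -((dims[3] - 1) / 2) * voxel)
  }
  vals <- array(0, dim = dims)
  clipped <- 0L
  if (nrow(sites) > 0) {
    hw <- ceiling(4 * sigma / voxel)  # kernel half-width in voxels
    for (a in seq_len(nrow(sites))) {
      p <- c(sites$x[a], sites$y[a], sites$z[a])
      ci <- (p - origin) / voxel + 1  # fractional voxel index of the atom
      if (any(ci < 1) || any(ci > dims)) clipped <- clipped + 1L
      i0 <- pmax(1L, floor(ci) - hw); i1 <- pmin(dims, ceiling(ci) + hw)
      if (any(i0 > i1)) next
      ix <- i0[1]:i1[1]; iy <- i0[2]:i1[2]; iz <- i0[3]:i1[3]
      kx <- stats::dnorm((ix - ci[1]) * voxel, sd = sigma)
      ky <- stats::dnorm((iy - ci[2]) * voxel, sd = sigma)
      kz <- stats::dnorm((iz - ci[3]) * voxel, sd = sigma)
      # as.vector: keep elementwise addition valid when an index has length 1
      vals[ix, iy, iz] <- vals[ix, iy, iz] +
        as.vector(sites$weight[a] * (kx %o% ky %o% kz))
    }
  }
  if (clipped > 0)
    warning(sprintf("%d atom(s) outside the box were clipped", clipped))
  out <- density_map(vals, voxel, origin)
  attr(out, "clipped") <- clipped
  out
}

#' Project a map and compute its power spectrum
#'
#' Sums the map along the x (transverse) axis to a 2-D projection, then
#' takes the squared magnitude of its 2-D Fourier transform. Rows of the
#' spectrum index axial (z) frequency, columns transverse (y, "radial")
#' frequency; element (1,1) is the zero-frequency term (unshifted layout).
#'
#' @param map a [density_map()] with the filament axis along z.
#' @param window apodization along z before the transform: "hann"
#'   (default) confines spectral leakage of the strong equator to the
#'   immediately adjacent rows (a periodic Hann window is exactly zero at
#'   all other integer frequency bins), or "none".
#' @return a `filament_spectrum`: `projection` (matrix y x z, unwindowed),
#'   `power` (matrix nz x ny), `axial_step` and `radial_step` (1/Angstrom
#'   per index).
#' @export
project_and_spectrum <- function(map, window = c("hann", "none")) {
  stopifnot(inherits(map, "density_map"))
  window <- match.arg(window)
  proj <- apply(map$values, c(2, 3), sum)  # ny x nz
  pz <- t(proj)                            # nz x ny
  if (window == "hann") {
    nz <- nrow(pz)
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nz) - 1) / nz)
    pz <- pz * w
  }
  pw <- Mod(stats::fft(pz))^2              # rows = axial frequency
  structure(list(projection = proj, power = pw,
                 axial_step = 1 / (ncol(proj) * map$voxel),
                 radial_step = 1 / (nrow(proj) * map$voxel)),
            class = "filament_spectrum")
}

#' Add seeded Gaussian noise
#'
#' @param x a [density_map()], matrix or array.
#' @param sigma noise standard deviation (>= 0); 0 returns the input.
#' @param seed integer seed (global RNG state is restored).
#' @return same type as `x`.
#' @export
add_noise <- function(x, sigma, seed = 1) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(x)
  if (inherits(x, "density_map")) {
    x$values <- x$values +
      with_seed(seed, array(stats::rnorm(length(x$values), 0, sigma),
                            dim = dim(x$values)))
    return(x)
  }
  x + with_seed(seed, array(stats::rnorm(length(x), 0, sigma),
                            dim = dim(as.array(x))))
}

#' Self-correlation under the helical symmetry operation
#'
#' Resamples the map at coordinates rotated by `twist` about z and shifted
#' down by `rise` (trilinear interpolation) and correlates with the
#' original over an interior mask (radius within the filament, central z
#' half, away from box faces). For a noiseless rasterized filament this
#' should be ~1.
#'
#' @param map a [density_map()].
#' @param sym the [helical_symmetry()] used to build it.
#' @param r_max radial extent of the mask (Angstrom); default from map size.
#' @return Pearson correlation (scalar).
#' @export
helical_self_correlation <- function(map, sym, r_max = NULL) {
  sym <- as_helical_symmetry(sym)
  d <- dim(map$values)
  xs <- map_axis(map, 1); ys <- map_axis(map, 2); zs <- map_axis(map, 3)
  if (is.null(r_max)) r_max <- 0.75 * min(max(abs(xs)), max(abs(ys)))
  zq <- range(zs) + c(0.3, -0.3) * diff(range(zs))
  g <- expand.grid(x = xs, y = ys, z = zs)
  mask <- sqrt(g$x^2 + g$y^2) <= r_max & g$z >= zq[1] & g$z <= zq[2]
  a <- -deg2rad(sym$twist)  # inverse rotation: sample where density came from
  gx <- g$x[mask] * cos(a) - g$y[mask] * sin(a)
  gy <- g$x[mask] * sin(a) + g$y[mask] * cos(a)
  gz <- g$z[mask] - sym$rise
  v1 <- map$values[mask]
  v2 <- trilinear(map, gx, gy, gz)
  ok <- !is.na(v2)
  stats::cor(v1[ok], v2[ok])
}

# trilinear interpolation of a density_map at arbitrary Angstrom coords;
# NA outside the grid
trilinear <- function(map, x, y, z) {
  d <- dim(map$values)
  fx <- (x - map$origin[1]) / map$voxel + 1
  fy <- (y - map$origin[2]) / map$voxel + 1
  fz <- (z - map$origin[3]) / map$voxel + 1
  out <- rep(NA_real_, length(fx))
  ok <- fx >= 1 & fx <= d[1] & fy >= 1 & fy <= d[2] & fz >= 1 & fz <= d[3]
  if (!any(ok)) return(out)
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  x0 <- pmin(floor(fx), d[1] - 1); y0 <- pmin(floor(fy), d[2] - 1)
  z0 <- pmin(floor(fz), d[3] - 1)
  tx <- fx - x0; ty <- fy - y0; tz <- fz - z0
  v <- map$values
  idx <- function(i, j, k) v[cbind(i, j, k)]
  val <-
    idx(x0,     y0,     z0)     * (1 - tx) * (1 - ty) * (1 - tz) +
    idx(x0 + 1, y0,     z0)     * tx       * (1 - ty) * (1 - tz) +
    idx(x0,     y0 + 1, z0)     * (1 - tx) * ty       * (1 - tz) +
    idx(x0,     y0,     z0 + 1) * (1 - tx) * (1 - ty) * tz       +
    idx(x0 + 1, y0 + 1, z0)     * tx       * ty       * (1 - tz) +
    idx(x0 + 1, y0,     z0 + 1) * tx       * (1 - ty) * tz       +
    idx(x0,     y0 + 1, z0 + 1) * (1 - tx) * ty       * tz       +
    idx(x0 + 1, y0 + 1, z0 + 1) * tx       * ty       * tz
  out[ok] <- val
  out
}
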