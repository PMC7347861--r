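#' Detect layer lines in a filament power spectrum
#'
#' A helical filament's power spectrum is non-zero only on layer lines:
#' rows of constant axial frequency. Rows whose integrated power exceeds
#' `min_snr` times a robust background (the median row power over positive
#' axial frequencies) are grouped into contiguous runs; each run yields one
#' layer line with a power-weighted centroid height, the radial frequency
#' of the first intensity maximum of its strongest row, and that row's
#' power as intensity. The equator (height 0) is excluded.
#'
#' @param spec a `filament_spectrum` from [project_and_spectrum()], or a
#'   list with `power`, `axial_step`, `radial_step`.
#' @param min_snr detection threshold as a multiple of the background.
#' @return data.frame (`height`, `peak_radius` in 1/Angstrom, `intensity`);
#'   zero rows when nothing exceeds the threshold.
#' @export
detect_layer_lines <- function(spec, min_snr = 5) {
  stopifnot(min_snr > 0)
  pw <- spec$power
  nz <- nrow(pw); ny <- ncol(pw)
  # positive axial frequencies; drop the equator and the bin next to it
  # (with a Hann window the equator leaks exactly one bin out)
  rows <- 3:floor(nz / 2)
  half <- pw[, 1:floor(ny / 2), drop = FALSE]
  # fold the two radial half-planes (real input: inversion symmetric)
  fold <- half
  fold[, 2:ncol(half)] <- (half[, 2:ncol(half)] +
                           pw[, ny:(ny - ncol(half) + 2)]) / 2
  rp <- rowSums(fold)[rows]
  bg <- stats::median(rp)
  if (bg <= 0) return(empty_lines())
  above <- rp > min_snr * bg
  if (!any(above)) return(empty_lines())
  runs <- split(which(above), cumsum(c(1, diff(which(above)) != 1)))
  out <- lapply(runs, function(ii) {
    rr <- rows[ii]
    w <- rp[ii]
    # centroid over rows within 2 bins of the run maximum (avoids skew
    # when a weak neighbouring line merges into the same run)
    near <- abs(rr - rr[which.max(w)]) <= 2
    height <- sum((rr[near] - 1) * w[near]) / sum(w[near]) * spec$axial_step
    prof <- fold[rr[which.max(w)], ]
    pk <- first_local_max(prof)
    data.frame(height = height,
               peak_radius = (pk - 1) * spec$radial_step,
               intensity = max(w))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$height), ]
}

empty_lines <- function() {
  data.frame(height = numeric(0), peak_radius = numeric(0),
             intensity = numeric(0))
}

# index of the first local maximum of a (lightly smoothed) radial profile
first_local_max <- function(v) {
  if (length(v) >= 5) {
    s <- stats::filter(v, rep(1 / 3, 3), sides = 2)
    s[is.na(s)] <- v[is.na(s)]
    v <- as.numeric(s)
  }
  for (i in seq_along(v)) {
    left_ok <- i == 1 || v[i] >= v[i - 1]
    right_ok <- i == length(v) || v[i] > v[i + 1]
    if (left_ok && right_ok) return(i)
  }
  which.max(v)
}

#' Bessel-order magnitude interval from a layer line's first maximum
#'
#' The first intensity maximum of the Bessel function J_n falls near
#' x = |n| + 2 for moderate n, so a layer line peaking at radial frequency
#' r on a filament of radius R suggests |n| ~ 2*pi*R*r - 2. Returns that
#' centre estimate +/- `slack`, floored at 0.
#'
#' @param peak_radius radial frequency of the first maximum (1/Angstrom).
#' @param filament_radius filament radius R (Angstrom).
#' @param slack half-width of the returned interval (default 1).
#' @return integer vector `c(lo, hi)`.
#' @export
estimate_order_magnitude <- function(peak_radius, filament_radius, slack = 1) {
  stopifnot(peak_radius >= 0, filament_radius > 0, slack >= 0)
  centre <- max(0, round(2 * pi * filament_radius * peak_radius - 2))
  c(max(0L, as.integer(centre - slack)), as.integer(centre + slack))
}

#' Layer lines predicted by a helical symmetry
#'
#' Heights follow Z(n, m) = n * twist / (360 * rise) + m / rise for Bessel
#' order n and meridional harmonic m (equivalently the selection rule
#' l = t n + u m on the (u, t) lattice); peak radii invert the
#' first-maximum heuristic, r = (|n| + 2) / (2 pi R).
#'
#' @param sym a [helical_symmetry()].
#' @param filament_radius filament radius R (Angstrom).
#' @param n_max maximum |n|.
#' @param height_max maximum height returned (1/Angstrom).
#' @return data.frame (`height`, `peak_radius`, `n`, `m`), heights
#'   deduplicated keeping the smallest |n|, sorted by height; the equator
#'   (n = 0, m = 0) is excluded. For each order the full range of
#'   harmonics m with 0 <= Z <= height_max is enumerated.
#' @export
predicted_layer_lines <- function(sym, filament_radius, n_max, height_max) {
  sym <- as_helical_symmetry(sym)
  per_n <- lapply(seq.int(-n_max, n_max), function(n) {
    zn <- n * sym$twist / (360 * sym$rise)
    m <- seq.int(ceiling((0 - zn) * sym$rise), floor((height_max - zn) * sym$rise))
    if (length(m) == 0) return(NULL)
    data.frame(n = n, m = m)
  })
  g <- do.call(rbind, per_n)
  g <- g[!(g$n == 0 & g$m == 0), ]
  z <- g$n * sym$twist / (360 * sym$rise) + g$m / sym$rise
  keep <- z >= 0 & z <= height_max
  g <- g[keep, ]; z <- z[keep]
  o <- order(z, abs(g$n))
  g <- g[o, ]; z <- z[o]
  # dedupe near-identical heights, keeping the lowest |n|
  dup <- c(FALSE, diff(z) < 1e-9)
  g <- g[!dup, ]; z <- z[!dup]
  data.frame(height = z,
             peak_radius = (abs(g$n) + 2) / (2 * pi * filament_radius),
             n = g$n, m = g$m)
}

#' Enumerate helical symmetries consistent with observed layer lines
#'
#' The indexing ambiguity at the heart of helical reconstruction: many
#' (rise, twist) pairs can predict the same set of layer-line heights.
#' The rise is fixed by a meridional (n = 0) line at height 1/rise; every
#' line whose first maximum lies close enough to the meridian (Bessel
#' argument 2 pi R r below 2.5 — J1 already peaks at 1.84) is tried as a
#' rise hypothesis, wrong ones being eliminated by the scoring stage. For
#' each line of height Z, each Bessel order n compatible with its
#' first-maximum interval, and each harmonic |m| <= m_max, the twist
#' hypothesis 360 * (Z * rise - m) / n is scored by forward-predicting all
#' layer lines (orders up to `score_n_max`) and requiring every observed
#' line to match a prediction within `tol`. Because a single projection
#' cannot fix handedness, candidates are emitted in +/- twist pairs unless
#' `mirror = FALSE`.
#'
#' @param lines data.frame from [detect_layer_lines()] (or exact lines from
#'   [predicted_layer_lines()]).
#' @param filament_radius filament radius R (Angstrom).
#' @param n_max maximum |n| used to seed twist hypotheses.
#' @param m_max maximum |m| used to seed twist hypotheses.
#' @param tol height matching tolerance (1/Angstrom).
#' @param rise explicit rise (Angstrom), required if no meridional line.
#' @param slack order-interval slack passed to [estimate_order_magnitude()].
#' @param mirror emit both signs of twist (default TRUE).
#' @param score_n_max maximum |n| in the forward model used for scoring;
#'   defaults to 2 * n_max so that genuine high-order lines do not
#'   disqualify a correct low-order candidate.
#' @return data.frame (`rise`, `twist`, `residual`, `n_seed`, `m_seed`),
#'   deduplicated (0.02 Angstrom / 0.1 degree), sorted by residual then
#'   |n_seed| then twist. `twist` is signed; negative values are the
#'   mirror (left-handed 1-start) interpretations.
#' @export
enumerate_symmetries <- function(lines, filament_radius, n_max = 10,
                                 m_max = 2, tol = 0.002, rise = NULL,
                                 slack = 1, mirror = TRUE,
                                 score_n_max = 2 * n_max) {
  stopifnot(n_max >= 1)
  if (nrow(lines) == 0) return(empty_candidates())
  # meridional (n = 0) candidates peak on/near the meridian
  is_merid <- 2 * pi * filament_radius * lines$peak_radius < 2.5
  if (is.null(rise)) {
    if (!any(is_merid))
      stop("rise unconstrained: no meridional line and no explicit rise")
    rises <- 1 / lines$height[is_merid]
  } else {
    rises <- rise
  }
  if (all(is_merid) && is.null(rise)) return(empty_candidates())
  cands <- list()
  for (rise_h in rises) {
    for (i in seq_len(nrow(lines))) {
      Z <- lines$height[i]
      iv <- estimate_order_magnitude(lines$peak_radius[i], filament_radius,
                                     slack)
      orders <- setdiff(seq.int(max(1L, iv[1]), min(iv[2], n_max)), 0L)
      if (length(orders) == 0) next
      for (n_abs in orders) for (sgn in c(1, -1)) {
        for (m in seq.int(-m_max, m_max)) {
          n <- sgn * n_abs
          twist <- 360 * (Z * rise_h - m) / n
          if (!is.finite(twist) || twist <= 0 || twist >= 360) next
          cands[[length(cands) + 1L]] <-
            data.frame(rise = rise_h, twist = twist, n_seed = n, m_seed = m)
        }
      }
    }
  }
  if (length(cands) == 0) return(empty_candidates())
  cands <- do.call(rbind, cands)
  # identical (rise, twist) hypotheses arise from many seeds; score each once,
  # keeping the lowest-|n| seed
  cands <- cands[order(abs(cands$n_seed), abs(cands$m_seed)), ]
  cands <- cands[!duplicated(paste(round(cands$rise, 9),
                                   round(cands$twist, 7))), ]
  # score each hypothesis: every observed line must match a predicted height
  hmax <- max(lines$height) + tol
  keep <- logical(nrow(cands)); resid <- numeric(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    pred <- predicted_layer_lines(
      helical_symmetry(cands$rise[i], cands$twist[i]),
      filament_radius, score_n_max, height_max = hmax)
    d <- vapply(lines$height, function(z) min(abs(z - pred$height)),
                numeric(1))
    keep[i] <- all(d <= tol)
    resid[i] <- mean(d)
  }
  cands$residual <- resid
  cands <- cands[keep, , drop = FALSE]
  if (nrow(cands) == 0) return(empty_candidates())
  cands <- cands[order(cands$residual, abs(cands$n_seed), cands$twist), ]
  # deduplicate: same rise within 0.02 A and twist within 0.1 deg
  sel <- rep(TRUE, nrow(cands))
  for (i in seq_len(nrow(cands))) {
    if (!sel[i]) next
    if (i < nrow(cands)) {
      later <- (i + 1):nrow(cands)
      dup <- abs(cands$twist[later] - cands$twist[i]) < 0.1 &
        abs(cands$rise[later] - cands$rise[i]) < 0.02
      sel[later][dup] <- FALSE
    }
  }
  cands <- cands[sel, , drop = FALSE]
  if (mirror) {
    mirr <- cands
    mirr$twist <- -mirr$twist
    mirr$n_seed <- -mirr$n_seed
    cands <- rbind(cands, mirr)
    cands <- cands[order(cands$residual, abs(cands$n_seed), cands$twist), ]
  }
  rownames(cands) <- NULL
  cands[, c("rise", "twist", "residual", "n_seed", "m_seed")]
}

empty_candidates <- function() {
  data.frame(rise = numeric(0), twist = numeric(0), residual = numeric(0),
             n_seed = integer(0), m_seed = integer(0))
}
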