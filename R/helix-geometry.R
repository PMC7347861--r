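#' Helical symmetry of a one-start filament
#'
#' A filament with C1 point-group symmetry is generated from one subunit by
#' repeated application of a screw operation: a rotation (`twist`, degrees)
#' about the filament axis followed by a translation (`rise`, Angstrom) along
#' it. Positive twist denotes a right-handed 1-start helix; all handedness
#' in this package derives from that sign convention.
#'
#' @param rise axial rise per subunit in Angstrom; must be > 0.
#' @param twist rotation per subunit in degrees, signed; 0 < |twist| <= 360.
#' @param point_group point-group label; only "C1" is supported.
#' @return an object of class `helical_symmetry` with fields `rise`, `twist`,
#'   `point_group`.
#' @examples
#' helical_symmetry(5.26, 101.69)
#' @export
helical_symmetry <- function(rise, twist, point_group = "C1") {
  if (!is.numeric(rise) || length(rise) != 1 || !is.finite(rise) || rise <= 0)
    stop("invalid helical symmetry: 'rise' must be a single positive number")
  if (!is.numeric(twist) || length(twist) != 1 || !is.finite(twist) ||
      twist == 0 || abs(twist) > 360)
    stop("invalid helical symmetry: 'twist' must satisfy 0 < |twist| <= 360")
  if (!identical(point_group, "C1"))
    stop("only point group C1 is supported")
  structure(list(rise = rise, twist = twist, point_group = point_group),
            class = "helical_symmetry")
}

#' @export
print.helical_symmetry <- function(x, ...) {
  cat(sprintf("helical symmetry (%s): rise %.4g Angstrom, twist %.6g deg\n",
              x$point_group, x$rise, x$twist))
  invisible(x)
}

as_helical_symmetry <- function(sym) {
  if (inherits(sym, "helical_symmetry")) return(sym)
  if (is.numeric(sym) && length(sym) == 2)
    return(helical_symmetry(sym[[1]], sym[[2]]))
  stop("expected a helical_symmetry or a (rise, twist) pair")
}

#' Subunits per turn of the 1-start helix
#'
#' @param sym a [helical_symmetry()].
#' @return 360 / |twist|, the (generally irrational) number of subunits in
#'   one full turn.
#' @examples
#' subunits_per_turn(helical_symmetry(5.26, 101.69))  # ~3.54
#' @export
subunits_per_turn <- function(sym) {
  sym <- as_helical_symmetry(sym)
  360 / abs(sym$twist)
}

#' Subunits in a given number of turns
#'
#' The distinction between "slightly more" and "slightly less" than 3.5
#' subunits/turn is what flips the handedness of the dominant 7-start
#' family, so this count (conventionally reported over two turns, one
#' decimal, rounding half away from zero) is diagnostic.
#'
#' @param sym a [helical_symmetry()].
#' @param n_turns positive integer number of turns.
#' @return n_turns * 360 / |twist|.
#' @examples
#' round_half_away(subunits_in_turns(helical_symmetry(5.26, 101.69), 2))  # 7.1
#' @export
subunits_in_turns <- function(sym, n_turns) {
  stopifnot(is.numeric(n_turns), length(n_turns) == 1, n_turns >= 1,
            n_turns == round(n_turns))
  n_turns * subunits_per_turn(sym)
}

#' Pitch of the 1-start helix
#'
#' @param sym a [helical_symmetry()].
#' @return axial distance (Angstrom) per full 360 degree turn:
#'   rise * 360 / |twist|.
#' @export
pitch <- function(sym) {
  sym <- as_helical_symmetry(sym)
  sym$rise * 360 / abs(sym$twist)
}

#' The n-start helix family of a symmetry
#'
#' The n-start family connects every n-th subunit. Its effective twist is
#' n * twist reduced to (-180, 180]; its effective rise is n * rise. The
#' family is right-handed iff the effective twist is strictly positive.
#'
#' @param sym a [helical_symmetry()].
#' @param n positive integer family order.
#' @return a `start_family` list with `n`, `eff_twist` (deg), `eff_rise`
#'   (Angstrom) and `handedness` ("right"/"left").
#' @examples
#' start_family(helical_symmetry(5.26, 101.69), 7)  # -8.17 deg: left-handed
#' @export
start_family <- function(sym, n) {
  sym <- as_helical_symmetry(sym)
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("'n' must be a positive integer")
  eff <- wrap_angle(n * sym$twist)
  structure(list(n = as.integer(n),
                 eff_twist = eff,
                 eff_rise = n * sym$rise,
                 handedness = if (eff > 0) "right" else "left"),
            class = "start_family")
}

#' @export
print.start_family <- function(x, ...) {
  cat(sprintf("%d-start family: eff. twist %.4g deg (%s-handed), eff. rise %.4g Angstrom\n",
              x$n, x$eff_twist, x$handedness, x$eff_rise))
  invisible(x)
}

#' Dominant (long-pitch) start family
#'
#' The visually dominant family of long-pitch helices is the one whose
#' effective twist is closest to zero: its strands run nearly parallel to
#' the filament axis. With ~3.5 subunits/turn this is the 7-start family.
#'
#' @param sym a [helical_symmetry()].
#' @param n_max largest family order searched.
#' @return the [start_family()] with minimal |eff_twist| for n in 1..n_max;
#'   ties broken towards smaller n.
#' @export
dominant_start_family <- function(sym, n_max = 10) {
  stopifnot(n_max >= 1)
  fams <- lapply(seq_len(n_max), function(n) start_family(sym, n))
  abs_tw <- vapply(fams, function(f) abs(f$eff_twist), numeric(1))
  fams[[which.min(abs_tw)]]  # which.min takes the first (smallest n) on ties
}

#' Table of start families
#'
#' @param sym a [helical_symmetry()].
#' @param n_max largest family order.
#' @return data.frame with one row per n in 1..n_max.
#' @export
start_family_table <- function(sym, n_max = 10) {
  fams <- lapply(seq_len(n_max), function(n) start_family(sym, n))
  data.frame(n = vapply(fams, `[[`, integer(1), "n"),
             eff_twist = vapply(fams, `[[`, numeric(1), "eff_twist"),
             eff_rise = vapply(fams, `[[`, numeric(1), "eff_rise"),
             handedness = vapply(fams, `[[`, character(1), "handedness"))
}

#' Helical net (unrolled surface lattice)
#'
#' Unrolls the cylindrical surface at a given radius onto a plane, viewed
#' from the outside of the filament: subunit k sits at axial coordinate
#' k * rise and arc coordinate radius * radians(k * twist), wrapped into
#' [0, 2 * pi * radius). Arc increases with positive twist.
#'
#' @param sym a [helical_symmetry()].
#' @param radius surface radius in Angstrom (> 0). The radius at which a
#'   net is drawn is a presentation choice and must be supplied.
#' @param k integer vector of subunit indices.
#' @return data.frame with columns `k`, `arc` and `axial` (Angstrom).
#' @export
helical_net <- function(sym, radius, k = 0:13) {
  sym <- as_helical_symmetry(sym)
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0)
    stop("'radius' must be a single positive number")
  if (length(k) == 0) stop("'k' must be non-empty")
  circ <- 2 * pi * radius
  data.frame(k = as.integer(k),
             arc = (radius * deg2rad(k * sym$twist)) %% circ,
             axial = k * sym$rise)
}

#' Best rational approximation: u subunits in t turns
#'
#' Finds coprime integers (u, t), u <= max_u, minimizing the per-subunit
#' closure residual |u * twist - 360 * t| / u. A helix with an exactly
#' rational twist repeats after u subunits and t turns; for irrational
#' twists this is the approximation underlying the selection rule.
#'
#' @param sym a [helical_symmetry()] (or its twist via a (rise, twist) pair).
#' @param max_u largest number of subunits per repeat searched (default 100).
#' @return a `rational_repeat` list with integer `u`, `t` and `residual`
#'   (degrees per subunit). Ties broken towards smaller u.
#' @export
rational_repeat <- function(sym, max_u = 100) {
  sym <- as_helical_symmetry(sym)
  stopifnot(max_u >= 1)
  twist <- abs(sym$twist)
  best <- NULL
  for (u in seq_len(max_u)) {
    t <- max(1L, as.integer(round(u * twist / 360)))
    res <- abs(u * twist - 360 * t) / u
    # also consider the neighbouring t in case rounding jumped a boundary
    for (tt in unique(c(t, max(1L, t - 1L), t + 1L))) {
      r <- abs(u * twist - 360 * tt) / u
      if (gcd_int(u, tt) != 1L) next
      if (is.null(best) || r < best$residual - 1e-12) {
        best <- list(u = as.integer(u), t = as.integer(tt), residual = r)
      }
    }
  }
  structure(best, class = "rational_repeat")
}

gcd_int <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  while (b != 0L) { tmp <- a %% b; a <- b; b <- tmp }
  abs(a)
}

#' Bessel orders allowed on a layer line by the selection rule
#'
#' For a C1 helix with u subunits in t turns, layer line l carries Bessel
#' order n iff integers (n, m) exist with l = t * n + u * m.
#'
#' @param l integer layer-line index.
#' @param repeat_ut a [rational_repeat()] or a list/vector with `u` and `t`.
#' @param n_max maximum |n| considered.
#' @return integer vector of allowed orders, sorted by |n| (positive first
#'   on ties).
#' @examples
#' allowed_bessel_orders(5, list(u = 18, t = 5), n_max = 10)  # 1
#' @export
allowed_bessel_orders <- function(l, repeat_ut, n_max) {
  u <- as.integer(repeat_ut[["u"]])
  t <- as.integer(repeat_ut[["t"]])
  stopifnot(n_max >= 0, u >= 1)
  n <- seq.int(-n_max, n_max)
  ok <- ((l - t * n) %% u) == 0L
  n <- n[ok]
  n[order(abs(n), -n)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
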