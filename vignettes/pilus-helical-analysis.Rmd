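---
title: "Helical lattices, symmetry ambiguity and glycan difference density in archaeal pili"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Helical lattices, symmetry ambiguity and glycan difference density in archaeal pili}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pilihelix)
```

`pilihelix` implements the analysis chain used to characterise helical
filaments — archaeal type IV pili in particular — from cryo-EM style data:
the exact arithmetic of one-start helical lattices, enumeration of
candidate symmetries from layer lines in filament power spectra,
difference-density quantification of surface glycosylation, rigid
comparison of helix bundles, and pilin sequence statistics. This vignette
is the package's own account of the underlying models, the tunable
parameters, and the numerical choices made where the design was open.

## The helical lattice model

A filament with C1 point-group symmetry is a single subunit repeated by a
screw operation: rotation by a twist $\Delta\phi$ (degrees) about the
filament axis and translation by a rise $\Delta z$ (Å) along it. Positive
twist is defined as a right-handed 1-start helix; every handedness the
package reports derives from that sign. All angles are kept in degrees
end-to-end, converted to radians only inside trigonometric calls.

From $(\Delta z, \Delta\phi)$ everything else is arithmetic:

* subunits per turn $= 360/|\Delta\phi|$; pitch $= \Delta z \cdot
  360/|\Delta\phi|$;
* the $n$-start family connects every $n$-th subunit, with effective
  twist $\mathrm{wrap}(n\,\Delta\phi)$ reduced to $(-180, 180]$
  (exactly $+180$ maps to $+180$, tested) and effective rise
  $n\,\Delta z$;
* the *dominant* (long-pitch) family is the one whose effective twist is
  closest to zero, ties broken to the smaller $n$;
* a rational repeat of $u$ subunits in $t$ turns (coprime, $u \le$
  `max_u` $= 100$ by default, minimal per-subunit residual
  $|u\Delta\phi - 360t|/u$, ties to the smaller $u$) supports the
  selection rule $\ell = t n + u m$ linking layer line $\ell$ to the
  Bessel orders $n$ it may carry.

With $\approx 3.5$ subunits per turn both pilus lattices treated here
(rise 5.26 Å / twist 101.69° and rise 4.97 Å / twist 104.57°) have a
dominant 7-start family; because one lattice sits slightly above 3.5
subunits/turn (7.1 subunits in two turns) and the other slightly below
(6.9), the same 7-start family is left-handed in the first and
right-handed in the second:

```{r lattice}
dominant_start_family(helical_symmetry(5.26, 101.69), 10)
dominant_start_family(helical_symmetry(4.97, 104.57), 10)
```

The equivalence "dominant order = subunits in two turns, rounded" holds
in a band around 3.5 subunits/turn (roughly 3.40–3.66, covering both
lattices) but **not** across the whole 3.25–3.75 range: at resonant
twists another family closes exactly (at 108° the 10-start has zero
effective twist) and takes over under the minimal-|twist| definition.
The test suite pins both the generic band and the resonant case.

Helical nets (`helical_net()`) unroll the cylindrical surface at a
user-chosen radius, viewed from the outside, with the arc coordinate
increasing with positive twist. The radius at which a net is drawn is a
presentation choice with no canonical value, so it is a required
argument rather than a default.

## The synthetic filament generator

Every downstream stage is exercised on synthetic filaments, so no
external map or model is needed. `make_toy_pilin()` builds a
coarse-grained two-domain pilin with one pseudo-atom per residue
(Cα-level): 135 residues, of which the first 35 trace an ideal α-helix
(1.5 Å rise/residue, 2.3 Å helix radius, 100°/residue) running parallel
to the filament axis at 8 Å radial offset — the hydrophobic tail that
forms the filament core — and the remaining 100 are placed uniformly
(seeded, with the global RNG state restored) in a 14 Å ball centred
radially outward, standing in for the Ig-like β-sandwich. A hard-core
minimum spacing (4 Å, or looser when geometrically infeasible) mimics
real Cα packing; plain uniform sampling produces unphysically close
pairs. Filaments assembled from these defaults are ~80–90 Å in outer
diameter, matching the scale of the real pili.

Glycans are extra pseudo-atoms placed 5 Å radially outward of chosen
globular residues (about one sugar ring from the modified side chain)
with weight 3 residue-equivalents — the real glycan mass is unknown, and
this value is an explicit free parameter. `surface_residues()` selects
plant sites the way nature does: exposed residues, here the most
radially distant globular residues subject to (i) no other residue
within 5.5 Å of the would-be glycan position (so the peak is
unambiguously nearest its own residue) and (ii) ≥ 8 Å mutual separation
(so two glycan peaks stay resolved under a 7 Å filter). Some random
globular domains cannot host 7 such sites; `make_glyco_fixture()`
deterministically tries successive monomer seeds until one can.

`rasterize()` renders each site as an isotropic Gaussian with
$\sigma = \mathrm{resolution}/(2\pi\sqrt2)$ (0.79 Å at the default 7 Å),
normalised so the map integral equals the summed weights (mass
conservation holds to <1%; Poisson summation makes the discrete sum
accurate even at $\sigma <$ voxel). The default voxel is 1.08 Å, a
typical physical pixel size for modern direct detectors. The filament
axis is +z, the helical origin at the grid centre in x/y.

What the generator deliberately does **not** emulate: all-atom
structure, B-factors, CTF, per-subunit occupancy variation, or realistic
micrograph noise (noise is plain additive Gaussian). Passing tests
therefore demonstrate the correctness of the lattice arithmetic, the
indexing logic and the difference-density bookkeeping — not robustness
to the full pathology of experimental maps.

## Symmetry indexing from power spectra

`project_and_spectrum()` sums the map along one transverse axis and
takes the squared 2-D Fourier magnitude, rows indexing axial frequency.
A periodic Hann window is applied along z by default: the equator of a
filament spectrum is orders of magnitude stronger than any layer line,
and with a periodic Hann its leakage is exactly zero at all integer
frequency bins beyond the first, so near-equatorial layer lines survive.
(Consistently, `detect_layer_lines()` ignores the equator and the single
bin adjacent to it.) For indexing runs the simulated filament is built
longer than the box on purpose, so the density is effectively
z-stationary and the window sees no end effects; the resulting clipping
warning is expected.

`detect_layer_lines()` thresholds row power at `min_snr` (default 5)
times the median row power — a robust background, so detection is
invariant to intensity scaling — groups contiguous rows, and takes a
power-weighted centroid height over rows within two bins of each group
maximum (sub-bin height accuracy; a 553 Å box gives twist estimates well
inside 1°). Each line's radial first-maximum position feeds the standard
heuristic $|n| \approx 2\pi R r_{peak} - 2$ (`estimate_order_magnitude()`,
slack ±1 by default): the first maximum of $J_n$ falls near argument
$n + 2$ for moderate $n$.

`enumerate_symmetries()` reproduces the indexing ambiguity analysis.
Lines whose first maximum is essentially on the meridian
($2\pi R r_{peak} < 2.5$; $J_1$ already peaks at 1.84) are meridional
candidates, and *each* provides a rise hypothesis $1/Z$ — wrong ones are
eliminated at scoring rather than guessed away. For every line of height
$Z$, every compatible order $n$ (both signs) and harmonic $|m| \le 2$,
the twist hypothesis $360(Z\,\Delta z - m)/n$ is forward-modelled:
$Z(n, m) = n\Delta\phi/(360\Delta z) + m/\Delta z$ with the harmonic
range derived per order, and a candidate survives only if **every**
observed line matches a predicted height within `tol` (default 0.002
Å⁻¹). Scoring uses a deeper order bound (`score_n_max = 2 n_max`) than
seeding, so a genuine high-order line cannot disqualify the correct
low-order candidate. Candidates are deduplicated at 0.02 Å / 0.1°,
sorted by residual, then seed |n|, then twist, and emitted in ± twist
pairs because a single projection cannot fix handedness (`mirror =
FALSE` suppresses the mirrors). Several distinct lattices typically
survive — the ambiguity that, with real data, is resolved by trial
reconstructions — and the property tests require the generating lattice
(and its mirror) always to be among them.

## Difference density and glycan calling

`lowpass()` filters in Fourier space with a transfer function flat to
$k_c - 3w$ and a Gaussian roll-off of width $w = k_c/8$, so the response
has decayed to ~1% *at* the cutoff $k_c = 1/\mathrm{resolution}$: the
filtered map retains <1% of its power beyond the nominal resolution,
while the soft edge keeps the real-space ringing halo of strong features
to a few percent — a hard cutoff would imprint sinc ripples on the
difference map. The zero-frequency term is preserved exactly, and the
filter is linear, so filtering twice equals one pass of the squared
kernel to rounding error.

`difference_map()` filters both maps to a common resolution (default
7 Å, coarse enough that flexible, partially occupied surface sugars
become coherent density), scales the model map by least squares and
subtracts. The scale is fitted over the model *core* (voxels above half
the model maximum) rather than the full envelope: peripheral unmodelled
density is precisely the signal of interest and must not leak into the
scale factor. The inside/outside classifier used downstream is the
gentler envelope — lowpassed model above 10% of maximum, dilated one
voxel.

`extra_density_fraction()` reports, for display thresholds of 3, 5 and
8 robust sigma (1.4826 × MAD, falling back to the ordinary SD when the
median deviation is exactly zero, as on noiseless fixtures), the
fraction of all voxels that are simultaneously above threshold and
outside the envelope. The thresholds stand in for display contour
levels, so comparisons between conditions are ordinal, per threshold.

`call_glyco_sites()` finds strict 26-neighbourhood local maxima above
`min_peak` sigma (default 5), refines each peak to sub-voxel precision
with a per-axis parabolic fit, and assigns it to the nearest protein
residue within `max_dist` (default 6 Å, one sugar ring away from a Cα).
One call is kept per (chain, residue) — the strongest peak — and
unassignable peaks are reported rather than dropped. A second, absolute
floor (`min_frac`, default 25% of the difference-map maximum) guards the
degenerate noise-free case, where the robust sigma collapses towards
zero and filter ripple would otherwise be called; on noisy maps with
peaks at ≥5 sigma the floor sits below the sigma threshold and is
inert. In the noisy-recovery test, SNR is defined as the clean filtered
glycan peak height divided by the filtered noise standard deviation, and
recall is counted over unique residues across subunits — the natural
reading for a helical filament, where every subunit provides an
independent copy of each site.

## Bundle comparison

`extract_bundle()` cuts `k` chains adjacent along the 1-start helix
(default 5), restricted to a residue range (default 1–35, the N-terminal
helix), in deterministic chain-major order. Correspondence between
bundles is positional (chain rank × residue rank); the bundles compared
are equal-length by construction, and sequence-independent structural
alignment is out of scope. `superpose()` is the closed-form
least-squares (Kabsch) solution with the reflection branch excluded by a
determinant sign correction; the suite cross-checks it against both an
independent dense rotation-grid search (2° z-x-z Euler grid, exact
trace-based evaluation) and `bio3d`'s fitted RMSD.

`tm_score()` computes $\mathrm{TM} = L^{-1}\sum_i (1 + (d_i/d_0)^2)^{-1}$
with $d_0 = 1.24 (L - 15)^{1/3} - 1.8$ Å, maximised over rigid
transforms by iterating trimmed superpositions on pairs with
$d_i < d_0$ (at least 3 pairs, at most 50 iterations, best score kept) —
a documented approximation to the published heuristic search that is
exact for identical inputs (`tm_score(a, a)` is exactly 1) and adequate
for the rigid, equal-length bundles compared here. `L_norm` defaults to
the number of mapped pairs and must exceed 15, the domain of the $d_0$
formula. `cys_pair_candidates()` flags cysteine pairs within 7.5 Å at
Cα level, the distance band where a disulfide staple is geometrically
possible.

## Sequence features

Composition scans take a region argument; the default globular-domain
region for a mature pilin is residues 36 to the end, after the
~35-residue N-terminal helix. "Charged" means {D, E, K, R} by default —
histidine is mostly neutral at growth pH and is a flag, not a default —
which puts a ~135-residue pilin with 2 charged residues at the ~1.5%
scale. Position indexing is 1-based on the mature protein. The
prepilin-peptidase scan reports every (K/R)(G/A) dipeptide within the
signal window (default 30 residues) as a candidate cleavage site, with
consensus status of the (+1, +2) positions against (L/I/F)(S/T/A) and
the deviating positions listed — deviant cleavage sites occur in nature
and must not be silently discarded. The sequon scan is the literal
N-x-S/T by default; the stricter no-proline variant is a flag.
`global_identity()` is a Needleman–Wunsch global alignment (BLOSUM62,
affine gaps 10/0.5, via Biostrings) with identity = identical columns /
alignment columns; dividing by the shorter sequence instead is a flag,
since conventions differ.

## Problem sizes and determinism

The shipped analyses and tests run at deliberately modest sizes chosen
to exercise every code path: indexing uses a 120-subunit filament in a
96 × 256 × 512 box at 1.08 Å/voxel (a 553 Å repeat gives sub-degree
twist resolution); difference mapping uses 9-subunit filaments in
auto-sized boxes (~10⁶ voxels); recovery properties use 20 randomised
lattices with rise in [4, 6] Å and twist in [95°, 115°]. Every random
draw is seeded, and functions that consume seeds restore the global RNG
state. The helical self-correlation check resamples the rotated map by
trilinear interpolation and therefore uses a 0.6 Å test voxel, at which
the interpolation error is negligible relative to the 0.99 correlation
bound.

## Known limitations

* The indexing module recovers lattices from layer-line *heights*; it
  does not model Bessel amplitudes, CTF or out-of-plane tilt, and the
  first-maximum order heuristic assumes scattering mass near the outer
  radius — order intervals can be off by one for mid-radius mass, which
  the ± slack absorbs.
* Difference-density calling assumes the model and map share a
  coordinate frame; no fitting/docking is performed.
* TM-score uses a local iterative transform search, not the published
  exhaustive fragment search; for strongly divergent structures it can
  underestimate the optimum.
* Checks against the deposited pilus models (charged fractions, Ser/Thr
  content, pairwise identity, cross-filament bundle RMSD) require the
  deposited coordinates and sequences, which are not redistributed with
  the package; `accession_checks()` runs them from local copies.
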