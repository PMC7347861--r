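# pilihelix

Helical-lattice analysis and simulation for archaeal type IV pili (and
helical filaments generally), in R.

Archaeal type IV pili are screw-symmetric polymers of a small two-domain
pilin: a ~35-residue hydrophobic N-terminal α-helix buried in the
filament core and a C-terminal Ig-like globular domain on the surface,
often heavily O-glycosylated. Characterising such a filament from cryo-EM
means answering a chain of questions that this package implements as
reusable, tested functions:

1. **Lattice arithmetic** (`helical_symmetry`, `subunits_per_turn`,
   `start_family`, `dominant_start_family`, `helical_net`,
   `rational_repeat`, `allowed_bessel_orders`). A helix with rise Δz and
   twist Δφ has 360/|Δφ| subunits per turn; the n-start family has
   effective twist `wrap(nΔφ)` in (−180°, 180°], and the family closest
   to 0° dominates visually. A repeat of u subunits in t turns gives the
   selection rule ℓ = tn + um for the Bessel orders n allowed on layer
   line ℓ.
2. **Symmetry indexing from power spectra**
   (`project_and_spectrum`, `detect_layer_lines`,
   `estimate_order_magnitude`, `predicted_layer_lines`,
   `enumerate_symmetries`). Layer-line heights obey
   Z(n, m) = nΔφ/(360Δz) + m/Δz; the first intensity maximum of a line
   suggests its order via |n| ≈ 2πR·r_peak − 2. Many lattices can
   predict the same line set — the package enumerates all of them, which
   is exactly the ambiguity that must be resolved by trial
   reconstructions.
3. **Synthetic filaments** (`make_toy_pilin`, `decorate_glycans`,
   `build_filament`, `rasterize`, `add_noise`, `make_glyco_fixture`,
   MRC/PDB I/O): coarse-grained two-domain pilins assembled under any
   symmetry and rendered as density, so every stage above and below is
   testable with planted ground truth and no downloads.
4. **Glycan difference density** (`lowpass`, `scale_to`,
   `difference_map`, `extra_density_fraction`, `radial_profile`,
   `call_glyco_sites`): filter experimental and model maps to a common
   resolution (7 Å default), least-squares scale, subtract, and locate
   peripheral unmodelled density — the glycosylation signature.
5. **Bundle comparison** (`extract_bundle`, `superpose`, `rmsd_matrix`,
   `tm_score`, `cys_pair_candidates`): cut five adjacent N-terminal
   helices from a filament, compare all-against-all by least-squares
   (Kabsch) RMSD and by the length-normalised TM-score with
   d0 = 1.24(L−15)^{1/3} − 1.8 Å.
6. **Pilin sequence features** (`st_fraction`, `charged_fraction`,
   `proteome_distribution`, `scan_pibd`, `scan_sequons`,
   `global_identity`): Ser/Thr and charged-residue content, the
   prepilin-peptidase consensus (Lys/Arg)-(Gly/Ala)↓(Leu/Ile/Phe)-(Ser/Thr/Ala),
   N-glycosylation sequons N-x-S/T, and global percent identity.

The `analysis/` directory holds five numbered drivers that run the whole
chain on the two pilus lattices (rise 5.26 Å / twist 101.69° and
4.97 Å / 104.57°) and write tables under `results/`.

## Worked example

```r
library(pilihelix)

par <- helical_symmetry(5.26, 101.69)   # P. arsenaticum-like lattice
sso <- helical_symmetry(4.97, 104.57)   # S. solfataricus-like lattice

round_half_away(subunits_in_turns(par, 2))   # 7.1
round_half_away(subunits_in_turns(sso, 2))   # 6.9
dominant_start_family(par, 10)
#> 7-start family: eff. twist -8.17 deg (left-handed), eff. rise 36.82 Angstrom
dominant_start_family(sso, 10)
#> 7-start family: eff. twist 11.99 deg (right-handed), eff. rise 34.79 Angstrom
```

Both lattices pack ~3.5 subunits per turn, so both have a dominant
7-start family — but 7.1 subunits in two turns puts the first just above
3.5 (left-handed 7-start) and 6.9 puts the second just below
(right-handed). Running the indexing driver:

```
$ Rscript analysis/02_symmetry_indexing.R
Simulated filament: 120 subunits, outer diameter 87.3 A
Detected 6 layer lines; meridional at 0.1904 1/A (1/rise = 0.1901)
82 candidate symmetries survive scoring (41 per handedness).
The generating symmetry is among them: rise 5.253 A, twist 101.663 deg
...
Exact-line control: 20/20 randomized lattices recovered.
```

The meridional layer line fixes the rise at 1/Z; enumerating orders for
the remaining lines yields dozens of internally consistent lattices —
the recovered one differs from the generating 5.26 Å / 101.69° by under
0.01 Å and 0.03°. The glycosylation driver plants seven surface glycans
per subunit and recovers exactly those residues from the 7 Å difference
map, with the no-glycan control showing more than an order of magnitude
less unexplained peripheral density at every display threshold:

```
$ Rscript analysis/03_glycosylation_density.R
Planted 7 glycans per subunit on residues: 57, 63, 85, 104, 112, 132, 133
Model scaled by 1.0001 before subtraction (7 A filter).
Difference peaks call residues: 57, 63, 85, 104, 112, 132, 133 (7/7 planted, 0 false)
Single-glycan filament: 1 unique residue called (residue 57).
```

See `vignettes/pilus-helical-analysis.Rmd` for the models, parameter
choices and numerical conventions behind each stage.

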