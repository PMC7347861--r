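Package: pilihelix
Title: Helical Lattice Analysis and Simulation for Archaeal Type IV Pili
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis chain used to characterise archaeal
    type IV pilus filaments from cryo-EM: exact helical-lattice arithmetic
    (subunits per turn, pitch, n-start families, helical nets, the
    selection rule), enumeration of candidate helical symmetries from
    layer lines in filament power spectra, synthetic two-domain pilin and
    filament density simulation with optional surface glycans, model-map
    difference mapping to localise and quantify unmodelled (glycan)
    density, rigid superposition with RMSD matrices and TM-scores for
    helix-bundle comparison, and pilin sequence statistics (Ser/Thr and
    charged-residue composition, prepilin-peptidase cleavage motifs,
    N-glycosylation sequons, pairwise identity).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
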