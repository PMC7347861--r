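#' Composition, identity and bundle checks against deposited structures
#'
#' Recomputes the headline sequence/structure numbers for the real
#' filaments from locally supplied copies of the deposited models. The
#' coordinate and sequence data are NOT packaged (they are third-party
#' database depositions); download them and point `dir` at:
#'
#' * `6w8u_ca.pdb` — Calpha records of one chain of the
#'   *P. arsenaticum* pilus model (PDB 6W8U)
#' * `6w8x_ca.pdb` — Calpha records of one chain of the
#'   *S. solfataricus* pilus model (PDB 6W8X)
#' * `pilins.fasta` — mature pilin sequences with ids `par_pilA`,
#'   `sso_pilA`, `sis_pilA` (*S. islandicus*)
#' * `iho670_bundle_ca.pdb`, `6w8x_bundle_ca.pdb` — five adjacent
#'   N-terminal helices (35 residues each) of the Iho670 filament and the
#'   *S. solfataricus* pilus
#'
#' @param dir directory containing the files above.
#' @param helix_len N-terminal helix length for the globular-domain split.
#' @return named list: `charged_frac_par`, `charged_frac_sso`,
#'   `st_frac_globular_sso`, `st_frac_par`, `identity_sso_sis`,
#'   `bundle_rmsd_iho_sso` (fractions as percentages).
#' @export
accession_checks <- function(dir, helix_len = 35) {
  need <- c("6w8u_ca.pdb", "6w8x_ca.pdb", "pilins.fasta",
            "iho670_bundle_ca.pdb", "6w8x_bundle_ca.pdb")
  paths <- file.path(dir, need)
  missing <- need[!file.exists(paths)]
  if (length(missing) > 0)
    stop("deposited reference data not available locally; missing: ",
         paste(missing, collapse = ", "))
  seqs <- read_proteins(file.path(dir, "pilins.fasta"))
  ids <- vapply(seqs, function(r) r$id, character(1))
  get_seq <- function(id) {
    i <- match(id, ids)
    if (is.na(i)) stop("pilins.fasta lacks record ", id)
    seqs[[i]]
  }
  par <- get_seq("par_pilA"); sso <- get_seq("sso_pilA")
  sis <- get_seq("sis_pilA")
  b_iho <- read_ca_pdb(file.path(dir, "iho670_bundle_ca.pdb"))
  b_sso <- read_ca_pdb(file.path(dir, "6w8x_bundle_ca.pdb"))
  list(
    charged_frac_par = 100 * charged_fraction(par),
    charged_frac_sso = 100 * charged_fraction(sso),
    st_frac_globular_sso = 100 * st_fraction(sso, globular_region(sso, helix_len)),
    st_frac_par = 100 * st_fraction(par),
    identity_sso_sis = global_identity(sso, sis),
    bundle_rmsd_iho_sso = superpose(b_iho, b_sso)$rmsd)
}
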