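#' Write a density map in MRC format
#'
#' MRC2014 single-volume file, mode 2 (32-bit float), little-endian, with
#' the voxel size in the cell header and the map origin (Angstrom) in the
#' ORIGIN fields. Values are stored as float32; re-reading therefore
#' returns float32-rounded values. No R package on hand reads MRC volumes,
#' so the (simple) format is implemented here directly.
#'
#' @param map a [density_map()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  d <- dim(map$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                      # NX NY NZ
  wi(2L)                     # MODE 2 = float32
  wi(c(0L, 0L, 0L))          # NXSTART..
  wi(d)                      # MX MY MZ
  wf(d * map$voxel)          # CELLA
  wf(c(90, 90, 90))          # CELLB
  wi(c(1L, 2L, 3L))          # MAPC MAPR MAPS
  wf(c(min(map$values), max(map$values), mean(map$values)))
  wi(c(0L, 0L))              # ISPG, NSYMBT
  wi(integer(25))            # EXTRA (words 26-50 incl. EXTTYP/NVERSION zeroed)
  wf(map$origin)             # ORIGIN (words 50-52)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(0)                      # RMS (unset)
  wi(0L)                     # NLABL
  writeBin(raw(800), con)    # labels
  writeBin(as.numeric(map$values), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC density map
#'
#' Reads mode-2 (float32) MRC volumes with axis order X, Y, Z as written
#' by [write_mrc()] and most reconstruction packages.
#'
#' @param path MRC file.
#' @return a [density_map()].
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2L) stop("only mode-2 (float32) MRC volumes are supported")
  ri(3)                      # NXSTART..
  m <- ri(3)                 # MX MY MZ
  cella <- rf(3)
  rf(3)                      # CELLB
  mapcrs <- ri(3)
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stop("only axis order X,Y,Z (MAPC,MAPR,MAPS = 1,2,3) is supported")
  rf(3)                      # min/max/mean
  ri(2)                      # ISPG, NSYMBT
  ri(25)                     # EXTRA
  origin <- rf(3)
  seek(con, 1024)
  vals <- readBin(con, "numeric", prod(d), size = 4, endian = "little")
  voxel <- cella[1] / m[1]
  density_map(array(vals, dim = d), voxel = voxel, origin = origin)
}

#' Write a coarse-grained model as a PDB file
#'
#' One Calpha record per (non-glycan) residue site, one chain per subunit;
#' glycan sites are written as HETATM-style Calpha records of residue
#' "GLC". Delegates to `bio3d::write.pdb`.
#'
#' @param model a `filament_model` or `pilin_model`.
#' @param path output file.
#' @param resid three-letter residue name for protein sites.
#' @return `path`, invisibly.
#' @export
write_model_pdb <- function(model, path, resid = "ALA") {
  s <- model$sites
  chains <- chain_letters(s$chain)
  n <- nrow(s)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(s[, c("x", "y", "z")]))),
                   resno = s$resno,
                   chain = chains,
                   resid = ifelse(s$role == "glycan", "GLC", resid),
                   elety = rep("CA", n), eleno = seq_len(n),
                   o = rep(1, n), b = rep(0, n))
  invisible(path)
}

#' Read a Calpha coordinate set from a PDB file
#'
#' @param path PDB file.
#' @return a [coord_set()] of the Calpha atoms, labelled by chain and
#'   residue number, with residue names in `labels$resid`.
#' @export
read_ca_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  ca <- bio3d::atom.select(pdb, elety = "CA")
  at <- pdb$atom[ca$atom, ]
  coord_set(cbind(at$x, at$y, at$z),
            chain = at$chain, resno = at$resno, resid = at$resid)
}

# map integer subunit indices to single-character PDB chain ids (cycled)
chain_letters <- function(chain_idx) {
  pool <- c(LETTERS, letters, as.character(0:9))
  pool[(as.integer(chain_idx) %% length(pool)) + 1L]
}
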