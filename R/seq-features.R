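#' Protein record
#'
#' @param id identifier string.
#' @param sequence amino-acid sequence (20 standard one-letter codes; X
#'   allowed for unknowns).
#' @return a `protein_record`.
#' @export
protein_record <- function(id, sequence) {
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  if (nchar(sequence) == 0) stop("empty sequence")
  bad <- setdiff(strsplit(sequence, "")[[1]], c(strsplit(AA20, "")[[1]], "X"))
  if (length(bad) > 0)
    stop("invalid residue letter(s): ", paste(unique(bad), collapse = ", "))
  structure(list(id = as.character(id), sequence = sequence),
            class = "protein_record")
}

AA20 <- "ACDEFGHIKLMNPQRSTVWY"

#' Read protein records from a FASTA file
#'
#' @param path FASTA file (multi-record).
#' @return list of [protein_record()]s.
#' @export
read_proteins <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  mapply(function(nm, sq) protein_record(sub("\\s.*", "", nm), sq),
         names(aa), as.character(aa), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

as_protein <- function(rec) {
  if (inherits(rec, "protein_record")) return(rec)
  if (is.character(rec) && length(rec) == 1)
    return(protein_record("seq", rec))
  stop("expected a protein_record or a sequence string")
}

region_chars <- function(rec, region) {
  ch <- strsplit(rec$sequence, "")[[1]]
  if (is.null(region)) return(ch)
  region <- as.integer(region)
  if (length(region) == 0 || any(region < 1 | region > length(ch)))
    stop("region outside the sequence")
  ch[region]
}

#' Serine + threonine fraction
#'
#' The Ser/Thr content of the globular domain is the signature of heavy
#' O-glycosylation potential in archaeal pilins (~37% in the acidophiles'
#' pilins versus ~20% typically).
#'
#' @param rec a [protein_record()] or sequence string.
#' @param region residue indices (default: whole sequence). For the
#'   globular domain of a mature archaeal pilin use
#'   [globular_region()].
#' @return (#S + #T) / region length, in `[0, 1]`.
#' @export
st_fraction <- function(rec, region = NULL) {
  ch <- region_chars(as_protein(rec), region)
  if (length(ch) == 0) stop("empty region")
  mean(ch %in% c("S", "T"))
}

#' Charged-residue fraction
#'
#' @param rec a [protein_record()] or sequence string.
#' @param region residue indices (default: whole sequence).
#' @param charged_set charged residue letters. Default D, E, K, R;
#'   histidine (mostly neutral at growth pH) is excluded unless added
#'   via `include_his`.
#' @param include_his add H to the charged set.
#' @return fraction in `[0, 1]`.
#' @export
charged_fraction <- function(rec, region = NULL,
                             charged_set = c("D", "E", "K", "R"),
                             include_his = FALSE) {
  stopifnot(all(charged_set %in% strsplit(AA20, "")[[1]]))
  if (include_his) charged_set <- union(charged_set, "H")
  ch <- region_chars(as_protein(rec), region)
  if (length(ch) == 0) stop("empty region")
  mean(ch %in% charged_set)
}

#' Default globular-domain region of a mature pilin
#'
#' Residues after the ~35-residue N-terminal helix to the C terminus.
#'
#' @param rec a [protein_record()] or sequence string.
#' @param helix_len N-terminal helix length (default 35).
#' @return integer vector of residue indices.
#' @export
globular_region <- function(rec, helix_len = 35) {
  rec <- as_protein(rec)
  n <- nchar(rec$sequence)
  if (helix_len >= n) stop("helix length leaves no globular domain")
  (helix_len + 1):n
}

#' Proteome-wide Ser+Thr distribution
#'
#' Per-protein Ser+Thr fractions with the summary statistics used in
#' violin/box displays (median, interquartile range).
#'
#' @param records list of [protein_record()]s.
#' @param region optional region applied to every record (default whole
#'   sequence).
#' @return data.frame (`id`, `st_fraction`, `length`), ordered by id;
#'   attribute `summary` holds `median`, `q1`, `q3`.
#' @export
proteome_distribution <- function(records, region = NULL) {
  if (length(records) == 0) stop("no records")
  records <- lapply(records, as_protein)
  df <- data.frame(
    id = vapply(records, function(r) r$id, character(1)),
    st_fraction = vapply(records, function(r) st_fraction(r, region),
                         numeric(1)),
    length = vapply(records, function(r) nchar(r$sequence), numeric(1)),
    stringsAsFactors = FALSE)
  df <- df[order(df$id), ]
  rownames(df) <- NULL
  q <- stats::quantile(df$st_fraction, c(0.25, 0.5, 0.75), type = 7)
  attr(df, "summary") <- list(median = unname(q[2]), q1 = unname(q[1]),
                              q3 = unname(q[3]))
  df
}

#' Scan for prepilin-peptidase (PibD) cleavage sites
#'
#' Class III signal peptides are cleaved by the prepilin peptidase PibD at
#' a (Lys/Arg)-(Gly/Ala) | (Leu/Ile/Phe)-(Ser/Thr/Ala) consensus. Every
#' position p within the signal-search window where residues (p-1, p) fit
#' (K/R)(G/A) is reported (cleavage occurs after p); `consensus_match` is
#' true when the (+1, +2) residues also fit, otherwise the failing
#' positions are listed in `deviations` ("+1"/"+2"). Cleavage sites that
#' deviate at +1/+2 do occur (e.g. Arg-Gly|Met-Thr), so candidate sites
#' are reported regardless.
#'
#' @param rec a [protein_record()] or sequence string (the prepilin,
#'   signal peptide included).
#' @param max_signal_len cleavage searched at positions p <= this
#'   (default 30).
#' @return data.frame (`position` = p, the residue preceding cleavage;
#'   `window` = the -2,-1,+1,+2 residues; `consensus_match`;
#'   `deviations`); zero rows when none found or sequence shorter than 4.
#' @export
scan_pibd <- function(rec, max_signal_len = 30) {
  stopifnot(max_signal_len >= 2)
  rec <- as_protein(rec)
  ch <- strsplit(rec$sequence, "")[[1]]
  out <- data.frame(position = integer(0), window = character(0),
                    consensus_match = logical(0), deviations = character(0),
                    stringsAsFactors = FALSE)
  if (length(ch) < 4) return(out)
  for (p in 2:min(max_signal_len, length(ch) - 2)) {
    if (!(ch[p - 1] %in% c("K", "R") && ch[p] %in% c("G", "A"))) next
    dev <- character(0)
    if (!(ch[p + 1] %in% c("L", "I", "F"))) dev <- c(dev, "+1")
    if (!(ch[p + 2] %in% c("S", "T", "A"))) dev <- c(dev, "+2")
    out <- rbind(out, data.frame(
      position = p,
      window = paste0(ch[p - 1], ch[p], ch[p + 1], ch[p + 2]),
      consensus_match = length(dev) == 0,
      deviations = paste(dev, collapse = ","),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Scan for N-glycosylation sequons (NxS/T)
#'
#' @param rec a [protein_record()] or sequence string.
#' @param exclude_proline skip matches with P at the x position (the
#'   stricter eukaryotic convention); off by default — the motif is taken
#'   literally as N-x-S/T.
#' @return integer positions of the N residues (1-based), possibly
#'   overlapping.
#' @export
scan_sequons <- function(rec, exclude_proline = FALSE) {
  rec <- as_protein(rec)
  ch <- strsplit(rec$sequence, "")[[1]]
  n <- length(ch)
  if (n < 3) return(integer(0))
  i <- seq_len(n - 2)
  hit <- ch[i] == "N" & ch[i + 2] %in% c("S", "T")
  if (exclude_proline) hit <- hit & ch[i + 1] != "P"
  i[hit]
}

#' Global pairwise sequence identity
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gaps) via
#' Biostrings; identity = identical columns / alignment columns. In a
#' pairwise alignment no column is a double gap, so the denominator is the
#' full alignment length; `denominator = "shorter"` divides by the shorter
#' sequence length instead.
#'
#' @param a,b [protein_record()]s or sequence strings.
#' @param gap_opening,gap_extension affine gap parameters.
#' @param denominator "alignment" (default) or "shorter".
#' @return identity percentage in `[0, 100]`.
#' @export
global_identity <- function(a, b, gap_opening = 10, gap_extension = 0.5,
                            denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  a <- as_protein(a); b <- as_protein(b)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$sequence), Biostrings::AAString(b$sequence),
    substitutionMatrix = get("BLOSUM62", envir = environment()),
    gapOpening = gap_opening, gapExtension = gap_extension,
    type = "global")
  nm <- Biostrings::nmatch(pa)
  den <- switch(denominator,
                alignment = Biostrings::nchar(pa),
                shorter = min(nchar(a$sequence), nchar(b$sequence)))
  100 * nm / den
}
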