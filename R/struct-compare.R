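#' Labelled coordinate set
#'
#' @param xyz n x 3 numeric matrix of coordinates (Angstrom).
#' @param chain,resno per-point chain and residue labels.
#' @param resid optional residue names (e.g. "CYS").
#' @return a `coord_set` with `xyz` and `labels` (data.frame).
#' @export
coord_set <- function(xyz, chain = 0L, resno = seq_len(nrow(xyz)),
                      resid = NULL) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, nrow(xyz) >= 1)
  labels <- data.frame(chain = rep_len(chain, nrow(xyz)),
                       resno = rep_len(resno, nrow(xyz)),
                       stringsAsFactors = FALSE)
  if (!is.null(resid)) labels$resid <- rep_len(resid, nrow(xyz))
  structure(list(xyz = unname(xyz), labels = labels), class = "coord_set")
}

#' @export
print.coord_set <- function(x, ...) {
  cat(sprintf("coord set: %d sites, %d chain(s)\n", nrow(x$xyz),
              length(unique(x$labels$chain))))
  invisible(x)
}

#' Extract a bundle of adjacent helices from a filament
#'
#' Cuts out `k` chains adjacent along the 1-start helix (consecutive
#' subunits), restricted to a residue range — by default the N-terminal
#' helix (residues 1-35), the region whose packing is compared across
#' filaments.
#'
#' @param filament a `filament_model` or a [coord_set()] (e.g. from
#'   [read_ca_pdb()]).
#' @param k number of adjacent chains (default 5).
#' @param residue_range integer range of residues (default 1:35).
#' @param start_chain first chain (0-based for `filament_model`; for a
#'   `coord_set`, index into the sorted unique chain ids).
#' @return a [coord_set()], chain-major, residues ascending.
#' @export
extract_bundle <- function(filament, k = 5, residue_range = 1:35,
                           start_chain = 0) {
  if (inherits(filament, "filament_model")) {
    s <- filament$sites[filament$sites$role != "glycan", ]
    chains <- sort(unique(s$chain))
  } else if (inherits(filament, "coord_set")) {
    s <- cbind(filament$labels,
               data.frame(x = filament$xyz[, 1], y = filament$xyz[, 2],
                          z = filament$xyz[, 3]))
    chains <- sort(unique(s$chain))
  } else stop("'filament' must be a filament_model or coord_set")
  i0 <- if (inherits(filament, "filament_model")) {
    match(start_chain, chains)
  } else start_chain + 1L
  if (is.na(i0) || i0 + k - 1 > length(chains))
    stop(sprintf("requested %d chains from chain %s but only %d available",
                 k, as.character(start_chain), length(chains)))
  want <- chains[i0:(i0 + k - 1)]
  s <- s[s$chain %in% want & s$resno %in% residue_range, ]
  if (nrow(s) == 0) stop("residue range selects no sites")
  s <- s[order(match(s$chain, want), s$resno), ]
  coord_set(as.matrix(s[, c("x", "y", "z")]), chain = s$chain,
            resno = s$resno,
            resid = if ("resid" %in% names(s)) s$resid else NULL)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Closed-form optimal rotation + translation mapping `b` onto `a` over a
#' point correspondence, with the reflection branch excluded (proper
#' rotation enforced via determinant sign correction on the smallest
#' singular vector).
#'
#' @param a,b [coord_set()]s (or n x 3 matrices).
#' @param mapping two-column integer matrix of (index in a, index in b)
#'   pairs; `NULL` maps positionally (requires equal sizes).
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3;
#'   the transform is x_b %*% t(R) + t), and `rmsd` (Angstrom) over the
#'   mapped pairs.
#' @export
superpose <- function(a, b, mapping = NULL) {
  A <- if (inherits(a, "coord_set")) a$xyz else as.matrix(a)
  B <- if (inherits(b, "coord_set")) b$xyz else as.matrix(b)
  if (is.null(mapping)) {
    if (nrow(A) != nrow(B))
      stop("positional mapping requires equal point counts")
    mapping <- cbind(seq_len(nrow(A)), seq_len(nrow(B)))
  }
  if (nrow(mapping) < 3) stop("at least 3 point pairs are required")
  P <- A[mapping[, 1], , drop = FALSE]  # target
  Q <- B[mapping[, 2], , drop = FALSE]  # moving
  if (qr(sweep(P, 2, colMeans(P)))$rank < 2)
    stop("degenerate (collinear) point set")
  kb <- kabsch(P, Q)
  moved <- Q %*% t(kb$R)
  moved <- sweep(moved, 2, kb$t, `+`)
  rmsd <- sqrt(mean(rowSums((moved - P)^2)))
  list(rotation = kb$R, translation = kb$t, rmsd = rmsd)
}

# Kabsch: proper rotation R and translation t minimizing ||(Q R^T + t) - P||
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(Q, 2, cq)) %*% sweep(P, 2, cp)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  list(R = R, t = as.numeric(cp - R %*% cq))
}

# apply a superposition result to a coordinate matrix
apply_transform <- function(xyz, tr) {
  sweep(xyz %*% t(tr$rotation), 2, tr$translation, `+`)
}

#' All-against-all RMSD matrix of bundles
#'
#' @param bundles list of [coord_set()]s.
#' @param labels optional names for rows/columns.
#' @return symmetric matrix of superposition RMSDs (Angstrom), zero
#'   diagonal; pairs with unequal point counts are `NA` (flagged, not
#'   dropped).
#' @export
rmsd_matrix <- function(bundles, labels = NULL) {
  n <- length(bundles)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    M[i, j] <- M[j, i] <- tryCatch(
      superpose(bundles[[i]], bundles[[j]])$rmsd,
      error = function(e) NA_real_)
  }
  if (!is.null(labels)) dimnames(M) <- list(labels, labels)
  M
}

#' TM-score of two structures under a fixed correspondence
#'
#' TM = (1 / L_norm) * sum over mapped pairs of 1 / (1 + (d_i / d0)^2),
#' maximized over rigid transforms, with d0 = 1.24 (L_norm - 15)^(1/3)
#' - 1.8 Angstrom. Unlike RMSD it is length-independent, which is why it
#' is preferred for comparing globular domains of different sizes. The
#' transform search starts from the whole-set superposition and iterates
#' trimmed superpositions on pairs closer than d0 (a documented
#' approximation to the published heuristic search); the best score seen
#' is returned.
#'
#' @param a,b [coord_set()]s or n x 3 matrices.
#' @param mapping as in [superpose()]; `NULL` for positional.
#' @param L_norm normalization length (default: number of mapped pairs);
#'   must be > 15 for the d0 formula.
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(a, b, mapping = NULL, L_norm = NULL) {
  A <- if (inherits(a, "coord_set")) a$xyz else as.matrix(a)
  B <- if (inherits(b, "coord_set")) b$xyz else as.matrix(b)
  if (is.null(mapping)) {
    if (nrow(A) != nrow(B))
      stop("positional mapping requires equal point counts")
    mapping <- cbind(seq_len(nrow(A)), seq_len(nrow(B)))
  }
  if (is.null(L_norm)) L_norm <- nrow(mapping)
  if (L_norm <= 15) stop("'L_norm' must exceed 15 (d0 formula domain)")
  d0 <- tm_d0(L_norm)
  P <- A[mapping[, 1], , drop = FALSE]
  Q <- B[mapping[, 2], , drop = FALSE]
  score_of <- function(tr) {
    d <- sqrt(rowSums((apply_transform(Q, tr) - P)^2))
    list(score = sum(1 / (1 + (d / d0)^2)) / L_norm, d = d)
  }
  tr <- superpose(P, Q)
  cur <- score_of(tr)
  best <- cur$score
  for (it in seq_len(50)) {
    keep <- which(cur$d < d0)
    if (length(keep) < 3) break
    tr2 <- tryCatch(superpose(P[keep, , drop = FALSE],
                              Q[keep, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(tr2)) break
    nxt <- score_of(tr2)
    if (nxt$score <= best + 1e-12) break
    best <- nxt$score
    cur <- nxt
  }
  best
}

#' d0 distance scale of the TM-score
#'
#' @param L normalization length (> 15).
#' @return 1.24 * (L - 15)^(1/3) - 1.8, in Angstrom.
#' @export
tm_d0 <- function(L) {
  stopifnot(L > 15)
  1.24 * (L - 15)^(1 / 3) - 1.8
}

#' Candidate disulfide pairs from Calpha positions
#'
#' All cysteine-cysteine pairs within `cutoff` Angstrom. At Calpha
#' resolution a disulfide-bonded pair sits around 4-6.5 Angstrom apart,
#' hence the generous default cutoff.
#'
#' @param coords a [coord_set()] whose labels include `resid` residue names
#'   (three-letter, "CYS") or one-letter ("C").
#' @param cutoff maximum Calpha-Calpha distance (default 7.5 Angstrom).
#' @return data.frame (`chain1`, `resno1`, `chain2`, `resno2`, `distance`,
#'   `intra_chain`).
#' @export
cys_pair_candidates <- function(coords, cutoff = 7.5) {
  stopifnot(inherits(coords, "coord_set"))
  if (is.null(coords$labels$resid))
    stop("residue identities ('resid') are required")
  is_cys <- toupper(coords$labels$resid) %in% c("CYS", "C")
  idx <- which(is_cys)
  out <- data.frame(chain1 = character(0), resno1 = integer(0),
                    chain2 = character(0), resno2 = integer(0),
                    distance = numeric(0), intra_chain = logical(0))
  if (length(idx) < 2) return(out)
  cmb <- utils::combn(idx, 2)
  for (c_i in seq_len(ncol(cmb))) {
    i <- cmb[1, c_i]; j <- cmb[2, c_i]
    d <- sqrt(sum((coords$xyz[i, ] - coords$xyz[j, ])^2))
    if (d <= cutoff) {
      out <- rbind(out, data.frame(
        chain1 = as.character(coords$labels$chain[i]),
        resno1 = coords$labels$resno[i],
        chain2 = as.character(coords$labels$chain[j]),
        resno2 = coords$labels$resno[j],
        distance = d,
        intra_chain = coords$labels$chain[i] == coords$labels$chain[j]))
    }
  }
  rownames(out) <- NULL
  out
}
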