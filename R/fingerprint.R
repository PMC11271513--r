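#' Surface-contact fingerprint bits for one snapshot
#'
#' A residue's surface-contact bit is set iff the smaller of the two probe
#' distances to the residue anchor is below `contact_cutoff`. Interaction
#' types beyond surface contact (hydrogen bonds, ionic, etc.) are part of
#' the fingerprint schema but have no detector in this coarse-grained model.
#'
#' @param snapshot A [ligand()].
#' @param residue_anchors Matrix of anchor coordinates with row names as
#'   residue labels (or a named list of coordinate vectors).
#' @param contact_cutoff Contact distance cutoff (> 0).
#' @return Named logical vector, one bit per residue.
#' @export
compute_bits <- function(snapshot, residue_anchors, contact_cutoff = 4.5) {
  stopifnot(inherits(snapshot, "ligand"))
  if (contact_cutoff <= 0) stop("`contact_cutoff` must be positive")
  a <- as_anchor_matrix(residue_anchors)
  if (ncol(a) != length(snapshot$probe_cf3)) stop("anchor dimension mismatch")
  d1 <- sqrt(rowSums((a - matrix(snapshot$probe_cf3, nrow(a), ncol(a),
                                 byrow = TRUE))^2))
  d2 <- sqrt(rowSums((a - matrix(snapshot$probe_o1, nrow(a), ncol(a),
                                 byrow = TRUE))^2))
  stats::setNames(pmin(d1, d2) < contact_cutoff, rownames(a))
}

#' Fingerprint matrix of a trajectory
#'
#' Applies [compute_bits()] to every frame.
#'
#' @param trajectory A `trajectory` (typically subsampled snapshots).
#' @param residue_anchors As in [compute_bits()].
#' @param contact_cutoff Contact cutoff.
#' @param ligand_id Label for the ligand the snapshots belong to.
#' @return A `fingerprint_matrix`: logical snapshots x residue-bits matrix
#'   with attributes `ligand_id` and `interaction_type`.
#' @export
compute_fingerprints <- function(trajectory, residue_anchors,
                                 contact_cutoff = 4.5, ligand_id = "ligand") {
  a <- as_anchor_matrix(residue_anchors)
  n <- n_frames(trajectory)
  m <- matrix(FALSE, n, nrow(a), dimnames = list(NULL, rownames(a)))
  for (i in seq_len(n))
    m[i, ] <- compute_bits(trajectory_frame(trajectory, i), a, contact_cutoff)
  fingerprint_matrix(m, ligand_id = ligand_id)
}

#' Construct a fingerprint matrix
#'
#' @param bits Logical snapshots x residue-bits matrix with unique column
#'   names.
#' @param ligand_id Ligand label.
#' @param interaction_type One of `"surface_contact"`, `"hbond_donor"`,
#'   `"hbond_acceptor"`, `"ionic"` (applied to all columns).
#' @return A `fingerprint_matrix`.
#' @export
fingerprint_matrix <- function(bits, ligand_id = "ligand",
                               interaction_type = "surface_contact") {
  interaction_type <- match.arg(interaction_type,
                                c("surface_contact", "hbond_donor",
                                  "hbond_acceptor", "ionic"))
  if (!is.matrix(bits) || !is.logical(bits)) stop("`bits` must be logical matrix")
  if (is.null(colnames(bits)) || anyDuplicated(colnames(bits)))
    stop("residue-bit columns must have unique names")
  structure(bits, ligand_id = ligand_id, interaction_type = interaction_type,
            class = c("fingerprint_matrix", class(bits)))
}

#' Tally fingerprint bits
#'
#' Per residue-bit, `Cb` is the number of snapshots with the bit set and
#' `C0` the total snapshot count, following the usual interaction-fingerprint
#' bookkeeping.
#'
#' @param matrix A [fingerprint_matrix()].
#' @return A `bit_counts` list: `Cb` (named integer vector), `C0`,
#'   `ligand_id`.
#' @export
tally_bits <- function(matrix) {
  if (nrow(matrix) == 0) stop("empty fingerprint matrix")
  structure(list(Cb = colSums(matrix), C0 = nrow(matrix),
                 ligand_id = attr(matrix, "ligand_id"),
                 interaction_type = attr(matrix, "interaction_type")),
            class = "bit_counts")
}

#' Comparative fingerprint statistic Qb between two ligands
#'
#' For each residue bit with per-ligand occurrence probabilities
#' `pA = Cb_A / C0_A` and `pB = Cb_B / C0_B`:
#' \deqn{P_b = p_A / (p_A + p_B), \qquad
#'       Q_b = p_A \cdot 2 (P_b - 1/2),}
#' with `Pb = 1/2` (hence `Qb = 0`) when both probabilities are zero. `Qb`
#' lies in `[-1, 1]`; positive values mark residues contacted more often by
#' ligand A, and the statistic is directional (it scores ligand A against
#' ligand B, weighting by ligand A's own contact frequency).
#'
#' @param counts_a,counts_b [tally_bits()] results over the same residue
#'   bits.
#' @return A `qb_table` data frame: `residue`, `Pb`, `Qb`, sorted by `Qb`
#'   descending (ties by residue label).
#' @export
qb_score <- function(counts_a, counts_b) {
  stopifnot(inherits(counts_a, "bit_counts"), inherits(counts_b, "bit_counts"))
  if (!identical(names(counts_a$Cb), names(counts_b$Cb)))
    stop("residue bits differ between the two ligands")
  pa <- counts_a$Cb / counts_a$C0
  pb <- counts_b$Cb / counts_b$C0
  prel <- ifelse(pa + pb == 0, 0.5, pa / (pa + pb))
  qb <- pa * 2 * (prel - 0.5)
  type <- counts_a$interaction_type
  out <- data.frame(residue = names(counts_a$Cb),
                    type = if (is.null(type)) "surface_contact" else type,
                    Pb = unname(prel), Qb = unname(qb))
  out <- out[order(-out$Qb, out$residue), ]
  rownames(out) <- NULL
  class(out) <- c("qb_table", "data.frame")
  out
}

#' Rank residues by Qb
#'
#' @param table A [qb_score()] result.
#' @param top_n Optionally keep only the first `top_n` residues.
#' @return Character vector of residue labels, Qb descending, ties broken by
#'   label.
#' @export
rank_residues <- function(table, top_n = NULL) {
  if (nrow(table) == 0) stop("empty Qb table")
  ord <- table$residue[order(-table$Qb, table$residue)]
  if (!is.null(top_n)) ord <- utils::head(ord, top_n)
  ord
}

as_anchor_matrix <- function(residue_anchors) {
  if (is.matrix(residue_anchors)) {
    a <- residue_anchors
  } else if (is.list(residue_anchors)) {
    a <- do.call(rbind, residue_anchors)
    rownames(a) <- names(residue_anchors)
  } else stop("`residue_anchors` must be a matrix or named list")
  if (is.null(rownames(a))) rownames(a) <- paste0("res", seq_len(nrow(a)))
  a
}
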