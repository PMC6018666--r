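# Geometry primitives: ring centroids, superposed backbone RMSD, rigid and
# torsion moves over a RigidGroupPartition.

# Fixed ring-atom name sets per residue type. Phe uses the six-membered
# phenyl ring; purines the six-membered pyrimidine-type ring (the ring that
# stacks on Phe); pyrimidines their single ring.
.RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  A = c("N1", "C2", "N3", "C4", "C5", "C6"),
  G = c("N1", "C2", "N3", "C4", "C5", "C6"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"),
  U = c("N1", "C2", "N3", "C4", "C5", "C6")
)

#' Centroid of an aromatic ring
#'
#' Arithmetic centroid of the named ring atoms of a residue: the phenyl ring
#' for Phe, the six-membered ring for purines and pyrimidines. Used by the
#' stacking-interface restraints, which act on ring-center distances.
#'
#' @param model an `AtomicModel`.
#' @param chain chain id.
#' @param resno residue number.
#' @return length-3 numeric vector (Angstrom).
#' @export
ring_center <- function(model, chain, resno) {
  sel <- model$atoms$chain == chain & model$atoms$resno == resno
  if (!any(sel)) stop("no atoms for residue ", chain, ":", resno)
  resname <- model$atoms$resname[sel][1]
  ring <- .RING_ATOMS[[resname]]
  if (is.null(ring)) {
    stop("no ring definition for residue type ", resname,
         " (", chain, ":", resno, ")")
  }
  idx <- .atom_idx(model, chain = chain, resno = resno, names = ring)
  have <- model$atoms$name[idx]
  missing <- setdiff(ring, have)
  if (length(missing) > 0) {
    stop("residue ", chain, ":", resno, " (", resname,
         ") is missing ring atoms: ", paste(missing, collapse = ", "))
  }
  colMeans(coords(model, idx))
}

# Backbone atom names for a chain role.
.backbone_names <- function(role) {
  if (role == "protein") .BACKBONE_PROTEIN else .BACKBONE_RNA
}

# Matched backbone coordinate matrices for two models over a selection.
.matched_backbone <- function(model_a, model_b, selection = NULL) {
  pick <- function(model) {
    idx <- if (is.null(selection)) seq_len(nrow(model$atoms)) else
      .selection_idx(model, selection)
    a <- model$atoms[idx, ]
    if (nrow(a) == 0) return(a)
    keep <- mapply(function(ch, nm) nm %in% .backbone_names(model$roles[ch]),
                   a$chain, a$name)
    a[keep, ]
  }
  aa <- pick(model_a)
  bb <- pick(model_b)
  if (nrow(aa) == 0 || nrow(bb) == 0) stop("empty backbone selection")
  ka <- paste(aa$chain, aa$resno, aa$name)
  kb <- paste(bb$chain, bb$resno, bb$name)
  unmatched <- c(setdiff(ka, kb), setdiff(kb, ka))
  if (length(unmatched) > 0) {
    stop("unmatched backbone atoms: ",
         paste(utils::head(unmatched, 8), collapse = "; "))
  }
  bb <- bb[match(ka, kb), ]
  list(a = as.matrix(aa[c("x", "y", "z")]),
       b = as.matrix(bb[c("x", "y", "z")]))
}

#' Backbone RMSD between two models
#'
#' Root-mean-square deviation over backbone atoms (N, CA, C, O for protein;
#' P, O5', C5', C4', C3', O3' for RNA) matched one-to-one by
#' (chain, residue, atom name). With `superpose = TRUE` the optimal
#' least-squares (Kabsch) superposition is applied first, all atoms weighted
#' equally.
#'
#' @param model_a,model_b `AtomicModel`s.
#' @param selection optional selection (string in the
#'   `"chain:from-to[:atoms]"` mini-language, or a parsed selection table);
#'   `NULL` means all residues.
#' @param superpose logical; superpose before computing the RMSD.
#' @return RMSD in Angstrom.
#' @export
backbone_rmsd <- function(model_a, model_b, selection = NULL,
                          superpose = TRUE) {
  m <- .matched_backbone(model_a, model_b, selection)
  xa <- as.vector(t(m$a))
  xb <- as.vector(t(m$b))
  as.numeric(bio3d::rmsd(xa, xb, fit = superpose))
}

#' Apply a rigid-body or torsion move
#'
#' A rigid move rotates a named group about its centroid by a proper
#' rotation matrix and then translates it; intra-group distances are
#' preserved to machine precision. A torsion move rotates everything
#' C-terminal of a linker backbone torsion axis (phi: N-CA; psi: CA-C),
#' including rigid groups whose protein residues all lie downstream (their
#' RNA passengers ride along).
#'
#' @param model an `AtomicModel`.
#' @param partition a `RigidGroupPartition`.
#' @param group name of the rigid group to move (rigid mode).
#' @param rotation 3x3 proper rotation matrix (determinant +1).
#' @param translation length-3 translation vector in Angstrom.
#' @param torsions data.frame with columns `resno`, `dihedral`, `delta_deg`
#'   (torsion mode); applied in order.
#' @return the moved `AtomicModel`.
#' @export
apply_move <- function(model, partition, group = NULL,
                       rotation = diag(3), translation = c(0, 0, 0),
                       torsions = NULL) {
  if (!is.null(torsions)) {
    for (i in seq_len(nrow(torsions))) {
      model <- .apply_torsion(model, partition, torsions$resno[i],
                              torsions$dihedral[i], torsions$delta_deg[i])
    }
    return(model)
  }
  if (is.null(group)) stop("either a group or torsions must be given")
  if (!group %in% names(partition$groups)) {
    stop("unknown rigid group: ", group)
  }
  if (abs(det(rotation) - 1) > 1e-8) {
    stop("rotation must be proper (determinant +1)")
  }
  g <- partition$groups[[group]]
  idx <- integer(0)
  for (i in seq_len(nrow(g))) {
    idx <- c(idx, .atom_idx(model, chain = g$chain[i], resno = g$resno[i]))
  }
  xyz <- coords(model, idx)
  ctr <- colMeans(xyz)
  moved <- sweep(sweep(xyz, 2, ctr) %*% t(rotation), 2, ctr + translation, "+")
  model$atoms[idx, c("x", "y", "z")] <- moved
  model
}

# Atoms C-terminal of a torsion axis on the protein chain: for phi(i) the
# axis is N(i)->CA(i) and C(i), O(i) plus residues > i rotate; for psi(i)
# the axis is CA(i)->C(i) and O(i) plus residues > i rotate. Rigid groups
# whose protein residues all lie downstream carry their non-protein
# members with them.
.apply_torsion <- function(model, partition, resno, dihedral, delta_deg) {
  ch <- partition$protein_chain
  atom_xyz <- function(nm) {
    i <- .atom_idx(model, chain = ch, resno = resno, names = nm)
    if (length(i) != 1) stop("torsion axis atom ", nm, " missing at ",
                             ch, ":", resno)
    coords(model, i)[1, ]
  }
  if (dihedral == "phi") {
    p0 <- atom_xyz("N"); p1 <- atom_xyz("CA")
    local_names <- c("C", "O")
  } else if (dihedral == "psi") {
    p0 <- atom_xyz("CA"); p1 <- atom_xyz("C")
    local_names <- "O"
  } else {
    stop("unknown dihedral '", dihedral, "'")
  }
  idx <- c(
    .atom_idx(model, chain = ch, resno = resno, names = local_names),
    which(model$atoms$chain == ch & model$atoms$resno > resno)
  )
  for (gname in names(partition$groups)) {
    g <- partition$groups[[gname]]
    prot <- g$resno[g$chain == ch]
    if (length(prot) > 0 && all(prot > resno)) {
      other <- g[g$chain != ch, ]
      for (i in seq_len(nrow(other))) {
        idx <- c(idx, .atom_idx(model, chain = other$chain[i],
                                resno = other$resno[i]))
      }
    }
  }
  idx <- sort(unique(idx))
  if (length(idx) == 0) return(model)
  R <- rotation_about_axis(p1 - p0, delta_deg * pi / 180)
  xyz <- coords(model, idx)
  model$atoms[idx, c("x", "y", "z")] <-
    sweep(sweep(xyz, 2, p1) %*% t(R), 2, p1, "+")
  model
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `angle` radians about `axis` (need not be unit
#' length).
#'
#' @param axis length-3 direction vector.
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
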