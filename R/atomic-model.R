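# Atomic-model data layer: container, validation, chain roles, selections.

# Residue-name tables used to infer chain roles.
.PROTEIN_RESNAMES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)
.RNA_RESNAMES <- c("A", "C", "G", "U", "RA", "RC", "RG", "RU")

.BACKBONE_PROTEIN <- c("N", "CA", "C", "O")
.BACKBONE_RNA <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'")

#' Construct an atomic model
#'
#' An `AtomicModel` is the coordinate container used throughout the package:
#' a table of atoms (serial, name, element, residue number/name, chain,
#' Cartesian coordinates in Angstrom) plus annotations: the role of each
#' chain (protein or RNA), secondary-structure segments and the flexible
#' linker range of the protein chain.
#'
#' @param atoms data.frame with columns `serial`, `name`, `elem`, `resno`,
#'   `resname`, `chain`, `x`, `y`, `z`.
#' @param roles named character vector mapping chain id to `"protein"` or
#'   `"rna"`. If `NULL`, roles are inferred from residue names (standard
#'   amino acids -> protein, A/C/G/U -> RNA).
#' @param ss_segments optional data.frame of secondary-structure segments
#'   with columns `chain`, `from`, `to` (residue numbers, inclusive).
#' @param linker optional length-2 integer vector, the residue range of the
#'   flexible inter-domain linker on the protein chain.
#' @return an object of class `AtomicModel`.
#' @export
atomic_model <- function(atoms, roles = NULL, ss_segments = NULL,
                         linker = NULL) {
  required <- c("serial", "name", "elem", "resno", "resname", "chain",
                "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atoms table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  atoms <- as.data.frame(atoms)[required]
  atoms$name <- as.character(atoms$name)
  atoms$elem <- as.character(atoms$elem)
  atoms$resname <- as.character(atoms$resname)
  atoms$chain <- as.character(atoms$chain)
  if (nrow(atoms) == 0) stop("empty atom table")
  xyz <- as.matrix(atoms[c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in atom table")
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue, atom name): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  if (is.null(roles)) roles <- infer_chain_roles(atoms)
  chains <- unique(atoms$chain)
  if (!all(chains %in% names(roles))) {
    stop("chains without a role assignment: ",
         paste(setdiff(chains, names(roles)), collapse = ", "))
  }
  if (!all(roles %in% c("protein", "rna"))) {
    stop("chain roles must be 'protein' or 'rna'")
  }
  structure(
    list(atoms = atoms, roles = roles, ss_segments = ss_segments,
         linker = linker),
    class = "AtomicModel"
  )
}

#' Infer chain roles from residue names
#'
#' Standard amino-acid residue names map to `"protein"`, single-letter
#' ribonucleotide names (A, C, G, U) to `"rna"`. A chain with a mixture or
#' with unrecognized residue names is an error.
#'
#' @param atoms atom table as in [atomic_model()].
#' @return named character vector chain -> role.
#' @export
infer_chain_roles <- function(atoms) {
  chains <- unique(atoms$chain)
  roles <- vapply(chains, function(ch) {
    res <- unique(atoms$resname[atoms$chain == ch])
    is_prot <- res %in% .PROTEIN_RESNAMES
    is_rna <- res %in% .RNA_RESNAMES
    if (all(is_prot)) return("protein")
    if (all(is_rna)) return("rna")
    stop("cannot infer role of chain ", ch, ": residues ",
         paste(res[!(is_prot | is_rna)], collapse = ", "),
         " are neither standard amino acids nor A/C/G/U")
  }, character(1))
  names(roles) <- chains
  roles
}

#' @export
print.AtomicModel <- function(x, ...) {
  cat("AtomicModel:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chain(s)\n")
  for (ch in names(x$roles)) {
    sel <- x$atoms$chain == ch
    cat(sprintf("  chain %s (%s): %d atoms, residues %d-%d\n",
                ch, x$roles[ch], sum(sel),
                min(x$atoms$resno[sel]), max(x$atoms$resno[sel])))
  }
  if (!is.null(x$linker)) {
    cat("  linker residues:", x$linker[1], "-", x$linker[2], "\n")
  }
  invisible(x)
}

#' Coordinate matrix of a model
#'
#' @param model an `AtomicModel`.
#' @param idx optional row indices into the atom table.
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(model, idx = NULL) {
  m <- as.matrix(model$atoms[c("x", "y", "z")])
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  m
}

# Row indices of atoms matching (chain, resno in range, optional atom names).
.atom_idx <- function(model, chain = NULL, resno = NULL, names = NULL) {
  keep <- rep(TRUE, nrow(model$atoms))
  if (!is.null(chain)) keep <- keep & model$atoms$chain %in% chain
  if (!is.null(resno)) keep <- keep & model$atoms$resno %in% resno
  if (!is.null(names)) keep <- keep & model$atoms$name %in% names
  which(keep)
}

#' Parse a selection expression
#'
#' Selections use the mini-language `"chain:from-to[:atoms]"`, e.g.
#' `"A:1-24"` or `"A:25-34:N,CA,C,O"`; several comma-free segments can be
#' combined in a character vector. `"chain:*"` selects a whole chain.
#'
#' @param sel character vector of selection segments.
#' @return data.frame with columns `chain`, `resno`, `name` (`NA` name means
#'   any atom of the residue).
#' @export
parse_selection <- function(sel) {
  out <- lapply(sel, function(s) {
    parts <- strsplit(s, ":", fixed = TRUE)[[1]]
    if (length(parts) < 2 || length(parts) > 3) {
      stop("malformed selection '", s, "': expected chain:from-to[:atoms]")
    }
    chain <- parts[1]
    if (parts[2] == "*") {
      resno <- NA_integer_
    } else {
      rng <- suppressWarnings(
        as.integer(strsplit(parts[2], "-", fixed = TRUE)[[1]]))
      if (length(rng) == 1) rng <- c(rng, rng)
      if (length(rng) != 2 || any(is.na(rng))) {
        stop("malformed residue range in selection '", s, "'")
      }
      resno <- seq(rng[1], rng[2])
    }
    atoms <- if (length(parts) == 3) {
      strsplit(parts[3], ",", fixed = TRUE)[[1]]
    } else {
      NA_character_
    }
    expand.grid(chain = chain, resno = resno, name = atoms,
                stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Resolve a parsed selection (or selection string) to atom-table row indices.
.selection_idx <- function(model, sel) {
  if (is.character(sel)) sel <- parse_selection(sel)
  idx <- integer(0)
  for (i in seq_len(nrow(sel))) {
    chain <- sel$chain[i]
    resno <- if (is.na(sel$resno[i])) NULL else sel$resno[i]
    nm <- if (is.na(sel$name[i])) NULL else sel$name[i]
    idx <- c(idx, .atom_idx(model, chain = chain, resno = resno, names = nm))
  }
  sort(unique(idx))
}

#' Rigid-group partition of a model
#'
#' Describes the degrees of freedom used in refinement: named rigid groups
#' (residue sets, possibly spanning chains -- RNA nucleotides bound to a
#' domain ride with that domain) and the flexible backbone torsions of the
#' linker.
#'
#' @param groups named list; each element a data.frame with columns `chain`,
#'   `resno` listing the residues of that rigid group.
#' @param flexible data.frame with columns `resno`, `dihedral`
#'   (`"phi"` or `"psi"`) for the movable linker torsions (protein chain).
#' @param protein_chain chain id carrying the torsions.
#' @param linker length-2 residue range of the linker; every flexible
#'   torsion must lie inside it.
#' @param model optional `AtomicModel` used to check coverage: groups must
#'   be disjoint and, together with the linker, cover all residues.
#' @return object of class `RigidGroupPartition`.
#' @export
rigid_partition <- function(groups, flexible, protein_chain, linker,
                            model = NULL) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  keys <- unlist(lapply(groups, function(g) paste(g$chain, g$resno)))
  if (anyDuplicated(keys)) stop("rigid groups are not disjoint")
  if (!all(flexible$dihedral %in% c("phi", "psi"))) {
    stop("dihedral names must be 'phi' or 'psi'")
  }
  if (any(flexible$resno < linker[1] | flexible$resno > linker[2])) {
    stop("flexible torsions outside the annotated linker range")
  }
  if (!is.null(model)) {
    all_res <- unique(model$atoms[c("chain", "resno")])
    covered <- paste(all_res$chain, all_res$resno) %in%
      c(keys, paste(protein_chain, seq(linker[1], linker[2])))
    if (!all(covered)) {
      stop("residues not covered by groups or linker: ",
           paste(utils::head(paste(all_res$chain, all_res$resno)[!covered], 5),
                 collapse = "; "))
    }
  }
  structure(
    list(groups = groups, flexible = flexible,
         protein_chain = protein_chain, linker = linker),
    class = "RigidGroupPartition"
  )
}
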