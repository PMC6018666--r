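# PDB coordinate I/O. Parsing and writing go through bio3d; this layer adds
# strict validation (malformed records and insertion codes are rejected with
# the offending line number) and converts to/from the AtomicModel container.

#' Read an atomic model from a PDB file
#'
#' Reads `ATOM`/`HETATM` records, infers chain roles from residue names and
#' returns an [atomic_model()]. Files with insertion codes or records whose
#' coordinate fields do not parse are rejected with an error naming the
#' offending line. Coordinates round-trip through [write_pdb()] to three
#' decimals.
#'
#' @param path path to a PDB-format file.
#' @param roles optional explicit chain-role vector (see [atomic_model()]).
#' @return an `AtomicModel`.
#' @export
read_pdb <- function(path, roles = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM") |
    substr(lines, 1, 5) == "ATOM "
  if (length(lines) == 0 || !any(is_atom)) {
    stop("no ATOM/HETATM records in ", path)
  }
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop("malformed PDB record at line ", i, ": too short")
    }
    xyz <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54)
    )))
    if (any(is.na(xyz))) {
      stop("malformed PDB record at line ", i,
           ": coordinate fields do not parse")
    }
    if (substr(ln, 27, 27) != " ") {
      stop("insertion codes are not supported (line ", i, ")")
    }
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  elem <- at$elesy
  blank <- is.na(elem) | trimws(elem) == ""
  elem[blank] <- .elem_from_name(at$elety[blank])
  atoms <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    elem = trimws(elem),
    resno = at$resno,
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  atomic_model(atoms, roles = roles)
}

# Element symbol from an atom name (first alphabetic character, with the
# usual two-letter cases not needed for protein/RNA heavy atoms + H).
.elem_from_name <- function(name) {
  nm <- gsub("[^A-Za-z].*$", "", gsub("^[0-9]*", "", trimws(name)))
  substr(nm, 1, 1)
}

#' Write an atomic model to a PDB file
#'
#' @param model an `AtomicModel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  a <- model$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(as.matrix(a[c("x", "y", "z")]))),
    resno = a$resno, resid = a$resname, eleno = a$serial,
    elety = a$name, chain = a$chain, elesy = a$elem
  )
  invisible(path)
}
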