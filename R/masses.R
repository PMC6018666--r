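# Average molecular masses of protein and RNA chains, used for the
# static-light-scattering stoichiometry check (a 1:1 complex has the sum
# of the component masses).

# Standard average residue masses (Da): amino-acid residues within a
# peptide chain (monomer minus water).
.AA_RESIDUE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
.WATER_MASS <- 18.0153

# Average internal-residue masses (Da) of ribonucleotides
# (nucleoside-5'-monophosphate minus water) and the 5'-phosphate mass
# removed for synthetic 5'-OH oligonucleotides.
.NT_RESIDUE_MASS <- c(A = 329.2059, C = 305.1808, G = 345.2053,
                      U = 306.1653)
.HPO3_MASS <- 79.9799

#' Average mass of a protein sequence
#'
#' @param seq one-letter amino-acid string or character vector.
#' @return mass in Da.
#' @export
protein_mass <- function(seq) {
  aa <- if (length(seq) == 1) strsplit(seq, "")[[1]] else seq
  aa <- toupper(aa[aa != ""])
  unknown <- setdiff(aa, names(.AA_RESIDUE_MASS))
  if (length(unknown) > 0) {
    stop("unknown residues: ", paste(unknown, collapse = ", "))
  }
  sum(.AA_RESIDUE_MASS[aa]) + .WATER_MASS
}

#' Average mass of an RNA sequence
#'
#' @param seq RNA sequence (A/C/G/U).
#' @param five_prime `"OH"` for chemically synthesized oligos (default) or
#'   `"phosphate"` for transcripts.
#' @return mass in Da.
#' @export
rna_mass <- function(seq, five_prime = c("OH", "phosphate")) {
  five_prime <- match.arg(five_prime)
  nt <- if (length(seq) == 1) strsplit(toupper(seq), "")[[1]] else
    toupper(seq)
  unknown <- setdiff(nt, names(.NT_RESIDUE_MASS))
  if (length(unknown) > 0) {
    stop("unknown nucleotides: ", paste(unknown, collapse = ", "))
  }
  m <- sum(.NT_RESIDUE_MASS[nt]) + .WATER_MASS
  if (five_prime == "OH") m <- m - .HPO3_MASS
  m
}

#' The tandem-RRM fragment (UP1) sequence
#'
#' Residues 1-196 of human hnRNP A1 (UniProt P09651), shipped as a
#' plain-text FASTA. [up1_checkpoints()] lists the residue identities that
#' pin the sequence (RNP aromatics, interface salt-bridge residues, the
#' spin-label site and the native cysteines); `up1_sequence()` validates
#' all of them on load.
#'
#' @return character scalar, the 196-residue sequence.
#' @export
up1_sequence <- function() {
  path <- system.file("extdata", "up1_hnrnpa1_1-196.fasta",
                      package = "metafold")
  lines <- readLines(path)
  seq <- paste(lines[!startsWith(lines, ">")], collapse = "")
  if (nchar(seq) != 196) stop("expected 196 residues, got ", nchar(seq))
  cp <- up1_checkpoints()
  got <- substring(seq, cp$resno, cp$resno)
  bad <- got != cp$aa
  if (any(bad)) {
    stop("sequence checkpoints violated at residues ",
         paste(cp$resno[bad], collapse = ", "))
  }
  seq
}

#' @rdname up1_sequence
#' @export
up1_checkpoints <- function() {
  data.frame(
    resno = c(15, 17, 43, 55, 57, 59, 66, 75, 85, 87, 88, 106, 108, 146,
              148, 150, 155, 157, 175, 176, 178, 179),
    aa = c("K", "F", "C", "R", "F", "F", "E", "R", "E", "K", "R", "K",
           "F", "R", "F", "F", "D", "D", "C", "E", "R", "K"),
    stringsAsFactors = FALSE
  )
}

#' Theoretical mass of the 1:1 protein-RNA complex
#'
#' Sum of the average masses of the UP1 fragment and a bound RNA
#' (default: the 12-mer AGUAGAUUAGCA), the quantity compared against the
#' static-light-scattering estimate to establish 1:1 stoichiometry.
#'
#' @param rna_seq RNA sequence.
#' @return list with `protein_Da`, `rna_Da`, `complex_kDa`.
#' @export
complex_mass <- function(rna_seq = "AGUAGAUUAGCA") {
  p <- protein_mass(up1_sequence())
  r <- rna_mass(rna_seq)
  list(protein_Da = p, rna_Da = r, complex_kDa = (p + r) / 1000)
}
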