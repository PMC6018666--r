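# Residual dipolar couplings: alignment-tensor (Saupe) fitting by singular
# value decomposition, back-calculation, Q-factor, the two-replica average
# and the correlation-based refinement restraint.

#' Construct an RDC set
#'
#' A table of measured couplings, one row per bond: chain, residue and the
#' two atom names defining the bond vector (amide N-H by default), the
#' coupling in Hz and an optional uncertainty.
#'
#' @param chain,resno,atom1,atom2 bond identity vectors.
#' @param D measured couplings (Hz).
#' @param sigma optional uncertainties (Hz, > 0).
#' @return object of class `RDCSet` (a data.frame).
#' @export
rdc_set <- function(chain, resno, atom1 = "N", atom2 = "H", D,
                    sigma = NULL) {
  n <- max(length(resno), length(D))
  D <- rep_len(D, n)
  out <- data.frame(chain = rep_len(as.character(chain), n),
                    resno = rep_len(resno, n),
                    atom1 = rep_len(atom1, n), atom2 = rep_len(atom2, n),
                    D = D)
  if (!is.null(sigma)) {
    if (any(sigma <= 0)) stop("RDC uncertainties must be > 0")
    out$sigma <- rep_len(sigma, n)
  }
  class(out) <- c("RDCSet", "data.frame")
  out
}

#' Read/write RDC tables
#'
#' Whitespace text with columns `chain resid atom1 atom2 D [sigma]` and
#' `#` comments.
#'
#' @param path file path.
#' @return [read_rdc()] returns an `RDCSet`.
#' @export
read_rdc <- function(path) {
  tab <- utils::read.table(path, comment.char = "#", fill = TRUE,
                           col.names = c("chain", "resno", "atom1",
                                         "atom2", "D", "sigma")[1:6])
  sigma <- if (!all(is.na(tab$sigma))) tab$sigma else NULL
  rdc_set(tab$chain, tab$resno, tab$atom1, tab$atom2, tab$D, sigma)
}

#' @rdname read_rdc
#' @param rdcs an `RDCSet`.
#' @export
write_rdc <- function(rdcs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# chain resid atom1 atom2 D sigma", con)
  utils::write.table(as.data.frame(rdcs), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

# Unit bond vectors for an RDC set resolved in a model. Errors list every
# bond whose atoms are missing.
.bond_vectors <- function(model, rdcs) {
  n <- nrow(rdcs)
  B <- matrix(NA_real_, n, 3)
  missing <- character(0)
  for (i in seq_len(n)) {
    i1 <- .atom_idx(model, chain = rdcs$chain[i], resno = rdcs$resno[i],
                    names = rdcs$atom1[i])
    i2 <- .atom_idx(model, chain = rdcs$chain[i], resno = rdcs$resno[i],
                    names = rdcs$atom2[i])
    if (length(i1) != 1 || length(i2) != 1) {
      missing <- c(missing, paste0(rdcs$chain[i], ":", rdcs$resno[i], ":",
                                   rdcs$atom1[i], "-", rdcs$atom2[i]))
      next
    }
    v <- coords(model, i2)[1, ] - coords(model, i1)[1, ]
    B[i, ] <- v / sqrt(sum(v^2))
  }
  if (length(missing) > 0) {
    stop("bonds not resolvable in model: ", paste(missing, collapse = "; "))
  }
  B
}

# Design matrix of the linear Saupe problem for unit bond vectors b:
# D = Szz' parametrized by the 5 independent components
# (Sxx - Szz implicit through tracelessness):
# D_i = Sxx (x^2 - z^2) + Syy (y^2 - z^2) + 2 Sxy xy + 2 Sxz xz + 2 Syz yz
.saupe_design <- function(B) {
  x <- B[, 1]; y <- B[, 2]; z <- B[, 3]
  cbind(x^2 - z^2, y^2 - z^2, 2 * x * y, 2 * x * z, 2 * y * z)
}

.saupe_matrix <- function(s) {
  S <- matrix(c(s[1], s[3], s[4],
                s[3], s[2], s[5],
                s[4], s[5], -s[1] - s[2]), 3, 3, byrow = TRUE)
  S
}

#' Fit the alignment tensor by singular value decomposition
#'
#' Least-squares Saupe tensor of an RDC set against a model: the
#' dipolar-interaction prefactor and bond-length term are absorbed into the
#' tensor scale, so fitted couplings are directly in Hz and
#' `D_calc_i = b_i' S b_i` for unit bond vectors `b_i`. Also returns the
#' quality-of-fit Q-factor `sqrt(sum (D_calc - D_exp)^2 / sum D_exp^2)` and
#' the Pearson correlation.
#'
#' @param model an `AtomicModel`.
#' @param rdcs an `RDCSet` with at least 5 bonds of full orientational rank.
#' @return list with `tensor` (class `AlignmentTensor`: the traceless
#'   symmetric 3x3 Saupe matrix with derived axial component `Da` and
#'   rhombicity `R`), `D_calc`, `Q`, `r` and `residual` (sum of squares).
#' @export
fit_tensor_svd <- function(model, rdcs) {
  if (nrow(rdcs) < 5) {
    stop("under-determined tensor: at least 5 bonds are required")
  }
  B <- .bond_vectors(model, rdcs)
  A <- .saupe_design(B)
  sv <- svd(A)
  if (sum(sv$d > max(sv$d) * 1e-10) < 5) {
    stop("under-determined tensor: bond orientations have rank < 5")
  }
  s <- sv$v %*% (crossprod(sv$u, rdcs$D) / sv$d)
  S <- .saupe_matrix(drop(s))
  D_calc <- rowSums((B %*% S) * B)
  ev <- eigen(S, symmetric = TRUE)$values
  ev <- ev[order(abs(ev))]  # |Sxx| <= |Syy| <= |Szz| convention
  Szz <- ev[3]; Syy <- ev[2]; Sxx <- ev[1]
  Da <- Szz / 2
  Rh <- if (Szz != 0) (Sxx - Syy) / (1.5 * Szz) else NA_real_
  tensor <- structure(list(S = S, Da = Da, rhombicity = Rh,
                           eigenvalues = c(Sxx, Syy, Szz)),
                      class = "AlignmentTensor")
  resid <- rdcs$D - D_calc
  list(tensor = tensor, D_calc = D_calc,
       Q = sqrt(sum(resid^2) / sum(rdcs$D^2)),
       r = stats::cor(D_calc, rdcs$D),
       residual = sum(resid^2))
}

#' Back-calculate couplings from a tensor
#'
#' @param model an `AtomicModel`.
#' @param rdcs an `RDCSet` naming the bonds.
#' @param tensor an `AlignmentTensor` or a 3x3 Saupe matrix.
#' @return numeric vector of couplings (Hz).
#' @export
back_calc_rdc <- function(model, rdcs, tensor) {
  S <- if (inherits(tensor, "AlignmentTensor")) tensor$S else tensor
  B <- .bond_vectors(model, rdcs)
  rowSums((B %*% S) * B)
}

#' Average couplings over two replicas
#'
#' Element-wise arithmetic mean of the couplings back-calculated from two
#' replica models, which accounts for multiple possible alignments of the
#' complex in the medium.
#'
#' @param rep1,rep2 numeric coupling vectors or `RDCSet`s over the same
#'   bond list.
#' @return numeric vector (or `RDCSet` if both inputs are `RDCSet`s).
#' @export
replica_average <- function(rep1, rep2) {
  if (inherits(rep1, "RDCSet") && inherits(rep2, "RDCSet")) {
    k1 <- paste(rep1$chain, rep1$resno, rep1$atom1, rep1$atom2)
    k2 <- paste(rep2$chain, rep2$resno, rep2$atom1, rep2$atom2)
    if (!identical(k1, k2)) stop("replica bond lists differ")
    out <- rep1
    out$D <- (rep1$D + rep2$D) / 2
    return(out)
  }
  if (length(rep1) != length(rep2)) stop("replica bond lists differ")
  (rep1 + rep2) / 2
}

#' Correlation-based RDC restraint energy
#'
#' Linear restraint on the Pearson correlation between replica-averaged
#' calculated couplings and the experimental ones:
#' `E = slope * cor(calc, exp)`. With the default slope of -20000 kJ/mol the
#' energy is minimized (-20000 kJ/mol) at perfect correlation.
#'
#' @param calc_avg replica-averaged calculated couplings.
#' @param exp experimental couplings.
#' @param slope restraint slope in kJ/mol.
#' @return energy in kJ/mol.
#' @export
rdc_correlation_energy <- function(calc_avg, exp, slope = -20000) {
  if (length(calc_avg) < 3) stop("at least 3 bonds are required")
  if (stats::sd(calc_avg) == 0 || stats::sd(exp) == 0) {
    stop("zero variance in couplings: correlation undefined")
  }
  slope * stats::cor(calc_avg, exp)
}
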