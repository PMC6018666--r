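# Hybrid energy: Bayesian metainference data terms (representative SAXS
# intensities with a Gaussian likelihood per point and a bounded scale
# nuisance), the correlation-based RDC term, harmonic upper-wall structural
# restraints, and a surrogate physical term (chain-connectivity bonds plus
# soft-sphere repulsion) standing in for a molecular force field.

#' Harmonic upper-wall potential
#'
#' One-sided penalty: zero at or below the wall center, `k (v - center)^2`
#' above it (no 1/2 factor). Continuous and once-differentiable at the wall.
#'
#' @param value the restrained quantity (same units as `center`).
#' @param center wall position.
#' @param k energy constant (kJ/mol per squared unit).
#' @return energy in kJ/mol.
#' @export
upper_wall <- function(value, center, k) {
  if (any(k <= 0)) stop("k must be > 0")
  ifelse(value <= center, 0, k * (value - center)^2)
}

#' Metainference energy of a data term
#'
#' Negative log of a per-point Gaussian likelihood with a multiplicative
#' scale nuisance:
#' `E = sum_i ( (lambda f_i - d_i)^2 / (2 sigma_i^2) + log sigma_i )`.
#' Used here in the no-replica limit with the ensemble standard error set
#' to zero, where metainference reduces to inferential structure
#' determination. The scale prior is flat on `lambda_bounds`; evaluating
#' outside the bounds is an error (the sampler rejects such proposals
#' before evaluation).
#'
#' @param forward_values forward-calculated data `f_i`.
#' @param d experimental data points `d_i`.
#' @param sigma per-point uncertainties (scalar recycled).
#' @param lambda scale nuisance.
#' @param lambda_bounds flat-prior support for `lambda`.
#' @return energy (dimensionless negative log-likelihood, treated as
#'   kJ/mol inside the hybrid score).
#' @export
metainference_energy <- function(forward_values, d, sigma, lambda = 1,
                                 lambda_bounds = c(0.9, 1.1)) {
  if (lambda < lambda_bounds[1] || lambda > lambda_bounds[2]) {
    stop("lambda outside the flat prior bounds [",
         lambda_bounds[1], ", ", lambda_bounds[2], "]")
  }
  if (any(sigma <= 0)) stop("sigma must be > 0")
  sigma <- rep_len(sigma, length(d))
  sum((lambda * forward_values - d)^2 / (2 * sigma^2) + log(sigma))
}

#' Declare the structural restraint set
#'
#' Three typed blocks mirroring the refinement restraints:
#' \describe{
#'   \item{interface}{harmonic upper walls on distances between aromatic
#'     ring centers of protein (Phe) and RNA residues, default center
#'     3.5 A, k 1000 kJ/mol.}
#'   \item{salt_bridges}{upper walls on the minimum distance between the
#'     Arg side-chain nitrogens (NE, NH1, NH2) and Asp carboxylate oxygens
#'     (OD1, OD2), default center 4 A, k 1000 kJ/mol.}
#'   \item{ss_rmsd}{upper walls centered at 0 A on the superposed backbone
#'     RMSD of each secondary-structure segment to a reference model,
#'     k 10000 kJ/mol. Each segment is superposed independently, so the
#'     restraint preserves internal structure without fixing the
#'     inter-domain arrangement.}
#' }
#'
#' @param interface data.frame with columns `chain1`, `resno1`, `chain2`,
#'   `resno2` and optionally `center`, `k`.
#' @param salt_bridges data.frame with columns `chain_arg`, `resno_arg`,
#'   `chain_asp`, `resno_asp` and optionally `center`, `k`.
#' @param ss_reference reference `AtomicModel` for the secondary-structure
#'   restraint (usually the starting crystal-like model).
#' @param ss_segments list of selections (mini-language strings), one per
#'   restrained secondary-structure segment.
#' @param ss_center,ss_k wall parameters of the RMSD restraints.
#' @return object of class `RestraintSet`.
#' @export
restraint_set <- function(interface = NULL, salt_bridges = NULL,
                          ss_reference = NULL, ss_segments = NULL,
                          ss_center = 0, ss_k = 10000) {
  if (!is.null(interface)) {
    if (is.null(interface$center)) interface$center <- 3.5
    if (is.null(interface$k)) interface$k <- 1000
  }
  if (!is.null(salt_bridges)) {
    if (is.null(salt_bridges$center)) salt_bridges$center <- 4
    if (is.null(salt_bridges$k)) salt_bridges$k <- 1000
  }
  structure(list(interface = interface, salt_bridges = salt_bridges,
                 ss_reference = ss_reference, ss_segments = ss_segments,
                 ss_center = ss_center, ss_k = ss_k),
            class = "RestraintSet")
}

.ARG_N_ATOMS <- c("NE", "NH1", "NH2")
.ASP_O_ATOMS <- c("OD1", "OD2")

# Minimum distance between Arg guanidinium nitrogens and Asp carboxylate
# oxygens.
.salt_bridge_distance <- function(model, chain_arg, resno_arg,
                                  chain_asp, resno_asp) {
  ia <- .atom_idx(model, chain = chain_arg, resno = resno_arg,
                  names = .ARG_N_ATOMS)
  id <- .atom_idx(model, chain = chain_asp, resno = resno_asp,
                  names = .ASP_O_ATOMS)
  if (length(ia) == 0 || length(id) == 0) {
    stop("salt-bridge atoms missing for ", chain_arg, ":", resno_arg,
         " - ", chain_asp, ":", resno_asp)
  }
  xa <- coords(model, ia)
  xd <- coords(model, id)
  min(sqrt(outer(rowSums(xa^2), rowSums(xd^2), "+") - 2 * xa %*% t(xd)))
}

#' Structural restraint energy of a model
#'
#' Evaluates every restraint in a [restraint_set()] on a model and returns
#' the total together with a per-restraint breakdown.
#'
#' @param model an `AtomicModel`.
#' @param restraints a `RestraintSet`.
#' @return list with `total` (kJ/mol) and `breakdown` (named numeric
#'   vector).
#' @export
restraint_energy <- function(model, restraints) {
  br <- numeric(0)
  if (!is.null(restraints$interface)) {
    ri <- restraints$interface
    for (i in seq_len(nrow(ri))) {
      d <- sqrt(sum((ring_center(model, ri$chain1[i], ri$resno1[i]) -
                     ring_center(model, ri$chain2[i], ri$resno2[i]))^2))
      br[paste0("interface_", ri$chain1[i], ri$resno1[i], "_",
                ri$chain2[i], ri$resno2[i])] <-
        upper_wall(d, ri$center[i], ri$k[i])
    }
  }
  if (!is.null(restraints$salt_bridges)) {
    rs <- restraints$salt_bridges
    for (i in seq_len(nrow(rs))) {
      d <- .salt_bridge_distance(model, rs$chain_arg[i], rs$resno_arg[i],
                                 rs$chain_asp[i], rs$resno_asp[i])
      br[paste0("salt_", rs$chain_arg[i], rs$resno_arg[i], "_",
                rs$chain_asp[i], rs$resno_asp[i])] <-
        upper_wall(d, rs$center[i], rs$k[i])
    }
  }
  if (!is.null(restraints$ss_reference)) {
    for (j in seq_along(restraints$ss_segments)) {
      rmsd <- backbone_rmsd(model, restraints$ss_reference,
                            selection = restraints$ss_segments[[j]],
                            superpose = TRUE)
      br[paste0("ss_rmsd_", j)] <-
        upper_wall(rmsd, restraints$ss_center, restraints$ss_k)
    }
  }
  list(total = sum(br), breakdown = br)
}

#' Surrogate physical term
#'
#' A minimal physics stand-in used instead of an explicit-solvent force
#' field: harmonic virtual bonds between consecutive residues along each
#' chain (protein C(i)-N(i+1); RNA O3'(i)-P(i+1)) with reference lengths
#' recorded from `reference`, plus soft-sphere repulsion
#' `k_rep (d0 - d)^2` between non-bonded atom pairs closer than `d0`.
#' Prevents chain breaks and steric collapse while leaving the inter-domain
#' arrangement to the data terms.
#'
#' @param reference `AtomicModel` supplying the bond topology and reference
#'   lengths.
#' @param k_bond bond constant (kJ/mol/A^2).
#' @param k_rep repulsion constant (kJ/mol/A^2).
#' @param d0 repulsion onset distance (A).
#' @return object of class `PhysicalTerm`.
#' @export
physical_term <- function(reference, k_bond = 200, k_rep = 10, d0 = 2.5) {
  a <- reference$atoms
  bonds <- NULL
  for (ch in names(reference$roles)) {
    role <- reference$roles[ch]
    link <- if (role == "protein") c("C", "N") else c("O3'", "P")
    res <- sort(unique(a$resno[a$chain == ch]))
    for (r in res[-length(res)]) {
      if (!(r + 1) %in% res) next
      i1 <- .atom_idx(reference, chain = ch, resno = r, names = link[1])
      i2 <- .atom_idx(reference, chain = ch, resno = r + 1, names = link[2])
      if (length(i1) == 1 && length(i2) == 1) {
        d <- sqrt(sum((coords(reference, i1) - coords(reference, i2))^2))
        bonds <- rbind(bonds, data.frame(i = i1, j = i2, d0 = d))
      }
    }
  }
  if (is.null(bonds)) bonds <- data.frame(i = integer(0), j = integer(0),
                                          d0 = numeric(0))
  structure(list(bonds = bonds, k_bond = k_bond, k_rep = k_rep, d0 = d0,
                 resno = a$resno, chain = a$chain,
                 chain_id = as.integer(factor(a$chain))),
            class = "PhysicalTerm")
}

#' Evaluate the surrogate physical term
#'
#' @param model an `AtomicModel` with the same atom ordering as the term's
#'   reference.
#' @param term a `PhysicalTerm`.
#' @return energy in kJ/mol.
#' @export
physical_energy <- function(model, term) {
  xyz <- if (is.matrix(model)) model else coords(model)
  .physical_kernel(xyz, term$bonds$i, term$bonds$j, term$bonds$d0,
                   term$k_bond, term$resno, term$chain_id, term$d0,
                   term$k_rep)
}

#' Assemble the hybrid energy model
#'
#' Combines the enabled terms into a single scoring object. The SAXS term
#' is a metainference term on representative intensities; the RDC term is
#' the correlation restraint evaluated with a fixed back-calculation tensor
#' (the restraint is invariant to its scale); the restraint set and the
#' surrogate physical term are evaluated at every step, the data terms at
#' the schedule's stride.
#'
#' @param saxs_term output of [prepare_saxs_term()], or `NULL` to disable.
#' @param rdc_term output of [prepare_rdc_term()], or `NULL` to disable.
#' @param restraints a `RestraintSet`, or `NULL`.
#' @param physical a `PhysicalTerm`, or `NULL`.
#' @return object of class `HybridEnergyModel`.
#' @export
hybrid_energy_model <- function(saxs_term = NULL, rdc_term = NULL,
                                restraints = NULL, physical = NULL) {
  structure(list(saxs = saxs_term, rdc = rdc_term,
                 restraints = restraints, physical = physical),
            class = "HybridEnergyModel")
}

#' Prepare the metainference SAXS term
#'
#' Reduces an experimental curve to representative intensities
#' ([prepare_representative_intensities()]), estimates the initial
#' experiment-to-model scale from a starting model
#' ([estimate_scale()]) and fixes the per-point uncertainty.
#'
#' @param exp_curve experimental `ScatteringCurve`.
#' @param start_model `AtomicModel` used to estimate the initial scale.
#' @param sigma per-point uncertainty of the representative intensities;
#'   `NULL` uses `sigma_frac` times each representative intensity.
#' @param sigma_frac fractional uncertainty used when `sigma` is `NULL`.
#' @param lambda_bounds flat-prior support of the residual scale nuisance.
#' @param ... passed to [prepare_representative_intensities()].
#' @return list term description used by [total_energy()].
#' @export
prepare_saxs_term <- function(exp_curve, start_model, sigma = NULL,
                              sigma_frac = 0.02,
                              lambda_bounds = c(0.9, 1.1), ...) {
  rep_curve <- prepare_representative_intensities(exp_curve, ...)
  calc <- debye_intensity(start_model, rep_curve$q)
  scale0 <- estimate_scale(rep_curve, calc)
  d <- rep_curve$I / scale0  # data on the model intensity scale
  if (is.null(sigma)) sigma <- sigma_frac * abs(d)
  list(q = rep_curve$q, d = d, sigma = sigma, scale0 = scale0,
       lambda_bounds = lambda_bounds)
}

#' Prepare the RDC correlation term
#'
#' @param rdcs experimental `RDCSet`.
#' @param slope restraint slope (kJ/mol), default -20000.
#' @param tensor_calc fixed Saupe matrix used for back-calculation during
#'   refinement; defaults to an axial tensor along the laboratory z axis
#'   (the correlation restraint is invariant to its magnitude).
#' @return list term description used by [total_energy()].
#' @export
prepare_rdc_term <- function(rdcs, slope = -20000,
                             tensor_calc = diag(c(-0.5, -0.5, 1))) {
  list(rdcs = rdcs, slope = slope, tensor_calc = tensor_calc)
}

#' Total hybrid energy of a model
#'
#' Sums the enabled terms: metainference SAXS, RDC correlation, structural
#' restraints and the surrogate physical term. The breakdown sums to the
#' total exactly.
#'
#' @param model an `AtomicModel` (for the two-replica RDC average, pass
#'   `replica2` as well; otherwise the single model is used for both).
#' @param hem a `HybridEnergyModel`.
#' @param lambda current SAXS scale nuisance.
#' @param sigma optional override of the SAXS per-point uncertainty (the
#'   sampled-sigma mode passes the current value).
#' @param replica2 optional second replica for the RDC average.
#' @return list with `total` and named `breakdown`.
#' @export
total_energy <- function(model, hem, lambda = 1, sigma = NULL,
                         replica2 = NULL) {
  br <- numeric(0)
  if (!is.null(hem$saxs)) {
    f <- debye_intensity(model, hem$saxs$q)$I
    sg <- if (is.null(sigma)) hem$saxs$sigma else sigma
    br["saxs"] <- metainference_energy(f, hem$saxs$d, sg, lambda,
                                       hem$saxs$lambda_bounds)
  }
  if (!is.null(hem$rdc)) {
    c1 <- back_calc_rdc(model, hem$rdc$rdcs, hem$rdc$tensor_calc)
    c2 <- if (is.null(replica2)) c1 else
      back_calc_rdc(replica2, hem$rdc$rdcs, hem$rdc$tensor_calc)
    br["rdc"] <- rdc_correlation_energy(replica_average(c1, c2),
                                        hem$rdc$rdcs$D, hem$rdc$slope)
  }
  if (!is.null(hem$restraints)) {
    br["restraints"] <- restraint_energy(model, hem$restraints)$total
  }
  if (!is.null(hem$physical)) {
    br["physical"] <- physical_energy(model, hem$physical)
  }
  list(total = sum(br), breakdown = br)
}
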