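# SAXS forward calculation: Cromer-Mann atomic form factors with a
# Fraser-style excluded-solvent correction, the Debye double sum,
# representative-intensity restraint preparation, and Rg/Dmax summaries.

# 4-Gaussian Cromer-Mann coefficients (International Tables, vol. C):
# f(q) = sum_k a_k exp(-b_k s^2) + c with s = q / (4 pi). f(0) equals the
# element's electron count.
.CROMER_MANN <- list(
  H = list(a = c(0.489918, 0.262003, 0.196767, 0.049879),
           b = c(20.6593, 7.74039, 49.5519, 2.20159), c = 0.001305),
  C = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
           b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
           b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
  O = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
           b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  P = list(a = c(6.43450, 4.17910, 1.78000, 1.49080),
           b = c(1.90670, 27.1570, 0.526000, 68.1645), c = 1.11490),
  S = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
           b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900)
)

# Average atomic volumes displaced in solution (A^3), Fraser-style dummy
# atoms (values as used by standard solvent-corrected scattering schemes).
.ATOM_VOLUME <- c(H = 5.15, C = 16.44, N = 2.49, O = 9.13, P = 5.73,
                  S = 19.86)

#' Tabulated electron count of an element
#'
#' @param elem character vector of element symbols.
#' @return numeric vector of electron counts (f(0) of the vacuum form
#'   factor).
#' @export
electron_count <- function(elem) {
  vapply(elem, function(e) {
    cm <- .CROMER_MANN[[e]]
    if (is.null(cm)) stop("no form-factor coefficients for element ", e)
    sum(cm$a) + cm$c
  }, numeric(1))
}

#' Atomic form factors on a q grid
#'
#' Vacuum Cromer-Mann form factors, optionally reduced by a Gaussian
#' excluded-solvent (dummy-atom) term
#' `g(q) = rho_s * V * exp(-V^(2/3) q^2 / (4 pi))`, so that the corrected
#' factor at q = 0 is the electron count minus the displaced-solvent
#' electrons. No hydration-shell term is modelled.
#'
#' @param elem character vector of element symbols.
#' @param q numeric vector of momentum transfer values (1/Angstrom).
#' @param solvent_correction logical; subtract the dummy-atom term.
#' @param solvent_density bulk solvent electron density (e/A^3).
#' @return matrix `length(q)` x `length(elem)` of form-factor values.
#' @export
form_factors <- function(elem, q, solvent_correction = TRUE,
                         solvent_density = 0.334) {
  if (any(q < 0)) stop("q must be non-negative")
  s2 <- (q / (4 * pi))^2
  uniq <- unique(elem)
  per_elem <- vapply(uniq, function(e) {
    cm <- .CROMER_MANN[[e]]
    if (is.null(cm)) stop("no form-factor coefficients for element ", e)
    f <- rep(cm$c, length(q))
    for (k in 1:4) f <- f + cm$a[k] * exp(-cm$b[k] * s2)
    if (solvent_correction) {
      V <- .ATOM_VOLUME[[e]]
      f <- f - solvent_density * V * exp(-V^(2 / 3) * q^2 / (4 * pi))
    }
    f
  }, numeric(length(q)))
  per_elem <- matrix(per_elem, nrow = length(q), ncol = length(uniq))
  per_elem[, match(elem, uniq), drop = FALSE]
}

#' Construct a scattering curve
#'
#' @param q strictly increasing momentum-transfer grid (1/Angstrom).
#' @param I intensities (arbitrary units).
#' @param sigma optional per-point uncertainties (> 0).
#' @return object of class `ScatteringCurve` (a data.frame).
#' @export
scattering_curve <- function(q, I, sigma = NULL) {
  if (length(q) != length(I)) stop("q and I must have equal length")
  if (is.unsorted(q, strictly = TRUE)) stop("q must be strictly increasing")
  if (!all(is.finite(I))) stop("intensities must be finite")
  if (!is.null(sigma)) {
    if (length(sigma) != length(q) || any(sigma <= 0)) {
      stop("sigma must be positive and match q in length")
    }
  }
  out <- data.frame(q = q, I = I)
  if (!is.null(sigma)) out$sigma <- sigma
  class(out) <- c("ScatteringCurve", "data.frame")
  out
}

#' Read/write scattering curves
#'
#' Three-column whitespace text (`q I [sigma]`) with `#` comment lines, the
#' common small-angle `.dat` dialect.
#'
#' @param path file path.
#' @return [read_curve()] returns a `ScatteringCurve`.
#' @export
read_curve <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("q", "I", "sigma")[1:3],
                           fill = TRUE)
  sigma <- if (ncol(tab) >= 3 && !all(is.na(tab[[3]]))) tab[[3]] else NULL
  scattering_curve(tab[[1]], tab[[2]], sigma)
}

#' @rdname read_curve
#' @param curve a `ScatteringCurve`.
#' @export
write_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# q(1/A) I sigma", con)
  utils::write.table(format(as.data.frame(curve), digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' SAXS intensity by the Debye formula
#'
#' Orientationally averaged intensity of an atomic model,
#' `I(q) = sum_i sum_j f_i(q) f_j(q) sin(q r_ij) / (q r_ij)`, with
#' `sin(x)/x -> 1` as `x -> 0`, so `I(0) = (sum_i f_i(0))^2`. The double
#' sum is evaluated exactly (no distance binning) in a compiled kernel;
#' [debye_reference()] provides the independent plain-R path.
#'
#' @param model an `AtomicModel`.
#' @param q momentum-transfer grid (1/Angstrom, non-negative).
#' @param solvent_correction,solvent_density see [form_factors()].
#' @return a `ScatteringCurve`.
#' @export
debye_intensity <- function(model, q, solvent_correction = TRUE,
                            solvent_density = 0.334) {
  if (nrow(model$atoms) == 0) stop("empty model")
  if (any(q < 0)) stop("q must be non-negative")
  FF <- form_factors(model$atoms$elem, q,
                     solvent_correction = solvent_correction,
                     solvent_density = solvent_density)
  I <- .debye_kernel(coords(model), FF, q)
  scattering_curve(q, I)
}

#' Prepare representative intensities for restraint use
#'
#' Fits a least-squares polynomial of degree `poly_degree` to the measured
#' intensities with `q <= fit_qmax` (after rescaling q to [-1, 1] for
#' conditioning) and evaluates the fit on a regular grid. With the default
#' settings (degree 16, fit up to 0.5 1/A, grid 0.03-0.45 in 0.01 steps)
#' the grid has 43 points, which become the per-point data of the
#' metainference SAXS term.
#'
#' @param curve a `ScatteringCurve`.
#' @param fit_qmax upper q bound of the fit range (1/Angstrom).
#' @param poly_degree polynomial degree.
#' @param grid_min,grid_max,grid_step representative grid (1/Angstrom).
#' @return a `ScatteringCurve` on the regular grid.
#' @export
prepare_representative_intensities <- function(curve, fit_qmax = 0.5,
                                               poly_degree = 16,
                                               grid_min = 0.03,
                                               grid_max = 0.45,
                                               grid_step = 0.01) {
  keep <- curve$q <= fit_qmax
  qf <- curve$q[keep]
  If <- curve$I[keep]
  if (poly_degree >= length(qf)) {
    stop("polynomial degree must be smaller than the number of fit points")
  }
  grid <- seq(grid_min, grid_max, by = grid_step)
  if (grid_min < min(qf) - 1e-9 || grid_max > max(qf) + 1e-9) {
    stop("representative grid extends outside the fitted q range")
  }
  # rescale to [-1, 1] and fit with an orthogonal polynomial basis
  scale01 <- function(x) 2 * (x - min(qf)) / (max(qf) - min(qf)) - 1
  basis <- stats::poly(scale01(qf), degree = poly_degree)
  fit <- stats::lm.fit(cbind(1, basis), If)
  if (any(is.na(fit$coefficients))) {
    warning("ill-conditioned polynomial fit: rank-deficient basis")
  }
  pred_basis <- stats::predict(basis, scale01(grid))
  I_rep <- drop(cbind(1, pred_basis) %*% ifelse(is.na(fit$coefficients), 0,
                                                fit$coefficients))
  scattering_curve(grid, I_rep)
}

#' Scale factor between experimental and calculated curves
#'
#' Mean over points of `I_exp / I_calc`, the approximate scaling relating
#' measured to model intensities. The calculated curve is linearly
#' interpolated onto the experimental grid when the grids differ.
#'
#' @param exp_curve,calc_curve `ScatteringCurve`s.
#' @return positive scalar.
#' @export
estimate_scale <- function(exp_curve, calc_curve) {
  Ic <- if (isTRUE(all.equal(exp_curve$q, calc_curve$q))) {
    calc_curve$I
  } else {
    stats::approx(calc_curve$q, calc_curve$I, xout = exp_curve$q)$y
  }
  if (any(is.na(Ic))) stop("calculated curve does not cover the q range")
  if (any(Ic == 0)) stop("calculated intensity is zero at some points")
  mean(exp_curve$I / Ic)
}

#' Model-based radius of gyration and maximum dimension
#'
#' `model_rg` is the root-mean-square distance of atoms from their
#' centroid, weighted by electron count by default (what a scattering
#' experiment measures); `model_dmax` is the maximum interatomic distance.
#'
#' @param model an `AtomicModel`.
#' @param weighted weight atoms by electron count (`TRUE`) or uniformly.
#' @return Angstrom.
#' @export
model_rg <- function(model, weighted = TRUE) {
  xyz <- coords(model)
  w <- if (weighted) electron_count(model$atoms$elem) else
    rep(1, nrow(xyz))
  ctr <- colSums(xyz * w) / sum(w)
  d2 <- rowSums(sweep(xyz, 2, ctr)^2)
  sqrt(sum(w * d2) / sum(w))
}

#' @rdname model_rg
#' @export
model_dmax <- function(model) {
  max(stats::dist(coords(model)))
}

#' Guinier radius of gyration from a curve
#'
#' Linear fit of `ln I` versus `q^2` in the low-q Guinier region, shrinking
#' the window until `q * Rg <= qrg_max` for every point used.
#'
#' @param curve a `ScatteringCurve`.
#' @param qrg_max Guinier validity bound on `q * Rg` (default 1.3).
#' @return list with `rg` (Angstrom), `I0`, and `n_points` used.
#' @export
guinier_rg <- function(curve, qrg_max = 1.3) {
  q <- curve$q[curve$q > 0]
  I <- curve$I[curve$q > 0]
  n <- length(q)
  repeat {
    if (n < 5) stop("fewer than 5 points in the Guinier window")
    fit <- stats::lm(log(I[1:n]) ~ I(q[1:n]^2))
    slope <- stats::coef(fit)[2]
    if (slope >= 0) {
      n <- n - 1
      next
    }
    rg <- sqrt(-3 * slope)
    if (q[n] * rg <= qrg_max) {
      return(list(rg = as.numeric(rg),
                  I0 = exp(as.numeric(stats::coef(fit)[1])),
                  n_points = n))
    }
    n <- sum(q * rg <= qrg_max)
  }
}
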