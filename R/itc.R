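# One-site ITC binding model: forward simulation of injection heats with
# displaced-volume dilution, nonlinear fitting of (N, K_D, dH), derived
# thermodynamics, and the published-titration consistency analyses.

.R_CAL <- 1.987    # gas constant, cal/(mol K)
.T_DEFAULT <- 298.15  # 25 C

#' Describe a titration experiment
#'
#' Cell species (the macromolecule, here RNA) is titrated with the syringe
#' species (protein). Concentrations in micromolar, volumes in microliter,
#' heats in microcalories.
#'
#' @param cell_volume_uL calorimeter cell volume.
#' @param cell_conc_uM cell species concentration at the start.
#' @param syringe_conc_uM syringe species concentration.
#' @param injection_volumes_uL vector of injection volumes.
#' @param heats_ucal optional observed per-injection heats.
#' @param sigma_ucal optional per-injection heat uncertainties; when
#'   present, [fit_one_site()] weights the residuals by them.
#' @param temperature_K experiment temperature (default 298.15 K, 25 C).
#' @return object of class `TitrationExperiment`.
#' @export
titration_experiment <- function(cell_volume_uL = 200, cell_conc_uM,
                                 syringe_conc_uM, injection_volumes_uL,
                                 heats_ucal = NULL, sigma_ucal = NULL,
                                 temperature_K = .T_DEFAULT) {
  if (cell_conc_uM <= 0 || syringe_conc_uM <= 0 || cell_volume_uL <= 0 ||
      any(injection_volumes_uL <= 0)) {
    stop("concentrations and volumes must be positive")
  }
  if (!is.null(heats_ucal)) {
    if (length(heats_ucal) != length(injection_volumes_uL)) {
      stop("one heat per injection required")
    }
    if (!all(is.finite(heats_ucal))) stop("heats must be finite")
  }
  if (!is.null(sigma_ucal) && any(sigma_ucal <= 0)) {
    stop("sigma_ucal must be positive")
  }
  structure(list(cell_volume_uL = cell_volume_uL,
                 cell_conc_uM = cell_conc_uM,
                 syringe_conc_uM = syringe_conc_uM,
                 injection_volumes_uL = injection_volumes_uL,
                 heats_ucal = heats_ucal, sigma_ucal = sigma_ucal,
                 temperature_K = temperature_K),
            class = "TitrationExperiment")
}

#' Read/write titration CSVs
#'
#' Two-column CSV `injection_volume_uL,heat_ucal`.
#'
#' @param path file path.
#' @param cell_volume_uL,cell_conc_uM,syringe_conc_uM,temperature_K
#'   experiment metadata (not stored in the CSV).
#' @return a `TitrationExperiment`.
#' @export
read_titration <- function(path, cell_volume_uL = 200, cell_conc_uM,
                           syringe_conc_uM, temperature_K = .T_DEFAULT) {
  tab <- utils::read.csv(path)
  titration_experiment(cell_volume_uL, cell_conc_uM, syringe_conc_uM,
                       tab$injection_volume_uL, tab$heat_ucal,
                       temperature_K)
}

#' @rdname read_titration
#' @param experiment a `TitrationExperiment` with heats.
#' @export
write_titration <- function(experiment, path) {
  utils::write.csv(
    data.frame(injection_volume_uL = experiment$injection_volumes_uL,
               heat_ucal = experiment$heats_ucal),
    path, row.names = FALSE)
  invisible(path)
}

#' Forward one-site injection heats
#'
#' Per-injection heats of a single-site binding isotherm with
#' stoichiometry `N`. Cell concentrations follow the overfill-cell
#' displacement convention: each injection of volume `dV` displaces its own
#' volume of pre-injection cell content, so the cell species concentration
#' is multiplied by `(1 - dV/V0)` and the titrant gains
#' `syringe_conc * dV/V0`. The bound concentration is the closed-form root
#' of the one-site mass-action quadratic, the heat content is
#' `Q_i = V0 * [bound]_i * dH`, and the injection heat is
#' `q_i = Q_i - Q_(i-1) + (dV_i/V0) * (Q_i + Q_(i-1))/2` (the displaced
#' aliquot carries heat content out of the cell). At saturation the
#' cumulative heat tends to `N * dH * (moles of cell species)`.
#'
#' @param N stoichiometry (sites per cell-species molecule).
#' @param K_D dissociation constant (molar, >= 0; 0 gives the
#'   stoichiometric limit).
#' @param dH binding enthalpy (cal/mol).
#' @param experiment a `TitrationExperiment`.
#' @return numeric vector of per-injection heats (microcal).
#' @export
one_site_heats <- function(N, K_D, dH, experiment) {
  if (N <= 0 || K_D < 0) stop("N must be > 0 and K_D >= 0")
  V0 <- experiment$cell_volume_uL * 1e-6          # L
  M <- experiment$cell_conc_uM * 1e-6             # mol/L
  Xs <- experiment$syringe_conc_uM * 1e-6
  X <- 0
  Qprev <- 0
  heats <- numeric(length(experiment$injection_volumes_uL))
  for (i in seq_along(heats)) {
    f <- experiment$injection_volumes_uL[i] * 1e-6 / V0
    M <- M * (1 - f)
    X <- X * (1 - f) + Xs * f
    b <- N * M + X + K_D
    bound <- (b - sqrt(b^2 - 4 * N * M * X)) / 2
    Q <- V0 * bound * dH * 1e6                    # microcal
    heats[i] <- Q - Qprev + f * (Q + Qprev) / 2
    Qprev <- Q
  }
  heats
}

#' Fit the one-site binding model
#'
#' Nonlinear least squares over (N, K_D, dH) against observed injection
#' heats, with K_D fitted on a log scale for stability. Derived quantities
#' use `dG = R T ln(K_D)` and `dS = (dH - dG)/T` with
#' R = 1.987 cal/(mol K). The heat of dilution can be corrected by a
#' constant offset estimated from the last post-saturation injections, by
#' subtracting a blank, or not at all.
#'
#' @param experiment a `TitrationExperiment` carrying heats.
#' @param dilution one of `"none"`, `"post_saturation"` (subtract the mean
#'   of the last `n_post` heats) or `"blank"`.
#' @param n_post injections used by the post-saturation estimate.
#' @param blank_heats per-injection blank heats for `dilution = "blank"`.
#' @param start optional named list of starting values `N`, `K_D`, `dH`.
#' @return object of class `BindingFit`: `N`, `K_D` (M), `dH` (cal/mol),
#'   `dG` (cal/mol), `dS` (cal/mol/K), standard errors, the c-value and
#'   the fitted heats.
#' @export
fit_one_site <- function(experiment, dilution = c("none", "post_saturation",
                                                  "blank"),
                         n_post = 3, blank_heats = NULL, start = NULL) {
  dilution <- match.arg(dilution)
  q <- experiment$heats_ucal
  if (is.null(q)) stop("experiment carries no heats")
  n <- length(q)
  if (n < 10) stop("at least 10 injections are required")
  if (dilution == "post_saturation") {
    q <- q - mean(q[(n - n_post + 1):n])
  } else if (dilution == "blank") {
    if (is.null(blank_heats)) stop("blank_heats required")
    q <- q - blank_heats
  }
  if (max(abs(q)) < 1e-9 || stats::sd(q) < 1e-6 * max(abs(q), 1e-12)) {
    stop("no binding signal: flat isotherm")
  }
  if (is.null(start)) {
    # equivalence point from the steepest heat change, crude dH from the
    # first injections
    V0 <- experiment$cell_volume_uL
    inj_mol <- experiment$injection_volumes_uL * 1e-6 *
      experiment$syringe_conc_uM * 1e-6
    dH0 <- sum(q[1:2]) * 1e-6 / sum(inj_mol[1:2])
    start <- list(N = 1, K_D = experiment$cell_conc_uM * 1e-6 / 50,
                  dH = dH0)
  }
  expt <- experiment
  model_fn <- function(N, lnK, dH) {
    one_site_heats(N, exp(lnK), dH, expt)
  }
  dat <- data.frame(q = q)
  w <- if (!is.null(experiment$sigma_ucal)) {
    1 / experiment$sigma_ucal^2
  } else {
    rep(1, n)
  }
  fit <- minpack.lm::nlsLM(
    q ~ model_fn(N, lnK, dH), data = dat, weights = w,
    start = list(N = start$N, lnK = log(start$K_D), dH = start$dH),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  K_D <- exp(cf[["lnK"]])
  Tk <- experiment$temperature_K
  dG <- .R_CAL * Tk * log(K_D)
  dH <- cf[["dH"]]
  structure(list(
    N = cf[["N"]], K_D = K_D, dH = dH, dG = dG, dS = (dH - dG) / Tk,
    se = c(N = unname(se[1]),
           K_D = K_D * unname(se[2]),  # delta method from lnK
           dH = unname(se[3])),
    c_value = cf[["N"]] * experiment$cell_conc_uM * 1e-6 / K_D,
    fitted = model_fn(cf[["N"]], cf[["lnK"]], cf[["dH"]]),
    temperature_K = Tk
  ), class = "BindingFit")
}

#' @export
print.BindingFit <- function(x, ...) {
  cat(sprintf("One-site fit: N = %.3f, K_D = %.4g M, dH = %.4g cal/mol\n",
              x$N, x$K_D, x$dH))
  cat(sprintf("  dG = %.4g cal/mol, dS = %.4g cal/mol/K (T = %.2f K), c = %.3g\n",
              x$dG, x$dS, x$temperature_K, x$c_value))
  invisible(x)
}

#' Dissociation constant from enthalpy and entropy
#'
#' `dG = dH - T dS`; `K_D = exp(dG / (R T))` with R = 1.987 cal/(mol K).
#' Inverts the thermodynamic relations used to report titration tables.
#'
#' @param dH enthalpy (cal/mol).
#' @param dS entropy (cal/mol/K).
#' @param T_K temperature (K).
#' @return dissociation constant (molar).
#' @export
kd_from_enthalpy_entropy <- function(dH, dS, T_K = .T_DEFAULT) {
  if (any(T_K <= 0)) stop("temperature must be positive")
  exp((dH - T_K * dS) / (.R_CAL * T_K))
}

#' Affinity fold change
#'
#' @param K_D_a,K_D_b dissociation constants (> 0, same units).
#' @return the ratio `K_D_a / K_D_b`.
#' @export
fold_change <- function(K_D_a, K_D_b) {
  if (any(K_D_a <= 0) || any(K_D_b <= 0)) stop("K_D must be positive")
  K_D_a / K_D_b
}

#' Published titration parameter presets
#'
#' The thermodynamic parameters of the protein-RNA titrations used as
#' simulation presets: stoichiometry N, K_D (micromolar), dH (cal/mol) and
#' dS (cal/mol/K) per binding pair.
#'
#' @return data.frame of presets keyed by `label`.
#' @export
itc_presets <- function() {
  data.frame(
    label = c("RRM1+7-mer", "RRM2+7-mer", "UP1+7-mer", "UP1+17-mer(A35C)",
              "UP1+pri-mir-18a", "UP1+12-mer", "UP1+12-mer-mut1",
              "UP1+12-mer-mut2", "UP1+12-mer-mut3", "UP1+10-mer",
              "UP1(R75E/R88A)+12-mer", "UP1(R75E/R88E)+12-mer"),
    N = c(1.01, 1.09, 0.75, 1.07, 1.35, 1.01, 1.06, 1.08, 0.98, 1.07,
          1.08, 1.1),
    K_D_uM = c(20.4, 6.8, 3.4, 3.1, 0.1477, 0.0155, 0.1541, 0.330,
               0.00833, 0.01912, 0.0190, 0.0401),
    dH_cal = 1e4 * c(-1.99, -1.64, -3.53, -1.98, -3.52, -3.81, -2.97,
                     -2.45, -4.10, -3.94, -3.84, -3.68),
    dS_cal = c(-45.2, -31.6, -93.4, -41.2, -86.8, -92.0, -68.6, -52.5,
               -101, -96.8, -93.5, -89.5),
    stringsAsFactors = FALSE
  )
}

#' Thermodynamic consistency of a titration table
#'
#' For each preset row, recomputes K_D from the tabulated dH and dS and
#' reports the ratio to the tabulated K_D (residual disagreement reflects
#' rounding of the printed dH and dS).
#'
#' @param presets data.frame as from [itc_presets()].
#' @param T_K temperature (K).
#' @return data.frame with tabulated and recomputed K_D (micromolar) and
#'   their ratio.
#' @export
itc_consistency <- function(presets = itc_presets(), T_K = .T_DEFAULT) {
  kd_calc <- kd_from_enthalpy_entropy(presets$dH_cal, presets$dS_cal,
                                      T_K) * 1e6
  data.frame(label = presets$label, K_D_uM = presets$K_D_uM,
             K_D_calc_uM = kd_calc, ratio = kd_calc / presets$K_D_uM)
}
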