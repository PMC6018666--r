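# Orchestration: the refine-and-validate workflow over the toy complex,
# independent validation paths (naive Debye sum, normal-equation tensor
# fit), config handling and reports.

#' Reference Debye sum (plain R)
#'
#' Independent re-implementation of the Debye double sum in interpreted R
#' over the full distance matrix, sharing no evaluation code with the
#' compiled production kernel. Used by [validate_model()] and as a
#' cross-check in tests.
#'
#' @param model an `AtomicModel`.
#' @param q momentum-transfer grid (1/A).
#' @param solvent_correction,solvent_density see [form_factors()].
#' @return a `ScatteringCurve`.
#' @export
debye_reference <- function(model, q, solvent_correction = TRUE,
                            solvent_density = 0.334) {
  FF <- form_factors(model$atoms$elem, q,
                     solvent_correction = solvent_correction,
                     solvent_density = solvent_density)
  D <- as.matrix(stats::dist(coords(model)))
  I <- vapply(seq_along(q), function(k) {
    x <- q[k] * D
    S <- sin(x) / x
    S[x == 0] <- 1
    drop(FF[k, ] %*% S %*% FF[k, ])
  }, numeric(1))
  scattering_curve(q, I)
}

#' Reference alignment-tensor fit (normal equations)
#'
#' Independent least-squares Saupe fit solving the normal equations
#' `(A'A) s = A'D` directly, used to confirm [fit_tensor_svd()].
#'
#' @param model an `AtomicModel`.
#' @param rdcs an `RDCSet`.
#' @return list with `S` (3x3 Saupe matrix), `D_calc` and `Q`.
#' @export
fit_tensor_reference <- function(model, rdcs) {
  B <- .bond_vectors(model, rdcs)
  A <- .saupe_design(B)
  s <- solve(crossprod(A), crossprod(A, rdcs$D))
  S <- .saupe_matrix(drop(s))
  D_calc <- rowSums((B %*% S) * B)
  list(S = S, D_calc = D_calc,
       Q = sqrt(sum((D_calc - rdcs$D)^2) / sum(rdcs$D^2)))
}

#' Validate a model against experimental data
#'
#' Scores a model against SAXS and/or RDC data through paths independent
#' of the scoring used in refinement: the SAXS fit uses the naive
#' [debye_reference()] sum with an error-weighted scale, the RDC fit the
#' normal-equation tensor of [fit_tensor_reference()]. Also tabulates the
#' satisfaction of the structural restraints.
#'
#' @param model an `AtomicModel`.
#' @param saxs optional experimental `ScatteringCurve` (with sigma).
#' @param rdcs optional experimental `RDCSet`.
#' @param restraints optional `RestraintSet`.
#' @return list report: `saxs` (scale, chi), `rdc` (Q, r), `restraints`
#'   (per-restraint energies), `ok` fields per block.
#' @export
validate_model <- function(model, saxs = NULL, rdcs = NULL,
                           restraints = NULL) {
  if (is.null(saxs) && is.null(rdcs)) {
    stop("at least one data set is required")
  }
  report <- list()
  if (!is.null(saxs)) {
    calc <- debye_reference(model, saxs$q)
    sg <- if (!is.null(saxs$sigma)) saxs$sigma else rep(1, length(saxs$q))
    scale <- sum(saxs$I * calc$I / sg^2) / sum(calc$I^2 / sg^2)
    chi <- sqrt(mean(((saxs$I - scale * calc$I) / sg)^2))
    report$saxs <- list(scale = scale, chi = chi)
  }
  if (!is.null(rdcs)) {
    fit <- fit_tensor_reference(model, rdcs)
    report$rdc <- list(Q = fit$Q, r = stats::cor(fit$D_calc, rdcs$D))
  }
  if (!is.null(restraints)) {
    re <- restraint_energy(model, restraints)
    report$restraints <- list(total = re$total, breakdown = re$breakdown)
  }
  report
}

#' Default pipeline configuration
#'
#' @param seed global seed expanded into per-stage streams.
#' @param out_dir output directory.
#' @return nested list of every tunable with its default.
#' @export
default_config <- function(seed = 1, out_dir = tempfile("metafold_run_")) {
  list(
    seed = seed,
    out_dir = out_dir,
    toy = list(perturbation_rmsd = 8),
    saxs = list(noise_frac = 0.02, q_min = 0.01, q_max = 0.5,
                n_q = 120, sigma_frac = 0.02),
    rdc = list(noise_hz = 0.3, slope = -20000),
    schedule = list(T_high = 300, T_low = 100, steps_per_half = 20,
                    n_cycles = 30, selection_window = 10, stride = 10,
                    rot_max = 5, trans_max = 0.5, torsion_max = 10,
                    p_rigid = 0.35),
    use_saxs = TRUE,
    use_rdc = TRUE,
    n_replicas = 2
  )
}

#' Read/write a pipeline config
#'
#' YAML on disk; [read_config()] fills unset fields with the defaults of
#' [default_config()].
#'
#' @param path file path.
#' @return [read_config()] returns the config list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  merge_in <- function(base, new) {
    for (nm in names(new)) {
      base[[nm]] <- if (is.list(new[[nm]]) && is.list(base[[nm]])) {
        merge_in(base[[nm]], new[[nm]])
      } else {
        new[[nm]]
      }
    }
    base
  }
  merge_in(cfg, user)
}

#' @rdname read_config
#' @param config config list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# Stable hash of the semantic config content.
.config_hash <- function(config) {
  config$out_dir <- NULL
  s <- yaml::as.yaml(config[order(names(config))])
  # small rolling hash; stable across sessions
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Run the end-to-end refine-and-validate workflow
#'
#' Generates the toy complex and its synthetic SAXS/RDC data, prepares the
#' metainference and structural restraint terms, refines the perturbed
#' start model by simulated annealing, selects the refined model, and
#' validates it through the independent paths. Writes into the run
#' directory: `refined.pdb`, `start.pdb`, `truth.pdb`, `trajectory.tsv`,
#' `energy.json`, `validation.json` and `manifest.json` (seed, config
#' hash, realized perturbation, final RMSD).
#'
#' @param config config list from [default_config()]/[read_config()], or a
#'   path to a YAML config.
#' @param verbose print per-cycle progress.
#' @return (invisibly) list with `refined`, `report`, `rmsd_start`,
#'   `rmsd_refined`, `dir`.
#' @export
run_pipeline <- function(config = default_config(), verbose = FALSE) {
  if (is.character(config)) config <- read_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  toy <- make_toy_complex(seed = config$seed,
                          perturbation_rmsd = config$toy$perturbation_rmsd)
  q_grid <- seq(config$saxs$q_min, config$saxs$q_max,
                length.out = config$saxs$n_q)
  saxs_exp <- simulate_saxs(toy$truth, q_grid,
                            noise_frac = config$saxs$noise_frac,
                            seed = config$seed)
  rdc_exp <- simulate_rdc(toy$truth, noise_hz = config$rdc$noise_hz,
                          seed = config$seed)

  grid_max <- min(0.45, config$saxs$q_max - 0.05)
  saxs_term <- if (isTRUE(config$use_saxs)) {
    prepare_saxs_term(saxs_exp, toy$start,
                      sigma_frac = config$saxs$sigma_frac,
                      fit_qmax = config$saxs$q_max,
                      grid_max = grid_max)
  } else NULL
  rdc_term <- if (isTRUE(config$use_rdc)) {
    prepare_rdc_term(rdc_exp, slope = config$rdc$slope)
  } else NULL
  hem <- hybrid_energy_model(
    saxs_term = saxs_term, rdc_term = rdc_term,
    restraints = toy$restraints,
    physical = physical_term(toy$truth))

  sch <- config$schedule
  schedule <- anneal_schedule(
    T_high = sch$T_high, T_low = sch$T_low,
    steps_per_half = sch$steps_per_half, n_cycles = sch$n_cycles,
    selection_window = sch$selection_window, stride = sch$stride,
    seed = split_seed(config$seed, "anneal"), rot_max = sch$rot_max,
    trans_max = sch$trans_max, torsion_max = sch$torsion_max,
    p_rigid = sch$p_rigid)
  traj <- run_annealing(toy$start, toy$partition, hem, schedule,
                        n_replicas = config$n_replicas, verbose = verbose)
  refined <- select_refined(traj)

  report <- validate_model(refined, saxs = saxs_exp, rdcs = rdc_exp,
                           restraints = toy$restraints)
  rmsd_start <- backbone_rmsd(toy$start, toy$truth)
  rmsd_refined <- backbone_rmsd(refined, toy$truth)

  write_pdb(toy$truth, file.path(config$out_dir, "truth.pdb"))
  write_pdb(toy$start, file.path(config$out_dir, "start.pdb"))
  write_pdb(refined, file.path(config$out_dir, "refined.pdb"))
  utils::write.table(traj$log, file.path(config$out_dir, "trajectory.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  final_energy <- total_energy(refined, hem, lambda = 1)
  jsonlite::write_json(
    list(total = final_energy$total,
         breakdown = as.list(final_energy$breakdown)),
    file.path(config$out_dir, "energy.json"), auto_unbox = TRUE,
    digits = NA)
  jsonlite::write_json(report, file.path(config$out_dir, "validation.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(seed = config$seed, config_hash = .config_hash(config),
         realized_perturbation_A = toy$manifest$realized_rmsd,
         rmsd_start_A = rmsd_start, rmsd_refined_A = rmsd_refined,
         selected_cycle = attr(refined, "cycle"),
         metainference_energy = attr(refined, "E_meta")),
    file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE,
    digits = NA)

  invisible(list(refined = refined, report = report,
                 rmsd_start = rmsd_start, rmsd_refined = rmsd_refined,
                 dir = config$out_dir))
}
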