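# Simulated-annealing Monte Carlo refinement: rigid-body and linker-torsion
# moves, Metropolis acceptance at a triangular temperature schedule cycling
# between T_high and T_low, the metainference SAXS term applied at a step
# stride with scale (and optionally uncertainty) nuisances sampled
# alongside, and selection of the refined model among the high-temperature
# samples of the last cycles.
#
# The sampler works on a bare coordinate matrix with atom indices resolved
# once up front; the user-facing operations (apply_move, restraint_energy,
# total_energy) remain the reference implementations and are cross-checked
# against this fast path in the tests.

.KB_KJ <- 0.0083144621  # Boltzmann constant, kJ/(mol K)

#' Annealing schedule
#'
#' One cycle sweeps the temperature linearly from `T_high` down to `T_low`
#' and back over `2 * steps_per_half` Monte Carlo steps. The metainference
#' SAXS term is refreshed (and its nuisances updated) every `stride` steps;
#' all structural terms act at every step. The refined model is selected
#' among the `T_high` samples of the last `selection_window` cycles.
#'
#' @param T_high,T_low temperature extremes (K).
#' @param steps_per_half Monte Carlo steps per half-cycle.
#' @param n_cycles number of annealing cycles.
#' @param selection_window number of final cycles eligible for selection.
#' @param stride step stride of the metainference data term.
#' @param seed RNG seed making the run reproducible.
#' @param rot_max,trans_max,torsion_max move amplitudes at `T_high`
#'   (degrees, Angstrom, degrees); amplitudes scale with `T / T_high`.
#' @param p_rigid probability of proposing a rigid-body move (otherwise a
#'   single linker-torsion move).
#' @return object of class `AnnealSchedule`.
#' @export
anneal_schedule <- function(T_high = 300, T_low = 100, steps_per_half = 500,
                            n_cycles = 300, selection_window = 30,
                            stride = 10, seed = 1, rot_max = 5,
                            trans_max = 0.5, torsion_max = 10,
                            p_rigid = 0.5) {
  if (!(T_high > T_low && T_low > 0)) stop("need T_high > T_low > 0")
  if (!(n_cycles >= selection_window && selection_window >= 1)) {
    stop("need n_cycles >= selection_window >= 1")
  }
  if (stride < 1) stop("stride must be >= 1")
  structure(list(T_high = T_high, T_low = T_low,
                 steps_per_half = steps_per_half, n_cycles = n_cycles,
                 selection_window = selection_window, stride = stride,
                 seed = seed, rot_max = rot_max, trans_max = trans_max,
                 torsion_max = torsion_max, p_rigid = p_rigid),
            class = "AnnealSchedule")
}

# Pre-resolve atom indices so the per-step energy avoids repeated table
# scans: interface ring atoms, salt-bridge atoms, the matched backbone of
# each secondary-structure segment, RDC bond atoms, the physical term and
# the form-factor matrix of the SAXS grid.
.compile_scoring <- function(model, hem) {
  cs <- list()
  r <- hem$restraints
  if (!is.null(r) && !is.null(r$interface)) {
    cs$interface <- lapply(seq_len(nrow(r$interface)), function(i) {
      ri <- r$interface[i, ]
      res1 <- model$atoms$resname[.atom_idx(model, ri$chain1, ri$resno1)][1]
      res2 <- model$atoms$resname[.atom_idx(model, ri$chain2, ri$resno2)][1]
      list(i1 = .atom_idx(model, ri$chain1, ri$resno1,
                          .RING_ATOMS[[res1]]),
           i2 = .atom_idx(model, ri$chain2, ri$resno2,
                          .RING_ATOMS[[res2]]),
           center = ri$center, k = ri$k)
    })
  }
  if (!is.null(r) && !is.null(r$salt_bridges)) {
    cs$salt <- lapply(seq_len(nrow(r$salt_bridges)), function(i) {
      rs <- r$salt_bridges[i, ]
      list(ia = .atom_idx(model, rs$chain_arg, rs$resno_arg, .ARG_N_ATOMS),
           id = .atom_idx(model, rs$chain_asp, rs$resno_asp, .ASP_O_ATOMS),
           center = rs$center, k = rs$k)
    })
  }
  if (!is.null(r) && !is.null(r$ss_reference)) {
    mkey <- paste(model$atoms$chain, model$atoms$resno, model$atoms$name)
    cs$ss <- lapply(r$ss_segments, function(sel) {
      idx_ref <- .selection_idx(r$ss_reference, sel)
      aref <- r$ss_reference$atoms[idx_ref, ]
      keep <- mapply(function(ch, nm) {
        nm %in% .backbone_names(r$ss_reference$roles[ch])
      }, aref$chain, aref$name)
      aref <- aref[keep, ]
      idx_mod <- match(paste(aref$chain, aref$resno, aref$name), mkey)
      if (any(is.na(idx_mod))) stop("ss restraint atoms missing in model")
      ref <- as.matrix(aref[c("x", "y", "z")])
      refc <- sweep(ref, 2, colMeans(ref))
      list(idx = idx_mod, refc = refc, center = r$ss_center, k = r$ss_k)
    })
  }
  if (!is.null(hem$rdc)) {
    rd <- hem$rdc$rdcs
    i1 <- vapply(seq_len(nrow(rd)), function(i) {
      .atom_idx(model, rd$chain[i], rd$resno[i], rd$atom1[i])
    }, integer(1))
    i2 <- vapply(seq_len(nrow(rd)), function(i) {
      .atom_idx(model, rd$chain[i], rd$resno[i], rd$atom2[i])
    }, integer(1))
    cs$rdc <- list(i1 = i1, i2 = i2, D = rd$D, slope = hem$rdc$slope,
                   S = hem$rdc$tensor_calc)
  }
  cs$physical <- hem$physical
  if (!is.null(hem$saxs)) {
    cs$FF <- form_factors(model$atoms$elem, hem$saxs$q)
  }
  cs
}

# Superposed RMSD of xyz[idx, ] against a pre-centered reference (Kabsch).
.kabsch_rmsd <- function(x, refc) {
  xc <- sweep(x, 2, colMeans(x))
  s <- svd(crossprod(xc, refc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((xc %*% R - refc)^2)))
}

# Per-replica structural energy (walls + secondary structure + physical
# term; the replica-coupled RDC term is handled separately) from a raw
# coordinate matrix, using compiled indices.
.struct_energy <- function(xyz, cs, hem) {
  e <- 0
  for (p in cs$interface) {
    d <- sqrt(sum((colMeans(xyz[p$i1, , drop = FALSE]) -
                   colMeans(xyz[p$i2, , drop = FALSE]))^2))
    e <- e + upper_wall(d, p$center, p$k)
  }
  for (p in cs$salt) {
    xa <- xyz[p$ia, , drop = FALSE]
    xd <- xyz[p$id, , drop = FALSE]
    d <- min(sqrt(outer(rowSums(xa^2), rowSums(xd^2), "+") -
                    2 * xa %*% t(xd)))
    e <- e + upper_wall(d, p$center, p$k)
  }
  for (seg in cs$ss) {
    rmsd <- .kabsch_rmsd(xyz[seg$idx, , drop = FALSE], seg$refc)
    e <- e + upper_wall(rmsd, seg$center, seg$k)
  }
  if (!is.null(cs$physical)) {
    e <- e + physical_energy(xyz, cs$physical)
  }
  e
}

# Back-calculated couplings of one replica under the fixed tensor.
.rdc_calc <- function(xyz, cs) {
  B <- xyz[cs$rdc$i2, , drop = FALSE] - xyz[cs$rdc$i1, , drop = FALSE]
  B <- B / sqrt(rowSums(B^2))
  rowSums((B %*% cs$rdc$S) * B)
}

# Correlation restraint on the replica-averaged couplings.
.rdc_energy <- function(Dcs, cs) {
  if (is.null(cs$rdc)) return(0)
  avg <- Reduce(`+`, Dcs) / length(Dcs)
  cs$rdc$slope * stats::cor(avg, cs$rdc$D)
}

# Pre-resolve the move machinery: atom indices per mobile rigid group and,
# per flexible torsion, the axis atom indices and downstream atom set
# (same semantics as apply_move).
.compile_moves <- function(model, partition, mobile_groups) {
  group_idx <- lapply(partition$groups[mobile_groups], function(g) {
    idx <- integer(0)
    for (i in seq_len(nrow(g))) {
      idx <- c(idx, .atom_idx(model, chain = g$chain[i],
                              resno = g$resno[i]))
    }
    idx
  })
  ch <- partition$protein_chain
  torsions <- lapply(seq_len(nrow(partition$flexible)), function(i) {
    resno <- partition$flexible$resno[i]
    dihedral <- partition$flexible$dihedral[i]
    if (dihedral == "phi") {
      i0 <- .atom_idx(model, ch, resno, "N")
      i1 <- .atom_idx(model, ch, resno, "CA")
      local_names <- c("C", "O")
    } else {
      i0 <- .atom_idx(model, ch, resno, "CA")
      i1 <- .atom_idx(model, ch, resno, "C")
      local_names <- "O"
    }
    idx <- c(.atom_idx(model, ch, resno, local_names),
             which(model$atoms$chain == ch & model$atoms$resno > resno))
    for (g in partition$groups) {
      prot <- g$resno[g$chain == ch]
      if (length(prot) > 0 && all(prot > resno)) {
        other <- g[g$chain != ch, ]
        for (k in seq_len(nrow(other))) {
          idx <- c(idx, .atom_idx(model, other$chain[k], other$resno[k]))
        }
      }
    }
    list(i0 = i0, i1 = i1, idx = sort(unique(idx)))
  })
  list(groups = group_idx, torsions = torsions)
}

#' Run simulated-annealing refinement
#'
#' Monte Carlo refinement of a model under a [hybrid_energy_model()]:
#' rigid-body perturbations of the mobile groups and single linker-torsion
#' perturbations, Metropolis-accepted at the instantaneous temperature of
#' the triangular annealing schedule. The metainference SAXS term is
#' re-evaluated every `stride`-th step (proposals on those steps face the
#' full energy difference), and the scale nuisance `lambda` (plus, in
#' sampled-sigma mode, a global uncertainty scale with a Jeffreys prior) is
#' updated by Metropolis-within-Gibbs at the same stride. All structural
#' terms and the RDC correlation act at every step. Snapshots are recorded
#' at every `T_high` pass (one per cycle).
#'
#' @param start_model starting `AtomicModel`.
#' @param partition a `RigidGroupPartition`.
#' @param hem a `HybridEnergyModel`.
#' @param schedule an `AnnealSchedule`.
#' @param mobile_groups names of rigid groups moved by rigid proposals;
#'   default all but the first (the first group anchors the frame).
#' @param sigma_mode `"fixed"` (default) or `"sampled"`.
#' @param sigma_start initial global sigma scale in sampled mode (start
#'   large so the data restraint tightens gradually).
#' @param n_replicas number of replicas; with 2 the RDC correlation acts
#'   on the replica-averaged couplings (accounting for multiple alignments
#'   of the complex in the medium) while every other term restrains each
#'   replica independently.
#' @param verbose print a per-cycle summary line.
#' @return object of class `Trajectory`: per-step log, per-cycle snapshots
#'   (one per replica: coordinates, energies, lambda), the schedule and the
#'   model template.
#' @export
run_annealing <- function(start_model, partition, hem, schedule,
                          mobile_groups = NULL, sigma_mode = "fixed",
                          sigma_start = 10, n_replicas = 1,
                          verbose = FALSE) {
  if (is.null(mobile_groups)) {
    mobile_groups <- names(partition$groups)[-1]
  }
  n_dof <- length(mobile_groups) + nrow(partition$flexible)
  if (n_dof == 0) stop("no movable degrees of freedom")
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  })
  set.seed(schedule$seed)

  cs <- .compile_scoring(start_model, hem)
  mv <- .compile_moves(start_model, partition, mobile_groups)
  n_tor <- length(mv$torsions)
  R <- n_replicas
  xyzs <- rep(list(coords(start_model)), R)
  lambda <- 1
  sscale <- if (sigma_mode == "sampled") sigma_start else 1
  sigma_now <- function() {
    if (is.null(hem$saxs)) return(NULL)
    sscale * hem$saxs$sigma
  }
  meta_e <- function(f, lam, sg) {
    metainference_energy(f, hem$saxs$d, sg, lam, hem$saxs$lambda_bounds)
  }
  e_structs <- vapply(xyzs, .struct_energy, numeric(1), cs = cs, hem = hem)
  Dcs <- if (!is.null(cs$rdc)) lapply(xyzs, .rdc_calc, cs = cs) else NULL
  e_rdc <- if (!is.null(cs$rdc)) .rdc_energy(Dcs, cs) else 0
  fs <- if (!is.null(hem$saxs)) {
    lapply(xyzs, function(x) .debye_kernel(x, cs$FF, hem$saxs$q))
  } else NULL
  e_datas <- if (!is.null(hem$saxs)) {
    vapply(fs, meta_e, numeric(1), lam = lambda, sg = sigma_now())
  } else rep(0, R)

  half <- schedule$steps_per_half
  steps_per_cycle <- 2 * half
  total_steps <- schedule$n_cycles * steps_per_cycle
  log_step <- integer(total_steps)
  log_cycle <- integer(total_steps)
  log_T <- numeric(total_steps)
  log_E <- numeric(total_steps)
  log_acc <- logical(total_steps)
  snapshots <- vector("list", schedule$n_cycles)

  step <- 0L
  for (cycle in seq_len(schedule$n_cycles)) {
    n_acc <- 0L
    for (s in seq_len(steps_per_cycle)) {
      step <- step + 1L
      phase <- if (s <= half) (s - 1) / half else (steps_per_cycle - s) / half
      temp <- schedule$T_high - (schedule$T_high - schedule$T_low) * phase
      amp <- temp / schedule$T_high
      data_step <- !is.null(hem$saxs) && step %% schedule$stride == 0
      r <- if (R > 1) sample.int(R, 1) else 1L
      xyz <- xyzs[[r]]

      # propose a structural move on the replica's coordinate matrix
      prop <- xyz
      if (stats::runif(1) < schedule$p_rigid && length(mv$groups) > 0) {
        gi <- mv$groups[[sample.int(length(mv$groups), 1)]]
        ang <- stats::runif(1, -1, 1) * schedule$rot_max * amp * pi / 180
        Rm <- rotation_about_axis(stats::rnorm(3), ang)
        tr <- stats::runif(3, -1, 1) * schedule$trans_max * amp
        sub <- xyz[gi, , drop = FALSE]
        ctr <- colMeans(sub)
        prop[gi, ] <- sweep(sweep(sub, 2, ctr) %*% t(Rm), 2, ctr + tr, "+")
      } else {
        ti <- mv$torsions[[sample.int(n_tor, 1)]]
        ang <- stats::runif(1, -1, 1) * schedule$torsion_max * amp * pi / 180
        Rm <- rotation_about_axis(xyz[ti$i1, ] - xyz[ti$i0, ], ang)
        pivot <- xyz[ti$i1, ]
        sub <- xyz[ti$idx, , drop = FALSE]
        prop[ti$idx, ] <- sweep(sweep(sub, 2, pivot) %*% t(Rm), 2, pivot,
                                "+")
      }

      e_struct_new <- .struct_energy(prop, cs, hem)
      Dc_new <- if (!is.null(cs$rdc)) .rdc_calc(prop, cs) else NULL
      e_rdc_new <- if (!is.null(cs$rdc)) {
        Dcs_prop <- Dcs
        Dcs_prop[[r]] <- Dc_new
        .rdc_energy(Dcs_prop, cs)
      } else 0
      if (data_step) {
        fs <- lapply(xyzs, function(x) .debye_kernel(x, cs$FF, hem$saxs$q))
        e_datas <- vapply(fs, meta_e, numeric(1), lam = lambda,
                          sg = sigma_now())
        f_prop <- .debye_kernel(prop, cs$FF, hem$saxs$q)
        e_data_new <- meta_e(f_prop, lambda, sigma_now())
      } else {
        e_data_new <- e_datas[r]
      }
      dE <- (e_struct_new + e_rdc_new + e_data_new) -
        (e_structs[r] + e_rdc + e_datas[r])
      accept <- dE <= 0 || stats::runif(1) < exp(-dE / (.KB_KJ * temp))
      if (accept) {
        xyzs[[r]] <- prop
        e_structs[r] <- e_struct_new
        e_rdc <- e_rdc_new
        if (!is.null(cs$rdc)) Dcs[[r]] <- Dc_new
        e_datas[r] <- e_data_new
        if (data_step) fs[[r]] <- f_prop
        n_acc <- n_acc + 1L
      }

      # nuisance updates at the data stride; lambda and sigma do not move
      # the atoms, so the cached forward values are reused
      if (data_step) {
        lam_prop <- lambda + stats::runif(1, -0.02, 0.02)
        bounds <- hem$saxs$lambda_bounds
        if (lam_prop >= bounds[1] && lam_prop <= bounds[2]) {
          e_new <- vapply(fs, meta_e, numeric(1), lam = lam_prop,
                          sg = sigma_now())
          dE <- sum(e_new) - sum(e_datas)
          if (dE <= 0 || stats::runif(1) < exp(-dE / (.KB_KJ * temp))) {
            lambda <- lam_prop
            e_datas <- e_new
          }
        }
        if (sigma_mode == "sampled") {
          s_prop <- sscale * exp(stats::runif(1, -0.2, 0.2))
          e_new <- vapply(fs, meta_e, numeric(1), lam = lambda,
                          sg = s_prop * hem$saxs$sigma)
          # Jeffreys prior on the sigma scale: p(s) ~ 1/s
          dE <- (sum(e_new) + log(s_prop)) - (sum(e_datas) + log(sscale))
          if (dE <= 0 || stats::runif(1) < exp(-dE / (.KB_KJ * temp))) {
            sscale <- s_prop
            e_datas <- e_new
          }
        }
      }

      log_step[step] <- step
      log_cycle[step] <- cycle
      log_T[step] <- temp
      log_E[step] <- sum(e_structs) + e_rdc + sum(e_datas)
      log_acc[step] <- accept

      # snapshots of every replica at the T_high pass of each cycle
      if (s == 1) {
        snapshots[[cycle]] <- lapply(seq_len(R), function(rr) {
          e_meta <- if (!is.null(hem$saxs)) {
            meta_e(.debye_kernel(xyzs[[rr]], cs$FF, hem$saxs$q), lambda,
                   sigma_now())
          } else {
            # without the metainference term, fall back to the remaining
            # hybrid energy (data-restraint part first)
            e_structs[rr] + e_rdc
          }
          list(cycle = cycle, step = step, T = temp, replica = rr,
               E_meta = e_meta, E_total = e_structs[rr] + e_rdc + e_meta,
               lambda = lambda, sigma_scale = sscale, xyz = xyzs[[rr]])
        })
      }
    }
    if (verbose) {
      message(sprintf(
        "cycle %d/%d  T-span %g-%g K  acc %.2f  E %.1f  lambda %.3f",
        cycle, schedule$n_cycles, schedule$T_high, schedule$T_low,
        n_acc / steps_per_cycle,
        sum(e_structs) + e_rdc + sum(e_datas), lambda))
    }
  }
  structure(list(
    log = data.frame(step = log_step, cycle = log_cycle, T = log_T,
                     E = log_E, accepted = log_acc),
    snapshots = snapshots, schedule = schedule, template = start_model
  ), class = "Trajectory")
}

#' Select the refined model from a trajectory
#'
#' Returns the snapshot with the lowest metainference energy among the
#' `T_high` samples of the last `selection_window` cycles; ties are broken
#' by the earliest step.
#'
#' @param trajectory a `Trajectory` from [run_annealing()].
#' @param schedule optional schedule override (defaults to the trajectory's
#'   own).
#' @return the selected `AtomicModel`, with attributes `cycle`, `step` and
#'   `E_meta` of the chosen snapshot.
#' @export
select_refined <- function(trajectory, schedule = NULL) {
  if (is.null(schedule)) schedule <- trajectory$schedule
  first_ok <- schedule$n_cycles - schedule$selection_window + 1
  flat <- unlist(lapply(trajectory$snapshots, function(s) {
    if (is.null(s)) return(NULL)
    if (!is.null(s$cycle)) list(s) else s  # single snapshot or replica list
  }), recursive = FALSE)
  snaps <- Filter(function(s) {
    !is.null(s) && s$cycle >= first_ok && s$T >= schedule$T_high - 1e-9
  }, flat)
  if (length(snaps) == 0) stop("no qualifying high-temperature samples")
  e <- vapply(snaps, function(s) s$E_meta, numeric(1))
  best <- snaps[[which.min(e)]]  # which.min takes the earliest tie
  model <- trajectory$template
  model$atoms[, c("x", "y", "z")] <- best$xyz
  attr(model, "cycle") <- best$cycle
  attr(model, "step") <- best$step
  attr(model, "E_meta") <- best$E_meta
  model
}
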