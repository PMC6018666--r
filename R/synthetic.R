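# Synthetic-data module: a toy two-domain protein / single-stranded RNA
# complex with known ground truth, plus seeded simulators for every
# experimental input the pipeline consumes (SAXS curves, RDC sets, ITC
# titrations, CSP/PRE/relaxation tables).

# One global seed expands into independent per-generator streams through a
# fixed affine splitting rule, so adding a generator never shifts the
# stream of an existing one.
.SEED_STREAMS <- c(toy = 1L, saxs = 2L, rdc = 3L, itc = 4L, nmr = 5L,
                   anneal = 6L, pipeline = 7L)

#' Derive a per-generator sub-seed
#'
#' @param seed global integer seed.
#' @param stream one of `"toy"`, `"saxs"`, `"rdc"`, `"itc"`, `"nmr"`,
#'   `"anneal"`, `"pipeline"`.
#' @return integer sub-seed in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(seed, stream) {
  sid <- .SEED_STREAMS[[stream]]
  as.integer((as.numeric(seed) * 48271 + sid * 2654435) %% 2147483646 + 1)
}

# --- toy-complex geometry -------------------------------------------------

.TOY_RNA_SEQ <- c("A", "G", "U", "A", "G", "A", "U", "U", "A", "G",
                  "C", "A")

# Hexagonal ring atoms around a center, in the plane perpendicular to
# `normal`, radius 1.4 A.
.hexagon <- function(center, normal, names, radius = 1.4) {
  n <- normal / sqrt(sum(normal^2))
  ref <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  ang <- (0:5) * pi / 3
  xyz <- t(vapply(ang, function(a) {
    center + radius * (cos(a) * e1 + sin(a) * e2)
  }, numeric(3)))
  data.frame(name = names, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

# Interior points of an arched path between two anchors: a straight line
# plus a sine bump (in +z) whose amplitude is solved so consecutive steps
# (including the anchor gaps) have length `target_step`.
.arc_points <- function(P0, P1, n_interior, target_step) {
  base <- sqrt(sum((P1 - P0)^2))
  n_seg <- n_interior + 1
  target_len <- target_step * n_seg
  path_len <- function(h) {
    t <- seq(0, 1, length.out = 400)
    pts <- outer(t, P1 - P0) + matrix(P0, 400, 3, byrow = TRUE)
    pts[, 3] <- pts[, 3] + h * sin(pi * t)
    sum(sqrt(rowSums(diff(pts)^2)))
  }
  h <- if (target_len <= base * 1.001) 0 else {
    stats::uniroot(function(h) path_len(h) - target_len,
                   c(0, 2 * target_len))$root
  }
  t <- seq(0, 1, length.out = 400)
  pts <- outer(t, P1 - P0) + matrix(P0, 400, 3, byrow = TRUE)
  pts[, 3] <- pts[, 3] + h * sin(pi * t)
  s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  s_want <- seq_len(n_interior) * s[length(s)] / n_seg
  t(vapply(s_want, function(sw) {
    k <- findInterval(sw, s)
    w <- (sw - s[k]) / (s[k + 1] - s[k])
    pts[k, ] * (1 - w) + pts[k + 1, ] * w
  }, numeric(3)))
}

# Points along a polyline at equal arclength spacing.
.polyline_points <- function(corners, n) {
  seg <- diff(corners)
  len <- sqrt(rowSums(seg^2))
  s <- c(0, cumsum(len))
  s_want <- seq(0, s[length(s)], length.out = n)
  t(vapply(s_want, function(sw) {
    k <- min(findInterval(sw, s), length(len))
    w <- (sw - s[k]) / len[k]
    corners[k, ] * (1 - w) + corners[k + 1, ] * w
  }, numeric(3)))
}

# Backbone atoms (N, CA, C, O, H) from a CA trace. N and C sit 1.2 A from
# the CA toward the previous/next CA; O and the amide H sit on rotating
# perpendiculars so bond orientations sample many directions.
.backbone_from_trace <- function(ca, resno_start) {
  n <- nrow(ca)
  u_prev <- rbind(ca[1, ] - ca[2, ], ca[-n, ] - ca[-1, ])
  u_prev <- u_prev / sqrt(rowSums(u_prev^2))
  u_next <- rbind(ca[-1, ] - ca[-n, ], ca[n, ] - ca[n - 1, ])
  u_next <- u_next / sqrt(rowSums(u_next^2))
  perp <- function(u, phase) {
    ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- ref - sum(ref * u) * u
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2],
            u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    cos(phase) * e1 + sin(phase) * e2
  }
  out <- lapply(seq_len(n), function(i) {
    Np <- ca[i, ] + 1.2 * u_prev[i, ]
    Cp <- ca[i, ] + 1.2 * u_next[i, ]
    Op <- Cp + 1.2 * perp(u_next[i, ], 2.5 * i)
    Hp <- Np + 1.0 * perp(u_prev[i, ], 2.5 * i + 1.3)
    data.frame(resno = resno_start + i - 1,
               name = c("N", "CA", "C", "O", "H"),
               x = c(Np[1], ca[i, 1], Cp[1], Op[1], Hp[1]),
               y = c(Np[2], ca[i, 2], Cp[2], Op[2], Hp[2]),
               z = c(Np[3], ca[i, 3], Cp[3], Op[3], Hp[3]))
  })
  do.call(rbind, out)
}

#' Generate the toy protein-RNA complex
#'
#' Builds a ground-truth complex emulating a tandem-domain protein bound to
#' a 12-nucleotide single-stranded RNA: two 16-residue helical
#' pseudo-domains (residues 1-16 and 25-40 of chain A) joined by an
#' 8-residue flexible linker (17-24), and RNA chain B (sequence
#' AGUAGAUUAGCA) whose nucleotides 1-6 bind domain 1 and 7-12 bind
#' domain 2. Four Phe/nucleotide stacking pairs (Phe10-U3, Phe13-G5,
#' Phe30-A9, Phe34-C11) and two inter-domain salt bridges (Arg15-Asp25,
#' Arg14-Asp26) are built to satisfy their restraint centers exactly, so
#' the truth has zero restraint energy. A perturbed start model is produced
#' by random linker-torsion rotations scaled (by bisection) until the
#' superposed backbone RMSD to the truth falls within 10% of
#' `perturbation_rmsd`.
#'
#' @param seed integer seed (only the perturbation is stochastic; the truth
#'   is deterministic).
#' @param perturbation_rmsd requested backbone RMSD (A) of the start model.
#' @return list with `truth`, `start` (`AtomicModel`s), `partition`
#'   (`RigidGroupPartition`), `restraints` (`RestraintSet`) and `manifest`
#'   (ground-truth bookkeeping: atom counts, realized RMSD, restraint
#'   tables).
#' @export
make_toy_complex <- function(seed = 1, perturbation_rmsd = 8) {
  a100 <- 100 * pi / 180
  ca1 <- t(vapply(1:16, function(i) {
    c(2.3 * cos(a100 * i), 2.3 * sin(a100 * i), 1.5 * i)
  }, numeric(3)))
  ca2 <- t(vapply(1:16, function(k) {
    c(12 + 2.3 * cos(a100 * k), 2.3 * sin(a100 * k), 24 - 1.5 * k)
  }, numeric(3)))
  link <- .arc_points(ca1[16, ], ca2[1, ], 8, 3.2)
  ca <- rbind(ca1, link, ca2)
  prot <- .backbone_from_trace(ca, 1)
  resnames <- rep("ALA", 40)
  resnames[c(10, 13, 30, 34)] <- "PHE"
  resnames[c(14, 15)] <- "ARG"
  resnames[c(25, 26)] <- "ASP"
  prot$resname <- resnames[prot$resno]
  prot$chain <- "A"

  # RNA backbone along a U-shaped path facing the two domains
  corners <- rbind(c(0, -7.5, 6), c(0, -7.5, 20),
                   c(12, -7.5, 20), c(12, -7.5, 6))
  nt_pos <- .polyline_points(corners, 12)
  w <- rbind(nt_pos[2, ] - nt_pos[1, ],
             nt_pos[-1, ] - nt_pos[-12, ])
  w <- w / sqrt(rowSums(w^2))
  p_off <- c(0, 1, 0)
  rna <- lapply(1:12, function(i) {
    pos <- nt_pos[i, ]
    wi <- w[i, ]
    at <- rbind(pos - 1.9 * wi,
                pos - 1.2 * wi + 0.5 * p_off,
                pos - 0.5 * wi,
                pos + 0.2 * wi + 0.5 * p_off,
                pos + 0.9 * wi,
                pos + 1.6 * wi + 0.5 * p_off)
    data.frame(resno = i,
               name = c("P", "O5'", "C5'", "C4'", "C3'", "O3'"),
               x = at[, 1], y = at[, 2], z = at[, 3],
               resname = .TOY_RNA_SEQ[i], chain = "B")
  })
  rna <- do.call(rbind, rna)

  # stacking interfaces: Phe ring 2.0 A from its CA toward the partner
  # nucleotide, nucleotide ring 3.3 A further along the same axis
  pairs <- data.frame(phe = c(10, 13, 30, 34), nt = c(3, 5, 9, 11))
  ring_rows <- list()
  for (i in seq_len(nrow(pairs))) {
    ca_phe <- ca[pairs$phe[i], ]
    axis <- nt_pos[pairs$nt[i], ] - ca_phe
    axis <- axis / sqrt(sum(axis^2))
    phe_ctr <- ca_phe + 2.0 * axis
    nt_ctr <- phe_ctr + 3.3 * axis
    hex_p <- .hexagon(phe_ctr, axis, .RING_ATOMS$PHE)
    hex_p$resno <- pairs$phe[i]
    hex_p$resname <- "PHE"
    hex_p$chain <- "A"
    hex_n <- .hexagon(nt_ctr, axis, .RING_ATOMS$A)
    hex_n$resno <- pairs$nt[i]
    hex_n$resname <- .TOY_RNA_SEQ[pairs$nt[i]]
    hex_n$chain <- "B"
    ring_rows[[length(ring_rows) + 1]] <- hex_p
    ring_rows[[length(ring_rows) + 1]] <- hex_n
  }
  # rings of the remaining nucleotides, offset away from the protein
  for (i in setdiff(1:12, pairs$nt)) {
    hex_n <- .hexagon(nt_pos[i, ] + c(0, -1.8, 0), c(0, 1, 0),
                      .RING_ATOMS$A)
    hex_n$resno <- i
    hex_n$resname <- .TOY_RNA_SEQ[i]
    hex_n$chain <- "B"
    ring_rows[[length(ring_rows) + 1]] <- hex_n
  }

  # salt bridges: guanidinium N and carboxylate O pseudo-atoms placed on
  # the inter-domain axis so the closest N-O distance is 3.6 A
  bridges <- data.frame(arg = c(15, 14), asp = c(25, 26))
  side_rows <- list()
  for (i in seq_len(nrow(bridges))) {
    ca_r <- ca[bridges$arg[i], ]
    ca_d <- ca[bridges$asp[i], ]
    u <- ca_d - ca_r
    d <- sqrt(sum(u^2))
    u <- u / d
    arm <- d / 2 - 1.8
    ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- ref - sum(ref * u) * u
    e1 <- e1 / sqrt(sum(e1^2))
    npos <- ca_r + arm * u
    opos <- ca_d - arm * u
    side_rows[[length(side_rows) + 1]] <- data.frame(
      resno = bridges$arg[i],
      name = c("NE", "NH1", "NH2"),
      x = c(npos[1], npos[1] + 0.8 * e1[1], npos[1] - 0.8 * e1[1]),
      y = c(npos[2], npos[2] + 0.8 * e1[2], npos[2] - 0.8 * e1[2]),
      z = c(npos[3], npos[3] + 0.8 * e1[3], npos[3] - 0.8 * e1[3]),
      resname = "ARG", chain = "A")
    side_rows[[length(side_rows) + 1]] <- data.frame(
      resno = bridges$asp[i],
      name = c("OD1", "OD2"),
      x = c(opos[1] + 0.4 * e1[1], opos[1] - 0.4 * e1[1]),
      y = c(opos[2] + 0.4 * e1[2], opos[2] - 0.4 * e1[2]),
      z = c(opos[3] + 0.4 * e1[3], opos[3] - 0.4 * e1[3]),
      resname = "ASP", chain = "A")
  }

  atoms <- rbind(prot,
                 do.call(rbind, side_rows),
                 rna,
                 do.call(rbind, ring_rows))
  atoms$elem <- .elem_from_name(atoms$name)
  atoms <- atoms[order(match(atoms$chain, c("A", "B")), atoms$resno,
                       atoms$name), ]
  atoms$serial <- seq_len(nrow(atoms))
  truth <- atomic_model(atoms[c("serial", "name", "elem", "resno",
                                "resname", "chain", "x", "y", "z")],
                        linker = c(17, 24))
  truth$ss_segments <- data.frame(chain = "A", from = c(1, 25),
                                  to = c(16, 40))

  partition <- rigid_partition(
    groups = list(
      dom1 = data.frame(chain = c(rep("A", 16), rep("B", 6)),
                        resno = c(1:16, 1:6)),
      dom2 = data.frame(chain = c(rep("A", 16), rep("B", 6)),
                        resno = c(25:40, 7:12))
    ),
    flexible = data.frame(resno = rep(17:24, each = 2),
                          dihedral = rep(c("phi", "psi"), 8)),
    protein_chain = "A", linker = c(17, 24), model = truth)

  restraints <- restraint_set(
    interface = data.frame(chain1 = "A", resno1 = pairs$phe,
                           chain2 = "B", resno2 = pairs$nt),
    salt_bridges = data.frame(chain_arg = "A", resno_arg = bridges$arg,
                              chain_asp = "A", resno_asp = bridges$asp),
    ss_reference = truth,
    ss_segments = list("A:1-16", "A:25-40"))

  # perturbed start: random linker torsions, scaled by bisection into the
  # requested RMSD band
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  })
  set.seed(split_seed(seed, "toy"))
  direction <- stats::rnorm(nrow(partition$flexible))
  perturbed_at <- function(scale) {
    apply_move(truth, partition, torsions = data.frame(
      resno = partition$flexible$resno,
      dihedral = partition$flexible$dihedral,
      delta_deg = scale * direction))
  }
  # fast superposed backbone RMSD for the bisection (atom order shared)
  bb <- mapply(function(ch, nm) nm %in% .backbone_names(truth$roles[ch]),
               truth$atoms$chain, truth$atoms$name)
  ref <- coords(truth)[bb, ]
  refc <- sweep(ref, 2, colMeans(ref))
  fast_rmsd <- function(m) .kabsch_rmsd(coords(m)[bb, ], refc)
  lo <- 0; hi <- 60
  while (fast_rmsd(perturbed_at(hi)) < perturbation_rmsd && hi < 400) {
    hi <- hi * 2
  }
  for (it in 1:30) {
    mid <- (lo + hi) / 2
    if (fast_rmsd(perturbed_at(mid)) < perturbation_rmsd) {
      lo <- mid
    } else {
      hi <- mid
    }
  }
  start <- perturbed_at((lo + hi) / 2)
  realized <- backbone_rmsd(start, truth)

  manifest <- list(
    seed = seed,
    n_atoms = nrow(truth$atoms),
    n_atoms_per_chain = table(truth$atoms$chain),
    rna_sequence = paste(.TOY_RNA_SEQ, collapse = ""),
    requested_rmsd = perturbation_rmsd,
    realized_rmsd = realized,
    interface_pairs = pairs,
    salt_bridges = bridges
  )
  list(truth = truth, start = start, partition = partition,
       restraints = restraints, manifest = manifest)
}

# --- observable simulators ------------------------------------------------

# Run `expr` under a temporary RNG state seeded from (seed, stream).
.with_stream <- function(seed, stream, expr) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  })
  set.seed(split_seed(seed, stream))
  force(expr)
}

#' Simulate a noisy SAXS curve
#'
#' Debye forward intensity of the model plus relative Gaussian noise; the
#' sigma column records the nominal noise level.
#'
#' @param model an `AtomicModel`.
#' @param q momentum-transfer grid (1/A).
#' @param noise_frac relative Gaussian noise level (0 = exact forward
#'   curve).
#' @param seed integer seed.
#' @return a `ScatteringCurve` with sigma.
#' @export
simulate_saxs <- function(model, q, noise_frac = 0.02, seed = 1) {
  truth <- debye_intensity(model, q)
  sigma <- pmax(noise_frac * abs(truth$I), .Machine$double.eps)
  I <- if (noise_frac > 0) {
    .with_stream(seed, "saxs", truth$I + stats::rnorm(length(q), 0, sigma))
  } else {
    truth$I
  }
  scattering_curve(q, I, sigma)
}

#' Simulate residual dipolar couplings
#'
#' Back-calculates couplings from a known alignment tensor for the amide
#' N-H bonds of the protein chain (or an explicit bond table) and adds
#' Gaussian noise.
#'
#' @param model an `AtomicModel`.
#' @param tensor 3x3 traceless Saupe matrix of the ground-truth alignment
#'   (default axial, Da = 4 Hz along z).
#' @param bonds optional `RDCSet`-like table naming the bonds; default all
#'   protein residues with N and H atoms.
#' @param noise_hz Gaussian noise (Hz).
#' @param seed integer seed.
#' @return an `RDCSet` (sigma = `noise_hz` when positive).
#' @export
simulate_rdc <- function(model, tensor = diag(c(-4, -4, 8)), bonds = NULL,
                         noise_hz = 0, seed = 1) {
  if (is.null(bonds)) {
    prot <- names(model$roles)[model$roles == "protein"][1]
    a <- model$atoms
    res <- sort(unique(a$resno[a$chain == prot]))
    has <- vapply(res, function(r) {
      all(c("N", "H") %in% a$name[a$chain == prot & a$resno == r])
    }, logical(1))
    bonds <- rdc_set(prot, res[has], "N", "H", D = 0)
  }
  D <- back_calc_rdc(model, bonds, tensor)
  if (noise_hz > 0) {
    D <- .with_stream(seed, "rdc",
                      D + stats::rnorm(length(D), 0, noise_hz))
  }
  rdc_set(bonds$chain, bonds$resno, bonds$atom1, bonds$atom2, D,
          sigma = if (noise_hz > 0) noise_hz else NULL)
}

#' Simulate an ITC titration
#'
#' Forward one-site heats for a named preset (see [itc_presets()]) or
#' explicit parameters, plus per-injection Gaussian noise with standard
#' deviation `noise_frac` times each heat's magnitude (plus a 0.1%-of-peak
#' constant floor, emulating baseline-integration error). Default design
#' and concentrations follow the published protocol: 26 injections of
#' 1.5 uL (or 20 of 2 uL) into a 200 uL cell at 25 C.
#'
#' @param preset preset label, or `NULL` when `N`, `K_D`, `dH` are given.
#' @param design `"26x1.5"` or `"20x2"`.
#' @param noise_frac relative Gaussian noise per injection heat.
#' @param seed integer seed.
#' @param N,K_D,dH explicit parameters (K_D molar, dH cal/mol).
#' @param cell_conc_uM,syringe_conc_uM,cell_volume_uL experiment geometry.
#'   Concentrations default to the published protocol ranges, chosen by
#'   affinity as in the protocol: the low ends (20 uM cell, 300 uM
#'   syringe) for sub-100 nM binders, mid-range (60 uM, 650 uM) otherwise.
#' @return a `TitrationExperiment` with heats and attribute `truth`.
#' @export
simulate_itc <- function(preset = "UP1+12-mer", design = "26x1.5",
                         noise_frac = 0, seed = 1, N = NULL, K_D = NULL,
                         dH = NULL, cell_conc_uM = NULL,
                         syringe_conc_uM = NULL, cell_volume_uL = 200) {
  if (!is.null(preset)) {
    tab <- itc_presets()
    row <- tab[tab$label == preset, ]
    if (nrow(row) != 1) {
      stop("unknown preset '", preset, "'; available: ",
           paste(tab$label, collapse = ", "))
    }
    N <- row$N
    K_D <- row$K_D_uM * 1e-6
    dH <- row$dH_cal
  }
  if (is.null(cell_conc_uM)) {
    cell_conc_uM <- if (K_D < 1e-7) 20 else 60
  }
  if (is.null(syringe_conc_uM)) {
    syringe_conc_uM <- if (K_D < 1e-7) 300 else 650
  }
  inj <- switch(design,
                "26x1.5" = rep(1.5, 26),
                "20x2" = rep(2, 20),
                stop("unknown design '", design, "'"))
  expt <- titration_experiment(cell_volume_uL, cell_conc_uM,
                               syringe_conc_uM, inj)
  q <- one_site_heats(N, K_D, dH, expt)
  if (noise_frac > 0) {
    sg <- noise_frac * abs(q) + 0.001 * max(abs(q))
    q <- .with_stream(seed, "itc",
                      q + stats::rnorm(length(q), 0, sg))
    expt$sigma_ucal <- sg
  }
  expt$heats_ucal <- q
  attr(expt, "truth") <- list(N = N, K_D = K_D, dH = dH,
                              noise_frac = noise_frac,
                              cell_conc_uM = cell_conc_uM,
                              syringe_conc_uM = syringe_conc_uM)
  expt
}

#' Simulate NMR observables from a model
#'
#' Generates (i) a PRE intensity-ratio profile for a nitroxide label on a
#' given residue, from the label-to-amide-proton distances of the model;
#' (ii) a per-residue relaxation series of exponential decays; and (iii)
#' free/bound shift tables whose perturbations mark the RNA-facing
#' residues.
#'
#' @param model an `AtomicModel` (PRE distances are measured from the
#'   label residue's CA to each residue's amide H).
#' @param label_resno spin-label residue.
#' @param tau_c,field_MHz PRE constant parameters (see [pre_constant()]).
#' @param R2_dia,t_total diamagnetic rate (1/s) and evolution time (s).
#' @param T1_ms ground-truth relaxation times (recycled over residues).
#' @param delays_ms relaxation delays; the default is the published
#'   12-delay longitudinal series with two duplicates appended.
#' @param interface_resno residues given a bound-state shift perturbation.
#' @param noise relative Gaussian noise on ratios/intensities/shifts.
#' @param seed integer seed.
#' @return list with `pre` (`PRESeries`), `relaxation`
#'   (`RelaxationSeries`), `shifts_free`, `shifts_bound` (`ShiftTable`s)
#'   and `truth` (distances, T1, CSP pattern).
#' @export
simulate_nmr <- function(model, label_resno = 12, tau_c = 5e-9,
                         field_MHz = 600, R2_dia = 20, t_total = 0.01,
                         T1_ms = 500,
                         delays_ms = c(21.6, 86.4, 162, 248.4, 345.6, 432,
                                       518.4, 669.6, 885.6, 1144.8, 1404,
                                       1782, 21.6, 432),
                         interface_resno = c(10, 13, 30, 34),
                         noise = 0, seed = 1) {
  prot <- names(model$roles)[model$roles == "protein"][1]
  a <- model$atoms
  res <- sort(unique(a$resno[a$chain == prot]))
  res <- res[vapply(res, function(r) {
    "H" %in% a$name[a$chain == prot & a$resno == r]
  }, logical(1))]
  lab_idx <- .atom_idx(model, chain = prot, resno = label_resno,
                       names = "CA")
  if (length(lab_idx) != 1) stop("label residue has no CA atom")
  lab <- coords(model, lab_idx)[1, ]
  h_xyz <- t(vapply(res, function(r) {
    coords(model, .atom_idx(model, chain = prot, resno = r,
                            names = "H"))[1, ]
  }, numeric(3)))
  dist_A <- sqrt(rowSums(sweep(h_xyz, 2, lab)^2))
  K <- pre_constant(tau_c, field_MHz)
  gamma2 <- K / dist_A^6
  ratio <- R2_dia * exp(-gamma2 * t_total) / (R2_dia + gamma2)

  T1 <- rep_len(T1_ms, length(res))
  I <- outer(seq_along(res), seq_along(delays_ms),
             function(i, j) exp(-delays_ms[j] / T1[i]))

  csp_truth <- 0.02 + ifelse(res %in% interface_resno, 0.25, 0)
  H_free <- 8 + 0.3 * sin(res)
  N_free <- 118 + 4 * cos(res)

  out <- .with_stream(seed, "nmr", {
    nr <- if (noise > 0) stats::rnorm(length(ratio), 0, noise) else 0
    ratio_n <- pmin(pmax(ratio + nr, 0), 1.2)
    I_n <- I * (1 + if (noise > 0) {
      matrix(stats::rnorm(length(I), 0, noise), nrow(I))
    } else 0)
    I_n[I_n <= 0] <- .Machine$double.eps
    dH <- csp_truth / sqrt(2)
    dN <- csp_truth / (sqrt(2) * 0.2)
    jit <- function(x) {
      if (noise > 0) x + stats::rnorm(length(x), 0, noise) else x
    }
    list(ratio = ratio_n, I = I_n,
         H_bound = jit(H_free + dH), N_bound = jit(N_free + dN))
  })
  list(
    pre = pre_series(res, out$ratio, label_resno, R2_dia, t_total),
    relaxation = relaxation_series(delays_ms, out$I, resno = res),
    shifts_free = shift_table(res, H_free, N_free),
    shifts_bound = shift_table(res, out$H_bound, out$N_bound),
    truth = list(distances_A = dist_A, T1_ms = T1, csp = csp_truth,
                 resno = res)
  )
}
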