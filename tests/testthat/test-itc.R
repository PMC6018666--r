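# One-site ITC: forward isotherm, fitting, derived thermodynamics and the
# published-table consistency checks.

test_that("stoichiometric and zero-enthalpy limits are exact", {
  expt <- titration_experiment(cell_volume_uL = 200, cell_conc_uM = 20,
                               syringe_conc_uM = 300,
                               injection_volumes_uL = rep(1.5, 26))
  # K_D -> 0: every pre-equivalence injection delivers dH per mole
  # injected; post-equivalence heats vanish
  q <- one_site_heats(N = 1, K_D = 0, dH = -3e4, expt)
  inj_mol <- 1.5e-6 * 300e-6
  expect_equal(q[2] * 1e-6 / inj_mol, -3e4, tolerance = 0.02)
  # post-equivalence heats vanish (to the second-order displaced-volume
  # residual of the overfill convention)
  expect_lt(abs(q[26]), abs(q[1]) * 1e-3)
  # dH = 0 gives no heat at all
  expect_equal(one_site_heats(1, 1e-8, 0, expt), rep(0, 26))
  expect_error(one_site_heats(-1, 1e-8, -3e4, expt), "N must be")
})

test_that("closed-form bound fraction matches a bisection equilibrium solver", {
  expt <- titration_experiment(cell_volume_uL = 200, cell_conc_uM = 50,
                               syringe_conc_uM = 500,
                               injection_volumes_uL = rep(2, 20))
  N <- 0.9; K_D <- 2e-6; dH <- -2.5e4
  q_closed <- one_site_heats(N, K_D, dH, expt)
  # independent oracle: track concentrations identically but solve the
  # binding equilibrium by bisection on the free-titrant concentration
  V0 <- 200e-6; M <- 50e-6; X <- 0; Qprev <- 0
  q_oracle <- numeric(20)
  for (i in 1:20) {
    f <- 2e-6 / V0
    M <- M * (1 - f)
    X <- X * (1 - f) + 500e-6 * f
    g <- function(xf) xf + N * M * xf / (K_D + xf) - X
    xf <- uniroot(g, c(0, X), tol = 1e-16)$root
    bound <- N * M * xf / (K_D + xf)
    Q <- V0 * bound * dH * 1e6
    q_oracle[i] <- Q - Qprev + f * (Q + Qprev) / 2
    Qprev <- Q
  }
  expect_equal(q_closed, q_oracle, tolerance = 1e-8)
})

test_that("noise-free data are recovered exactly and designs agree", {
  truth <- list(N = 1.01, K_D = 15.5e-9, dH = -3.81e4)
  e26 <- simulate_itc("UP1+12-mer", design = "26x1.5", noise_frac = 0)
  f26 <- fit_one_site(e26)
  expect_equal(f26$N, truth$N, tolerance = 1e-6)
  expect_equal(f26$K_D, truth$K_D, tolerance = 1e-6)
  expect_equal(f26$dH, truth$dH, tolerance = 1e-6)
  # derived quantities satisfy their defining identities
  expect_equal(f26$dG, 1.987 * 298.15 * log(f26$K_D), tolerance = 1e-9)
  expect_equal(f26$dS, (f26$dH - f26$dG) / 298.15, tolerance = 1e-6)

  e20 <- simulate_itc("UP1+12-mer", design = "20x2", noise_frac = 0)
  f20 <- fit_one_site(e20)
  expect_equal(f20$K_D, truth$K_D, tolerance = 1e-6)
})

test_that("preset parameters are recovered within 5% at 0.5% noise", {
  truth <- list(N = 1.01, K_D = 15.5e-9, dH = -3.81e4)
  # protocol: three replicate titrations, fitted jointly via their mean
  reps <- sapply(1:3, function(r) {
    simulate_itc("UP1+12-mer", noise_frac = 0.005, seed = 400 + r)$heats_ucal
  })
  e <- simulate_itc("UP1+12-mer", noise_frac = 0.005, seed = 401)
  e$heats_ucal <- rowMeans(reps)
  e$sigma_ucal <- e$sigma_ucal / sqrt(3)
  fit <- fit_one_site(e)
  expect_lt(abs(fit$N - truth$N) / truth$N, 0.05)
  expect_lt(abs(fit$K_D - truth$K_D) / truth$K_D, 0.05)
  expect_lt(abs(fit$dH - truth$dH) / abs(truth$dH), 0.05)
})

test_that("degenerate titrations are rejected with clear errors", {
  expt <- titration_experiment(cell_volume_uL = 200, cell_conc_uM = 20,
                               syringe_conc_uM = 300,
                               injection_volumes_uL = rep(1.5, 26),
                               heats_ucal = rep(0, 26))
  expect_error(fit_one_site(expt), "no binding signal")
  short <- titration_experiment(cell_volume_uL = 200, cell_conc_uM = 20,
                                syringe_conc_uM = 300,
                                injection_volumes_uL = rep(1.5, 5),
                                heats_ucal = rnorm(5))
  expect_error(fit_one_site(short), "at least 10")
  expect_error(titration_experiment(200, -1, 300, rep(1.5, 26)),
               "positive")
})

test_that("K_D from enthalpy and entropy inverts the thermodynamics", {
  R <- 1.987; T0 <- 298.15
  expect_equal(kd_from_enthalpy_entropy(-R * T0 * log(1e6), 0, T0), 1e-6,
               tolerance = 1e-12)
  # tabulated row: recomputed K_D within 10% of the printed value
  kd <- kd_from_enthalpy_entropy(-3.81e4, -92.0, T0)
  expect_equal(kd * 1e6, 0.0155, tolerance = 0.10)
  # exp/log round trip
  set.seed(21)
  for (k in 1:20) {
    dH <- rnorm(1, -3e4, 1e4); dS <- rnorm(1, -80, 30)
    kd <- kd_from_enthalpy_entropy(dH, dS, T0)
    expect_equal(R * T0 * log(kd), dH - T0 * dS, tolerance = 1e-8)
  }
})

test_that("fold changes reproduce the published affinity ratios", {
  expect_equal(fold_change(2, 2), 1)
  tab <- itc_presets()
  kd <- function(lbl) tab$K_D_uM[tab$label == lbl]
  expect_gte(fold_change(kd("UP1+7-mer"), kd("UP1+12-mer")), 200)
  expect_equal(fold_change(kd("UP1+12-mer-mut1"), kd("UP1+12-mer")), 10,
               tolerance = 0.15)
  expect_equal(fold_change(kd("UP1+12-mer-mut2"), kd("UP1+12-mer")), 20,
               tolerance = 0.15)
  expect_error(fold_change(-1, 2), "positive")
})

test_that("every tabulated row is thermodynamically self-consistent", {
  cons <- itc_consistency()
  # residual disagreement reflects rounding of the printed dH and dS; the
  # row with dS printed as -101 (3 significant figures, so +-0.5
  # cal/mol/K ~ +-25% on K_D) is the one outlier beyond 15%
  expect_gte(sum(abs(cons$ratio - 1) < 0.15), nrow(cons) - 1)
  expect_true(all(abs(cons$ratio - 1) < 0.30))
})

test_that("cumulative heat is monotone and stable under re-binning", {
  expt26 <- titration_experiment(cell_volume_uL = 200, cell_conc_uM = 20,
                                 syringe_conc_uM = 300,
                                 injection_volumes_uL = rep(1.5, 26))
  q <- one_site_heats(1, 1e-8, -3e4, expt26)
  # negative dH: cumulative heat decreases (allowing the second-order
  # displaced-volume residual after saturation)
  expect_true(all(diff(cumsum(q)) <= abs(q[1]) * 1e-3))
  # same total titrant in half as many double-volume injections
  expt13 <- titration_experiment(cell_volume_uL = 200, cell_conc_uM = 20,
                                 syringe_conc_uM = 300,
                                 injection_volumes_uL = rep(3, 13))
  q13 <- one_site_heats(1, 1e-8, -3e4, expt13)
  expect_equal(sum(q13), sum(q), tolerance = 1e-3)
})

test_that("titration CSVs round-trip", {
  e <- simulate_itc("UP1+7-mer", noise_frac = 0.005, seed = 30)
  p <- tempfile(fileext = ".csv")
  write_titration(e, p)
  back <- read_titration(p, cell_conc_uM = e$cell_conc_uM,
                         syringe_conc_uM = e$syringe_conc_uM)
  expect_equal(back$heats_ucal, e$heats_ucal, tolerance = 1e-8)
})
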